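`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a fixed RNG state, restoring the caller's state afterwards.
## Mersenne-Twister + Rejection sampling pinned so samples are reproducible
## across R versions >= 3.6.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

## All parent configurations in canonical row-major order: the FIRST parent
## varies slowest, the last fastest.  Returns a data.frame (1 row, 0 cols
## when there are no parents) whose row index matches rowMajorIndex().
parentConfigs <- function(levelsList) {
  k <- length(levelsList)
  if (k == 0L) return(as.data.frame(matrix(nrow = 1L, ncol = 0L)))
  g <- expand.grid(rev(levelsList), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_len(k)), drop = FALSE]
  names(g) <- names(levelsList)
  rownames(g) <- NULL
  g
}

## Row-major configuration index (first column most significant) from a
## matrix/data.frame of 1-based level indices; vectorized over rows.
rowMajorIndex <- function(idx, card) {
  idx <- as.matrix(idx)
  if (ncol(idx) == 0L) return(rep(1L, nrow(idx)))
  out <- rep(0, nrow(idx))
  for (j in seq_along(card)) out <- out * card[j] + (idx[, j] - 1)
  as.integer(out + 1)
}

## Configuration index for a data.frame of level labels (columns = parents in
## declared order).  Rows with an NA level yield NA.
configIndex <- function(levelsList, df) {
  n <- nrow(df)
  if (length(levelsList) == 0L) return(rep(1L, n))
  idx <- matrix(NA_integer_, n, length(levelsList))
  for (j in seq_along(levelsList))
    idx[, j] <- match(df[[names(levelsList)[j]]], levelsList[[j]])
  rowMajorIndex(idx, lengths(levelsList))
}

## Column-major (native R array) linear index from a matrix of 1-based
## per-dimension indices.
linearIndex <- function(card, idx) {
  if (length(card) == 0L) return(rep(1L, nrow(idx)))
  stride <- cumprod(c(1, card[-length(card)]))
  as.integer(1 + (as.matrix(idx) - 1) %*% stride)
}

## Label a parent configuration for error messages: "A=a1, B=b2".
configLabel <- function(config)
  paste(names(config), unlist(config), sep = "=", collapse = ", ")

stopf <- function(...) stop(sprintf(...), call. = FALSE)

isString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

assertCount <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x))
    stopf("%s must be a single nonnegative integer", what)
  as.integer(x)
}
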