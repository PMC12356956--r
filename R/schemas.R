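## Fixture networks for demos and tests.  Both schemas mimic the SHAPE of
## real reporting data (a crash-report file; a health survey) but every CPT
## value is invented and chosen only to be plausible and strictly monotone in
## the obvious directions.  They are synthetic stand-ins, not fitted to any
## dataset.

#' Synthetic crash-domain network
#'
#' A six-variable crash-report-like network: `weather` {clear, rain,
#' snowfall}, `light` {day, dark}, `physical_condition` {normal, fatigued,
#' dui}, `surface` {dry, wet, snow} (child of weather), `safety_equipment`
#' {belt, none}, and `severity` {damage, injury, fatal} (child of physical
#' condition, surface and safety equipment).  The fatal-severity probability
#' is strictly increasing in each risk direction (normal < fatigued < dui;
#' dry < wet < snow; belt < none), so posterior checks have a known sign.
#'
#' All probabilities are invented plausible values; the network is a
#' documented synthetic fixture, not fitted to crash data.
#'
#' @return a valid [DiscreteNetwork-class].
#' @export
crashSchema <- function() {
  mp <- c(normal = 1, fatigued = 2, dui = 4)
  ms <- c(dry = 1, wet = 1.8, snow = 3)
  mb <- c(belt = 1, none = 8)
  variables <- list(
    weather = c("clear", "rain", "snowfall"),
    light = c("day", "dark"),
    physical_condition = names(mp),
    surface = names(ms),
    safety_equipment = names(mb),
    severity = c("damage", "injury", "fatal"))
  edges <- list(c("weather", "surface"),
                c("physical_condition", "severity"),
                c("surface", "severity"),
                c("safety_equipment", "severity"))
  surface <- rbind(clear = c(0.92, 0.06, 0.02),
                   rain = c(0.15, 0.80, 0.05),
                   snowfall = c(0.10, 0.25, 0.65))
  # severity parents in declaration order: physical_condition, surface,
  # safety_equipment; rows in canonical row-major order
  cfg <- parentConfigs(variables[c("physical_condition", "surface",
                                   "safety_equipment")])
  fatal <- 0.002 * mp[cfg$physical_condition] * ms[cfg$surface] *
    mb[cfg$safety_equipment]
  injury <- pmin(0.45, 0.08 * sqrt(mp[cfg$physical_condition] *
                                   ms[cfg$surface]) *
                         ifelse(cfg$safety_equipment == "none", 1.5, 1))
  severity <- cbind(1 - injury - fatal, injury, fatal)
  discreteNetwork(variables, edges, cpts = list(
    weather = c(0.70, 0.22, 0.08),
    light = c(0.65, 0.35),
    physical_condition = c(0.90, 0.07, 0.03),
    surface = unname(surface),
    safety_equipment = c(0.90, 0.10),
    severity = unname(severity)))
}

#' Synthetic health-survey network
#'
#' A four-variable health-survey-like network: `age_band` {18_39, 40_59,
#' 60_plus}, `bmi_band` {normal, overweight, obese} (child of age),
#' `activity` {active, inactive}, and a binary `outcome` {no_diabetes,
#' diabetes} whose probability increases with age band, BMI band and
#' inactivity.  Supports three-factor scenarios out of the box.
#'
#' As with [crashSchema()], every value is an invented plausible number; the
#' network is a synthetic fixture, not fitted to survey data.
#'
#' @return a valid [DiscreteNetwork-class].
#' @export
healthSchema <- function() {
  ma <- c("18_39" = 1, "40_59" = 2, "60_plus" = 3.2)
  mbmi <- c(normal = 1, overweight = 2.2, obese = 4)
  mact <- c(active = 1, inactive = 1.7)
  variables <- list(
    age_band = names(ma),
    bmi_band = names(mbmi),
    activity = names(mact),
    outcome = c("no_diabetes", "diabetes"))
  edges <- list(c("age_band", "bmi_band"),
                c("age_band", "outcome"),
                c("bmi_band", "outcome"),
                c("activity", "outcome"))
  bmi <- rbind(c(0.45, 0.35, 0.20),
               c(0.30, 0.40, 0.30),
               c(0.25, 0.45, 0.30))
  cfg <- parentConfigs(variables[c("age_band", "bmi_band", "activity")])
  p <- pmin(0.85, 0.03 * ma[cfg$age_band] * mbmi[cfg$bmi_band] *
                    mact[cfg$activity])
  discreteNetwork(variables, edges, cpts = list(
    age_band = c(0.35, 0.35, 0.30),
    bmi_band = bmi,
    activity = c(0.55, 0.45),
    outcome = matrix(unname(c(1 - p, p)), ncol = 2L)))
}
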