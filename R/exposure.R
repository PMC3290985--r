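#' Screening exposure assumptions
#'
#' Conservative defaults for chronic drinking-water screening: 2 L of water
#' consumed per day, 100% oral absorption and a 60 kg body weight. Doses are
#' computed as `concentration * water_intake * absorption_fraction /
#' body_weight`, so halving the body weight doubles every hazard quotient.
#'
#' @param water_intake Daily water consumption, L/day.
#' @param body_weight Body weight, kg.
#' @param absorption_fraction Oral absorption fraction in `(0, 1]`.
#' @return An object of class `exposure_assumptions`.
#' @export
exposure_assumptions <- function(water_intake = 2, body_weight = 60,
                                 absorption_fraction = 1) {
  check_number(water_intake, "water_intake", lower = 0, allow_zero = FALSE)
  check_number(body_weight, "body_weight", lower = 0, allow_zero = FALSE)
  check_number(absorption_fraction, "absorption_fraction", lower = 0, allow_zero = FALSE)
  if (absorption_fraction > 1) {
    abort_domain("`absorption_fraction` must lie in (0, 1].")
  }
  structure(
    list(
      water_intake = water_intake,
      body_weight = body_weight,
      absorption_fraction = absorption_fraction
    ),
    class = "exposure_assumptions"
  )
}

#' @export
print.exposure_assumptions <- function(x, ...) {
  cat(sprintf(
    "<exposure_assumptions> %g L/day, %g kg, absorption %g\n",
    x$water_intake, x$body_weight, x$absorption_fraction
  ))
  invisible(x)
}

#' Impute a concentration for a non-detect
#'
#' Two treatments of analytes measured but not detected: `"case1"` sets the
#' concentration to zero (non-detects assumed absent) and `"case2"` to the
#' detection limit divided by `sqrt(2)`, the usual substitution for
#' lognormally distributed environmental data. Comparing results under both
#' cases bounds the influence of censored observations on a mixture's
#' hazard index.
#'
#' @param detection_limit Detection limit, mg/L (non-negative).
#' @param nd_case `"case1"` or `"case2"`.
#' @return Imputed concentration, mg/L.
#' @examples
#' impute_nd(1, "case2") # 1/sqrt(2)
#' @export
impute_nd <- function(detection_limit, nd_case) {
  check_number(detection_limit, "detection_limit", lower = 0)
  nd_case <- match_nd_case(nd_case)
  ifelse(nd_case == "case1", 0, detection_limit / sqrt(2))
}

#' Convert a water concentration to a chronic daily dose
#'
#' @param concentration Concentration in water, mg/L (non-negative).
#' @param assumptions An [exposure_assumptions()] object.
#' @return Dose, mg/kg/day.
#' @examples
#' concentration_to_dose(30) # 1 mg/kg/day under the defaults
#' @export
concentration_to_dose <- function(concentration, assumptions = exposure_assumptions()) {
  check_number(concentration, "concentration", lower = 0)
  stopifnot(inherits(assumptions, "exposure_assumptions"))
  concentration * assumptions$water_intake * assumptions$absorption_fraction /
    assumptions$body_weight
}

#' Hazard quotient of a single chemical
#'
#' The hazard quotient is the dose divided by the chemical's permitted dose:
#' a toxicity-normalised measure of exposure. HQ = 1 means the exposure
#' exactly reaches the protective dose.
#'
#' @param dose Dose, mg/kg/day (non-negative).
#' @param pd Permitted dose, mg/kg/day (strictly positive).
#' @return Unitless hazard quotient.
#' @export
hazard_quotient <- function(dose, pd) {
  check_number(dose, "dose", lower = 0)
  check_number(pd, "pd", lower = 0, allow_zero = FALSE)
  dose / pd
}

#' Per-chemical hazard quotients for a table of measurements
#'
#' Takes a long sample-by-analyte measurement table and returns one HQ row
#' per measured analyte that resolves to a permitted dose. Detected analytes
#' use their reported concentration (even when reported below the detection
#' limit); non-detects are imputed according to `nd_case`. Analytes with no
#' PD (directly or through a parent compound) contribute nothing and are
#' dropped; under case 2, a non-detect with no recorded detection limit
#' cannot be imputed and is dropped with a warning.
#'
#' @param samples Data frame with columns `sample_id`, `analyte`, `measured`
#'   (logical), `detected` (logical), `concentration_mg_L` (present iff
#'   detected) and `detection_limit_mg_L` (present iff measured). See
#'   [read_samples()] for the CSV dialect.
#' @param registry A `pd_registry`.
#' @param assumptions An [exposure_assumptions()] object.
#' @param nd_case `"case1"` or `"case2"` (scalar).
#' @return A tibble with columns `sample_id`, `analyte`, `detected`,
#'   `concentration_used`, `dose`, `pd`, `hq` and `nd_case`.
#' @export
compute_hq <- function(samples, registry, assumptions = exposure_assumptions(),
                       nd_case = "case2") {
  samples <- validate_samples(samples)
  stopifnot(inherits(registry, "pd_registry"), length(nd_case) == 1)
  nd_case <- match_nd_case(nd_case)

  x <- dplyr::filter(samples, .data$measured)
  pd_tbl <- lookup_pd(registry, unique(x$analyte))
  x <- dplyr::left_join(
    x,
    dplyr::select(pd_tbl, analyte = "chemical", "pd"),
    by = "analyte"
  )
  x <- dplyr::filter(x, !is.na(.data$pd))

  no_dl <- !x$detected & (is.na(x$detection_limit_mg_L) | x$detection_limit_mg_L <= 0)
  if (nd_case == "case2" && any(no_dl)) {
    warn(sprintf(
      "%d non-detect measurement(s) lack a detection limit and are treated as unmeasured under case2.",
      sum(no_dl)
    ), class = "mcrscreen_missing_dl")
    x <- x[!no_dl, , drop = FALSE]
  }

  imputed <- if (nd_case == "case1") {
    rep(0, nrow(x))
  } else {
    dplyr::coalesce(x$detection_limit_mg_L, 0) / sqrt(2)
  }
  conc <- dplyr::if_else(x$detected, x$concentration_mg_L, imputed)
  conc <- as.numeric(conc)
  dose <- concentration_to_dose(conc, assumptions)
  tibble(
    sample_id = x$sample_id,
    analyte = x$analyte,
    detected = x$detected,
    concentration_used = conc,
    dose = dose,
    pd = x$pd,
    hq = dose / x$pd,
    nd_case = nd_case
  )
}

validate_samples <- function(samples) {
  samples <- as_tibble(samples)
  required <- c(
    "sample_id", "analyte", "measured", "detected",
    "concentration_mg_L", "detection_limit_mg_L"
  )
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "Sample table is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  samples$measured <- as.logical(samples$measured)
  samples$detected <- as.logical(samples$detected)
  if (any(samples$detected & !samples$measured)) {
    abort_validation("`detected` implies `measured`.")
  }
  if (any(samples$detected & (is.na(samples$concentration_mg_L) |
    samples$concentration_mg_L < 0))) {
    abort_validation("Detected measurements need a non-negative concentration.")
  }
  samples
}
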