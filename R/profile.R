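#' Exposure profile
#'
#' The parameter set of the average-daily-intake equation
#' `ADI = Mc * IR * CF * EF * ED / (BW * ATn)`:
#' ingestion rate IR (g/day), exposure frequency EF (day/year), exposure
#' duration ED (years), body weight BW (kg), averaging time ATn (days)
#' and the unit conversion factor CF (10^-3 converts IR grams to kg).
#' ED is held in years and ATn in days, matching the convention the
#' intake equation is evaluated under.
#'
#' @param IR ingestion rate, g/day.
#' @param EF exposure frequency, day/year (<= 365).
#' @param ED exposure duration, years.
#' @param BW body weight, kg.
#' @param ATn averaging time, days (>= ED in days).
#' @param CF conversion factor (dimensionless scale on IR).
#' @param Mc_convention rule converting an ethanol % v/v level to Mc in
#'   mg/kg of drink: `"mass_fraction"` (abv% -> abv/100 * 1e6 mg/kg) or
#'   `"table2"` (abv% -> abv * 100 mg/kg, the literal printed convention).
#' @param density drink density, kg/L, used to convert ug/L metal levels
#'   to mg per kg of drink (default 1: 1 L weighs 1 kg).
#' @return list of class `exposure_profile`.
#' @export
#' @examples
#' acoli_exposure_profile()
exposure_profile <- function(IR, EF, ED, BW, ATn, CF = 1e-3,
                             Mc_convention = c("mass_fraction", "table2"),
                             density = 1) {
  Mc_convention <- match.arg(Mc_convention)
  vals <- c(IR = IR, EF = EF, ED = ED, BW = BW, ATn = ATn, CF = CF,
            density = density)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all exposure parameters must be strictly positive")
  }
  if (EF > 365) stop("EF cannot exceed 365 day/year")
  if (ED * 365 > ATn * (1 + 1e-9)) {
    stop("exposure duration (ED * 365 days) cannot exceed averaging time ATn")
  }
  structure(list(IR = IR, EF = EF, ED = ED, BW = BW, ATn = ATn, CF = CF,
                 Mc_convention = Mc_convention, density = density),
            class = "exposure_profile")
}

#' Adult exposure profile for the Acoli sachet-consumption scenario
#'
#' 2.5 sachets of 100 mL 40% (v/v) spirit per day (IR 78.54 g ethanol/day),
#' 5 drinking days a week (EF 240 day/year), consumption from age 15 over
#' a 58.65-year life expectancy (ED 43.65 years, ATn 21,407 days), 60 kg
#' body weight.
#'
#' @inheritParams exposure_profile
#' @return an [exposure_profile()].
#' @export
acoli_exposure_profile <- function(Mc_convention = "mass_fraction") {
  exposure_profile(IR = 78.54, EF = 240, ED = 43.65, BW = 60, ATn = 21407,
                   CF = 1e-3, Mc_convention = Mc_convention)
}

#' Exposure duration and averaging time in days
#'
#' ED (days) = 365 x (lifespan - onset age); ATn (days) = 365 x lifespan.
#'
#' @param lifespan_years life expectancy, years.
#' @param onset_age age at which exposure begins, years.
#' @return tibble with `ED_years`, `ED_days`, `ATn_days`.
#' @export
#' @examples
#' exposure_times(58.65, 15) # ED 15,932 d; ATn 21,407 d
exposure_times <- function(lifespan_years = 58.65, onset_age = 15) {
  stopifnot(lifespan_years > onset_age, onset_age >= 0)
  ed_years <- lifespan_years - onset_age
  tibble::tibble(
    ED_years = ed_years,
    ED_days = 365 * ed_years,
    ATn_days = 365 * lifespan_years
  )
}

#' Read an exposure profile from YAML or JSON
#'
#' Keys are exactly `IR`, `EF`, `ED`, `BW`, `ATn`, `CF` plus optional
#' `Mc_convention` and `density`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return an [exposure_profile()].
#' @export
read_exposure_profile <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  req <- c("IR", "EF", "ED", "BW", "ATn")
  missing_keys <- setdiff(req, names(vals))
  if (length(missing_keys) > 0) {
    stop("profile is missing keys: ", paste(missing_keys, collapse = ", "))
  }
  exposure_profile(
    IR = vals$IR, EF = vals$EF, ED = vals$ED, BW = vals$BW, ATn = vals$ATn,
    CF = vals$CF %||% 1e-3,
    Mc_convention = vals$Mc_convention %||% "mass_fraction",
    density = vals$density %||% 1
  )
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat("<exposure_profile>\n")
  cat(sprintf("  IR  %g g/day   EF %g day/yr   ED %g yr\n", x$IR, x$EF, x$ED))
  cat(sprintf("  BW  %g kg      ATn %g day    CF %g\n", x$BW, x$ATn, x$CF))
  cat(sprintf("  ethanol Mc convention: %s; drink density %g kg/L\n",
              x$Mc_convention, x$density))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ethanol ingestion rate
#'
#' IR = sachets/day x sachet volume (mL) x abv/100 x ethanol density
#' (g/mL), the ethanol mass ingested per day.
#'
#' @param sachets_per_day sachets consumed per day.
#' @param sachet_volume sachet volume, mL.
#' @param abv alcohol by volume, % v/v.
#' @param ethanol_density g/mL (pure ethanol, 0.7854).
#' @return ingestion rate, g/day.
#' @export
#' @examples
#' ingestion_rate(2.5, 100, 40) # 78.54 g/day
ingestion_rate <- function(sachets_per_day, sachet_volume, abv,
                           ethanol_density = 0.7854) {
  stopifnot(sachets_per_day > 0, sachet_volume > 0,
            abv >= 0, abv <= 100, ethanol_density > 0)
  sachets_per_day * sachet_volume * abv / 100 * ethanol_density
}

#' Ethanol concentration as Mc (mg per kg of drink)
#'
#' Under the `mass_fraction` convention a 40% (v/v) drink is treated as
#' 40 g ethanol per 100 g of sample, i.e. Mc = abv/100 x 1e6 mg/kg. The
#' `table2` convention is the literal printed alternative
#' (Mc = abv x 100 mg/kg), retained because it does not reproduce the
#' documented intake arithmetic but may be wanted for comparison.
#'
#' @param abv alcohol by volume, % v/v, in `[0, 100]`.
#' @param convention `"mass_fraction"` (default) or `"table2"`.
#' @return Mc in mg per kg of drink.
#' @export
#' @examples
#' ethanol_mc(40) # 400,000 mg/kg
ethanol_mc <- function(abv, convention = c("mass_fraction", "table2")) {
  convention <- match.arg(convention)
  if (any(abv < 0 | abv > 100)) stop("abv must lie in [0, 100]")
  switch(convention,
    mass_fraction = abv / 100 * 1e6,
    table2 = abv * 100
  )
}

#' Metal level to Mc (mg per kg of drink)
#'
#' Converts a ug/L level to mg per kg of drink, assuming the stated drink
#' density (default 1 kg/L, so ug/L = ug/kg).
#'
#' @param level_ugL metal level, ug/L.
#' @param density drink density, kg/L.
#' @return Mc, mg/kg.
#' @export
metal_mc <- function(level_ugL, density = 1) {
  stopifnot(density > 0)
  level_ugL * 1e-3 / density
}
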