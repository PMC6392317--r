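#' Per-analyte summary statistics
#'
#' Sum, mean, sample SD, minimum, quartiles, maximum and IQR (Q3 - Q1)
#' for each analyte across brands, in the measurement units of the panel
#' (ug/L for metals). Quartiles use linear interpolation between order
#' statistics at position p(n-1)+1 (`stats::quantile` type 7, the
#' "inclusive" spreadsheet convention) unless another type is requested.
#' The `outlier` column applies the mean > 2 x IQR rule.
#'
#' @param panel a [conc_panel()] tibble (levels already on the active
#'   non-detect policy).
#' @param quartile_type `type` passed to [stats::quantile()].
#' @return tibble with one row per analyte: `analyte`, `n`, `sum`, `mean`,
#'   `sd`, `minimum`, `q1`, `median`, `q3`, `maximum`, `iqr`, `outlier`.
#'   The quartile convention is recorded in attribute `quartile_type`.
#' @export
summarize_analytes <- function(panel, quartile_type = 7) {
  if (nrow(panel) == 0) stop("empty input")
  out <- panel |>
    dplyr::filter(.data$unit == "ug/L") |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(summarize_values(.data$level, quartile_type),
                     .groups = "drop")
  attr(out, "quartile_type") <- quartile_type
  out
}

summarize_values <- function(values, quartile_type = 7) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("empty input")
  if (any(values < 0)) stop("values must be non-negative")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = quartile_type))
  tibble::tibble(
    n = n,
    sum = sum(values),
    mean = mean(values),
    sd = if (n == 1) 0 else sd(values),
    minimum = min(values),
    q1 = q[1],
    median = q[2],
    q3 = q[3],
    maximum = max(values),
    iqr = q[3] - q[1],
    outlier = iqr_outlier_flag(mean(values), q[3] - q[1])
  )
}

#' IQR outlier rule
#'
#' An analyte is flagged as an outlier when its mean strictly exceeds
#' twice its interquartile range, the criterion used to single out Cu in
#' spirit contamination panels.
#'
#' @param mean analyte mean, ug/L.
#' @param iqr interquartile range, ug/L (>= 0).
#' @return logical, `TRUE` iff `mean > 2 * iqr`. Vectorized.
#' @export
#' @examples
#' iqr_outlier_flag(1079, 311.5) # TRUE: 1079 > 623
iqr_outlier_flag <- function(mean, iqr) {
  stopifnot(all(iqr >= 0 | is.na(iqr)))
  mean > 2 * iqr
}

#' Composition shares
#'
#' Per-brand analyte shares (percent of the brand's metal total) and
#' grand-total shares (percent of the sum over all brands and metals).
#' Ethanol (% v/v, different unit) is excluded. Brands whose metal total
#' is zero get `NA` shares: "share undefined", not zero.
#'
#' @param panel a [conc_panel()] tibble.
#' @return tibble `brand`, `analyte`, `level`, `brand_share`,
#'   `grand_share` (percent, full precision).
#' @export
composition_shares <- function(panel) {
  metals <- dplyr::filter(panel, .data$unit == "ug/L")
  if (nrow(metals) == 0 || all(metals$level <= 0, na.rm = TRUE)) {
    stop("need at least one positive level")
  }
  grand <- sum(metals$level, na.rm = TRUE)
  metals |>
    dplyr::group_by(.data$brand) |>
    dplyr::mutate(brand_total = sum(.data$level, na.rm = TRUE)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      brand_share = ifelse(.data$brand_total > 0,
                           .data$level / .data$brand_total * 100, NA_real_),
      grand_share = .data$level / grand * 100
    ) |>
    dplyr::select("brand", "analyte", "level", "brand_share", "grand_share")
}

#' Guideline exceedance
#'
#' Percent by which each measured level exceeds a per-analyte guideline
#' limit: `(level - limit)/limit * 100` where the level is above the
#' limit, otherwise the cell is within limit (`pct_above` 0 at equality).
#' Analytes without a limit are skipped with a warning.
#'
#' @param panel a [conc_panel()] tibble.
#' @param limits named numeric vector or tibble (`analyte`, `limit`) of
#'   guideline values, ug/L.
#' @return tibble `brand`, `analyte`, `level`, `limit`, `pct_above`,
#'   `within_limit`.
#' @export
#' @examples
#' p <- conc_panel("AWE", "Cu", 4214)
#' threshold_exceedance(p, c(Cu = 2000)) # ~111% above the guideline
threshold_exceedance <- function(panel, limits) {
  if (is.data.frame(limits)) {
    lim <- tibble::as_tibble(limits[c("analyte", "limit")])
  } else {
    lim <- tibble::tibble(analyte = names(limits), limit = as.numeric(limits))
  }
  if (any(lim$limit <= 0)) stop("limits must be positive")
  metals <- dplyr::filter(panel, .data$unit == "ug/L")
  missing_lim <- setdiff(unique(metals$analyte), lim$analyte)
  if (length(missing_lim) > 0) {
    warning("no guideline limit for: ", paste(missing_lim, collapse = ", "),
            "; skipped")
  }
  metals |>
    dplyr::inner_join(lim, by = "analyte") |>
    dplyr::mutate(
      pct_above = pmax(0, (.data$level - .data$limit) / .data$limit * 100),
      within_limit = .data$level <= .data$limit
    ) |>
    dplyr::select("brand", "analyte", "level", "limit", "pct_above",
                  "within_limit")
}
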