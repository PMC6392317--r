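#' Average daily intake
#'
#' `ADI = Mc * IR * CF * EF * ED / (BW * ATn)` in mg/kg/day, with Mc in
#' mg per kg of drink, IR in g/day (CF = 1e-3 converts grams to kg),
#' EF in day/year, ED in years and ATn in days — the equation evaluated
#' exactly as the exposure profile states it.
#'
#' @param Mc concentration, mg per kg of drink (vectorized).
#' @param profile an [exposure_profile()].
#' @return ADI, mg/kg/day.
#' @export
#' @examples
#' average_daily_intake(ethanol_mc(40), acoli_exposure_profile()) # ~256
average_daily_intake <- function(Mc, profile) {
  stopifnot(inherits(profile, "exposure_profile"))
  if (any(Mc < 0, na.rm = TRUE)) stop("Mc must be non-negative")
  if (profile$BW <= 0 || profile$ATn <= 0) stop("BW and ATn must be positive")
  Mc * profile$IR * profile$CF * profile$EF * profile$ED /
    (profile$BW * profile$ATn)
}

#' Target hazard quotient
#'
#' THQ = ADI / RfD. An analyte lacking an RfD yields `NA` ("no
#' reference"), never 0, so absence of a reference dose is
#' distinguishable from absence of risk.
#'
#' @param adi average daily intake, mg/kg/day.
#' @param rfd oral reference dose, mg/kg/day (> 0 or `NA`).
#' @return THQ (dimensionless), `NA` where `rfd` is missing.
#' @export
target_hazard_quotient <- function(adi, rfd) {
  if (any(!is.na(rfd) & rfd <= 0)) stop("RfD must be > 0")
  ifelse(is.na(rfd), NA_real_, adi / rfd)
}

#' Row-percentage transformation
#'
#' Rescales each row (default: brands) of a THQ matrix to sum to 100,
#' the compositional view that keeps a single dominant analyte (Cu in
#' artisanal spirits) from swamping the joint risk profile. All-zero
#' rows are reported as missing (`NA` row), not as zeros.
#'
#' @param x numeric matrix, or long tibble with columns `brand`,
#'   `analyte` and a value column.
#' @param margin `"brands"` (rows = brands, default) or `"analytes"`
#'   (transform within analyte instead).
#' @param value name of the value column when `x` is a tibble.
#' @return object of the same shape as `x` with rows summing to 100.
#' @export
#' @examples
#' row_percent_transform(matrix(c(1, 3), nrow = 1)) # 25, 75
row_percent_transform <- function(x, margin = c("brands", "analytes"),
                                  value = "thq") {
  margin <- match.arg(margin)
  if (is.data.frame(x)) {
    group <- if (margin == "brands") "brand" else "analyte"
    out <- x |>
      dplyr::group_by(.data[[group]]) |>
      dplyr::mutate(
        "{value}" := row_percent_values(.data[[value]])
      ) |>
      dplyr::ungroup()
    return(out)
  }
  m <- as.matrix(x)
  if (margin == "analytes") m <- t(m)
  res <- t(apply(m, 1, row_percent_values))
  if (nrow(m) == 1) res <- matrix(res, nrow = 1, dimnames = dimnames(m))
  if (margin == "analytes") res <- t(res)
  dimnames(res) <- dimnames(x)
  res
}

row_percent_values <- function(v) {
  s <- sum(v, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) return(rep(NA_real_, length(v)))
  v / s * 100
}

#' Hazard index for one brand
#'
#' HI = sum of the included THQs (missing THQs are excluded and listed),
#' with the "1-in-x" interpretation ratio and a category: `safe`
#' (HI < 1), `concern` (1 <= HI < 5), `high` (HI >= 5).
#'
#' @param thqs numeric vector of per-analyte THQs for one brand, named by
#'   analyte; `NA` = analyte without a reference dose.
#' @param include optional character vector of analytes to include.
#' @return one-row tibble: `hi`, `n_included`, `excluded` (list column of
#'   analyte names without a THQ), `ratio`, `category`.
#' @export
#' @examples
#' hazard_index(c(Cu = 0.05, As = 0.023)) # HI 7.3e-2, ratio "1/14"
hazard_index <- function(thqs, include = NULL) {
  if (!is.null(include)) thqs <- thqs[names(thqs) %in% include]
  if (length(thqs) == 0) stop("empty inclusion set")
  if (all(is.na(thqs))) stop("at least one non-missing THQ required")
  hi <- sum(thqs, na.rm = TRUE)
  tibble::tibble(
    hi = hi,
    n_included = sum(!is.na(thqs)),
    excluded = list(names(thqs)[is.na(thqs)]),
    ratio = hi_ratio(hi),
    category = hi_category(hi)
  )
}

#' "1-in-x" ratio string for a hazard index
#'
#' For HI < 1 the ratio is `"1/x"` with `x = round(1/HI)` (one person in
#' every x may be affected); for HI >= 1 it is `">1"` (every exposed
#' person). Vectorized.
#'
#' @param hi hazard index (>= 0).
#' @return character ratio strings.
#' @export
hi_ratio <- function(hi) {
  stopifnot(all(hi >= 0, na.rm = TRUE))
  out <- rep(NA_character_, length(hi))
  ok <- !is.na(hi)
  out[ok & hi >= 1] <- ">1"
  out[ok & hi == 0] <- "0"
  frac <- ok & hi > 0 & hi < 1
  out[frac] <- sprintf("1/%.0f", round(1 / hi[frac]))
  out
}

#' Hazard index category
#'
#' `safe` below 1, `concern` in [1, 5), `high` at or above 5.
#'
#' @param hi hazard index.
#' @return factor with levels safe, concern, high.
#' @export
hi_category <- function(hi) {
  cut(hi, breaks = c(-Inf, 1, 5, Inf), right = FALSE,
      labels = c("safe", "concern", "high"))
}

#' Incremental lifetime carcinogenic risk
#'
#' CR = sum over analytes with a cancer slope factor of ADI x CSF, the
#' lifetime probability of developing cancer from the assessed ingestion.
#' Analytes without a CSF are listed as excluded. `persons_per_case` is
#' `round(1/CR)` (one case per that many consumers), infinite when CR is
#' zero.
#'
#' @param mc named numeric vector of concentrations, mg per kg of drink,
#'   named by analyte.
#' @param profile an [exposure_profile()].
#' @param reference toxicity reference tibble (see
#'   [default_toxicity_reference()]).
#' @return one-row tibble: `cr`, `persons_per_case`, `n_included`,
#'   `included`, `excluded` (list columns of analyte names).
#' @export
#' @examples
#' carcinogenic_risk(c(As = 1.3e-3), acoli_exposure_profile())
carcinogenic_risk <- function(mc, profile,
                              reference = default_toxicity_reference()) {
  stopifnot(!is.null(names(mc)), all(nzchar(names(mc))))
  csf <- setNames(reference$csf, reference$analyte)[names(mc)]
  has_csf <- !is.na(csf)
  if (!any(has_csf)) stop("no analyte with a cancer slope factor")
  adi <- average_daily_intake(mc[has_csf], profile)
  cr <- sum(adi * csf[has_csf])
  tibble::tibble(
    cr = cr,
    persons_per_case = persons_per_case(cr),
    n_included = sum(has_csf),
    included = list(names(mc)[has_csf]),
    excluded = list(names(mc)[!has_csf])
  )
}

#' Consumers per expected cancer case
#'
#' @param cr carcinogenic risk probability in `[0, 1)`.
#' @return `round(1/cr)`; `Inf` for zero risk.
#' @export
#' @examples
#' persons_per_case(9.8e-6) # 102041
persons_per_case <- function(cr) {
  stopifnot(all(cr >= 0, na.rm = TRUE))
  ifelse(cr == 0, Inf, round(1 / cr))
}

#' Full risk assessment of a concentration panel
#'
#' Runs the four-step assessment over every brand and analyte: converts
#' levels to Mc (ug/L metals via the drink density; ethanol % v/v via the
#' profile's Mc convention), evaluates ADI, THQ = ADI/RfD, the
#' row-percentage THQ view, per-brand hazard indices over the metals with
#' ratio strings and categories, per-analyte hazard indices across
#' brands (column sums of the row-percent matrix), and per-brand plus
#' pooled carcinogenic risk from the analytes with slope factors.
#'
#' @param panel a [conc_panel()] tibble.
#' @param reference toxicity reference tibble.
#' @param profile an [exposure_profile()].
#' @param mode ethanol intake arithmetic: `"paper"` reproduces the
#'   documented sachet arithmetic in which IR is already ethanol mass and
#'   Mc the ethanol mass fraction (THQ 4.1 for a 40% drink); `"strict"`
#'   removes the double count by setting ethanol Mc to 1e6 mg/kg (the
#'   ingested IR mass is pure ethanol), giving ~640 mg/kg/day.
#' @param row_percent orientation of the row-percent transform.
#' @return object of class `risk_assessment`: list with tibbles `adi`,
#'   `thq` (long, `NA` where no RfD), `thq_rowpct`, `hi` (per brand,
#'   sorted descending), `hi_analyte` (per analyte across brands),
#'   `ethanol` (per-brand ethanol THQ when present), `cancer` (per brand
#'   + pooled), and the inputs/options used.
#' @export
assess_risk <- function(panel, reference = default_toxicity_reference(),
                        profile = acoli_exposure_profile(),
                        mode = c("paper", "strict"),
                        row_percent = c("brands", "analytes")) {
  mode <- match.arg(mode)
  row_percent <- match.arg(row_percent)
  validate_panel(panel)

  mc_tbl <- panel
  is_metal <- mc_tbl$unit == "ug/L"
  mc_tbl$mc <- NA_real_
  mc_tbl$mc[is_metal] <- metal_mc(mc_tbl$level[is_metal], profile$density)
  if (any(!is_metal)) {
    mc_tbl$mc[!is_metal] <- if (mode == "strict") {
      1e6
    } else {
      ethanol_mc(mc_tbl$level[!is_metal], profile$Mc_convention)
    }
  }

  adi <- mc_tbl |>
    dplyr::mutate(adi = average_daily_intake(.data$mc, profile)) |>
    dplyr::select("brand", "analyte", "mc", "adi")

  rfd <- setNames(reference$rfd, reference$analyte)
  no_ref <- setdiff(unique(adi$analyte), reference$analyte)
  if (length(no_ref) > 0) {
    message("no RfD for: ", paste(no_ref, collapse = ", "),
            " (THQ reported as missing)")
  }
  thq <- adi |>
    dplyr::mutate(thq = target_hazard_quotient(
      .data$adi, unname(rfd[.data$analyte])
    )) |>
    dplyr::select("brand", "analyte", "thq")

  thq_metals <- dplyr::filter(thq, .data$analyte != HM_ETHANOL)
  thq_rowpct <- row_percent_transform(thq_metals, margin = row_percent)

  hi <- if (nrow(thq_metals) > 0) {
    thq_metals |>
      dplyr::group_by(.data$brand) |>
      dplyr::group_modify(~ hazard_index(setNames(.x$thq, .x$analyte))) |>
      dplyr::ungroup() |>
      dplyr::arrange(dplyr::desc(.data$hi))
  } else {
    tibble::tibble(brand = character(0), hi = numeric(0),
                   n_included = integer(0), excluded = list(),
                   ratio = character(0), category = hi_category(numeric(0)))
  }

  hi_analyte <- thq_rowpct |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(hi = sum(.data$thq, na.rm = TRUE), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$hi))

  ethanol <- thq |>
    dplyr::filter(.data$analyte == HM_ETHANOL) |>
    dplyr::mutate(ratio = hi_ratio(.data$thq),
                  category = hi_category(.data$thq))

  metals_mc <- dplyr::filter(mc_tbl, .data$unit == "ug/L")
  has_csf_analyte <- any(metals_mc$analyte %in%
                           reference$analyte[!is.na(reference$csf)])
  empty_cr <- tibble::tibble(
    brand = character(0), cr = numeric(0), persons_per_case = numeric(0),
    n_included = integer(0), included = list(), excluded = list()
  )
  if (nrow(metals_mc) > 0 && has_csf_analyte) {
    cancer_brand <- metals_mc |>
      dplyr::group_by(.data$brand) |>
      dplyr::group_modify(~ carcinogenic_risk(
        setNames(.x$mc, .x$analyte), profile, reference
      )) |>
      dplyr::ungroup()
    pooled_mc <- metals_mc |>
      dplyr::group_by(.data$analyte) |>
      dplyr::summarise(mc = mean(.data$mc), .groups = "drop")
    cancer_pooled <- carcinogenic_risk(
      setNames(pooled_mc$mc, pooled_mc$analyte), profile, reference
    )
  } else {
    cancer_brand <- empty_cr
    cancer_pooled <- tibble::tibble(
      cr = NA_real_, persons_per_case = NA_real_, n_included = 0L,
      included = list(character(0)), excluded = list(character(0))
    )
  }

  structure(
    list(adi = adi, thq = thq, thq_rowpct = thq_rowpct, hi = hi,
         hi_analyte = hi_analyte, ethanol = ethanol,
         cancer = cancer_brand, cancer_pooled = cancer_pooled,
         profile = profile, reference = reference, mode = mode,
         row_percent = row_percent,
         nondetect_policy = attr(panel, "nondetect_policy") %||% "as_measured"),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("<risk_assessment> ", dplyr::n_distinct(x$adi$brand), " brands, ",
      dplyr::n_distinct(x$adi$analyte), " analytes (mode: ", x$mode,
      ")\n", sep = "")
  cat("Top brands by metal hazard index:\n")
  print(head(x$hi, 5))
  if (nrow(x$ethanol) > 0) {
    cat(sprintf("Ethanol THQ: %s (category %s)\n",
                paste(unique(signif(x$ethanol$thq, 2)), collapse = ", "),
                paste(unique(x$ethanol$category), collapse = ", ")))
  }
  cat(sprintf("Pooled carcinogenic risk: %.3g (1 case per %s consumers)\n",
              x$cancer_pooled$cr,
              format(x$cancer_pooled$persons_per_case, big.mark = ",")))
  invisible(x)
}

#' @rdname assess_risk
#' @param x a `risk_assessment`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.risk_assessment <- function(x, ...) {
  dplyr::left_join(x$adi, x$thq, by = c("brand", "analyte"))
}

#' @rdname assess_risk
#' @exportS3Method generics::glance
glance.risk_assessment <- function(x, ...) {
  tibble::tibble(
    n_brands = dplyr::n_distinct(x$adi$brand),
    n_analytes = dplyr::n_distinct(x$adi$analyte),
    max_hi = max(x$hi$hi),
    max_hi_brand = x$hi$brand[which.max(x$hi$hi)],
    ethanol_thq = if (nrow(x$ethanol) > 0) max(x$ethanol$thq) else NA_real_,
    pooled_cr = x$cancer_pooled$cr,
    persons_per_case = x$cancer_pooled$persons_per_case,
    mode = x$mode
  )
}

#' @rdname assess_risk
#' @param object a `risk_assessment`.
#' @exportS3Method ggplot2::autoplot
autoplot.risk_assessment <- function(object, ...) {
  dat <- dplyr::mutate(object$hi,
                       brand = factor(.data$brand, levels = rev(.data$brand)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$hi, y = .data$brand,
                                    fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard index (metals, log scale)", y = NULL,
                  fill = "Category") +
    ggplot2::theme_minimal()
}
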