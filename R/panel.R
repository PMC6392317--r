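#' Construct a concentration panel
#'
#' A concentration panel is a long tidy tibble with one row per brand and
#' analyte: metal levels in ug/L and, when present, ethanol in % v/v.
#' Below-detection values carry `censored = TRUE` and a stored level that
#' reflects the active non-detect substitution policy (see
#' [apply_nondetect_policy()]).
#'
#' @param brand character, brand identifiers.
#' @param analyte character, element symbols (plus `"ethanol"`).
#' @param level numeric measured level: ug/L for metals, % v/v for ethanol.
#' @param sd optional duplicate-measurement standard deviation, same units.
#' @param censored logical, `TRUE` where the measurement is below the MDL.
#' @param mdl per-row method detection limit (ug/L), `NA` where not stated.
#' @param policy non-detect substitution policy recorded for the panel.
#'
#' @return A tibble of class `conc_panel` with columns `brand`, `analyte`,
#'   `level`, `sd`, `censored`, `mdl`, `unit`.
#' @export
#' @examples
#' conc_panel(
#'   brand = c("UGW", "UGW"), analyte = c("Cu", "Pb"),
#'   level = c(3.4, 0.1)
#' )
conc_panel <- function(brand, analyte, level, sd = NA_real_,
                       censored = FALSE, mdl = NA_real_,
                       policy = "as_measured") {
  out <- tibble::tibble(
    brand = as.character(brand),
    analyte = as.character(analyte),
    level = as.numeric(level),
    sd = as.numeric(sd),
    censored = as.logical(censored),
    mdl = as.numeric(mdl)
  )
  out$unit <- ifelse(out$analyte == HM_ETHANOL, "pct_vv", "ug/L")
  out <- validate_panel(out)
  attr(out, "nondetect_policy") <- policy
  class(out) <- c("conc_panel", class(tibble::tibble()))
  out
}

#' Validate concentration-panel invariants
#'
#' Checks that brand/analyte pairs are unique, analyte symbols are known,
#' and uncensored levels are non-negative.
#'
#' @param panel a panel tibble (see [conc_panel()]).
#' @param allow_unknown allow analyte symbols outside the built-in set.
#' @return the panel, invisibly unchanged, or an error.
#' @export
validate_panel <- function(panel, allow_unknown = FALSE) {
  req <- c("brand", "analyte", "level", "censored")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(panel) == 0) stop("panel has no rows")
  key <- paste(panel$brand, panel$analyte)
  if (anyDuplicated(key)) {
    dup <- unique(panel$brand[duplicated(key)])
    stop("duplicate brand id / analyte combination: ",
         paste(dup, collapse = ", "))
  }
  if (!allow_unknown) {
    unknown <- setdiff(unique(panel$analyte), c(HM_ANALYTES, HM_ETHANOL))
    if (length(unknown) > 0) {
      stop("unknown analyte symbol: ", paste(unknown, collapse = ", "))
    }
  }
  bad <- !panel$censored & !is.na(panel$level) & panel$level < 0
  if (any(bad)) {
    stop("negative level for ",
         paste(unique(panel$brand[bad]), collapse = ", "))
  }
  invisible(panel)
}

#' Read a concentration panel from delimited text
#'
#' Expects a header row naming analytes, a first column of brand ids and
#' one row per brand. Cells equal to `nd_token` (or numerically below the
#' analyte's MDL) are flagged censored and stored at the value implied by
#' `policy`.
#'
#' @param path file path (comma- or tab-separated, "." decimal).
#' @param mdl per-analyte method detection limits: a named numeric vector,
#'   a two-column tibble (`analyte`, `mdl`) or a path to one.
#' @param sd_path optional path to a same-shaped table of duplicate SDs.
#' @param nd_token string marking a non-detect cell (default `"ND"`).
#' @param policy substitution policy for censored cells, see
#'   [apply_nondetect_policy()].
#' @return A [conc_panel()] tibble.
#' @export
read_panel <- function(path, mdl = NULL, sd_path = NULL, nd_token = "ND",
                       policy = c("zero", "half_mdl", "mdl")) {
  policy <- match.arg(policy)
  # read as text: numeric cells are parsed once, by strtod, so values
  # survive a write/read cycle bit-exactly
  raw <- read_delim_auto(path, as_character = TRUE)
  if (ncol(raw) < 2) stop("panel file needs a brand column plus analytes")
  names(raw)[1] <- "brand"
  if (anyDuplicated(raw$brand)) {
    stop("duplicate brand id: ",
         paste(unique(raw$brand[duplicated(raw$brand)]), collapse = ", "))
  }
  analytes <- names(raw)[-1]
  unknown <- setdiff(analytes, c(HM_ANALYTES, HM_ETHANOL))
  if (length(unknown) > 0) {
    stop("unknown analyte symbol: ", paste(unknown, collapse = ", "))
  }
  mdl_tbl <- normalize_mdl(mdl, analytes)

  long <- raw |>
    tidyr::pivot_longer(-"brand", names_to = "analyte",
                        values_to = "cell") |>
    dplyr::left_join(mdl_tbl, by = "analyte")
  long$censored <- trimws(long$cell) == nd_token
  long$level <- suppressWarnings(as.numeric(long$cell))
  if (any(is.na(long$level) & !long$censored)) {
    bad <- long[is.na(long$level) & !long$censored, ]
    stop("non-numeric cell for brand ", bad$brand[1],
         ", analyte ", bad$analyte[1])
  }
  # numeric values below the MDL are also non-detects
  below <- !long$censored & !is.na(long$mdl) & long$level < long$mdl
  long$censored <- long$censored | below

  sds <- NA_real_
  if (!is.null(sd_path)) {
    sd_raw <- read_delim_auto(sd_path)
    names(sd_raw)[1] <- "brand"
    sd_long <- tidyr::pivot_longer(sd_raw, -"brand",
                                   names_to = "analyte", values_to = "sd")
    long <- dplyr::left_join(long, sd_long, by = c("brand", "analyte"))
    sds <- long$sd
  }

  panel <- conc_panel(long$brand, long$analyte,
                      level = ifelse(long$censored, NA_real_, long$level),
                      sd = sds, censored = long$censored, mdl = long$mdl,
                      policy = "as_measured")
  apply_nondetect_policy(panel, policy)
}

read_delim_auto <- function(path, as_character = FALSE) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  types <- if (as_character) readr::cols(.default = "c") else NULL
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, col_types = types)
}

normalize_mdl <- function(mdl, analytes) {
  if (is.null(mdl)) {
    return(tibble::tibble(analyte = analytes, mdl = NA_real_))
  }
  if (is.character(mdl) && length(mdl) == 1) {
    mdl <- read_delim_auto(mdl)
  }
  if (is.data.frame(mdl)) {
    stopifnot(all(c("analyte", "mdl") %in% names(mdl)))
    tbl <- tibble::as_tibble(mdl[c("analyte", "mdl")])
  } else {
    tbl <- tibble::tibble(analyte = names(mdl), mdl = as.numeric(mdl))
  }
  dplyr::left_join(tibble::tibble(analyte = analytes), tbl, by = "analyte")
}

#' Substitute non-detect values by policy
#'
#' Censored cells (below the method detection limit) are replaced by 0,
#' MDL/2 or the MDL; uncensored cells are unchanged. The policy is
#' recorded on the panel and the operation is idempotent for a fixed
#' policy.
#'
#' @param panel a [conc_panel()] tibble.
#' @param policy one of `"zero"`, `"half_mdl"`, `"mdl"`.
#' @return the panel with substituted levels and updated policy attribute.
#' @export
apply_nondetect_policy <- function(panel, policy = c("zero", "half_mdl", "mdl")) {
  policy <- match.arg(policy)
  cens <- panel$censored
  if (any(cens & is.na(panel$mdl))) {
    bad <- panel[cens & is.na(panel$mdl), ]
    stop("censored cell with missing MDL: brand ", bad$brand[1],
         ", analyte ", bad$analyte[1])
  }
  panel$level[cens] <- switch(policy,
    zero = 0,
    half_mdl = panel$mdl[cens] / 2,
    mdl = panel$mdl[cens]
  )
  attr(panel, "nondetect_policy") <- policy
  panel
}

#' Write a concentration panel to delimited text
#'
#' Inverse of [read_panel()]: wide layout, first column the brand id,
#' censored cells written as the non-detect token so a round trip
#' reproduces every level and censoring flag exactly.
#'
#' @param panel a [conc_panel()] tibble.
#' @param path output path (`.csv` comma-separated).
#' @param nd_token token written for censored cells.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, nd_token = "ND") {
  wide <- panel |>
    dplyr::mutate(cell = ifelse(.data$censored, nd_token,
                                sprintf("%.17g", .data$level))) |>
    dplyr::select("brand", "analyte", "cell") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "cell")
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Matrix view of a panel
#'
#' @param panel a [conc_panel()] tibble.
#' @param analytes optional subset/order of analytes.
#' @return numeric matrix, brands as rows.
#' @export
panel_matrix <- function(panel, analytes = NULL) {
  if (!is.null(analytes)) {
    panel <- dplyr::filter(panel, .data$analyte %in% analytes)
  }
  wide <- panel |>
    dplyr::select("brand", "analyte", "level") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "level")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$brand
  m
}
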