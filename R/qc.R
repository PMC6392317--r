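#' Build a table of quality-control records
#'
#' @param kind one of `"blank"`, `"spike_duplicate"`, `"vessel_leach"`.
#' @param analyte analyte symbol.
#' @param level measured level, ug/L.
#' @param expected expected level for spike duplicates, ug/L (`NA` for
#'   blanks and vessel leach checks).
#' @param mdl method detection limit for the analyte, ug/L.
#' @return tibble of QC records.
#' @export
qc_record <- function(kind, analyte, level, expected = NA_real_,
                      mdl = NA_real_) {
  kind <- match.arg(kind, c("blank", "spike_duplicate", "vessel_leach"),
                    several.ok = TRUE)
  tibble::tibble(kind = kind, analyte = analyte, level = as.numeric(level),
                 expected = as.numeric(expected), mdl = as.numeric(mdl))
}

#' Validate a QC batch
#'
#' Blanks (and vessel-leach checks) pass when every level is below the
#' MDL; spike duplicates pass when recovery (level/expected) falls inside
#' the recovery band. The batch is usable only if every record passes.
#'
#' @param records tibble of [qc_record()] rows; at least one blank.
#' @param recovery_band length-2 fraction pair, e.g. `c(0.85, 1.15)`.
#' @return tibble with per-record `pass` plus attributes `batch_usable`
#'   and `recovery_band`.
#' @export
#' @examples
#' rec <- rbind(
#'   qc_record("blank", "Cu", 0.1, mdl = 0.5),
#'   qc_record("spike_duplicate", "Cu", 10, expected = 10)
#' )
#' validate_qc(rec)
validate_qc <- function(records, recovery_band = c(0.85, 1.15)) {
  if (is.null(records) || nrow(records) == 0) stop("no QC in batch")
  stopifnot(length(recovery_band) == 2, recovery_band[1] < recovery_band[2])
  if (!any(records$kind == "blank")) stop("no QC in batch: need at least one blank")
  rec <- tibble::as_tibble(records)
  rec$recovery <- ifelse(rec$kind == "spike_duplicate",
                         rec$level / rec$expected, NA_real_)
  rec$pass <- dplyr::case_when(
    rec$kind %in% c("blank", "vessel_leach") ~
      !is.na(rec$mdl) & rec$level < rec$mdl,
    rec$kind == "spike_duplicate" ~
      !is.na(rec$recovery) & rec$recovery >= recovery_band[1] &
        rec$recovery <= recovery_band[2]
  )
  attr(rec, "batch_usable") <- all(rec$pass)
  attr(rec, "recovery_band") <- recovery_band
  rec
}
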