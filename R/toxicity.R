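#' Built-in oral toxicity reference table
#'
#' Per-analyte oral reference doses (RfD, mg/kg/day) and cancer slope
#' factors (CSF, per mg/kg/day) with a provenance string per row. Ethanol
#' carries the RfD of 62 used in the sachet-spirit risk framework; Pb uses
#' the study convention of 1.5 because no EPA oral RfD is established;
#' metal RfDs come from the US EPA IRIS/PPRTV/HEAST compilations. CSFs
#' exist only for As (1.5), Cr(VI) (0.5) and Pb (0.0085); other analytes
#' carry `NA` and are reported as excluded by the cancer-risk engine,
#' never silently zeroed.
#'
#' @return tibble with columns `analyte`, `rfd`, `csf`, `source`.
#' @export
#' @examples
#' default_toxicity_reference()
default_toxicity_reference <- function() {
  path <- system.file("extdata", "toxicity_reference.csv",
                      package = "hmrisk", mustWork = TRUE)
  read_toxicity_reference(path)
}

#' Read a toxicity reference table
#'
#' @param path delimited text with columns `analyte`, `rfd`, `csf` and
#'   optionally `source`.
#' @return validated tibble.
#' @export
read_toxicity_reference <- function(path) {
  tbl <- read_delim_auto(path)
  stopifnot(all(c("analyte", "rfd", "csf") %in% names(tbl)))
  if (!"source" %in% names(tbl)) tbl$source <- NA_character_
  tbl <- tibble::as_tibble(tbl[c("analyte", "rfd", "csf", "source")])
  if (any(!is.na(tbl$rfd) & tbl$rfd <= 0)) stop("RfD must be > 0 where present")
  if (any(!is.na(tbl$csf) & tbl$csf < 0)) stop("CSF must be >= 0 where present")
  if (anyDuplicated(tbl$analyte)) stop("duplicate analyte in reference table")
  tbl
}
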