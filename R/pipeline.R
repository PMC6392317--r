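#' Run the full assessment pipeline
#'
#' Executes the four assessment steps in sequence — hazard
#' identification (panel intake + QC-ready descriptive summary), daily
#' intake estimation, risk estimation (THQ) and risk characterization
#' (HI, cancer risk) — optionally followed by the cluster analysis of
#' THQ profiles, and writes every result table plus a JSON run manifest
#' to `out_dir`. Output files: `adi.csv`, `thq.csv`, `thq_rowpct.csv`,
#' `hi.csv`, `cancer_risk.csv`, `summary.csv`, `cluster_merges.csv`,
#' `dendrogram.nwk`, `report.md`, `manifest.json`.
#'
#' @param panel a [conc_panel()] or a path to a panel file.
#' @param reference toxicity reference tibble or path.
#' @param profile an [exposure_profile()] or path to YAML/JSON.
#' @param out_dir output directory (created if needed).
#' @param mode,row_percent passed to [assess_risk()].
#' @param nondetect non-detect policy applied on load.
#' @param mdl per-analyte MDLs when `panel` is a path.
#' @param cluster run the Ward cluster analysis of row-percent THQs.
#' @param exclude analytes excluded from clustering (default the
#'   dominant pair: Cu and ethanol).
#' @param cut_height optional dendrogram cut height.
#' @param splits number of split-half stability replicates (0 = skip).
#' @param seed integer seed used for the stability randomization.
#' @return (invisibly) list with the assessment, summary, cluster
#'   results and the manifest.
#' @export
run_pipeline <- function(panel, reference = default_toxicity_reference(),
                         profile = acoli_exposure_profile(),
                         out_dir,
                         mode = "paper", row_percent = "brands",
                         nondetect = "zero", mdl = NULL,
                         cluster = TRUE, exclude = c("Cu", "ethanol"),
                         cut_height = NULL, splits = 0, seed = 1L) {
  panel_path <- NULL
  if (is.character(panel)) {
    panel_path <- panel
    panel <- read_panel(panel, mdl = mdl, policy = nondetect)
  } else {
    panel <- apply_nondetect_policy(panel, nondetect)
  }
  if (is.character(reference)) reference <- read_toxicity_reference(reference)
  if (is.character(profile)) profile <- read_exposure_profile(profile)
  if (nrow(panel) == 0 || dplyr::n_distinct(panel$brand) == 0) {
    stop("no brands")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(stage, e) {
    unlink(file.path(out_dir, written))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  emit <- function(tbl, file) {
    readr::write_csv(drop_list_cols(tbl), file.path(out_dir, file),
                     progress = FALSE)
    written <<- c(written, file)
  }

  log_stage <- function(stage, n_row, n_col) {
    message(sprintf("[%s] %d rows x %d cols", stage, n_row, n_col))
  }

  summary_tbl <- tryCatch({
    s <- summarize_analytes(panel)
    log_stage("hazard identification", nrow(s), ncol(s))
    s
  }, error = function(e) on_fail("hazard identification", e))

  assessment <- tryCatch({
    a <- assess_risk(panel, reference, profile, mode = mode,
                     row_percent = row_percent)
    log_stage("intake estimation", nrow(a$adi), 4L)
    log_stage("risk estimation", nrow(a$thq), 3L)
    log_stage("risk characterization", nrow(a$hi), ncol(a$hi))
    a
  }, error = function(e) on_fail("risk assessment", e))

  cluster_res <- NULL
  if (isTRUE(cluster)) {
    cluster_res <- tryCatch({
      cl <- cluster_thq(assessment, exclude = exclude,
                        cut_height = cut_height,
                        splits = splits, seed = seed)
      log_stage("cluster analysis", length(cl$tree$labels), 1L)
      cl
    }, error = function(e) on_fail("cluster analysis", e))
  }

  emit(summary_tbl, "summary.csv")
  emit(assessment$adi, "adi.csv")
  emit(assessment$thq, "thq.csv")
  emit(assessment$thq_rowpct, "thq_rowpct.csv")
  hi_out <- dplyr::mutate(assessment$hi,
                          excluded = purrr::map_chr(.data$excluded,
                                                    paste, collapse = ";"))
  if (nrow(assessment$ethanol) > 0) {
    eth_rows <- assessment$ethanol |>
      dplyr::transmute(brand = paste0("ethanol:", .data$brand),
                       hi = .data$thq, n_included = 1L, excluded = "",
                       ratio = .data$ratio, category = .data$category)
    hi_out <- dplyr::bind_rows(eth_rows, hi_out)
  }
  emit(hi_out, "hi.csv")
  cancer_out <- dplyr::bind_rows(
    dplyr::mutate(assessment$cancer, scope = "brand"),
    dplyr::mutate(assessment$cancer_pooled, brand = "(pooled mean)",
                  scope = "pooled")
  ) |>
    dplyr::mutate(included = purrr::map_chr(.data$included, paste,
                                            collapse = ";"),
                  excluded = purrr::map_chr(.data$excluded, paste,
                                            collapse = ";"))
  emit(cancer_out, "cancer_risk.csv")
  if (!is.null(cluster_res)) {
    emit(tidy(cluster_res$tree), "cluster_merges.csv")
    write_tree_newick(cluster_res$tree, file.path(out_dir, "dendrogram.nwk"))
    written <- c(written, "dendrogram.nwk")
    if (!is.null(cluster_res$cut)) emit(cluster_res$cut, "clusters.csv")
    if (!is.null(cluster_res$stability)) {
      emit(cluster_res$stability, "stability.csv")
    }
  }
  report <- render_tables(assessment, summary_tbl, cluster_res)
  writeLines(report, file.path(out_dir, "report.md"))
  written <- c(written, "report.md")

  manifest <- build_manifest(
    out_dir, written,
    inputs = list(panel = panel_path %||% "(in-memory panel)"),
    config = list(mode = mode, row_percent = row_percent,
                  nondetect = nondetect, cluster = cluster,
                  exclude = exclude, cut_height = cut_height,
                  splits = splits, seed = seed,
                  Mc_convention = profile$Mc_convention)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)

  invisible(list(assessment = assessment, summary = summary_tbl,
                 cluster = cluster_res, manifest = manifest,
                 out_dir = out_dir))
}

drop_list_cols <- function(tbl) {
  tbl[!vapply(tbl, is.list, logical(1))]
}

#' Cluster THQ profiles of an assessment
#'
#' Builds the squared-Euclidean/Ward dendrogram of the row-percent THQ
#' matrix (configurable analyte exclusions, default Cu and ethanol),
#' with cophenetic validation, an optional cut, and optional split-half
#' stability.
#'
#' @param assessment a [assess_risk()] result.
#' @param exclude analytes to drop before clustering.
#' @param items cluster `"brands"` (rows) or `"analytes"` (columns).
#' @param cut_height optional cut height.
#' @param k optional number of clusters (alternative to `cut_height`).
#' @param splits number of split-half replicates (0 = none).
#' @param seed seed for the stability randomization.
#' @return list: `tree`, `cophenetic`, `cut` (or `NULL`), `stability`
#'   (or `NULL`), `matrix`.
#' @export
cluster_thq <- function(assessment, exclude = c("Cu", "ethanol"),
                        items = c("brands", "analytes"),
                        cut_height = NULL, k = NULL, splits = 0,
                        seed = 1L) {
  items <- match.arg(items)
  thq <- assessment$thq_rowpct |>
    dplyr::filter(!.data$analyte %in% exclude, !is.na(.data$thq))
  wide <- tidyr::pivot_wider(thq, names_from = "analyte",
                             values_from = "thq")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$brand
  if (items == "analytes") m <- t(m)
  d <- dist_squared_euclidean(m)
  tree <- ward_cluster(d)
  cut <- if (!is.null(cut_height) || !is.null(k)) {
    cut_tree(tree, height = cut_height, k = k)
  }
  stability <- if (splits > 0) {
    split_half_stability(m, n_splits = splits, seed = seed,
                         k = k %||% 2)
  }
  list(tree = tree, cophenetic = cophenetic_correlation(d, tree),
       cut = cut, stability = stability, matrix = m)
}

build_manifest <- function(out_dir, files, inputs, config) {
  hashes <- tools::md5sum(file.path(out_dir, files))
  list(
    package = "hmrisk",
    version = as.character(utils::packageVersion("hmrisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    config = config,
    outputs = setNames(as.list(unname(hashes)), files)
  )
}

#' Render result tables as a markdown report
#'
#' A summary-statistics section (Sum ... IQR layout) and a hazard-index
#' section (brand, metal content, HI, ratio) with brands sorted from the
#' highest HI down and an ethanol row on top, plus cancer risk and
#' cluster sections when available. Levels are printed to 3 significant
#' figures; THQ/HI values in scientific notation.
#'
#' @param assessment a [assess_risk()] result.
#' @param summary_tbl optional [summarize_analytes()] table.
#' @param cluster optional [cluster_thq()] result.
#' @return character vector of markdown lines.
#' @export
render_tables <- function(assessment, summary_tbl = NULL, cluster = NULL) {
  out <- c("# Health risk assessment report", "")
  fmt3 <- function(x) ifelse(is.na(x), "-", signif(x, 3))
  fmte <- function(x) ifelse(is.na(x), "-", formatC(x, format = "e",
                                                    digits = 1))
  if (!is.null(summary_tbl)) {
    out <- c(out, "## Summary statistics (ug/L)", "",
             "| Analyte | Sum | mean | SD | minimum | Q1 | Median | Q3 | maximum | IQR |",
             "|---|---|---|---|---|---|---|---|---|---|")
    s <- dplyr::arrange(summary_tbl, dplyr::desc(.data$sum))
    out <- c(out, sprintf(
      "| %s | %s | %s | %s | %s | %s | %s | %s | %s | %s |",
      s$analyte, fmt3(s$sum), fmt3(s$mean), fmt3(s$sd), fmt3(s$minimum),
      fmt3(s$q1), fmt3(s$median), fmt3(s$q3), fmt3(s$maximum),
      fmt3(s$iqr)), "")
  }

  out <- c(out, "## Hazard indices", "",
           "| Brand | Metal content (ug/L) | HI (metals) | Ratio |",
           "|---|---|---|---|")
  totals <- assessment$adi |>
    dplyr::filter(.data$analyte != HM_ETHANOL) |>
    dplyr::group_by(.data$brand) |>
    dplyr::summarise(total = sum(.data$mc * 1e3), .groups = "drop")
  hi <- dplyr::left_join(assessment$hi, totals, by = "brand")
  if (nrow(assessment$ethanol) > 0) {
    eth <- assessment$ethanol
    out <- c(out, sprintf("| Ethanol | - | %s | %s |",
                          paste(unique(fmte(eth$thq)), collapse = "; "),
                          paste(unique(eth$ratio), collapse = "; ")))
  }
  out <- c(out, sprintf("| %s | %s | %s | %s |", hi$brand,
                        fmt3(hi$total), fmte(hi$hi), hi$ratio), "")

  cp <- assessment$cancer_pooled
  out <- c(out, "## Carcinogenic risk", "",
           sprintf("Pooled (mean concentrations) risk: %s — about 1 case per %s consumers.",
                   fmte(cp$cr), format(cp$persons_per_case, big.mark = ",")),
           sprintf("Analytes with slope factors: %s; excluded (no CSF): %s.",
                   paste(cp$included[[1]], collapse = ", "),
                   paste(cp$excluded[[1]], collapse = ", ")), "")

  if (!is.null(cluster)) {
    out <- c(out, "## Cluster analysis", "",
             sprintf("Ward linkage on squared Euclidean distances; cophenetic correlation %s.",
                     fmt3(cluster$cophenetic)))
    if (!is.null(cluster$cut)) {
      memb <- cluster$cut |>
        dplyr::group_by(.data$cluster) |>
        dplyr::summarise(items = paste(.data$item, collapse = ", "),
                         .groups = "drop")
      out <- c(out, "", sprintf("- Cluster %d: %s", memb$cluster,
                                memb$items))
    }
    if (!is.null(cluster$stability)) {
      out <- c(out, "",
               sprintf("Split-half stability (mean co-membership agreement): %s.",
                       fmt3(attr(cluster$stability, "mean_agreement"))))
    }
    out <- c(out, "")
  }
  out
}
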