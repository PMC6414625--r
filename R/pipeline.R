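# End-to-end driver: synthetic inputs -> ICE -> TAD annotation -> ACF /
# concordance / grouping -> compartments & saddles -> track fold changes.

#' Default pipeline configuration
#'
#' @param seed Master seed for the synthetic inputs.
#' @param gamma_control,gamma_kd Domain-scaling exponents per condition.
#'   The defaults (0.7) are the manual calibration for the synthetic arm —
#'   the TAD caller's gamma is always chosen per dataset to give a good
#'   partitioning; the published fly maps used 1.12 (control) and 1.20
#'   (knock-down).
#' @param ice_iterations Balancing iterations (default 20).
#' @param split_kb,min_tad_kb Two-step annotation thresholds (600 / 60 kb).
#' @param saddle_quantiles Aggregated bins of the saddle plot (default 20).
#' @param synthetic Named list of [synth_spec()] overrides.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, gamma_control = 0.7, gamma_kd = 0.7,
                            ice_iterations = 20L, split_kb = 600,
                            min_tad_kb = 60, saddle_quantiles = 20L,
                            synthetic = list(), out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror [pipeline_config()]; missing fields take the defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) abort(sprintf("Unknown config fields: %s",
                                 paste(bad, collapse = ", ")))
  do.call(pipeline_config, y)
}

#' Run the full analysis on synthetic data
#'
#' Generates two replicates of two conditions, balances every map (ICE),
#' annotates TADs on the merged control map, computes per-TAD ACFs, applies
#' the four-ratio replicate-concordance filter, ranks TADs by Jaccard score
#' into groups A-D, summarises per-group ACF changes, annotates compartments
#' (control PC1 oriented by transcription), builds per-condition saddle plots
#' and their subtraction, classifies within/between-fraction contact changes,
#' and computes LAD versus inter-LAD expression fold changes.
#'
#' @param config A `pipeline_config` (or nothing for defaults).
#' @return A `pipeline_result` list; see Details.
#' @details The result carries: `spec`, `annotation_ctrl`, `annotation_kd`,
#'   `tad_table` (per-TAD metrics incl. group and ACF log2FC),
#'   `group_summary_acf`, `pc1`, `saddle_ctrl`, `saddle_kd`, `saddle_diff`,
#'   `ab_changes`, `track_log2fc`, `track_changes`, and `config_hash`.
#' @export
run_full_analysis <- function(config = pipeline_config()) {
  spec <- do.call(synth_spec, c(list(seed = config$seed), config$synthetic))
  truth <- make_annotations(spec)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  raw <- stage("simulate", list(
    ctrl_1 = make_hic(spec, "control", 1L), ctrl_2 = make_hic(spec, "control", 2L),
    kd_1 = make_hic(spec, "kd", 1L), kd_2 = make_hic(spec, "kd", 2L)))
  merged_raw <- stage("merge", list(
    ctrl = contact_map(raw$ctrl_1$counts + raw$ctrl_2$counts,
                       bin_size = spec$bin_size, arm_id = "synth_ctrl_merged"),
    kd = contact_map(raw$kd_1$counts + raw$kd_2$counts,
                     bin_size = spec$bin_size, arm_id = "synth_kd_merged")))
  ice <- stage("ice", lapply(c(raw, merged_raw), function(m) {
    ice_normalize(mask_bins(m), n_iterations = config$ice_iterations)$map
  }))

  ann_ctrl <- stage("tads", two_step_annotation(
    ice$ctrl, config$gamma_control, config$split_kb, config$min_tad_kb))
  ann_kd <- stage("tads", two_step_annotation(
    ice$kd, config$gamma_kd, config$split_kb, config$min_tad_kb))

  tad_table <- stage("acf", {
    tt <- acf_table(ice[c("ctrl_1", "ctrl_2", "kd_1", "kd_2", "ctrl", "kd")],
                    ann_ctrl)
    conc <- purrr::pmap(list(tt$acf_kd_1, tt$acf_kd_2,
                             tt$acf_ctrl_1, tt$acf_ctrl_2),
                        function(k1, k2, c1, c2) {
                          concordance_filter(c(k1, k2), c(c1, c2))
                        })
    tt <- mutate(tt,
                 keep = purrr::map_lgl(conc, "keep"),
                 direction = purrr::map_chr(conc, "direction"),
                 acf_log2fc = log2(.data$acf_kd / .data$acf_ctrl))
    filter(tt, .data$keep)
  })
  tad_table <- stage("grouping", jaccard_group(
    tad_table, truth$lads, truth$active, bin_size = spec$bin_size))
  group_summary_acf <- group_change_summary(tad_table, "acf_log2fc")

  compartments <- stage("compartments", {
    oe_ctrl <- observed_over_expected(ice$ctrl)
    oe_kd <- observed_over_expected(ice$kd)
    orient <- make_tracks(spec, "control", 1L)$bins$value
    pc1 <- compute_pc1(oe_ctrl, orient)
    s_ctrl <- saddle(oe_ctrl, pc1, config$saddle_quantiles)
    s_kd <- saddle(oe_kd, pc1, config$saddle_quantiles)
    list(pc1 = pc1, saddle_ctrl = s_ctrl, saddle_kd = s_kd,
         saddle_diff = saddle_subtract(s_kd, s_ctrl),
         ab_changes = ab_contact_changes(oe_kd, oe_ctrl, pc1))
  })

  tracks <- stage("tracks", {
    tabs <- list(ctrl_1 = make_tracks(spec, "control", 1L)$genes,
                 ctrl_2 = make_tracks(spec, "control", 2L)$genes,
                 kd_1 = make_tracks(spec, "kd", 1L)$genes,
                 kd_2 = make_tracks(spec, "kd", 2L)$genes)
    wide <- tibble(feature_id = tabs$ctrl_1$feature_id,
                   ctrl_1 = tabs$ctrl_1$value, ctrl_2 = tabs$ctrl_2$value,
                   kd_1 = tabs$kd_1$value, kd_2 = tabs$kd_2$value)
    fc <- normalize_and_log2fc(wide, kd_cols = c("kd_1", "kd_2"),
                               ctrl_cols = c("ctrl_1", "ctrl_2"))
    fc <- left_join(fc, select(tabs$ctrl_1, "feature_id", "lad_class"),
                    by = "feature_id")
    list(log2fc = fc, changes = lad_vs_interlad_change(fc))
  })

  result <- structure(list(
    spec = spec, truth = truth,
    annotation_ctrl = ann_ctrl, annotation_kd = ann_kd,
    tad_table = tad_table, group_summary_acf = group_summary_acf,
    pc1 = compartments$pc1,
    saddle_ctrl = compartments$saddle_ctrl,
    saddle_kd = compartments$saddle_kd,
    saddle_diff = compartments$saddle_diff,
    ab_changes = compartments$ab_changes,
    track_log2fc = tracks$log2fc, track_changes = tracks$changes,
    config = config,
    config_hash = rlang::hash(config)
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- result$config_hash
  wtsv <- function(x, f) {
    path <- file.path(dir, f)
    writeLines(sprintf("# config_hash: %s", hash), path)
    suppressWarnings(write.table(x, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    path
  }
  wtsv(result$tad_table, "tad_metrics.tsv")
  wtsv(result$group_summary_acf, "group_summary_acf.tsv")
  wtsv(result$pc1, "pc1.tsv")
  wtsv(tidy(result$saddle_ctrl), "saddle_ctrl.tsv")
  wtsv(tidy(result$saddle_kd), "saddle_kd.tsv")
  wtsv(result$track_log2fc, "track_log2fc.tsv")
  write_domains_bed(result$annotation_ctrl, file.path(dir, "tads_ctrl.bed"))
  write_domains_bed(result$annotation_kd, file.path(dir, "tads_kd.bed"))
  yaml::write_yaml(list(
    config_hash = hash,
    seed = result$config$seed,
    package_version = as.character(utils::packageVersion("laminatad")),
    n_tads_ctrl = sum(result$annotation_ctrl$label == "TAD"),
    n_tads_kd = sum(result$annotation_kd$label == "TAD"),
    groups = as.list(table(result$tad_table$group))
  ), file.path(dir, "run_log.yaml"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    paste0("<pipeline_result> %d retained TADs in %d groups; ",
           "%dx%d saddle per condition; %d track features\n"),
    nrow(x$tad_table), length(unique(x$tad_table$group)),
    nrow(x$saddle_ctrl), ncol(x$saddle_ctrl), nrow(x$track_log2fc)))
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(
    n_tads_ctrl = sum(x$annotation_ctrl$label == "TAD"),
    n_tads_kd = sum(x$annotation_kd$label == "TAD"),
    n_retained = nrow(x$tad_table),
    median_log2fc_A = x$group_summary_acf$median[x$group_summary_acf$group == "A"],
    median_log2fc_D = x$group_summary_acf$median[x$group_summary_acf$group == "D"],
    lad_track_median = x$track_changes$by_class$median[
      x$track_changes$by_class$lad_class == "LAD"],
    config_hash = x$config_hash
  )
}
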