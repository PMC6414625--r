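# Binned signal tracks, LAD/inter-LAD assignment, per-replicate sum
# normalisation with pseudocount, and log2 fold changes.

#' Bin a weighted interval signal
#'
#' Distributes each interval's weight over the bins it overlaps in proportion
#' to the overlap length, so total weight is conserved (after clipping to the
#' arm). Use for read coverage, transcription or ChIP signal.
#'
#' @param intervals Tibble with `start`, `end` (bp, 0-based half-open) and
#'   optionally `weight` (default 1 per interval).
#' @param bin_size Bin width in bp.
#' @param n_bins Number of bins on the arm.
#' @param log2 Return `log2(value + pseudocount)` instead of the linear sum.
#' @param pseudocount Added before the log (default: smallest positive bin
#'   value, 1 if all zero).
#' @return Tibble with `bin` (0-based) and `value`.
#' @export
bin_signal <- function(intervals, bin_size, n_bins, log2 = FALSE,
                       pseudocount = NULL) {
  vals <- numeric(n_bins)
  arm_end <- n_bins * bin_size
  if (nrow(intervals)) {
    w <- if ("weight" %in% names(intervals)) intervals$weight
         else rep(1, nrow(intervals))
    if (any(intervals$end > arm_end | intervals$start < 0)) {
      warn("Intervals extend beyond the arm; clipping.")
    }
    for (r in seq_len(nrow(intervals))) {
      s <- max(0, intervals$start[r]); e <- min(arm_end, intervals$end[r])
      if (e <= s) next
      len <- intervals$end[r] - intervals$start[r]
      b0 <- s %/% bin_size; b1 <- (e - 1) %/% bin_size
      for (b in b0:b1) {
        ov <- min(e, (b + 1) * bin_size) - max(s, b * bin_size)
        vals[b + 1] <- vals[b + 1] + w[r] * ov / len
      }
    }
  }
  if (log2) {
    if (is.null(pseudocount)) {
      pos <- vals[vals > 0]
      pseudocount <- if (length(pos)) min(pos) else 1
    }
    vals <- base::log2(vals + pseudocount)
  }
  tibble(bin = seq_len(n_bins) - 1L, value = vals)
}

#' Assign features to LADs or inter-LADs
#'
#' Genes are assigned by their TSS (strand-aware 5' end): inside a LAD ->
#' `LAD`; at least `min_dist` bp from every LAD -> `interLAD`; otherwise
#' `unassigned`. Regions/reads are assigned by overlap: any overlap with a
#' LAD -> `LAD`; at least `min_dist` away -> `interLAD`; otherwise
#' `unassigned`. The two classes deliberately do not tile the genome.
#'
#' @param features Tibble. For `kind = "gene"`: columns `start`, `end`,
#'   `strand` (`"+"`/`"-"`). For `kind = "region"`: columns `start`, `end`.
#' @param lads LAD interval tibble (bp); merged internally.
#' @param kind `"gene"` (TSS rule) or `"region"` (overlap rule).
#' @param min_dist Distance in bp defining "distant from LADs" (default 1000).
#' @return `features` with a `lad_class` column
#'   (`"LAD"`, `"interLAD"`, `"unassigned"`).
#' @export
assign_lad_class <- function(features, lads, kind = c("gene", "region"),
                             min_dist = 1000) {
  kind <- match.arg(kind)
  lads <- merge_intervals(lads)
  cls <- vapply(seq_len(nrow(features)), function(r) {
    if (kind == "gene") {
      if (is.null(features$strand)) abort("Gene features need a `strand` column.")
      st <- features$strand[r]
      if (!st %in% c("+", "-")) abort("Strand must be '+' or '-'.")
      tss <- if (st == "+") features$start[r] else features$end[r] - 1
      inside <- any(tss >= lads$start & tss < lads$end)
      if (inside) return("LAD")
      dist <- if (nrow(lads)) min(pmax(lads$start - tss, tss - lads$end + 1, 0))
              else Inf
      if (dist >= min_dist) "interLAD" else "unassigned"
    } else {
      s <- features$start[r]; e <- features$end[r]
      ovl <- any(pmin(e, lads$end) > pmax(s, lads$start))
      if (ovl) return("LAD")
      dist <- if (nrow(lads)) min(pmax(lads$start - e, s - lads$end, 0))
              else Inf
      if (dist >= min_dist) "interLAD" else "unassigned"
    }
  }, character(1))
  mutate(features, lad_class = cls)
}

#' Normalise replicates and compute log2 fold changes
#'
#' Each replicate column is divided by its total; features with zero signal
#' in every replicate are dropped; a pseudocount equal to the smallest
#' positive value of the pooled normalised table is added to every entry;
#' replicates are averaged per condition; `log2fc = log2(kd / control)`.
#'
#' @param values Tibble with a `feature_id` column plus one numeric column per
#'   replicate.
#' @param kd_cols,ctrl_cols Names of the knock-down and control replicate
#'   columns.
#' @return Tibble with `feature_id`, `mean_kd`, `mean_ctrl`, `log2fc`;
#'   the pseudocount used is attached as attribute `pseudocount`.
#' @export
normalize_and_log2fc <- function(values, kd_cols, ctrl_cols) {
  all_cols <- c(kd_cols, ctrl_cols)
  m <- as.matrix(values[, all_cols])
  if (any(colSums(m) == 0)) abort("A replicate has zero total signal.")
  m <- sweep(m, 2, colSums(m), "/")
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  pos <- m[m > 0]
  pc <- if (length(pos)) min(pos) else 1
  m <- m + pc
  mk <- rowMeans(m[, kd_cols, drop = FALSE])
  mc <- rowMeans(m[, ctrl_cols, drop = FALSE])
  out <- tibble(feature_id = values$feature_id[keep],
                mean_kd = mk, mean_ctrl = mc,
                log2fc = log2(mk / mc))
  attr(out, "pseudocount") <- pc
  out
}

#' LAD versus inter-LAD fold-change comparison
#'
#' Splits per-feature log2 fold changes by LAD class and reports
#' distribution summaries plus a two-sample Wilcoxon rank-sum test for a
#' location shift between the classes.
#'
#' @param log2fc Tibble with `log2fc` and `lad_class` columns (unassigned
#'   features are ignored).
#' @return A list with `by_class` (tibble: `lad_class`, `n`, `median`, `q25`,
#'   `q75`, `p_vs_zero`) and `p_between` (LAD vs inter-LAD location test;
#'   `NA` when a class is empty).
#' @export
lad_vs_interlad_change <- function(log2fc) {
  d <- filter(log2fc, .data$lad_class %in% c("LAD", "interLAD"),
              is.finite(.data$log2fc))
  by_class <- purrr::map_dfr(c("LAD", "interLAD"), function(cl) {
    v <- d$log2fc[d$lad_class == cl]
    tibble(lad_class = cl, n = length(v),
           median = if (length(v)) median(v) else NA_real_,
           q25 = if (length(v)) quantile(v, 0.25, names = FALSE) else NA_real_,
           q75 = if (length(v)) quantile(v, 0.75, names = FALSE) else NA_real_,
           p_vs_zero = if (length(v))
             suppressWarnings(wilcox.test(v)$p.value) else NA_real_)
  })
  v1 <- d$log2fc[d$lad_class == "LAD"]
  v2 <- d$log2fc[d$lad_class == "interLAD"]
  p <- if (length(v1) && length(v2))
    suppressWarnings(wilcox.test(v1, v2)$p.value) else NA_real_
  list(by_class = by_class, p_between = p)
}
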