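# ACF statistics, replicate concordance, LAD/chromatin composition,
# Jaccard ranking into groups A-D and group-level change summaries.

#' Average contact frequency within a TAD
#'
#' Mean corrected contact frequency over all unordered pairs of *interior*
#' bins of the TAD — the first and last bin are dropped from both sides, and
#' diagonal (self) pairs are excluded. TADs with fewer than two interior bins
#' have no defined ACF and return `NA` with a warning.
#'
#' @param map A corrected `contact_map`.
#' @param start_bin,end_bin TAD bounds, 0-based half-open bins.
#' @return Numeric scalar (or `NA`).
#' @export
acf_tad <- function(map, start_bin, end_bin) {
  if (end_bin - start_bin < 4L) {
    warn(sprintf("TAD [%d,%d) has < 2 interior bins; ACF undefined.",
                 start_bin, end_bin))
    return(NA_real_)
  }
  interior <- seq.int(start_bin + 2L, end_bin - 1L)  # 1-based matrix indices
  sub <- map$counts[interior, interior, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Average contact frequency within an inter-TAD
#'
#' Mean corrected contact frequency over all unordered pairs among the
#' inter-TAD bins plus the nearest boundary bin of each adjacent TAD
#' (diagonal excluded). An inter-TAD spanning the whole arm has no adjacent
#' TAD and returns `NA`.
#'
#' @param map A corrected `contact_map`.
#' @param start_bin,end_bin Inter-TAD bounds, 0-based half-open bins.
#' @param annotation The `domain_annotation` the segment belongs to.
#' @return Numeric scalar (or `NA`).
#' @export
acf_intertad <- function(map, start_bin, end_bin, annotation) {
  segs <- as_tibble(annotation)
  sb <- start_bin; eb <- end_bin      # avoid data-masking the arguments
  bins <- seq.int(sb + 1L, eb)        # 1-based
  left <- filter(segs, .data$label == "TAD", .data$end_bin == .env$sb)
  right <- filter(segs, .data$label == "TAD", .data$start_bin == .env$eb)
  if (nrow(left)) bins <- c(start_bin, bins)          # last bin of left TAD
  if (nrow(right)) bins <- c(bins, end_bin + 1L)      # first bin of right TAD
  if (nrow(left) + nrow(right) == 0L) {
    warn("inter-TAD has no adjacent TAD; ACF undefined.")
    return(NA_real_)
  }
  if (length(bins) < 2L) return(NA_real_)
  sub <- map$counts[bins, bins, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' ACF table over an annotation for several maps
#'
#' @param maps Named list of corrected `contact_map`s (e.g.
#'   `list(ctrl_1 = ..., ctrl_2 = ..., kd_1 = ...)`).
#' @param annotation A `domain_annotation`.
#' @param what `"TAD"` or `"interTAD"` segments.
#' @return Tibble with one row per segment: `tad_id`, `start_bin`, `end_bin`,
#'   and one `acf_<name>` column per map.
#' @export
acf_table <- function(maps, annotation, what = "TAD") {
  segs <- filter(as_tibble(annotation), .data$label == what)
  segs <- mutate(segs, tad_id = row_number())
  acfs <- map(maps, function(m) {
    vapply(seq_len(nrow(segs)), function(r) {
      if (what == "TAD") {
        suppressWarnings(acf_tad(m, segs$start_bin[r], segs$end_bin[r]))
      } else {
        suppressWarnings(acf_intertad(m, segs$start_bin[r], segs$end_bin[r],
                                      annotation))
      }
    }, numeric(1))
  })
  names(acfs) <- paste0("acf_", names(maps))
  bind_cols(select(segs, "tad_id", "start_bin", "end_bin"), as_tibble(acfs))
}

#' Replicate-concordance filter on ACF changes
#'
#' Forms the four ratios `KD_r / Ctrl_s` from two knock-down and two control
#' replicate ACFs. The direction of each ratio is the sign of its log2 (a
#' ratio of exactly 1 counts for neither side). A TAD is kept when at least
#' three ratios agree in direction (all four under `strict = TRUE`).
#'
#' @param acf_kd,acf_ctrl Numeric length-2: per-replicate ACFs.
#' @param strict Require all four ratios to agree.
#' @return A list with `keep` (logical) and `direction`
#'   (`"up"`, `"down"` or `"none"`).
#' @export
concordance_filter <- function(acf_kd, acf_ctrl, strict = FALSE) {
  stopifnot(length(acf_kd) == 2, length(acf_ctrl) == 2)
  if (any(!is.finite(c(acf_kd, acf_ctrl))) || any(c(acf_kd, acf_ctrl) <= 0)) {
    return(list(keep = FALSE, direction = "none"))
  }
  ratios <- as.vector(outer(acf_kd, acf_ctrl, "/"))
  s <- sign(log2(ratios))
  need <- if (strict) 4L else 3L
  if (sum(s > 0) >= need) {
    list(keep = TRUE, direction = "up")
  } else if (sum(s < 0) >= need) {
    list(keep = TRUE, direction = "down")
  } else {
    list(keep = FALSE, direction = "none")
  }
}

#' Fraction of a segment covered by an interval set
#'
#' Overlaps are clipped to the segment and merged before summing, so
#' overlapping annotation records are not double-counted.
#'
#' @param start_bp,end_bp Segment bounds in bp (0-based half-open).
#' @param intervals Tibble with `start`, `end` in bp.
#' @return Covered fraction in `[0, 1]`.
#' @export
interval_composition <- function(start_bp, end_bp, intervals) {
  stopifnot(end_bp > start_bp)
  covered_bp(intervals, start_bp, end_bp) / (end_bp - start_bp)
}

#' Jaccard score and A-D grouping of TADs
#'
#' For each TAD `T` the score is `|LAD ∩ T| / |(LAD ∪ active) ∩ T|` in bp
#' (0 when the denominator is 0): 0 for purely active, LAD-free TADs and 1
#' for fully lamina-associated, inactive ones. TADs are ranked by ascending
#' score and split into four equal-sized groups `A` (lowest) to `D`
#' (highest); group sizes differ by at most one and ties keep genomic order.
#'
#' @param tads Tibble with `start_bin`, `end_bin` (and any other columns,
#'   preserved).
#' @param lads,active Interval tibbles (bp) of LADs and active ("red" +
#'   "purple") chromatin.
#' @param bin_size Bin width in bp.
#' @return `tads` with `lad_coverage`, `active_prop`, `jaccard_score` and
#'   `group` columns added.
#' @export
jaccard_group <- function(tads, lads, active, bin_size = 20000L) {
  n <- nrow(tads)
  sc <- vapply(seq_len(n), function(r) {
    s <- tads$start_bin[r] * bin_size
    e <- tads$end_bin[r] * bin_size
    den <- covered_bp(union_intervals(lads, active), s, e)
    if (den == 0) return(0)
    covered_bp(lads, s, e) / den
  }, numeric(1))
  cov_lad <- vapply(seq_len(n), function(r) {
    interval_composition(tads$start_bin[r] * bin_size,
                         tads$end_bin[r] * bin_size, lads)
  }, numeric(1))
  cov_act <- vapply(seq_len(n), function(r) {
    interval_composition(tads$start_bin[r] * bin_size,
                         tads$end_bin[r] * bin_size, active)
  }, numeric(1))
  ord <- order(sc)                      # stable: ties keep genomic order
  grp <- character(n)
  grp[ord] <- LETTERS[ceiling(seq_len(n) / (n / 4))]
  mutate(tads, lad_coverage = cov_lad, active_prop = cov_act,
         jaccard_score = sc, group = grp)
}

#' Per-group distribution summary of log2 fold changes
#'
#' Summarises a per-TAD quantity (intra-TAD ACF log2FC, track log2FC, ...)
#' within the A-D groups: median, quartiles, variance, and a two-sided
#' Wilcoxon signed-rank test of symmetry around zero.
#'
#' @param tads Tibble with a `group` column and the value column.
#' @param value Name of the value column (default `"log2fc"`).
#' @return Tibble with one row per group: `group`, `n`, `median`, `q25`,
#'   `q75`, `variance`, `p_wilcoxon`.
#' @export
group_change_summary <- function(tads, value = "log2fc") {
  v <- tads[[value]]
  summarise(
    group_by(tibble(group = tads$group, v = v), .data$group),
    n = sum(is.finite(.data$v)),
    median = median(.data$v[is.finite(.data$v)]),
    q25 = quantile(.data$v[is.finite(.data$v)], 0.25, names = FALSE),
    q75 = quantile(.data$v[is.finite(.data$v)], 0.75, names = FALSE),
    variance = if (sum(is.finite(.data$v)) > 1) var(.data$v[is.finite(.data$v)])
               else NA_real_,
    p_wilcoxon = if (sum(is.finite(.data$v)) > 0)
      suppressWarnings(wilcox.test(.data$v[is.finite(.data$v)])$p.value)
    else NA_real_,
    .groups = "drop"
  )
}
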