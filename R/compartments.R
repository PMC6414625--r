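# A/B compartment annotation (PC1), saddle plots and contact-change
# statistics between and within the active/inactive chromatin fractions.

#' First principal component of an O/E map
#'
#' Computes PC1 of the Pearson correlation matrix of the observed/expected
#' map over unmasked bins — the standard compartment caller. The sign of an
#' eigenvector is arbitrary, so the track is oriented against a reference
#' (typically binned transcription): if the correlation with the reference is
#' negative the PC1 is negated, making positive values correspond to active
#' chromatin.
#'
#' @param oe An O/E `contact_map` (see [observed_over_expected()]).
#' @param orientation Numeric per-bin reference track (same binning), used
#'   only for the sign. `NULL` leaves the sign as computed.
#' @param ignore_diags Short-range diagonals (`|i - j| <= ignore_diags`)
#'   excluded from the correlation (default 2): they carry TAD-scale, not
#'   compartment-scale, structure.
#' @param clip_quantile Upper winsorising quantile applied to O/E before the
#'   correlation (default 0.995). O/E is heavy-tailed at weakly covered long
#'   ranges — single stray counts over a tiny expected value — and Pearson
#'   correlation is not robust to those outliers.
#' @return Tibble with columns `bin` (0-based) and `pc1` (`NA` on masked
#'   bins).
#' @export
compute_pc1 <- function(oe, orientation = NULL, ignore_diags = 2L,
                        clip_quantile = 0.995) {
  keep <- !oe$mask
  sub <- oe$counts[keep, keep, drop = FALSE]
  sub[abs(row(sub) - col(sub)) <= ignore_diags] <- NA_real_
  hi <- quantile(sub, clip_quantile, na.rm = TRUE)
  sub[sub > hi] <- hi
  cm <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  pca <- prcomp(cm, center = TRUE, scale. = FALSE)
  if (pca$sdev[1] <= 1e-12) abort("Degenerate O/E map: no principal component.")
  v <- pca$x[, 1]
  pc1 <- rep(NA_real_, n_bins(oe))
  pc1[keep] <- v
  if (!is.null(orientation)) {
    r <- suppressWarnings(cor(pc1, orientation, use = "complete.obs"))
    if (is.finite(r) && r < 0) pc1 <- -pc1
  }
  tibble(bin = seq_len(n_bins(oe)) - 1L, pc1 = pc1)
}

#' Saddle plot of compartmentalisation
#'
#' Unmasked bins are ordered by increasing PC1 (ties broken by bin index),
#' split into `n_quantiles` equal-count groups, and each cell `(p, q)` is the
#' log2 of the mean O/E over unmasked pairs with one bin in group `p` and one
#' in group `q` (diagonal pairs excluded).
#'
#' @param oe An O/E `contact_map`.
#' @param pc1 Output of [compute_pc1()] (control PC1 by convention, also for
#'   the knock-down map).
#' @param n_quantiles Number of aggregated bins (default 20).
#' @return A `saddle_matrix`: numeric `n_quantiles` x `n_quantiles` matrix of
#'   log2 enrichment with a `quantile_bins` attribute (the per-bin quantile
#'   assignment used).
#' @export
saddle <- function(oe, pc1, n_quantiles = 20L) {
  keep <- !oe$mask & is.finite(pc1$pc1)
  idx <- which(keep)
  if (length(idx) < n_quantiles) {
    abort(sprintf("Need at least %d unmasked bins for a saddle plot.",
                  n_quantiles))
  }
  ord <- idx[order(pc1$pc1[idx])]        # stable sort: ties keep bin order
  qa <- integer(n_bins(oe))              # 0 = unused
  qa[ord] <- ceiling(seq_along(ord) / (length(ord) / n_quantiles))
  s <- matrix(NA_real_, n_quantiles, n_quantiles)
  oec <- oe$counts
  diag(oec) <- NA_real_
  for (p in seq_len(n_quantiles)) {
    bp <- which(qa == p)
    for (q in p:n_quantiles) {
      bq <- which(qa == q)
      vals <- oec[bp, bq, drop = FALSE]
      s[p, q] <- s[q, p] <- log2(mean(vals, na.rm = TRUE))
    }
  }
  structure(s, quantile_bins = qa, class = c("saddle_matrix", "matrix", "array"))
}

#' Subtract two saddle plots
#'
#' Elementwise `kd - ctrl`; both saddles must have been built on the same
#' quantile assignment (the control PC1 ordering).
#'
#' @param kd,ctrl `saddle_matrix` objects.
#' @return A `saddle_matrix` of differences.
#' @export
saddle_subtract <- function(kd, ctrl) {
  if (!identical(attr(kd, "quantile_bins"), attr(ctrl, "quantile_bins"))) {
    abort("Saddle plots built on different quantile assignments.")
  }
  out <- unclass(kd) - unclass(ctrl)
  structure(out, quantile_bins = attr(kd, "quantile_bins"),
            class = class(kd))
}

#' @export
tidy.saddle_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "quantile_bins") <- NULL
  as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal") |>
    setNames(c("quantile_row", "quantile_col", "log2_enrichment")) |>
    mutate(quantile_row = as.integer(.data$quantile_row),
           quantile_col = as.integer(.data$quantile_col))
}

#' Contact changes within and between chromatin fractions
#'
#' Classifies unmasked bin pairs by the control PC1 sign (active: PC1 > 0,
#' inactive: PC1 < 0) and collects the per-pair `log2(O/E_kd / O/E_ctrl)`
#' into within-active, within-inactive and between-fraction distributions.
#' Diagonal pairs and pairs missing in either map are skipped.
#'
#' @param oe_kd,oe_ctrl O/E `contact_map`s on the same binning.
#' @param pc1 Control PC1 (see [compute_pc1()]).
#' @return A list with `changes` (tibble: `class`, `log2fc`) and `summary`
#'   (tibble per class: `n`, `median`, `q25`, `q75`, `p_wilcoxon`). Empty
#'   classes appear in `summary` with `n = 0`.
#' @export
ab_contact_changes <- function(oe_kd, oe_ctrl, pc1) {
  n <- n_bins(oe_ctrl)
  lab <- ifelse(pc1$pc1 > 0, "A", ifelse(pc1$pc1 < 0, "B", NA))
  ut <- upper.tri(oe_ctrl$counts)         # excludes the diagonal
  i <- row(oe_ctrl$counts)[ut]; j <- col(oe_ctrl$counts)[ut]
  fc <- log2(oe_kd$counts[ut] / oe_ctrl$counts[ut])
  cls <- dplyr::case_when(
    is.na(lab[i]) | is.na(lab[j]) ~ NA_character_,
    lab[i] == "A" & lab[j] == "A" ~ "within_active",
    lab[i] == "B" & lab[j] == "B" ~ "within_inactive",
    TRUE ~ "between"
  )
  ok <- is.finite(fc) & !is.na(cls)
  changes <- tibble(class = cls[ok], log2fc = fc[ok])
  all_classes <- c("within_active", "within_inactive", "between")
  summary <- purrr::map_dfr(all_classes, function(cl) {
    v <- changes$log2fc[changes$class == cl]
    tibble(class = cl, n = length(v),
           median = if (length(v)) median(v) else NA_real_,
           q25 = if (length(v)) quantile(v, 0.25, names = FALSE) else NA_real_,
           q75 = if (length(v)) quantile(v, 0.75, names = FALSE) else NA_real_,
           p_wilcoxon = if (length(v))
             suppressWarnings(wilcox.test(v)$p.value) else NA_real_)
  })
  list(changes = changes, summary = summary)
}
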