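# Synthetic-data generator: contact maps with planted TADs, compartments and
# biases; LAD/active-chromatin annotations; gene tracks with a planted
# LAD-specific shift. Every generator is deterministic given the spec seed.

#' Specification for synthetic data
#'
#' Collects every knob of the generator: arm geometry, planted TAD layout,
#' distance decay, planted effect sizes for the knock-down condition, noise
#' scales and the master seed. Defaults emulate a single fly chromosome arm
#' at 20-kb bins with detectable but non-trivial structure.
#'
#' @param n_bins Bins on the arm (default 500).
#' @param bin_size Bin width in bp (default 20000).
#' @param decay_exponent Contact decay exponent `alpha`:
#'   expected contacts fall off as `(s + 1)^-alpha` (default 1).
#' @param tad_boost Multiplicative intra-TAD contact boost `beta_T`
#'   (default 3).
#' @param compartment_strength Same-compartment contact boost `k`
#'   (default 1.6).
#' @param depth Total contacts per map (default 2e5).
#' @param bias_sdlog Log-normal sd of the planted per-bin biases
#'   (default 0.25).
#' @param mult_A,mult_D Knock-down intra-TAD contact multipliers for truth
#'   groups A and D (defaults 1.2 and 0.8) — the planted density changes.
#' @param mixing_mult Knock-down multiplier on between-compartment contacts
#'   (default 1: no compartment blurring planted).
#' @param delta_lad Planted LAD-specific log2 shift of the knock-down
#'   expression tracks (default 0.5).
#' @param n_genes Genes on the arm (default 1000, the gene density
#'   of a ~10-Mb fly arm).
#' @param lad_expr_mean,interlad_expr_mean Baseline expression scale of LAD
#'   and inter-LAD genes (defaults 1 and 100: background transcription inside
#'   lamina-associated chromatin is very weak).
#' @param expr_sdlog Between-gene log-normal spread of baseline expression
#'   (default 1).
#' @param gene_noise_sdlog Per-replicate log-normal expression noise
#'   (default 0.15, the technical spread of a well-sequenced RNA-seq
#'   replicate).
#' @param tad_len_range Planted TAD lengths in bins (default 5 to 25).
#' @param gap_len_range Planted inter-TAD gaps in bins (default 1 to 2).
#' @param lamina_autocor AR(1) coefficient of the per-TAD lamina fraction
#'   along the arm (default 0.6): lamina association clusters into
#'   contiguous blocks of TADs, as LADs do on real chromosomes.
#' @param n_replicates Replicates per condition (default 2).
#' @param seed Master seed; all generators derive their streams from it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_bins = 500L, bin_size = 20000L,
                       decay_exponent = 1, tad_boost = 3,
                       compartment_strength = 1.6, depth = 2e5,
                       bias_sdlog = 0.25, mult_A = 1.2, mult_D = 0.8,
                       mixing_mult = 1, delta_lad = 0.5, n_genes = 1000L,
                       lad_expr_mean = 1, interlad_expr_mean = 100,
                       expr_sdlog = 1, gene_noise_sdlog = 0.15, tad_len_range = c(5L, 25L),
                       gap_len_range = c(1L, 2L), lamina_autocor = 0.6,
                       n_replicates = 2L,
                       seed = 1L) {
  structure(as.list(environment()), class = "synth_spec")
}

# Deterministic planted layout: TAD segments, per-TAD lamina fraction and
# truth group, per-bin compartment label, LAD and active interval sets.
synth_layout <- function(spec) {
  with_rng_seed(spec$seed, {
    tads <- list()
    pos <- 0L
    repeat {
      len <- sample(spec$tad_len_range[1]:spec$tad_len_range[2], 1)
      if (pos + len > spec$n_bins - 2L) break
      tads[[length(tads) + 1L]] <- c(pos, pos + len)
      pos <- pos + len + sample(spec$gap_len_range[1]:spec$gap_len_range[2], 1)
    }
    tads <- do.call(rbind, tads)
    nt <- nrow(tads)
    # lamina fraction per TAD: AR(1) latent series -> uniform margins, so
    # lamina-associated TADs cluster into contiguous blocks
    rho <- spec$lamina_autocor
    zz <- numeric(nt)
    zz[1] <- rnorm(1)
    for (t in seq_len(nt)[-1]) zz[t] <- rho * zz[t - 1] + sqrt(1 - rho^2) * rnorm(1)
    zz <- (zz - mean(zz)) / sd(zz)       # stable ~50% lamina share per arm
    lam <- pnorm(zz)
    truth_group <- character(nt)
    truth_group[order(lam)] <- LETTERS[ceiling(seq_len(nt) / (nt / 4))]

    bs <- spec$bin_size
    lad_iv <- tibble(start = tads[, 1] * bs,
                     end = (tads[, 1] + (tads[, 2] - tads[, 1]) * lam) * bs)
    lad_iv <- filter(lad_iv, .data$end > .data$start)
    lad_iv <- mutate(lad_iv, start = round(.data$start), end = round(.data$end))
    act_len <- (tads[, 2] - tads[, 1]) * (1 - lam) * 0.6
    act_iv <- tibble(start = round((tads[, 2] - act_len) * bs),
                     end = tads[, 2] * bs)
    act_iv <- filter(act_iv, .data$end > .data$start)
    comp <- rep("A", spec$n_bins)          # per-bin compartment truth
    tad_of_bin <- rep(NA_integer_, spec$n_bins)
    for (t in seq_len(nt)) {
      b <- (tads[t, 1] + 1L):tads[t, 2]
      tad_of_bin[b] <- t
      if (lam[t] > 0.5) comp[b] <- "B"
    }
    # gaps buried inside an inactive block stay inactive; the rest are
    # active chromatin (inter-TADs are the most active regions)
    gap_b <- c(lam > 0.5, TRUE) & c(TRUE, lam > 0.5)   # both neighbours B
    gaps <- tibble(start = c(0L, tads[, 2]) * bs,
                   end = c(tads[, 1], spec$n_bins) * bs,
                   buried = gap_b)
    gaps <- filter(gaps, .data$end > .data$start)
    for (r in which(gaps$buried)) {
      b <- (gaps$start[r] %/% bs + 1L):(gaps$end[r] %/% bs)
      comp[b] <- "B"
    }
    act_iv <- merge_intervals(bind_rows(act_iv,
                                        select(filter(gaps, !.data$buried),
                                               "start", "end")))
    list(
      tads = tibble(tad_id = seq_len(nt), start_bin = tads[, 1],
                    end_bin = tads[, 2], lamina_frac = lam,
                    truth_group = truth_group),
      tad_of_bin = tad_of_bin,
      compartment = comp,
      lads = lad_iv,
      active = act_iv
    )
  })
}

# run code under a temporary RNG state
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# small deterministic sub-seed for a labelled stream
sub_seed <- function(seed, label) {
  (as.integer(seed) * 97L + sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) * 131L) %% 2000000011L
}

#' Expected (noise-free) contact intensity of the planted model
#'
#' `lambda_ij` proportional to `(|i-j| + 1)^-alpha * beta_T^[same TAD] *
#' k^[same compartment] * m_cond(i, j)`, scaled so the total over the upper
#' triangle equals `depth`. Used by [make_hic()] and by tests as a
#' closed-form oracle.
#'
#' @param spec A `synth_spec`.
#' @param condition `"control"` or `"kd"`.
#' @return List with `lambda` (n x n symmetric matrix, bias-free) and
#'   `layout`.
#' @export
synth_lambda <- function(spec, condition = c("control", "kd")) {
  condition <- match.arg(condition)
  lay <- synth_layout(spec)
  n <- spec$n_bins
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  w <- (s + 1)^(-spec$decay_exponent)
  tb <- lay$tad_of_bin
  same_tad <- outer(tb, tb, function(a, b) !is.na(a) & !is.na(b) & a == b)
  w[same_tad] <- w[same_tad] * spec$tad_boost
  same_comp <- outer(lay$compartment, lay$compartment, "==")
  w[same_comp] <- w[same_comp] * spec$compartment_strength
  if (condition == "kd") {
    for (g in c("A", "D")) {
      mult <- if (g == "A") spec$mult_A else spec$mult_D
      ids <- lay$tads$tad_id[lay$tads$truth_group == g]
      sel <- !is.na(tb) & tb %in% ids
      block <- outer(sel, sel, "&") & same_tad
      w[block] <- w[block] * mult
    }
    if (spec$mixing_mult != 1) {
      w[!same_comp] <- w[!same_comp] * spec$mixing_mult
    }
  }
  tot <- sum(w[upper.tri(w, diag = TRUE)])
  list(lambda = w * spec$depth / tot, layout = lay)
}

#' Simulate a raw Hi-C contact map
#'
#' Draws Poisson counts around the planted intensity [synth_lambda()], after
#' multiplying in log-normal per-bin biases (redrawn per replicate). Counts
#' are drawn on the upper triangle and mirrored, so the map is symmetric by
#' construction.
#'
#' @inheritParams synth_lambda
#' @param replicate Replicate id (1, 2, ...).
#' @return A raw `contact_map`.
#' @export
make_hic <- function(spec, condition = c("control", "kd"), replicate = 1L) {
  condition <- match.arg(condition)
  sl <- synth_lambda(spec, condition)
  n <- spec$n_bins
  with_rng_seed(sub_seed(spec$seed, paste0("hic_", condition, "_", replicate)), {
    b <- rlnorm(n, 0, spec$bias_sdlog)
    lam <- sl$lambda * outer(b, b)
    ut <- upper.tri(lam, diag = TRUE)
    cnt <- matrix(0, n, n)
    cnt[ut] <- rpois(sum(ut), lam[ut])
    cnt <- cnt + t(cnt) - diag(diag(cnt))
    contact_map(cnt, bin_size = spec$bin_size,
                arm_id = paste0("synth_", condition, "_", replicate))
  })
}

#' Planted annotations of the synthetic arm
#'
#' @param spec A `synth_spec`.
#' @return List with `tads` (truth table: bounds, lamina fraction, truth
#'   group), `lads` and `active` interval tibbles (bp), and `compartment`
#'   (per-bin truth label `"A"`/`"B"`).
#' @export
make_annotations <- function(spec) {
  lay <- synth_layout(spec)
  lay[c("tads", "lads", "active", "compartment")]
}

#' Simulate gene expression tracks
#'
#' Genes are scattered over the arm; baseline expression is low for
#' LAD genes and higher outside (weak background transcription inside
#' lamina-associated chromatin). In the knock-down condition LAD genes are
#' shifted up by `delta_lad` log2 units. Per-replicate multiplicative noise
#' is applied.
#'
#' @inheritParams make_hic
#' @return List with `genes` (tibble: `feature_id`, `start`, `end`, `strand`,
#'   `lad_class` truth, `value`) and `bins` (per-bin transcription track from
#'   [bin_signal()]).
#' @export
make_tracks <- function(spec, condition = c("control", "kd"), replicate = 1L) {
  condition <- match.arg(condition)
  lay <- synth_layout(spec)
  arm_bp <- spec$n_bins * spec$bin_size
  genes <- with_rng_seed(sub_seed(spec$seed, "genes"), {
    start <- sort(sample.int(arm_bp - 10000L, spec$n_genes))
    tibble(feature_id = sprintf("g%04d", seq_len(spec$n_genes)),
           start = start, end = start + sample(2000:8000, spec$n_genes,
                                               replace = TRUE),
           strand = sample(c("+", "-"), spec$n_genes, replace = TRUE))
  })
  genes <- assign_lad_class(genes, lay$lads, kind = "gene")
  base <- with_rng_seed(sub_seed(spec$seed, "gene_base"), {
    ifelse(genes$lad_class == "LAD", spec$lad_expr_mean,
           spec$interlad_expr_mean) * rlnorm(spec$n_genes, 0, spec$expr_sdlog)
  })
  val <- with_rng_seed(sub_seed(spec$seed,
                             paste0("expr_", condition, "_", replicate)), {
    shift <- if (condition == "kd") {
      ifelse(genes$lad_class == "LAD", 2^spec$delta_lad, 1)
    } else 1
    base * shift * rlnorm(spec$n_genes, 0, spec$gene_noise_sdlog)
  })
  genes <- mutate(genes, value = val)
  bins <- bin_signal(mutate(genes, weight = val), spec$bin_size, spec$n_bins)
  list(genes = genes, bins = bins)
}
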