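# R surface of the DPD polymer simulator: parameters, runs, block-level
# structural analysis and the ensemble distance map.

#' Simulation parameters for the DPD polymer model
#'
#' The model is a bead-and-spring block copolymer in explicit solvent near an
#' attractive wall (the lamina). Each block carries a run of "inactive"
#' (sticky, non-acetylated) particles followed by a short run of "active"
#' (inert, acetylated) ones. Inactive particles form reversible *saturating*
#' bonds — at most one per particle at a time — with each other and with the
#' wall; bonds are re-examined every `check_interval` steps.
#'
#' The published-scale system is `box = c(50, 50, 50)` at `density = 3`
#' (375,000 particles, 64 blocks of 500 + 50). The default here is a
#' desk-scale system with the same physics.
#'
#' @param box Box lengths in DPD units.
#' @param density Particles per unit volume (default 3); solvent fills the
#'   box to this density.
#' @param n_blocks Blocks in the copolymer.
#' @param inactive_per_block,active_per_block Particles per block.
#' @param p_bond_pp Per-check bond-creation probability between two inactive
#'   particles (default 0.001).
#' @param p_bond_ps Creation probability between an inactive particle and the
#'   wall (default 0.007).
#' @param p_break Per-check break probability of an existing bond
#'   (default 0.01).
#' @param check_interval DPD steps between bond updates (default 200).
#' @param dt Integration step (default 0.04).
#' @param a_rep Conservative repulsion amplitude (default 25).
#' @param friction_gamma Dissipative friction (default 4.5); the random-force
#'   amplitude is tied to it by the fluctuation-dissipation relation
#'   `sigma^2 = 2 * friction_gamma * kT`.
#' @param kT Thermostat temperature (default 1).
#' @param r_cut Interaction cutoff (default 1).
#' @param spring_k Harmonic spring constant for backbone and reversible bonds
#'   (default 4, zero rest length).
#' @param n_steps Steps per run.
#' @param n_runs Independent runs (published scale: 10).
#' @param snapshot_interval Steps between recorded snapshots.
#' @param wall Build the attractive wall (default `TRUE`).
#' @param init_near_wall Start the chain in the wall-adjacent half of the
#'   box (default `TRUE`), putting the surface within diffusive reach at
#'   desk scale; set `FALSE` for null controls so the chain equilibrates
#'   free of the wall.
#' @param no_solvent Omit solvent particles (for toy configurations).
#' @param seed Base seed; run `r` uses `seed + r - 1`.
#' @return A `sim_params` list.
#' @export
sim_params <- function(box = c(16, 16, 16), density = 3, n_blocks = 8L,
                       inactive_per_block = 55L, active_per_block = 5L,
                       p_bond_pp = 0.001, p_bond_ps = 0.007, p_break = 0.01,
                       check_interval = 200L, dt = 0.04, a_rep = 25,
                       friction_gamma = 4.5, kT = 1, r_cut = 1,
                       spring_k = 4, n_steps = 60000L, n_runs = 3L,
                       snapshot_interval = 2000L, wall = TRUE,
                       init_near_wall = TRUE, no_solvent = FALSE, seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$density > 0, all(p$box > 0),
            p$p_bond_pp >= 0, p$p_bond_pp <= 1,
            p$p_bond_ps >= 0, p$p_bond_ps <= 1,
            p$p_break >= 0, p$p_break <= 1)
  p$noise_sigma <- sqrt(2 * friction_gamma * kT)   # fluctuation-dissipation
  p$track_momentum <- FALSE
  structure(p, class = "sim_params")
}

#' Total particle count implied by the parameters
#'
#' `density * box volume`, the invariant the solvent filling enforces.
#'
#' @param params A `sim_params`.
#' @return Integer particle count.
#' @export
total_particles <- function(params) {
  round(params$density * prod(params$box))
}

#' Run DPD simulations
#'
#' Alternates `check_interval` integration steps with one reversible-bond
#' update, recording chain snapshots every `snapshot_interval` steps. Runs
#' are independent with seeds `seed, seed + 1, ...`; the same seed gives a
#' bit-identical trajectory.
#'
#' @param params A `sim_params`.
#' @param track_momentum Record the maximal total-momentum magnitude seen
#'   (diagnostic for the wall-free periodic configuration).
#' @return A `dpd_runs` list: one element per run, each with `snapshots`
#'   (list of `n_chain` x 3 position matrices), `snap_steps`, `temps`,
#'   `chain_types` (1 inactive, 2 active), `bonds_pp`/`bonds_ps` traces,
#'   `max_momentum` and `n_particles`; parameters attached as attribute.
#' @export
run_simulation <- function(params, track_momentum = FALSE) {
  stopifnot(is(params, "sim_params"))
  p <- unclass(params)
  p$track_momentum <- isTRUE(track_momentum)
  runs <- lapply(seq_len(params$n_runs), function(r) {
    dpd_engine(p, as.integer(params$n_steps), as.double(params$seed + r - 1))
  })
  structure(runs, params = params, class = "dpd_runs")
}

# block index (1-based) and within-block inactive flag for chain particles
chain_blocks <- function(params) {
  per <- params$inactive_per_block + params$active_per_block
  idx <- seq_len(params$n_blocks * per) - 1L
  tibble(particle = idx + 1L,
         block = idx %/% per + 1L,
         inactive = (idx %% per) < params$inactive_per_block)
}

#' Per-block structural summary of a snapshot
#'
#' For each inactive (sticky) block: the number of particles within `r_cut`
#' of the wall plane (`n_surface_contacts`), the number of non-backbone
#' particle pairs within `r_cut` (`n_intra_contacts`), the gyration-tensor
#' eigenvalues, an ellipsoid-equivalent volume proxy
#' `(4*pi/3) * sqrt(27 * l1 * l2 * l3)`, the oblateness `l3 / sqrt(l1 * l2)`
#' (small = pancake), the block centre's wall distance, and the LAD flag
#' (attached by at least one particle).
#'
#' @param positions `n_chain` x 3 matrix of chain positions (one snapshot).
#' @param params The `sim_params` used for the run.
#' @return Tibble, one row per block.
#' @export
block_summary <- function(positions, params) {
  cb <- chain_blocks(params)
  rc <- params$r_cut
  purrr::map_dfr(seq_len(params$n_blocks), function(b) {
    rows <- cb$particle[cb$block == b & cb$inactive]
    pos <- positions[rows, , drop = FALSE]
    nsc <- sum(pos[, 3] <= rc)
    d <- as.matrix(stats::dist(pos))
    near <- d < rc & upper.tri(d)
    # backbone neighbours are consecutive rows: exclude |i-j| == 1
    adj <- abs(row(d) - col(d)) == 1
    nic <- sum(near & !adj)
    ctr <- colMeans(pos)
    cen <- sweep(pos, 2, ctr)
    gyr <- crossprod(cen) / nrow(pos)
    ev <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    tibble(block = b,
           n_surface_contacts = nsc,
           n_intra_contacts = nic,
           lambda1 = ev[1], lambda2 = ev[2], lambda3 = ev[3],
           volume_proxy = 4 * pi / 3 * sqrt(prod(ev)) * 3^1.5,
           oblateness = ev[3] / sqrt(ev[1] * ev[2]),
           wall_distance = ctr[3],
           is_lad = nsc >= 1)
  })
}

#' Block summaries over the equilibrated part of all runs
#'
#' Applies [block_summary()] to every retained snapshot of every run,
#' discarding the first `burn_frac` of each trajectory as equilibration.
#'
#' @param runs A `dpd_runs` object.
#' @param burn_frac Fraction of snapshots discarded from the start
#'   (default 0.5).
#' @return Tibble with `run`, `snapshot`, and the [block_summary()] columns.
#' @export
analyze_runs <- function(runs, burn_frac = 0.5) {
  params <- attr(runs, "params")
  purrr::map_dfr(seq_along(runs), function(r) {
    snaps <- runs[[r]]$snapshots
    keep <- seq_along(snaps) > floor(length(snaps) * burn_frac)
    purrr::map_dfr(which(keep), function(s) {
      mutate(block_summary(snaps[[s]], params), run = r, snapshot = s,
             .before = 1)
    })
  })
}

#' Ensemble mean distance map of the chain
#'
#' Coarse-grains the chain into consecutive segments of `coarse_grain`
#' particles (segment position = centroid) and averages the pairwise 3D
#' distance matrix over the retained snapshots of all runs.
#'
#' @param runs A `dpd_runs` object (or a list of snapshot matrices).
#' @param coarse_grain Particles per segment (default 10).
#' @param burn_frac Fraction of snapshots discarded (default 0.5).
#' @return Symmetric matrix of mean distances.
#' @export
ensemble_distance_map <- function(runs, coarse_grain = 10L, burn_frac = 0.5) {
  snaps <- if (is(runs, "dpd_runs")) {
    unlist(lapply(runs, function(r) {
      s <- r$snapshots
      s[seq_along(s) > floor(length(s) * burn_frac)]
    }), recursive = FALSE)
  } else runs
  stopifnot(length(snaps) >= 1)
  nc <- nrow(snaps[[1]])
  nseg <- nc %/% coarse_grain
  seg_of <- rep(seq_len(nseg), each = coarse_grain)[seq_len(nc)]
  acc <- matrix(0, nseg, nseg)
  for (s in snaps) {
    cent <- apply(s[seq_along(seg_of), , drop = FALSE], 2, function(col) {
      tapply(col, seg_of, mean)
    })
    acc <- acc + as.matrix(stats::dist(cent))
  }
  acc / length(snaps)
}

#' Fig-style attachment trends from block summaries
#'
#' Summarises the structural consequences of surface attachment: Spearman
#' correlations of surface contacts with intra-block contacts and with block
#' volume, and the mean oblateness of attached versus detached blocks.
#'
#' @param blocks Output of [analyze_runs()].
#' @return One-row tibble: `cor_contacts` (surface vs intra-block contacts),
#'   `cor_volume` (surface vs volume proxy), `oblateness_attached`,
#'   `oblateness_detached`, `n_attached`, `n_detached`.
#' @export
attachment_trends <- function(blocks) {
  tibble(
    cor_contacts = suppressWarnings(
      cor(blocks$n_surface_contacts, blocks$n_intra_contacts,
          method = "spearman")),
    cor_volume = suppressWarnings(
      cor(blocks$n_surface_contacts, blocks$volume_proxy,
          method = "spearman")),
    oblateness_attached = mean(blocks$oblateness[blocks$is_lad]),
    oblateness_detached = mean(blocks$oblateness[!blocks$is_lad]),
    n_attached = sum(blocks$is_lad),
    n_detached = sum(!blocks$is_lad)
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> box %s, density %g -> %d particles; %d blocks of %d+%d; %d steps x %d runs\n",
    paste(x$box, collapse = "x"), x$density, total_particles(x),
    x$n_blocks, x$inactive_per_block, x$active_per_block,
    x$n_steps, x$n_runs))
  invisible(x)
}

#' Two-particle bond-kinetics toy
#'
#' Holds two isolated inactive particles at a fixed separation inside
#' `r_cut` and runs repeated reversible-bond updates through the simulator's
#' own code path. The bonded indicator follows a two-state Markov chain with
#' on-rate `p_on` and off-rate `p_off` per check, so its stationary mean is
#' `p_on / (p_on + p_off)`.
#'
#' @param p_on,p_off Per-check creation / break probabilities.
#' @param n_checks Number of bond updates.
#' @param seed RNG seed.
#' @return Integer vector of per-check bonded indicators.
#' @export
bond_toy <- function(p_on = 0.001, p_off = 0.01, n_checks = 1e5, seed = 1L) {
  bond_kinetics_toy(p_on, p_off, as.integer(n_checks), as.double(seed))
}
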