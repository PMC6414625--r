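# Contact-map data model, I/O, ICE balancing, expected-by-distance and O/E.

#' Construct a binned cis contact map
#'
#' A `contact_map` holds a symmetric, non-negative contact matrix for one
#' chromosome arm at a fixed bin size, together with a per-bin exclusion mask.
#' Bins are 0-based, half-open: bin `i` covers `[i * bin_size, (i + 1) * bin_size)`.
#'
#' @param counts Symmetric numeric matrix of raw counts or corrected
#'   frequencies. Must be finite and non-negative.
#' @param bin_size Bin width in bp.
#' @param arm_id Chromosome-arm label.
#' @param mask Logical vector, `TRUE` marks an excluded bin. Masked rows and
#'   columns are zeroed.
#' @param corrected Has the matrix been balanced (ICE) already?
#'
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(counts, bin_size = 20000L, arm_id = "arm",
                        mask = NULL, corrected = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    abort("`counts` must be square.")
  }
  if (any(!is.finite(counts))) {
    abort("`counts` must be finite.")
  }
  if (any(counts < 0)) {
    abort("`counts` must be non-negative.")
  }
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts)))) {
    abort("`counts` must be symmetric.")
  }
  counts <- (counts + t(counts)) / 2   # exact symmetry
  n <- nrow(counts)
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(mask) == n)
  if (any(mask)) {
    counts[mask, ] <- 0
    counts[, mask] <- 0
  }
  dimnames(counts) <- NULL
  structure(
    list(counts = counts, bin_size = as.integer(bin_size), arm_id = arm_id,
         mask = mask, corrected = isTRUE(corrected)),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "<contact_map> arm %s: %d bins x %d bp (%s), %d masked, total %.4g\n",
    x$arm_id, n_bins(x), x$bin_size,
    if (x$corrected) "corrected" else "raw",
    sum(x$mask), sum(x$counts) / 2 + sum(diag(x$counts)) / 2
  ))
  invisible(x)
}

#' Number of bins of a contact map
#' @param map A `contact_map`.
#' @return Integer bin count.
#' @export
n_bins <- function(map) nrow(map$counts)

#' Read a contact map from disk
#'
#' Two plain-text layouts are supported. `"dense-tsv"` is an n-by-n tab-separated
#' matrix whose header row carries the bin start coordinates. `"coo-tsv"` holds
#' sparse triplets `bin_i TAB bin_j TAB count` (0-based bins); duplicate
#' `(i, j)`/`(j, i)` triplets are summed and missing entries are zero.
#'
#' @param path File to read.
#' @param format `"dense-tsv"` or `"coo-tsv"`.
#' @param n_bins Bin count, required for COO input.
#' @inheritParams contact_map
#' @return A `contact_map` with raw counts.
#' @export
read_contact_map <- function(path, format = c("coo-tsv", "dense-tsv"),
                             n_bins = NULL, bin_size = 20000L, arm_id = "arm") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (format == "dense-tsv") {
    m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
    storage.mode(m) <- "double"
    return(contact_map(m, bin_size = bin_size, arm_id = arm_id))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    abort(sprintf("Malformed COO line %d in %s: expected 3 fields", bad[1], path))
  }
  rec <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 3, byrow = TRUE)
  nonnum <- which(!is.finite(rec[, 1]) | !is.finite(rec[, 2]) | !is.finite(rec[, 3]))
  if (length(nonnum)) {
    abort(sprintf("Malformed COO line %d in %s: non-numeric field", nonnum[1], path))
  }
  if (any(rec[, 3] < 0)) {
    abort(sprintf("Negative count at COO line %d", which(rec[, 3] < 0)[1]))
  }
  if (is.null(n_bins)) n_bins <- as.integer(max(rec[, 1:2])) + 1L
  if (any(rec[, 1:2] >= n_bins) || any(rec[, 1:2] < 0)) {
    abort("COO bin index out of range.")
  }
  m <- matrix(0, n_bins, n_bins)
  for (r in seq_len(nrow(rec))) {
    i <- rec[r, 1] + 1L; j <- rec[r, 2] + 1L
    m[i, j] <- m[i, j] + rec[r, 3]
    if (i != j) m[j, i] <- m[j, i] + rec[r, 3]
  }
  contact_map(m, bin_size = bin_size, arm_id = arm_id)
}

#' Write a contact map to disk
#'
#' @inheritParams read_contact_map
#' @param map A `contact_map`.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, format = c("coo-tsv", "dense-tsv")) {
  format <- match.arg(format)
  if (format == "dense-tsv") {
    m <- map$counts
    colnames(m) <- (seq_len(ncol(m)) - 1L) * map$bin_size
    write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(upper.tri(map$counts, diag = TRUE) & map$counts != 0,
                 arr.ind = TRUE)
    out <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                      count = map$counts[idx])
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Mask weakly covered bins
#'
#' Bins with a zero marginal, or a marginal below `min_marginal_frac` times the
#' median non-zero marginal, are excluded: their rows and columns are zeroed and
#' the mask flag is set. This is the usual preprocessing before matrix balancing.
#'
#' @param map A raw `contact_map`.
#' @param min_marginal_frac Fraction of the median non-zero marginal below which
#'   a bin is dropped (default 0.1).
#' @return The masked `contact_map`.
#' @export
mask_bins <- function(map, min_marginal_frac = 0.1) {
  marg <- rowSums(map$counts)
  med <- median(marg[marg > 0])
  bad <- marg == 0 | marg < min_marginal_frac * med
  bad <- bad | map$mask
  if (all(bad)) abort("empty map after filtering")
  contact_map(map$counts, bin_size = map$bin_size, arm_id = map$arm_id,
              mask = bad, corrected = map$corrected)
}

#' Iterative correction (ICE) of a contact map
#'
#' Factorises multiplicative per-bin biases so that unmasked bin marginals
#' equalise: `corrected[i, j] = raw[i, j] / (b_i * b_j)`. Runs a fixed number of
#' iterations (20 by default) and rescales the result so the
#' mean unmasked marginal is 1, making corrected values comparable across
#' conditions. Masked bins get an `NA` bias and all-zero rows.
#'
#' @param map A masked raw `contact_map`.
#' @param n_iterations Balancing iterations (default 20).
#' @return A list with `map` (the corrected `contact_map`) and `biases`
#'   (numeric vector, `NA` for masked bins, scaled so corrected marginals
#'   average 1).
#' @export
ice_normalize <- function(map, n_iterations = 20L) {
  stopifnot(n_iterations >= 1)
  keep <- !map$mask
  if (sum(keep) < 2) abort("Need at least 2 unmasked bins to balance.")
  w <- map$counts
  b <- rep(1, n_bins(map))
  prev_cv <- Inf
  grew <- FALSE
  for (it in seq_len(n_iterations)) {
    s <- rowSums(w)
    sk <- s[keep]
    cv <- sd(sk) / mean(sk)
    # growth below ~1e-12 is floating-point noise around the fixed point
    if (is.finite(prev_cv) && cv > prev_cv * (1 + 1e-12) && cv > 1e-12) {
      grew <- TRUE
    }
    prev_cv <- cv
    db <- s / mean(sk)
    db[!keep | db == 0] <- 1
    w <- w / outer(db, db)
    b <- b * db
  }
  if (grew) warn("ICE marginal spread grew during iteration; result may not be converged.")
  # rescale so the mean unmasked marginal equals 1
  sc <- mean(rowSums(w)[keep])
  w <- w / sc
  b <- b * sqrt(sc)
  b[!keep] <- NA_real_
  out <- contact_map(w, bin_size = map$bin_size, arm_id = map$arm_id,
                     mask = map$mask, corrected = TRUE)
  list(map = out, biases = b)
}

#' Expected contact frequency by genomic distance
#'
#' For each separation `s` (in bins), the mean corrected contact frequency over
#' unmasked bin pairs at `|i - j| = s` on the arm. Distances with no unmasked
#' pair are `NA`.
#'
#' @param map A corrected `contact_map`.
#' @return A tibble with columns `distance` (bins) and `expected`.
#' @export
expected_profile <- function(map) {
  n <- n_bins(map)
  keep <- !map$mask
  vals <- vapply(0:(n - 1L), function(s) {
    i <- seq_len(n - s)
    j <- i + s
    ok <- keep[i] & keep[j]
    if (!any(ok)) return(NA_real_)
    mean(map$counts[cbind(i[ok], j[ok])])
  }, numeric(1))
  tibble(distance = 0:(n - 1L), expected = vals)
}

#' Observed/expected transform
#'
#' Divides each entry by the expected value at its genomic distance. Masked
#' bins and distances without an expected value become `NA`.
#'
#' @param map A corrected `contact_map`.
#' @param profile Output of [expected_profile()] for the same map (computed if
#'   omitted).
#' @return A `contact_map` whose `counts` hold O/E ratios (`NA` marks missing);
#'   `corrected` stays `TRUE`.
#' @export
observed_over_expected <- function(map, profile = NULL) {
  if (is.null(profile)) profile <- expected_profile(map)
  n <- n_bins(map)
  exp_at <- profile$expected[abs(row(map$counts) - col(map$counts)) + 1L]
  exp_at[exp_at == 0] <- NA_real_       # populated distance with zero expected
  oe <- map$counts / matrix(exp_at, n, n)
  oe[map$mask, ] <- NA_real_
  oe[, map$mask] <- NA_real_
  out <- map
  out$counts <- oe
  out
}
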