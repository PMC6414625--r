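# Contact-map I/O, masking, ICE balancing, expected profile and O/E.

test_that("COO triplets are symmetrised and accumulated on read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\t1\t4", "1\t2\t2"), f)
  m <- read_contact_map(f, "coo-tsv", n_bins = 3)
  expect_equal(m$counts, matrix(c(0, 4, 0, 4, 0, 2, 0, 2, 0), 3, 3))

  # duplicate (i,j)/(j,i) triplets sum
  writeLines(c("0\t1\t3", "1\t0\t2"), f)
  m2 <- read_contact_map(f, "coo-tsv", n_bins = 2)
  expect_equal(m2$counts[1, 2], 5)
  expect_equal(m2$counts[2, 1], 5)
})

test_that("round-trips preserve the matrix in both formats", {
  set.seed(4)
  m <- random_sym_matrix(6)
  cm <- contact_map(m, bin_size = 1000L, arm_id = "rt")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_contact_map(cm, f1, "dense-tsv")
  write_contact_map(cm, f2, "coo-tsv")
  expect_equal(read_contact_map(f1, "dense-tsv", bin_size = 1000L)$counts,
               cm$counts, tolerance = 1e-12)
  expect_equal(read_contact_map(f2, "coo-tsv", n_bins = 6,
                                bin_size = 1000L)$counts,
               cm$counts, tolerance = 1e-12)
})

test_that("malformed and negative COO input is rejected with the line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\t1\t4", "oops"), f)
  expect_error(read_contact_map(f, "coo-tsv", n_bins = 3), "line 2")
  writeLines(c("0\t1\t-3"), f)
  expect_error(read_contact_map(f, "coo-tsv", n_bins = 3), "Negative")
})

test_that("bin masking follows the zero / fractional-marginal rule", {
  mk <- function(marg) {
    # diagonal matrix has row sums equal to marg without cross terms
    contact_map(diag(marg), bin_size = 1000L)
  }
  expect_equal(mask_bins(mk(c(0, 10, 12, 11)), 0.1)$mask,
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(mask_bins(mk(c(5, 5, 5, 5)), 0.1)$mask, rep(FALSE, 4))
  expect_equal(mask_bins(mk(c(1, 100, 100, 100)), 0.1)$mask,
               c(TRUE, FALSE, FALSE, FALSE))
  expect_error(mask_bins(mk(c(1, 1, 1, 1)), 2), "empty map")
})

test_that("ICE is a fixed point on balanced input and recovers planted biases", {
  # equal marginals: unchanged up to global scale, biases all equal
  m <- matrix(1, 5, 5)
  cm <- contact_map(m, bin_size = 1000L)
  res <- ice_normalize(cm)
  expect_equal(res$map$counts / res$map$counts[1, 2],
               m / m[1, 2], tolerance = 1e-9)
  expect_lt(diff(range(res$biases)), 1e-9)

  # planted biases over a doubly balanced matrix are recovered up to scale
  b <- c(1, 2, 4, 1.5, 3, 0.8)
  M <- matrix(1, 6, 6)
  raw <- contact_map(M * outer(b, b), bin_size = 1000L)
  res2 <- ice_normalize(mask_bins(raw))
  ratio <- res2$biases / b
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
  # corrected map proportional to M (direct-division oracle)
  oracle <- raw$counts / outer(b, b)
  expect_lt(max(abs(res2$map$counts / res2$map$counts[1, 2] -
                    oracle / oracle[1, 2])), 1e-9)
  # marginals equalised
  marg <- rowSums(res2$map$counts)
  expect_lt(sd(marg) / mean(marg), 1e-3)
  expect_equal(mean(marg), 1, tolerance = 1e-9)
})

test_that("masked bins get NA bias and zero rows after ICE", {
  set.seed(5)
  m <- random_sym_matrix(6) + 1
  m[3, ] <- m[, 3] <- 0
  cm <- contact_map(m, bin_size = 1000L, mask = c(F, F, T, F, F, F))
  res <- ice_normalize(cm)
  expect_true(is.na(res$biases[3]))
  expect_true(all(res$map$counts[3, ] == 0))
})

test_that("marginal CV is non-increasing over ICE iterations on planted-bias input", {
  set.seed(6)
  for (rep in 1:5) {
    b <- rlnorm(8, 0, 0.5)
    raw <- contact_map(matrix(1, 8, 8) * outer(b, b), bin_size = 1000L)
    cvs <- sapply(1:6, function(k) {
      marg <- rowSums(ice_normalize(raw, n_iterations = k)$map$counts)
      sd(marg) / mean(marg)
    })
    expect_true(all(diff(cvs) <= 1e-10))
  }
})

test_that("expected profile equals exhaustive per-diagonal means", {
  # Toeplitz case: exact equality with the diagonal values
  d <- c(9, 5, 3, 1)
  m <- outer(1:4, 1:4, function(i, j) d[abs(i - j) + 1])
  cm <- contact_map(m, bin_size = 1000L)
  cm$corrected <- TRUE
  expect_equal(expected_profile(cm)$expected, d)

  # arbitrary symmetric matrix vs brute force, with and without a mask
  set.seed(7)
  m2 <- random_sym_matrix(5)
  cm2 <- contact_map(m2, bin_size = 1000L)
  expect_equal(expected_profile(cm2)$expected, brute_diag_means(m2))
  cm3 <- contact_map(m2, bin_size = 1000L, mask = c(F, T, F, F, F))
  m3 <- cm3$counts
  expect_equal(expected_profile(cm3)$expected,
               brute_diag_means(m3, mask = c(F, T, F, F, F)))
})

test_that("O/E normalisation identity: every diagonal has mean 1", {
  set.seed(8)
  m <- random_sym_matrix(12) + 0.5
  cm <- contact_map(m, bin_size = 1000L)
  oe <- observed_over_expected(cm)
  dm <- brute_diag_means(oe$counts)
  expect_true(all(abs(dm - 1) < 1e-9))

  # all-constant map: O/E all ones off the diagonal
  cc <- contact_map(matrix(3, 6, 6), bin_size = 1000L)
  oe2 <- observed_over_expected(cc)
  expect_true(all(abs(oe2$counts - 1) < 1e-12))
})

test_that("zero expected at a populated distance is flagged, not divided", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 2          # distance 1 populated
  m[1, 1] <- 1
  cm <- contact_map(m, bin_size = 1000L)
  prof <- expected_profile(cm)
  prof$expected[2] <- 0            # force a zero expected at distance 1
  oe <- observed_over_expected(cm, prof)
  expect_true(is.na(oe$counts[1, 2]))
})

test_that("symmetry is preserved by masking, ICE and O/E", {
  set.seed(9)
  m <- random_sym_matrix(10) + 0.2
  cm <- mask_bins(contact_map(m, bin_size = 1000L))
  ic <- ice_normalize(cm)$map
  oe <- observed_over_expected(ic)
  expect_equal(cm$counts, t(cm$counts))
  expect_equal(ic$counts, t(ic$counts))
  expect_equal(oe$counts, t(oe$counts))
})
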