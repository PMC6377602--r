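test_that("checkerboard units follow the (r_i - S)(r_j - S) definition", {
  # two-site perfect checkerboard
  expect_equal(checkerboard_units(presence_matrix(diag(2)), 1, 2), 1)
  # identical occupancy vectors share every site: zero units
  m <- presence_matrix(cbind(a = c(1, 1, 0), b = c(1, 1, 0)))
  expect_equal(checkerboard_units(m, "a", "b"), 0)
  expect_error(checkerboard_units(m, "a", "zz"), "unknown species")
  expect_error(checkerboard_units(m, 1, 1), "distinct")
  # counts forced by the dry-valley survey's printed occupancies
  pm <- mdv_counts_matrix()
  expect_equal(checkerboard_units(pm, "Scottnema", "Plectus"),
               (289 - 32) * (50 - 32))
  expect_equal(checkerboard_units(pm, "Scottnema", "Plectus"), 4626)
})

test_that("C-score equals the mean of pairwise units (brute-force oracle)", {
  expect_equal(c_score(presence_matrix(diag(2))), 1)
  expect_equal(c_score(mdv_counts_matrix()), mean(c(4626, 1530, 1629)))
  expect_equal(c_score(mdv_counts_matrix()), 2595)
  expect_error(c_score(presence_matrix(matrix(1, 4, 1))), "2 species")
  for (seed in 1:8) {
    pm <- random_presence(15, 4, p = 0.5, seed = seed)
    expect_equal(c_score(pm), brute_c_score(unclass(pm)))
  }
})

test_that("SIM9 swaps preserve row and column totals exactly", {
  for (seed in 1:200) {
    pm <- random_presence(sample(3:12, 1), sample(2:6, 1), p = runif(1, 0.2, 0.8))
    out <- sim9_swap(pm, n_swaps = 500)
    expect_identical(rowSums(unclass(out)), rowSums(unclass(pm)))
    expect_identical(colSums(unclass(out)), colSums(unclass(pm)))
  }
})

test_that("a matrix without checkerboard submatrices is a SIM9 fixed point", {
  nested <- presence_matrix(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))
  out <- sim9_swap(nested, n_swaps = 5000, rng_seed = 1)
  expect_identical(unclass(out), unclass(nested))
  w <- testthat::capture_warnings(
    nd <- null_distribution(nested, n_iter = 10, burn_in = 100, thin = 10))
  expect_match(w, "no swappable", all = FALSE)
  expect_match(w, "SES undefined", all = FALSE)
  expect_true(all(nd$replicates == nd$observed))
})

test_that("the swap chain visits fixed-margin matrices uniformly", {
  # 3x3 with margins (1,1,1)/(1,1,1): the 6 permutation matrices
  perm <- enumerate_fixed_fixed(c(1, 1, 1), c(1, 1, 1))
  expect_length(perm, 6)
  start <- presence_matrix(diag(3))
  set.seed(42)
  n_samp <- 6000
  keys <- character(n_samp)
  cur <- start
  for (k in seq_len(n_samp)) {
    cur <- sim9_swap(cur, n_swaps = 30)
    keys[k] <- matrix_key(unclass(cur))
  }
  counts <- table(factor(keys, levels = vapply(perm, matrix_key, "")))
  expect_length(counts, 6)
  # each frequency within 3 binomial MC standard errors of 1/6
  # (samples are correlated; 30 attempts between draws keeps that mild)
  se <- sqrt((1 / 6) * (5 / 6) / n_samp)
  expect_true(all(abs(counts / n_samp - 1 / 6) < 6 * se))
  # richer margins: (2,1,1)/(2,1,1) with 3 matrices
  mats <- enumerate_fixed_fixed(c(2, 1, 1), c(2, 1, 1))
  cur <- presence_matrix(mats[[1]])
  keys <- character(n_samp)
  for (k in seq_len(n_samp)) {
    cur <- sim9_swap(cur, n_swaps = 30)
    keys[k] <- matrix_key(unclass(cur))
  }
  counts <- table(factor(keys, levels = vapply(mats, matrix_key, "")))
  p0 <- 1 / length(mats)
  se <- sqrt(p0 * (1 - p0) / n_samp)
  expect_true(all(abs(counts / n_samp - p0) < 6 * se))
})

test_that("null summaries obey the SES identity and are reproducible", {
  s <- cooccurspat:::.null_summary(4, c(1, 2, 3))
  expect_equal(s$null_mean, 2)
  expect_equal(s$null_sd, 1)
  expect_equal(s$ses, 2)
  s0 <- cooccurspat:::.null_summary(2, c(1, 2, 3))
  expect_equal(s0$ses, 0)

  pm <- random_presence(30, 4, p = 0.4, seed = 3)
  nd1 <- null_distribution(pm, n_iter = 200, burn_in = 2000, rng_seed = 77)
  nd2 <- null_distribution(pm, n_iter = 200, burn_in = 2000, rng_seed = 77)
  expect_identical(nd1$replicates, nd2$replicates)
  expect_equal(nd1$ses * nd1$null_sd + nd1$null_mean, nd1$observed,
               tolerance = 1e-9)
  expect_lte(nd1$ci_low, nd1$ci_high)
  expect_true(all(c(nd1$p_upper, nd1$p_lower) >= 0 &
                    c(nd1$p_upper, nd1$p_lower) <= 1))
})

test_that("a built-in segregation yields strongly positive SES", {
  # species 1 and 2 on opposite halves, a third species scattered so site
  # richness varies (a two-species matrix is degenerate under fixed-fixed)
  set.seed(5)
  occ <- cbind(sp1 = rep(c(1, 0), each = 30), sp2 = rep(c(0, 1), each = 30),
               sp3 = rbinom(60, 1, 0.5))
  overlap <- sample(60, 6)
  occ[overlap, 1:2] <- 1
  nd <- null_distribution(presence_matrix(occ), n_iter = 300,
                          burn_in = 5000, rng_seed = 9)
  expect_gt(nd$ses, 2)
})

test_that("a two-species matrix is degenerate under fixed-fixed margins", {
  # with 2 species the margins determine the shared-site count, so every
  # null replicate equals the observed value and SES is undefined
  chk <- presence_matrix(cbind(a = rep(c(1, 0), 10), b = rep(c(0, 1), 10)))
  expect_warning(pt <- pairwise_tests(chk, n_iter = 100, burn_in = 2000,
                                      rng_seed = 1),
                 "zero null variance")
  expect_true(is.na(pt$ses))
  expect_equal(pt$classification, "random")
})

test_that("pairwise tests classify forced patterns and stay quiet on noise", {
  # near-perfect checkerboard of species 1 and 2 inside a 3-species matrix
  set.seed(6)
  chk <- presence_matrix(cbind(a = rep(c(1, 0), 15), b = rep(c(0, 1), 15),
                               c = rbinom(30, 1, 0.5)))
  pt <- pairwise_tests(chk, n_iter = 300, burn_in = 5000, rng_seed = 1)
  ab <- pt[pt$pair == "a:b", ]
  expect_equal(ab$classification, "segregated")
  expect_gt(ab$ses, 0)
  expect_error(pairwise_tests(chk, alpha = 0.9), "alpha")

  # independent Bernoulli columns: mostly "random" calls
  set.seed(1)
  calls <- replicate(60, {
    pm <- presence_matrix(matrix(rbinom(180, 1, 0.5), 60, 3))
    pt <- pairwise_tests(pm, n_iter = 300, burn_in = 4000)
    all(pt$classification == "random")
  })
  expect_gte(mean(calls), 0.9)
})
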