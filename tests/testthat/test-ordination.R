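test_that("Hellinger transform normalizes rows", {
  expect_equal(unname(hellinger(rbind(c(1, 1, 1, 1)))), rbind(rep(0.5, 4)))
  expect_equal(unname(hellinger(rbind(c(4, 0, 0)))), rbind(c(1, 0, 0)))
  expect_error(hellinger(rbind(c(-1, 2))), "non-negative")
  expect_warning(h0 <- hellinger(rbind(c(0, 0), c(1, 3))), "all-zero")
  expect_equal(unname(h0[1, ]), c(0, 0))
  set.seed(1)
  m <- matrix(rexp(30), 10, 3)
  h <- hellinger(m)
  expect_equal(unname(sqrt(rowSums(h^2))), rep(1, 10))
})

test_that("RDA reproduces least squares and agrees with vegan", {
  set.seed(2)
  y <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  x <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("x", 1:4)))
  res <- rda(y, x, n_perm = 0)
  # column-wise least-squares oracle
  ss_fit <- 0; ss_tot <- 0
  for (j in 1:3) {
    fitj <- lm(y[, j] ~ x)
    ss_fit <- ss_fit + sum((fitted(fitj) - mean(y[, j]))^2)
    ss_tot <- ss_tot + sum((y[, j] - mean(y[, j]))^2)
  }
  expect_equal(res$r2, ss_fit / ss_tot, tolerance = 1e-10)
  # decomposition exactness
  expect_equal(res$fitted + res$residuals, res$response_centred,
               tolerance = 1e-10)
  skip_if_not_installed("vegan")
  vr <- vegan::rda(y ~ x)
  expect_equal(res$r2, vr$CCA$tot.chi / vr$tot.chi, tolerance = 1e-8)
  expect_equal(res$adj_r2, vegan::RsquareAdj(vr)$adj.r.squared,
               tolerance = 1e-8)
  expect_equal(res$canonical_eigenvalues, unname(vr$CCA$eig),
               tolerance = 1e-8)
})

test_that("RDA hits the exact-fit and null extremes", {
  set.seed(3)
  x <- matrix(rnorm(60), 20, 3)
  B <- matrix(runif(6), 3, 2)
  y <- x %*% B
  res <- rda(y, x, n_perm = 0)
  expect_equal(res$r2, 1, tolerance = 1e-10)
  expect_true(max(abs(res$residuals)) < 1e-10)
  # orthogonal predictor: r2 ~ 0, permutation test non-significant
  y2 <- matrix(rnorm(40), 20, 2)
  x2 <- matrix(rnorm(20), 20, 1)
  y2 <- qr.resid(qr(cbind(1, x2)), y2)    # exactly uncorrelated
  res2 <- rda(y2, x2, n_perm = 199, rng_seed = 1)
  expect_lt(res2$r2, 1e-10)
  expect_gt(res2$permutation_p, 0.5)
  # with one response column r2 equals univariate OLS R^2
  y1 <- matrix(rnorm(20), 20, 1)
  res1 <- rda(y1, x, n_perm = 0)
  expect_equal(res1$r2, summary(lm(y1 ~ x))$r.squared, tolerance = 1e-10)
  # adding a predictor never decreases raw r2
  res_less <- rda(y2, x2, n_perm = 0)
  res_more <- rda(y2, cbind(x2, rnorm(20)), n_perm = 0)
  expect_gte(res_more$r2, res_less$r2 - 1e-12)
  # rank deficiency is named
  expect_error(rda(y2, cbind(a = x2[, 1], b = 2 * x2[, 1]), n_perm = 0),
               "rank deficient")
})

test_that("adjusted R2 follows the Ezekiel formula", {
  expect_equal(adjusted_r2(1, 30, 4), 1)
  expect_equal(adjusted_r2(0.5, 11, 5), 0)
  expect_equal(adjusted_r2(0.37, 100, 0), 0.37)
  expect_error(adjusted_r2(0.5, 5, 5), "n > m")
})

test_that("variance partitioning sums to one and isolates known sources", {
  set.seed(4)
  y <- matrix(rnorm(150), 50, 3)
  xa <- matrix(rnorm(100), 50, 2)
  xb <- matrix(rnorm(100), 50, 2)
  xs <- matrix(rnorm(100), 50, 2)
  vp <- variance_partition(y, xa, xb, xs)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-9)

  # response built purely from the abiotic set
  y2 <- xa %*% matrix(c(1, -1, 0.5, 2, 0.3, -0.7), 2, 3)
  vp2 <- variance_partition(y2, xa, xb, xs)
  expect_gt(vp2$fractions["unique_abiotic"], 0.95)
  expect_lt(abs(vp2$fractions["unique_biotic"]), 0.05)
  expect_equal(sum(vp2$fractions), 1, tolerance = 1e-9)

  # orthogonal predictor sets explaining disjoint variance
  for (seed in 1:20) {
    set.seed(seed)
    n <- 60
    base <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
    oa <- base[, 1, drop = FALSE]; ob <- base[, 2, drop = FALSE]
    os <- base[, 3, drop = FALSE]
    y3 <- cbind(oa * 2, ob * 2, os * 2) + matrix(rnorm(n * 3, 0, 0.3), n, 3)
    vp3 <- variance_partition(y3, oa, ob, os)
    marg <- vp3$adj_r2_components
    expect_lt(abs(vp3$fractions["unique_abiotic"] - marg["abiotic"]), 0.05)
    expect_lt(abs(vp3$fractions["shared_all"]), 0.05)
    expect_equal(sum(vp3$fractions), 1, tolerance = 1e-9)
  }

  expect_warning(vp4 <- variance_partition(y, xa, NULL, xs), "empty")
  expect_equal(unname(vp4$fractions["unique_biotic"]), 0, tolerance = 1e-9)

  skip_if_not_installed("vegan")
  set.seed(9)
  y5 <- matrix(rnorm(120), 40, 3)
  xa5 <- matrix(rnorm(80), 40, 2); xb5 <- matrix(rnorm(40), 40, 1)
  xs5 <- matrix(rnorm(80), 40, 2)
  vp5 <- variance_partition(y5, xa5, xb5, xs5)
  vv <- vegan::varpart(y5, xa5, xb5, xs5)$part
  expect_equal(unname(vp5$fractions["unique_abiotic"]),
               vv$indfract$Adj.R.square[1], tolerance = 1e-8)
  expect_equal(unname(vp5$fractions["unique_biotic"]),
               vv$indfract$Adj.R.square[2], tolerance = 1e-8)
  expect_equal(unname(vp5$fractions["unique_spatial"]),
               vv$indfract$Adj.R.square[3], tolerance = 1e-8)
  expect_equal(unname(vp5$fractions["shared_all"]),
               vv$indfract$Adj.R.square[7], tolerance = 1e-8)
})

test_that("residual correlations recover trivial structure", {
  res <- list(residuals = cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2,
                                c = c(0, 0, 1, 0)))
  rc <- residual_correlations(res)
  expect_equal(rc$r[rc$pair == "a:b"], 1)
  res2 <- list(residuals = cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1)))
  expect_equal(residual_correlations(res2)$r, 0)
  res3 <- list(residuals = cbind(a = c(1, 2, 3), b = c(2, 2, 2)))
  expect_true(is.na(residual_correlations(res3)$r))
})
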