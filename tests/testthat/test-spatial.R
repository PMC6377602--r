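test_that("pairwise distances are Euclidean and validated", {
  expect_equal(pairwise_distances(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  expect_equal(pairwise_distances(rbind(c(2, 2))), matrix(0, 1, 1),
               ignore_attr = TRUE)
  set.seed(1)
  xy <- matrix(runif(20), 10, 2)
  D <- pairwise_distances(xy)
  for (i in 1:10) for (j in 1:10)
    expect_equal(D[i, j], sqrt(sum((xy[i, ] - xy[j, ])^2)))
  bad <- rbind(c(0, 0), c(NA, 1))
  rownames(bad) <- c("a", "b")
  expect_error(pairwise_distances(bad), "non-finite.*b")
})

test_that("spherical correlation has the textbook shape", {
  m <- spherical_model(range = 100, nugget = 0)
  expect_equal(spherical_corr(0, m), 1)
  expect_equal(spherical_corr(100, m), 0)
  expect_equal(spherical_corr(250, m), 0)
  expect_equal(spherical_corr(50, m), 0.3125)   # 1 - 0.75 + 0.0625
  # non-increasing, continuous at the range
  d <- seq(0, 150, by = 0.5)
  v <- spherical_corr(d, m)
  expect_true(all(diff(v) <= 1e-12))
  expect_lt(spherical_corr(100 - 1e-9, m), 1e-6)
  m2 <- spherical_model(range = 100, nugget = 0.3)
  expect_equal(spherical_corr(1e-12, m2), 0.7, tolerance = 1e-9)
  expect_error(spherical_model(range = -1), "range")
})

test_that("Moran's I matches the closed-form oracle and flags gradients", {
  # 4-point hand example, one distance class covering all pairs
  xy <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  vals <- c(1, 2, 3, 5)
  cg <- morans_i(vals, xy, class_edges = c(0, 2), n_perm = 99, rng_seed = 1)
  xc <- vals - mean(vals)
  W <- (pairwise_distances(xy) > 0) * 1
  I_hand <- (4 / sum(W)) * sum(outer(xc, xc) * W) / sum(xc^2)
  expect_equal(cg$morans_i[1], I_hand)
  skip_if_not_installed("ape")
  expect_equal(cg$morans_i[1],
               unname(suppressWarnings(ape::Moran.I(vals, W))$observed))

  # monotone surface on a transect: strong positive first-class I
  xy2 <- cbind(seq(0, 19), 0)
  cg2 <- morans_i(seq(0, 19), xy2, class_edges = c(0, 1.5, 5, 20),
                  n_perm = 199, rng_seed = 2)
  expect_gt(cg2$morans_i[1], 0)
  expect_lte(cg2$p_value[1], 0.05)
  expect_error(morans_i(rep(1, 10), cbind(1:10, 0)), "constant")
})

test_that("Moran permutation test holds its size on shuffled values", {
  set.seed(11)
  xy <- cbind(runif(25), runif(25))
  hits <- 0; total <- 0
  for (s in 1:100) {
    vals <- rnorm(25)
    cg <- morans_i(vals, xy, class_edges = c(0, 0.3, 0.6, 1.5),
                   n_perm = 99)
    hits <- hits + sum(cg$p_value <= 0.05, na.rm = TRUE)
    total <- total + sum(!is.na(cg$p_value))
  }
  expect_lt(hits / total, 0.12)
  expect_gt(hits / total, 0.005)
})

test_that("Moran's I is invariant to duplicating every site", {
  set.seed(3)
  xy <- cbind(runif(12, 0, 10), runif(12, 0, 10))
  vals <- rnorm(12)
  edges <- c(0, 4, 8, 15)
  base <- morans_i(vals, xy, class_edges = edges, n_perm = 0)
  doubled <- morans_i(rep(vals, 2), rbind(xy, xy), class_edges = edges,
                      n_perm = 0)
  # self-pairs (distance 0) are excluded by the lower-open bins
  expect_equal(doubled$morans_i, base$morans_i, tolerance = 1e-10)
})

test_that("PCNM construction matches vegan and the transect limit", {
  # regular 1-D transect: truncation = spacing, leading vector ~ cosine
  n <- 20
  xy <- cbind(seq_len(n) * 10, 0)
  sev <- build_pcnm(xy)
  expect_equal(sev$truncation, 10)
  expect_true(all(sev$eigenvalues > 0))
  cp <- crossprod(sev$vectors)
  expect_true(max(abs(cp - diag(ncol(cp)))) < 1e-8)
  expect_true(all(abs(colMeans(sev$vectors)) < 1e-10))
  # leading vectors are sinusoid-like with increasing frequency: the
  # best-matching cosine frequency of vector k is k
  cosine <- function(f) cos(pi * f * (seq_len(n) - 0.5) / n)
  for (k in 1:3) {
    cors <- vapply(1:6, function(f) abs(cor(sev$vectors[, k], cosine(f))),
                   numeric(1))
    expect_equal(which.max(cors), k)
  }
  expect_gt(abs(cor(sev$vectors[, 1], cosine(1))), 0.85)

  skip_if_not_installed("vegan")
  for (seed in c(7, 8)) {
    set.seed(seed)
    xy2 <- cbind(runif(15, 0, 100), runif(15, 0, 100))
    sev2 <- build_pcnm(xy2)
    vp <- vegan::pcnm(dist(xy2))
    expect_equal(sev2$truncation, vp$threshold, tolerance = 1e-10)
    keep <- vp$values > max(vp$values) * 1e-8
    expect_equal(sev2$eigenvalues, vp$values[keep], tolerance = 1e-8)
    for (k in seq_len(min(3, ncol(sev2$vectors))))
      expect_equal(abs(cor(sev2$vectors[, k], vp$vectors[, k])), 1,
                   tolerance = 1e-6)
  }
  # 4-site unit square against a direct eigen-decomposition oracle
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  sev3 <- build_pcnm(sq)
  D <- pairwise_distances(sq)
  t0 <- cooccurspat:::.mst_max_edge(D)
  D[D > t0] <- 4 * t0
  A <- -0.5 * D^2
  B <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  ev <- eigen(B, symmetric = TRUE)$values
  expect_equal(sev3$eigenvalues, ev[ev > max(ev) * 1e-9], tolerance = 1e-10)
})

test_that("AIC forward selection finds planted structure and stops on noise", {
  set.seed(21)
  xy <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  sev <- build_pcnm(xy)
  y <- sev$vectors[, 3] + rnorm(40, 0, 0.01)
  out <- forward_select_aic(cbind(y), sev)
  expect_equal(out$selected[1], 3)
  expect_true(all(diff(out$selection_path) < 0))

  # pure-noise responses: greedy AIC selection stays well short of the
  # full basis, and the signal scenario ranks the true vector first
  counts <- vapply(1:40, function(s) {
    set.seed(300 + s)
    noise <- matrix(rnorm(40 * 2), 40, 2)
    length(forward_select_aic(noise, sev)$selected)
  }, numeric(1))
  expect_lt(median(counts), ncol(sev$vectors) / 2)
})
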