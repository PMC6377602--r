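#' Hellinger transformation
#'
#' Square root of row-relative abundances: y' = sqrt(y_ij / row_sum_i).
#' Makes Euclidean-based ordination (RDA) appropriate for species abundance
#' data. All-zero rows map to zero rows with a warning.
#'
#' @param cm a [community_matrix()] or non-negative matrix.
#' @return Transformed matrix; nonzero rows have unit Euclidean norm.
#' @export
hellinger <- function(cm) {
  m <- unclass(as.matrix(cm))
  if (any(m < 0)) stop("abundances must be non-negative")
  rs <- rowSums(m)
  if (any(rs == 0)) warning(sum(rs == 0), " all-zero row(s) map to zero rows")
  out <- sqrt(sweep(m, 1, ifelse(rs == 0, 1, rs), "/"))
  class(out) <- "matrix"
  out
}

#' Redundancy analysis (multivariate linear regression + PCA of fits)
#'
#' Column-centres the response, regresses it on the predictors by least
#' squares, and reports the proportion of total response variance captured
#' by the fitted values. Canonical eigenvalues are the principal-component
#' variances of the fitted matrix. Overall significance by permutation of
#' predictor rows.
#'
#' @param y response matrix (e.g. Hellinger-transformed abundances).
#' @param x predictor matrix, full rank.
#' @param n_perm permutations for the overall test (default 999; 0 skips).
#' @param rng_seed optional seed for the permutation test.
#' @return An `rda_result` list: `r2`, `adj_r2`, `canonical_eigenvalues`,
#'   `fitted`, `residuals`, `response_centred`, `permutation_p`, `n`, `m`.
#' @export
rda <- function(y, x, n_perm = 999, rng_seed = NULL) {
  y <- as.matrix(y); x <- as.matrix(x)
  if (nrow(y) != nrow(x)) stop("y and x must have the same rows")
  qx <- qr(cbind(1, x))
  if (qx$rank < ncol(x) + 1) {
    aliased <- colnames(x)[qr(cbind(1, x))$pivot[-seq_len(qx$rank)] - 1]
    stop("predictor matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  yc <- scale(y, center = TRUE, scale = FALSE)
  attr(yc, "scaled:center") <- NULL
  r2_of <- function(xmat) {
    fit <- lm.fit(cbind(1, xmat), yc)
    sum(as.matrix(fit$fitted.values)^2) / sum(yc^2)
  }
  fit <- lm.fit(cbind(1, x), yc)
  fitted <- as.matrix(fit$fitted.values)
  residuals <- as.matrix(fit$residuals)
  dimnames(fitted) <- dimnames(residuals) <- dimnames(yc)
  ss_tot <- sum(yc^2)
  r2 <- sum(fitted^2) / ss_tot
  can_ev <- eigen(crossprod(fitted) / (nrow(y) - 1), symmetric = TRUE,
                  only.values = TRUE)$values
  can_ev <- can_ev[can_ev > max(can_ev, 0) * 1e-12]
  perm_p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    r2_perm <- vapply(seq_len(n_perm), function(i)
      r2_of(x[sample.int(nrow(x)), , drop = FALSE]), numeric(1))
    perm_p <- (1 + sum(r2_perm >= r2)) / (n_perm + 1)
  }
  out <- list(r2 = r2, adj_r2 = adjusted_r2(r2, nrow(y), ncol(x)),
              canonical_eigenvalues = can_ev, fitted = fitted,
              residuals = residuals, response_centred = yc,
              permutation_p = perm_p, n = nrow(y), m = ncol(x))
  class(out) <- "rda_result"
  out
}

#' Ezekiel-adjusted R-squared
#'
#' 1 - (1 - R2)(n - 1)/(n - m - 1); the unbiased scale on which explained
#' fractions from predictor sets of different sizes can be compared in
#' variance partitioning.
#'
#' @param r2 raw proportion of variance explained.
#' @param n number of sites.
#' @param m number of predictors.
#' @return Adjusted proportion (can be negative).
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (n <= m + 1) stop("need n > m + 1")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Three-set variance partitioning on adjusted R-squared
#'
#' Computes adjusted R2 for the seven non-empty unions of the abiotic,
#' biotic and spatial predictor sets and decomposes explained variation by
#' inclusion-exclusion into three unique fractions, three pairwise-shared
#' fractions, one triple-shared fraction and the residual. Negative shared
#' fractions (a known feature of adjusted-R2 partitioning) are reported
#' as-is and flagged.
#'
#' @param y response matrix.
#' @param x_abiotic,x_biotic,x_spatial predictor matrices (any may be
#'   `NULL`/empty: its fractions are zero, with a warning).
#' @return A `variance_partition` list: `fractions` (named numeric:
#'   `unique_abiotic`, `unique_biotic`, `unique_spatial`,
#'   `shared_abiotic_biotic`, `shared_biotic_spatial`,
#'   `shared_abiotic_spatial`, `shared_all`, `residual`),
#'   `total_explained`, `adj_r2_components`, `negative_fractions` flag.
#' @export
variance_partition <- function(y, x_abiotic, x_biotic, x_spatial) {
  y <- as.matrix(y)
  sets <- list(abiotic = x_abiotic, biotic = x_biotic, spatial = x_spatial)
  empty <- vapply(sets, function(s) is.null(s) || NCOL(s) == 0L, logical(1))
  if (any(empty))
    warning("empty predictor set(s): ",
            paste(names(sets)[empty], collapse = ", "),
            "; their fractions are 0")
  sets <- lapply(sets, function(s) if (is.null(s)) NULL else as.matrix(s))
  adj <- function(which_sets) {
    xs <- do.call(cbind, sets[which_sets])
    if (is.null(xs) || ncol(xs) == 0L) return(0)
    rda(y, xs, n_perm = 0)$adj_r2
  }
  RA <- adj("abiotic"); RB <- adj("biotic"); RS <- adj("spatial")
  RAB <- adj(c("abiotic", "biotic")); RAS <- adj(c("abiotic", "spatial"))
  RBS <- adj(c("biotic", "spatial"))
  TT <- adj(c("abiotic", "biotic", "spatial"))
  a <- TT - RBS                 # unique abiotic
  b <- TT - RAS                 # unique biotic
  c_ <- TT - RAB                # unique spatial
  d <- RAS + RBS - TT - RS      # shared abiotic-biotic
  e <- RAB + RAS - TT - RA      # shared biotic-spatial
  f <- RAB + RBS - TT - RB      # shared abiotic-spatial
  g <- TT - a - b - c_ - d - e - f
  fractions <- c(unique_abiotic = a, unique_biotic = b, unique_spatial = c_,
                 shared_abiotic_biotic = d, shared_biotic_spatial = e,
                 shared_abiotic_spatial = f, shared_all = g,
                 residual = 1 - TT)
  out <- list(fractions = fractions, total_explained = TT,
              adj_r2_components = c(abiotic = RA, biotic = RB, spatial = RS,
                                    abiotic_biotic = RAB,
                                    abiotic_spatial = RAS,
                                    biotic_spatial = RBS, all = TT),
              negative_fractions = any(fractions[1:7] < 0))
  class(out) <- "variance_partition"
  out
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Variance partitioning (adjusted R2 fractions)\n")
  print(round(x$fractions, 4))
  cat("Total explained:", round(x$total_explained, 4), "\n")
  invisible(x)
}

#' Pairwise correlations of RDA residuals
#'
#' Pearson correlation between residual columns for every species pair,
#' with a two-sided t-test. Negative residual correlation after removing
#' all measured predictors is the multivariate signature of a negative
#' biotic association.
#'
#' @param res an `rda_result`.
#' @return Data frame `pair`, `r`, `p_value` (undefined sentinel `NA` for
#'   zero-variance residual columns).
#' @export
residual_correlations <- function(res) {
  r <- res$residuals
  if (nrow(r) < 3L) stop("need at least 3 sites")
  p <- utils::combn(ncol(r), 2)
  rows <- apply(p, 2, function(ij) {
    a <- r[, ij[1]]; b <- r[, ij[2]]
    if (sd(a) == 0 || sd(b) == 0) return(c(NA_real_, NA_real_))
    ct <- cor.test(a, b)
    c(unname(ct$estimate), ct$p.value)
  })
  data.frame(pair = paste(colnames(r)[p[1, ]], colnames(r)[p[2, ]],
                          sep = ":"),
             r = rows[1, ], p_value = rows[2, ], stringsAsFactors = FALSE)
}
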