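#' Checkerboard units for one species pair
#'
#' For species i and j with occupancy counts r_i, r_j sharing S sites, the
#' number of checkerboard units is CU = (r_i - S)(r_j - S): the number of
#' mutually exclusive site pairs the two species form. High CU means the
#' pair co-occurs less than its occupancies allow.
#'
#' @param pm a [presence_matrix()].
#' @param i,j species names or column indices, distinct.
#' @return A single count.
#' @export
checkerboard_units <- function(pm, i, j) {
  m <- unclass(pm)
  idx <- function(k) {
    if (is.character(k)) {
      pos <- match(k, colnames(m))
      if (is.na(pos)) stop("unknown species: ", k)
      pos
    } else as.integer(k)
  }
  i <- idx(i); j <- idx(j)
  if (i == j) stop("i and j must be distinct species")
  ri <- sum(m[, i]); rj <- sum(m[, j]); S <- sum(m[, i] * m[, j])
  (ri - S) * (rj - S)
}

#' C-score of a presence matrix
#'
#' Arithmetic mean of [checkerboard_units()] over all unordered species
#' pairs. Species that rarely co-occur produce a high value.
#'
#' @param pm a [presence_matrix()] with at least two species.
#' @return A single value.
#' @export
c_score <- function(pm) {
  m <- unclass(pm)
  if (ncol(m) < 2L) stop("c_score needs at least 2 species")
  r <- colSums(m)
  S <- crossprod(m)
  cu <- outer(r, r) - r * t(S) - t(r * t(S)) + S * S
  # (r_i - S)(r_j - S) = r_i r_j - r_i S - r_j S + S^2, off-diagonal
  mean(cu[upper.tri(cu)])
}

.pair_cu_from_matrix <- function(m) {
  r <- colSums(m)
  S <- crossprod(m)
  p <- utils::combn(ncol(m), 2)
  cu <- (r[p[1, ]] - S[t(p)]) * (r[p[2, ]] - S[t(p)])
  names(cu) <- paste(colnames(m)[p[1, ]], colnames(m)[p[2, ]], sep = ":")
  cu
}

#' One SIM9 (fixed-fixed) randomization pass
#'
#' Performs `n_swaps` elementary attempts: each draws a random 2x2 submatrix
#' and, if it is a checkerboard, flips it to the opposite configuration.
#' Non-checkerboard draws are no-ops that still count toward `n_swaps`, so
#' the chain samples uniformly from the set of matrices sharing the input's
#' row and column totals.
#'
#' @param pm a [presence_matrix()].
#' @param n_swaps number of elementary attempts, `>= 0`.
#' @param rng_seed optional integer seed.
#' @return A [presence_matrix()] with identical row and column sums.
#' @export
sim9_swap <- function(pm, n_swaps, rng_seed = NULL) {
  if (n_swaps < 0) stop("n_swaps must be >= 0")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  m <- unclass(pm)
  storage.mode(m) <- "integer"
  out <- .sim9_swap_cpp(m, as.double(n_swaps))
  presence_matrix(out, rownames(pm), colnames(pm),
                  filtered = isTRUE(attr(pm, "filtered")))
}

.sim9_samples <- function(pm, n_iter, burn_in, thin) {
  m <- unclass(pm)
  storage.mode(m) <- "integer"
  res <- .sim9_chain_cpp(m, as.integer(n_iter), as.double(burn_in),
                         as.double(thin))
  res$dim <- dim(m)
  res$dimnames <- dimnames(m)
  res
}

.sample_matrix <- function(samples, k) {
  mk <- matrix(samples$samples[k, ], samples$dim[1], samples$dim[2],
               dimnames = samples$dimnames)
  mk
}

#' Null distribution of a matrix statistic under SIM9
#'
#' Runs a single sequential-swap chain, discards `burn_in` elementary
#' attempts, then records the statistic every `thin` attempts, `n_iter`
#' times. The standardized effect size is
#' (observed - null mean) / null SD, with the sample (n-1) standard
#' deviation; the 95% confidence limits are the empirical 2.5 and 97.5
#' percentiles of the replicates. Ties between the observed value and
#' replicates count toward both tails (conservative).
#'
#' @param pm a [presence_matrix()].
#' @param statistic a pure function of a binary matrix; default [c_score()]'s
#'   matrix kernel.
#' @param n_iter number of null matrices, `>= 2` (5000 is customary).
#' @param burn_in elementary attempts discarded before sampling.
#' @param thin attempts between samples; default = number of matrix cells.
#' @param rng_seed optional integer seed; fixing it makes the result
#'   bit-for-bit reproducible.
#' @return A `null_distribution` list: `observed`, `replicates`, `null_mean`,
#'   `null_sd`, `ses`, `ci_low`, `ci_high`, `p_upper`, `p_lower`, plus the
#'   bookkeeping fields `n_iter`, `burn_in`, `thin`, `seed`.
#' @export
null_distribution <- function(pm, statistic = NULL, n_iter = 5000,
                              burn_in = 30000, thin = NULL, rng_seed = NULL) {
  if (n_iter < 2) stop("n_iter must be >= 2")
  m <- unclass(pm)
  if (is.null(thin)) thin <- length(m)
  if (is.null(statistic))
    statistic <- function(x) c_score(presence_matrix(x))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  observed <- statistic(m)
  if (!.has_checkerboard_cpp(m))
    warning("matrix has no swappable 2x2 submatrix; ",
            "the fixed-fixed set is a single matrix and all replicates ",
            "equal the observed value")
  samples <- .sim9_samples(pm, n_iter, burn_in, thin)
  replicates <- vapply(seq_len(n_iter),
                       function(k) statistic(.sample_matrix(samples, k)),
                       numeric(1))
  .null_summary(observed, replicates, n_iter = n_iter, burn_in = burn_in,
                thin = thin, seed = rng_seed)
}

.null_summary <- function(observed, replicates, ...) {
  null_mean <- mean(replicates)
  null_sd <- sd(replicates)
  ses <- if (null_sd > 0) (observed - null_mean) / null_sd else NA_real_
  if (is.na(ses)) warning("null SD is zero; SES undefined")
  ci <- unname(quantile(replicates, c(0.025, 0.975), type = 7))
  out <- list(observed = observed, replicates = replicates,
              null_mean = null_mean, null_sd = null_sd, ses = ses,
              ci_low = ci[1], ci_high = ci[2],
              p_upper = mean(replicates >= observed),
              p_lower = mean(replicates <= observed), ...)
  class(out) <- "null_distribution"
  out
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("SIM9 null distribution (", length(x$replicates), " replicates)\n",
      sep = "")
  cat(sprintf("observed %.4g | null mean %.4g sd %.4g | SES %.3f\n",
              x$observed, x$null_mean, x$null_sd, x$ses))
  cat(sprintf("95%% null limits [%.4g, %.4g]; p_upper %.4g p_lower %.4g\n",
              x$ci_low, x$ci_high, x$p_upper, x$p_lower))
  invisible(x)
}

#' Pairwise segregation/aggregation tests
#'
#' Computes per-pair checkerboard units and their SIM9 null distributions
#' from a single swap chain, then classifies each pair. Following the
#' empirical-Bayes idea behind the Pairs program, the primary criterion
#' pools the null-standardized scores of all pairs into one reference
#' distribution and flags a pair whose standardized observed score falls
#' outside that pooled distribution's alpha/2 and 1-alpha/2 quantiles; a
#' two-sided per-pair tail test at level alpha (alpha/2 in the relevant
#' tail, ties conservative) is required to agree before a non-random call
#' is made. Benjamini-Hochberg adjusted per-pair
#' p-values are reported alongside.
#'
#' @inheritParams null_distribution
#' @param alpha two-sided significance level in (0, 0.5].
#' @return A data frame of class `pairwise_tests` with one row per pair:
#'   `pair`, `observed_cu`, `null_mean`, `null_sd`, `ses`, `ci_low`,
#'   `ci_high`, `p_upper`, `p_lower`, `p_two`, `p_adj`,
#'   `adjusted_significance`, `classification`.
#' @export
pairwise_tests <- function(pm, n_iter = 5000, burn_in = 30000, thin = NULL,
                           alpha = 0.05, rng_seed = NULL) {
  m <- unclass(pm)
  if (ncol(m) < 2L) stop("need at least 2 species")
  if (!(alpha > 0 && alpha <= 0.5)) stop("alpha must be in (0, 0.5]")
  if (is.null(thin)) thin <- length(m)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  observed <- .pair_cu_from_matrix(m)
  samples <- .sim9_samples(pm, n_iter, burn_in, thin)
  reps <- vapply(seq_len(n_iter),
                 function(k) .pair_cu_from_matrix(.sample_matrix(samples, k)),
                 numeric(length(observed)))
  reps <- t(matrix(reps, nrow = length(observed)))
  colnames(reps) <- names(observed)
  null_mean <- colMeans(reps)
  null_sd <- apply(reps, 2, sd)
  if (any(null_sd == 0))
    warning("pair(s) with zero null variance (the fixed-fixed margins ",
            "determine their shared-site count): ",
            paste(names(observed)[null_sd == 0], collapse = ", "),
            "; SES undefined, classified random")
  ses <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  # pooled empirical-Bayes reference: all pairs' null replicates on the
  # common standardized scale
  z_null <- sweep(sweep(reps, 2, null_mean), 2,
                  ifelse(null_sd > 0, null_sd, 1), "/")
  pooled_limits <- quantile(as.vector(z_null), c(alpha / 2, 1 - alpha / 2))
  p_upper <- colMeans(sweep(reps, 2, observed, ">=") * 1)
  p_lower <- colMeans(sweep(reps, 2, observed, "<=") * 1)
  p_two <- pmin(1, 2 * pmin(p_upper, p_lower))
  p_adj <- p.adjust(p_two, method = "BH")
  pooled_extreme <- ses < pooled_limits[1] | ses > pooled_limits[2]
  # two-sided test at level alpha: alpha/2 in the relevant tail
  tail_sig <- (ses > 0 & p_upper <= alpha / 2) |
    (ses < 0 & p_lower <= alpha / 2)
  nonrandom <- !is.na(ses) & pooled_extreme & tail_sig
  classification <- ifelse(!nonrandom, "random",
                           ifelse(ses > 0, "segregated", "aggregated"))
  out <- data.frame(pair = names(observed), observed_cu = unname(observed),
                    null_mean = null_mean, null_sd = null_sd, ses = ses,
                    ci_low = apply(reps, 2, quantile, 0.025),
                    ci_high = apply(reps, 2, quantile, 0.975),
                    p_upper = p_upper, p_lower = p_lower, p_two = p_two,
                    p_adj = p_adj,
                    adjusted_significance = p_adj <= alpha,
                    classification = classification,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "pooled_limits") <- pooled_limits
  attr(out, "alpha") <- alpha
  class(out) <- c("pairwise_tests", "data.frame")
  out
}
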