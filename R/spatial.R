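#' Euclidean distance matrix between sites
#'
#' @param coords 2-column matrix/data frame of planar metre coordinates.
#' @return Symmetric matrix with zero diagonal.
#' @export
pairwise_distances <- function(coords) {
  coords <- as.matrix(coords)
  bad <- which(!is.finite(rowSums(coords)))
  if (length(bad) > 0L)
    stop("non-finite coordinates for site(s): ",
         paste(if (is.null(rownames(coords))) bad else rownames(coords)[bad],
               collapse = ", "))
  as.matrix(dist(coords))
}

#' Spherical spatial correlation function
#'
#' Correlation declines as (1 - nugget) * (1 - 1.5 (d/range) +
#' 0.5 (d/range)^3) up to the range and is exactly zero beyond it; at d = 0
#' the correlation is 1 (the nugget applies to any positive distance).
#'
#' @param d distance(s), `>= 0`, metres.
#' @param model a [spherical_model()].
#' @return Correlation value(s) in `[0, 1]`.
#' @export
spherical_corr <- function(d, model) {
  u <- d / model$range
  base <- ifelse(u < 1, 1 - 1.5 * u + 0.5 * u^3, 0)
  ifelse(d == 0, 1, (1 - model$nugget) * base)
}

#' Spherical correlogram model
#'
#' @param range correlation range, metres, `> 0`.
#' @param nugget nugget proportion in `[0, 1)`.
#' @param sill variance scale (used by the simulator and variogram fits).
#' @return A `spherical_model` list.
#' @export
spherical_model <- function(range, nugget = 0, sill = 1) {
  if (range <= 0) stop("range must be > 0")
  if (nugget < 0 || nugget >= 1) stop("nugget must be in [0, 1)")
  structure(list(range = range, nugget = nugget, sill = sill),
            class = "spherical_model")
}

#' Default distance classes: equal-count (quantile) bins
#' @param coords site coordinates.
#' @param n_classes number of bins (default 10).
#' @return Vector of bin edges starting at 0.
#' @export
distance_classes <- function(coords, n_classes = 10) {
  D <- pairwise_distances(coords)
  dv <- D[upper.tri(D)]
  edges <- unique(quantile(dv, probs = seq(0, 1, length.out = n_classes + 1)))
  edges[1] <- 0
  edges
}

#' Moran's I correlogram with permutation tests
#'
#' Standard Moran's I per distance class with binary weights (1 when the
#' pair distance falls in the class), with a permutation p-value per class
#' obtained by randomizing site labels. The p-value is two-sided on the
#' permutation distribution with the observed value included.
#'
#' @param values per-site variable (non-constant).
#' @param coords site coordinates.
#' @param class_edges increasing vector of bin edges; default
#'   [distance_classes()] with 10 equal-count bins.
#' @param n_perm permutations per class (default 199).
#' @param rng_seed optional seed.
#' @return A `correlogram` data frame: `d_lower`, `d_upper`, `d_mid`,
#'   `n_pairs`, `morans_i`, `p_value`.
#' @export
morans_i <- function(values, coords, class_edges = NULL, n_perm = 199,
                     rng_seed = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("need at least 3 sites")
  if (sd(values) == 0) stop("variable is constant (zero variance)")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  D <- pairwise_distances(coords)
  if (is.null(class_edges)) class_edges <- distance_classes(coords)
  if (is.unsorted(class_edges, strictly = TRUE))
    stop("class_edges must be strictly increasing")
  k <- length(class_edges) - 1L
  perms <- replicate(n_perm, sample.int(n))
  moran_stat <- function(x, W, S0) {
    xc <- x - mean(x)
    (n / S0) * as.numeric(xc %*% W %*% xc) / sum(xc^2)
  }
  out <- data.frame(d_lower = class_edges[-(k + 1L)],
                    d_upper = class_edges[-1L])
  out$d_mid <- (out$d_lower + out$d_upper) / 2
  out$n_pairs <- NA_real_; out$morans_i <- NA_real_; out$p_value <- NA_real_
  for (b in seq_len(k)) {
    W <- (D > out$d_lower[b] & D <= out$d_upper[b]) * 1
    diag(W) <- 0
    S0 <- sum(W)
    out$n_pairs[b] <- S0 / 2
    if (S0 == 0) next
    I_obs <- moran_stat(values, W, S0)
    I_perm <- vapply(seq_len(n_perm),
                     function(p) moran_stat(values[perms[, p]], W, S0),
                     numeric(1))
    e0 <- -1 / (n - 1)
    out$morans_i[b] <- I_obs
    out$p_value[b] <- (1 + sum(abs(I_perm - e0) >= abs(I_obs - e0))) /
      (n_perm + 1)
  }
  class(out) <- c("correlogram", "data.frame")
  out
}

# Prim's algorithm: maximum edge weight of the minimum spanning tree.
.mst_max_edge <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- D[1, ]
  max_edge <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    max_edge <- max(max_edge, best[nxt])
    in_tree[nxt] <- TRUE
    best <- pmin(best, D[nxt, ])
  }
  max_edge
}

#' Spatial eigenvectors by principal coordinates of neighbour matrices
#'
#' Classic PCNM/db-MEM construction: the inter-site distance matrix is
#' truncated at t = the longest edge of its minimum spanning tree (the
#' smallest threshold keeping all sites connected); distances beyond t are
#' replaced by 4t; the truncated matrix is double-centred (Gower) and
#' eigen-decomposed. Eigenvectors with positive eigenvalues are retained;
#' they are orthonormal with mean zero and describe spatial structure from
#' broad (leading vectors) to fine scales.
#'
#' @param coords site coordinates (`>= 4` sites).
#' @param truncation optional truncation distance overriding the MST rule.
#' @return A `spatial_eigenvectors` list: `truncation`, `eigenvalues`
#'   (positive only), `vectors` (site x vector), `selected` (initially all),
#'   `selection_path` (`NULL` until [forward_select_aic()]).
#' @export
build_pcnm <- function(coords, truncation = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4L) stop("need at least 4 sites")
  if (anyDuplicated(coords))
    warning("coincident sites present; their distance is 0 and they share ",
            "identical eigenvector scores")
  D <- pairwise_distances(coords)
  if (is.null(truncation)) truncation <- .mst_max_edge(D)
  Dt <- D
  Dt[Dt > truncation] <- 4 * truncation
  A <- -0.5 * Dt^2
  n <- nrow(A)
  B <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n, byrow = TRUE) +
    mean(A)
  eig <- eigen(B, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-9
  vectors <- eig$vectors[, pos, drop = FALSE]
  colnames(vectors) <- paste0("PCNM", seq_len(ncol(vectors)))
  rownames(vectors) <- rownames(coords)
  out <- list(truncation = truncation, eigenvalues = eig$values[pos],
              vectors = vectors, selected = seq_len(ncol(vectors)),
              selection_path = NULL)
  class(out) <- "spatial_eigenvectors"
  out
}

.mv_aic <- function(y, x, k) {
  n <- nrow(y)
  if (is.null(x) || ncol(x) == 0L) {
    rss <- sum(scale(y, scale = FALSE)^2)
  } else {
    fit <- lm.fit(cbind(1, x), y)
    rss <- sum(as.matrix(fit$residuals)^2)
  }
  n * log(rss / n) + 2 * (k + 1)
}

#' Forward selection of spatial eigenvectors by multivariate AIC
#'
#' Greedy forward addition of the eigenvector that most reduces a
#' multivariate AIC, n log(RSS_total / n) + 2(k + 1), where RSS_total sums
#' the residual sums of squares of the multi-response linear fit over all
#' response columns and k is the number of selected vectors. Stops when no
#' candidate lowers the criterion; ties go to the lower vector index.
#'
#' @param response site x response numeric matrix (rows aligned with `sev`).
#' @param sev a `spatial_eigenvectors` object from [build_pcnm()].
#' @return `sev` with `selected` set to the chosen vector indices (in order
#'   of entry) and `selection_path` the AIC trace (starting at the null
#'   model's AIC).
#' @export
forward_select_aic <- function(response, sev) {
  y <- as.matrix(response)
  v <- sev$vectors
  if (nrow(y) != nrow(v)) stop("response rows must align with eigenvectors")
  chosen <- integer(0)
  path <- .mv_aic(y, NULL, 0L)
  repeat {
    remaining <- setdiff(seq_len(ncol(v)), chosen)
    if (length(remaining) == 0L) break
    aics <- vapply(remaining, function(j)
      .mv_aic(y, v[, c(chosen, j), drop = FALSE], length(chosen) + 1L),
      numeric(1))
    best <- which.min(aics)
    if (aics[best] >= path[length(path)]) break
    chosen <- c(chosen, remaining[best])
    path <- c(path, aics[best])
  }
  sev$selected <- chosen
  sev$selection_path <- path
  sev
}

#' Scores of the selected spatial eigenvectors
#' @param sev a `spatial_eigenvectors` object.
#' @return Matrix of selected eigenvector scores.
#' @export
pcnm_scores <- function(sev) sev$vectors[, sev$selected, drop = FALSE]
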