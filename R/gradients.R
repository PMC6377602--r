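#' Standardize covariate columns
#'
#' Centres each column to mean 0 and scales to sample SD 1. Constant columns
#' cannot be standardized; they are dropped with a warning naming them.
#' Missing values are mean-imputed (i.e. set to 0 after centring) and the
#' imputation count is recorded in the `"n_imputed"` attribute.
#'
#' @param x numeric matrix or data frame of covariates, `>= 2` rows.
#' @return A z-scored matrix.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("all columns must be numeric")
  if (nrow(x) < 2L) stop("need at least 2 rows")
  n_imp <- sum(is.na(x))
  if (n_imp > 0L)
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      x[nas, j] <- mean(x[, j], na.rm = TRUE)
    }
  sds <- apply(x, 2, sd)
  const <- sds == 0 | !is.finite(sds)
  if (all(const)) stop("all columns are constant")
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  z <- scale(x)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "n_imputed") <- n_imp
  z
}

#' Principal-component gradients from a correlation matrix
#'
#' Eigen-decomposition of the correlation matrix of standardized covariates;
#' axis scores summarize the major abiotic/biotic gradients and replace the
#' raw (collinear) variables as model predictors. Axes are ordered by
#' decreasing eigenvalue; each axis is signed so that its largest-magnitude
#' loading is positive.
#'
#' @param z standardized matrix from [standardize()], no missing values.
#' @param variable_groups optional character vector (`"abiotic"`/`"biotic"`)
#'   tagging each source column.
#' @return A `gradient_set` list: `scores` (site x axis), `loadings`
#'   (variable x axis eigenvectors), `eigenvalues`, `proportion_variance`,
#'   `selected` (logical mask, initially all `TRUE`), `variable_groups`.
#' @export
pca_gradients <- function(z, variable_groups = NULL) {
  z <- as.matrix(z)
  if (any(is.na(z)))
    stop("missing values present; impute first (standardize() mean-imputes)")
  R <- crossprod(z) / (nrow(z) - 1)
  eig <- eigen(R, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  vec <- eig$vectors
  for (a in seq_len(ncol(vec))) {
    top <- which.max(abs(vec[, a]))
    if (vec[top, a] < 0) vec[, a] <- -vec[, a]
  }
  dimnames(vec) <- list(colnames(z), paste0("PC", seq_len(ncol(vec))))
  scores <- z %*% vec
  out <- list(scores = scores, loadings = vec, eigenvalues = ev,
              proportion_variance = ev / sum(ev),
              selected = rep(TRUE, length(ev)),
              variable_groups = variable_groups)
  class(out) <- "gradient_set"
  out
}

#' Select leading axes covering a target fraction of variance
#'
#' Marks as selected the smallest leading prefix of axes whose cumulative
#' variance proportion reaches `target_fraction` (default 2/3).
#'
#' @param g a `gradient_set` from [pca_gradients()].
#' @param target_fraction proportion in (0, 1].
#' @return The `gradient_set` with an updated `selected` mask.
#' @export
select_axes <- function(g, target_fraction = 2 / 3) {
  if (!(target_fraction > 0 && target_fraction <= 1))
    stop("target_fraction must be in (0, 1]")
  cum <- cumsum(g$proportion_variance)
  k <- which(cum >= target_fraction - 1e-12)[1]
  if (is.na(k)) k <- length(cum)
  g$selected <- seq_along(cum) <= k
  g
}

#' Scores of the selected gradient axes
#' @param g a `gradient_set`.
#' @return Matrix of site scores restricted to selected axes.
#' @export
gradient_scores <- function(g) g$scores[, g$selected, drop = FALSE]
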