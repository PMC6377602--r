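#' Empirical semivariogram
#'
#' Binned method-of-moments semivariogram: for each distance class the
#' average of half the squared value differences over site pairs in the
#' class.
#'
#' @param values per-site variable.
#' @param coords site coordinates.
#' @param n_bins number of distance bins (default 12).
#' @param max_dist maximum pair distance used (default half the largest
#'   inter-site distance, the usual reliable variogram span).
#' @return Data frame `d_mid`, `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(values, coords, n_bins = 12,
                                max_dist = NULL) {
  D <- pairwise_distances(coords)
  iu <- upper.tri(D)
  d <- D[iu]
  g <- 0.5 * outer(values, values, "-")[iu]^2
  if (is.null(max_dist)) max_dist <- max(d) / 2
  keep <- d <= max_dist & d > 0
  d <- d[keep]; g <- g[keep]
  edges <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(d, edges, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    d_mid = tapply(d, bin, mean),
    gamma = tapply(g, bin, mean),
    n_pairs = as.numeric(table(factor(bin, levels = seq_len(n_bins)))[
      names(tapply(d, bin, mean))]))
  out[is.finite(out$gamma), , drop = FALSE]
}

#' Least-squares spherical fit to an empirical variogram
#'
#' Fits range, nugget proportion and sill of a spherical model by
#' pair-count-weighted least squares on the binned semivariogram.
#'
#' @param vg data frame from [empirical_variogram()].
#' @param nugget_max upper bound for the nugget proportion (default 0.9,
#'   which keeps the implied correlation matrix comfortably invertible).
#' @return A [spherical_model()].
#' @export
fit_spherical_variogram <- function(vg, nugget_max = 0.9) {
  s0 <- max(vg$gamma)
  if (s0 <= 0) return(spherical_model(range = max(vg$d_mid), nugget = 0,
                                      sill = 0))
  obj <- function(par) {
    r <- par[1]; nu <- par[2]; s <- par[3]
    u <- pmin(vg$d_mid / r, 1)
    gam <- s * (nu + (1 - nu) * (1.5 * u - 0.5 * u^3))
    sum(vg$n_pairs * (vg$gamma - gam)^2)
  }
  fit <- optim(c(stats::median(vg$d_mid), 0.1, s0), obj,
               method = "L-BFGS-B",
               lower = c(min(vg$d_mid) / 10, 0, s0 / 100),
               upper = c(max(vg$d_mid) * 4, nugget_max, s0 * 10))
  spherical_model(range = fit$par[1], nugget = fit$par[2], sill = fit$par[3])
}

#' Binomial occupancy regression with spatially correlated residuals
#'
#' Penalized quasi-likelihood fit of a logistic occupancy model whose
#' working residuals carry spherical spatial correlation. Each outer
#' iteration (a) linearizes: working response z = eta + (y - mu)/(mu(1-mu))
#' with weights w = mu(1-mu); (b) solves the generalized least-squares
#' problem for z on the design with covariance
#' diag(1/w)^0.5 R(theta) diag(1/w)^0.5, R the spherical correlation over
#' inter-site distances; (c) when `correlation = "estimate"`, re-fits theta
#' (range, nugget) to the empirical semivariogram of the Pearson residuals.
#' Standard errors come from the GLS information matrix (X' V^-1 X)^-1 and
#' p-values from t on n - p degrees of freedom.
#'
#' @param y binary response vector.
#' @param X design matrix of predictors (no intercept column; one is added),
#'   or `NULL` for an intercept-only model.
#' @param coords site coordinates.
#' @param correlation `"estimate"` (default), `"none"` (identity R, i.e. an
#'   ordinary logistic regression solved by the same machinery), or a fixed
#'   [spherical_model()].
#' @param max_iter,tol outer-loop controls: convergence when the largest
#'   coefficient change is below `tol` (default 1e-6) within `max_iter`
#'   (default 50) iterations.
#' @return A `glmm_fit` list: `coefficients` data frame (`estimate`,
#'   `std_error`, `t_value`, `p_value`), `estimates`, `std_errors`,
#'   `fitted_prob`, `working_residuals`, `standardized_residuals`,
#'   `correlation_estimate`, `converged`, `n_iterations`, `df_residual`.
#' @export
fit_binomial_pql <- function(y, X = NULL, coords, correlation = "estimate",
                             max_iter = 50, tol = 1e-6) {
  y <- as.numeric(y)
  n <- length(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary")
  design <- if (is.null(X)) matrix(1, n, 1, dimnames = list(NULL,
                                                            "(Intercept)"))
  else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    cbind("(Intercept)" = 1, X)
  }
  p <- ncol(design)
  if (qr(design)$rank < p) stop("design matrix is rank deficient")
  D <- pairwise_distances(coords)
  D[D == 0] <- 1e-8; diag(D) <- 0   # duplicate-location jitter
  estimate_theta <- identical(correlation, "estimate")
  theta <- if (inherits(correlation, "spherical_model")) correlation
  else spherical_model(range = max(D) / 4, nugget = 0.1)
  use_identity <- identical(correlation, "none")

  start <- suppressWarnings(stats::glm.fit(design, y,
                                           family = stats::binomial()))
  if (all(abs(y - start$fitted.values) < 1e-6))
    stop("response is completely separated by the predictors; the maximum ",
         "likelihood estimate is unbounded - consider penalizing or ",
         "dropping predictors")
  beta <- start$coefficients
  beta[!is.finite(beta)] <- 0
  converged <- FALSE
  cov_beta <- NULL
  eta_cap <- 15   # linearize at a capped predictor: keeps z and 1/w bounded
  for (iter in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(design %*% beta), -eta_cap), eta_cap)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    if (estimate_theta) {
      e <- (y - mu) / sqrt(w)
      vg <- empirical_variogram(e, coords)
      theta <- fit_spherical_variogram(vg)
    }
    if (use_identity || theta$sill == 0) {
      Vw <- diag(1 / w)
      R <- NULL
      U <- chol(Vw)
    } else {
      R <- (1 - theta$nugget) * {
        u <- pmin(D / theta$range, 1)
        1 - 1.5 * u + 0.5 * u^3
      }
      diag(R) <- 1
      sw <- 1 / sqrt(w)
      V <- R * tcrossprod(sw)
      U <- chol(V + diag(1e-10, n))
    }
    A <- backsolve(U, design, transpose = TRUE)
    b <- backsolve(U, z, transpose = TRUE)
    XtX <- crossprod(A)
    beta_new <- drop(solve(XtX, crossprod(A, b)))
    names(beta_new) <- colnames(design)
    cov_beta <- solve(XtX)
    # step-halve if the proposed step pushes the predictor past the cap
    halvings <- 0
    while (max(abs(design %*% beta_new)) > 2 * eta_cap && halvings < 12) {
      beta_new <- (beta + beta_new) / 2
      halvings <- halvings + 1
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(design %*% beta)
  mu <- plogis(eta)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  se <- sqrt(diag(cov_beta))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  coef_tab <- data.frame(term = colnames(design), estimate = unname(beta),
                         std_error = unname(se), t_value = unname(tval),
                         p_value = unname(pval), stringsAsFactors = FALSE)
  out <- list(coefficients = coef_tab,
              estimates = beta, std_errors = setNames(se, names(beta)),
              fitted_prob = mu,
              working_residuals = (y - mu) / pmax(mu * (1 - mu), 1e-10),
              standardized_residuals = (y - mu) / sqrt(mu * (1 - mu)),
              correlation_estimate = if (use_identity) NULL else theta,
              converged = converged, n_iterations = iter,
              df_residual = n - p, y = y)
  class(out) <- "glmm_fit"
  out
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial PQL fit with spherical residual correlation\n")
  if (!is.null(x$correlation_estimate))
    cat(sprintf("  range %.1f m, nugget %.3f (converged: %s, %d iterations)\n",
                x$correlation_estimate$range, x$correlation_estimate$nugget,
                x$converged, x$n_iterations))
  stats::printCoefmat(`rownames<-`(as.matrix(x$coefficients[, -1]),
                            x$coefficients$term),
               P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Standardized residuals with coordinates for mapping
#'
#' Per-site (y - mu)/sqrt(mu(1-mu)) residuals with coordinates and a sign
#' class, as plotted in occupancy residual maps (negative vs positive
#' symbols).
#'
#' @param fit a `glmm_fit`.
#' @param coords site coordinates.
#' @return Data frame `x`, `y`, `residual`, `sign` (`"negative"`,
#'   `"positive"`, `"zero"`).
#' @export
standardized_residual_map <- function(fit, coords) {
  coords <- as.matrix(coords)
  r <- fit$standardized_residuals
  data.frame(x = coords[, 1], y = coords[, 2], residual = r,
             sign = ifelse(r < 0, "negative",
                           ifelse(r > 0, "positive", "zero")))
}

#' Moran's I correlogram of model residuals
#'
#' @param fit a `glmm_fit`.
#' @param coords site coordinates.
#' @param class_edges distance-class edges (default equal-count bins).
#' @param n_perm,rng_seed passed to [morans_i()].
#' @return A `correlogram` data frame.
#' @export
residual_correlogram <- function(fit, coords, class_edges = NULL,
                                 n_perm = 199, rng_seed = NULL) {
  morans_i(fit$standardized_residuals, coords, class_edges, n_perm, rng_seed)
}
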