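#' Synthetic landscape configuration
#'
#' Full parameterization of a simulated survey: uniformly placed sites in a
#' rectangular domain; independent Gaussian random fields (spherical
#' covariance) standing in for abiotic/biotic gradients; per-species
#' logit-scale occupancy models with gradient coefficients and an
#' interaction matrix `gamma` (logit shift applied to a species when an
#' earlier-generated species is present); and conditional negative-binomial
#' abundances where present.
#'
#' @param n_sites number of sites, `>= 10`.
#' @param extent domain extent `c(x_max, y_max)` in metres.
#' @param fields named list; each element a list with `range`, `sill`,
#'   `nugget`, `group` (`"abiotic"` or `"biotic"`).
#' @param species character vector; also the generation order, which must
#'   make `gamma` acyclic (donors precede recipients).
#' @param intercepts named logit intercepts per species.
#' @param coefs species x field matrix of logit coefficients.
#' @param gamma species x species matrix; entry `[j, i]` is the logit shift
#'   on species `i` where species `j` is present. Diagonal must be zero.
#' @param abundance_base named log-scale mean abundance per species.
#' @param abundance_coefs species x field matrix on the log-mean.
#' @param dispersion named negative-binomial dispersion k per species
#'   (variance mu + mu^2/k), `> 0`.
#' @param seed integer seed for the whole landscape build.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_sites, extent, fields, species, intercepts,
                             coefs, gamma, abundance_base, abundance_coefs,
                             dispersion, seed = 1) {
  if (n_sites < 10) stop("n_sites must be >= 10")
  if (any(vapply(fields, function(f) f$range <= 0, logical(1))))
    stop("field ranges must be > 0")
  gamma <- as.matrix(gamma)
  if (any(diag(gamma) != 0)) stop("gamma diagonal must be 0")
  ord <- match(species, species)
  for (a in seq_along(species)) for (b in seq_along(species))
    if (gamma[a, b] != 0 && a >= b)
      stop("cyclic or backward conditioning: gamma['", species[a], "','",
           species[b], "'] requires the donor to be generated first; ",
           "reorder `species` so the interaction graph is a DAG")
  if (any(unlist(dispersion) <= 0)) stop("dispersion must be > 0")
  structure(list(n_sites = n_sites, extent = extent, fields = fields,
                 species = species, intercepts = intercepts, coefs = coefs,
                 gamma = gamma, abundance_base = abundance_base,
                 abundance_coefs = abundance_coefs, dispersion = dispersion,
                 seed = seed),
            class = "synthetic_config")
}

#' Uniform random site coordinates
#' @param cfg a [synthetic_config()].
#' @param seed optional seed (default `cfg$seed`).
#' @return n x 2 matrix of coordinates within the domain.
#' @export
sample_sites <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  cbind(x = runif(cfg$n_sites, 0, cfg$extent[1]),
        y = runif(cfg$n_sites, 0, cfg$extent[2]))
}

#' Gaussian random field with spherical covariance
#'
#' One multivariate-normal draw with covariance
#' sill * spherical(d; range) + nugget * I, via Cholesky factorization.
#'
#' @param coords site coordinates.
#' @param range spherical range, metres.
#' @param sill partial sill (spatially structured variance).
#' @param nugget unstructured variance added on the diagonal.
#' @param seed optional seed.
#' @return Per-site values (marginal variance sill + nugget).
#' @export
gaussian_field <- function(coords, range, sill = 1, nugget = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(coords)
  D <- pairwise_distances(coords)
  Sigma <- sill * spherical_corr(D, spherical_model(range)) +
    diag(nugget + 1e-10, n)
  U <- tryCatch(chol(Sigma),
                error = function(e) stop("field covariance is not positive ",
                                         "definite: ", conditionMessage(e)))
  drop(crossprod(U, rnorm(n)))
}

.field_matrix <- function(coords, cfg, seed) {
  f <- vapply(seq_along(cfg$fields), function(i) {
    p <- cfg$fields[[i]]
    gaussian_field(coords, p$range, p$sill, p$nugget, seed = seed + i)
  }, numeric(nrow(coords)))
  colnames(f) <- names(cfg$fields)
  f
}

#' Simulate species occupancy over gradient fields
#'
#' Species are generated in the fixed `cfg$species` order. For each species,
#' logit p = intercept + sum(coef * field) + sum(gamma * presence of
#' earlier species), followed by a Bernoulli draw.
#'
#' @param fields site x field matrix (row-aligned with sites).
#' @param cfg a [synthetic_config()].
#' @param seed optional seed.
#' @return A [presence_matrix()].
#' @export
simulate_occupancy <- function(fields, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(fields)
  occ <- matrix(0L, n, length(cfg$species),
                dimnames = list(paste0("s", seq_len(n)), cfg$species))
  for (k in seq_along(cfg$species)) {
    sp <- cfg$species[k]
    eta <- cfg$intercepts[[sp]] +
      drop(fields %*% cfg$coefs[sp, colnames(fields)])
    if (k > 1)
      for (j in seq_len(k - 1))
        eta <- eta + cfg$gamma[j, k] * occ[, j]
    occ[, k] <- rbinom(n, 1, plogis(eta))
  }
  presence_matrix(occ, filtered = FALSE)
}

#' Simulate abundances conditional on occupancy
#'
#' Abundance is 0 where a species is absent; where present, a
#' negative-binomial draw with log-mean = species base + gradient terms and
#' dispersion k (variance mu + mu^2/k).
#'
#' @param pm a [presence_matrix()] from [simulate_occupancy()].
#' @param fields site x field matrix.
#' @param cfg a [synthetic_config()].
#' @param seed optional seed.
#' @return A [community_matrix()].
#' @export
simulate_abundance <- function(pm, fields, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  occ <- unclass(pm)
  ab <- matrix(0, nrow(occ), ncol(occ), dimnames = dimnames(occ))
  for (k in seq_along(cfg$species)) {
    sp <- cfg$species[k]
    if (cfg$dispersion[[sp]] <= 0) stop("dispersion must be > 0")
    mu <- exp(cfg$abundance_base[[sp]] +
                drop(fields %*% cfg$abundance_coefs[sp, colnames(fields)]))
    present <- occ[, k] == 1L
    ab[present, k] <- rnbinom(sum(present), mu = mu[present],
                              size = cfg$dispersion[[sp]])
  }
  community_matrix(ab)
}

#' Build a complete synthetic landscape
#'
#' Deterministic under `cfg$seed`: coordinates, each gradient field, the
#' occupancy draw and the abundance draw consume separate seeds derived from
#' it by fixed offsets.
#'
#' @param cfg a [synthetic_config()].
#' @return A `synthetic_landscape` list: `sites` (a [site_table()] with the
#'   field values as covariate columns), `fields`, `presence`, `abundance`,
#'   `truth` (the generating config).
#' @export
simulate_landscape <- function(cfg) {
  coords <- sample_sites(cfg)
  fields <- .field_matrix(coords, cfg, seed = cfg$seed + 100L)
  pm <- simulate_occupancy(fields, cfg, seed = cfg$seed + 200L)
  cm <- simulate_abundance(pm, fields, cfg, seed = cfg$seed + 300L)
  st <- site_table(data.frame(site_id = rownames(pm), x = coords[, 1],
                              y = coords[, 2], fields,
                              stringsAsFactors = FALSE))
  structure(list(sites = st, fields = fields, presence = pm, abundance = cm,
                 truth = cfg),
            class = "synthetic_landscape")
}

# Solve per-species logit intercepts so expected occupancies hit the target
# frequencies, by fixed-seed Monte Carlo over the fields' marginal
# distribution (deterministic: local RNG state, internal seed).
.calibrate_intercepts <- function(fields, species, coefs, gamma, targets,
                                  n_draws = 40000) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(20260101)
  sds <- vapply(fields, function(f) sqrt(f$sill + f$nugget), numeric(1))
  g <- sapply(seq_along(fields), function(i) rnorm(n_draws, 0, sds[i]))
  colnames(g) <- names(fields)
  p_prev <- matrix(0, n_draws, 0)
  intercepts <- numeric(0)
  for (k in seq_along(species)) {
    sp <- species[k]
    base <- drop(g %*% coefs[sp, colnames(g)])
    donors <- if (k > 1) which(gamma[seq_len(k - 1), k] != 0) else integer(0)
    expected_p <- function(a) {
      p <- plogis(a + base)
      if (length(donors) > 0) {
        p <- rep(0, n_draws)
        combos <- expand.grid(rep(list(c(0, 1)), length(donors)))
        for (r in seq_len(nrow(combos))) {
          on_ <- unlist(combos[r, ])
          w <- rep(1, n_draws)
          for (di in seq_along(donors)) {
            pj <- p_prev[, donors[di]]
            w <- w * ifelse(on_[di] == 1, pj, 1 - pj)
          }
          shift <- sum(gamma[donors, k] * on_)
          p <- p + w * plogis(a + base + shift)
        }
      }
      mean(p)
    }
    a <- uniroot(function(a) expected_p(a) - targets[[sp]],
                 c(-20, 20), tol = 1e-6)$root
    intercepts[sp] <- a
    p_sp <- plogis(a + base)
    if (length(donors) > 0) {
      shift <- drop((p_prev[, donors, drop = FALSE] >= runif(n_draws)) %*%
                      gamma[donors, k])
      p_sp <- plogis(a + base + shift)
    }
    p_prev <- cbind(p_prev, p_sp)
  }
  intercepts
}

#' Shipped landscape presets
#'
#' Three calibrated study designs over a 20 x 11 km domain with 314 sites:
#' \describe{
#'   \item{`mdv_like`}{Dry-valley-like conditions: four spatially
#'     autocorrelated gradients (two abiotic: moisture, salinity/elevation;
#'     two biotic: microbial richness, microbial biomass; ranges 4.5 km and
#'     3 km), opposing species responses, expected occupancies 289/222/50
#'     of 314, and one negative interaction (logit shift -2 of the dominant
#'     species on the rarest).}
#'   \item{`null`}{No interactions and no shared fields: each species
#'     responds only to its own private gradient; the calibration target
#'     for pairwise-test type-I error.}
#'   \item{`env_only`}{No interactions, but strong opposing responses of the
#'     first and third species to the shared moisture gradient: segregation
#'     produced purely by the environment.}
#' }
#'
#' @param name one of `"mdv_like"`, `"null"`, `"env_only"`.
#' @param seed landscape seed.
#' @return A [synthetic_config()].
#' @export
preset_config <- function(name = c("mdv_like", "null", "env_only"),
                          seed = 1) {
  name <- match.arg(name)
  species <- c("Scottnema", "Eudorylaimus", "Plectus")
  targets <- c(Scottnema = 289, Eudorylaimus = 222, Plectus = 50) / 314
  fields <- list(
    moisture_gradient = list(range = 4500, sill = 1, nugget = 0.1,
                             group = "abiotic"),
    salinity_elevation = list(range = 4500, sill = 1, nugget = 0.1,
                              group = "abiotic"),
    microbial_richness = list(range = 3000, sill = 1, nugget = 0.1,
                              group = "biotic"),
    microbial_biomass = list(range = 3000, sill = 1, nugget = 0.1,
                             group = "biotic"))
  gamma <- matrix(0, 3, 3, dimnames = list(species, species))
  coefs <- matrix(0, 3, 4, dimnames = list(species, names(fields)))
  if (name == "mdv_like") {
    coefs["Scottnema", ] <- c(-0.7, 0.3, 0.5, 0)
    coefs["Eudorylaimus", ] <- c(0.3, -0.5, 0.5, 0)
    coefs["Plectus", ] <- c(0.6, 0, 0, 0.7)
    gamma["Scottnema", "Plectus"] <- -2
  } else if (name == "env_only") {
    coefs["Scottnema", ] <- c(-1.5, 0.3, 0.5, 0)
    coefs["Eudorylaimus", ] <- c(0.3, -0.5, 0.5, 0)
    coefs["Plectus", ] <- c(1.5, 0, 0, 0.7)
  } else {
    fields <- list(
      field_sc = list(range = 4500, sill = 1, nugget = 0.1,
                      group = "abiotic"),
      field_eu = list(range = 4500, sill = 1, nugget = 0.1,
                      group = "abiotic"),
      field_pl = list(range = 3000, sill = 1, nugget = 0.1,
                      group = "biotic"))
    coefs <- matrix(0, 3, 3, dimnames = list(species, names(fields)))
    coefs["Scottnema", "field_sc"] <- 0.7
    coefs["Eudorylaimus", "field_eu"] <- 0.7
    coefs["Plectus", "field_pl"] <- 0.7
  }
  intercepts <- .calibrate_intercepts(fields, species, coefs, gamma, targets)
  abundance_base <- c(Scottnema = log(600), Eudorylaimus = log(80),
                      Plectus = log(50))
  synthetic_config(n_sites = 314, extent = c(20000, 11000), fields = fields,
                   species = species, intercepts = intercepts, coefs = coefs,
                   gamma = gamma, abundance_base = abundance_base,
                   abundance_coefs = 0.5 * coefs,
                   dispersion = c(Scottnema = 1, Eudorylaimus = 1,
                                  Plectus = 1),
                   seed = seed)
}
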