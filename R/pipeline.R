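#' Analysis configuration
#'
#' Bundles inputs and settings for [run_full_analysis()]. `sites` and
#' `abundance` may be in-memory objects or CSV paths.
#'
#' @param sites a [site_table()] or CSV path.
#' @param abundance a [community_matrix()] or CSV path (first column site
#'   id).
#' @param abiotic_vars,biotic_vars character vectors naming site-table
#'   columns entering the abiotic / biotic gradient PCAs.
#' @param aspect_var optional name of a categorical aspect column, entered
#'   in occupancy models as dummy variables (most frequent level as
#'   reference), not through the PCA.
#' @param species_order optional species ordering for reports.
#' @param null_iters,burn_in,thin,alpha SIM9 null-model settings.
#' @param pca_target cumulative variance fraction for axis selection
#'   (default 2/3).
#' @param glmm_correlation passed to [fit_binomial_pql()].
#' @param rda_permutations permutations for the RDA overall test.
#' @param seed single global seed; every stochastic stage consumes a seed
#'   derived from it by a fixed per-stage offset, so disabling one stage
#'   does not change another stage's randomness.
#' @param stages character vector of stages to run (default all):
#'   `"counts"`, `"nullmodel"`, `"gradients"`, `"spatial"`, `"glmm"`,
#'   `"correlogram"`, `"ordination"`.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(sites, abundance, abiotic_vars, biotic_vars,
                            aspect_var = NULL, species_order = NULL,
                            null_iters = 5000, burn_in = 30000, thin = NULL,
                            alpha = 0.05, pca_target = 2 / 3,
                            glmm_correlation = "estimate",
                            rda_permutations = 199, seed = 1,
                            stages = c("counts", "nullmodel", "gradients",
                                       "spatial", "glmm", "correlogram",
                                       "ordination")) {
  if (is.character(sites)) sites <- load_site_table(sites)
  if (is.character(abundance)) abundance <- read_community_matrix(abundance)
  structure(list(sites = sites, abundance = abundance,
                 abiotic_vars = abiotic_vars, biotic_vars = biotic_vars,
                 aspect_var = aspect_var, species_order = species_order,
                 null_iters = null_iters, burn_in = burn_in, thin = thin,
                 alpha = alpha, pca_target = pca_target,
                 glmm_correlation = glmm_correlation,
                 rda_permutations = rda_permutations, seed = seed,
                 stages = stages),
            class = "analysis_config")
}

#' Configuration for a synthetic landscape
#'
#' Convenience wrapper building an [analysis_config()] from a
#' [simulate_landscape()] result, grouping the generator's fields by their
#' declared abiotic/biotic tags.
#'
#' @param land a `synthetic_landscape`.
#' @param ... further arguments to [analysis_config()].
#' @export
analysis_config_from_landscape <- function(land, ...) {
  groups <- vapply(land$truth$fields, function(f) f$group, character(1))
  analysis_config(sites = land$sites, abundance = land$abundance,
                  abiotic_vars = names(groups)[groups == "abiotic"],
                  biotic_vars = names(groups)[groups == "biotic"],
                  species_order = land$truth$species, ...)
}

.stage_seed <- function(cfg, k) (cfg$seed + k * 10007L) %% .Machine$integer.max

.aspect_dummies <- function(st, aspect_var) {
  if (is.null(aspect_var)) return(NULL)
  f <- factor(st[[aspect_var]])
  f <- stats::relevel(f, ref = names(which.max(table(f))))
  mm <- model.matrix(~f)[, -1, drop = FALSE]
  colnames(mm) <- sub("^f", paste0(aspect_var, " "), colnames(mm))
  mm
}

#' Run the full co-occurrence analysis chain
#'
#' Descriptive counts, SIM9 null models (matrix-wide and pairwise), abiotic
#' and biotic gradient PCAs, PCNM spatial eigenvectors with AIC forward
#' selection, per-species spatial binomial GLMMs (predictors: selected
#' gradient axes, optional aspect dummies, and the presence of the other
#' species), residual correlograms, and the Hellinger-RDA stage with
#' three-set variance partitioning and residual cross-species correlations.
#' Stage failures are caught and recorded; the report is still emitted for
#' the stages that completed. Fully deterministic under `cfg$seed`.
#'
#' @param cfg an [analysis_config()].
#' @return An `analysis_report` list; elements may be `NULL` for disabled
#'   or failed stages, with failures recorded in `$errors`.
#' @export
run_full_analysis <- function(cfg) {
  report <- list(errors = list(),
                 provenance = list(package = "cooccurspat",
                                   version = as.character(
                                     utils::packageVersion("cooccurspat")),
                                   seed = cfg$seed))
  run_stage <- function(name, expr) {
    if (!(name %in% cfg$stages)) return(NULL)
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  pm_all <- to_presence(cfg$abundance)
  pm <- filter_occupied_sites(pm_all)
  if (!is.null(cfg$species_order)) {
    pm <- presence_matrix(unclass(pm)[, cfg$species_order, drop = FALSE],
                          filtered = TRUE)
  }
  st <- cfg$sites[match(rownames(pm), cfg$sites$site_id), , drop = FALSE]
  cm <- cfg$abundance[rownames(pm), colnames(pm), drop = FALSE]
  coords <- as.matrix(st[, c("x", "y")])

  report$counts <- run_stage("counts", cooccurrence_counts(pm))
  report$null_matrix <- run_stage("nullmodel",
    null_distribution(pm, n_iter = cfg$null_iters, burn_in = cfg$burn_in,
                      thin = cfg$thin, rng_seed = .stage_seed(cfg, 1)))
  report$pairwise <- run_stage("nullmodel",
    pairwise_tests(pm, n_iter = cfg$null_iters, burn_in = cfg$burn_in,
                   thin = cfg$thin, alpha = cfg$alpha,
                   rng_seed = .stage_seed(cfg, 2)))

  gradients <- run_stage("gradients", {
    list(abiotic = select_axes(pca_gradients(
           standardize(st[, cfg$abiotic_vars, drop = FALSE]),
           variable_groups = rep("abiotic", length(cfg$abiotic_vars))),
           cfg$pca_target),
         biotic = select_axes(pca_gradients(
           standardize(st[, cfg$biotic_vars, drop = FALSE]),
           variable_groups = rep("biotic", length(cfg$biotic_vars))),
           cfg$pca_target))
  })
  report$gradients <- gradients

  hel <- hellinger(cm)
  spatial <- run_stage("spatial", {
    sev <- build_pcnm(coords)
    forward_select_aic(hel, sev)
  })
  report$spatial <- spatial

  if (!is.null(gradients)) {
    ab_scores <- gradient_scores(gradients$abiotic)
    colnames(ab_scores) <- paste0("abiotic_", colnames(ab_scores))
    bi_scores <- gradient_scores(gradients$biotic)
    colnames(bi_scores) <- paste0("biotic_", colnames(bi_scores))
    aspect <- .aspect_dummies(st, cfg$aspect_var)

    report$glmm <- run_stage("glmm", {
      fits <- lapply(colnames(pm), function(sp) {
        others <- unclass(pm)[, setdiff(colnames(pm), sp), drop = FALSE]
        colnames(others) <- paste0(colnames(others), " (yes)")
        X <- cbind(ab_scores, bi_scores, aspect, others)
        fit_binomial_pql(unclass(pm)[, sp], X, coords,
                         correlation = cfg$glmm_correlation)
      })
      names(fits) <- colnames(pm)
      fits
    })

    report$correlograms <- run_stage("correlogram", {
      if (is.null(report$glmm)) stop("glmm stage unavailable")
      lapply(report$glmm, residual_correlogram, coords = coords,
             rng_seed = .stage_seed(cfg, 3))
    })

    report$ordination <- run_stage("ordination", {
      x_env <- cbind(ab_scores, bi_scores)
      full <- rda(hel, x_env, n_perm = cfg$rda_permutations,
                  rng_seed = .stage_seed(cfg, 4))
      vp <- variance_partition(hel, ab_scores, bi_scores,
                               if (is.null(spatial)) NULL
                               else pcnm_scores(spatial))
      list(rda = full, variance_partition = vp,
           residual_correlations = residual_correlations(full))
    })
  }
  report$coords <- coords
  class(report) <- "analysis_report"
  report
}

.report_to_list <- function(report) {
  num <- function(x) if (is.null(x)) NULL else unclass(x)
  nd_list <- function(nd) if (is.null(nd)) NULL else
    nd[c("observed", "null_mean", "null_sd", "ses", "ci_low", "ci_high",
         "p_upper", "p_lower", "n_iter", "burn_in", "thin")]
  list(
    provenance = report$provenance,
    errors = report$errors,
    counts = num(report$counts),
    null_matrix = nd_list(report$null_matrix),
    pairwise = if (is.null(report$pairwise)) NULL else
      as.data.frame(report$pairwise),
    glmm = if (is.null(report$glmm)) NULL else
      lapply(report$glmm, function(f)
        list(coefficients = f$coefficients, converged = f$converged,
             correlation = f$correlation_estimate[c("range", "nugget")])),
    correlograms = if (is.null(report$correlograms)) NULL else
      lapply(report$correlograms, as.data.frame),
    ordination = if (is.null(report$ordination)) NULL else list(
      r2 = report$ordination$rda$r2,
      adj_r2 = report$ordination$rda$adj_r2,
      permutation_p = report$ordination$rda$permutation_p,
      variance_partition =
        as.list(report$ordination$variance_partition$fractions),
      total_explained = report$ordination$variance_partition$total_explained,
      residual_correlations = report$ordination$residual_correlations))
}

#' Write the report JSON and diagnostic figures
#'
#' Writes `report.json` plus, per species, a residual map (sign-coded
#' circles over the site coordinates), per species pair a residual scatter
#' plot, and one residual-correlogram figure.
#'
#' @param report an `analysis_report`.
#' @param outdir output directory (created if needed).
#' @param timestamp logical; include a timestamp in the JSON provenance
#'   (disable for byte-identical reruns).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, outdir, timestamp = TRUE) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  lst <- .report_to_list(report)
  if (timestamp) lst$provenance$timestamp <- format(Sys.time(), tz = "UTC")
  json_path <- file.path(outdir, "report.json")
  jsonlite::write_json(lst, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  paths <- json_path
  coords <- report$coords
  if (!is.null(report$glmm)) {
    for (sp in names(report$glmm)) {
      p <- file.path(outdir, paste0("residual_map_", sp, ".png"))
      grDevices::png(p, width = 700, height = 500)
      rmap <- standardized_residual_map(report$glmm[[sp]], coords)
      plot(rmap$x, rmap$y, pch = 21,
           bg = ifelse(rmap$residual < 0, "black", "grey70"),
           cex = 0.4 + abs(rmap$residual) / max(abs(rmap$residual)),
           xlab = "x (m)", ylab = "y (m)",
           main = paste("Standardized occupancy residuals:", sp))
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  if (!is.null(report$ordination)) {
    res <- report$ordination$rda$residuals
    prs <- utils::combn(colnames(res), 2)
    for (k in seq_len(ncol(prs))) {
      p <- file.path(outdir, paste0("residual_scatter_", prs[1, k], "_",
                                    prs[2, k], ".png"))
      grDevices::png(p, width = 500, height = 500)
      plot(res[, prs[1, k]], res[, prs[2, k]], pch = 16, cex = 0.6,
           xlab = paste("RDA residual,", prs[1, k]),
           ylab = paste("RDA residual,", prs[2, k]))
      graphics::abline(lm.fit(cbind(1, res[, prs[1, k]]),
                              res[, prs[2, k]])$coefficients, col = 2)
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  if (!is.null(report$correlograms)) {
    p <- file.path(outdir, "residual_correlograms.png")
    grDevices::png(p, width = 700, height = 500)
    first <- TRUE
    cols <- seq_along(report$correlograms)
    for (k in cols) {
      cg <- report$correlograms[[k]]
      if (first) {
        plot(cg$d_mid, cg$morans_i, type = "b", col = k, pch = 16,
             xlab = "distance class midpoint (m)", ylab = "Moran's I",
             ylim = range(unlist(lapply(report$correlograms,
                                        function(z) z$morans_i)),
                          na.rm = TRUE),
             main = "Residual correlograms")
        first <- FALSE
      } else graphics::lines(cg$d_mid, cg$morans_i, type = "b", col = k,
                             pch = 16)
    }
    graphics::abline(h = 0, lty = 2)
    graphics::legend("topright", legend = names(report$correlograms),
                     col = cols, lty = 1, pch = 16, bty = "n")
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}
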