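#' Site tables, community matrices and presence/absence views
#'
#' A `site_table` is a data frame of sampling locations with projected planar
#' coordinates in metres (`x`, `y`), a unique `site_id`, and any number of
#' abiotic/biotic covariate columns (elevation, aspect, moisture, pH,
#' conductivity, organic C, total N, microbial biomass and richness proxies,
#' other-fauna counts, ...). A `community_matrix` is a site-by-species matrix
#' of non-negative abundances (individuals per kg dry soil); a
#' `presence_matrix` is its binary occupancy view.
#'
#' Geographic (longitude/latitude) coordinates must be projected before use:
#' all distances are planar Euclidean, which is adequate at the landscape
#' scales (tens of km) these methods address.
#'
#' @name community-data
NULL

.required_site_cols <- c("site_id", "x", "y")

#' Construct a site table
#'
#' @param df data frame containing at least `site_id`, `x`, `y`.
#' @return A `site_table` (a classed data frame).
#' @export
site_table <- function(df) {
  missing_cols <- setdiff(.required_site_cols, names(df))
  if (length(missing_cols) > 0L)
    stop("site table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df$site_id <- as.character(df$site_id)
  df$x <- as.double(df$x)
  df$y <- as.double(df$y)
  dup <- unique(df$site_id[duplicated(df$site_id)])
  if (length(dup) > 0L)
    stop("duplicated site_id(s): ", paste(dup, collapse = ", "))
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad) > 0L) {
    warning("rejecting ", length(bad), " row(s) with missing/non-finite ",
            "coordinates at row index: ", paste(bad, collapse = ", "))
    df <- df[-bad, , drop = FALSE]
  }
  if (!is.null(df[["moisture"]]) &&
      any(!is.na(df[["moisture"]]) & df[["moisture"]] < 0))
    stop("moisture must be >= 0")
  rownames(df) <- NULL
  class(df) <- c("site_table", "data.frame")
  df
}

#' Read a site table from CSV
#'
#' @param path path to a CSV file with a header row and "." decimal points.
#' @return A [site_table()].
#' @export
load_site_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  site_table(df)
}

#' Write a site table to CSV
#'
#' Numeric columns are written with 15 significant digits so a write/read
#' round trip reproduces values to better than 1e-12 relative error.
#'
#' @param st a [site_table()].
#' @param path output path.
#' @export
write_site_table <- function(st, path) {
  out <- as.data.frame(st)
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- formatC(out[[nm]], digits = 15,
                                                   format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a community (abundance) matrix
#'
#' @param abundance numeric site-by-species matrix, non-negative and finite.
#' @param sites,species optional id vectors; default taken from `dimnames`.
#' @return A `community_matrix`.
#' @export
community_matrix <- function(abundance, sites = rownames(abundance),
                             species = colnames(abundance)) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(sites)) sites <- paste0("site", seq_len(nrow(abundance)))
  if (is.null(species)) species <- paste0("sp", seq_len(ncol(abundance)))
  if (length(sites) != nrow(abundance) || length(species) != ncol(abundance))
    stop("dimension of abundance matrix does not match id lists")
  if (any(!is.finite(abundance)) || any(abundance < 0))
    stop("abundances must be finite and >= 0")
  dimnames(abundance) <- list(as.character(sites), as.character(species))
  class(abundance) <- c("community_matrix", class(abundance))
  abundance
}

#' Read a community matrix from CSV (first column = site id)
#' @param path CSV path.
#' @return A [community_matrix()].
#' @export
read_community_matrix <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  community_matrix(m)
}

#' Write a community matrix to CSV
#' @param cm a [community_matrix()].
#' @param path output path.
#' @export
write_community_matrix <- function(cm, path) {
  df <- data.frame(site_id = rownames(cm), check.names = FALSE)
  for (j in seq_len(ncol(cm)))
    df[[colnames(cm)[j]]] <- formatC(cm[, j], digits = 15, format = "g")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a presence/absence matrix
#'
#' @param occupancy site-by-species matrix with entries in \{0, 1\}.
#' @param sites,species optional id vectors.
#' @param filtered logical flag recording whether zero-richness sites have
#'   been dropped (see [filter_occupied_sites()]).
#' @return A `presence_matrix`.
#' @export
presence_matrix <- function(occupancy, sites = rownames(occupancy),
                            species = colnames(occupancy), filtered = FALSE) {
  occupancy <- as.matrix(occupancy)
  storage.mode(occupancy) <- "integer"
  if (!all(occupancy %in% c(0L, 1L)))
    stop("occupancy entries must be 0 or 1")
  if (is.null(sites)) sites <- paste0("site", seq_len(nrow(occupancy)))
  if (is.null(species)) species <- paste0("sp", seq_len(ncol(occupancy)))
  dimnames(occupancy) <- list(as.character(sites), as.character(species))
  attr(occupancy, "filtered") <- isTRUE(filtered)
  class(occupancy) <- c("presence_matrix", class(occupancy))
  occupancy
}

#' Binary occupancy view of a community matrix
#'
#' Presence is abundance strictly greater than `threshold` (default 0), so
#' any recorded individual counts as presence.
#'
#' @param cm a [community_matrix()].
#' @param threshold abundance threshold, `>= 0`.
#' @return A [presence_matrix()].
#' @export
to_presence <- function(cm, threshold = 0) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a single value >= 0")
  occ <- (unclass(cm) > threshold) * 1L
  presence_matrix(occ, rownames(cm), colnames(cm), filtered = FALSE)
}

#' Drop sites where no species occurs
#'
#' @param pm a [presence_matrix()].
#' @return A [presence_matrix()] restricted to sites with at least one
#'   species, in the original site order, with the `filtered` flag set.
#' @export
filter_occupied_sites <- function(pm) {
  keep <- rowSums(unclass(pm)) > 0L
  presence_matrix(unclass(pm)[keep, , drop = FALSE],
                  rownames(pm)[keep], colnames(pm), filtered = TRUE)
}

#' Descriptive co-occurrence counts
#'
#' Per-species occupancy counts, per-pair co-occurrence counts, and the
#' richness histogram (number of sites holding 0, 1, ..., S species).
#'
#' @param pm a [presence_matrix()], normally filtered to occupied sites.
#' @return A `cooccurrence_summary` list with elements `n_sites`,
#'   `occupancy`, `pair_counts` (named by `"sp1:sp2"`), `richness_histogram`,
#'   and `sites_with_at_least_two`.
#' @export
cooccurrence_counts <- function(pm) {
  m <- unclass(pm)
  sp <- colnames(m)
  occupancy <- colSums(m)
  S <- crossprod(m)
  pairs <- utils::combn(length(sp), 2)
  pair_counts <- setNames(
    S[t(pairs)],
    apply(pairs, 2, function(p) paste(sp[p[1]], sp[p[2]], sep = ":")))
  richness <- rowSums(m)
  hist <- setNames(tabulate(richness + 1L, nbins = length(sp) + 1L),
                   0:length(sp))
  out <- list(n_sites = nrow(m),
              occupancy = occupancy,
              pair_counts = pair_counts,
              richness_histogram = hist,
              sites_with_at_least_two = sum(richness >= 2L))
  class(out) <- "cooccurrence_summary"
  out
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat("Co-occurrence summary over", x$n_sites, "sites\n")
  cat("Occupancy:\n"); print(x$occupancy)
  cat("Pair co-occurrence:\n"); print(x$pair_counts)
  cat("Richness histogram (0..S species):\n"); print(x$richness_histogram)
  cat("Sites with >= 2 species:", x$sites_with_at_least_two, "\n")
  invisible(x)
}

#' Reconstruct a three-species presence matrix from printed count summaries
#'
#' For a fixed-fixed (SIM9) null-model analysis the presence matrix enters
#' only through its row and column totals, and for three species the full
#' site-composition multiset is determined by the per-species occupancies,
#' the three pairwise co-occurrence counts, the number of sites holding all
#' three species, and the total number of occupied sites. Published count
#' summaries are therefore sufficient to rebuild an exact null-model input
#' even when the underlying site-by-species table is not available.
#'
#' @param occupancy named vector of 3 per-species occupancy counts.
#' @param pair_counts named vector of 3 pairwise co-occurrence counts in the
#'   order (1,2), (1,3), (2,3) of `names(occupancy)`.
#' @param triple number of sites where all three species co-occur.
#' @param n_sites total number of sites (each holding >= 1 species).
#' @return A filtered [presence_matrix()] (site order: composition blocks).
#' @export
presence_from_counts <- function(occupancy, pair_counts, triple, n_sites) {
  if (length(occupancy) != 3L || length(pair_counts) != 3L)
    stop("exactly three species are supported")
  sp <- names(occupancy)
  if (is.null(sp)) sp <- paste0("sp", 1:3)
  s12 <- pair_counts[[1]]; s13 <- pair_counts[[2]]; s23 <- pair_counts[[3]]
  n123 <- triple
  n12 <- s12 - n123; n13 <- s13 - n123; n23 <- s23 - n123
  n1 <- occupancy[[1]] - n12 - n13 - n123
  n2 <- occupancy[[2]] - n12 - n23 - n123
  n3 <- occupancy[[3]] - n13 - n23 - n123
  comp <- c(n123, n12, n13, n23, n1, n2, n3)
  if (any(comp < 0))
    stop("inconsistent counts: a site-composition class would be negative")
  if (sum(comp) != n_sites)
    stop("inconsistent counts: composition classes sum to ", sum(comp),
         ", not n_sites = ", n_sites)
  patterns <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
                    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  occ <- patterns[rep(seq_len(7L), comp), , drop = FALSE]
  presence_matrix(occ, sites = paste0("site", seq_len(n_sites)),
                  species = sp, filtered = TRUE)
}
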