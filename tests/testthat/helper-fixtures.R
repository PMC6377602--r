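# Shared fixtures: small random binary matrices and the presence matrix
# rebuilt from the dry-valley survey's published count summaries.

random_presence <- function(nr, nc, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  presence_matrix(matrix(rbinom(nr * nc, 1, p), nr, nc))
}

mdv_counts_matrix <- function() {
  presence_from_counts(
    occupancy = c(Scottnema = 289, Eudorylaimus = 222, Plectus = 50),
    pair_counts = c(204, 32, 41), triple = 30, n_sites = 314)
}

# brute-force oracle: per-pair checkerboard units by an explicit site loop
brute_pair_cu <- function(m, i, j) {
  ri <- 0; rj <- 0; s <- 0
  for (k in seq_len(nrow(m))) {
    ri <- ri + m[k, i]; rj <- rj + m[k, j]
    s <- s + m[k, i] * m[k, j]
  }
  (ri - s) * (rj - s)
}

brute_c_score <- function(m) {
  cu <- c()
  for (i in seq_len(ncol(m) - 1))
    for (j in (i + 1):ncol(m))
      cu <- c(cu, brute_pair_cu(m, i, j))
  mean(cu)
}

# exhaustive enumeration of all binary matrices with given margins
enumerate_fixed_fixed <- function(rs, cs) {
  nr <- length(rs); nc <- length(cs)
  cells <- expand.grid(rep(list(0:1), nr * nc))
  keep <- apply(cells, 1, function(v) {
    m <- matrix(v, nr, nc)
    all(rowSums(m) == rs) && all(colSums(m) == cs)
  })
  lapply(which(keep), function(r) matrix(unlist(cells[r, ]), nr, nc))
}

matrix_key <- function(m) paste(as.integer(m), collapse = "")
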