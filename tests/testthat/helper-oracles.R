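# Independent oracles and small fixture builders shared across tests.

# Brute-force weighted Newman-Girvan modularity straight from the definition:
# Q = sum_ij (A_ij / 2m - k_i k_j / (2m)^2) [c_i == c_j]
modularity_brute <- function(graph, labels) {
  A <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  m2 <- sum(A) # = 2m for an undirected graph stored symmetrically
  k <- rowSums(A)
  same <- outer(labels, labels, `==`)
  sum((A / m2 - outer(k, k) / m2^2) * same)
}

# All set partitions of n items as integer label vectors (restricted growth
# strings).
set_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      recurse(c(prefix, lab), max(maxlab, lab))
    }
  }
  recurse(integer(), 0L)
  out
}

# Brute-force Rao quadratic entropy decomposition via the double sum
# sum_i sum_j p_i p_j d_ij with d_ij = 1 - delta_ij.
rao_brute <- function(comps, counts = NULL,
                      weights = c("cell_count", "equal")) {
  weights <- match.arg(weights)
  m <- as.matrix(comps)
  counts <- if (is.null(counts)) rep(1, nrow(m)) else counts
  w <- if (weights == "cell_count") counts / sum(counts) else {
    rep(1 / nrow(m), nrow(m))
  }
  dmat <- 1 - diag(ncol(m))
  q_of <- function(p) as.numeric(t(p) %*% dmat %*% p)
  alpha_k <- apply(m, 1, q_of)
  pooled <- colSums(m * w)
  list(
    alpha_k = alpha_k,
    alpha = sum(w * alpha_k),
    total = q_of(pooled),
    beta = q_of(pooled) - sum(w * alpha_k)
  )
}

# A random composition matrix (rows sum to 1).
random_comps <- function(n_comm, n_species) {
  m <- matrix(stats::rexp(n_comm * n_species), n_comm)
  m / rowSums(m)
}

# Minimal valid IHC4 cell table for schema/io tests.
tiny_ihc4_cells <- function(n = 3) {
  tibble::tibble(
    cell_id = paste0("c", seq_len(n)),
    case_id = "L01", core_id = "L01_r1",
    x = seq_len(n) * 10, y = seq_len(n) * 5, area = 100,
    DAPI = 2000,
    ER = 100, PR = 200, HER2 = 50, Ki67 = 10, CK = 800
  )
}

# Small two-blob feature matrix with known membership.
two_blob_features <- function(n_per = 30, sep = 8, seed = 42) {
  withr::with_seed(seed, {
    rbind(
      matrix(stats::rnorm(n_per * 2), n_per, 2),
      matrix(stats::rnorm(n_per * 2, mean = sep), n_per, 2)
    )
  })
}
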