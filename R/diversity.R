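#' Simpson diversity of a composition (Rao's Q under identity dissimilarity)
#'
#' `1 - sum(p_i^2)`: the probability that two cells drawn at random from the
#' community belong to different cluster groups. This is Rao's quadratic
#' entropy with the dissimilarity `d_ij = 1 - delta_ij`, i.e. with no
#' dissimilarity tree applied.
#'
#' @param p Proportion vector; non-negative, summing to 1 within 1e-9.
#' @return Simpson diversity in `[0, 1 - 1/length(p))`.
#' @examples
#' simpson_alpha(c(0.5, 0.5)) # 0.5
#' simpson_alpha(rep(1 / 18, 18)) # 1 - 1/18
#' @export
simpson_alpha <- function(p) {
  check_prob_vector(p, "p")
  1 - sum(p^2)
}

#' Alpha/beta decomposition of Rao quadratic entropy across communities
#'
#' Given the cluster-group compositions of several communities (cores),
#' computes: per-community Simpson diversity `alpha_k`; their weighted mean
#' `alpha`; the Simpson diversity of the pooled composition (`total`); and
#' `beta = total - alpha`, the among-community component. Weights are cell
#' counts by default (cores differ in cellularity) or equal. The pairwise
#' among-community matrix `D_kl = 1 - sum_i p_ki p_li` is also returned
#' since "among-community diversity" is sometimes read pairwise; the
#' additive decomposition beta is the headline value.
#'
#' @param comps Matrix or data frame, one row per community, one column per
#'   cluster group; rows are proportions summing to 1 (shared species
#'   space).
#' @param counts Cell count per community, used for `weights = "cell_count"`
#'   and for pooling. Defaults to 1 per community.
#' @param weights `"cell_count"` or `"equal"`.
#' @return Object of class `rao_decomposition`: list with `alpha_k`,
#'   `alpha`, `total`, `beta`, `pairwise` (D_kl matrix), `weights_used`,
#'   `counts`.
#' @examples
#' comps <- rbind(a = c(1, 0), b = c(0, 1))
#' rao_decomposition(comps)$beta # 0.5
#' @export
rao_decomposition <- function(comps, counts = NULL,
                              weights = c("cell_count", "equal")) {
  weights <- match.arg(weights)
  m <- as.matrix(comps)
  if (nrow(m) < 1) {
    abort("At least one community is required",
      class = "mxifhet_validation_error"
    )
  }
  if (anyNA(m)) {
    abort("Compositions must share one species space with no missing values",
      class = "mxifhet_validation_error"
    )
  }
  for (kk in seq_len(nrow(m))) {
    check_prob_vector(m[kk, ], paste0("comps[", kk, ", ]"))
  }
  counts <- counts %||% rep(1, nrow(m))
  stopifnot(length(counts) == nrow(m), all(counts >= 1))
  w <- if (weights == "cell_count") counts / sum(counts) else {
    rep(1 / nrow(m), nrow(m))
  }
  alpha_k <- apply(m, 1, function(p) 1 - sum(p^2))
  alpha <- sum(w * alpha_k)
  pooled <- colSums(m * w)
  total <- 1 - sum(pooled^2)
  pairwise <- 1 - m %*% t(m)
  rn <- rownames(m) %||% as.character(seq_len(nrow(m)))
  dimnames(pairwise) <- list(rn, rn)
  names(alpha_k) <- rn
  structure(
    list(
      alpha_k = alpha_k, alpha = alpha, total = total,
      beta = total - alpha, pairwise = pairwise,
      weights_used = weights, counts = counts
    ),
    class = "rao_decomposition"
  )
}

#' @export
print.rao_decomposition <- function(x, ...) {
  cat("<rao_decomposition> ", length(x$alpha_k), " communities\n", sep = "")
  cat(sprintf(
    "  alpha = %.4f  beta = %.4f  total = %.4f (%s weights)\n",
    x$alpha, x$beta, x$total, x$weights_used
  ))
  invisible(x)
}

#' @export
tidy.rao_decomposition <- function(x, ...) {
  tibble(
    community = names(x$alpha_k),
    alpha = unname(x$alpha_k),
    n = x$counts,
    mean_pairwise_d = unname(
      (rowSums(x$pairwise) - diag(x$pairwise)) /
        max(1, ncol(x$pairwise) - 1)
    )
  )
}

#' @export
glance.rao_decomposition <- function(x, ...) {
  off <- x$pairwise[upper.tri(x$pairwise)]
  tibble(
    n_communities = length(x$alpha_k),
    alpha = x$alpha, beta = x$beta, total = x$total,
    beta_pairwise_mean = if (length(off)) mean(off) else NA_real_,
    weights = x$weights_used
  )
}

#' Per-case alpha and beta diversity of cluster compositions
#'
#' Builds, for every core, its composition over the global cluster label
#' set (clusters absent from a core contribute 0), then decomposes each
#' case's diversity into the mean within-core component (`alpha`,
#' intra-core heterogeneity) and the among-core component (`beta`,
#' intra-tumoral heterogeneity) with [rao_decomposition()]. Cases with a
#' single analysed core report `beta = NA` (not 0): a one-core case carries
#' no among-core information.
#'
#' @param cells Cell tibble with `case_id`, `core_id` and a cluster label
#'   column.
#' @param cluster Name of the cluster label column (default `"cluster"`).
#' @param weights Community weighting; see [rao_decomposition()].
#' @return A tibble with one row per case: `case_id`, `n_cores`, `n_cells`,
#'   `alpha`, `total`, `beta`, `beta_pairwise_mean`. The per-core alpha
#'   table is attached as attribute `cores`.
#' @export
cohort_diversity <- function(cells, cluster = "cluster",
                             weights = c("cell_count", "equal")) {
  weights <- match.arg(weights)
  if (!cluster %in% names(cells)) {
    abort(paste0("Column '", cluster, "' not found"),
      class = "mxifhet_schema_error"
    )
  }
  species <- sort(unique(as.character(cells[[cluster]])))
  # one global pivot, so every core shares the full cluster label space
  wide <- cells |>
    count(.data$case_id, .data$core_id,
      label = as.character(.data[[cluster]])
    ) |>
    tidyr::pivot_wider(
      names_from = "label", values_from = "n", values_fill = 0L
    )
  per_case <- wide |>
    group_by(.data$case_id) |>
    dplyr::group_modify(function(m, key) {
      counts <- rowSums(m[, species, drop = FALSE])
      comp <- as.matrix(m[, species, drop = FALSE]) / counts
      rownames(comp) <- m$core_id
      dec <- rao_decomposition(comp, counts = counts, weights = weights)
      g <- glance(dec)
      tibble(
        n_cores = nrow(comp),
        n_cells = sum(counts),
        alpha = g$alpha,
        total = if (nrow(comp) >= 2) g$total else g$alpha,
        beta = if (nrow(comp) >= 2) g$beta else NA_real_,
        beta_pairwise_mean = g$beta_pairwise_mean,
        core_alpha = list(tibble(
          core_id = rownames(comp),
          n_cells = unname(counts),
          alpha = unname(dec$alpha_k)
        ))
      )
    }) |>
    ungroup()
  cores <- per_case |>
    select("case_id", "core_alpha") |>
    tidyr::unnest("core_alpha")
  out <- select(per_case, -"core_alpha")
  attr(out, "cores") <- cores
  out
}
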