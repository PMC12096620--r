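#' Build a Jaccard-weighted K-nearest-neighbour graph
#'
#' Connects each item to its `k` nearest neighbours under Euclidean
#' distance (self excluded; ties broken deterministically by item index).
#' The directed neighbour lists are symmetrized by union, and each edge is
#' weighted by the Jaccard index of the two endpoints' closed neighbour
#' sets (each item plus its `k` neighbours — the PhenoGraph convention,
#' `weighting = "jaccard"`) or set to 1 (`weighting = "binary"`).
#' Zero-Jaccard edges are dropped.
#'
#' @param features Numeric matrix or data frame (items x features), no
#'   missing values.
#' @param k Number of neighbours; must satisfy `1 <= k < nrow(features)`.
#' @param weighting `"jaccard"` or `"binary"`.
#' @return An undirected weighted [igraph][igraph::aaa-igraph-package]
#'   graph with `nrow(features)` vertices.
#' @examples
#' g <- knn_graph(matrix(rnorm(40), 20, 2), k = 3)
#' igraph::vcount(g)
#' @export
knn_graph <- function(features, k, weighting = c("jaccard", "binary")) {
  weighting <- match.arg(weighting)
  x <- as.matrix(features)
  if (!is.numeric(x) || anyNA(x)) {
    abort("'features' must be a complete numeric matrix",
      class = "mxifhet_validation_error"
    )
  }
  n <- nrow(x)
  if (k < 1 || k >= n) {
    abort(paste0("'k' must satisfy 1 <= k < n_items (n_items = ", n, ")"),
      class = "mxifhet_validation_error"
    )
  }
  d <- as.matrix(dist(x))
  # k smallest distances per row, self excluded; ties resolved by index
  # because order() is stable for equal keys.
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    nn[i, ] <- ord[seq_len(k)]
  }
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k), j = as.vector(t(nn)),
    x = 1, dims = c(n, n)
  )
  sym <- methods::as(adj + Matrix::t(adj), "TsparseMatrix")
  keep <- sym@i < sym@j
  edges <- cbind(sym@i[keep] + 1L, sym@j[keep] + 1L)
  if (weighting == "jaccard") {
    # closed neighbourhoods (self included), so coincident points sharing
    # all other neighbours get weight exactly 1
    adj_c <- adj + Matrix::Diagonal(n)
    inter <- Matrix::tcrossprod(adj_c)
    iv <- inter[edges]
    w <- iv / (2 * (k + 1) - iv)
  } else {
    w <- rep(1, nrow(edges))
  }
  keep <- w > 0
  igraph::graph_from_data_frame(
    data.frame(
      from = edges[keep, 1], to = edges[keep, 2], weight = w[keep]
    ),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
}

#' Louvain community detection with modularity report
#'
#' Greedy modularity-maximizing partition of a weighted graph (the backend
#' of PhenoGraph). The partition depends on a randomized vertex order, so a
#' seed makes the result reproducible.
#'
#' @param graph Weighted undirected igraph graph.
#' @param seed Integer seed controlling the randomized sweep order.
#' @return A list with `labels` (integer community per vertex, in vertex
#'   order) and `modularity` (Q of the returned partition).
#' @export
louvain_communities <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0) {
    abort("Graph has no vertices", class = "mxifhet_validation_error")
  }
  withr::local_seed(seed)
  cl <- igraph::cluster_louvain(graph)
  labels <- as.integer(igraph::membership(cl))
  list(labels = labels, modularity = modularity_q(graph, labels))
}

#' Weighted Newman-Girvan modularity of a labelled partition
#'
#' Fraction of edge weight inside communities minus its expectation under
#' the configuration null model; ranges from -1 to 1, with 0 for the
#' all-in-one partition.
#'
#' @param graph Weighted undirected igraph graph.
#' @param labels Community label per vertex (any atomic type), length
#'   `vcount(graph)`.
#' @return Modularity Q.
#' @export
modularity_q <- function(graph, labels) {
  if (length(labels) != igraph::vcount(graph)) {
    abort("'labels' must cover every vertex exactly once",
      class = "mxifhet_validation_error"
    )
  }
  w <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
  igraph::modularity(graph, as.integer(factor(labels)), weights = w)
}

#' PhenoGraph-style clustering of a feature table
#'
#' Runs [knn_graph()] then [louvain_communities()], and summarizes the
#' partition: per-cluster mean feature vectors (centroids), sizes, and the
#' modularity of the partition. Cluster ids are relabelled in decreasing
#' size order for stable reporting.
#'
#' @param features Numeric matrix or data frame (items x features).
#' @param k Neighbour count. Conventional defaults in this package are 300
#'   for single-cell IHC4 co-expression clustering and 30 for image-patch
#'   composition clustering.
#' @param seed Integer seed.
#' @param weighting Edge weighting; see [knn_graph()].
#' @return An object of class `phenograph_clust`: list with `labels`
#'   (integer vector), `k`, `modularity`, `centroids` (tibble with
#'   `cluster`, `n`, `pct`, and one column per feature), and `n_clusters`.
#' @examples
#' x <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, 6), 30, 2))
#' cl <- phenograph(x, k = 10, seed = 1)
#' cl$n_clusters
#' @export
phenograph <- function(features, k = 30, seed = 1L,
                       weighting = c("jaccard", "binary")) {
  weighting <- match.arg(weighting)
  x <- as.matrix(features)
  g <- knn_graph(x, k = k, weighting = weighting)
  res <- louvain_communities(g, seed = seed)
  labels <- res$labels
  # relabel by decreasing cluster size (ties by original id)
  sizes <- sort(table(labels), decreasing = TRUE)
  remap <- setNames(seq_along(sizes), names(sizes))
  labels <- unname(remap[as.character(labels)])
  feat_names <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- feat_names
  cent <- as_tibble(x) |>
    mutate(cluster = labels) |>
    group_by(.data$cluster) |>
    summarise(
      n = dplyr::n(),
      across(dplyr::all_of(feat_names), mean),
      .groups = "drop"
    ) |>
    mutate(pct = 100 * .data$n / length(labels)) |>
    relocate("cluster", "n", "pct") |>
    arrange(.data$cluster)
  structure(
    list(
      labels = labels, k = k, seed = seed,
      modularity = res$modularity,
      centroids = cent,
      n_clusters = length(sizes),
      n_items = length(labels)
    ),
    class = "phenograph_clust"
  )
}

#' Select the neighbour count K by modularity maximization
#'
#' Clusters the features once per candidate K and returns the K whose
#' Louvain partition attains the highest modularity; ties go to the
#' smallest K (favouring finer graphs). The full scan is attached for
#' inspection.
#'
#' @param features Numeric matrix or data frame.
#' @param k_scan Candidate K values; values `>= nrow(features)` are dropped
#'   (an error if none survive).
#' @param seed Integer seed (used for every candidate).
#' @param weighting Edge weighting; see [knn_graph()].
#' @return The winning `phenograph_clust` object, with a `scan` attribute:
#'   a tibble of `k`, `modularity`, `n_clusters`.
#' @export
select_k <- function(features, k_scan = c(15, 30, 50, 100, 150, 300),
                     seed = 1L, weighting = "jaccard") {
  n <- nrow(as.matrix(features))
  k_scan <- sort(unique(as.integer(k_scan)))
  k_scan <- k_scan[k_scan >= 1 & k_scan < n]
  if (length(k_scan) == 0) {
    abort("'k_scan' contains no valid K below the number of items",
      class = "mxifhet_validation_error"
    )
  }
  fits <- purrr::map(k_scan, function(k) {
    phenograph(features, k = k, seed = seed, weighting = weighting)
  })
  scan <- tibble(
    k = k_scan,
    modularity = purrr::map_dbl(fits, "modularity"),
    n_clusters = purrr::map_int(fits, "n_clusters")
  )
  best <- fits[[which.max(scan$modularity)]] # which.max takes first (smallest K) tie
  attr(best, "scan") <- scan
  best
}

#' Aggregate fine clusters into phenotype groups by centroid similarity
#'
#' Average-linkage hierarchical clustering of the Euclidean distances
#' between cluster centroid feature vectors, cut into `n_groups`. This is
#' the dendrogram-based aggregation step used to merge fine spatial
#' clusters with similar cell-density patterns into interpretable
#' phenotypes.
#'
#' @param result A `phenograph_clust` object, or a tibble of centroids with
#'   a `cluster` column and numeric feature columns.
#' @param n_groups Number of groups to cut the tree into
#'   (`1 <= n_groups <= n_clusters`).
#' @return A list of class `cluster_merge`: `tree` (hclust), `map` (tibble
#'   `cluster` -> `group`), `n_groups`.
#' @export
merge_clusters <- function(result, n_groups) {
  cent <- if (inherits(result, "phenograph_clust")) {
    select(result$centroids, -dplyr::any_of(c("n", "pct")))
  } else {
    as_tibble(result)
  }
  if (!"cluster" %in% names(cent)) {
    abort("Centroid table must carry a 'cluster' column",
      class = "mxifhet_validation_error"
    )
  }
  m <- as.matrix(select(cent, -"cluster"))
  rownames(m) <- cent$cluster
  if (n_groups < 1 || n_groups > nrow(m)) {
    abort("'n_groups' must lie between 1 and the number of clusters",
      class = "mxifhet_validation_error"
    )
  }
  tree <- hclust(dist(m), method = "average")
  grp <- cutree(tree, k = n_groups)
  structure(
    list(
      tree = tree,
      map = tibble(cluster = cent$cluster, group = unname(grp)),
      n_groups = as.integer(n_groups)
    ),
    class = "cluster_merge"
  )
}

#' @export
print.phenograph_clust <- function(x, ...) {
  cat("<phenograph_clust> ", x$n_items, " items, K = ", x$k,
    ", ", x$n_clusters, " clusters, Q = ", round(x$modularity, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.phenograph_clust <- function(x, ...) x$centroids

#' @export
glance.phenograph_clust <- function(x, ...) {
  tibble(
    n_items = x$n_items, k = x$k, n_clusters = x$n_clusters,
    modularity = x$modularity
  )
}
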