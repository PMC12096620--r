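test_that("KNN graph respects neighbour geometry and tie-breaking", {
  # two coincident items whose closed neighbour sets coincide -> weight 1
  x <- rbind(
    c(0, 0), c(0, 0), # coincident pair
    c(10, 0), c(10, 1), c(11, 0) # a far triplet
  )
  g <- knn_graph(x, k = 2)
  w <- igraph::E(g)$weight
  e12 <- igraph::get_edge_ids(g, c("1", "2"))
  expect_gt(e12, 0)
  expect_equal(w[e12], 1)

  # two well-separated clouds, k below cloud size: no cross edges
  y <- two_blob_features(n_per = 20, sep = 50)
  g2 <- knn_graph(y, k = 5)
  ends <- igraph::ends(g2, igraph::E(g2))
  side <- function(v) as.integer(as.integer(v) > 20)
  expect_true(all(side(ends[, 1]) == side(ends[, 2])))

  # K = 1 on collinear equidistant points: ties resolved by item index
  z <- cbind(c(0, 1, 2), 0)
  g3 <- knn_graph(z, k = 1)
  e <- apply(igraph::ends(g3, igraph::E(g3)), 1, function(r) {
    paste(sort(as.integer(r)), collapse = "-")
  })
  # 2's nearest is 1 (index tie-break between 1 and 3); 1 -> 2 and 3 -> 2
  expect_setequal(e, c("1-2", "2-3"))

  expect_error(knn_graph(y, k = 40), class = "mxifhet_validation_error")
  expect_error(knn_graph(matrix(c(1, NA), 2, 1), k = 1),
    class = "mxifhet_validation_error"
  )
})

test_that("Louvain separates disconnected cliques and reports brute-force Q", {
  clique_edges <- function(members) t(utils::combn(members, 2))
  edges <- rbind(clique_edges(1:5), clique_edges(6:10))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- 1
  res <- louvain_communities(g, seed = 3)
  expect_equal(length(unique(res$labels)), 2)
  expect_equal(res$labels[1:5], rep(res$labels[1], 5))
  expect_equal(res$labels[6:10], rep(res$labels[6], 5))
  expect_equal(res$modularity, modularity_brute(g, res$labels),
    tolerance = 1e-12
  )
  # determinism under a fixed seed
  expect_identical(res$labels, louvain_communities(g, seed = 3)$labels)
})

test_that("modularity matches the exhaustive brute force on small graphs", {
  withr::with_seed(5, {
    for (n in c(5, 6)) {
      g <- igraph::sample_gnp(n, 0.6)
      while (igraph::ecount(g) < 2) g <- igraph::sample_gnp(n, 0.6)
      igraph::E(g)$weight <- runif(igraph::ecount(g), 0.2, 2)
      parts <- set_partitions(n)
      q_pkg <- vapply(parts, function(p) modularity_q(g, p), numeric(1))
      q_brute <- vapply(parts, function(p) modularity_brute(g, p), numeric(1))
      expect_lt(max(abs(q_pkg - q_brute)), 1e-12)
      expect_true(all(q_pkg >= -1 - 1e-12 & q_pkg <= 1 + 1e-12))
    }
  })
  # all-in-one partition has Q = 0; all-singletons on a clique is negative
  k5 <- igraph::make_full_graph(5)
  igraph::E(k5)$weight <- 1
  expect_equal(modularity_q(k5, rep(1, 5)), 0)
  expect_lt(modularity_q(k5, 1:5), 0)
  expect_error(modularity_q(k5, 1:4), class = "mxifhet_validation_error")
})

test_that("phenograph recovers well-separated archetypes", {
  cells <- simulate_archetype_cells(1000, seed = 2)
  norm <- normalize_markers(cells, panel_markers("IHC4"), mode = "range_0_15")
  feats <- as.matrix(norm[, paste0(panel_markers("IHC4"), "_norm")])
  cl <- phenograph(feats, k = 30, seed = 1)
  expect_equal(cl$n_clusters, 5)
  expect_gte(mclust::adjustedRandIndex(cl$labels, cells$archetype), 0.9)
  # labels relabelled by decreasing size
  expect_true(all(diff(cl$centroids$n) <= 0))
  expect_equal(sum(cl$centroids$n), nrow(feats))
  expect_equal(sum(cl$centroids$pct), 100, tolerance = 1e-9)
  # the partition found beats the trivial all-in-one partition
  expect_gt(cl$modularity, 0)
})

test_that("select_k maximizes modularity with the smallest-K tie-break", {
  y <- two_blob_features(n_per = 40, sep = 10)
  best <- select_k(y, k_scan = c(3, 5, 10, 200), seed = 1)
  scan <- attr(best, "scan")
  expect_equal(nrow(scan), 3) # 200 >= n dropped
  # the winner is the smallest K attaining the maximal Q
  expect_equal(
    best$k,
    min(scan$k[scan$modularity == max(scan$modularity)])
  )
  expect_equal(
    best$modularity, max(scan$modularity),
    tolerance = 1e-12
  )

  one <- select_k(y, k_scan = 7, seed = 1)
  expect_equal(one$k, 7)
  expect_error(select_k(y, k_scan = c(100, 400)),
    class = "mxifhet_validation_error"
  )
})

test_that("cluster merge groups centroids by similarity", {
  # identity merge
  y <- two_blob_features(n_per = 30, sep = 12)
  cl <- phenograph(y, k = 8, seed = 1)
  mg <- merge_clusters(cl, n_groups = cl$n_clusters)
  expect_equal(sort(unique(mg$map$group)), seq_len(cl$n_clusters))
  expect_equal(anyDuplicated(mg$map$group), 0L)

  # an identical centroid pair merges first
  cent <- tibble::tibble(
    cluster = 1:4,
    a = c(0, 0, 5, 9), b = c(1, 1, 5, 0)
  )
  mg2 <- merge_clusters(cent, n_groups = 3)
  expect_equal(mg2$map$group[1], mg2$map$group[2])
  expect_equal(length(unique(mg2$map$group)), 3)

  # 12 centroids built from 8 known niche compositions + noise: cut at 8
  # recovers the construction
  niches <- as.matrix(default_niches()[, patch_features()])
  withr::with_seed(6, {
    src <- c(1:8, sample(1:8, 4))
    noisy <- niches[src, ] + matrix(rnorm(12 * 10, 0, 0.01), 12)
  })
  mg3 <- merge_clusters(
    tibble::as_tibble(noisy) |> dplyr::mutate(cluster = 1:12),
    n_groups = 8
  )
  expect_equal(mclust::adjustedRandIndex(mg3$map$group, src), 1)

  expect_error(merge_clusters(cent, n_groups = 0),
    class = "mxifhet_validation_error"
  )
})

test_that("row permutation permutes the recovered partition identically", {
  # K large enough that the Louvain sweep is order-stable on this geometry
  y <- two_blob_features(n_per = 35, sep = 9)
  cl <- phenograph(y, k = 20, seed = 4)
  perm <- withr::with_seed(10, sample(nrow(y)))
  cl_p <- phenograph(y[perm, ], k = 20, seed = 4)
  # same partition up to label names
  expect_equal(mclust::adjustedRandIndex(cl$labels[perm], cl_p$labels), 1)
})

test_that("tidy and glance summarize a clustering fit", {
  y <- two_blob_features(n_per = 25, sep = 10)
  cl <- phenograph(y, k = 6, seed = 1)
  td <- tidy(cl)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("cluster", "n", "pct") %in% names(td)))
  gl <- glance(cl)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_clusters, cl$n_clusters)
})
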