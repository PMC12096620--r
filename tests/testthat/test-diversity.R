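test_that("Simpson diversity matches its closed forms", {
  expect_equal(simpson_alpha(1), 0)
  expect_equal(simpson_alpha(c(0.5, 0.5)), 0.5)
  expect_equal(simpson_alpha(rep(1 / 18, 18)), 1 - 1 / 18)
  expect_error(simpson_alpha(c(0.5, 0.4)), class = "mxifhet_validation_error")
  expect_error(simpson_alpha(c(-0.2, 1.2)), class = "mxifhet_validation_error")
})

test_that("rao decomposition handles the canonical community layouts", {
  # identical communities: no among-community diversity
  same <- rbind(c(.3, .7), c(.3, .7))
  d <- rao_decomposition(same, counts = c(10, 30))
  expect_equal(d$beta, 0, tolerance = 1e-12)
  expect_equal(d$total, d$alpha, tolerance = 1e-12)

  # two disjoint single-species communities, equal weight
  disj <- rbind(a = c(1, 0), b = c(0, 1))
  d2 <- rao_decomposition(disj, weights = "equal")
  expect_equal(unname(d2$alpha_k), c(0, 0))
  expect_equal(d2$total, 0.5)
  expect_equal(d2$beta, 0.5)
  expect_equal(unname(d2$pairwise["a", "b"]), 1)

  # single community: total collapses to alpha
  d3 <- rao_decomposition(matrix(c(.2, .8), 1))
  expect_equal(d3$beta, 0)
  expect_equal(d3$total, d3$alpha)

  expect_error(rao_decomposition(rbind(c(.5, NA), c(.5, .5))),
    class = "mxifhet_validation_error"
  )
})

test_that("decomposition agrees with the brute-force double sum", {
  withr::with_seed(13, {
    worst <- 0
    for (rep in 1:1000) {
      m <- random_comps(sample(2:6, 1), sample(2:8, 1))
      counts <- sample(5:500, nrow(m), replace = TRUE)
      w <- sample(c("cell_count", "equal"), 1)
      got <- rao_decomposition(m, counts = counts, weights = w)
      want <- rao_brute(m, counts = counts, weights = w)
      worst <- max(
        worst,
        abs(got$alpha - want$alpha), abs(got$total - want$total),
        abs(got$beta - want$beta), max(abs(got$alpha_k - want$alpha_k))
      )
    }
    expect_lt(worst, 1e-12)
  })
})

test_that("additivity, bounds and non-negative beta hold on random inputs", {
  withr::with_seed(17, {
    for (rep in 1:200) {
      k <- sample(2:7, 1)
      m <- random_comps(sample(2:5, 1), k)
      counts <- sample(5:200, nrow(m), replace = TRUE)
      d <- rao_decomposition(m, counts = counts)
      expect_equal(d$alpha + d$beta, d$total, tolerance = 1e-12)
      expect_gte(d$beta, -1e-12)
      expect_true(all(d$alpha_k >= 0 & d$alpha_k <= 1 - 1 / k + 1e-12))
      expect_lte(d$total, 1 - 1 / k + 1e-12)
    }
  })
})

test_that("duplicating a community leaves the decomposition unchanged", {
  withr::with_seed(19, {
    m <- random_comps(3, 4)
    counts <- c(20, 30, 50)
  })
  base <- rao_decomposition(m, counts = counts)
  dup <- rao_decomposition(m[c(1, 1, 2, 3), ],
    counts = c(10, 10, 30, 50)
  )
  expect_equal(dup$alpha, base$alpha, tolerance = 1e-12)
  expect_equal(dup$total, base$total, tolerance = 1e-12)
  expect_equal(dup$beta, base$beta, tolerance = 1e-12)
})

test_that("decomposition agrees with picante's raoD on shared ground", {
  # picante pools communities by abundance but averages Dkk unweighted, so
  # compare at equal community sizes where the two conventions coincide.
  comm <- matrix(
    c(
      30, 10, 10,
      10, 30, 10,
      10, 10, 30
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("k1", "k2", "k3"), c("s1", "s2", "s3"))
  )
  ref <- picante::raoD(comm)
  got <- rao_decomposition(comm / rowSums(comm), counts = rowSums(comm))
  expect_equal(got$alpha, unname(ref$alpha), tolerance = 1e-12)
  expect_equal(got$total, unname(ref$total), tolerance = 1e-12)
  expect_equal(got$beta, unname(ref$beta), tolerance = 1e-12)
  expect_equal(
    got$pairwise["k1", "k2"],
    unname(ref$Dkl["k1", "k2"]),
    tolerance = 1e-12
  )
})

test_that("cohort diversity reproduces hand-built compositions", {
  cells <- tibble::tibble(
    case_id = c(rep("A", 8), "B", "B"),
    core_id = c(rep("A1", 4), rep("A2", 4), "B1", "B1"),
    cluster = c(1, 1, 2, 2, 1, 1, 1, 1, 1, 2)
  )
  d <- cohort_diversity(cells)
  a <- d[d$case_id == "A", ]
  # A1 = (.5,.5) -> 0.5; A2 = (1,0) -> 0; equal counts -> alpha .25
  expect_equal(a$alpha, 0.25, tolerance = 1e-12)
  # pooled A = (6/8, 2/8) -> 1 - (0.5625 + 0.0625) = 0.375
  expect_equal(a$total, 0.375, tolerance = 1e-12)
  expect_equal(a$beta, 0.125, tolerance = 1e-12)
  # single-core case: beta is missing, not zero
  b <- d[d$case_id == "B", ]
  expect_true(is.na(b$beta))
  expect_equal(b$alpha, 0.5, tolerance = 1e-12)
  # per-core table attached
  cores <- attr(d, "cores")
  expect_equal(cores$alpha[cores$core_id == "A1"], 0.5)

  # core/row order invariance
  perm <- withr::with_seed(3, sample(nrow(cells)))
  d2 <- cohort_diversity(cells[perm, ])
  expect_equal(d2[order(d2$case_id), ], d[order(d$case_id), ],
    tolerance = 1e-12
  )
})

test_that("identical cores give zero intra-tumoral (beta) diversity", {
  cells <- tibble::tibble(
    case_id = "A",
    core_id = rep(c("A1", "A2", "A3"), each = 6),
    cluster = rep(c(1, 1, 1, 2, 2, 3), 3)
  )
  d <- cohort_diversity(cells)
  expect_equal(d$beta, 0, tolerance = 1e-12)
})

test_that("diversity tidiers expose per-community and summary views", {
  m <- rbind(a = c(.2, .8), b = c(.6, .4))
  d <- rao_decomposition(m, counts = c(10, 20))
  td <- tidy(d)
  expect_equal(td$community, c("a", "b"))
  expect_equal(td$alpha, unname(d$alpha_k))
  gl <- glance(d)
  expect_equal(gl$beta, d$beta)
  expect_equal(gl$n_communities, 2)
})
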