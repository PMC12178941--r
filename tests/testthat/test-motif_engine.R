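test_that("edge lengths are Euclidean centroid distances", {
  atlas <- data.frame(region_id = 1:2, x = c(0, 3), y = c(0, 4),
                      z = c(0, 0), anatomical_label = "a",
                      functional_label = "f")
  class(atlas) <- c("pmv_atlas", "data.frame")
  d <- compute_edge_lengths(atlas)
  expect_equal(d[1, 2], 5)

  big <- generate_atlas(10, seed = 5)
  dd <- compute_edge_lengths(big)
  expect_equal(dd, t(dd))
  expect_equal(unname(diag(dd)), rep(0, 10))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(dd[i, j],
                 sqrt(sum((as.numeric(big[i, c("x", "y", "z")]) -
                             as.numeric(big[j, c("x", "y", "z")]))^2)),
                 tolerance = 1e-12)
  }
})

test_that("thresholds pool edge weights across the whole cohort", {
  w <- matrix(1, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.6
  w[1, 3] <- w[3, 1] <- 0.75
  w[2, 3] <- w[3, 2] <- 0.9
  d <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  thr <- compute_thresholds(list(w), d)
  expect_equal(thr$strength_median, 0.75)
  expect_equal(thr$length_median, 2)

  # pooling two identical subjects leaves the medians unchanged
  thr2 <- compute_thresholds(list(w, w), d)
  expect_equal(thr2$strength_median, thr$strength_median)

  # 20-subject cohort against a full-sort oracle
  set.seed(8)
  nets <- lapply(1:20, function(i) {
    m <- matrix(0, 6, 6)
    m[upper.tri(m)] <- runif(15, -1, 1)
    m <- m + t(m); diag(m) <- 1
    m
  })
  d6 <- as.matrix(dist(matrix(rnorm(18), 6, 3)))
  thr3 <- compute_thresholds(nets, d6)
  pooled <- sort(unlist(lapply(nets, function(m) m[upper.tri(m)])))
  expect_equal(thr3$strength_median,
               (pooled[150] + pooled[151]) / 2)
  expect_equal(thr3$length_median, median(sort(d6[upper.tri(d6)])))

  expect_error(compute_thresholds(list(), d), "empty")
})

test_that("edges are labelled by the median rule with ties going weak/short", {
  thr <- structure(list(strength_median = 0.75, length_median = 76.11,
                        provenance = "reference"),
                   class = "threshold_pair")
  net <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  d <- matrix(c(0, 80, 80, 0), 2, 2)
  lab <- label_edges(net, d, thr)
  expect_equal(lab[1, 2], 1L)  # STRONG_LONG
  expect_true(is.na(lab[1, 1]))

  # value exactly at the median falls on the WEAK / SHORT side
  net[1, 2] <- net[2, 1] <- 0.75
  d[1, 2] <- d[2, 1] <- 76.11
  expect_equal(label_edges(net, d, thr)[1, 2], 4L)  # WEAK_SHORT

  # all-equal weights: every edge weak
  flat <- matrix(0.5, 4, 4); diag(flat) <- 1
  d4 <- as.matrix(dist(matrix(rnorm(12), 4, 3)))
  thr4 <- compute_thresholds(list(flat), d4)
  lab4 <- label_edges(flat, d4, thr4)
  expect_true(all(lab4[upper.tri(lab4)] >= 3L))  # WEAK_{LONG,SHORT} only

  expect_error(label_edges(net, d4, thr), "shape")
})

test_that("the catalog canonicalizes 64 ordered triples into 20 types", {
  catalog <- motif_catalog()
  expect_equal(nrow(catalog), 20)
  expect_equal(nrow(catalog), choose(6, 3))
  expect_equal(anyDuplicated(catalog$label), 0L)

  # permutation invariance of the type lookup
  expect_equal(motif_type_of(1, 4, 1, catalog),
               motif_type_of(4, 1, 1, catalog))
  types <- expand.grid(a = 1:4, b = 1:4, c = 1:4)
  idx <- motif_type_of(types$a, types$b, types$c, catalog)
  expect_equal(length(unique(idx)), 20)
  expect_true(all(idx %in% 1:20))

  # homogeneous triples form 4 distinct singleton classes
  homog <- motif_type_of(1:4, 1:4, 1:4, catalog)
  expect_equal(length(unique(homog)), 4)
  # the all-WEAK_SHORT type is the last catalog entry (the sign anchor)
  expect_equal(homog[4], 20)
  expect_equal(catalog$label[20], "WS-WS-WS")
})

test_that("count_motifs satisfies the conservation identities", {
  catalog <- motif_catalog()

  m3 <- matrix(4L, 3, 3); diag(m3) <- NA_integer_
  counts3 <- count_motifs(m3, catalog)
  expect_equal(unname(counts3[20, ]), c(1, 1, 1))
  expect_equal(sum(counts3), 3)

  lab4 <- random_label_matrix(4, seed = 2)
  counts4 <- count_motifs(lab4, catalog)
  expect_equal(unname(colSums(counts4)), rep(choose(3, 2), 4))
  expect_equal(sum(counts4), 3 * choose(4, 3))

  expect_error(count_motifs(matrix(1L, 2, 2)), "3 regions")
})

test_that("census equals the brute-force triple-loop oracle", {
  catalog <- motif_catalog()
  for (seed in 1:20) {
    n <- sample(5:15, 1)
    lab <- random_label_matrix(n, seed = seed)
    expect_identical(count_motifs(lab, catalog),
                     oracle_count_motifs(lab, catalog))
  }
})

test_that("relabelling regions permutes count columns identically", {
  catalog <- motif_catalog()
  lab <- random_label_matrix(9, seed = 42)
  perm <- sample(9)
  permuted <- lab[perm, perm]
  colnames(permuted) <- rownames(permuted) <- colnames(lab)[perm]
  c1 <- count_motifs(lab, catalog)
  c2 <- count_motifs(permuted, catalog)
  expect_identical(unname(c1[, perm]), unname(c2))
})
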