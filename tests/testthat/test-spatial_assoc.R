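test_that("PLS1 with a single predictor reduces to simple correlation", {
  set.seed(41)
  x <- matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "g1"))
  y <- 0.6 * x[, 1] + rnorm(50, sd = 0.5)
  fit <- pls1_association(x, y, n_perm = 99, seed = 1)
  expect_equal(abs(fit$r_with_target), abs(cor(x[, 1], y)),
               tolerance = 1e-12)
  expect_equal(fit$variance_explained, 1, tolerance = 1e-12)
})

test_that("PLS1 finds a planted target column and its permutation null", {
  set.seed(42)
  n <- 60
  target <- rnorm(n)
  # noise maps carry no target signal (residualized against the target);
  # raw i.i.d. noise columns would each still correlate O(1/sqrt(n)) with
  # the target and collectively dilute the component
  genes <- cbind(planted = target + rnorm(n, sd = 0.01),
                 make_orthogonal_noise(target, 20, seed = 420,
                                       names = sprintf("noise%02d", 1:20)))
  fit <- pls1_association(genes, target, n_perm = 999, seed = 2)
  expect_gt(fit$r_with_target, 0.99)
  expect_lte(fit$p_perm, 2 / 1000)
  expect_equal(fit$permutation_scheme, "uniform")
  expect_equal(names(which.max(abs(fit$gene_weights))), "planted")
})

test_that("supplied permutations are validated and reproduce uniform mode", {
  set.seed(43)
  n <- 30
  genes <- matrix(rnorm(n * 10), n, 10)
  target <- rnorm(n)
  perms <- t(replicate(99, sample.int(n)))
  a <- pls1_association(genes, target, permutations = perms)
  b <- pls1_association(genes, target, permutations = perms)
  expect_identical(a$p_perm, b$p_perm)
  expect_equal(a$permutation_scheme, "supplied")
  bad <- perms
  bad[1, 1:2] <- c(1, 1)
  expect_error(pls1_association(genes, target, permutations = bad),
               "not permutations")
  expect_error(pls1_association(genes, target[-1], n_perm = 9), "length")
})

test_that("PLS1 is invariant to gene order and positive rescaling", {
  set.seed(44)
  n <- 40
  genes <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, letters[1:8]))
  target <- rnorm(n)
  base <- pls1_association(genes, target, n_perm = 49, seed = 5)
  shuffled <- genes[, sample(8)]
  fit2 <- pls1_association(shuffled, target, n_perm = 49, seed = 5)
  expect_equal(sort(abs(base$gene_weights)), sort(abs(fit2$gene_weights)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(base$component_scores, fit2$component_scores,
               tolerance = 1e-12)
  rescaled <- sweep(genes, 2, runif(8, 0.5, 4), "*")
  fit3 <- pls1_association(rescaled, target, n_perm = 49, seed = 5)
  expect_equal(base$component_scores, fit3$component_scores,
               tolerance = 1e-12)
})

test_that("PLS1 weights agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(45)
  n <- 50
  genes <- matrix(rnorm(n * 12), n, 12,
                  dimnames = list(NULL, sprintf("g%02d", 1:12)))
  target <- genes[, 1] * 0.8 + rnorm(n)
  ours <- pls1_association(genes, target, n_perm = 9, seed = 1)
  ref <- mixOmics::pls(genes, target, ncomp = 1, scale = TRUE)
  w_ref <- as.numeric(ref$loadings$X[, 1])
  cos <- abs(sum(w_ref * ours$gene_weights)) /
    sqrt(sum(w_ref^2) * sum(ours$gene_weights^2))
  expect_gt(cos, 1 - 1e-8)
})

test_that("bootstrap gene Z-scores rank a planted gene first", {
  set.seed(46)
  n <- 60
  target <- rnorm(n)
  genes <- cbind(signal = target + rnorm(n, sd = 0.2),
                 matrix(rnorm(n * 30), n, 30,
                        dimnames = list(NULL, sprintf("noise%02d", 1:30))))
  boot <- bootstrap_gene_zscores(genes, target, n_boot = 300, seed = 3,
                                 top_k = 10)
  expect_equal(boot$table$gene[1], "signal")
  expect_length(boot$top_genes, 10)

  # duplicated gene under two names: near-identical Z
  dup <- cbind(genes, signal_copy = genes[, "signal"])
  boot2 <- bootstrap_gene_zscores(dup, target, n_boot = 1000, seed = 4,
                                  top_k = 5)
  za <- boot2$table$z[boot2$table$gene == "signal"]
  zb <- boot2$table$z[boot2$table$gene == "signal_copy"]
  expect_lt(abs(za - zb), 0.2)

  expect_warning(capped <- bootstrap_gene_zscores(genes, target,
                                                  n_boot = 100, seed = 5,
                                                  top_k = 500),
                 "exceeds the gene count")
  expect_length(capped$top_genes, ncol(genes))
  expect_error(bootstrap_gene_zscores(genes, target, n_boot = 10), "n_boot")
})

test_that("map correlation panels report per-map permutation p-values", {
  atlas <- generate_atlas(70, seed = 47)
  target <- rnorm(70)
  names(target) <- as.character(atlas$region_id)

  panel_maps <- generate_spatial_maps(atlas, target, n_maps = 28,
                                      target_corr = 0.4, seed = 6,
                                      map_names = ad_risk_genes())
  panel <- map_correlation_panel(target, panel_maps, n_perm = 199, seed = 7)
  expect_equal(nrow(panel), 28)
  expect_true(all(panel$p_adj >= panel$p_perm - 1e-15))

  # the target itself correlates perfectly
  with_self <- cbind(panel_maps, self = as.numeric(scale(target)))
  p2 <- map_correlation_panel(target, with_self, n_perm = 99, seed = 8)
  expect_equal(p2$r[p2$name == "self"], 1, tolerance = 1e-12)

  expect_error(map_correlation_panel(target[-1], panel_maps, n_perm = 9),
               "mismatch")
})

test_that("null panels keep Bonferroni rejections at the nominal level", {
  atlas <- generate_atlas(50, seed = 48)
  set.seed(49)
  rejected <- vapply(1:30, function(i) {
    target <- rnorm(50)
    maps <- generate_spatial_maps(atlas, target, n_maps = 10,
                                  target_corr = 0, seed = 100 + i)
    any(map_correlation_panel(target, maps, n_perm = 99,
                              seed = 200 + i)$significant)
  }, TRUE)
  expect_lte(mean(rejected), 0.15)
})
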