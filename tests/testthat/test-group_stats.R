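test_that("normality screen is calibrated and flags skewed data", {
  set.seed(21)
  # Gaussian draws: rejection near the nominal level
  gauss <- matrix(rnorm(50 * 500), 50, 500)
  ns <- normality_screen(gauss, rep("NC", 50))
  expect_gt(ns$rejection_rate, 0.02)
  expect_lt(ns$rejection_rate, 0.09)

  # heavily skewed values: rejected nearly always
  skewed <- matrix(exp(rnorm(50 * 50, sd = 1.5)), 50, 50)
  ns2 <- normality_screen(skewed, rep("NC", 50))
  expect_gt(ns2$rejection_rate, 0.9)

  # constant within-group values: invalid cell, not a crash
  const <- cbind(rep(1, 10), rnorm(10))
  ns3 <- normality_screen(const, rep("NC", 10))
  expect_true(is.na(ns3$p_values[1, 1]))
  expect_equal(ns3$n_invalid, 1)

  expect_warning(normality_screen(gauss[1:5, 1:3], c("A", "A", "A", "B", "B")),
                 "fewer than 3")
})

test_that("Kruskal-Wallis H matches the hand-computed rank statistic", {
  pmv <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  g <- c("a", "a", "b", "b", "c", "c")
  kw <- kruskal_wallis_map(pmv, g)
  # ranks 1..6, rank sums 3/7/11: H = 12/(6*7) * sum(R^2/n) - 3*7 = 32/7
  expect_equal(kw$H, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$p, pchisq(32 / 7, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  set.seed(22)
  shifted <- rbind(matrix(rnorm(30 * 4), 30, 4),
                   matrix(rnorm(30 * 4, mean = 3), 30, 4),
                   matrix(rnorm(30 * 4, mean = 6), 30, 4))
  kw2 <- kruskal_wallis_map(shifted, rep(c("NC", "MCI", "AD"), each = 30))
  expect_true(all(kw2$significant))
  expect_true(all(kw2$p_adj >= kw2$p))

  expect_error(kruskal_wallis_map(pmv, rep("a", 6)), "2 groups")
})

test_that("Mann-Whitney Z follows the printed closed form", {
  # complete separation at n1 = n2 = 3: Z = (9 - 4.5) / sqrt(5.25)
  pmv <- matrix(c(4, 5, 6, 1, 2, 3), ncol = 1)
  g <- rep(c("AD", "NC"), each = 3)
  mw <- mannwhitney_zmap(pmv, g, "AD", "NC")
  expect_equal(as.numeric(mw$z), (9 - 4.5) / sqrt(5.25), tolerance = 1e-12)
  expect_equal(as.numeric(mw$z), 1.9640, tolerance = 1e-4)
  expect_equal(mw$table$U, 9)

  # antisymmetry under group swap
  set.seed(23)
  pmv2 <- matrix(rnorm(20 * 6), 20, 6)
  g2 <- rep(c("AD", "NC"), each = 10)
  za <- mannwhitney_zmap(pmv2, g2, "AD", "NC")$z
  zb <- mannwhitney_zmap(pmv2, g2, "NC", "AD")$z
  expect_equal(as.numeric(za), -as.numeric(zb), tolerance = 1e-12)

  # U at its null mean gives Z = 0
  tied <- matrix(c(1, 2, 3, 4), ncol = 1)
  z0 <- mannwhitney_zmap(tied, c("A", "B", "B", "A"), "A", "B")$z
  expect_equal(as.numeric(z0), 0)

  # ties shrink sigma_U only under the tie-corrected flag
  with_ties <- matrix(c(1, 1, 2, 2, 2, 3), ncol = 1)
  gt <- rep(c("A", "B"), each = 3)
  plain <- mannwhitney_zmap(with_ties, gt, "A", "B")$z
  corr <- mannwhitney_zmap(with_ties, gt, "A", "B",
                           tie_correction = TRUE)$z
  expect_gt(abs(corr), abs(plain))

  expect_warning(out <- mannwhitney_zmap(pmv2, g2, "AD", "NC",
                                         restrict_to = character(0)),
                 "empty")
  expect_equal(nrow(out$table), 0)
  expect_error(mannwhitney_zmap(pmv2, g2, "AD", "XX"), "nonempty")
})

test_that("U statistics match wilcox.test on random data", {
  set.seed(24)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(9)
    mw <- mannwhitney_zmap(cbind(c(x, y)), rep(c("A", "B"), c(7, 9)),
                           "A", "B")
    expect_equal(mw$table$U,
                 unname(wilcox.test(x, y)$statistic))
  }
})

test_that("clinical correlation maps recover planted score structure", {
  set.seed(25)
  pmv <- matrix(rnorm(40 * 8), 40, 8)
  records <- data.frame(subject_id = sprintf("S%02d", 1:40),
                        group = rep(c("NC", "AD"), each = 20))
  # score identical to region 3's PMV: r = 1 there
  records$echo <- pmv[, 3]
  cors <- clinical_correlation_map(pmv, records, "echo")
  expect_equal(cors$echo$r[3], 1, tolerance = 1e-12)

  # missing values are dropped pairwise; all-missing scores are skipped
  records$holey <- records$echo
  records$holey[1:5] <- NA
  cors2 <- clinical_correlation_map(pmv, records, "holey")
  expect_equal(cors2$holey$n[3], 35)
  records$void <- NA_real_
  expect_warning(out <- clinical_correlation_map(pmv, records,
                                                 c("echo", "void")),
                 "entirely missing")
  expect_named(out, "echo")

  # planted dose-linked score: sign of r matches the slope sign
  dose <- ifelse(records$group == "AD", 1, 0)
  target_pmv <- pmv
  target_pmv[, 1] <- pmv[, 1] + 2 * dose
  records$score <- 10 - 3 * dose + rnorm(40, sd = 0.3)
  cors3 <- clinical_correlation_map(target_pmv, records, "score")
  expect_lt(cors3$score$r[1], 0)
})

test_that("Z-map agreement and Stouffer meta-analysis behave as closed forms", {
  set.seed(26)
  z <- rnorm(100)
  expect_equal(compare_zmaps(z, z)$r, 1, tolerance = 1e-12)
  expect_equal(compare_zmaps(z, -z)$r, -1, tolerance = 1e-12)
  expect_error(compare_zmaps(z, z[-1]), "different region")

  # two identical sites with equal weights: meta-Z = Z * sqrt(2)
  meta <- stouffer_meta(list(z, z), weights = c(1, 1))
  expect_equal(meta, z * sqrt(2), tolerance = 1e-12)
  expect_equal(stouffer_meta(list(z)), z, ignore_attr = TRUE)

  # independent standard-normal site maps stay standard normal
  sites <- lapply(1:4, function(i) rnorm(1000))
  meta2 <- stouffer_meta(sites, weights = sqrt(c(50, 80, 120, 60)))
  expect_gt(sd(meta2), 0.9)
  expect_lt(sd(meta2), 1.1)

  expect_error(stouffer_meta(list(z, z), weights = 1), "length")
})

test_that("independent null Z-maps are uncorrelated", {
  set.seed(27)
  n <- 100
  rs <- replicate(100, compare_zmaps(rnorm(n), rnorm(n))$r)
  expect_gt(mean(abs(rs) < 2 / sqrt(n)), 0.9)
})

test_that("partition summaries aggregate and compare labels", {
  atlas <- generate_atlas(60, seed = 31)
  # single-label partition: one row, no pairwise table needed
  one <- atlas
  one$anatomical_label <- "all"
  s1 <- summarize_by_partition(rnorm(60), one, "anatomical")
  expect_equal(nrow(s1$summary), 1)

  # planted subcortex-positive map
  vals <- rnorm(60, sd = 0.1)
  vals[atlas$anatomical_label == "subcortex"] <- vals[
    atlas$anatomical_label == "subcortex"] + 3
  s2 <- summarize_by_partition(vals, atlas, "anatomical")
  sub_mean <- s2$summary$mean[s2$summary$label == "subcortex"]
  expect_true(all(sub_mean > s2$summary$mean[s2$summary$label != "subcortex"]))
  expect_equal(sum(s2$summary$n), 60)

  s3 <- summarize_by_partition(matrix(rnorm(5 * 60), 5, 60), atlas,
                               "functional")
  expect_equal(sum(s3$summary$n), 60)
  expect_error(summarize_by_partition(vals, atlas, "spectral"),
               "arg")
})
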