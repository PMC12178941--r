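# Per-region nonparametric inference on PMV maps: normality screening,
# Kruskal-Wallis maps, Mann-Whitney Z maps, clinical correlations,
# cross-dataset Z-map agreement, Stouffer meta-analysis, partition summaries.

#' Null mean of the Mann-Whitney U statistic
#' @param n1,n2 group sample sizes.
#' @return `n1 * n2 / 2`.
#' @export
mw_null_mean <- function(n1, n2) n1 * n2 / 2

#' Null standard deviation of the Mann-Whitney U statistic
#'
#' The plain (tie-free) closed form `sqrt(n1 n2 (n1 + n2 + 1) / 12)`; with
#' `tie_sizes` supplied, the tie-corrected variant.
#'
#' @param n1,n2 group sample sizes.
#' @param tie_sizes optional integer vector of tie-group sizes in the
#'   pooled sample.
#' @return standard deviation of U under the null.
#' @export
mw_null_sd <- function(n1, n2, tie_sizes = NULL) {
  n <- n1 + n2
  if (is.null(tie_sizes) || all(tie_sizes <= 1L)) {
    return(sqrt(n1 * n2 * (n + 1) / 12))
  }
  tt <- sum(tie_sizes^3 - tie_sizes)
  sqrt(n1 * n2 / 12 * ((n + 1) - tt / (n * (n - 1))))
}

mw_u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Shapiro-Wilk normality screen per group and region
#'
#' @param pmv subjects x regions PMV matrix.
#' @param groups group label per subject (row).
#' @param alpha level used for the reported rejection fraction.
#' @return list: `p_values` (groups x regions, `NA` for degenerate cells
#'   such as constant values), `rejection_rate` (fraction of valid cells
#'   with p < alpha), `n_invalid`, `alpha`.
#' @export
normality_screen <- function(pmv, groups, alpha = 0.05) {
  pmv <- as.matrix(pmv)
  stopifnot(length(groups) == nrow(pmv))
  tab <- table(groups)
  small <- names(tab)[tab < 3L]
  if (length(small) > 0L) {
    warning("group(s) with fewer than 3 subjects excluded from the ",
            "normality screen: ", paste(small, collapse = ", "))
  }
  keep <- setdiff(names(tab), small)
  p <- matrix(NA_real_, length(keep), ncol(pmv),
              dimnames = list(keep, colnames(pmv)))
  for (g in keep) {
    rows <- which(groups == g)
    for (j in seq_len(ncol(pmv))) {
      x <- pmv[rows, j]
      if (stats::sd(x) == 0) next  # degenerate: reported as NA, not a crash
      p[g, j] <- tryCatch(stats::shapiro.test(x)$p.value,
                          error = function(e) NA_real_)
    }
  }
  list(p_values = p,
       rejection_rate = mean(p < alpha, na.rm = TRUE),
       n_invalid = sum(is.na(p)),
       alpha = alpha)
}

#' Per-region Kruskal-Wallis map with Bonferroni control
#'
#' Tie-corrected H statistic with its chi-square p-value per region;
#' Bonferroni adjustment across the N regions (a region is significant when
#' its raw p falls below `alpha / N`).
#'
#' @param pmv subjects x regions PMV matrix.
#' @param groups group label per subject (>= 2 distinct labels, each with
#'   >= 2 subjects).
#' @param alpha family-wise level.
#' @return data.frame of class `"region_stat_map"` with columns `region`,
#'   `H`, `p`, `p_adj`, `significant`; test metadata in attributes.
#' @export
kruskal_wallis_map <- function(pmv, groups, alpha = 0.05) {
  pmv <- as.matrix(pmv)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(pmv))
  if (nlevels(groups) < 2L) {
    stop("at least 2 groups are required", call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 subjects", call. = FALSE)
  }
  n_regions <- ncol(pmv)
  res <- vapply(seq_len(n_regions), function(j) {
    kt <- stats::kruskal.test(pmv[, j], groups)
    c(unname(kt$statistic), kt$p.value)
  }, numeric(2L))
  p <- res[2L, ]
  out <- data.frame(
    region = colnames(pmv) %||% as.character(seq_len(n_regions)),
    H = res[1L, ],
    p = p,
    p_adj = pmin(p * n_regions, 1),
    significant = p < alpha / n_regions,
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("region_stat_map", "data.frame"),
            test = "kruskal-wallis",
            alpha = alpha, n_tests = n_regions,
            groups = levels(groups),
            group_sizes = as.integer(table(groups)))
}

#' Pairwise Mann-Whitney Z map
#'
#' For each region, the Mann-Whitney U statistic of `group_a` versus
#' `group_b` is standardized to `Z = (U - n1 n2 / 2) /
#' sqrt(n1 n2 (n1 + n2 + 1) / 12)`.  By default no tie correction is
#' applied to the denominator (PMV values derived from continuous networks
#' make exact ties measure-zero); `tie_correction = TRUE` switches to the
#' tie-corrected variance.  Two-sided normal p-values are Bonferroni
#' adjusted over the tested region set, which defaults to all regions but
#' is typically restricted to the Kruskal-Wallis-significant set.
#'
#' @param pmv subjects x regions PMV matrix.
#' @param groups group label per subject.
#' @param group_a,group_b labels to compare; U and Z are oriented as the
#'   statistic of `group_a` (positive Z: `group_a` ranks higher).
#' @param restrict_to optional region names/indices to test.
#' @param alpha family-wise level.
#' @param tie_correction use tie-corrected sigma_U.
#' @return list with `z` (named numeric over the tested regions) and
#'   `table` (data.frame of class `"region_stat_map"` with `region`, `U`,
#'   `Z`, `p`, `p_adj`, `significant`); attributes carry the group sizes.
#' @export
mannwhitney_zmap <- function(pmv, groups, group_a, group_b,
                             restrict_to = NULL, alpha = 0.05,
                             tie_correction = FALSE) {
  pmv <- as.matrix(pmv)
  stopifnot(length(groups) == nrow(pmv))
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  region_names <- colnames(pmv) %||% as.character(seq_len(ncol(pmv)))
  if (is.null(restrict_to)) {
    cols <- seq_len(ncol(pmv))
  } else if (is.character(restrict_to)) {
    cols <- match(restrict_to, region_names)
    if (anyNA(cols)) stop("unknown region(s) in `restrict_to`", call. = FALSE)
  } else {
    cols <- as.integer(restrict_to)
  }
  if (length(cols) == 0L) {
    warning("empty region set: nothing to test")
    empty <- data.frame(region = character(), U = numeric(), Z = numeric(),
                        p = numeric(), p_adj = numeric(),
                        significant = logical())
    return(list(z = stats::setNames(numeric(), character()), table = empty))
  }
  n1 <- length(ia); n2 <- length(ib)
  mu <- mw_null_mean(n1, n2)
  u <- numeric(length(cols))
  sig <- numeric(length(cols))
  for (k in seq_along(cols)) {
    xa <- pmv[ia, cols[k]]; xb <- pmv[ib, cols[k]]
    u[k] <- mw_u_stat(xa, xb)
    if (tie_correction) {
      ties <- table(c(xa, xb))
      sig[k] <- mw_null_sd(n1, n2, tie_sizes = as.integer(ties))
    } else {
      sig[k] <- mw_null_sd(n1, n2)
    }
  }
  z <- ifelse(sig > 0, (u - mu) / sig, 0)
  p <- 2 * stats::pnorm(-abs(z))
  names(z) <- region_names[cols]
  tab <- data.frame(
    region = region_names[cols], U = u, Z = z, p = p,
    p_adj = pmin(p * length(cols), 1),
    significant = p < alpha / length(cols),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  tab <- structure(tab, class = c("region_stat_map", "data.frame"),
                   test = "mann-whitney",
                   alpha = alpha, n_tests = length(cols),
                   groups = c(group_a, group_b), n1 = n1, n2 = n2)
  z <- structure(z, groups = c(group_a, group_b), n1 = n1, n2 = n2,
                 n_total = n1 + n2)
  list(z = z, table = tab)
}

#' Pearson correlation maps between PMV and clinical scores
#'
#' For each score, the per-region Pearson correlation between PMV and the
#' score over the pooled subject subset; subjects with a missing score are
#' dropped pairwise; Bonferroni adjustment over regions, per score.
#'
#' @param pmv subjects x regions PMV matrix.
#' @param records manifest data.frame aligned with `pmv` rows, carrying a
#'   `group` column and the score columns.
#' @param scores character vector of score column names.
#' @param subset group labels to pool (explicit; `NULL` pools everyone).
#' @param alpha family-wise level.
#' @return named list (one `"region_stat_map"` data.frame per score with
#'   columns `region`, `r`, `p`, `p_adj`, `significant`, `n`).
#' @export
clinical_correlation_map <- function(pmv, records, scores, subset = NULL,
                                     alpha = 0.05) {
  pmv <- as.matrix(pmv)
  stopifnot(nrow(records) == nrow(pmv))
  rows <- if (is.null(subset)) seq_len(nrow(pmv)) else
    which(records$group %in% subset)
  if (length(rows) < 3L) {
    stop("need at least 3 subjects in the pooled subset", call. = FALSE)
  }
  region_names <- colnames(pmv) %||% as.character(seq_len(ncol(pmv)))
  out <- list()
  for (sc in scores) {
    y <- records[[sc]][rows]
    if (all(is.na(y))) {
      warning("score '", sc, "' is entirely missing in the subset; skipped")
      next
    }
    n_regions <- ncol(pmv)
    r <- p <- rep(NA_real_, n_regions)
    nn <- integer(n_regions)
    for (j in seq_len(n_regions)) {
      x <- pmv[rows, j]
      ok <- !is.na(y) & !is.na(x)
      nn[j] <- sum(ok)
      if (nn[j] >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- stats::cor.test(x[ok], y[ok])
        r[j] <- unname(ct$estimate)
        p[j] <- ct$p.value
      }
    }
    tab <- data.frame(region = region_names, r = r, p = p,
                      p_adj = pmin(p * n_regions, 1),
                      significant = !is.na(p) & p < alpha / n_regions,
                      n = nn, stringsAsFactors = FALSE)
    out[[sc]] <- structure(tab, class = c("region_stat_map", "data.frame"),
                           test = "pearson", alpha = alpha,
                           n_tests = n_regions, score = sc)
  }
  out
}

zmap_values <- function(z) {
  if (is.list(z) && !is.null(z$z)) z$z else z
}

#' Agreement between two Z maps
#'
#' Pearson correlation (with its p-value) of two per-region Z maps over the
#' shared region set, the cross-dataset replication measure.
#'
#' @param za,zb numeric Z vectors or [mannwhitney_zmap()] results.
#' @return list with `r`, `p`, `n`.
#' @export
compare_zmaps <- function(za, zb) {
  za <- zmap_values(za); zb <- zmap_values(zb)
  if (length(za) != length(zb)) {
    stop("Z maps cover different region sets", call. = FALSE)
  }
  ct <- stats::cor.test(za, zb)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(za))
}

#' Stouffer weighted-Z meta-analysis across sites
#'
#' `meta_Z[j] = sum_s w_s Z_s[j] / sqrt(sum_s w_s^2)`.  The default weight
#' is the square root of each site's total sample size (read from the Z-map
#' attributes when available, otherwise equal weights).
#'
#' @param zmaps list of per-site Z maps (numeric vectors or
#'   [mannwhitney_zmap()] results) over the same regions.
#' @param weights optional per-site weights.
#' @return numeric meta-analytic Z map.
#' @export
stouffer_meta <- function(zmaps, weights = NULL) {
  stopifnot(length(zmaps) >= 1L)
  vals <- lapply(zmaps, zmap_values)
  n <- length(vals[[1L]])
  if (!all(vapply(vals, length, 0L) == n)) {
    stop("site Z maps cover different region sets", call. = FALSE)
  }
  if (is.null(weights)) {
    sizes <- vapply(vals, function(v) {
      nt <- attr(v, "n_total")
      if (is.null(nt)) NA_real_ else as.numeric(nt)
    }, 0)
    weights <- if (anyNA(sizes)) rep(1, length(vals)) else sqrt(sizes)
  }
  if (length(weights) != length(vals)) {
    stop("`weights` length does not match the number of sites",
         call. = FALSE)
  }
  num <- Reduce(`+`, Map(`*`, vals, as.list(weights)))
  out <- as.numeric(num) / sqrt(sum(weights^2))
  names(out) <- names(vals[[1L]])
  out
}

#' Summarize PMV by atlas partition
#'
#' Distribution summaries (n, mean, median, quartiles) of the cohort-mean
#' PMV map per partition label, plus pairwise label comparisons via
#' Mann-Whitney tests with Bonferroni correction.
#'
#' @param pmv_maps subjects x regions matrix or a single per-region vector.
#' @param atlas a [generate_atlas()]-style atlas.
#' @param which `"functional"` or `"anatomical"` partition.
#' @param alpha level for the pairwise comparisons.
#' @return list with `summary` and `pairwise` data.frames and `which`.
#' @export
summarize_by_partition <- function(pmv_maps, atlas,
                                   which = c("functional", "anatomical"),
                                   alpha = 0.05) {
  which <- match.arg(which)
  col <- paste0(which, "_label")
  if (!col %in% names(atlas)) {
    stop("atlas has no '", col, "' column", call. = FALSE)
  }
  mean_map <- if (is.matrix(pmv_maps)) colMeans(pmv_maps) else
    as.numeric(pmv_maps)
  labels <- atlas[[col]]
  stopifnot(length(mean_map) == length(labels))
  labs <- sort(unique(labels))
  summ <- do.call(rbind, lapply(labs, function(l) {
    v <- mean_map[labels == l]
    data.frame(label = l, n = length(v), mean = mean(v),
               median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  pairwise <- NULL
  if (length(labs) >= 2L) {
    prs <- utils::combn(labs, 2L)
    n_pairs <- ncol(prs)
    pairwise <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
      a <- mean_map[labels == prs[1L, k]]
      b <- mean_map[labels == prs[2L, k]]
      p <- if (length(a) >= 1L && length(b) >= 1L) {
        suppressWarnings(stats::wilcox.test(a, b)$p.value)
      } else NA_real_
      data.frame(label_a = prs[1L, k], label_b = prs[2L, k], p = p,
                 stringsAsFactors = FALSE)
    }))
    pairwise$p_adj <- pmin(pairwise$p * n_pairs, 1)
    pairwise$significant <- !is.na(pairwise$p_adj) & pairwise$p_adj < alpha
  }
  list(summary = summ, pairwise = pairwise, which = which)
}
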