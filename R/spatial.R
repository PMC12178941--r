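# Spatial association between a per-region target map (typically a Z map)
# and region x map matrices: one-component PLS with permutation nulls,
# bootstrap gene Z-scores, and correlation panels.

standardize_matrix_cols <- function(m, what = "map") {
  m <- as.matrix(m)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(m)[sds == 0] %||% as.character(which(sds == 0))
    stop("constant ", what, " column(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  scale(m)
}

check_permutations <- function(permutations, n) {
  permutations <- as.matrix(permutations)
  if (ncol(permutations) != n) {
    stop("permutation rows must have length ", n, call. = FALSE)
  }
  ref <- seq_len(n)
  ok <- apply(permutations, 1L, function(p) identical(sort(as.integer(p)), ref))
  if (!all(ok)) {
    stop("supplied rows are not permutations of 1..", n, call. = FALSE)
  }
  permutations
}

draw_permutations <- function(n_perm, n, seed) {
  with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  })
}

pls1_weights <- function(x, y) {
  w <- as.numeric(crossprod(x, y))
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) rep(0, length(w)) else w / nrm
}

#' One-component PLS association with permutation significance
#'
#' Predictor columns and the target are column-standardized; the first PLS
#' component is computed in closed form (for a univariate target the NIPALS
#' iteration converges in one step: the weight vector is the normalized
#' covariance of each predictor with the target).  `r_with_target` is the
#' Pearson correlation between the component scores and the target;
#' `variance_explained` is the share of the predictor-block variance
#' captured by component 1.  Significance uses the permutation estimate
#' `p_perm = (1 + #{permuted |r| >= observed |r|}) / (1 + n_perm)`,
#' permuting the target over regions.  Spatially constrained nulls (spin or
#' variogram permutations computed by an external tool on real atlas
#' coordinates) can be supplied as precomputed index rows; otherwise
#' uniform permutations are drawn from `seed`.
#'
#' @param genes regions x maps numeric matrix (e.g. gene expression).
#' @param target per-region numeric vector (e.g. a Z map).
#' @param n_perm number of permutations.
#' @param permutations optional `n_perm` x N matrix of precomputed
#'   permutation index rows (1-based).
#' @param seed seed for uniform permutations.
#' @return object of class `"pls1_result"` with `component_scores`,
#'   `gene_weights` (unit norm), `r_with_target`, `variance_explained`,
#'   `p_perm`, `n_perm`, `permutation_scheme`.
#' @export
pls1_association <- function(genes, target, n_perm = 999L,
                             permutations = NULL, seed = 1L) {
  genes <- as.matrix(genes)
  n <- nrow(genes)
  if (n < 3L) stop("need at least 3 regions", call. = FALSE)
  if (length(target) != n) {
    stop("target length does not match the number of regions",
         call. = FALSE)
  }
  x <- standardize_matrix_cols(genes, "gene")
  y <- as.numeric(scale(target))
  w <- pls1_weights(x, y)
  scores <- as.numeric(x %*% w)
  r_obs <- if (stats::sd(scores) == 0) 0 else stats::cor(scores, y)
  loadings <- as.numeric(crossprod(x, scores)) / sum(scores^2)
  variance_explained <- sum(scores^2) * sum(loadings^2) / sum(x^2)

  if (!is.null(permutations)) {
    permutations <- check_permutations(permutations, n)
    n_perm <- nrow(permutations)
    scheme <- "supplied"
  } else {
    permutations <- draw_permutations(n_perm, n, seed)
    scheme <- "uniform"
  }
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    yp <- y[permutations[i, ]]
    wp <- pls1_weights(x, yp)
    sp <- as.numeric(x %*% wp)
    rp <- if (stats::sd(sp) == 0) 0 else stats::cor(sp, yp)
    if (abs(rp) >= abs(r_obs)) exceed <- exceed + 1L
  }
  structure(
    list(component_scores = stats::setNames(scores, rownames(genes)),
         gene_weights = stats::setNames(w, colnames(genes)),
         r_with_target = r_obs,
         variance_explained = variance_explained,
         p_perm = (1 + exceed) / (1 + n_perm),
         n_perm = n_perm,
         permutation_scheme = scheme),
    class = "pls1_result"
  )
}

#' @export
print.pls1_result <- function(x, ...) {
  cat(sprintf(paste0("PLS1 association: r = %.3f, variance explained = ",
                     "%.1f%%, p_perm = %.4g (%s permutations, n = %d)\n"),
              x$r_with_target, 100 * x$variance_explained, x$p_perm,
              x$permutation_scheme, x$n_perm))
  invisible(x)
}

#' Bootstrap Z-scores for PLS1 gene weights
#'
#' Regions are resampled with replacement; the one-component weights are
#' refitted per replicate and sign-aligned to the original component; each
#' gene's Z-score is its original weight divided by the bootstrap standard
#' error.  Genes are returned sorted by absolute Z, and the top `top_k`
#' symbols (default 500, capped at the gene count) are exported for
#' external enrichment analysis.
#'
#' @param genes regions x genes matrix.
#' @param target per-region numeric vector.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param top_k how many top genes to export.
#' @return list with `table` (data.frame: gene, weight, se, z, sorted by
#'   |z|), `top_genes` (character), `n_boot`.
#' @export
bootstrap_gene_zscores <- function(genes, target, n_boot = 1000L,
                                   seed = 1L, top_k = 500L) {
  genes <- as.matrix(genes)
  n <- nrow(genes)
  n_boot <- assert_scalar_count(n_boot, "n_boot", min = 100L)
  fit <- pls1_association(genes, target, n_perm = 0L, seed = seed)
  w0 <- fit$gene_weights
  boots <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, ncol(genes))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      xb <- genes[idx, , drop = FALSE]
      yb <- target[idx]
      sdx <- apply(xb, 2L, stats::sd)
      if (stats::sd(yb) == 0 || all(sdx == 0)) next
      xb <- sweep(xb, 2L, colMeans(xb), "-")
      xb[, sdx > 0] <- sweep(xb[, sdx > 0, drop = FALSE], 2L,
                             sdx[sdx > 0], "/")
      wb <- pls1_weights(xb, as.numeric(scale(yb)))
      if (sum(wb * w0) < 0) wb <- -wb  # sign-align to original component
      out[b, ] <- wb
    }
    out
  })
  se <- apply(boots, 2L, stats::sd, na.rm = TRUE)
  z <- ifelse(se > 0, w0 / se, NA_real_)
  gene_names <- colnames(genes) %||% sprintf("gene_%04d", seq_len(ncol(genes)))
  ord <- order(abs(z), decreasing = TRUE)
  tab <- data.frame(gene = gene_names[ord], weight = unname(w0)[ord],
                    se = se[ord], z = unname(z)[ord],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  if (top_k > ncol(genes)) {
    warning("`top_k` (", top_k, ") exceeds the gene count (", ncol(genes),
            "); returning all genes")
    top_k <- ncol(genes)
  }
  list(table = tab, top_genes = tab$gene[seq_len(top_k)], n_boot = n_boot)
}

#' Correlation panel between a target map and named spatial maps
#'
#' Pearson (or Spearman) correlation of the target with each map, a
#' permutation p-value per map (same permutation machinery as
#' [pls1_association()], shared draws across the panel), and Bonferroni
#' adjustment across the panel.
#'
#' @param target per-region numeric vector (named by region when possible).
#' @param maps regions x maps matrix, e.g. from [generate_spatial_maps()]
#'   or [read_spatial_maps()].
#' @param n_perm number of permutations.
#' @param permutations optional precomputed permutation index rows.
#' @param seed seed for uniform permutations.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha family-wise level.
#' @return data.frame with `name`, `r`, `p_perm`, `p_adj`, `significant`.
#' @export
map_correlation_panel <- function(target, maps, n_perm = 999L,
                                  permutations = NULL, seed = 1L,
                                  method = c("pearson", "spearman"),
                                  alpha = 0.05) {
  method <- match.arg(method)
  maps <- as.matrix(maps)
  n <- length(target)
  if (nrow(maps) != n) {
    bad <- colnames(maps) %||% "unnamed"
    stop("region set mismatch (target has ", n, " regions, maps have ",
         nrow(maps), "): ", paste(utils::head(bad, 3L), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(names(target)) && !is.null(rownames(maps)) &&
      !identical(names(target), rownames(maps))) {
    bad <- colnames(maps)[1L] %||% "map 1"
    stop("region ids of the maps do not match the target (first map: ",
         bad, ")", call. = FALSE)
  }
  r_obs <- as.numeric(stats::cor(target, maps, method = method))
  if (!is.null(permutations)) {
    permutations <- check_permutations(permutations, n)
    n_perm <- nrow(permutations)
  } else {
    permutations <- draw_permutations(n_perm, n, seed)
  }
  exceed <- integer(ncol(maps))
  for (i in seq_len(n_perm)) {
    rp <- as.numeric(stats::cor(target[permutations[i, ]], maps,
                                method = method))
    exceed <- exceed + (abs(rp) >= abs(r_obs))
  }
  p_perm <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(
    name = colnames(maps) %||% sprintf("map_%03d", seq_len(ncol(maps))),
    r = r_obs,
    p_perm = p_perm,
    p_adj = pmin(p_perm * ncol(maps), 1),
    significant = pmin(p_perm * ncol(maps), 1) < alpha,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
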