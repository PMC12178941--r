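# Principal Motif Value: PCA summary of the 20-type regional motif census.

standardize_rows <- function(m) {
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))  # population (1/N) convention
  z <- (m - mu) / sd_pop
  z[sd_pop == 0, ] <- 0
  z
}

standardize_cols <- function(m) t(standardize_rows(t(m)))

#' Standardize a motif count matrix
#'
#' Each motif-type row is standardized to mean 0 and unit variance across
#' the regions (population SD convention); a zero-variance row maps to all
#' zeros.  This is the default motifs-as-variables orientation; see
#' [fit_pmv_model()] for the alternative.
#'
#' @param mcm 20 x N motif count matrix (numeric).
#' @param orientation `"motifs"` standardizes rows across regions,
#'   `"regions"` standardizes each region column across the 20 types.
#' @return numeric matrix of the same shape.
#' @export
standardize_counts <- function(mcm, orientation = c("motifs", "regions")) {
  orientation <- match.arg(orientation)
  m <- as.matrix(mcm)
  storage.mode(m) <- "double"
  if (orientation == "motifs") standardize_rows(m) else standardize_cols(m)
}

#' Fit the Principal Motif Value model on a reference cohort
#'
#' All subjects' standardized count matrices are stacked along the region
#' axis (observations are region columns pooled over subjects; variables
#' are the 20 motif types), the 20 x 20 covariance matrix (1/(n-1)
#' convention) is eigendecomposed, and the loading is the eigenvector of
#' the largest eigenvalue.  The eigenvector's sign is fixed so that the
#' loading of the anchor motif type (default: the all-WEAK_SHORT triangle,
#' catalog type 20) is nonnegative, which makes repeated fits and the
#' interpretation of positive PMV (regions dominated by weaker, shorter
#' connections) deterministic.
#'
#' One cohort-common loading is fitted and applied to every subject;
#' per-subject PCA would leave per-subject sign and rotation ambiguity and
#' break group comparison.
#'
#' @param cohort_counts list of 20 x N count matrices (or one matrix).
#' @param sign_anchor motif type index whose loading is forced >= 0
#'   (default: last type, the all-WEAK_SHORT triangle under the default
#'   catalog).
#' @param orientation `"motifs"` (default, see above) or `"regions"`, the
#'   literal alternative in which regions are the variables; provided for
#'   comparison only.
#' @return object of class `"pmv_model"`: `loading` (unit norm),
#'   `eigenvalues` (descending), `variance_explained_1`, `contributions`
#'   (squared loadings), `sign_anchor`, `orientation`, `n_types`.
#' @export
fit_pmv_model <- function(cohort_counts, sign_anchor = NULL,
                          orientation = c("motifs", "regions")) {
  orientation <- match.arg(orientation)
  if (is.matrix(cohort_counts)) cohort_counts <- list(cohort_counts)
  stopifnot(length(cohort_counts) >= 1L)
  zs <- lapply(cohort_counts, standardize_counts, orientation = orientation)
  if (orientation == "motifs") {
    pooled <- t(do.call(cbind, zs))  # (subjects*regions) x 20
  } else {
    pooled <- do.call(rbind, zs)     # (subjects*20) x regions
  }
  if (nrow(pooled) < 2L) {
    stop("fewer than 2 pooled observations", call. = FALSE)
  }
  cv <- stats::cov(pooled)
  eig <- eigen(cv, symmetric = TRUE)
  loading <- eig$vectors[, 1L]
  if (is.null(sign_anchor)) {
    sign_anchor <- if (orientation == "motifs") length(loading) else 1L
  }
  anchor_val <- loading[sign_anchor]
  if (anchor_val < 0 ||
      (anchor_val == 0 && loading[which(loading != 0)[1L]] < 0)) {
    loading <- -loading
  }
  ev <- pmax(eig$values, 0)
  structure(
    list(loading = loading,
         eigenvalues = eig$values,
         variance_explained_1 = ev[1L] / sum(ev),
         contributions = loading^2,
         sign_anchor = sign_anchor,
         orientation = orientation,
         n_types = if (orientation == "motifs") length(loading) else
           nrow(cohort_counts[[1L]])),
    class = "pmv_model"
  )
}

#' @export
print.pmv_model <- function(x, ...) {
  cat("PMV model (", x$orientation, " orientation)\n", sep = "")
  cat(sprintf("  first component explains %.1f%% of variance\n",
              100 * x$variance_explained_1))
  top <- order(x$contributions, decreasing = TRUE)[1:3]
  cat("  top contributing variables:",
      paste(sprintf("#%d (%.0f%%)", top, 100 * x$contributions[top]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Project one subject's motif census onto the PMV loading
#'
#' The subject's own count matrix is standardized (subject-internal
#' z-scores, keeping subjects exchangeable) and projected:
#' `PMV[j] = sum_t Z[t, j] * loading[t]` in the default orientation,
#' giving one value per region.
#'
#' @param mcm 20 x N count matrix.
#' @param model a fitted [fit_pmv_model()].
#' @return numeric vector (length N in the default orientation), named by
#'   region when `mcm` has column names.
#' @export
project_pmv <- function(mcm, model) {
  stopifnot(inherits(model, "pmv_model"))
  if (nrow(mcm) != model$n_types) {
    stop("count matrix has ", nrow(mcm), " motif types but the model was ",
         "fitted with ", model$n_types, call. = FALSE)
  }
  z <- standardize_counts(mcm, orientation = model$orientation)
  if (model$orientation == "motifs") {
    out <- as.numeric(crossprod(z, model$loading))
    names(out) <- colnames(mcm)
  } else {
    out <- as.numeric(z %*% model$loading)
    names(out) <- rownames(mcm)
  }
  out
}

#' Per-motif contributions to the PMV
#'
#' Contributions are the squared loadings (they sum to 1), reported in
#' descending order.
#'
#' @param model a fitted [fit_pmv_model()].
#' @param catalog optional [motif_catalog()] to attach type labels.
#' @return data.frame with `type`, optional `label`, `contribution`,
#'   `cumulative`, ordered by decreasing contribution.
#' @export
motif_contributions <- function(model, catalog = NULL) {
  stopifnot(inherits(model, "pmv_model"))
  ord <- order(model$contributions, decreasing = TRUE)
  out <- data.frame(type = ord, contribution = model$contributions[ord])
  if (!is.null(catalog)) out$label <- catalog$label[ord]
  out$cumulative <- cumsum(out$contribution)
  rownames(out) <- NULL
  out
}
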