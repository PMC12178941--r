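#' Min-max normalize a regional feature matrix
#'
#' Rescales each feature column to `[0, 1]` across the regions of one
#' subject.  The scope is per feature, within subject, so subjects remain
#' independent and each network is an individual construction.
#'
#' @param fm numeric matrix, regions x features.
#' @return matrix of the same shape with every column in `[0, 1]`.
#' @seealso [build_r2sn()]
#' @export
minmax_normalize <- function(fm) {
  fm <- as.matrix(fm)
  rng <- apply(fm, 2L, range)
  const <- which(rng[1L, ] == rng[2L, ])
  if (length(const) > 0L) {
    nm <- colnames(fm)[const] %||% as.character(const)
    stop("constant feature(s) cannot be min-max normalized: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  sweep(sweep(fm, 2L, rng[1L, ], "-"), 2L, rng[2L, ] - rng[1L, ], "/")
}

#' Correlation-based greedy feature selection
#'
#' Computes the cohort-mean absolute pairwise feature correlation
#' (correlating feature columns across regions within each subject, then
#' averaging the absolute correlation matrices over subjects) and greedily
#' eliminates features: while any surviving pair exceeds `r_cap` or more
#' than `target_count` features remain, the feature with the highest mean
#' absolute correlation to the other survivors is dropped.  Ties are broken
#' by original feature index (the lower-indexed feature is kept).
#'
#' @param cohort a list of regions x features matrices (or a single matrix).
#' @param target_count number of features to retain (default 25).
#' @param r_cap maximum tolerated absolute pairwise correlation.
#' @return character vector of surviving feature names (original order), or
#'   integer indices when the matrices are unnamed.
#' @export
select_features <- function(cohort, target_count = 25L, r_cap = 0.90) {
  if (is.matrix(cohort)) cohort <- list(cohort)
  stopifnot(length(cohort) >= 1L)
  target_count <- assert_scalar_count(target_count, "target_count", min = 2L)
  nf <- ncol(cohort[[1L]])
  if (target_count > nf) {
    stop("`target_count` (", target_count, ") exceeds the number of ",
         "features (", nf, ")", call. = FALSE)
  }
  acc <- matrix(0, nf, nf)
  for (fm in cohort) {
    cc <- abs(stats::cor(fm))
    if (any(!is.finite(cc))) {
      stop("feature correlation undefined (constant feature column?)",
           call. = FALSE)
    }
    acc <- acc + cc
  }
  m <- acc / length(cohort)
  diag(m) <- NA_real_
  surv <- seq_len(nf)
  repeat {
    if (length(surv) < 2L) break
    sub <- m[surv, surv, drop = FALSE]
    max_off <- max(sub, na.rm = TRUE)
    if (length(surv) <= target_count && max_off <= r_cap) break
    score <- rowMeans(sub, na.rm = TRUE)
    worst <- which(score >= max(score) - 1e-15)
    surv <- surv[-max(worst)]  # among ties drop the highest original index
  }
  nms <- colnames(cohort[[1L]])
  if (is.null(nms)) surv else nms[surv]
}

#' Build one subject's regional radiomics similarity network
#'
#' The R2SN edge weight between two regions is the Pearson correlation of
#' their selected-feature vectors; the diagonal is set to 1.
#'
#' @param fm numeric matrix, regions x features (normalized).
#' @param selected feature names or indices to use (>= 2).
#' @return symmetric N x N matrix with unit diagonal, region ids as
#'   dimnames when `fm` carries rownames.
#' @export
build_r2sn <- function(fm, selected = colnames(fm)) {
  fm <- as.matrix(fm)
  if (is.null(selected)) selected <- seq_len(ncol(fm))
  sub <- fm[, selected, drop = FALSE]
  if (ncol(sub) < 2L) {
    stop("at least 2 selected features are required", call. = FALSE)
  }
  vr <- apply(sub, 1L, stats::var)
  flat <- which(vr == 0)
  if (length(flat) > 0L) {
    nm <- rownames(sub)[flat] %||% as.character(flat)
    stop("region(s) with zero-variance feature profile: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  w <- stats::cor(t(sub))
  diag(w) <- 1
  dimnames(w) <- list(rownames(fm), rownames(fm))
  w
}
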