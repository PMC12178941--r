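# Triangle motif engine: edge labelling by cohort-median strength/length
# thresholds and the 20-type census over all region triples.

# Fixed edge-class order; catalog order and all integer codes derive from it.
EDGE_CLASSES <- c("STRONG_LONG", "STRONG_SHORT", "WEAK_LONG", "WEAK_SHORT")
EDGE_ABBREV <- c("SL", "SS", "WL", "WS")

#' Inter-regional Euclidean distance matrix
#'
#' @param atlas a [generate_atlas()]-style atlas (columns `x`, `y`, `z`).
#' @return symmetric N x N matrix of centroid distances in mm, zero
#'   diagonal, region ids as dimnames.
#' @export
compute_edge_lengths <- function(atlas) {
  stopifnot(all(c("x", "y", "z") %in% names(atlas)))
  d <- as.matrix(stats::dist(as.matrix(atlas[, c("x", "y", "z")])))
  dimnames(d) <- list(as.character(atlas$region_id),
                      as.character(atlas$region_id))
  d
}

#' Cohort-median binarization thresholds
#'
#' The strength threshold is the median of the pooled upper-triangle edge
#' weights of all subjects' networks; the length threshold is the median of
#' the C(N, 2) pairwise centroid distances (identical for every subject
#' since the atlas is fixed).
#'
#' @param r2sns list of subject R2SN matrices (>= 1).
#' @param distances matrix from [compute_edge_lengths()].
#' @param provenance free-text cohort identifier stored with the pair.
#' @return list of class `"threshold_pair"` with `strength_median`,
#'   `length_median`, `provenance`.
#' @export
compute_thresholds <- function(r2sns, distances, provenance = "cohort") {
  if (is.matrix(r2sns)) r2sns <- list(r2sns)
  if (length(r2sns) == 0L) stop("empty cohort", call. = FALSE)
  ut <- upper.tri(distances)
  pooled <- unlist(lapply(r2sns, function(m) {
    stopifnot(all(dim(m) == dim(distances)))
    m[ut]
  }), use.names = FALSE)
  structure(
    list(strength_median = stats::median(pooled),
         length_median = stats::median(distances[ut]),
         provenance = provenance),
    class = "threshold_pair"
  )
}

#' Label every edge by strength and length class
#'
#' Edges with weight strictly above the strength median are STRONG,
#' otherwise WEAK (values equal to the median fall on the WEAK side);
#' distances strictly above the length median are LONG, otherwise SHORT.
#' Subject-level variation in edge weights is preserved: only the strength
#' comparison differs between subjects, the thresholds are cohort-level.
#'
#' @param net subject R2SN matrix.
#' @param distances matrix from [compute_edge_lengths()].
#' @param thr a [compute_thresholds()] pair.
#' @return integer N x N matrix with codes 1..4 indexing
#'   `c("STRONG_LONG", "STRONG_SHORT", "WEAK_LONG", "WEAK_SHORT")`;
#'   the diagonal is `NA` (self-edges are not labelled).
#' @export
label_edges <- function(net, distances, thr) {
  stopifnot(inherits(thr, "threshold_pair"))
  if (!all(dim(net) == dim(distances))) {
    stop("network and distance matrices have different shapes",
         call. = FALSE)
  }
  strong <- net > thr$strength_median
  long <- distances > thr$length_median
  code <- ifelse(strong, ifelse(long, 1L, 2L), ifelse(long, 3L, 4L))
  diag(code) <- NA_integer_
  storage.mode(code) <- "integer"
  dimnames(code) <- dimnames(net)
  attr(code, "classes") <- EDGE_CLASSES
  code
}

#' The canonical catalog of 20 triangle motif types
#'
#' A triangle's identity is the multiset of its three edge classes, so
#' orderings that differ only by rotation or reflection collapse to one
#' type.  The catalog enumerates all 4^3 = 64 ordered class triples,
#' canonicalizes each by sorting under the fixed class order
#' STRONG_LONG < STRONG_SHORT < WEAK_LONG < WEAK_SHORT, and deduplicates,
#' yielding exactly choose(6, 3) = 20 types ordered lexicographically by
#' canonical triple.  Type 20 is the all-WEAK_SHORT triangle.
#'
#' @return data.frame with columns `type`, `edge1`, `edge2`, `edge3`,
#'   `label`; attribute `"codes"` holds the 20 x 3 integer code matrix and
#'   `"key_map"` the 64-entry lookup from ordered triples to type index.
#' @export
motif_catalog <- function() {
  grid <- expand.grid(e1 = 1:4, e2 = 1:4, e3 = 1:4)
  keep <- grid$e1 <= grid$e2 & grid$e2 <= grid$e3
  canon <- grid[keep, , drop = FALSE]
  canon <- canon[order(canon$e1, canon$e2, canon$e3), , drop = FALSE]
  codes <- as.matrix(canon)
  rownames(codes) <- NULL
  # ordered-triple key -> canonical type index, for all 64 ordered triples
  key_map <- integer(64L)
  for (a in 1:4) for (b in 1:4) for (c in 1:4) {
    s <- sort(c(a, b, c))
    idx <- which(codes[, 1L] == s[1L] & codes[, 2L] == s[2L] &
                   codes[, 3L] == s[3L])
    key_map[(a - 1L) * 16L + (b - 1L) * 4L + c] <- idx
  }
  out <- data.frame(
    type = seq_len(nrow(codes)),
    edge1 = EDGE_CLASSES[codes[, 1L]],
    edge2 = EDGE_CLASSES[codes[, 2L]],
    edge3 = EDGE_CLASSES[codes[, 3L]],
    label = apply(codes, 1L, function(r) {
      paste(EDGE_ABBREV[r], collapse = "-")
    }),
    stringsAsFactors = FALSE
  )
  attr(out, "codes") <- codes
  attr(out, "key_map") <- key_map
  out
}

#' Canonical motif type of edge-class triples
#'
#' Vectorized lookup: permutations of the same three classes map to the
#' same type index.
#'
#' @param e1,e2,e3 integer edge-class codes (1..4).
#' @param catalog a [motif_catalog()].
#' @return integer type indices in 1..20.
#' @export
motif_type_of <- function(e1, e2, e3, catalog = motif_catalog()) {
  key_map <- attr(catalog, "key_map")
  key_map[(e1 - 1L) * 16L + (e2 - 1L) * 4L + e3]
}

#' Census of triangle motifs per region
#'
#' Every unordered triple of regions in the complete labelled graph is a
#' triangle; its type is the multiset of its three edge classes, and each
#' of the three constituent regions contributes one count to that type.
#' The result satisfies the conservation identities: each region's column
#' sums to `choose(N - 1, 2)` and the grand total is `3 * choose(N, 3)`.
#'
#' The census is computed algebraically from per-class indicator matrices
#' (summing `diag(A_s A_u A_t)` over ordered class patterns and halving),
#' which avoids enumerating the C(N, 3) triples.
#'
#' @param labels integer edge-class matrix from [label_edges()].
#' @param catalog a [motif_catalog()].
#' @return 20 x N integer matrix; rows named by catalog label, columns by
#'   region id.
#' @export
count_motifs <- function(labels, catalog = motif_catalog()) {
  n <- nrow(labels)
  if (is.null(n) || n < 3L) {
    stop("at least 3 regions are required to form a triangle",
         call. = FALSE)
  }
  off <- labels[upper.tri(labels) | lower.tri(labels)]
  if (any(is.na(off)) || any(off < 1L | off > 4L)) {
    stop("labels must be complete with codes in 1..4 off the diagonal",
         call. = FALSE)
  }
  ind <- lapply(1:4, function(s) {
    m <- (labels == s)
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  counts <- matrix(0, 20L, n)
  for (s in 1:4) {
    for (u in 1:4) {
      b <- ind[[s]] %*% ind[[u]]
      for (tt in 1:4) {
        m <- motif_type_of(s, u, tt, catalog)
        # diag(A_s A_u A_t)[j] counts ordered walks j -> i -> k -> j whose
        # edges carry classes (s, u, t); each triangle at j appears twice
        counts[m, ] <- counts[m, ] + rowSums(b * ind[[tt]])
      }
    }
  }
  counts <- counts / 2
  stopifnot(max(abs(counts - round(counts))) < 1e-9)
  counts <- round(counts)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(catalog$label, colnames(labels))
  counts
}
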