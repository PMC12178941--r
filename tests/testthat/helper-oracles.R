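# Independent oracles and fixture builders used across the suite.

# Naive triple-loop motif census: enumerate every unordered region triple,
# classify its edge-class multiset by sorting, count at each corner.
oracle_count_motifs <- function(labels, catalog = motif_catalog()) {
  codes <- attr(catalog, "codes")
  n <- nrow(labels)
  counts <- matrix(0L, nrow(codes), n)
  triples <- utils::combn(n, 3L)
  for (t in seq_len(ncol(triples))) {
    a <- triples[1L, t]; b <- triples[2L, t]; c <- triples[3L, t]
    s <- sort(c(labels[a, b], labels[a, c], labels[b, c]))
    m <- which(codes[, 1L] == s[1L] & codes[, 2L] == s[2L] &
                 codes[, 3L] == s[3L])
    counts[m, a] <- counts[m, a] + 1L
    counts[m, b] <- counts[m, b] + 1L
    counts[m, c] <- counts[m, c] + 1L
  }
  dimnames(counts) <- list(catalog$label, colnames(labels))
  counts
}

# Random symmetric edge-class matrix on n regions (codes 1..4, NA diagonal).
random_label_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(NA_integer_, n, n)
  ut <- upper.tri(m)
  m[ut] <- sample.int(4L, sum(ut), replace = TRUE)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  colnames(m) <- rownames(m) <- as.character(seq_len(n))
  m
}

# Small planted-effect cohort run through features -> R2SN -> motifs -> PMV.
# Returns the subjects x regions PMV matrix plus records and counts.
run_pmv_stage <- function(atlas, group_sizes, effect = NULL,
                          n_features = 30L, noise_sd = 0.1, seed = 1L,
                          distances = NULL, catalog = NULL) {
  coh <- generate_cohort(atlas, group_sizes, n_features = n_features,
                         effect = effect, noise_sd = noise_sd, seed = seed)
  sel <- select_features(coh$features, target_count = min(25L, n_features),
                         r_cap = 0.9)
  r2sns <- lapply(coh$features, function(fm) {
    build_r2sn(minmax_normalize(fm), sel)
  })
  if (is.null(distances)) distances <- compute_edge_lengths(atlas)
  if (is.null(catalog)) catalog <- motif_catalog()
  thr <- compute_thresholds(r2sns, distances)
  counts <- lapply(r2sns, function(net) {
    count_motifs(label_edges(net, distances, thr), catalog)
  })
  model <- fit_pmv_model(counts)
  pmv <- t(vapply(counts, project_pmv, numeric(nrow(atlas)), model = model))
  list(pmv = pmv, records = coh$records, counts = counts, model = model)
}

# Noise spatial maps residualized against a target map, so they carry no
# target signal at all (the synthetic analogue of expression maps unrelated
# to the contrast of interest).
make_orthogonal_noise <- function(target, n_maps, seed,
                                  names = sprintf("noise%03d", seq_len(n_maps))) {
  set.seed(seed)
  n <- length(target)
  yc <- target - mean(target)
  x <- matrix(rnorm(n * n_maps), n, n_maps)
  x <- sweep(x, 2, colMeans(x))
  x <- x - yc %*% (crossprod(yc, x) / sum(yc^2))
  colnames(x) <- names
  x
}

# Pearson correlation between two vectors, written out from the definition
# (independent of stats::cor) for cross-checking build_r2sn.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
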