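#' Generate a synthetic brain atlas
#'
#' Samples `n_regions` centroids uniformly inside a bounded ellipsoid
#' (semi-axes in mm, roughly MNI-brain sized) and assigns anatomical and
#' functional partition labels by deterministic spatial rules: the innermost
#' `subcortex_frac` of regions (by radial position) are labelled
#' `"subcortex"`, the next `limbic_frac` `"limbic"`, and the remaining
#' cortical regions are split into frontal/parietal/temporal/occipital lobes
#' by their direction on the ellipsoid.  Functional labels emulate a
#' 7-network cortical partition (subcortical regions are left unassigned as
#' `"none"`), carved out of equal angular sectors.
#'
#' @param n_regions number of regions (>= 3).
#' @param seed integer seed; identical arguments give identical atlases.
#' @param radii semi-axes (x, y, z) of the bounding ellipsoid in mm.
#' @param subcortex_frac fraction of regions labelled subcortex (innermost
#'   radial shell).
#' @param limbic_frac fraction labelled limbic (next shell).
#' @return A `data.frame` of class `"pmv_atlas"` with columns `region_id`,
#'   `x`, `y`, `z`, `anatomical_label`, `functional_label`.
#' @examples
#' atlas <- generate_atlas(60, seed = 1)
#' table(atlas$anatomical_label)
#' @export
generate_atlas <- function(n_regions, seed = 1L, radii = c(70, 85, 60),
                           subcortex_frac = 0.15, limbic_frac = 0.10) {
  n_regions <- assert_scalar_count(n_regions, "n_regions", min = 3L)
  stopifnot(length(radii) == 3L, all(is.finite(radii)), all(radii > 0))
  with_seed(seed, {
    dir <- matrix(stats::rnorm(n_regions * 3L), ncol = 3L)
    dir <- dir / sqrt(rowSums(dir^2))
    u <- stats::runif(n_regions)^(1 / 3)  # radial fraction, uniform in ball
    xyz <- dir * u * matrix(radii, n_regions, 3L, byrow = TRUE)
  })
  rr <- rank(u, ties.method = "first") / n_regions
  anat <- character(n_regions)
  anat[rr <= subcortex_frac] <- "subcortex"
  anat[rr > subcortex_frac & rr <= subcortex_frac + limbic_frac] <- "limbic"
  cortex <- anat == ""
  dy <- dir[, 2]; dz <- dir[, 3]
  anat[cortex & dy < -0.5] <- "occipital"
  anat[cortex & anat == "" & dy > 0.35] <- "frontal"
  anat[cortex & anat == "" & dz < -0.35] <- "temporal"
  anat[anat == ""] <- "parietal"

  yeo <- c("VIS", "SM", "DAN", "VAN", "LIMB", "FPN", "DMN")
  theta <- atan2(dz, dy)  # angular sector on the sagittal circle
  sector <- pmin(7L, 1L + floor((theta + pi) / (2 * pi) * 7))
  func <- yeo[sector]
  func[anat == "subcortex"] <- "none"

  atlas <- data.frame(
    region_id = seq_len(n_regions),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    anatomical_label = anat,
    functional_label = func,
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("pmv_atlas", "data.frame")
  atlas
}

#' Describe a planted regional effect
#'
#' Specifies how a synthetic cohort perturbs the feature profiles of a set
#' of target regions in the affected diagnostic groups.  Two modes are
#' supported: `"strength-shift"` blends each target region's archetype
#' profile towards the cohort-mean profile (raising that region's R2SN edge
#' strengths), and `"profile-decorrelation"` adds a fixed random direction
#' to the profile (lowering its correlations with every other region).
#'
#' @param target_regions integer region ids to perturb.
#' @param effect_size nonnegative magnitude; 0 is the null. For
#'   `"strength-shift"` it is the blending weight (capped at 1).
#' @param effect_mode `"strength-shift"` or `"profile-decorrelation"`.
#' @param groups_affected group labels receiving the perturbation.
#' @return list of class `"effect_spec"`.
#' @export
effect_spec <- function(target_regions = integer(),
                        effect_size = 0,
                        effect_mode = c("strength-shift",
                                        "profile-decorrelation"),
                        groups_affected = "AD") {
  effect_mode <- match.arg(effect_mode)
  if (!is.numeric(effect_size) || length(effect_size) != 1L ||
      !is.finite(effect_size) || effect_size < 0) {
    stop("`effect_size` must be a single nonnegative number", call. = FALSE)
  }
  structure(
    list(target_regions = as.integer(target_regions),
         effect_size = effect_size,
         effect_mode = effect_mode,
         groups_affected = groups_affected),
    class = "effect_spec"
  )
}

#' Generate a synthetic cohort of regional feature tables
#'
#' Regional archetype profiles are built from a small number of latent
#' spatial gradients of the atlas centroids plus region-specific offsets,
#' which gives the resulting R2SN matrices a realistic block structure and
#' non-degenerate motif distributions.  Each subject observes the archetype
#' (perturbed per [effect_spec()] in affected groups) plus i.i.d. Gaussian
#' noise.  Effects are injected upstream of network construction so every
#' downstream stage is exercised.
#'
#' @param atlas a [generate_atlas()] atlas.
#' @param group_sizes named integer vector, e.g. `c(NC = 30, MCI = 30, AD = 30)`.
#' @param n_features number of features per region (>= 2).
#' @param effect an [effect_spec()] or `NULL` for a null cohort.
#' @param noise_sd subject-level Gaussian noise SD (archetype profiles have
#'   roughly unit scale).
#' @param seed integer seed.
#' @param n_sites number of acquisition sites, assigned round-robin.
#' @return list with `records` (data.frame: subject_id, group, site_id,
#'   dose) and `features` (named list of region x feature matrices).
#' @export
generate_cohort <- function(atlas, group_sizes, n_features = 30L,
                            effect = NULL, noise_sd = 0.1, seed = 1L,
                            n_sites = 1L) {
  stopifnot(inherits(atlas, "pmv_atlas"))
  n_features <- assert_scalar_count(n_features, "n_features", min = 2L)
  if (length(group_sizes) == 0L || is.null(names(group_sizes))) {
    stop("`group_sizes` must be a nonempty named vector", call. = FALSE)
  }
  if (!is.null(effect)) {
    stopifnot(inherits(effect, "effect_spec"))
    bad <- setdiff(effect$target_regions, atlas$region_id)
    if (length(bad) > 0L) {
      stop("effect target regions not in atlas: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  n <- nrow(atlas)
  feat_names <- sprintf("feat%03d", seq_len(n_features))
  region_ids <- as.character(atlas$region_id)

  with_seed(seed, {
    # latent spatial gradients: scaled coordinates + radial position
    xyz <- as.matrix(atlas[, c("x", "y", "z")])
    g <- sweep(xyz, 2L, apply(abs(xyz), 2L, max), "/")
    r <- sqrt(rowSums(g^2)); r <- r / max(r)
    basis <- cbind(g, r)
    w <- matrix(stats::rnorm(ncol(basis) * n_features), ncol(basis),
                n_features)
    offsets <- matrix(stats::rnorm(n * n_features, sd = 0.5), n, n_features)
    archetype <- basis %*% w + offsets

    decor_dirs <- NULL
    if (!is.null(effect) && effect$effect_mode == "profile-decorrelation" &&
        length(effect$target_regions) > 0L) {
      decor_dirs <- matrix(stats::rnorm(length(effect$target_regions) *
                                          n_features),
                           length(effect$target_regions), n_features)
    }
    mean_profile <- colMeans(archetype)

    records <- list()
    features <- list()
    k <- 0L
    for (gname in names(group_sizes)) {
      base <- archetype
      dose <- 0
      if (!is.null(effect) && gname %in% effect$groups_affected &&
          effect$effect_size > 0 && length(effect$target_regions) > 0L) {
        dose <- effect$effect_size
        tr <- match(effect$target_regions, atlas$region_id)
        if (effect$effect_mode == "strength-shift") {
          wgt <- min(effect$effect_size, 1)
          base[tr, ] <- (1 - wgt) * base[tr, , drop = FALSE] +
            wgt * matrix(mean_profile, length(tr), n_features, byrow = TRUE)
        } else {
          sds <- apply(base[tr, , drop = FALSE], 1L, stats::sd)
          base[tr, ] <- base[tr, , drop = FALSE] +
            effect$effect_size * sds * decor_dirs
        }
      }
      for (i in seq_len(group_sizes[[gname]])) {
        k <- k + 1L
        sid <- sprintf("S%04d", k)
        fm <- base + matrix(stats::rnorm(n * n_features, sd = noise_sd),
                            n, n_features)
        dimnames(fm) <- list(region_ids, feat_names)
        features[[sid]] <- fm
        records[[k]] <- data.frame(
          subject_id = sid, group = gname,
          site_id = paste0("site", ((k - 1L) %% n_sites) + 1L),
          dose = dose, stringsAsFactors = FALSE
        )
      }
    }
  })
  list(records = do.call(rbind, records), features = features)
}

#' Attach synthetic clinical scores to a subject manifest
#'
#' Each score follows `baseline + slope * dose + Gaussian(sd)` where the
#' dose is the planted effect size for subjects in the affected groups and
#' zero otherwise (controls always have dose 0).
#'
#' @param records manifest data.frame with `group` column.
#' @param effect an [effect_spec()] defining dose, or `NULL` (all doses 0).
#' @param score_model named list, each entry `c(baseline, slope, sd)`.
#' @param seed integer seed.
#' @param missing_rate fraction of scores set missing at random.
#' @return `records` with one numeric column per score and a `dose` column.
#' @export
generate_clinical_scores <- function(records, effect = NULL, score_model,
                                     seed = 1L, missing_rate = 0) {
  if (length(score_model) == 0L || is.null(names(score_model))) {
    stop("`score_model` must be a nonempty named list", call. = FALSE)
  }
  dose <- rep(0, nrow(records))
  if (!is.null(effect)) {
    stopifnot(inherits(effect, "effect_spec"))
    dose[records$group %in% effect$groups_affected] <- effect$effect_size
  }
  records$dose <- dose
  with_seed(seed, {
    for (nm in names(score_model)) {
      par <- score_model[[nm]]
      stopifnot(length(par) == 3L)
      val <- par[[1]] + par[[2]] * dose +
        stats::rnorm(nrow(records), sd = par[[3]])
      if (missing_rate > 0) {
        val[stats::runif(nrow(records)) < missing_rate] <- NA_real_
      }
      records[[nm]] <- val
    }
  })
  records
}

#' Generate spatial maps with a controlled correlation to a target map
#'
#' Each map is a mixture `rho * z(target) + sqrt(1 - rho^2) * z(noise)` so
#' its expected Pearson correlation with the target is `target_corr`; maps
#' are mutually independent given the target.  With `target_corr = 1` the
#' map is an exact affine image of the target.
#'
#' @param atlas a [generate_atlas()] atlas (fixes the region set).
#' @param target_map numeric vector, one value per atlas region.
#' @param n_maps number of maps.
#' @param target_corr desired correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @param map_names optional character names (default `map_001`, ...).
#' @return numeric matrix regions x maps with region-id rownames.
#' @export
generate_spatial_maps <- function(atlas, target_map, n_maps,
                                  target_corr = 0, seed = 1L,
                                  map_names = NULL) {
  stopifnot(inherits(atlas, "pmv_atlas"))
  n <- nrow(atlas)
  if (length(target_map) != n) {
    stop("`target_map` length (", length(target_map),
         ") does not match atlas size (", n, ")", call. = FALSE)
  }
  if (!is.numeric(target_corr) || abs(target_corr) > 1) {
    stop("`target_corr` must be in [-1, 1]", call. = FALSE)
  }
  n_maps <- assert_scalar_count(n_maps, "n_maps", min = 1L)
  zt <- as.numeric(scale(target_map))
  out <- with_seed(seed, {
    m <- matrix(NA_real_, n, n_maps)
    for (j in seq_len(n_maps)) {
      eps <- as.numeric(scale(stats::rnorm(n)))
      m[, j] <- target_corr * zt + sqrt(1 - target_corr^2) * eps
    }
    m
  })
  if (is.null(map_names)) map_names <- sprintf("map_%03d", seq_len(n_maps))
  stopifnot(length(map_names) == n_maps)
  dimnames(out) <- list(as.character(atlas$region_id), map_names)
  out
}

#' Simulate rank-1 motif-count cohorts with a planted loading direction
#'
#' Builds per-subject 20 x regions count matrices whose standardized rows
#' are (up to the noise) a sign pattern times a common regional pattern, so
#' the first principal component of the pooled motif covariance equals the
#' planted direction.  Used to validate [fit_pmv_model()] recovery and the
#' sign-anchor convention.
#'
#' @param n_subjects,n_regions cohort dimensions.
#' @param noise_sd additive Gaussian noise SD on the counts.
#' @param seed integer seed.
#' @return list with `counts` (list of 20 x regions matrices) and
#'   `direction` (unit 20-vector, the planted loading).
#' @export
simulate_rank1_counts <- function(n_subjects, n_regions, noise_sd = 0.05,
                                  seed = 1L) {
  n_subjects <- assert_scalar_count(n_subjects, "n_subjects")
  n_regions <- assert_scalar_count(n_regions, "n_regions", min = 3L)
  with_seed(seed, {
    s <- sample(c(-1, 1), 20L, replace = TRUE)
    s[20L] <- 1  # keep the planted direction on the anchor's positive side
    p <- stats::rnorm(n_regions)
    counts <- lapply(seq_len(n_subjects), function(i) {
      m <- 50 + outer(s, p) +
        matrix(stats::rnorm(20L * n_regions, sd = noise_sd), 20L, n_regions)
      rownames(m) <- sprintf("type%02d", 1:20)
      colnames(m) <- as.character(seq_len(n_regions))
      m
    })
    list(counts = counts, direction = s / sqrt(20))
  })
}
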