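# Delimited-text readers and writers.  Everything is tab-separated,
# diffable, and round-trips through its reader at full double precision.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read an atlas table
#'
#' Columns: `region_id`, `x`, `y`, `z`, `anatomical_label`,
#' `functional_label`, tab-separated with a header row.
#'
#' @param atlas a [generate_atlas()] atlas.
#' @param path file path.
#' @return `write_atlas` the path (invisibly); `read_atlas` the atlas.
#' @export
write_atlas <- function(atlas, path) {
  write_tsv(as.data.frame(atlas), path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "x", "y", "z", "anatomical_label",
            "functional_label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("atlas file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$region_id)) {
    stop("duplicate region_id in ", path, call. = FALSE)
  }
  class(df) <- c("pmv_atlas", "data.frame")
  df
}

#' Write / read a square region-by-region matrix
#'
#' The first column holds region ids; the header row repeats them.
#'
#' @param m square numeric matrix with region-id dimnames.
#' @param path file path.
#' @return `write_square_matrix` the path; `read_square_matrix` the matrix.
#' @export
write_square_matrix <- function(m, path) {
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  df <- data.frame(region_id = ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("region_id", ids)
  write_tsv(df, path)
}

#' @rdname write_square_matrix
#' @export
read_square_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(ids, ids)
  m
}

#' Write / read a per-subject feature table
#'
#' First column `region_id`, one column per feature, header row of feature
#' names.
#'
#' @param fm regions x features matrix with region-id rownames.
#' @param path file path.
#' @return `write_feature_table` the path; `read_feature_table` the matrix.
#' @export
write_feature_table <- function(fm, path) {
  df <- data.frame(region_id = rownames(fm) %||%
                     as.character(seq_len(nrow(fm))),
                   fm, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "region_id") {
    stop("feature table ", path, " must start with a region_id column",
         call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df$region_id)
  m
}

#' Write / read a subject manifest
#'
#' Columns `subject_id`, `group`, `site_id` plus any clinical score
#' columns; missing scores are written as `NA`.
#'
#' @param records manifest data.frame.
#' @param path file path.
#' @return `write_manifest` the path; `read_manifest` the data.frame.
#' @export
write_manifest <- function(records, path) {
  write_tsv(records, path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("manifest ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id in ", path, call. = FALSE)
  }
  df
}

#' Write / read a motif count matrix
#'
#' Rows are the 20 canonical types (first columns: type index and label),
#' remaining columns one per region.
#'
#' @param mcm 20 x N count matrix from [count_motifs()].
#' @param path file path.
#' @return `write_motif_counts` the path; `read_motif_counts` the matrix.
#' @export
write_motif_counts <- function(mcm, path) {
  df <- data.frame(type = seq_len(nrow(mcm)),
                   label = rownames(mcm) %||%
                     sprintf("type%02d", seq_len(nrow(mcm))),
                   mcm, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_motif_counts
#' @export
read_motif_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$label
  m
}

#' Read a region x map table (genes, receptors, ...)
#'
#' First column `region_id`, one numeric column per named map.
#'
#' @param path file path.
#' @return numeric matrix with region-id rownames.
#' @export
read_spatial_maps <- function(path) {
  read_feature_table(path)
}

#' @rdname read_spatial_maps
#' @param maps regions x maps matrix.
#' @export
write_spatial_maps <- function(maps, path) {
  write_feature_table(maps, path)
}

#' Serialize / restore a PMV model
#'
#' Structured-text (YAML) record of loadings, eigenvalues, anchor and
#' orientation.
#'
#' @param model a [fit_pmv_model()] model.
#' @param path file path.
#' @return `write_pmv_model` the path; `read_pmv_model` the model.
#' @export
write_pmv_model <- function(model, path) {
  yaml::write_yaml(unclass(model), path, precision = 15L)
  invisible(path)
}

#' @rdname write_pmv_model
#' @export
read_pmv_model <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$loading <- as.numeric(obj$loading)
  obj$eigenvalues <- as.numeric(obj$eigenvalues)
  obj$contributions <- as.numeric(obj$contributions)
  class(obj) <- "pmv_model"
  obj
}

#' Serialize / restore a threshold pair
#' @param thr a [compute_thresholds()] pair.
#' @param path file path.
#' @return `write_threshold_pair` the path; `read_threshold_pair` the pair.
#' @export
write_threshold_pair <- function(thr, path) {
  yaml::write_yaml(unclass(thr), path, precision = 15L)
  invisible(path)
}

#' @rdname write_threshold_pair
#' @export
read_threshold_pair <- function(path) {
  obj <- yaml::read_yaml(path)
  class(obj) <- "threshold_pair"
  obj
}

#' Load and validate a cohort from disk
#'
#' Reads the atlas, manifest and one feature table per subject
#' (`<features_dir>/<subject_id>.tsv`), harmonizes region order to atlas
#' order (tables with permuted rows are silently reordered, with a
#' message), and rejects malformed inputs with named errors.
#'
#' @param config list with entries `atlas`, `manifest`, `features_dir`
#'   (paths), as produced by [pipeline_config()].
#' @return list of class `"cohort_bundle"`: `atlas`, `records`, `features`.
#' @export
load_cohort <- function(config) {
  atlas <- if (inherits(config$atlas, "pmv_atlas")) config$atlas else
    read_atlas(config$atlas)
  records <- if (is.data.frame(config$manifest)) config$manifest else
    read_manifest(config$manifest)
  if (anyDuplicated(records$subject_id)) {
    stop("duplicate subject_id in manifest", call. = FALSE)
  }
  want <- as.character(atlas$region_id)
  features <- list()
  for (sid in records$subject_id) {
    path <- file.path(config$features_dir, paste0(sid, ".tsv"))
    if (!file.exists(path)) {
      stop("missing feature table for subject ", sid, ": ", path,
           call. = FALSE)
    }
    fm <- read_feature_table(path)
    have <- rownames(fm)
    extra <- setdiff(have, want)
    missing <- setdiff(want, have)
    if (length(extra) > 0L || length(missing) > 0L) {
      stop("feature table ", path, " region set mismatch",
           if (length(extra) > 0L) paste0("; not in atlas: ",
                                          paste(extra, collapse = ", ")),
           if (length(missing) > 0L) paste0("; absent regions: ",
                                            paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    if (!identical(have, want)) {
      message("reordering regions of ", path, " to atlas order")
      fm <- fm[want, , drop = FALSE]
    }
    features[[sid]] <- fm
  }
  structure(list(atlas = atlas, records = records, features = features),
            class = "cohort_bundle")
}

#' Write a full synthetic cohort to disk
#'
#' Companion to [generate_cohort()]: writes the atlas table, the manifest
#' and one feature table per subject in the layout [load_cohort()] expects.
#'
#' @param atlas a [generate_atlas()] atlas.
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(atlas, cohort, dir) {
  dir.create(file.path(dir, "features"), recursive = TRUE,
             showWarnings = FALSE)
  write_atlas(atlas, file.path(dir, "atlas.tsv"))
  write_manifest(cohort$records, file.path(dir, "manifest.tsv"))
  for (sid in names(cohort$features)) {
    write_feature_table(cohort$features[[sid]],
                        file.path(dir, "features", paste0(sid, ".tsv")))
  }
  invisible(dir)
}
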