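# FeatureTable: the container every pipeline stage transforms.
#
# intensities  samples x features numeric matrix (NA = missing)
# sample_meta  data.frame: sample_id, role (study/qc/blank), injection_order,
#              group (required for study rows), pair_id, plus free columns
#              (e.g. subgroup indicator columns)
# feature_meta data.frame: feature_id, assay (metabolomics/lipidomics),
#              annotation, block_id, lipid_class

SAMPLE_ROLES <- c("study", "qc", "blank")
ASSAYS <- c("metabolomics", "lipidomics")

#' Construct a feature table
#'
#' Bundles a samples-by-features intensity matrix with per-sample and
#' per-feature metadata and validates the result. This is the object every
#' stage of the pipeline consumes and returns.
#'
#' @param intensities numeric matrix, rows = samples, columns = features;
#'   `NA` marks a missing measurement, zeros are measured values.
#' @param sample_meta data.frame with columns `sample_id`, `role`
#'   (`"study"`, `"qc"` or `"blank"`), `injection_order` (unique positive
#'   integers) and, for study rows, a non-missing `group`. Optional columns
#'   (`pair_id`, subgroup indicators, ...) are carried along untouched.
#' @param feature_meta data.frame with columns `feature_id` and `assay`
#'   (`"metabolomics"` or `"lipidomics"`); optional `annotation`,
#'   `block_id`, `lipid_class`.
#' @return an object of class `feature_table`
#' @export
feature_table <- function(intensities, sample_meta, feature_meta) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)
  rownames(intensities) <- as.character(sample_meta$sample_id)
  colnames(intensities) <- as.character(feature_meta$feature_id)
  rownames(sample_meta) <- NULL
  rownames(feature_meta) <- NULL
  ft <- structure(
    list(intensities = intensities,
         sample_meta = sample_meta,
         feature_meta = feature_meta),
    class = "feature_table")
  validate_feature_table(ft)
  ft
}

#' Validate a feature table
#'
#' Checks the structural invariants: unique sample and feature ids, unique
#' injection orders, known roles and assays, a group label on every study
#' sample, and finite non-negative intensities where present.
#'
#' @param ft a `feature_table`
#' @return `ft`, invisibly; errors describe the first violated invariant
#' @export
validate_feature_table <- function(ft) {
  sm <- ft$sample_meta
  fm <- ft$feature_meta
  x <- ft$intensities
  for (col in c("sample_id", "role", "injection_order")) {
    if (is.null(sm[[col]])) stopf("sample_meta lacks required column '%s'", col)
  }
  for (col in c("feature_id", "assay")) {
    if (is.null(fm[[col]])) stopf("feature_meta lacks required column '%s'", col)
  }
  if (nrow(sm) != nrow(x)) stopf("sample_meta rows (%d) != intensity rows (%d)", nrow(sm), nrow(x))
  if (nrow(fm) != ncol(x)) stopf("feature_meta rows (%d) != intensity columns (%d)", nrow(fm), ncol(x))
  if (anyDuplicated(sm$sample_id)) stopf("duplicated sample_id: %s",
    paste(unique(sm$sample_id[duplicated(sm$sample_id)]), collapse = ", "))
  if (anyDuplicated(fm$feature_id)) stopf("duplicated feature_id: %s",
    paste(unique(fm$feature_id[duplicated(fm$feature_id)]), collapse = ", "))
  bad_role <- setdiff(unique(sm$role), SAMPLE_ROLES)
  if (length(bad_role)) stopf("unknown sample role(s): %s", paste(bad_role, collapse = ", "))
  bad_assay <- setdiff(unique(fm$assay), ASSAYS)
  if (length(bad_assay)) stopf("unknown assay(s): %s", paste(bad_assay, collapse = ", "))
  ord <- sm$injection_order
  if (any(is.na(ord)) || any(ord != round(ord)) || any(ord < 1))
    stopf("injection_order must be positive integers")
  if (anyDuplicated(ord)) stopf("injection_order values must be unique")
  study <- sm$role == "study"
  if (any(study)) {
    grp <- sm$group
    if (is.null(grp) || any(is.na(grp[study]) | grp[study] == ""))
      stopf("every study sample needs a non-missing group label")
  }
  vals <- x[!is.na(x)]
  if (length(vals) && (any(!is.finite(vals)) || any(vals < 0)))
    stopf("intensities must be finite and >= 0 where present")
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  sm <- x$sample_meta
  cat(sprintf("feature_table: %d samples x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(table(sm$role)), table(sm$role)),
                    collapse = ", ")))
  cat(sprintf("  assays: %s\n",
              paste(sprintf("%s=%d", names(table(x$feature_meta$assay)),
                            table(x$feature_meta$assay)), collapse = ", ")))
  cat(sprintf("  missing: %d cells\n", sum(is.na(x$intensities))))
  invisible(x)
}

#' Subset a feature table
#'
#' @param ft a `feature_table`
#' @param samples logical/integer/character index into samples (default all)
#' @param features logical/integer/character index into features (default all)
#' @return the subsetted `feature_table`
#' @export
subset_table <- function(ft, samples = NULL, features = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(ft$intensities)) else samples
  if (is.character(si)) si <- match(si, ft$sample_meta$sample_id)
  fi <- if (is.null(features)) seq_len(ncol(ft$intensities)) else features
  if (is.character(fi)) fi <- match(fi, ft$feature_meta$feature_id)
  feature_table(ft$intensities[si, fi, drop = FALSE],
                ft$sample_meta[si, , drop = FALSE],
                ft$feature_meta[fi, , drop = FALSE])
}

# Row index helpers
study_idx <- function(ft) which(ft$sample_meta$role == "study")
qc_idx <- function(ft) which(ft$sample_meta$role == "qc")
blank_idx <- function(ft) which(ft$sample_meta$role == "blank")

#' Study-group factor of a feature table
#'
#' @param ft a `feature_table`
#' @return factor of group labels over the study rows (2 levels expected)
#' @export
study_groups <- function(ft) {
  factor(ft$sample_meta$group[study_idx(ft)])
}

#' Read a feature table from disk
#'
#' Expects the three-CSV layout written by [write_feature_table()]: an
#' intensity matrix whose header row holds feature ids and whose first
#' column holds sample ids, plus a sample-metadata and a feature-metadata
#' CSV keyed by those ids. The token `NA` (or an empty cell) marks a
#' missing intensity; any other non-numeric cell is a format error.
#'
#' @param intensity_path path to the intensity CSV
#' @param sample_meta_path path to the sample metadata CSV
#' @param feature_meta_path path to the feature metadata CSV
#' @return a validated `feature_table`; row/column order follows the files
#' @export
read_feature_table <- function(intensity_path, sample_meta_path, feature_meta_path) {
  for (p in c(intensity_path, sample_meta_path, feature_meta_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  raw <- utils::read.csv(intensity_path, check.names = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 1L) stopf("intensity file has no columns: %s", intensity_path)
  ids <- raw[[1L]]
  mat_chr <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(mat <- apply(mat_chr, 2L, function(col) {
    col[col == "" | col == "NA"] <- NA_character_
    as.numeric(col)
  }))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = nrow(raw),
                                     dimnames = list(NULL, colnames(mat_chr)))
  bad <- !is.na(mat_chr) & mat_chr != "" & mat_chr != "NA" & is.na(mat)
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1L, ]
    stopf("non-numeric intensity '%s' at sample '%s', feature '%s'",
          mat_chr[j[1L], j[2L]], ids[j[1L]], colnames(mat_chr)[j[2L]])
  }
  rownames(mat) <- ids
  sm <- utils::read.csv(sample_meta_path, stringsAsFactors = FALSE)
  fm <- utils::read.csv(feature_meta_path, stringsAsFactors = FALSE)
  if (!identical(as.character(sm$sample_id), as.character(ids)))
    stopf("sample ids in %s do not match intensity rows", sample_meta_path)
  if (!identical(as.character(fm$feature_id), as.character(colnames(mat))))
    stopf("feature ids in %s do not match intensity columns", feature_meta_path)
  feature_table(mat, sm, fm)
}

#' Write a feature table to disk
#'
#' Emits `intensities.csv`, `sample_meta.csv` and `feature_meta.csv` in the
#' dialect [read_feature_table()] accepts. Intensities are written with full
#' double precision so a round trip is lossless to ~1e-15 relative.
#'
#' @param ft a `feature_table`
#' @param out_dir output directory, created if absent
#' @return named character vector of the three file paths, invisibly
#' @export
write_feature_table <- function(ft, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L) stopf("directory not writable: %s", out_dir)
  ip <- file.path(out_dir, "intensities.csv")
  sp <- file.path(out_dir, "sample_meta.csv")
  fp <- file.path(out_dir, "feature_meta.csv")
  df <- data.frame(sample_id = ft$sample_meta$sample_id,
                   stringsAsFactors = FALSE, check.names = FALSE)
  x <- ft$intensities
  if (ncol(x)) {
    chr <- matrix(formatC(x, format = "g", digits = 17), nrow = nrow(x))
    chr[is.na(x)] <- "NA"
    colnames(chr) <- colnames(x)
    df <- cbind(df, as.data.frame(chr, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  }
  utils::write.csv(df, ip, row.names = FALSE, quote = TRUE)
  utils::write.csv(ft$sample_meta, sp, row.names = FALSE, quote = TRUE)
  utils::write.csv(ft$feature_meta, fp, row.names = FALSE, quote = TRUE)
  invisible(c(intensities = ip, sample_meta = sp, feature_meta = fp))
}
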