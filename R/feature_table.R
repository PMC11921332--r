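#' Construct a feature table
#'
#' A \code{feature_table} is the universal carrier between analysis stages:
#' an integer matrix of ASV counts with features as rows and samples as
#' columns. Row names are feature (ASV) identifiers, column names sample
#' identifiers; both must be unique and all counts non-negative integers.
#'
#' @param counts integer matrix, features x samples, with dimnames.
#' @return an object of class \code{feature_table} (a validated matrix).
#' @export
feature_table <- function(counts) {
  counts <- as.matrix(counts)
  validate_feature_table(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("feature_table", "matrix", "array")
  counts
}

validate_feature_table <- function(counts) {
  if ((is.null(rownames(counts)) && nrow(counts) > 0L) ||
      (is.null(colnames(counts)) && ncol(counts) > 0L))
    stop("feature table must have feature ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature id: ", rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ", colnames(counts)[duplicated(colnames(counts))][1])
  if (anyNA(counts)) {
    idx <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("missing count at feature '%s', sample '%s'",
                 rownames(counts)[idx[1]], colnames(counts)[idx[2]]))
  }
  bad <- counts < 0 | counts != round(counts)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("count at feature '%s', sample '%s' is not a non-negative integer (value %s)",
                 rownames(counts)[idx[1]], colnames(counts)[idx[2]],
                 counts[idx[1], idx[2]]))
  }
  invisible(counts)
}

#' @export
`[.feature_table` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)
  r <- if (missing(i) && missing(j)) m
       else if (missing(i)) m[, j, drop = drop]
       else if (missing(j)) m[i, , drop = drop]
       else m[i, j, drop = drop]
  if (is.matrix(r)) class(r) <- c("feature_table", "matrix", "array")
  r
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (total count %s)\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read a feature table from TSV
#'
#' Expects a tab-delimited UTF-8 file with header \code{feature_id} followed
#' by sample ids, one feature per row, integer cells. Round-trips bit-exactly
#' with \code{\link{write_feature_table}}.
#'
#' @param path path to a TSV file.
#' @return a \code{\link{feature_table}}.
#' @export
read_feature_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "feature_id")
    stop("malformed header in ", path, ": first cell must be 'feature_id'")
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(df[, -1, drop = FALSE])),
                               nrow = nrow(df)))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 df[[1]][idx[1]], header[-1][idx[2]], path))
  }
  dimnames(m) <- list(df[[1]], header[-1])
  feature_table(m)
}

#' Write a feature table to TSV
#'
#' @param t a \code{\link{feature_table}}.
#' @param path output path.
#' @export
write_feature_table <- function(t, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(t)), collapse = "\t"), con)
  body <- apply(t, 1L, paste, collapse = "\t")
  writeLines(paste(rownames(t), body, sep = "\t"), con)
  invisible(path)
}

#' Drop features with low total counts
#'
#' Retains features whose summed count across all samples in the table is at
#' least \code{min_total}; default 3, the inclusion floor balancing false
#' positives against falsely calling taxa absent. The sum is taken over the
#' whole table, so filtering should be applied to the full set of samples in
#' an analysis run (inocula plus all recipient samples) before tables are
#' split by group or timepoint. Idempotent; sample set and feature order are
#' preserved.
#'
#' @param t a \code{\link{feature_table}}.
#' @param min_total positive integer, minimum feature row sum.
#' @return a filtered \code{\link{feature_table}}.
#' @export
filter_low_count_features <- function(t, min_total = 3L) {
  stopifnot(inherits(t, "feature_table"))
  if (length(min_total) != 1L || is.na(min_total) || min_total < 1)
    stop("min_total must be a positive integer")
  keep <- rowSums(t) >= min_total
  feature_table(unclass(t)[keep, , drop = FALSE])
}

#' Per-sample relative abundances
#'
#' @param t a \code{\link{feature_table}} whose sample sums are all positive.
#' @return a numeric matrix of the same shape; every column sums to 1.
#' @export
relative_abundance <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  tot <- colSums(t)
  if (any(tot == 0))
    stop("sample '", colnames(t)[which(tot == 0)[1]], "' has zero total count")
  sweep(unclass(t) * 1.0, 2L, tot, "/")
}

#' Read sample metadata from TSV
#'
#' Mandatory columns: sample_id, subject_id, group, timepoint, sample_type,
#' pen, litter, sex. Group, timepoint and sample_type are restricted to the
#' study's enumerations.
#'
#' @param path path to a TSV file.
#' @return a data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  validate_sample_metadata(md)
}

#' Validate sample metadata
#'
#' @param md a data.frame of per-sample metadata.
#' @param table optional \code{\link{feature_table}}; if given, every sample
#'   in the table must have exactly one metadata row.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_sample_metadata <- function(md, table = NULL) {
  required <- c("sample_id", "subject_id", "group", "timepoint",
                "sample_type", "pen", "litter", "sex")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols))
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1])
  check_enum <- function(values, allowed, what) {
    bad <- setdiff(unique(values), allowed)
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                   paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  }
  check_enum(md$group, study_groups(), "group")
  check_enum(md$timepoint, study_timepoints(), "timepoint")
  check_enum(md$sample_type, c("fecal", "cecal", "inoculum"), "sample_type")
  if (!is.null(table)) {
    absent <- setdiff(colnames(table), md$sample_id)
    if (length(absent))
      stop("samples without metadata: ", paste(absent, collapse = ", "))
  }
  md
}

#' @rdname study_groups
#' @export
study_timepoints <- function() c("PND21", "PND27", "PND48")

#' Study enumerations
#'
#' The four treatment groups (Control, cultured sow community, cultured wild
#' boar community, 1:1 mixture) and the three sampling timepoints (weaning
#' baseline, day 6 and day 28 post-transplantation).
#'
#' @return character vector of allowed labels.
#' @export
study_groups <- function() c("Control", "Sow", "WB", "Mix")

#' Read a metabolite concentration table with per-metabolite LOD
#'
#' Concentrations are a metabolites x samples TSV (first header cell
#' \code{metabolite_id}); missing values are "NA" or empty cells. The
#' companion LOD file has columns metabolite_id and lod, one row per
#' metabolite, lod strictly positive in the same units as concentrations.
#'
#' @param path concentrations TSV.
#' @param lod_path limit-of-detection TSV.
#' @return a list of class \code{metabolite_table} with elements
#'   \code{concentrations} (matrix, NA where missing) and \code{lod}
#'   (named numeric).
#' @export
read_metabolite_table <- function(path, lod_path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), comment.char = "")
  if (names(df)[1] != "metabolite_id")
    stop("malformed header in ", path, ": first cell must be 'metabolite_id'")
  conc <- as.matrix(df[, -1, drop = FALSE])
  rownames(conc) <- df[[1]]
  lod_df <- utils::read.table(lod_path, header = TRUE, sep = "\t", quote = "",
                              stringsAsFactors = FALSE)
  lod <- stats::setNames(lod_df$lod, lod_df$metabolite_id)
  metabolite_table(conc, lod)
}

#' @rdname read_metabolite_table
#' @param concentrations metabolites x samples numeric matrix (NA = missing).
#' @param lod named positive numeric vector of detection limits.
#' @export
metabolite_table <- function(concentrations, lod) {
  if (any(concentrations < 0, na.rm = TRUE))
    stop("negative metabolite concentration")
  lod <- lod[rownames(concentrations)]
  if (anyNA(lod) || any(lod <= 0))
    stop("every metabolite needs a positive lod")
  structure(list(concentrations = concentrations, lod = lod),
            class = "metabolite_table")
}

#' Write a metabolite table (concentrations + LOD companion)
#'
#' @param m a \code{metabolite_table}.
#' @param path concentrations TSV path.
#' @param lod_path LOD TSV path.
#' @export
write_metabolite_table <- function(m, path, lod_path) {
  conc <- m$concentrations
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(paste(c("metabolite_id", colnames(conc)), collapse = "\t"), con)
  body <- apply(conc, 1L, function(r)
    paste(ifelse(is.na(r), "NA", format(r, digits = 10, scientific = FALSE,
                                        trim = TRUE)), collapse = "\t"))
  writeLines(paste(rownames(conc), body, sep = "\t"), con)
  close(con)
  utils::write.table(
    data.frame(metabolite_id = names(m$lod), lod = m$lod),
    lod_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
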