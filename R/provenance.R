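#' Classify inoculum ASVs as donor-unique or common
#'
#' An inoculum ASV is \emph{common} if it was observed (count >= 1) in at
#' least one recipient sample before inoculation, and \emph{unique} if it
#' was absent from every pre-inoculation sample — "not present in all
#' piglets" in the partition sense: unique + common together exhaust each
#' donor's (post-filter) inoculum feature set. The shared-unique set is
#' the intersection of the donors' unique sets. Both tables should already
#' carry the global low-count filter (see
#' \code{\link{filter_low_count_features}}).
#'
#' @param inocula \code{\link{feature_table}} whose samples are donor
#'   inocula (one column per donor; column names identify the donors,
#'   a leading "inoculum_" prefix is stripped).
#' @param baseline \code{\link{feature_table}} of pre-inoculation recipient
#'   samples only.
#' @return object of class \code{provenance_classification}: per donor the
#'   \code{unique} and \code{common} ASV sets, the \code{shared_unique}
#'   set, and a \code{counts} summary data.frame.
#' @export
classify_inoculum_asvs <- function(inocula, baseline) {
  stopifnot(inherits(inocula, "feature_table"),
            inherits(baseline, "feature_table"))
  if (ncol(baseline) == 0L)
    stop("baseline table has no samples; classification is undefined")
  donors <- sub("^inoculum_", "", colnames(inocula))
  present_baseline <- rownames(baseline)[rowSums(baseline >= 1L) > 0L]
  uniq <- list(); comm <- list()
  for (k in seq_along(donors)) {
    members <- rownames(inocula)[unclass(inocula)[, k] >= 1L]
    comm[[donors[k]]] <- intersect(members, present_baseline)
    uniq[[donors[k]]] <- setdiff(members, present_baseline)
  }
  shared <- if (length(donors) >= 2L) Reduce(intersect, uniq) else character(0)
  counts <- data.frame(
    donor = donors,
    n_total = vapply(donors, function(d) length(uniq[[d]]) + length(comm[[d]]),
                     integer(1)),
    n_unique = vapply(donors, function(d) length(uniq[[d]]), integer(1)),
    n_common = vapply(donors, function(d) length(comm[[d]]), integer(1)),
    row.names = NULL)
  structure(list(unique = uniq, common = comm, shared_unique = shared,
                 counts = counts, n_shared_unique = length(shared)),
            class = "provenance_classification")
}

#' @export
print.provenance_classification <- function(x, ...) {
  cat("provenance_classification\n")
  print(x$counts)
  cat("shared unique ASVs across donors:", x$n_shared_unique, "\n")
  invisible(x)
}

# resolve a provenance stratum to its ASV set
stratum_set <- function(cls, source, stratum = c("all_unique", "specific", "shared")) {
  stratum <- match.arg(stratum)
  uniq <- cls$unique[[source]]
  if (is.null(uniq)) stop("unknown source: ", source)
  switch(stratum,
         all_unique = uniq,
         specific = setdiff(uniq, cls$shared_unique),
         shared = cls$shared_unique)
}

# subset helper: sample ids of a group at a timepoint
group_samples <- function(table, metadata, group, timepoint,
                          sample_type = NULL) {
  if (!group %in% metadata$group) stop("unknown group: ", group)
  if (!timepoint %in% metadata$timepoint) stop("unknown timepoint: ", timepoint)
  keep <- metadata$group == group & metadata$timepoint == timepoint &
    metadata$sample_id %in% colnames(table)
  if (!is.null(sample_type)) keep <- keep & metadata$sample_type == sample_type
  ids <- metadata$sample_id[keep]
  if (!length(ids))
    stop(sprintf("no samples for group %s at %s in the table", group, timepoint))
  ids
}

#' Detect engrafted donor-unique ASVs in a recipient group
#'
#' An ASV from the requested source stratum counts as engrafted at a
#' timepoint if it is observed (count >= \code{floor}) in at least one
#' sample of the group at that timepoint. Strata are reported separately:
#' \code{"specific"} (source-unique minus the cross-donor shared set),
#' \code{"shared"} (the shared-unique set), or \code{"all_unique"} (their
#' union).
#'
#' @param post \code{\link{feature_table}} of post-transplantation samples.
#' @param cls a \code{provenance_classification}.
#' @param metadata sample metadata (see \code{\link{read_sample_metadata}}).
#' @param group,timepoint recipient group and timepoint labels.
#' @param source donor label.
#' @param stratum which provenance stratum to scan.
#' @param sample_type optional restriction (e.g. "fecal").
#' @param floor per-sample detection floor (counts), default 1.
#' @return character vector of detected ASV ids.
#' @export
detect_engrafted_asvs <- function(post, cls, metadata, group, source,
                                  timepoint, stratum = "all_unique",
                                  sample_type = NULL, floor = 1L) {
  ids <- group_samples(post, metadata, group, timepoint, sample_type)
  pool <- intersect(stratum_set(cls, source, stratum), rownames(post))
  sub <- unclass(post)[pool, ids, drop = FALSE]
  pool[rowSums(sub >= floor) > 0L]
}

#' Summarize the community share carried by engrafted ASVs
#'
#' Per sample of the group at the timepoint, the engrafted relative
#' abundance is 100 x (counts over the detected set) / (total counts in
#' the sample); the summary reports min, max and mean across samples.
#'
#' @param post \code{\link{feature_table}} of post-transplantation samples.
#' @param detected ASV set from \code{\link{detect_engrafted_asvs}}.
#' @param metadata sample metadata.
#' @param group,timepoint recipient group and timepoint labels.
#' @param sample_type optional restriction.
#' @return object of class \code{engraftment_summary}: \code{n_detected},
#'   per-sample \code{abundance_pct}, and \code{min}/\code{mean}/\code{max}.
#' @export
summarize_engraftment_abundance <- function(post, detected, metadata, group,
                                            timepoint, sample_type = NULL) {
  ids <- group_samples(post, metadata, group, timepoint, sample_type)
  m <- unclass(post)[, ids, drop = FALSE]
  tot <- colSums(m)
  if (any(tot == 0))
    stop("sample '", ids[which(tot == 0)[1]], "' has zero total count")
  eng <- colSums(m[intersect(detected, rownames(m)), , drop = FALSE])
  pct <- 100 * eng / tot
  structure(list(group = group, timepoint = timepoint,
                 n_detected = length(detected), abundance_pct = pct,
                 min = min(pct), mean = mean(pct), max = max(pct)),
            class = "engraftment_summary")
}

#' @export
print.engraftment_summary <- function(x, ...) {
  cat(sprintf(
    "engraftment_summary: %s @ %s — %d ASVs detected; %% of community min %.2f, mean %.2f, max %.2f\n",
    x$group, x$timepoint, x$n_detected, x$min, x$mean, x$max))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration with the minimum-likelihood two-sided
#' rule: the p-value sums the probabilities of every table with the same
#' margins whose point probability does not exceed that of the observed
#' table. The odds ratio is the sample odds ratio (a d)/(b c), infinite
#' when b c = 0 and a d > 0.
#'
#' @param t 2x2 matrix of non-negative integer counts, at least one
#'   positive.
#' @return list with \code{odds_ratio}, \code{p}, and the \code{table}.
#' @export
fisher_exact_two_sided <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == 2L)) stop("need a 2x2 table")
  if (any(t < 0) || any(t != round(t))) stop("cells must be non-negative integers")
  if (sum(t) == 0) stop("all-zero table")
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  r1 <- a + b; c1 <- a + c; n <- sum(t)
  supp <- max(0L, c1 - (n - r1)):min(r1, c1)
  lp <- stats::dhyper(supp, r1, n - r1, c1, log = TRUE)
  lobs <- stats::dhyper(a, r1, n - r1, c1, log = TRUE)
  # relative tolerance guards ties against floating-point noise
  p <- sum(exp(lp[lp <= lobs + 1e-7]))
  p <- min(p, 1)
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  list(odds_ratio = or, p = p, table = t)
}

#' Contrast engraftment success between two strata with Fisher's test
#'
#' Builds the 2x2 table (engrafted vs not engrafted) x (cell A vs cell B)
#' from two engraftment cells — each a (source, stratum, group, timepoint)
#' specification — and applies \code{\link{fisher_exact_two_sided}}. The
#' constructed table is returned alongside the p-value for auditability.
#' The two cells must draw on non-overlapping ASV strata.
#'
#' @param post \code{\link{feature_table}} of post-transplantation samples.
#' @param cls a \code{provenance_classification}.
#' @param metadata sample metadata.
#' @param cell_a,cell_b lists with elements \code{source}, \code{stratum},
#'   \code{group}, \code{timepoint} (and optionally \code{sample_type}).
#' @return list with \code{table} (the 2x2), \code{odds_ratio}, \code{p},
#'   and the two per-cell detected sets.
#' @export
compare_engraftment_success <- function(post, cls, metadata, cell_a, cell_b) {
  eval_cell <- function(cell) {
    pool <- stratum_set(cls, cell$source, cell$stratum)
    det <- detect_engrafted_asvs(post, cls, metadata, group = cell$group,
                                 source = cell$source,
                                 timepoint = cell$timepoint,
                                 stratum = cell$stratum,
                                 sample_type = cell$sample_type)
    list(pool = pool, detected = det)
  }
  a <- eval_cell(cell_a); b <- eval_cell(cell_b)
  same_cell <- identical(cell_a, cell_b)
  if (!same_cell && length(intersect(a$pool, b$pool)))
    stop("contrast cells draw on overlapping ASV strata")
  tab <- matrix(c(length(a$detected), length(a$pool) - length(a$detected),
                  length(b$detected), length(b$pool) - length(b$detected)),
                2L, 2L, byrow = TRUE,
                dimnames = list(cell = c("A", "B"),
                                status = c("engrafted", "not_engrafted")))
  ft <- fisher_exact_two_sided(tab)
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p,
       detected_a = a$detected, detected_b = b$detected)
}
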