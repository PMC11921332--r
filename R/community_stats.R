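#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's counts without replacement (multivariate
#' hypergeometric) to a common depth. Samples whose total is below the
#' requested depth are dropped with a warning, matching the convention of
#' rarefying to the smallest retained sample.
#'
#' @param t a \code{\link{feature_table}}.
#' @param depth positive integer target depth; default the minimum sample
#'   sum.
#' @param seed integer seed; the draw is deterministic given it.
#' @return a rarefied \code{\link{feature_table}} whose columns all sum to
#'   \code{depth}.
#' @export
rarefy <- function(t, depth = min(colSums(t)), seed) {
  stopifnot(inherits(t, "feature_table"))
  if (length(depth) != 1L || is.na(depth) || depth <= 0)
    stop("depth must be a positive integer")
  depth <- as.integer(depth)
  set.seed(seed)
  tot <- colSums(t)
  shallow <- tot < depth
  if (any(shallow)) {
    warning("dropping ", sum(shallow), " sample(s) below depth ", depth, ": ",
            paste(colnames(t)[shallow], collapse = ", "))
    t <- t[, !shallow]
  }
  m <- unclass(t)
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    drawn <- sample.int(sum(m[, j]), depth)
    cum <- cumsum(m[, j])
    out[, j] <- tabulate(findInterval(drawn - 1L, cum) + 1L, nbins = nrow(m))
  }
  feature_table(out)
}

#' Alpha diversity indices
#'
#' Observed richness (features with positive count), Shannon entropy
#' (natural log by default) and the Gini-Simpson index 1 - sum(p^2),
#' computed per sample from proportions.
#'
#' @param t a \code{\link{feature_table}} with positive sample sums.
#' @param base logarithm base for Shannon; default \code{exp(1)}.
#' @return data.frame with columns sample_id, observed, shannon, simpson.
#' @export
alpha_diversity <- function(t, base = exp(1)) {
  p <- relative_abundance(t)
  shannon <- apply(p, 2L, function(x) {
    x <- x[x > 0]
    -sum(x * log(x, base = base))
  })
  data.frame(sample_id = colnames(t),
             observed = as.integer(colSums(unclass(t) > 0L)),
             shannon = shannon,
             simpson = 1 - colSums(p^2),
             row.names = NULL)
}

# midranks with the tie-correction term sum(t^3 - t)
tied_ranks <- function(x) {
  r <- rank(x, ties.method = "average")
  tab <- table(x)
  list(ranks = r, tie_term = sum(tab^3 - tab))
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction and a chi-square reference distribution
#' on k - 1 degrees of freedom. When every value is identical the test is
#' degenerate and returns H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels, same length; at least two non-empty groups.
#' @return list with \code{H}, \code{df}, \code{p}.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(tabulate(groups, nbins = nlevels(groups)) == 0L)) stop("empty group")
  n <- length(values)
  tr <- tied_ranks(values)
  rsum <- tapply(tr$ranks, groups, sum)
  ng <- tabulate(groups, nbins = nlevels(groups))
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / ng) - 3 * (n + 1)
  corr <- 1 - tr$tie_term / (n^3 - n)
  if (corr == 0) return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  h <- h / corr
  list(H = h, df = nlevels(groups) - 1L,
       p = stats::pchisq(h, nlevels(groups) - 1L, lower.tail = FALSE))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' For each pair of groups, z = (meanrank_i - meanrank_j) /
#' sqrt((N(N+1)/12 - tie_term/(12(N-1))) (1/n_i + 1/n_j)) with two-sided
#' normal p-values, optionally Benjamini-Hochberg adjusted.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param adjust \code{"none"} or \code{"bh"}.
#' @return data.frame with columns group_a, group_b, z, p (and q when
#'   adjusted).
#' @export
dunn_posthoc <- function(values, groups, adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  groups <- as.factor(groups)
  if (any(tabulate(groups, nbins = nlevels(groups)) == 0L)) stop("empty group")
  if (nlevels(groups) < 2L) stop("need at least two groups")
  n <- length(values)
  tr <- tied_ranks(values)
  mrank <- tapply(tr$ranks, groups, mean)
  ng <- tabulate(groups, nbins = nlevels(groups))
  names(ng) <- levels(groups)
  var_term <- n * (n + 1) / 12 - tr$tie_term / (12 * (n - 1))
  pairs <- utils::combn(levels(groups), 2L)
  z <- apply(pairs, 2L, function(pr) {
    se <- sqrt(var_term * (1 / ng[pr[1]] + 1 / ng[pr[2]]))
    if (se == 0) return(0)
    (mrank[pr[1]] - mrank[pr[2]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    z = z, p = p, row.names = NULL)
  if (adjust == "bh") out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Distance matrix container
#'
#' @param values symmetric numeric matrix with zero diagonal and matching
#'   dimnames.
#' @return object of class \code{distance_matrix}.
#' @export
distance_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("distance matrix needs sample ids")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12,
                        check.attributes = FALSE)))
    stop("distance matrix is not symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  class(values) <- c("distance_matrix", "matrix", "array")
  values
}

#' Bray-Curtis dissimilarity
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), equivalently
#' 1 - 2 sum min(x_i, y_i) / (sum x + sum y), computed on raw counts or on
#' relative abundances.
#'
#' @param t a \code{\link{feature_table}} with positive sample sums.
#' @param use \code{"counts"} (default) or \code{"relative"}.
#' @return a \code{\link{distance_matrix}} with values in [0, 1].
#' @export
bray_curtis <- function(t, use = c("counts", "relative")) {
  use <- match.arg(use)
  m <- if (use == "counts") {
    if (any(colSums(t) == 0))
      stop("sample '", colnames(t)[which(colSums(t) == 0)[1]],
           "' has zero total count")
    unclass(t) * 1.0
  } else relative_abundance(t)
  man <- as.matrix(stats::dist(t(m), method = "manhattan"))
  tot <- colSums(m)
  denom <- outer(tot, tot, "+")
  d <- man / denom
  diag(d) <- 0
  distance_matrix(d)
}

#' Principal-coordinate analysis
#'
#' Classical metric scaling: eigendecomposition of -1/2 J D^2 J with J the
#' centering operator. Axes with positive eigenvalues are kept, coordinates
#' scaled by sqrt(eigenvalue); the total magnitude of any dropped negative
#' eigenvalues is reported via \code{message} (no Cailliez/Lingoes
#' correction is applied).
#'
#' @param d a \code{\link{distance_matrix}}.
#' @return object of class \code{ordination_result}: \code{coordinates}
#'   (samples x axes), \code{eigenvalues} (positive, descending),
#'   \code{proportion_explained}, \code{negative_eigenvalue_magnitude}.
#' @export
pcoa <- function(d) {
  d <- distance_matrix(unclass(d))
  n <- nrow(d)
  a <- -0.5 * unclass(d)^2
  b <- a - rowMeans(a)[row(a)] - colMeans(a)[col(a)] + mean(a)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  neg_mag <- sum(abs(e$values[e$values < -tol]))
  if (neg_mag > 0)
    message(sprintf("pcoa: dropping negative eigenvalues (total magnitude %.4g)",
                    neg_mag))
  ev <- e$values[pos]
  coords <- matrix(0, n, length(ev),
                   dimnames = list(rownames(d),
                                   if (length(ev)) paste0("PCo", seq_along(ev))))
  if (length(ev))
    coords[] <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev), length(ev))
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = if (length(ev)) ev / sum(ev) else numeric(0),
                 negative_eigenvalue_magnitude = neg_mag),
            class = "ordination_result")
}

# pseudo-F and R^2 from squared distances for one grouping
permanova_stat <- function(d2, groups) {
  n <- nrow(d2)
  a <- nlevels(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(F = f, R2 = ss_between / ss_total)
}

#' PERMANOVA (adonis-style permutation test)
#'
#' Partitions the sum of squared dissimilarities between and within groups;
#' pseudo-F = (SS_b/(a-1)) / (SS_w/(n-a)), R^2 = SS_b/SS_total;
#' significance by permuting group labels, with the (x+1)/(N+1) p-value
#' estimator. \code{n_permutations = "exhaustive"} enumerates every
#' permutation of the labels (feasible for small n) and returns the exact
#' permutation p-value #\{F_perm >= F_obs\} / n! including the identity.
#'
#' @param d a \code{\link{distance_matrix}}.
#' @param groups group labels in sample order; at least two groups, and no
#'   singleton groups when only two groups are present.
#' @param n_permutations integer (default 999) or \code{"exhaustive"}.
#' @param seed integer seed for the Monte-Carlo draw.
#' @return object of class \code{permanova_result} with \code{pseudo_F},
#'   \code{r_squared}, \code{p}, \code{n_permutations}, \code{seed}.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = NULL) {
  groups <- droplevels(as.factor(as.character(groups)))
  n <- nrow(d)
  if (length(groups) != n) stop("groups length must match the distance matrix")
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (nlevels(groups) == 2L && any(tabulate(groups) < 2L))
    stop("a singleton group leaves zero within-group degrees of freedom")
  d2 <- unclass(d)^2
  obs <- permanova_stat(d2, groups)
  if (identical(n_permutations, "exhaustive")) {
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1L, function(idx) permanova_stat(d2, groups[idx])[["F"]])
    p <- mean(f_perm >= obs[["F"]] - 1e-12)
    np <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    f_perm <- replicate(n_permutations,
                        permanova_stat(d2, groups[sample.int(n)])[["F"]])
    p <- (sum(f_perm >= obs[["F"]] - 1e-12) + 1) / (n_permutations + 1)
    np <- n_permutations
  }
  structure(list(pseudo_F = obs[["F"]], r_squared = obs[["R2"]], p = p,
                 n_permutations = np, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$r_squared, x$p, x$n_permutations))
  invisible(x)
}

# all n! permutations of 1..n as rows (small n only)
all_permutations <- function(n) {
  if (n > 9L) stop("exhaustive enumeration limited to n <= 9")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Beta-dispersion test (PERMDISP)
#'
#' Distances of samples to their group centroid are computed in the
#' positive-eigenvalue PCoA space of the dissimilarity matrix; a one-way
#' ANOVA F on those distances is assessed by permuting them across groups.
#'
#' @param d a \code{\link{distance_matrix}}.
#' @param groups group labels in sample order.
#' @param n_permutations integer, default 999.
#' @param seed integer seed.
#' @return list with \code{F}, \code{p}, \code{centroid_distances}.
#' @export
permdisp <- function(d, groups, n_permutations = 999L, seed = NULL) {
  groups <- droplevels(as.factor(as.character(groups)))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  coords <- suppressMessages(pcoa(d))$coordinates
  cd <- numeric(nrow(coords))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cen <- colMeans(coords[idx, , drop = FALSE])
    cd[idx] <- sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2L, cen)^2))
  }
  f_stat <- function(x, gr) {
    gm <- tapply(x, gr, mean); ng <- tabulate(gr)
    ssb <- sum(ng * (gm - mean(x))^2)
    ssw <- sum((x - gm[gr])^2)
    dfw <- length(x) - nlevels(gr)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / (nlevels(gr) - 1)) / (ssw / dfw)
  }
  f_obs <- f_stat(cd, groups)
  if (!is.null(seed)) set.seed(seed)
  f_perm <- replicate(n_permutations,
                      f_stat(cd[sample.int(length(cd))], groups))
  p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_permutations + 1)
  list(F = f_obs, p = p, centroid_distances = stats::setNames(cd, rownames(coords)))
}
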