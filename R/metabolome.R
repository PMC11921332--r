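#' Preprocess a metabolite table
#'
#' Missing concentrations are imputed as half the metabolite's limit of
#' detection (LOD/2), values are log-transformed, and variables optionally
#' autoscaled (mean-centred, unit variance).
#'
#' @param m a \code{metabolite_table}
#'   (see \code{\link{read_metabolite_table}}).
#' @param transform \code{"ln"} (default) or \code{"log10"}.
#' @param scale \code{"autoscale"} or \code{"none"}.
#' @return samples x metabolites numeric matrix.
#' @export
preprocess_metabolites <- function(m, transform = c("ln", "log10"),
                                   scale = c("autoscale", "none")) {
  transform <- match.arg(transform)
  scale <- match.arg(scale)
  conc <- m$concentrations
  for (i in seq_len(nrow(conc))) {
    if (anyNA(conc[i, ])) {
      if (is.na(m$lod[i]))
        stop("metabolite '", rownames(conc)[i],
             "' has missing values but no LOD")
      conc[i, is.na(conc[i, ])] <- m$lod[i] / 2
    }
  }
  x <- t(if (transform == "ln") log(conc) else log10(conc))
  if (scale == "autoscale") {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      stop("metabolite '", colnames(x)[which(sds == 0)[1]],
           "' is constant; cannot autoscale")
    x <- scale(x, center = TRUE, scale = sds)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  }
  x
}

#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis by NIPALS on a one-hot
#' (dummy) response: latent components are extracted iteratively with
#' deflation of both blocks. X should already be preprocessed (e.g. by
#' \code{\link{preprocess_metabolites}}); Y dummies are centred.
#'
#' @param x samples x variables numeric matrix.
#' @param groups class labels, one per sample; at least two classes.
#' @param n_components number of latent components (default 2).
#' @return object of class \code{plsda_result}: \code{scores},
#'   \code{x_weights}, \code{x_loadings}, \code{y_loadings},
#'   \code{y_explained_ss}, \code{groups}, \code{n_components}, and
#'   \code{vip} (see \code{\link{vip_scores}}).
#' @export
plsda_fit <- function(x, groups, n_components = 2L) {
  x <- as.matrix(x)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need at least two classes")
  if (n_components > min(nrow(x) - 1L, ncol(x)))
    stop("n_components exceeds min(samples - 1, variables)")
  if (any(apply(x, 2L, stats::sd) == 0))
    stop("constant variable in X; remove or rescale before fitting")
  y <- stats::model.matrix(~ groups - 1)
  colnames(y) <- levels(groups)
  y <- scale(y, center = TRUE, scale = FALSE)
  xr <- scale(x, center = TRUE, scale = FALSE)
  n <- nrow(x); p <- ncol(x)
  w_mat <- matrix(0, p, n_components)
  p_mat <- matrix(0, p, n_components)
  q_mat <- matrix(0, ncol(y), n_components)
  t_mat <- matrix(0, n, n_components)
  ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- y[, which.max(colSums(y^2))]
    t_old <- rep(Inf, n)
    for (iter in 1:500) {
      w <- crossprod(xr, u)
      w <- w / sqrt(sum(w^2))
      tt <- xr %*% w
      q <- crossprod(y, tt) / sum(tt^2)
      u <- y %*% q / sum(q^2)
      if (sum((tt - t_old)^2) < 1e-12 * sum(tt^2)) break
      t_old <- tt
    }
    pl <- crossprod(xr, tt) / sum(tt^2)
    w_mat[, a] <- w; p_mat[, a] <- pl; q_mat[, a] <- q; t_mat[, a] <- tt
    ssy[a] <- sum(tt^2) * sum(q^2)   # SS of Y explained by component a
    xr <- xr - tcrossprod(tt, pl)
    y <- y - tcrossprod(tt, q)
  }
  dimnames(w_mat) <- dimnames(p_mat) <-
    list(colnames(x), paste0("comp", seq_len(n_components)))
  dimnames(t_mat) <- list(rownames(x), colnames(w_mat))
  res <- structure(list(scores = t_mat, x_weights = w_mat,
                        x_loadings = p_mat, y_loadings = q_mat,
                        y_explained_ss = ssy, groups = groups,
                        n_components = n_components),
                   class = "plsda_result")
  res$vip <- vip_scores(res)
  res
}

#' Variable importance in projection (VIP) scores
#'
#' VIP_j = sqrt(p * sum_a(SSY_a w_ja^2) / sum_a SSY_a) with p the number of
#' variables and w the (unit-norm) component weights; the mean squared VIP
#' is exactly 1. \code{top_vip} reports the k highest-scoring variables.
#'
#' @param r a fitted \code{plsda_result}.
#' @return named numeric vector of VIP scores, one per variable.
#' @export
vip_scores <- function(r) {
  if (sum(r$y_explained_ss) <= 0) stop("model explains no Y variance")
  p <- nrow(r$x_weights)
  w2 <- r$x_weights^2   # columns already unit-norm
  v <- sqrt(p * as.vector(w2 %*% r$y_explained_ss) / sum(r$y_explained_ss))
  stats::setNames(v, rownames(r$x_weights))
}

#' @rdname vip_scores
#' @param k how many variables to report (default 15).
#' @export
top_vip <- function(r, k = 15L) {
  v <- if (inherits(r, "plsda_result")) r$vip else r
  head(sort(v, decreasing = TRUE), k)
}

#' Spearman correlation matrix with BH FDR control
#'
#' For every taxon x metabolite pair, Spearman's rho is the Pearson
#' correlation of midranks, with a two-sided p-value from the
#' t approximation t = rho sqrt((n-2)/(1-rho^2)). All pairs tested in one
#' call form a single Benjamini-Hochberg family; pairs involving a
#' constant variable have undefined rho and are excluded from the family.
#'
#' @param taxa samples x taxa numeric matrix (e.g. relative abundances).
#' @param metabolites samples x metabolites numeric matrix, same sample
#'   order.
#' @param alpha significance threshold on the adjusted q (default 0.01).
#' @return object of class \code{correlation_result}: matrices \code{rho},
#'   \code{p}, \code{q} (taxa x metabolites) and logical
#'   \code{significant} at q < alpha.
#' @export
spearman_matrix <- function(taxa, metabolites, alpha = 0.01) {
  taxa <- as.matrix(taxa); metabolites <- as.matrix(metabolites)
  if (nrow(taxa) != nrow(metabolites))
    stop("sample sets differ between the two matrices")
  n <- nrow(taxa)
  rt <- apply(taxa, 2L, rank, ties.method = "average")
  rm_ <- apply(metabolites, 2L, rank, ties.method = "average")
  const_t <- apply(taxa, 2L, function(x) length(unique(x)) == 1L)
  const_m <- apply(metabolites, 2L, function(x) length(unique(x)) == 1L)
  rho <- suppressWarnings(stats::cor(rt, rm_))
  rho[const_t, ] <- NA_real_
  rho[, const_m] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[which(abs(rho) >= 1 - 1e-12)] <- 0
  q <- p
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  structure(list(rho = rho, p = p, q = q,
                 significant = !is.na(q) & q < alpha, alpha = alpha),
            class = "correlation_result")
}

#' Symmetric Procrustes analysis with PROTEST significance
#'
#' Both coordinate matrices are column-centred and scaled to unit total
#' sum of squares; the optimal rotation comes from the SVD of the
#' cross-product. The residual m^2 = 1 - (sum of singular values)^2 and the
#' Procrustes correlation sqrt(1 - m^2) are reported, with significance by
#' permuting the rows of the second configuration (PROTEST), p estimated
#' as (x+1)/(N+1).
#'
#' @param x_coords,y_coords samples x axes matrices (same sample order,
#'   at least 3 samples); column counts may differ (zero-padded).
#' @param n_permutations integer, default 999.
#' @param seed integer seed.
#' @return object of class \code{procrustes_result}: \code{m_squared},
#'   \code{correlation}, \code{p}, \code{n_permutations}, \code{seed}.
#' @export
procrustes_protest <- function(x_coords, y_coords, n_permutations = 999L,
                               seed = NULL) {
  x <- as.matrix(x_coords); y <- as.matrix(y_coords)
  if (nrow(x) != nrow(y)) stop("configurations must share their sample set")
  if (nrow(x) < 3L) stop("need at least 3 samples")
  k <- max(ncol(x), ncol(y))
  pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
  unitize <- function(m) {
    m <- scale(m, center = TRUE, scale = FALSE)
    m / sqrt(sum(m^2))
  }
  x <- unitize(pad(x)); y <- unitize(pad(y))
  pro_cor <- function(yy) sum(svd(crossprod(x, yy))$d)
  r_obs <- min(pro_cor(y), 1)
  if (!is.null(seed)) set.seed(seed)
  r_perm <- replicate(n_permutations,
                      pro_cor(unitize(y[sample.int(nrow(y)), , drop = FALSE])))
  p <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_permutations + 1)
  structure(list(m_squared = 1 - r_obs^2, correlation = r_obs, p = p,
                 n_permutations = n_permutations, seed = seed),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes: m2 = %.4f, correlation = %.4f, p = %.4g (%d permutations)\n",
              x$m_squared, x$correlation, x$p, x$n_permutations))
  invisible(x)
}
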