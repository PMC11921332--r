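# small in-code fixtures shared across test files

make_table <- function(counts, features = NULL, samples = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- features %||% sprintf("f%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  feature_table(m)
}

random_table <- function(n_features, n_samples, seed, lambda = 20) {
  set.seed(seed)
  make_table(matrix(rpois(n_features * n_samples, lambda),
                    n_features, n_samples))
}

# a tiny but complete synthetic study, cheap enough for many tests
small_config <- function(seed = 42, ...) {
  defaults <- list(seed = seed,
                   donor_richness = c(WB = 40L, Sow = 30L),
                   n_shared_unique = 5L,
                   n_common_with_baseline = c(WB = 10L, Sow = 8L),
                   n_piglets_per_group = 3L,
                   baseline_extra_features = 25L,
                   depth = 2e4)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# metadata-free Bray-Curtis on a plain matrix of points -> Euclidean distances
euclid_dm <- function(pts) {
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- sprintf("s%02d", seq_len(nrow(d)))
  distance_matrix(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
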