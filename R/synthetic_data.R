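#' Configuration for the synthetic study generator
#'
#' Builds the parameter set for a simulated microbiota-transplantation
#' study: two donor inocula (wild boar "WB", domestic sow "Sow"), four
#' recipient groups of piglets sampled at a weaning baseline (PND21) and
#' two post-transplantation timepoints (PND27 fecal, PND48 fecal + cecal),
#' and a cecal metabolite panel. Defaults mirror the study design the
#' package targets: 439/275 donor ASVs of which 101/98 are shared with the
#' recipient baseline pool and 42 donor-unique ASVs are shared between the
#' donors; 12 piglets per group; engrafted donor ASVs carrying about 6.5%
#' of the post-transplant community.
#'
#' @param seed integer seed; every stage derives its RNG stream from it.
#' @param donor_richness named vector, ASVs per donor inoculum.
#' @param n_shared_unique donor-unique ASVs common to both donors.
#' @param n_common_with_baseline named vector, donor ASVs also present in
#'   the recipient baseline pool.
#' @param n_piglets_per_group recipients per treatment group.
#' @param baseline_extra_features baseline-pool ASVs found in no inoculum.
#' @param baseline_occupancy probability a baseline-pool ASV is present in
#'   any given piglet before inoculation.
#' @param engraftment_prob groups x sources matrix of per-ASV engraftment
#'   probabilities; rows Control/Sow/WB/Mix, columns WB/Sow.
#' @param depth mean sequencing depth; per-sample depths are Poisson.
#' @param abundance_lognormal c(mu, sigma) of the latent log-normal
#'   relative-abundance model.
#' @param engrafted_share latent fraction of a recipient's post-transplant
#'   community carried by engrafted donor ASVs (when any engrafted).
#' @param inoculum_floor guaranteed minimum count for every inoculum
#'   member ASV (a cultured inoculum contains all its members well above
#'   the detection floor).
#' @param n_metabolites size of the metabolite panel.
#' @param metabolite_sigma log-scale SD of metabolite concentrations.
#' @param metabolite_effects groups x metabolites matrix of log-scale group
#'   shifts; NULL for the built-in default (a handful of shifted
#'   metabolites per treatment group, none for Control).
#' @param planted_rho target Spearman correlation between one engrafted
#'   taxon's relative abundance and one metabolite.
#' @param lod_mult per-metabolite LOD is exp(mu_j - lod_mult * sigma);
#'   large values push the LOD to zero so no value goes missing.
#' @return a list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed,
                             donor_richness = c(WB = 439L, Sow = 275L),
                             n_shared_unique = 42L,
                             n_common_with_baseline = c(WB = 101L, Sow = 98L),
                             n_piglets_per_group = 12L,
                             baseline_extra_features = 300L,
                             baseline_occupancy = 0.5,
                             engraftment_prob = NULL,
                             depth = 5e4,
                             abundance_lognormal = c(mu = 0, sigma = 1),
                             engrafted_share = 0.065,
                             inoculum_floor = 3L,
                             n_metabolites = 70L,
                             metabolite_sigma = 0.6,
                             metabolite_effects = NULL,
                             planted_rho = 0.8,
                             lod_mult = 2.3) {
  groups <- study_groups()
  sources <- names(donor_richness)
  if (is.null(engraftment_prob)) {
    engraftment_prob <- matrix(0, length(groups), length(sources),
                               dimnames = list(groups, sources))
    engraftment_prob["WB", "WB"] <- 0.31
    engraftment_prob["Sow", "Sow"] <- 0.32
    engraftment_prob["Mix", "WB"] <- 0.17
    engraftment_prob["Mix", "Sow"] <- 0.05
  }
  cfg <- list(seed = as.integer(seed), donor_richness = donor_richness,
              n_shared_unique = as.integer(n_shared_unique),
              n_common_with_baseline = n_common_with_baseline,
              n_piglets_per_group = as.integer(n_piglets_per_group),
              groups = groups, sources = sources,
              baseline_extra_features = as.integer(baseline_extra_features),
              baseline_occupancy = baseline_occupancy,
              engraftment_prob = engraftment_prob, depth = depth,
              abundance_lognormal = abundance_lognormal,
              engrafted_share = engrafted_share,
              inoculum_floor = as.integer(inoculum_floor),
              n_metabolites = as.integer(n_metabolites),
              metabolite_sigma = metabolite_sigma,
              metabolite_effects = metabolite_effects,
              planted_rho = planted_rho, lod_mult = lod_mult)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  n_unique <- cfg$donor_richness - cfg$n_common_with_baseline
  if (any(n_unique < 0))
    stop("n_common_with_baseline exceeds donor_richness")
  if (cfg$n_shared_unique > min(n_unique))
    stop(sprintf("n_shared_unique (%d) exceeds the smallest donor-unique set (%d)",
                 cfg$n_shared_unique, min(n_unique)))
  if (any(cfg$engraftment_prob < 0 | cfg$engraftment_prob > 1))
    stop("engraftment_prob entries must lie in [0, 1]")
  if (cfg$depth <= 0) stop("depth must be positive")
  if (cfg$depth < cfg$inoculum_floor * max(cfg$donor_richness))
    stop("depth too small to place the inoculum floor under every member ASV")
  if (cfg$baseline_occupancy <= 0 || cfg$baseline_occupancy > 1)
    stop("baseline_occupancy must lie in (0, 1]")
  cfg
}

# distinct, reproducible RNG stream per generator stage
stage_seed <- function(seed, stage) {
  offsets <- c(inocula = 1L, baseline = 2L, post = 3L, metabolome = 4L)
  (abs(seed) %% 1000000000L) * 2L + offsets[[stage]]
}

# lognormal latents over the given feature ids, renormalized
draw_latent <- function(ids, mu, sigma) {
  x <- stats::rlnorm(length(ids), meanlog = mu, sdlog = sigma)
  names(x) <- ids
  x / sum(x)
}

# multinomial draw guaranteeing `floor` counts to every category
rmultinom_floor <- function(depth, prob, floor = 0L) {
  base <- rep.int(floor, length(prob))
  rest <- depth - sum(base)
  if (rest < 0) stop("depth below the guaranteed floor total")
  base + as.integer(stats::rmultinom(1L, rest, prob))
}

piglet_ids <- function(cfg) {
  n <- cfg$n_piglets_per_group * length(cfg$groups)
  sprintf("P%02d", seq_len(n))
}

piglet_group <- function(cfg) {
  rep(cfg$groups, each = cfg$n_piglets_per_group)
}

#' Generate the two donor inoculum samples
#'
#' Partitions a synthetic ASV universe into donor-unique, donor/baseline
#' common, cross-donor shared-unique, and baseline-only sets of exactly the
#' configured sizes, then draws the two inoculum count profiles (lognormal
#' latent abundances, multinomial sampling at Poisson depth, with every
#' member ASV guaranteed at least \code{inoculum_floor} counts).
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return list with \code{table} (a \code{\link{feature_table}} of the two
#'   inoculum samples) and \code{truth} (the planted membership sets).
#' @export
generate_inocula <- function(cfg) {
  set.seed(stage_seed(cfg$seed, "inocula"))
  n_unique <- cfg$donor_richness - cfg$n_common_with_baseline
  sizes <- c(shared = cfg$n_shared_unique,
             wb_only = n_unique[["WB"]] - cfg$n_shared_unique,
             sow_only = n_unique[["Sow"]] - cfg$n_shared_unique,
             wb_common = cfg$n_common_with_baseline[["WB"]],
             sow_common = cfg$n_common_with_baseline[["Sow"]],
             baseline_only = cfg$baseline_extra_features)
  ids <- sprintf("ASV%04d", seq_len(sum(sizes)))
  part <- split(ids, rep(names(sizes), sizes))
  truth <- list(
    unique = list(WB = c(part$shared, part$wb_only),
                  Sow = c(part$shared, part$sow_only)),
    common = list(WB = part$wb_common, Sow = part$sow_common),
    shared_unique = part$shared,
    baseline_only = part$baseline_only)
  truth$donor_features <- list(
    WB = c(truth$unique$WB, truth$common$WB),
    Sow = c(truth$unique$Sow, truth$common$Sow))
  mu <- cfg$abundance_lognormal[["mu"]]
  sg <- cfg$abundance_lognormal[["sigma"]]
  counts <- matrix(0L, length(ids), 2L,
                   dimnames = list(ids, paste0("inoculum_", cfg$sources)))
  for (s in cfg$sources) {
    feats <- truth$donor_features[[s]]
    lat <- draw_latent(feats, mu, sg)
    depth_s <- stats::rpois(1L, cfg$depth)
    counts[feats, paste0("inoculum_", s)] <-
      rmultinom_floor(depth_s, lat, cfg$inoculum_floor)
  }
  list(table = feature_table(counts), truth = truth)
}

#' Generate the pre-inoculation baseline cohort
#'
#' Each piglet's baseline community is a random subset of the baseline pool
#' (donor-common plus baseline-only ASVs) at the configured occupancy;
#' every donor-common ASV is guaranteed present in at least one piglet. No
#' donor-unique ASV ever appears at baseline, by construction.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param truth membership sets from \code{\link{generate_inocula}}.
#' @return list with \code{table} (baseline PND21 \code{\link{feature_table}}
#'   over the full ASV universe) and \code{truth} (augmented with per-piglet
#'   baseline membership).
#' @export
generate_baseline_cohort <- function(cfg, truth) {
  set.seed(stage_seed(cfg$seed, "baseline"))
  pool <- c(truth$common$WB, truth$common$Sow, truth$baseline_only)
  pigs <- piglet_ids(cfg)
  npig <- length(pigs)
  present <- matrix(stats::runif(length(pool) * npig) < cfg$baseline_occupancy,
                    length(pool), npig, dimnames = list(pool, pigs))
  for (f in c(truth$common$WB, truth$common$Sow))
    if (!any(present[f, ])) present[f, sample.int(npig, 1L)] <- TRUE
  all_ids <- sort(unique(c(unlist(truth$donor_features), pool)))
  mu <- cfg$abundance_lognormal[["mu"]]
  sg <- cfg$abundance_lognormal[["sigma"]]
  counts <- matrix(0L, length(all_ids), npig,
                   dimnames = list(all_ids, paste0(pigs, "_PND21_fecal")))
  for (j in seq_len(npig)) {
    feats <- pool[present[, j]]
    lat <- draw_latent(feats, mu, sg)
    counts[feats, j] <- as.integer(stats::rmultinom(1L, stats::rpois(1L, cfg$depth), lat))
  }
  truth$baseline_membership <- present
  list(table = feature_table(counts), truth = truth)
}

#' Generate post-transplantation samples
#'
#' For every (group, source) pair, each source-unique ASV engrafts into the
#' group independently with the configured probability; engrafted ASVs are
#' present in every piglet of the group from PND27 on, jointly carrying the
#' configured latent community share, with abundances redrawn independently
#' per sample (no within-host dynamics are modelled). Emits PND27 fecal,
#' PND48 fecal, and PND48 cecal samples for all piglets.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param truth output truth of \code{\link{generate_baseline_cohort}}.
#' @return list with \code{table} and \code{truth} (augmented with the
#'   planted engrafted sets per group and source and the planted share).
#' @export
generate_post_transplant <- function(cfg, truth) {
  set.seed(stage_seed(cfg$seed, "post"))
  pigs <- piglet_ids(cfg)
  grp <- piglet_group(cfg)
  truth$engrafted <- list()
  engrafted_by_group <- list()
  for (g in cfg$groups) {
    truth$engrafted[[g]] <- list()
    eng <- character(0)
    for (s in cfg$sources) {
      p <- cfg$engraftment_prob[g, s]
      uniq <- truth$unique[[s]]
      drawn <- uniq[stats::runif(length(uniq)) < p]
      truth$engrafted[[g]][[s]] <- drawn
      eng <- union(eng, drawn)
    }
    engrafted_by_group[[g]] <- eng
  }
  truth$engrafted_share <- cfg$engrafted_share
  all_ids <- rownames(truth$baseline_membership)
  all_ids <- sort(unique(c(unlist(truth$donor_features), all_ids)))
  slots <- expand.grid(pig = seq_along(pigs),
                       tp = c("PND27_fecal", "PND48_fecal", "PND48_cecal"),
                       stringsAsFactors = FALSE)
  mu <- cfg$abundance_lognormal[["mu"]]
  sg <- cfg$abundance_lognormal[["sigma"]]
  counts <- matrix(0L, length(all_ids), nrow(slots),
                   dimnames = list(all_ids,
                                   paste(pigs[slots$pig], slots$tp, sep = "_")))
  for (k in seq_len(nrow(slots))) {
    j <- slots$pig[k]
    resident <- rownames(truth$baseline_membership)[truth$baseline_membership[, j]]
    eng <- engrafted_by_group[[grp[j]]]
    lat_res <- draw_latent(resident, mu, sg)
    if (length(eng)) {
      lat_eng <- draw_latent(eng, mu, sg)
      lat <- c(lat_res * (1 - cfg$engrafted_share),
               lat_eng * cfg$engrafted_share)
    } else lat <- lat_res
    counts[names(lat), k] <-
      as.integer(stats::rmultinom(1L, stats::rpois(1L, cfg$depth), lat))
  }
  list(table = feature_table(counts), truth = truth)
}

#' Generate the cecal metabolite panel
#'
#' Log-normal concentrations per metabolite with group shifts applied on
#' the log scale. One metabolite (\code{met01}) is coupled to the relative
#' abundance of a planted engrafted taxon through a Gaussian copula tuned
#' so its Spearman correlation approximates \code{planted_rho}. Values
#' below the per-metabolite LOD are emitted as missing.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param truth output truth of \code{\link{generate_post_transplant}}.
#' @param post_table the post-transplant \code{\link{feature_table}}.
#' @return list with \code{table} (a \code{metabolite_table} over the PND48
#'   cecal samples) and \code{truth} (augmented with the planted effects and
#'   correlation target).
#' @export
generate_metabolome <- function(cfg, truth, post_table) {
  set.seed(stage_seed(cfg$seed, "metabolome"))
  cecal <- grep("_PND48_cecal$", colnames(post_table), value = TRUE)
  if (!length(cecal)) stop("post table holds no PND48 cecal samples")
  pigs <- sub("_PND48_cecal$", "", cecal)
  grp <- piglet_group(cfg)[match(pigs, piglet_ids(cfg))]
  mets <- sprintf("met%02d", seq_len(cfg$n_metabolites))
  mu_j <- stats::runif(cfg$n_metabolites, log(1), log(100))
  sg <- cfg$metabolite_sigma
  eff <- cfg$metabolite_effects
  if (is.null(eff)) {
    eff <- matrix(0, length(cfg$groups), cfg$n_metabolites,
                  dimnames = list(cfg$groups, mets))
    # emulate group-specific enrichments: a few shifted metabolites per
    # treatment group, Control untouched, planted-correlation metabolite
    # (met01) untouched
    eff["WB", 2:9] <- 0.6
    eff["Sow", 10:13] <- 0.5
    eff["Mix", 14:15] <- 0.5
  }
  dimnames(eff) <- list(cfg$groups, mets)
  n <- length(cecal)
  z <- matrix(stats::rnorm(cfg$n_metabolites * n), cfg$n_metabolites, n)
  # couple met01 to the planted taxon via a Gaussian copula;
  # r = 2 sin(pi*rho/6) inverts the bivariate-normal Spearman identity
  taxon <- truth$engrafted$WB$WB[1]
  if (!is.na(taxon) && cfg$planted_rho != 0) {
    ra <- relative_abundance(post_table[, cecal])[taxon, ]
    zt <- stats::qnorm((rank(ra, ties.method = "average") - 0.5) / n)
    r <- 2 * sin(pi * cfg$planted_rho / 6)
    z[1, ] <- r * zt + sqrt(1 - r^2) * z[1, ]
  }
  logc <- mu_j + sg * z + t(eff[grp, , drop = FALSE])
  conc <- exp(logc)
  dimnames(conc) <- list(mets, cecal)
  lod <- exp(mu_j - cfg$lod_mult * sg)
  names(lod) <- mets
  conc[conc < lod] <- NA_real_
  truth$metabolite_effects <- eff
  truth$planted_correlation <- list(taxon = taxon, metabolite = "met01",
                                    rho = cfg$planted_rho)
  list(table = metabolite_table(conc, lod), truth = truth)
}

#' Run the full synthetic study
#'
#' Chains inoculum, baseline, post-transplant and metabolome generation
#' under one seed and assembles the study metadata. Optionally writes every
#' artifact (feature tables, metadata, metabolite + LOD tables,
#' ground_truth.json) as plain text; outputs are bit-identical for a fixed
#' seed and configuration.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param outdir optional directory to write TSV/JSON artifacts into.
#' @return list with \code{inocula}, \code{baseline}, \code{post}
#'   (\code{\link{feature_table}}s), \code{metabolome}
#'   (\code{metabolite_table}), \code{metadata} (data.frame) and
#'   \code{truth}.
#' @export
simulate_study <- function(cfg, outdir = NULL) {
  ino <- generate_inocula(cfg)
  base <- generate_baseline_cohort(cfg, ino$truth)
  post <- generate_post_transplant(cfg, base$truth)
  metab <- generate_metabolome(cfg, post$truth, post$table)
  md <- study_metadata(cfg)
  out <- list(inocula = ino$table, baseline = base$table, post = post$table,
              metabolome = metab$table, metadata = md, truth = metab$truth,
              cfg = cfg)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(out$inocula, file.path(outdir, "inocula.tsv"))
    write_feature_table(out$baseline, file.path(outdir, "baseline.tsv"))
    write_feature_table(out$post, file.path(outdir, "post_transplant.tsv"))
    write_metabolite_table(out$metabolome,
                           file.path(outdir, "metabolites.tsv"),
                           file.path(outdir, "lod.tsv"))
    utils::write.table(md, file.path(outdir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out$truth[c("unique", "common", "shared_unique",
                                     "engrafted", "engrafted_share")],
                         file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Metadata table for a synthetic study
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return data.frame with one row per sample (inocula, baseline,
#'   post-transplant fecal and cecal).
#' @export
study_metadata <- function(cfg) {
  pigs <- piglet_ids(cfg)
  grp <- piglet_group(cfg)
  pen <- sprintf("pen%d", (seq_along(pigs) - 1L) %/% 6L + 1L)
  litter <- sprintf("litter%d", (seq_along(pigs) - 1L) %% 6L + 1L)
  sex <- rep(c("M", "F"), length.out = length(pigs))
  slots <- rbind(
    data.frame(tp = "PND21", st = "fecal"),
    data.frame(tp = "PND27", st = "fecal"),
    data.frame(tp = "PND48", st = "fecal"),
    data.frame(tp = "PND48", st = "cecal"))
  rows <- do.call(rbind, lapply(seq_len(nrow(slots)), function(k)
    data.frame(sample_id = paste(pigs, slots$tp[k], slots$st[k], sep = "_"),
               subject_id = pigs, group = grp, timepoint = slots$tp[k],
               sample_type = slots$st[k], pen = pen, litter = litter,
               sex = sex, stringsAsFactors = FALSE)))
  ino <- data.frame(sample_id = paste0("inoculum_", cfg$sources),
                    subject_id = paste0("donor_", cfg$sources),
                    group = cfg$sources, timepoint = "PND21",
                    sample_type = "inoculum", pen = "none", litter = "none",
                    sex = "unknown", stringsAsFactors = FALSE)
  validate_sample_metadata(rbind(ino, rows))
}

#' Align feature tables on the union of their features
#'
#' Missing features fill with zero counts; sample sets must be disjoint.
#' Used to pool inocula and recipient samples before the global low-count
#' filter.
#'
#' @param tables list of \code{\link{feature_table}}s.
#' @return one merged \code{\link{feature_table}}.
#' @export
merge_feature_tables <- function(tables) {
  all_feats <- sort(unique(unlist(lapply(tables, rownames))))
  all_samps <- unlist(lapply(tables, colnames))
  if (anyDuplicated(all_samps))
    stop("sample ids overlap across tables: ",
         all_samps[duplicated(all_samps)][1])
  m <- matrix(0L, length(all_feats), length(all_samps),
              dimnames = list(all_feats, all_samps))
  for (t in tables) m[rownames(t), colnames(t)] <- unclass(t)
  feature_table(m)
}
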