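# hand-built inoculum/baseline pair used by several blocks:
# donor WB holds a,b,c,d; donor Sow holds b,d,e; baseline piglets carry c,d,e
tiny_provenance <- function() {
  ino <- make_table(rbind(a = c(5, 0), b = c(4, 3), c = c(2, 0),
                          d = c(6, 7), e = c(0, 9)),
                    features = letters[1:5],
                    samples = c("inoculum_WB", "inoculum_Sow"))
  base <- make_table(rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0),
                           d = c(0, 2), e = c(3, 0)),
                     features = letters[1:5], samples = c("p1", "p2"))
  list(ino = ino, base = base)
}

test_that("inoculum ASVs partition into unique and common by baseline presence", {
  tp <- tiny_provenance()
  cls <- classify_inoculum_asvs(tp$ino, tp$base)
  expect_setequal(cls$unique$WB, c("a", "b"))
  expect_setequal(cls$common$WB, c("c", "d"))
  expect_setequal(cls$unique$Sow, "b")
  expect_setequal(cls$common$Sow, c("d", "e"))
  expect_setequal(cls$shared_unique, "b")
  expect_identical(cls$counts$n_total, c(4L, 3L))

  # baseline covering every inoculum ASV -> nothing unique
  allbase <- make_table(matrix(1, 5, 1), features = letters[1:5])
  cls2 <- classify_inoculum_asvs(tp$ino, allbase)
  expect_length(cls2$unique$WB, 0)
  expect_length(cls2$unique$Sow, 0)

  empty <- feature_table(matrix(0L, 5, 0,
                                dimnames = list(letters[1:5], character(0))))
  expect_error(classify_inoculum_asvs(tp$ino, empty), "no samples")
})

test_that("classification is monotone: extra baseline samples only move unique -> common", {
  set.seed(14)
  for (rep in 1:20) {
    ino <- random_table(30, 2, seed = rep, lambda = 2)
    colnames(ino) <- c("inoculum_WB", "inoculum_Sow")
    base_small <- random_table(30, 3, seed = rep + 100, lambda = 0.3)
    extra <- random_table(30, 2, seed = rep + 200, lambda = 0.3)
    colnames(extra) <- c("x1", "x2")
    base_big <- merge_feature_tables(list(base_small, extra))
    c1 <- classify_inoculum_asvs(ino, base_small)
    c2 <- classify_inoculum_asvs(ino, base_big)
    for (d in c("WB", "Sow")) {
      expect_true(all(c2$unique[[d]] %in% c1$unique[[d]]))
      expect_true(all(c1$common[[d]] %in% c2$common[[d]]))
    }
  }
})

test_that("engrafted ASV detection is scoped to group, timepoint and stratum", {
  tp <- tiny_provenance()
  cls <- classify_inoculum_asvs(tp$ino, tp$base)
  # ASV a present at PND27 only; b engrafted at both timepoints in WB group
  post <- make_table(
    rbind(a = c(2, 0, 0), b = c(3, 5, 0), c = c(1, 1, 1),
          d = c(0, 0, 4), e = c(0, 0, 0)),
    features = letters[1:5], samples = c("w1_27", "w1_48", "s1_48"))
  md <- data.frame(sample_id = c("w1_27", "w1_48", "s1_48"),
                   subject_id = c("w1", "w1", "s1"),
                   group = c("WB", "WB", "Sow"),
                   timepoint = c("PND27", "PND48", "PND48"),
                   sample_type = "fecal", pen = "p", litter = "l", sex = "F")
  expect_setequal(
    detect_engrafted_asvs(post, cls, md, "WB", "WB", "PND27"), c("a", "b"))
  expect_setequal(
    detect_engrafted_asvs(post, cls, md, "WB", "WB", "PND48"), "b")
  # strata: b is shared-unique, a is WB-specific
  expect_setequal(
    detect_engrafted_asvs(post, cls, md, "WB", "WB", "PND27", stratum = "specific"),
    "a")
  expect_setequal(
    detect_engrafted_asvs(post, cls, md, "WB", "WB", "PND27", stratum = "shared"),
    "b")
  # Sow group at PND48 shows no Sow-unique ASVs (b absent in s1_48)
  expect_length(detect_engrafted_asvs(post, cls, md, "Sow", "Sow", "PND48"), 0)
  expect_error(detect_engrafted_asvs(post, cls, md, "Boar", "WB", "PND48"),
               "unknown group")
  expect_error(detect_engrafted_asvs(post, cls, md, "WB", "WB", "PND33"),
               "unknown timepoint")
})

test_that("engrafted abundance summary matches hand arithmetic and bounds", {
  post <- make_table(matrix(c(65, 935), 2, 1), samples = "w1",
                     features = c("eng", "other"))
  md <- data.frame(sample_id = "w1", subject_id = "w1", group = "WB",
                   timepoint = "PND48", sample_type = "fecal",
                   pen = "p", litter = "l", sex = "M")
  s <- summarize_engraftment_abundance(post, "eng", md, "WB", "PND48")
  expect_equal(c(s$min, s$mean, s$max), c(6.5, 6.5, 6.5))
  # empty set -> identically 0; full feature set -> identically 100
  s0 <- summarize_engraftment_abundance(post, character(0), md, "WB", "PND48")
  expect_equal(c(s0$min, s0$mean, s0$max), c(0, 0, 0))
  s100 <- summarize_engraftment_abundance(post, c("eng", "other"), md, "WB", "PND48")
  expect_equal(c(s100$min, s100$mean, s100$max), c(100, 100, 100))
})

test_that("planted engrafted share is recovered at high depth", {
  zero <- matrix(0, 4, 2, dimnames = list(study_groups(), c("WB", "Sow")))
  pr <- zero; pr["WB", "WB"] <- 0.5
  cfg <- small_config(seed = 77, engraftment_prob = pr, depth = 1e5,
                      engrafted_share = 0.05)
  sim <- simulate_study(cfg)
  filt <- filter_low_count_features(
    merge_feature_tables(list(sim$inocula, sim$baseline, sim$post)))
  cls <- classify_inoculum_asvs(filt[, colnames(sim$inocula)],
                                filt[, colnames(sim$baseline)])
  det <- detect_engrafted_asvs(filt, cls, sim$metadata, "WB", "WB", "PND48",
                               sample_type = "fecal")
  s <- summarize_engraftment_abundance(filt, det, sim$metadata, "WB", "PND48",
                                       sample_type = "fecal")
  expect_gt(s$mean, 4)
  expect_lt(s$mean, 6)
})

test_that("two-sided Fisher matches enumeration, conventions and fisher.test", {
  # perfect homogeneity
  expect_equal(fisher_exact_two_sided(matrix(5, 2, 2))$p, 1)
  # full enumeration by hand: point probs (.05,.45,.45,.05) -> p = 0.1
  expect_equal(fisher_exact_two_sided(matrix(c(3, 0, 0, 3), 2, 2))$p, 0.1)
  # the study's unique/common contrast
  res <- fisher_exact_two_sided(matrix(c(338, 101, 177, 98), 2, 2, byrow = TRUE))
  expect_equal(round(res$p, 4), 3e-04)
  expect_equal(res$odds_ratio, (338 * 98) / (101 * 177))
  # odds-ratio conventions
  expect_identical(fisher_exact_two_sided(matrix(c(3, 0, 0, 3), 2, 2))$odds_ratio, Inf)
  expect_identical(fisher_exact_two_sided(matrix(c(0, 3, 3, 0), 2, 2))$odds_ratio, 0)
  expect_error(fisher_exact_two_sided(matrix(0L, 2, 2)), "all-zero")
  expect_error(fisher_exact_two_sided(matrix(c(1, 2, 3), 1, 3)), "2x2")
  # independent route: stats::fisher.test on random tables
  set.seed(31)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_two_sided(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("engraftment contrasts build auditable 2x2 tables", {
  sim <- simulate_study(small_config(seed = 15, depth = 1e5))
  filt <- filter_low_count_features(
    merge_feature_tables(list(sim$inocula, sim$baseline, sim$post)))
  cls <- classify_inoculum_asvs(filt[, colnames(sim$inocula)],
                                filt[, colnames(sim$baseline)])
  cell_wb <- list(source = "WB", stratum = "specific", group = "WB",
                  timepoint = "PND48", sample_type = "fecal")
  cell_sow <- list(source = "Sow", stratum = "specific", group = "Sow",
                   timepoint = "PND48", sample_type = "fecal")
  res <- compare_engraftment_success(filt, cls, sim$metadata, cell_wb, cell_sow)
  expect_identical(sum(res$table[1, ]),
                   length(setdiff(cls$unique$WB, cls$shared_unique)))
  expect_true(res$p >= 0 && res$p <= 1)
  # identical cells contrasted against themselves -> p = 1
  self <- compare_engraftment_success(filt, cls, sim$metadata, cell_wb, cell_wb)
  expect_equal(self$p, 1)
  # overlapping strata are refused
  cell_all <- modifyList(cell_wb, list(stratum = "all_unique"))
  cell_shared <- modifyList(cell_wb, list(stratum = "shared"))
  expect_error(
    compare_engraftment_success(filt, cls, sim$metadata, cell_all, cell_shared),
    "overlapping")
})

test_that("all-vs-none contrast reproduces the hypergeometric enumeration value", {
  # 20 engrafted of 20 vs 0 of 20: p = 2 / C(40,20) summed over the two
  # extreme tables, by direct enumeration
  tab <- matrix(c(20, 0, 0, 20), 2, 2, byrow = TRUE)
  supp <- 0:20
  w <- choose(20, supp) * choose(20, 20 - supp)
  p_oracle <- sum(w[w <= w[21]]) / choose(40, 20)
  expect_equal(fisher_exact_two_sided(tab)$p, p_oracle, tolerance = 1e-12)
})

test_that("equal planted engraftment gives well-calibrated Fisher nulls", {
  # under equal engraftment probabilities the contrast should not reject
  # systematically: with discrete p-values, P(p <= 0.05) <= 0.05
  set.seed(99)
  zero <- matrix(0, 4, 2, dimnames = list(study_groups(), c("WB", "Sow")))
  pr <- zero; pr["WB", "WB"] <- 0.4; pr["Sow", "Sow"] <- 0.4
  hits <- 0; n_rep <- 12
  for (i in seq_len(n_rep)) {
    sim <- simulate_study(small_config(seed = 500 + i, engraftment_prob = pr,
                                       depth = 5e4))
    filt <- filter_low_count_features(
      merge_feature_tables(list(sim$inocula, sim$baseline, sim$post)))
    cls <- classify_inoculum_asvs(filt[, colnames(sim$inocula)],
                                  filt[, colnames(sim$baseline)])
    res <- compare_engraftment_success(
      filt, cls, sim$metadata,
      list(source = "WB", stratum = "specific", group = "WB",
           timepoint = "PND48", sample_type = "fecal"),
      list(source = "Sow", stratum = "specific", group = "Sow",
           timepoint = "PND48", sample_type = "fecal"))
    if (res$p <= 0.05) hits <- hits + 1
  }
  expect_lte(hits, 3)  # P(>=4 rejections | binom(12, .05)) < 0.003
})
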