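---
title: "Tracking donor-microbiota engraftment: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking donor-microbiota engraftment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engraftr)
```

## The analysis problem

Microbiota-transplantation experiments ask whether microbes administered in
a donor inoculum actually establish themselves — *engraft* — in the
recipient gut, and whether engraftment reshapes the recipient's community
and metabolite pool. With 16S amplicon data the trackable unit is the ASV
(amplicon sequence variant, an exact denoised sequence). The central
difficulty is attribution: an ASV seen in a recipient after transplantation
may have come from the inoculum or may have been there all along.

`engraftr` resolves attribution by presence/absence logic against a
pre-inoculation baseline:

* an inoculum ASV observed in **at least one** recipient sample before
  inoculation is **common** — it cannot serve as evidence of transfer;
* an inoculum ASV absent from **every** recipient at baseline is
  **unique** to its donor source, and its later appearance in a recipient
  is evidence of engraftment.

Unique and common sets partition each donor's feature set, and the
intersection of the two donors' unique sets (the *shared-unique* stratum)
is tracked separately, because an ASV carried by both inocula cannot be
attributed to one source in the mixed-inoculum group. Engraftment success
between two strata is contrasted with a two-sided Fisher exact test on the
(engrafted / not-engrafted) × (stratum A / stratum B) table; the 2×2 table
is always returned with the p-value so the contrast is auditable.

### Semantics that matter

* **"Absent" means count 0 in every baseline sample.** This is the only
  reading under which unique + common sum to the donor's total richness,
  and it is exposed as a fixed semantic, not an option.
* **The low-count filter runs first, on raw counts, over the whole run.**
  Features with a summed count below 3 across *all* samples loaded for an
  analysis (inocula + every recipient sample) are removed before any
  classification or normalization. Filtering after normalization would be
  meaningless (every column sums to 1), and per-subset filtering would let
  a feature be "present" in one stratum and "absent" in another on the
  same evidence. The threshold and its scope are arguments of
  `filter_low_count_features()`; the default scope is the merged run,
  which is the more conservative choice against falsely calling a taxon
  absent.
* **Detection floor.** Within a group at a timepoint, an ASV counts as
  engrafted if it reaches count ≥ 1 in ≥ 1 sample (the `floor` argument of
  `detect_engrafted_asvs()`). The global ≥ 3 filter already guards against
  singleton noise; a higher per-sample floor is available but not the
  default.

## The synthetic study generator

Real transplantation datasets require full upstream read processing, so
the package ships a generator (`synthetic_config()`, `simulate_study()`)
that emulates the targeted study design end to end with known ground
truth: two donor inocula (wild-boar-derived "WB" and sow-derived "Sow"),
four recipient groups (Control, Sow, WB, Mix) of 12 piglets, fecal
sampling at PND21 (baseline), PND27 and PND48, cecal sampling at PND48,
and a 70-metabolite cecal panel.

Defaults are the study's stated design parameters where stated: donor
richness 439 (WB) and 275 (Sow); 101 and 98 donor ASVs shared with the
recipient baseline pool; 42 donor-unique ASVs shared between donors; 12
piglets per group; an engrafted community share averaging 6.5%. Where the
design gives no value the defaults are fixed at what amplicon practice
would call realistic and are not revisited: mean depth 50,000 reads with
Poisson per-sample variation; log-normal(0, 1) latent relative abundances
renormalized and multinomially sampled; a baseline pool with 300
piglet-only ASVs at 0.5 per-piglet occupancy; engraftment probabilities
(WB←WB 0.31, Sow←Sow 0.32, Mix←WB 0.17, Mix←Sow 0.05, Control 0) chosen
to echo the detection fractions such experiments report.

Model choices worth knowing:

* **Engraftment is a group-level, per-ASV Bernoulli event.** A
  source-unique ASV either establishes in a recipient group or it does
  not; established ASVs appear in every piglet of the group from PND27
  on, with abundances redrawn independently per sample. No within-host
  dynamics between PND27 and PND48 are modelled — the study design gives
  no dynamic information, and anything richer would be invention.
* **Inoculum occupancy is guaranteed.** Every member ASV of an inoculum
  receives at least `inoculum_floor` (default 3) counts: a cultured,
  plate-pooled inoculum contains all of its members well above trace
  level, and this keeps the generator's membership sets exact at finite
  depth. Recipient samples have no such floor, so a planted resident ASV
  can legitimately go unobserved — the realistic failure direction
  (present but unsequenced).
* **The metabolome** is log-normal per metabolite with group shifts
  applied on the log scale, and one metabolite (`met01`) coupled to a
  planted engrafted taxon's relative abundance through a Gaussian copula
  (`r = 2 sin(pi * rho / 6)` inverts the bivariate-normal Spearman
  identity). Because the coupled taxon is absent (relative abundance 0,
  hence tied ranks) in groups where it never engrafted, the realized
  Spearman correlation is attenuated below the target when computed over
  all 48 samples; that attenuation is a property of zero-inflated
  abundance data, not a bug, and tests allow for it. Values below the
  per-metabolite LOD are emitted as missing.

What passing tests on this generator do **not** show: robustness to
compositional artifacts of real sequencing (primer bias, contamination,
batch effects), strain-level ambiguity below the ASV radius, or violations
of the per-ASV independence assumption. Conclusions about the code's
correctness transfer to real data; conclusions about statistical power do
not.

## Community statistics

The ecology statistics are implemented from first principles (the package
exists to make each step inspectable), with the conventions of the
standard ecology toolchain:

* **Rarefaction** subsamples without replacement (multivariate
  hypergeometric) to a common depth, by default the smallest sample sum;
  shallower samples are dropped with a warning. A seed is required — the
  draw is deterministic given it.
* **Alpha diversity**: observed richness, Shannon entropy with natural
  log (the ecology default; the base is an argument), Gini-Simpson
  1 − Σp². All are computed on proportions, so they are invariant to
  rescaling counts.
* **Kruskal–Wallis** uses midranks with the standard tie correction and a
  chi-square reference on k − 1 df; all-identical input is degenerate and
  returns H = 0, p = 1 by convention. **Dunn's** pairwise z statistics use
  the pooled tie-corrected variance, two-sided normal p-values, optional
  Benjamini–Hochberg adjustment.
* **Bray–Curtis** is Σ|x−y| / Σ(x+y) on raw counts by default (relative
  abundances by option).
* **PCoA** double-centers the squared distances (−½ J D² J) and keeps
  axes with positive eigenvalues, scaled by √eigenvalue. Negative
  eigenvalues are dropped and their total magnitude reported via
  `message()`; no Cailliez/Lingoes correction is applied — the simplest
  defensible default, and the dropped magnitude makes its cost visible.
  `proportion_explained` is relative to the positive-eigenvalue total.
* **PERMANOVA** partitions Σd² between and within groups, permuting raw
  labels without strata. The pen/litter structure of a real study is
  *not* honoured by the permutation scheme — a documented limitation, the
  price of a from-scratch implementation kept simple. p-values use the
  (x+1)/(N+1) estimator so they are never zero;
  `n_permutations = "exhaustive"` enumerates all label permutations for
  small n and then reports the exact permutation p including the
  identity.
* **Beta-dispersion (PERMDISP)** measures distances to group centroids in
  the positive-eigenvalue PCoA space and permutes those distances across
  groups around a one-way ANOVA F.

Numerical conventions used throughout: ties always get average ranks;
permutation comparisons use a 1e-12 slack so that ties at the observed
statistic count as at least as extreme; symmetric matrices are
symmetrized (d + t(d))/2 before eigendecomposition to absorb
floating-point asymmetry.

## Metabolome integration

* **Preprocessing** imputes missing concentrations as LOD/2, then
  log-transforms (natural log by default, log10 by option), then
  optionally autoscales each metabolite to mean 0, variance 1. Autoscaling
  is the default for PLS-DA, matching common metabolomics practice.
* **PLS-DA** is NIPALS PLS2 on a centered one-hot response, two
  components by default (the component count is an argument; the
  study-style default is deliberately small since discriminant components
  beyond the first few mostly fit noise at n ≈ 48). Weights are unit-norm
  per component, scores come out mutually orthogonal, and both blocks are
  deflated per component.
* **VIP** is the multi-component aggregate
  √(p · Σₐ SSYₐ w²ₐⱼ / Σₐ SSYₐ); the mean squared VIP is exactly 1, which
  the test suite asserts to 1e-9 on every fit. `top_vip()` reports the
  top-k (default 15) metabolites.
* **Spearman correlation** is Pearson on midranks with a two-sided t
  approximation; all pairs tested in one call form a single BH family
  (the heat-map convention), with significance marked at q < 0.01.
  Constant variables have undefined rho and are excluded from the family
  rather than diluting it.
* **Procrustes/PROTEST** is the symmetric form: both configurations
  centered and scaled to unit total sum of squares, rotation from the SVD
  of the cross-product, m² = 1 − (Σ singular values)², correlation
  √(1 − m²) — the identity is asserted to 1e-9 on every run. Significance
  permutes the rows of the second configuration. The intended inputs are
  the PCoA coordinate matrices of the two data sets, which is how the
  package interprets ordination-concordance analysis between a microbiome
  and a metabolome.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 1)
sim <- simulate_study(cfg)

filt <- filter_low_count_features(
  merge_feature_tables(list(sim$inocula, sim$baseline, sim$post)))
cls <- classify_inoculum_asvs(filt[, colnames(sim$inocula)],
                              filt[, colnames(sim$baseline)])
cls
#> provenance_classification
#>   donor n_total n_unique n_common
#> 1    WB     439      338      101
#> 2   Sow     275      177       98
#> shared unique ASVs across donors: 42

fisher_exact_two_sided(matrix(c(338, 101, 177, 98), 2, 2, byrow = TRUE))$p
#> [1] 0.0003084639

det <- detect_engrafted_asvs(filt, cls, sim$metadata,
                             group = "WB", source = "WB",
                             timepoint = "PND48", sample_type = "fecal")
summarize_engraftment_abundance(filt, det, sim$metadata,
                                "WB", "PND48", sample_type = "fecal")
#> engraftment_summary: WB @ PND48 — 100 ASVs detected; % of community
#> min 6.36, mean 6.56, max 6.67
```

## Problem sizes and validation scope

The test suite validates every statistic against an independent route:
exact integer enumeration for Fisher (all 2×2 tables with total ≤ 40),
brute-force permutation enumeration for PERMANOVA (n = 6), Gower's
embedding theorem for PCoA (Euclidean inputs reproduced to 1e-9),
`stats::kruskal.test`, `vegan::vegdist`, `vegan::adonis2`,
`vegan::betadisper`, `vegan::protest` and `stats::cmdscale` as external
oracles, and the generator's planted truth for the classification and
engraftment chain. Null-calibration checks use 1,000 replicates for
permutation p-value uniformity and 10,000 for the Kruskal–Wallis type-I
rate; the engraftment-probability recovery check uses 20 independent
study replicates at depth 5×10⁴. These sizes make the whole suite run in
well under a minute while leaving Monte-Carlo margins wide enough that
the assertions are not seed-lottery tickets.

## Known limitations

* Classification is presence/absence; a common ASV that also engrafted is
  invisible to the method (no Bayesian attribution of ambiguous ASVs).
* ASV identity is the resolution limit: strain-level transfer cannot be
  distinguished.
* PERMANOVA/PERMDISP permute freely; clustered designs (pen, litter)
  need restricted permutation, which is not implemented.
* The generator draws per-ASV engraftment independently; real engraftment
  is correlated through ecological interactions.
* Procrustes p-values, like all permutation p-values here, are bounded
  below by 1/(N+1).
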