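---
title: "Methods: paired rank-shift analysis of soil microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired rank-shift analysis of soil microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizorank)
```

`rhizorank` analyses OTU count tables from blocked factorial soil surveys:
α-diversity with factorial ANOVA, Bray-Curtis β-diversity with PERMANOVA and
NMDS, and a paired rank-abundance statistic (Δ_rank) for detecting taxa whose
dominance differs between whole soil and the rhizosphere. This vignette is
the package's account of the underlying models, the knobs that matter, and
the design decisions taken where more than one defensible choice existed.

## The data model

An `otu_table` couples a samples × taxa matrix of non-negative integer
counts with a seven-rank Greengenes-style lineage per taxon and a metadata
row per sample. The supported field designs are fully crossed:
`sim_design("2011")` is 3 topographic positions × 2 cropping systems ×
3 plots × 3 dates (54 whole-soil samples), and `sim_design("2012")` is
2 positions × 2 systems × 2 soil origins × 3 plots (24 samples, the paired
design the rank analysis needs).

## Preprocessing

Counts below a total of `min_count = 2` across all samples are removed
first; rarefaction follows, then taxonomic collapsing. Rarefaction draws a
uniform subsample *without replacement* from each sample's reads down to
`depth` (default 6678 reads, a realistic lower bound for a filtered MiSeq
run), so each taxon's subsampled count is exactly multivariate
hypergeometric and its expected proportion is unchanged. One seeded draw is
taken per sample; repeated-draw averaging is deliberately not offered — a
single rarefied table keeps every downstream statistic an honest function of
one realized dataset. Samples shallower than `depth` are dropped (or, with
`drop_small = FALSE`, raise an error).

Collapsing at a rank sums counts over all taxa sharing the lineage prefix up
to that rank. Taxa unassigned at the rank are kept as explicit
`unclassified_<parent>` groups, one per parent prefix: discarding them would
break per-sample count conservation and bias evenness downward. The
collapse-before/after-rarefaction order is not dictated by anything in the
statistics; the pipeline rarefies OTUs first and collapses second, so that
the rarefied table is shared by every downstream analysis.

## α-diversity and ANOVA

Richness is the count of observed taxa; Shannon's H′ uses natural logarithms
by default (configurable — community ecology has used both e and 2, and the
choice only rescales H′); Pielou evenness J′ = H′/ln S is undefined below
two taxa and reported as `NA`. `fit_alpha_anova()` fits the full crossing of
the design factors by fixed-effects least squares and prunes interactions
iteratively: among interactions not marginal to a retained higher-order
term, the one with the largest p-value above `prune_alpha = 0.1` is dropped,
highest order first, and the model refit until none qualifies. Main effects
are never pruned. Sums of squares are sequential (Type I), which coincides
with all other types under the balanced designs generated here. No response
transformation is applied by default; a z-score option exists because
published workflows sometimes standardize diversity indices before ANOVA —
F and p are invariant to that, so the option only changes effect-size
scales. Tukey's HSD runs on retained factors with three or more levels.
Block/plot is not modelled as a random effect: at three replicates the
mixed model buys nothing and costs the Tukey machinery.

## β-diversity

Bray-Curtis dissimilarity D_xy = Σ|x−y| / Σ(x+y) is computed on rarefied
counts; on tables with unequal totals the default switches to proportions,
otherwise library size would masquerade as composition (this matters for the
un-rarefied robustness re-run, `unrarefied: true` in the pipeline config).
PERMANOVA partitions the Gower-centred distance sums of squares over the
sequential model terms; each term's pseudo-F is referred to free permutation
of sample labels with the add-one convention p = (1 + #{F* ≥ F}) / (1 +
n_perm), so p is never zero and is bounded below by 1/(n_perm+1). The same
α > 0.1 interaction-pruning protocol as the ANOVA applies. A
`strata` argument restricts permutations within blocks when the design
demands it; the default is free permutation because the final models carry
no block term. NMDS minimizes Kruskal stress-1 over `n_restarts = 20` random
starts (best solution reported, non-convergence warned); stress below ~0.1
is conventionally a good embedding.

## The Δ_rank statistic

Within every cropping system × topographic position × plot cell holding
exactly one whole and one rhizosphere sample, taxa are ranked by abundance
over the union of taxa present in either member (rank 1 = most abundant;
ties, including all absent taxa, get average ranks, which keeps rank sums
exactly T(T+1)/2 and the statistic exactly antisymmetric under label
swaps). Then Δ_rank = rank_rhizosphere − rank_whole, so positive values mean
higher standing in whole soil. A `universe = "global"` option ranks over all
taxa in the table instead; the pair-union default reflects that a taxon
absent from both members of a pair carries no pairwise information.

Per-plot Δ_rank values are bootstrapped within strata (cropping system ×
position): each of `B = 10000` resamples redraws every stratum with
replacement and recomputes the mean. Two reporting units are emitted: one CI
per taxon per topographic position (pooling the two cropping systems after
stratified resampling — the default, matching the "consistent on both
positions" style of claim), and per-stratum tables via `by = "stratum"`. The
statistic defaults to the mean; the median is available.

### Why the default interval is a bootstrap-t

With 6 pairs per reporting unit, interval choice dominates the operating
characteristics. Monte-Carlo measurement on iid normal values (n = 6, two
strata of 3, nominal 95%) gives a false-positive rate for "CI excludes 0" of
roughly **20%** for the plain percentile interval and **13%** for
Hesterberg's expanded percentile — both far off nominal, and enough to
swamp a taxon list with spurious calls. The studentized (bootstrap-t)
interval, in which each resample's mean is studentized by its own stratified
standard error, measures at **2–3%**: slightly conservative, which is the
right side to err on for an un-corrected per-taxon screen (no
multiple-testing correction is applied across taxa, by design — the
procedure is a screen, not a confirmatory test). All three are available via
`ci_type`; all collapse to the point interval [c, c] on constant data, so a
uniformly shifted taxon is still called. Degenerate resamples (zero resample
SE with a shifted mean) are assigned a capped t of ±1e12; if such resamples
reach the quantile being read, the corresponding interval side is reported
as unbounded (`±Inf`) rather than as a fabricated finite bound. `B < 100` is
refused outright.

Orders significant at the order level are drilled down: the analysis is
repeated at family and genus rank restricted to each order's descendant
lineages. An order with a single family yields a one-taxon family analysis
and is reported as such (flagged degenerate when fewer than two pairs
contribute), not suppressed.

## The synthetic-data generator

The generator exists so that every pipeline stage is testable against known
truth. Per sample: the base composition is perturbed by (i) a lognormal
plot-level offset (sd `plot_sigma = 0.25` on the log scale) shared by the
whole/rhizosphere pair — this is what makes the pairing informative — and
(ii) any planted fold effects whose factor level matches the sample; the
result is renormalized, true proportions are drawn from a Dirichlet with
that mean and total concentration `concentration = 200`, and counts are
multinomial at a library size uniform on [6678, 23359], the span typical of
a filtered MiSeq run. The default taxonomy is 30 orders × 2 families ×
2 genera × 2 OTUs with geometric base decay 0.88 between successive orders
(and 0.7 within the nested levels).

Two generator constants were calibrated jointly, once, against the
recovery harness the package promises to pass (a 5-fold enrichment of one
mid-rank order must be detected in ≥80% of replicate 24-sample datasets
while unperturbed orders stay below a 10% flag rate): the 0.88 order decay
makes a 5-fold change worth log(5)/log(1/0.88) ≈ 13 rank positions, and
concentration 200 sets between-replicate rank noise of a few positions —
enough to wash out the ±1 "displacement" shifts that a large planted effect
mechanically imposes on bystander taxa (ranks are relative: when one taxon
jumps 13 places, 13 others slip one), without obscuring the planted signal.
Measured under these conditions: ~93% detection at fold 5, ~4% null flag
rate, detection monotone over folds {1, 2, 5}.

What the generator does **not** emulate: phylogenetic correlation among
taxa, sequencing error, chimeras, zero-inflation beyond the multinomial, and
taxon-specific dispersion. Passing the recovery tests therefore shows the
procedure works when its assumptions hold — it does not certify performance
on real soil data, where overdispersion is heavier-tailed and effects are
not single-taxon.

A subtlety worth recording: the plot-level offset makes samples
cluster-correlated, so a *free-permutation* PERMANOVA of a between-plot
factor (e.g. cropping system) is anticonservative under the generator's null
(~24% measured at α = 0.05) — textbook pseudo-replication, not an
implementation defect. The type-I calibration of the PERMANOVA machinery is
therefore run with `plot_sigma = 0` (iid samples, genuinely exchangeable
labels), where the measured size sits inside the binomial 99% band around
0.05; analyses of real blocked designs should pass `strata` when testing
between-block factors.

## Reproducibility and problem sizes

Every stochastic step (simulation, rarefaction, permutations, bootstrap,
NMDS restarts) accepts a seed; `run_pipeline()` derives one seed per stage
from a single master seed, so a config file plus one integer reproduces the
entire output bundle byte-for-byte. The test suite exercises the pipeline at
the design's native sizes — 24 samples, 30 orders, 9999 permutations, 10,000
bootstrap resamples for single runs — and scales replication (200 recovery
replicates at B = 1000; 1000 null datasets at 999 permutations; 20,000
rarefaction draws) so the whole suite completes in minutes on one CPU.

## Known limitations

* Δ_rank inference treats plots as the unit of replication; with 3 plots per
  stratum the bootstrap-t is the only interval here with usable calibration,
  and it is mildly conservative.
* No multiple-testing correction across taxa; interpret the per-taxon flags
  as a screen and require consistency across positions for enrichment
  claims.
* Free permutation is the PERMANOVA default; use `strata` for between-block
  factors in genuinely blocked data.
* BIOM support covers JSON v1.0 only (no HDF5), matching the package's
  classic-TSV era.
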