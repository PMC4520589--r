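# rhizorank

Community-structure analysis for paired whole-soil / rhizosphere 16S
amplicon surveys from blocked factorial field designs.

Soil microbiologists comparing cropping systems across a topographic
gradient routinely ask two questions of an OTU table: do the usual summary
statistics (α-diversity, Bray-Curtis β-diversity) respond to the design
factors, and — more pointedly — *which* taxa change their standing in the
community when a plant root is nearby? Compositional tests can miss the
second kind of change: a taxon may move several positions up the dominance
hierarchy while barely moving the community-wide dissimilarity. `rhizorank`
implements a rank-based statistic for exactly that contrast, embedded in a
complete, reproducible pipeline.

## The Δ_rank statistic

Within each field plot sampled twice — once as bulk ("whole") soil, once as
rhizosphere soil — taxa are ranked by abundance (rank 1 = most abundant,
average ranks for ties, taxa observed in either member of the pair form the
ranking universe). For each taxon *t* and plot *p*,

```
Δ_rank(t, p) = rank_rhizosphere(t, p) − rank_whole(t, p)
```

so Δ_rank > 0 means the taxon is more dominant (numerically smaller rank) in
the whole soil, and Δ_rank < 0 means it is more dominant in the rhizosphere.
Per-plot values are resampled with replacement within each cropping system ×
topographic position stratum; the bootstrap distribution of the mean gives a
95% confidence interval per taxon and topographic position (a studentized
bootstrap-t interval by default — see the methods vignette for why the plain
percentile interval misbehaves at n = 6). A taxon whose interval excludes 0
is called enriched on the corresponding side. Significant orders are drilled
down: the same analysis is repeated at family and genus level within their
descendant lineages.

Around the statistic the package provides:

* **IO** — classic QIIME-style OTU TSV and BIOM-JSON v1.0, plus sample
  metadata TSV (`read_otu_table()`, `write_otu_table()`).
* **Preprocessing** — minimum-count filtering (default: total count ≥ 2),
  rarefaction by subsampling without replacement (default depth 6678),
  taxonomic collapsing with explicit unclassified groups
  (`filter_min_count()`, `rarefy()`, `collapse_taxonomy()`).
* **α-diversity** — richness, Shannon's H′, Pielou evenness, full-factorial
  ANOVA with iterative pruning of non-significant interactions (α > 0.1) and
  Tukey HSD (`alpha_diversity()`, `fit_alpha_anova()`).
* **β-diversity** — Bray-Curtis dissimilarity, multi-factor PERMANOVA with
  9999 permutations and the same pruning rule, NMDS ordination
  (`bray_curtis()`, `permanova()`, `nmds()`).
* **Simulation** — a Dirichlet-multinomial generator reproducing the two
  supported designs (54-sample within-season; 24-sample paired
  whole/rhizosphere), with plot-level compositional offsets shared within
  pairs and plantable fold effects, so every claim the package makes is
  testable against known truth (`sim_design()`, `sim_params()`,
  `generate_dataset()`).
* **Orchestration** — `run_pipeline()` drives every stage from one config
  (YAML or list) and a single master seed, writing tidy TSV tables.

Results are tibbles or small S3 objects with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Simulate the 24-sample paired design with a 5-fold rhizosphere enrichment
planted in one mid-abundance order, preprocess exactly as a practitioner
would, and run the rank analysis:

```r
library(rhizorank)

sim <- generate_dataset(
  sim_design("2012"),                                  # 2 positions x 2 systems x 2 origins x 3 plots
  sim_params(effects = sim_effect("Order15", fold = 5)),
  seed = 42
)
counts <- sim$table |>
  filter_min_count(2) |>
  rarefy(depth = 6678, seed = 42)

result <- delta_rank(counts, level = "order", B = 10000, seed = 42,
                     drilldown = TRUE)
result
#> <delta_rank_result> level = order, B = 10000, conf = 0.95
#> 30 taxa tested; 3 significant in >=1 unit
#>     taxon topographic_position n mean_delta  ci_lo ci_hi significant
#> 1 Order06               summit 6       3.17   1.75   Inf        TRUE
#> 2 Order15               summit 6     -10.42 -16.88 -1.91        TRUE
#> 3 Order15             toeslope 6     -13.17 -22.80 -3.32        TRUE
#> 4 Order19               summit 6       7.17   2.76 10.53        TRUE
#> (positive delta_rank = higher rank in whole soil; negative = higher rank in rhizosphere)
```

The planted order is recovered with the right sign on **both** topographic
positions: `Order15` sits on average 10–13 rank positions higher (more
dominant) in the rhizosphere than in the paired whole soil, and its interval
is well clear of zero. The two other flags are single-position calls of the
kind a 95% interval produces occasionally; requiring consistency across both
positions — the sensible rule for a claim of general enrichment — leaves
only the planted order. An `Inf` bound means the bootstrap could not bound
that side (too many degenerate resamples), which never creates a
significance call on its own.

The companion tests on the same data:

```r
d <- bray_curtis(counts)
permanova(d, counts$metadata,
          c("cropping_system", "topographic_position", "soil_origin"),
          n_perm = 9999, seed = 42)
#> <permanova> 9999 permutations
#>                   term df  sumsq r.squared statistic p.value
#> 1      cropping_system  1 0.1079   0.03941    0.9372  0.6462
#> 2 topographic_position  1 0.1150   0.04199    0.9986  0.4872
#> 3          soil_origin  1 0.2124   0.07757    1.8446  0.0001
#> 4             Residual 20 2.3034   0.84103        NA      NA
#> 5                Total 23 2.7388   1.00000        NA      NA
```

The planted taxon shifts whole-community composition too (soil_origin
p = 1e-4, the add-one minimum at 9999 permutations), but explains only ~8%
of the distance variance — the rank analysis tells you *who* moved.

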