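# phyllonet

Community-structure analysis for seasonal phyllosphere (leaf-surface) and
air 16S rRNA OTU tables. The package takes a count matrix of OTUs by
samples — nine plant-species habitats sampled in summer and winter plus an
air sample per season, in the reference design — and carries it through the
full analysis a phyllosphere ecologist would run:

- **Normalisation**: singleton removal, rarefaction without replacement to
  a common depth, exclusion of chloroplast and domain-unclassified OTUs.
- **Alpha diversity**: richness, Shannon *H*, Simpson *1−D*, Pielou *J*,
  with paired summer/winter t-tests by habitat (and per-taxon variants).
- **Niche structure**: abundant (>1% of all reads) / rare (<0.1%) classes,
  habitat occupancy (universal vs single-habitat OTUs), and Levins niche
  breadth
  *B*<sub>j</sub> = 1 / Σ<sub>i</sub> *p*<sub>ij</sub>², where
  *p*<sub>ij</sub> is the share of OTU *j*'s reads in sample *i*:
  generalists at *B*<sub>j</sub> > 10, specialists at *B*<sub>j</sub> < 5.
- **Community clustering**: Bray–Curtis dissimilarities, group-average
  (UPGMA) dendrograms with percent-similarity cuts, and SIMPER
  decomposition of within-group similarity into additive per-OTU
  contributions (between-group decomposition included).
- **Co-occurrence networks**: Maximal Information Coefficient (MIC)
  between OTU abundance vectors — computed *exactly* over all admissible
  grid partitions at these sample sizes, with the classical
  equipartition heuristic as an option — thresholded at MIC > 0.5 with a
  positive rank-correlation requirement; twelve Cytoscape-style topological
  parameters; uniform G(n,m) random-graph nulls.
- **Synthetic communities**: a generator that plants generalist /
  specialist / intermediate roles, seasonal richness enrichment, and
  optional summer association blocks, with ground truth for recovery
  scoring — so the whole pipeline is testable end to end without
  external data.

## Worked example

```r
library(phyllonet)

sim <- generate_community(synthetic_config(seed = 1))
tab <- sim$table
tab
#> <otu_table> 613 OTUs x 20 samples (100,760 reads)
#> samples:
#>        summer winter
#>   air       1      1
#>   leaf      9      9

div  <- diversity_profile(tab)
seasonal_diversity_comparison(div)
#>   attribute summer_mean summer_se winter_mean winter_se    df      t     p
#> 1 richness       71.3       4.22       54.1       2.19      8  4.79  0.001
#> 2 shannon         2.15      0.1         2.03      0.064     8  1.01  0.34
#> 3 simpson         0.729     0.028       0.727     0.019     8  0.07  0.946
#> 4 pielou          0.505     0.018       0.509     0.013     8 -0.156 0.88
```

Summer leaves carry significantly more OTUs than winter leaves
(paired t-test over the nine habitats, df = 8), while evenness-weighted
indices barely move — the planted seasonal effect is a richness effect,
carried by specialists active only in summer.

```r
niche <- levins_index(tab)
dplyr::count(niche, category)
#>   category         n
#> 1 generalist      10
#> 2 intermediate    23
#> 3 specialist     580

recovery_report(sim$truth, niche)$roles
#>   class         tp    fp    fn precision recall
#> 1 generalist    10     0     0     1          1
#> 2 specialist   526    33     0     0.941      1
```

All ten planted generalists are recovered with no false calls; specialist
calls are >94% precise (the false positives are intermediate-breadth OTUs
whose few sampled reads happened to concentrate). Unit conversions for
airborne bacterial load follow the air-density quotient:

```r
air_copies_per_gram(2.45e6)   # copies m^-3 over 1250 g m^-3
#> [1] 1960
```

The one-call orchestrator runs every stage and writes all tables,
Newick trees, GraphML networks and a manifest:

```r
res <- run_pipeline(pipeline_config(simulate = synthetic_config(seed = 1)),
                    out_dir = "results/run1")
pipeline_consistency_check(res)
```

## Documentation

The methods vignette (`vignettes/phyllonet-methods.Rmd`) describes the
models and procedures, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical conventions. Function-level documentation is in the
roxygen comments in `R/`.
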