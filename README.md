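# MucosaNet

Co-occurrence network analysis of lung mucosa-colonizing bacteria, built
for studies that relate the community structure of the lower-airway
microbiome to clinical features of non-small cell lung cancer (NSCLC) —
in particular metastasis. Starting from a genus-level taxon × sample count
table, the package

- subtracts negative-control (pure water) sequencing counts from every
  sample to remove reagent/kit contamination;
- infers, per clinical stratum (healthy / NSCLC / metastatic / …), a signed
  co-occurrence network over the top-50 genera from Spearman rank
  correlations, keeping an edge only when |ρ| ≥ 0.5 **and** a
  resampling-based p-value (999 permutations by default) is < 0.05;
- partitions the positive-edge subgraph into bacterial communities under
  three principles — a community is a densely connected net, every member
  correlates positively with at least one co-member, and no positive edge
  joins two communities — and matches the result to the four reference
  communities via their core member lists;
- compares per-community degree counts across strata with pooled
  two-sample t-tests;
- tests differential abundance (Wilcoxon rank-sum with Benjamini–Hochberg
  FDR; multiple t-tests with the Benjamini–Krieger–Yekutieli two-stage
  step-up as an alternative), Shannon/Chao1 alpha diversity, and
  Bray–Curtis / PCoA / PERMANOVA beta diversity;
- correlates taxon abundances with peripheral-blood clinical factors
  (immune-cell densities, cancer-marker concentrations) per stratum,
  exporting the |r| > 0.5 & p < 0.05 masked matrix and the bipartite
  taxon–factor network;
- ships a planted-structure synthetic cohort generator (four correlated
  genus blocks, cohort effects, factor couplings, a contaminant profile)
  so the entire pipeline is testable without sequencing data.

The model at the core: for taxa *i*, *j* with relative abundances
*x_i*, *x_j* over the samples of a stratum, the edge statistic is the
Spearman rank correlation ρ(*x_i*, *x_j*); its significance comes from an
exchangeable permutation null, p = (1 + #{b : |ρ_b| ≥ |ρ_obs|}) / (B + 1)
(exact enumeration over all n! permutations when n! ≤ B). Communities are
the connected components (≥ 2 nodes) of the positive subgraph of the
filtered network, which is the unique parameter-free reading under which
the three principles above hold simultaneously.

## Worked example

```r
library(MucosaNet)

spec <- syntheticSpec(seed = 1)          # the default emulated cohort
ds   <- generateDataset(spec)            # counts, metadata, factors, control

tab  <- subtractControl(ds$table, ds$control)
rel  <- selectTopTaxa(toRelative(tab), 50)
nsclc <- selectStratum(ds$metadata, cohort = "NSCLC")

net <- buildNetwork(rel, samples = nsclc,
                    config = correlationConfig(seed = 1), stratum = "NSCLC")
net
#> TaxonNetwork [NSCLC]: 50 nodes, 188 edges (188 positive, 0 negative)

asg <- matchToReference(partitionCommunities(net), referenceCores())
asg
#> CommunityAssignment: 4 communities, 40/50 taxa assigned
#>   sizes: 1=14, 2=12, 3=8, 4=6
#>   core matches: 1->community 2(6), 2->community 1(3), 3->community 4(3), 4->community 3(3)

degreeTable(degreeSummary(net, asg))
#>   community  n mean_degree
#> 1         1 14   12.000000
#> 2         2 12   11.000000
#> 3         3  8    6.000000
#> 4         4  6    4.666667
```

The four detected communities are exactly the four planted genus blocks:
the largest (14 members, mean degree 12.0) is matched to reference
community 2 through 6 core members, and the 10 uncorrelated background
taxa stay unassigned. Summary statistics and group tests reproduce
published-style cohort tables from (mean, SD, n) triples:

```r
groupSummaryFromStats(1.30, 0.52, 26, variable = "lymphocytes", group = "no_met")
#>      variable  group  n mean   sd ci_low ci_high level
#> 1 lymphocytes no_met 26  1.3 0.52   1.09    1.51  0.95

p <- twoSampleTFromStats(1.30, 0.52, 26, 1.61, 0.55, 29)
#> t = -2.141, df = 53, p = 0.0369
```

i.e. the 95% confidence interval (1.09, 1.51) for lymphocyte density in
non-metastatic patients and a significant metastatic increase (p ≈ 0.037).

The whole analysis can also be driven by one call (or from a shell via
`inst/scripts/run-pipeline.R`):

```r
report <- runPipeline(defaultRunConfig(outdir = "run1", seed = 1))
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end analysis on the
default synthetic cohort from scratch (generation → decontamination →
top-50 selection → per-stratum networks → community partition and
reference matching → degree comparison → differential abundance →
diversity → taxon–factor correlation) under a caller-supplied seed:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
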