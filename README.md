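# defensome

Tools for surveying the antiviral defense repertoires (*defensomes*) of
prokaryotic genome cohorts, with a focus on the methodological gaps that
bite hardest in Archaea: restriction-modification (RM) systems that
architecture-rule annotation tools under-call, prevalence estimates that
depend on assembly completeness, and presence/absence models that separate
when rare systems meet small phyla.

## Who this is for

Comparative genomicists and microbial ecologists who have per-genome
defense-system annotations (Padloc/DefenseFinder-style call tables), protein
FASTA + GFF3 gene annotations, and genome metadata (domain, phylum, size,
completeness, optimal growth temperature), and who want domain- or
phylum-scale statistics out the other end — plus a synthetic-cohort
generator with recorded ground truth so every step can be validated.

## What it computes

**RM system calling.** Query proteins are assigned to a REBASE-style
reference catalogue by filtered best hit (identity ≥ 0.65; coverage of both
query and target ≥ 0.8; lowest e-value wins, ties broken deterministically).
Assignments claimed by a non-RM call from an external tool are removed.
Each remaining restriction-nuclease anchor's ±5-gene neighborhood is tested
against per-type architecture rules:

- Type I: type-I R anchor + type-I M and S in the window
- Type II / III: type-matched R anchor + M
- Type IV / IIG: the single-protein module alone

Anchors are processed left to right; calls consume their genes, so calls are
disjoint and deterministic. RM calls then replace the external tool's RM
rows in the merged per-genome defensome (`DMS`/`VSPR` rows are discarded as
non-defense categories), from which the package computes prevalence,
core-defensome (top-20 per domain) membership, defenseless fractions and
per-Mb densities.

**The statistical battery.** Wilson score intervals; Firth bias-reduced
logistic regression (Newton iteration on the modified score, maximizing
`l(b) + 0.5 log det I(b)` — finite estimates under separation);
phylum-versus-overall-mean prevalence contrasts with Benjamini–Hochberg
adjustment; completeness-adjusted prevalence extrapolated to fully complete
genomes via logistic regression and inverse-logit–transformed Wald
intervals; log-link negative-binomial GLMs of defense counts (effects
reported as percent change per 10 °C, `100(exp(10*beta) - 1)`); hurdle
models with a zero-truncated NB count part; Nagelkerke pseudo-R²; Spearman
correlation, size-regression residual tests, two-block variance
partitioning by adjusted R²; OGT binning with Kruskal–Wallis + Dunn tests.

Fitted objects support `tidy()` and `glance()`; result types have
`plot_*()`/`autoplot()` builders.

## Worked example

```r
library(defensome)

cfg <- defensome_config(
  output_dir = file.path(tempdir(), "survey"), seed = 42,
  n_genomes = 20, cohort = cohort_config(n_per_domain = 1000)
)
res <- run_all(cfg)

res$detect$metrics
#> # A tibble: 1 × 5
#>      tp    fp    fn precision recall
#>   <int> <int> <int>     <dbl>  <dbl>
#> 1   100     0     0         1      1

res$stats$count_models$nb_ogt$percent_change_per_10c
#> [1] 34.15786

dplyr::filter(res$stats$completeness_adjusted, system_name == "CRISPR-Cas")
#> # A tibble: 2 × 5
#>   system_name domain   prevalence_at_1 ci_low ci_high
#> 1 CRISPR-Cas  Archaea            0.529  0.476   0.582
#> 2 CRISPR-Cas  Bacteria           0.413  0.379   0.448
```

Reading the output: the 20 simulated genomes carried 100 planted RM operons
(one of each of the five types per genome), and the caller recovered every
one with no false calls. The simulated cohort plants a +35.7% change in
defense counts per 10 °C of growth temperature; the NB-GLM refit estimates
+34.2% on this draw. The CRISPR-like system is generated with 55% archaeal
prevalence at full completeness but is observed at ~33% because archaeal
completeness averages 0.85; the completeness-adjusted model extrapolates
back to 52.9% (CI 47.6–58.2%), covering the planted truth.

Stage outputs (reference FASTA, per-genome FASTA/GFF3, call tables, cohort
tables, contrast and model reports, a manifest with the config hash) land
under `cfg$output_dir`; everything is a pure function of (config, seed).

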