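---
title: "Methods: surveying prokaryotic defensomes with homology-based RM calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying prokaryotic defensomes with homology-based RM calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defensome)
```

## What this package models

Prokaryotic genomes carry repertoires of antiviral defense systems — their
*defensomes* — dominated by restriction-modification (RM) and CRISPR-Cas,
with a long tail of rarer systems (CBASS, viperins, abortive-infection
modules, single-gene candidates). Domain-scale surveys of these repertoires
face three methodological problems this package addresses as reusable,
tested components:

1. **RM systems are under-called by architecture-rule annotation tools.**
   A homology route against a curated restriction-enzyme catalogue
   (REBASE-style) recovers many more systems, but raw best hits must be
   disciplined by gene-neighborhood rules to avoid calling isolated
   methyltransferases or mislabelled proteins as full systems.
2. **Observed prevalence depends on assembly completeness.** Most archaeal
   genomes are metagenome-assembled and incomplete, so presence/absence
   must be modelled with completeness as a covariate and extrapolated to
   fully complete genomes.
3. **Presence of rare systems in small phyla separates logistic fits.**
   Bias-reduced (Firth) logistic regression keeps estimates and standard
   errors finite, so phylum-versus-overall-mean contrasts remain usable.

Because the real inputs (tens of thousands of genomes, a licensed enzyme
catalogue) are not shippable, the package includes a first-class synthetic
data generator with recorded ground truth. Every claim the test-suite makes
is a claim about recovery of quantities the generator planted.

## The RM caller

### Homology assignment

Query proteins are matched to catalogue entries carrying an RM *type*
(I, II, III, IV, IIG) and *role* — restriction endonuclease (R),
methyltransferase (M), specificity subunit (S, Type I only), or a
single-protein module (Types IV and IIG). A hit survives when

- identity ≥ 0.65, and
- coverage of **both** query and target ≥ 0.8 (the both-sided convention
  of `cov_mod 0` in tabular search tools).

Among a query's surviving hits the lowest e-value wins; without e-values
(the internal aligner) the highest score wins, with ties broken by score
then lexicographically smallest reference id, so assignment is invariant to
input order. One assignment per protein.

The internal aligner (`align_identity()`) is a global Needleman–Wunsch with
affine gaps (BLOSUM62, open 11, extend 1). Identity is matches over
alignment columns excluding terminal gaps, which approximates the identity
a local search tool reports on these globally alignable stand-ins; coverage
comes from the non-terminal-gap span. `compute_hits()` screens candidate
pairs with a shared 4-mer prefilter (`min_kmer_share = 0.05`) before
aligning, as real search tools do: random unrelated proteins share
essentially no 4-mers, while homologs at the thresholds of interest
(≥ 0.6 identity, where 0.6^4 ≈ 13% of 4-mers survive untouched) are far
above the screen. A 14-column BLAST-tab reader (`parse_hit_table()`)
accepts external search output instead.

### Neighborhood rules

Anchors are assigned restriction nucleases (role R) and IIG/IV modules.
For each anchor, the ±5-gene neighborhood on its (linear) contig is
scanned and a call is emitted when the type's architecture rule is met:

| Type | rule |
|------|------|
| I    | type-I R anchor with type-I M **and** S in the window |
| II   | type-II R anchor with type-II M |
| III  | type-III R anchor with type-III M |
| IV   | type-IV module alone |
| IIG  | type-IIG module alone |

Components are drawn only from genes assigned to the anchor's own type; a
type-III M never completes a type-II anchor. Anchors are processed left to
right by coordinate and a successful call *consumes* its genes, so component
sets of distinct calls are disjoint and two R anchors flanking one M yield
exactly one call. The nearest eligible component wins, ties resolved
upstream. These three conventions (greedy left-to-right consumption,
nearest-component, type-restricted components) are design choices: locality
is the premise of the window rule, and greedy consumption is the simplest
rule that makes calls deterministic and disjoint. Modules still form their
own single-gene calls when they sit inside another anchor's window, since
their rule is "module alone".

Proteins claimed by an external tool's **non-RM** call are removed before
anchoring (the architecture evidence wins); proteins inside external RM
calls are kept, since the homology route replaces exactly those.

### Defensome aggregation

External call tables are filtered of `DMS` rows (DNA-modification proteins
that do not form complete systems) and `VSPR` rows (not defense systems),
then merged with the homology RM calls: for genomes on the REBASE path the
tool's RM rows are dropped and replaced; non-RM rows pass through
untouched. `summarize_cohort()` produces the per-genome count table —
`total_systems` counts every occurrence, `distinct_types` counts systems
present — and downstream summaries: per-domain prevalence (a system counts
once per genome regardless of copy number), the top-20-per-domain *core
defensome* (ties broken by total occurrences, then name), the fraction of
genomes defenseless beyond RM and CRISPR-Cas, and per-Mb density.

## The statistical battery

- **Wilson intervals** (`wilson_ci()`) for prevalence fractions.
- **Firth bias-reduced logistic regression** (`firth_logistic()`):
  Newton iteration on the modified score
  \(U^*(\beta) = X^\top(y - \mu + h(1/2 - \mu))\), where \(h\) is the hat
  diagonal, maximizing \(\ell(\beta) + \tfrac12 \log\det I(\beta)\), with
  step-halving on penalized-likelihood decrease, tolerance 1e-8 on the
  score max-norm, and at most 100 iterations. On a 2×2 table the slope
  equals the log odds ratio after adding ½ to every cell, which the tests
  exploit as a closed-form oracle alongside direct numerical maximization.
- **Phylum contrasts** (`phylum_contrasts()`): cell-means Firth fit of
  presence on phylum, so each coefficient is a phylum's prevalence on the
  logit scale; each phylum is contrasted against the *unweighted* mean of
  the phylum means on the link scale (the conventional estimated-marginal-
  means behaviour; the weighting is a documented choice) with a Wald z
  test, Benjamini–Hochberg adjustment across phyla within each system
  (adjustment pools within a model, not across systems — exposed by
  calling `bh_fdr()` yourself if pooling is wanted), and phyla under 10
  genomes excluded.
- **Completeness extrapolation**
  (`completeness_adjusted_prevalence()`): ordinary logistic fit of
  presence on completeness and domain, predictions at completeness 1 with
  Wald intervals built on the logit scale and inverse-logit transformed.
  Separation raises an error directing the caller to the Firth routine.
- **Count models**: `nb_glm()` (log-link negative binomial, via the
  alternating IRLS/theta-ML fit of `MASS::glm.nb`) with effects reported
  as percent change per 10 °C, `100(e^{10\beta} - 1)`; `hurdle_nb()`
  fits a logistic zero part plus a zero-truncated NB likelihood on the
  positives (each NB term divided by \(1 - P(0;\mu,\theta)\)), maximized
  numerically by BFGS with a Nelder–Mead polish; `nagelkerke_r2()`
  rescales the Cox–Snell pseudo-R². The theta of the truncated part is
  optimized on the log scale, keeping it positive.
- **Genome-size analyses**: Spearman correlation, OLS of counts on size
  with a rank-sum test of residuals between domains (large-sample form),
  and `varpart_two()`, a two-block variance partition from adjusted R² of
  the three OLS fits. Components sum to one by construction; adjusted R²
  can make individual components slightly negative and such values are
  passed through, not clamped (the convention of the reference
  partitioning tool, against which a test cross-checks numerically).
- **Thermal categories**: `bin_ogt()` uses mesophilic (< 50 °C),
  thermophilic [50, 80), hyperthermophilic (≥ 80 °C). The 50 °C boundary
  is assigned to thermophiles (a documented half-open convention), and
  values below 25 °C — outside the usual category definitions — are
  classified mesophilic. `kruskal_dunn()` runs the tie-corrected
  Kruskal–Wallis omnibus test with Dunn's pairwise z tests and Bonferroni
  correction.

## The synthetic-data generator

Two generators cover the two halves of the pipeline.

**Genome-level** (`plan_genome()`, `generate_genome()`,
`simulate_rm_cohort()`): genomes are one linear contig of non-overlapping
CDSs in coordinate order. Planted RM operons are contiguous by default,
with up to two decoy genes interleavable inside the operon (spread across
the gaps so every component stays within the anchor's window — this is what
the window rule must tolerate). RM components are catalogue entries mutated
to an exact planted identity: `mutate_to_identity()` substitutes exactly
`round((1 - t) L)` positions, so a 100-residue protein at `t = 0.70` has
exactly 70 matching positions. Decoys are uniform random sequences over the
20-letter alphabet; there is no codon model because the pipeline is
protein-level throughout. Assembly incompleteness is modelled as
independent per-gene dropout (`apply_incompleteness()`), matching the
per-gene granularity of every downstream rule; whether real MAG
incompleteness is better described by contig truncation is unknown, and
gene-level loss is recorded as a modelling assumption. Each genome draws
its own RNG stream from (master seed, genome index), so cohorts are
reproducible regardless of generation order. `emit_tool_calls()` emulates
the external annotation table: planted non-RM systems, `DMS`/`VSPR` decoy
rows, and a configurable subset of the true RM systems mimicking a weaker
tool, so the merge policy is exercised.

**Cohort-level** (`cohort_config()`, `generate_cohort()`): per-genome
covariates and responses with all generating coefficients recorded.
Defaults encode the study conditions the package documents:

- completeness `0.5 + 0.5 Beta(2.38, 1)` (Archaea, mean 0.852) and
  `0.5 + 0.5 Beta(10.4, 1)` (Bacteria, mean 0.956);
- OGT mixtures — Archaea 60% mesophiles N(35, 8), 30% thermophiles
  N(65, 7), 10% hyperthermophiles N(85, 4); Bacteria N(30, 6);
- log-normal genome sizes with means 1.8 Mb (Archaea) and 3.8 Mb
  (Bacteria);
- total counts NB with log link: `beta_ogt = log(1.357)/10` (+35.7% per
  10 °C), `beta_log_size = 1`, dispersion `theta = 2`, small per-phylum
  offsets (DPANN-like lineage −0.4), and intercepts solved so mean totals
  land near 6.1 (Archaea) and 14.4 (Bacteria);
- per-system presence logistic in completeness and domain; the
  CRISPR-Cas-like system solves `logit(0.55)` at completeness 1 and
  `logit(0.311)` at the archaeal mean completeness, giving slope 6.73 on
  completeness, with a domain offset from `logit(0.43)` for Bacteria; the
  RM-like system uses a mild slope of 2 around prevalences 0.72/0.76.

The count and presence models are *marginal*: `total_systems` is an NB
draw, not the sum of the presence indicators, so the call-table identity
`total_systems = sum of per-system counts` holds for cohorts built by
`summarize_cohort()` from calls, not for generated cohorts. Model-recovery
tests use the generated cohort; aggregation tests use call-derived tables.

What the generator does **not** emulate: nucleotide-level realism, codon
usage, HMM profile scores, CRISPR array structure, defense islands
(planted systems are placed independently), horizontal transfer structure,
or phylogenetic autocorrelation between genomes. Passing tests therefore
demonstrate that the *rules and estimators* behave as specified under the
stated generative assumptions — not that those assumptions exhaust real
archaeal data.

## Problem sizes and numerical choices

The test-suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the checked properties are stable: 200 genomes for
the RM rule engine (perfect precision/recall on clean input), cohorts of
5 000 genomes for count-model recovery (100 replicates) and extrapolation
coverage (200 replicates — enough that Monte Carlo noise cannot flip the
verdict on a nominal-95% interval), 10 000 binomial draws for Wilson
coverage, and 40 replicates of
6 phyla × 100 genomes for null calibration of the contrasts. Convergence
tolerances: Firth score max-norm 1e-8; truncated-NB likelihood BFGS
`reltol 1e-12` plus Nelder–Mead polish; theta handled on the log scale.
Degenerate inputs are errors with typed conditions (all-zero counts, no
zeros for the hurdle, constant vectors for Spearman, rank-deficient
designs), except aliased covariates in the completeness model (e.g.
completeness constant at 1), where predictions legitimately collapse to
observed prevalence.

## A worked example

```{r example, eval = FALSE}
cfg <- defensome_config(
  output_dir = tempfile("survey_"), seed = 42, n_genomes = 20,
  cohort = cohort_config(n_per_domain = 1000)
)
res <- run_all(cfg)
res$detect$metrics # type-level precision/recall vs planted truth
res$stats$count_models$nb_ogt$percent_change_per_10c
plot_core_defensome(res$detect$cohort, k = 5)
```

## Known limitations

- The RM caller detects complete systems only; orphan methyltransferases
  are out of scope by design.
- Contigs are treated as linear; circular replicons would split a window
  spanning the origin.
- Whether a neighborhood satisfying two type rules should yield two calls
  is resolved by restricting components to the anchor's type — an
  interpretation, flagged here.
- The hurdle model's zero and count parts default to the same predictor
  set; they are separately configurable.
- Per-system prevalence models are fitted independently; no multivariate
  model across systems is attempted.
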