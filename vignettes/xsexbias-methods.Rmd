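---
title: "Screening for sex-biased expression on the X chromosome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for sex-biased expression on the X chromosome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xsexbias)
library(dplyr)
```

## The scientific question

Female mammals carry two X chromosomes, males one. X-chromosome
inactivation (XCI) silences one female X almost completely, but a minority
of genes *escape* silencing and are expressed from both alleles, making
them candidates for constitutively higher expression in females. At the
same time, evolutionary theory makes competing predictions about whether
the X should accumulate male-beneficial ("masculinisation") or
female-beneficial ("feminisation") expression. Resolving this empirically
requires a chromosome-wide census of sex-biased expression in *somatic*
tissues, where meiotic sex chromosome inactivation cannot confound the
picture.

`xsexbias` implements that census as a reusable, testable pipeline:

1. per-probe screening for expression differences between the sexes within
   each tissue (Wilcoxon rank-sum and Welch t);
2. tabulation of biased probes by chromosome class and Fisher exact
   contrasts of the female- and male-biased fractions on X versus
   autosomes, with and without known XCI escapees;
3. cross-tissue consistency classification at a relaxed threshold, with
   gene-level aggregation and detection of small (<50 kb) clusters of
   female-biased genes;
4. phylostratigraphic ("gene age") analysis of biased X genes.

A seeded synthetic-data generator plants all of these signals so every
stage can be validated against a known truth, and transcriptions of the
published summary tables are packaged as fixtures so the desk-reproducible
numbers can be recomputed exactly.

## Screening model

Inputs are RMA-normalized log2 intensity matrices (probes × samples), one
per tissue, standardized by a **single affine transform of the pooled
matrix** to mean 8 and SD 2. Pooled (rather than per-array) scaling is the
simplest reading of dataset-level standardization; it is idempotent and
commutes with the symmetric effect model below, so on simulated data it is
a near no-op.

For each probe the female/male contrast is summarized by

* `delta` — difference of mean log2 intensities (female − male),
* `fold_change` — `2^delta`, the linear-scale female/male ratio,
* a two-sided Wilcoxon rank-sum p-value using the large-sample normal
  approximation with midranks, tie-corrected variance and a 0.5 continuity
  correction (the classical approximation, identical to the large-sample
  path of `stats::wilcox.test`),
* a two-sided t p-value (Welch by default; a pooled-variance option
  exists, and all distribution-free properties of the pipeline hold for
  both).

Calls are made at an **unadjusted** per-probe threshold: 0.001 for the
primary screen, 0.01 for the cross-tissue consistency screen. This is a
deliberate design: the downstream statements are about *counts and
fractions of probes per chromosome class*, compared between classes by
Fisher exact tests, not about any individual probe. Both thresholds are
surfaced in `pipeline_config()`; nothing hard-codes them.

The rank-sum machinery is vectorized over probes so that whole-array
screens and hundreds of simulation replicates run in seconds; the
implementation is checked in the test suite against `stats::wilcox.test`
(equality to 1e-12, including ties) and against exact rank-permutation
enumeration. One known limitation, documented and asserted in the tests:
at the smallest admissible design (2 observations per group) the
continuity-corrected approximation deviates from the exact two-sided
enumeration p by up to 0.088 (0.051 at 2 versus 3). From 3 observations
per group the deviation is below 0.04 everywhere. Real designs in this
setting have tens of samples per sex, where the approximation is accurate
but conservative at extreme thresholds (its attained level at
20 + 20 samples and nominal 0.001 is 0.0006, computable exactly from the
rank-sum null distribution); calibration checks therefore compare observed
false-positive counts to the analytically attained level rather than to
the nominal one.

## Enrichment and depletion contrasts

`tabulate_bias()` produces the per-tissue count table by chromosome class
(autosomes A, X, Y, unmapped NA). Three contrasts are built from it:

* `XF_vs_XM` — female- versus male-biased fractions within X;
* `XF_vs_AF` — female-biased fraction, X versus autosomes;
* `XM_vs_AM` — male-biased fraction, X versus autosomes.

Each is a 2×2 table tested with the two-sided Fisher exact test under the
probability-mass criterion (sum over tables, at the observed margins, with
hypergeometric probability at most that of the observed table — the
default of standard statistical environments; implemented directly from
`dhyper` and cross-checked against `stats::fisher.test`). For cross-class
contrasts the signed relative difference `(X fraction − A fraction) / A
fraction` is reported; −0.25 reads as a 25% relative depletion on X.
Unmapped probes never enter these contrasts.

The packaged summary-count fixture prints biased counts and the percentage
of each chromosome class they represent, but not the class totals. The
totals are therefore **derived constants**: pooling every count/percentage
pair per class gives approximately 42,990 autosomal and 1,428 X probes
(`derive_class_totals()` recomputes this; the packaged values live in
`class_totals.tsv` as fixture metadata, not in code). The derivation
carries roughly ±40-probe uncertainty from percentage rounding, which the
rounded depletion percentages tolerate; exact reproduction of the printed
Fisher p-values is not guaranteed by construction, although both (0.0032
kidney, 0.0099 liver) do reproduce to the printed precision.

The escapee-excluded ("X-prime") variant removes all probes of 17 known
mouse XCI escapees (packaged list, `mouse_escapees()`), by gene symbol
with alias and intronic-host matching. The scientific question it answers:
how much of the female excess on X survives once established escapees are
set aside?

## Cross-tissue consistency, gene entries and clusters

A probe is *consistently biased* when significant at the relaxed threshold
in **at least two** tissues with the same direction in every significant
tissue; probes significant in opposite directions in different tissues are
excluded (distinct probes of one gene remain independent, so a gene can
legitimately appear in both directions through different probes).
Quantifier conventions follow the source tables literally: "more than
one" = ≥2, "more than two" = ≥3, "four or more" = ≥4.

Probes sharing a numbered entry label aggregate into gene-level entries;
intron-marked probes merge into their numbered host entry, and unnumbered
intronic probes stay standalone. Tissue sets combine by union. Gene-level
counts deduplicate by gene symbol (with the entry label as fallback for
the unannotated intergenic transcript), because one gene can own several
numbered entries; probe-level counts use probe rows. This pairing — and
only this pairing — reproduces both published multi-tissue counts (25
female genes, 2 male probes).

Clusters are called by single-linkage chaining of female-biased entries
ordered by start coordinate: adjacent entries whose gap (next start minus
current stop, floored at 0 for overlaps, on 1-based inclusive coordinates,
with a running maximum of stop to handle nested entries) is **less than
50 kb** join one cluster; clusters need ≥2 members. Gaps are measured
between probe-alignment extents, the only coordinates the source prints.
Under that rule the printed coordinates recover the Kdm5c cluster (5
members) exactly; the printed Xist/Jpx/Ftx cluster has one printed gap of
~63 kb and therefore splits, so the total printed cluster count of 6 is
not reproducible from printed coordinates and is not asserted.

## Gene age

Each X probe is joined to a phylogenetic branch (0–11, the stratum at
which orthologs first appear), by Ensembl id with gene-symbol fallback.
Branches with fewer than 10 probes are excluded from proportion reports
(the filter is a parameter). The old/young boundary is fixed between
branches 5 and 6 (~100 million years, preceding the placental radiation)
as a configuration constant. The age split is tested by the same Fisher
machinery on the 2×2 (biased, not) × (old, young) table. Because the
published per-branch assignments are an external supplement, the published
age p-values are out of scope; the analysis is validated on synthetic data
with a planted age-by-bias interaction instead. Both probe-level and
(via aggregation) gene-level analyses are possible; probe-level is the
default since the minimum-probe filter is itself probe-based.

## The synthetic-data generator

`sim_config()` defaults define the study conditions the generator
emulates:

* probe composition A = 43,000, X = 1,428, Y = 16, unmapped = 30;
* per-probe baseline log2 intensities Normal(8, 2) — the between-probe
  spread that dominates the pooled SD-2 scale of standardized arrays —
  with within-probe residual SD 0.5 on the log2 scale. The residual value
  is a design choice: it is the order of magnitude required for
  fold-changes of 1.05–2 to be detectable at p < 0.001 with tens of
  arrays per sex, which is the empirical regime this kind of screen
  operates in; a residual SD equal to the full pooled spread would make
  every small X effect undetectable at any realistic sample size
  (normal-theory power ≈ 4% at delta = 1 with 20 per sex);
* female-biased X effects drawn from |delta| in [0.07, 1] (fold-changes
  1.05–2); autosomal effects up to |delta| = 2.5 in the two leading
  "dimorphic" (kidney/liver-like) tissues;
* effects planted as symmetric shifts ±delta/2 so the pooled mean stays at
  the baseline and standardization is a near no-op;
* Y probes expressed in males only, females reported at a fixed floor of
  4.0 (arrays report an intensity for every probe, so silent probes carry
  a floor value rather than missing rows);
* one Xist-like probe with female-only expression (delta = 7, a 128-fold
  change);
* escapee-like entries female-biased in every tissue; planted positional
  clusters whose members sit at gaps in [1 kb, max_gap) while all other X
  genes are spaced at least 5× the 50 kb threshold apart, so cluster
  recovery has an unambiguous truth;
* branch labels drawn independently of position, with an optional
  `old_bias_weight` that enriches old branches among female-biased genes
  to create a recoverable age signal.

Identical configurations produce bit-identical output (a single seed
drives all draws in fixed order). The generator does **not** model probe
sequence effects, hybridization physics, batch structure, or hormonal and
body-weight covariates; Gaussian log2 noise is an assumption of the
simulation, not a claim about real arrays. Passing the planted-recovery
tests therefore demonstrates correctness of the statistical machinery
under the stated model, not robustness to every artefact of real
microarray data. Coordinates are likewise synthetic: total spacing is not
constrained to a real chromosome length unless `x_length` is set, in
which case an oversized cluster layout is rejected.

## Numerical and degenerate-input conventions

* `delta = 0` with p below threshold (a measure-zero tie of means) is
  called `ns`: direction is undefined.
* A probe constant in both sexes gets Wilcoxon p = 1; constant in both
  with different values gets t p = 0 (complete separation) in the
  vectorized screen, while the scalar `t_test_p()` treats it as a
  degenerate-input error per its contract.
* Fisher tables with a zero margin are degenerate errors at the operation
  level; inside `run_pipeline()` a degenerate contrast is reported as `NA`
  rather than aborting the run.
* The two-sided Fisher mass comparison uses a `1 + 1e-7` relative
  tolerance so floating-point ties in hypergeometric probabilities do not
  flip the verdict.
* Standardization requires a nonzero pooled SD and is idempotent to 1e-9.

## Problem sizes used in validation

The packaged validation suite runs entirely on fixtures and seeded
simulations: null calibration uses one 20,000-probe experiment at 20
samples per sex plus 500 smaller (2,500-probe, 10 per sex) replicates for
the contrast-level error rate; power checks use 50 replicates of a
1,478-probe design at 20 per sex (probe-level recovery and the within-X
contrast) and 50–60 replicates of a 1,000-probe design at 25 per sex for
the age split; cluster recovery uses 300 X probes over three tissues.
These sizes were chosen so each property is measured with comfortable
Monte-Carlo margins while the whole suite stays fast enough to run on
every change.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 11, n_tissues = 3, samples_per_sex = 25,
                  n_probes = c(A = 2000, X = 500, Y = 8, "NA" = 10))
out <- run_pipeline(pipeline_config(sim = cfg))

filter(out$counts, chrom_class %in% c("A", "X"))
filter(out$enrichment, comparison == "XM_vs_AM")
out$clusters
plot_volcano(filter(out$results, tissue == "tissue1"), out$annotation)
```

And the packaged-fixture reproduction:

```{r fixtures}
fixtures_check()
```

## Known limitations

* The pipeline starts from normalized log2 matrices; raw-array processing
  (CEL parsing, RMA) is out of scope.
* No multiplicity adjustment is offered by design; users wanting FDR
  control over per-probe calls should treat the per-probe tables as input
  to their own adjustment.
* Escapee exclusion is list-based; it cannot discover novel escapees, only
  quantify how much signal the known ones explain.
* The printed cluster letters of the source table encode gene-model
  knowledge not recoverable from probe coordinates alone; cluster calls
  here are strictly coordinate-based.
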