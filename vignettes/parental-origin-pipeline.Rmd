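---
title: "Classifying the parental origin of pre-EGA embryo RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the parental origin of pre-EGA embryo RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaorigin)
library(dplyr)
```

## The problem

Before embryonic genome activation (EGA), a 2–4 cell embryo cannot yet
transcribe most of its own genome: the RNAs it contains were donated by the
oocyte, possibly by the sperm, or produced by the small pre-emptive wave of
transcription known as minor EGA. `rnaorigin` implements a presence/absence
integration strategy for attributing each embryo-detected RNA to one of four
parental-origin categories, together with the supporting analyses such a
study needs: negative-binomial differential expression between sire
fertility groups, 2^−ΔΔCT qRT-PCR validation, and paired comparisons of
embryo development rates.

The classification logic is deliberately simple and auditable. A gene
expressed in the embryo is:

* **sperm_and_oocyte** — detected in sperm and in both oocyte references;
* **oocyte_only** — detected in both oocyte references but not sperm;
* **sperm_only** — detected in sperm but in neither oocyte reference;
* **embryo_only** — detected in no gamete dataset (a candidate minor-EGA
  transcript);
* **provisional** — detected in exactly one of the two oocyte reference
  datasets. Disagreement between the references is treated as unresolved
  evidence: provisional genes are reported but excluded from the four
  confident category counts.

## Expression calling and its thresholds

Each dataset is reduced to a tri-state call per gene — `expressed`,
`not_expressed`, or `not_measured` — using fixed thresholds collected in
`threshold_config()`:

| threshold | default | units | applied to |
|---|---|---|---|
| `min_reads` | 5 (strict >) | raw reads | embryo, sperm, oocyte RNA-seq |
| `min_samples` | 1 | samples | count datasets |
| `array_min_intensity` | 40 (inclusive ≥) | raw intensity units | microarray reference |
| `ct_max` | 33 (strict >) | CT cycles | qPCR quantification limit |
| `fold_validation` | 1.5 (inclusive) | fold | per-replicate concordance |
| `fdr_cutoff` | 0.10 (strict <) | — | BH-adjusted significance |

Two boundary conventions deserve emphasis because they change individual
calls. "More than five reads" is read strictly, so a count of exactly 5 is
not detection; "a minimum intensity of 40" is read inclusively, so an
intensity of exactly 40 is. Counts must be raw integers: the thresholds are
defined on read counts, and normalized input is rejected at parse time.

A gene absent from a platform's measured universe is `not_measured`, and
`not_measured` is treated as *not found* when forming the oocyte consensus.
Absence of evidence on one platform therefore never upgrades a single
detection to a confident call — a gene seen in one oocyte reference and
unmeasured in the other is provisional, not oocyte-derived. Multiple array
probes for one gene act as redundant detectors (any passing probe suffices),
and probe intensities are averaged across replicate arrays before
thresholding (`average_replicates = FALSE` switches to per-array
thresholding; the choice is exposed because source descriptions of such
cutoffs rarely state it).

One reading ambiguity is worth recording: "found in only one gamete-specific
dataset" could in principle contrast sperm against oocyte rather than the
two oocyte references against each other. Because sperm contributes a single
dataset while the oocyte side has two independent references that can
genuinely disagree, the two-oocyte-reference reading is implemented.

## Differential expression

The fertility-group comparison uses an exact conditional negative-binomial
test with a single common dispersion, the minimal faithful version of the
classic count-based exact-test framework:

1. **Library-size equalization.** Counts are scaled to the geometric-mean
   depth and rounded (`equalize_library_sizes()`). The exact test requires
   exchangeable samples; this simple documented equalization was chosen over
   quantile-based pseudo-count machinery so that every number in the
   pipeline can be reproduced by hand.
2. **Common dispersion** (`estimate_common_dispersion()`), by maximizing the
   conditional likelihood of counts given each gene's group sum. Under the
   NB model with variance $m + \phi m^2$, conditioning removes the per-gene
   mean, avoiding the downward bias plug-in profile likelihood suffers with
   3 samples per group. No tagwise or trended shrinkage is attempted: with
   a single dispersion the model stays identifiable and auditable.
3. **Exact test** (`nb_exact_test()`). Conditional on a gene's total $t$,
   the split between groups follows a negative hypergeometric law free of
   the mean; the two-sided p-value sums the probabilities of all splits no
   more probable than the observed one (ties included at relative tolerance
   1e-12, rather than doubling a single tail). At dispersion 0 this reduces
   to the conditional binomial test.
4. **BH adjustment** (`bh_adjust()`), the explicit step-up rule, with
   significance declared strictly below the FDR cutoff of 0.10.

Genes failing the embryo presence call are excluded from testing and flagged
`tested = FALSE`; the presence call is the pipeline's only low-count filter,
so the tested universe coincides with the origin-classified universe. The
log2 fold change is high-over-low on equalized group means with a
pseudo-count of 0.5 per mean. The design is unpaired: nothing in the target
workflow identifies which high- and low-fertility samples share an IVF
replicate at the count-matrix stage, so no pairing structure is modeled.

## qPCR validation

`fold_change_ddct()` implements plain 2^−ΔΔCT (no amplification-efficiency
correction): ΔCT = CT~target~ − CT~reference~ within each condition, and
fold = 2^−(ΔCT~case~ − ΔCT~control~). Any of the four CTs missing or above
33 cycles makes the replicate *unquantifiable* — a reportable state, not an
error. Reference genes are chosen by `select_reference_gene()` as the
candidate with the smallest CT standard deviation across quantifiable
samples (ties broken lexicographically); SD of raw CT is used because it is
the simplest defensible stability proxy, and candidates with fewer than two
quantifiable CTs are excluded.

A replicate *validates* a sequencing result when its fold is ≥ 1.5 for an
up-regulated gene or ≤ 1/1.5 for a down-regulated one — the concordance rule
must be direction-aware or down-regulation could never validate. Both
boundaries are inclusive; `threshold_config(fold_validation =)` moves them.
Replicate folds are summarized by their arithmetic mean by default (matching
how validation tables are conventionally reported); a geometric mean —
unbiased on the log scale, and preferable when averaging many noisy
ratios — is available via `mean_type = "geometric"`. Significance across
replicates is a two-sided paired t-test on ΔCT values (not on folds), with
two degenerate-case conventions: all-zero differences give p = 1, constant
nonzero differences give p = 0 with a warning.

## Phenotype rates

`compute_rates()` uses the two denominators exactly as defined in embryology
practice: cleavage rate = cleaved/oocytes inseminated, blastocyst rate =
blastocysts/cleaved. `compare_arms_paired()` compares replicate-matched arms
on replicate-mean rates (not pooled counts, respecting the paired design)
and reports the *relative* percent change 100·(mean~t~ − mean~c~)/mean~c~.
Because "an X% increase" is ambiguous between relative change and
percentage points, the percentage-point difference is always reported
alongside.

## The synthetic-data generator

`simulate_dataset()` plants a complete ground truth and emits every input
table the pipeline consumes. Its defaults define the simulated study
conditions:

* 3 embryo RNA-seq replicates per fertility group, 2 sperm samples, 2
  oocyte RNA-seq replicates, and one microarray reference — the structure of
  the multi-platform design the classifier targets;
* origin proportions (0.356 both, 0.343 oocyte-only, 0.063 sperm-only,
  0.088 embryo-only, 0.15 provisional) patterned on the category composition
  observed in pre-EGA bovine embryos;
* NB counts with mean 50 and dispersion 0.1 for expressed genes — a
  moderate-depth, moderately overdispersed bulk library; "not expressed"
  gametes receive NB background counts with mean 0.5 rather than structural
  zeros, so threshold behavior is genuinely exercised;
* log-normal array intensities (`mean × exp(N(0, 0.25))`, expressed mean
  200, background mean 10), so intensities are positive, right-skewed, and a
  zero background mean stays exactly zero in noise-free configurations;
* planted DE in 5% of genes at |log2FC| = 3, split symmetrically around the
  base mean with random direction;
* provisional genes expressed in exactly one oocyte reference, the reference
  chosen by coin flip, with sperm evidence also randomized (the provisional
  label overrides sperm evidence either way);
* qPCR CT noise of 0.3 cycles, and development rates of 0.8 cleavage in both
  arms with blastocyst rates 0.35 (control) versus 0.43 (treated).

A single master seed drives one *named* random stream per generator
(truth, embryo, sperm, oocyte RNA-seq, array, qPCR, tallies), so drawing one
table never perturbs another and adding a new generator leaves existing
output bit-identical.

What the generator does **not** emulate: amplification bias from
whole-transcriptome amplification of picogram inputs, probe-level microarray
chemistry and cross-hybridization, gene-length and GC effects, correlated
expression between genes, annotation mismatches between platforms, or
tagwise dispersion. Passing recovery tests on this generator therefore
demonstrates that the pipeline's logic is correct under its stated model,
not that the thresholds are optimal for any particular real dataset.

## A worked run

```{r worked-run}
cfg <- sim_config(seed = 11, n_genes = 4000)
sim <- simulate_dataset(cfg)
assignments <- classify_sim(sim)
origin_summary(assignments)
mean(assignments$label == sim$truth$true_origin)

fit <- run_de(sim$embryo, sim$samples)
glance(fit)
annotate_de_origins(fit, assignments)
```

```{r plots, fig.width = 6, fig.height = 4}
library(ggplot2)
autoplot(assignments)
autoplot(fit)
```

## Numerical choices and degenerate inputs

* Exact-test ties are included using a relative tolerance of 1e-12, so a
  split with floating-point-equal probability to the observed one is always
  counted in the p-value.
* The dispersion search runs on the log scale over [1e-6, 10]; estimates at
  the lower boundary are reported as exactly 0 (the Poisson limit).
* All-zero count matrices, empty count vectors, a zero `n_genes`, zero-rate
  denominators, and mismatched replicate sets are errors; unquantifiable
  qPCR replicates and empty tally files are values (flagged rows / empty
  tables with a warning), because they occur in routine data.
* HTSeq summary rows (`__no_feature`, …) are stripped on read and reported;
  they are not genes and would otherwise distort presence calling and
  library sizes.
* Probe→gene maps may be many-probes-to-one-gene; a probe mapped to several
  genes is rejected as ambiguous rather than silently duplicated.

## Problem sizes used by the test suite

The packaged checks run the classifier recovery at 10,000 genes (noise-free
and at dispersion 0.2), DE calibration and power at 2,000 genes with 3
samples per group, the exact-test oracle sweep over all totals ≤ 30 at
dispersions 0 and 0.5, and BH equivalence on 1,000 random vectors — sizes at
which every property is informative while a full run stays comfortably
interactive on one CPU.

## Limitations

The classifier is presence/absence only: it cannot distinguish a transcript
carried over from a gamete from one independently transcribed by the embryo
when both sources are plausible, and it inherits whatever detection biases
the reference platforms have. Cross-platform gene matching is by exact
identifier string after probe→gene mapping — no fuzzy symbol matching — so
harmonization quality is the user's responsibility. The DE stage models a
single common dispersion and an unpaired two-group design; studies with
strong per-gene dispersion heterogeneity or an explicit pairing structure
need the heavier GLM machinery of dedicated DE packages.
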