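---
title: "Methods: subtype-level TME analysis with SubtypeTME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype-level TME analysis with SubtypeTME}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SubtypeTME)
```

SubtypeTME asks how the tumor microenvironment differs between molecular
subtypes of a cancer, using only a bulk expression matrix, subtype labels,
and (optionally) survival, somatic mutation and copy-number layers. This
vignette explains the statistical machinery, the parameters that matter, the
design choices that were genuinely open, and what the synthetic validation
does and does not establish.

## Data model

`alignCohort()` fixes the sample universe as the intersection of expression
samples and annotated samples; survival, mutation and CNV layers are
restricted to that universe and per-layer coverage is recorded. The
expression matrix carries a *declared* scale (`"fpkm"` or `"log2p1"`). Most
scores are rank-based and scale-insensitive; the MHC score is the exception
(it averages log-centered values, so its input scale matters) and therefore
enforces FPKM input unless told the values are already logged. For microarray
or other non-FPKM cohorts the scale is metadata the analyst declares; the
package deliberately does not guess.

Gene identifiers are matched as exact, case-sensitive strings. Signature
genes absent from the matrix are dropped per set with a warning; they are not
imputed as zero expression, because a missing measurement is not evidence of
absence.

## ssGSEA scoring

For one sample, genes are ranked by decreasing expression. Walking down the
ranking, the enrichment score of a gene set accumulates the difference
between the weighted in-set empirical CDF (weights: bottom-up rank to the
power $\alpha$) and the uniform out-of-set CDF; the score is the sum of that
running difference over all positions. Only within-sample ranks enter, so
any strictly monotone transform of a sample's profile leaves its scores
unchanged — this is what makes mixed-scale cohorts workable.

Numerical choices:

* $\alpha = 0.25$ by default, the common ssGSEA convention; configurable.
* Ties in expression are broken by gene id in C-locale order after a stable
  radix sort, so scores are byte-reproducible across platforms.
* The batch path evaluates the running-sum total in closed form from each
  in-set gene's rank (the sum telescopes), which is what makes thousands of
  gene-permutation re-scorings affordable; the explicit walk
  (`ssgseaScore()`) is retained and the two are cross-checked in the tests
  against an independent brute-force oracle.
* "Normalized" scores divide the whole score matrix by its global
  (max − min), giving the matrix unit range. The GEP score uses this
  normalized form; the panel and abundance scores default to raw scores.
  Both variants are exposed because published analyses differ in which they
  use.

Degenerate inputs error loudly: a set with no gene in the matrix, a set
covering the whole matrix (the out-of-set CDF is then undefined), or a
single-gene matrix (ranking is meaningless).

## Named feature scores

* **MHC score** — core MHC class I genes are `log2(x+1)` transformed (the
  same transform used for expression preparation; the log base was an open
  choice and is configurable), median-centered per gene across patients, and
  averaged per sample. Median-centering makes the score cohort-relative.
* **GEP score** — normalized ssGSEA score of the 18-gene T-cell-inflamed
  profile.
* **TMB** — non-silent variants per coding megabase. The coding-area
  denominator is a required parameter (default 38 Mb, a conventional exome
  size) because no universal constant exists. The non-silent vocabulary
  defaults to the standard MAF protein-affecting classes and is
  configurable; unknown classes are a hard error unless `lenient = TRUE`,
  so typos cannot silently become zeros.
* **ESTIMATE-style scores** — immune and stromal ssGSEA scores, their sum,
  and the cosine purity transform with the original calibration constants.
  The purity mapping was calibrated on ESTIMATE-scale scores; outside the
  range where the cosine argument stays in $[0, \pi/2]$ the value is clamped
  to $[0,1]$ and flagged. The immune/stromal gene sets are user-supplied;
  the bundled sets are small synthetic stand-ins for tests and demos, not
  the published signatures.

## One-vs-rest effect sizes

Cohen's d with the pooled-SD definition compares each subtype against all
remaining samples, per feature. A zero pooled SD makes d undefined; a
sentinel `NA` is returned (and excluded from heatmaps) rather than
$\pm\infty$, so downstream matrices stay finite. Significance uses the
two-sided Mann-Whitney U test (exact for small tie-free groups, corrected
normal approximation otherwise, via the standard library routine), with
BH-FDR applied across the *whole feature x subtype family of one call* —
i.e. one correction family per heatmap. That family choice was open; it is
the most conservative reading consistent with flagging cells on a whole
figure, and it is configurable by calling the profiler per family.

## SubSEA

For each cell, samples are ranked by decreasing infiltration abundance
$r_j$; for a subtype $S$ the running sum increases by $|r_j|^p / N_R$ at
member samples and decreases by $1/N_{\text{NotS}}$ at non-members, and the
sample enrichment score (SES) is the signed value of the running difference
where its absolute value is maximal. $p = 1$ by default, weighting members
by abundance; $p = 0$ recovers the classic two-sample KS statistic on ranks
(verified in the tests). Abundances are shifted per cell so the cohort
minimum is zero, making the $|r_j|^p$ weighting direction unambiguous.

Determinism and ties: abundance ties are broken by sample id, so the ranked
list is a total order; among positions with equal maximal deviation the
earliest wins, with a $10^{-12}$ tolerance so floating-point summation noise
cannot flip the choice between exactly tied positions.

**Null model.** Significance comes from permuting gene labels of the
expression matrix, recomputing the full abundance matrix with the same
scorer, and recomputing every SES. One global relabeling per permutation is
shared by all cells — the coherent reading of a label shuffle, since all
cells see the same (relabeled) matrix; independent per-cell shuffles are
available as a flag. Label permutation preserves each sample's expression
profile exactly, so the null keeps the cohort's correlation structure among
samples and breaks only the marker-set/gene association.

**p-values.** The reported p is the literal empirical tail in the observed
direction: for SES > 0, the fraction of permuted SES values strictly
greater; for SES < 0, strictly smaller; an observed SES of exactly 0 is
treated as maximally null-consistent (p = 1) — the signed cases do not
cover it, and a zero maximal deviation means the membership tracks the null
walk everywhere. Pairs with p < 0.001 (strict) are called subtype-specific.
Defaults: 1000 permutations, the minimum resolution for that threshold (a
warning fires if the threshold is below 1/n_perm). An optional add-one
correction $(M+1)/(N+1)$ avoids exact zeros.

Two caveats are worth stating plainly. First, a directional empirical tail
is anti-conservative by up to a factor of two in the far tail (the direction
is chosen by the data); the `p_two_sided = min(1, 2p)` column is a valid
two-sided bound for users who want strict control at stringent thresholds.
In null calibration experiments the directional p is nonetheless close to
uniform in aggregate, because for small subtypes the member steps of the
running sum are much larger than the non-member steps, so null SES values
are predominantly positive and the directional tail behaves almost like a
fixed one-sided tail. Second, no multiplicity correction is applied to the
cells x subtypes family by default — the specific call uses the raw 0.001
threshold — but a BH column (`fdr_bh`) is always included.

## Prognostic screening

Within each subtype, a univariate Cox model regresses overall survival on
continuous cell abundance (Efron tie handling). Fits are skipped, with a
warning, for strata with fewer than 10 survival-covered samples, no events,
or constant abundance. The screening significance threshold defaults to
0.01.

For visualization, `optimalCutoff()` scans observed abundance values whose
high/low split keeps at least `minprop` (default 0.1, the conventional
choice) of samples on each side and picks the split maximizing the absolute
standardized log-rank statistic. The reported log-rank p of that split is
*naive*: the maximization makes it anti-conservative, which the package both
flags on every result (`selection_biased = TRUE`) and demonstrates in its
own test suite (null data yield naive p < 0.05 far more than 5% of the
time). A permutation-adjusted p for the maximal statistic is available. The
candidate scan is rank-based, so the chosen grouping is invariant to
monotone transforms of abundance.

## Genomic aberration

Mutation tables are collapsed to a gene x sample 0/1 matrix (any qualifying
variant counts once; binarization is idempotent). Genes mutated in strictly
more than 1% of samples enter a 2 x K chi-square test of mutated/wild-type
counts against the subtype partition — the 2 x K contingency is the standard
reading of comparing mutation status among subtypes — without continuity
correction, followed by BH-FDR across genes and a strict FDR < 0.01 call.
Genes mutated in no or all samples are excluded as degenerate. Tables with
expected counts below 5 are flagged, and a seeded Monte-Carlo p is available;
the package's own acceptance experiments use it, because at realistic
subtype sizes (a 14-sample subtype in a 170-sample cohort) the asymptotic
chi-square tail is visibly anti-conservative at the 10^-3 thresholds that
matter after FDR. CNV codes are collapsed to amplification (> 0) and
deletion (< 0) indicators — optionally high-level events only — and the two
analyses are corrected independently.

## The synthetic cohort generator

`generateCohort()` emulates exactly the structure the pipeline assumes:

* five subtype groups of unequal size (defaults 20/22/68/46/14, a 1/10-scale
  version of a large breast-cancer cohort's PAM50 composition);
* disjoint marker blocks per cell, with planted (cell, subtype, delta)
  triples adding a mean shift of delta baseline-SD units to that cell's
  markers in that subtype's samples;
* per gene x subtype Bernoulli mutation and CNV event probabilities;
* exponential survival with log-hazard linear in the standardized true cell
  abundances, censored administratively at the horizon that hits the target
  censoring rate (simple, reproducible, and sufficient for calibration
  work).

Expression noise is Gaussian on the log scale, shifted non-negative; since
all downstream scoring is rank-based within samples, the exact noise family
is non-critical. What the generator does *not* emulate: gene-gene
correlation beyond marker blocks, batch effects, overlapping marker sets,
covariate-dependent censoring, and the heavy-tailed count structure of real
RNA-seq. Passing recovery and calibration tests therefore shows that the
statistics do what they claim under their own assumptions — not that any
particular real cohort satisfies those assumptions.

## Validation experiments and problem sizes

The package's acceptance suite runs, at fixed seeds:

* exact equivalence of the SES engine with an exhaustive running-sum oracle
  on 1000 random instances (up to 20 samples, weight exponents 0, 1, 2),
  plus the boundary identities (top-packed membership gives SES = 1,
  bottom-packed −1, |SES| ≤ 1 always);
* null calibration of the permutation p-values on a 150-sample, 10-cell,
  five-subtype cohort with 200 permutations (KS against uniform at
  $\alpha = 0.01$);
* recovery of two planted (cell, subtype) pairs (delta = 1.5 SD, 30 markers,
  250 samples, 1000 permutations) in at least 19 of 20 seeded runs with at
  most one false call among 20 never-planted decoy pairs;
* Cox recovery of a planted log-hazard of 0.8 (200 samples, 200 replicates,
  mean within ±0.25) and null type-I behavior at 0.01 over 500 replicates;
* recovery of five subtype-biased mutated genes (60% vs 3% rates, sizes
  drawn from the miniature cohort) among 50 passenger-like 4% decoys at
  FDR < 0.01 with zero decoy flags in at least 19 of 20 runs;
* fixture identities: the 18-gene GEP set, the 9-gene core MHC-I set, the
  8-set TME panel, the strict >1% frequency filter and the strict p < 0.001
  call.

These sizes keep the full suite around three minutes on one core while
leaving each check statistically meaningful; `scripts/acceptance.R` re-runs
the pipeline end to end at a user-chosen seed and reports the computed
quantities as JSON.

## Known limitations

* The built-in marker-set abundance scorer shares the interface, not the
  machinery, of dedicated estimators such as xCell (no spillover
  compensation, no platform calibration); externally computed abundance
  matrices are first-class inputs via `readCellAbundance()`.
* SES p-values inherit the resolution of the permutation count; claims below
  1/n_perm are impossible by construction.
* The naive post-cutpoint log-rank p is reported for comparability with
  common practice, but it is selection-biased; treat it as descriptive and
  use the permutation-adjusted option for inference.
* PAM50 (or any) subtype classification is an input, not something the
  package computes; misclassified labels propagate into every downstream
  contrast.
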