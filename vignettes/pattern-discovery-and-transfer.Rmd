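---
title: "Discovering and transferring latent expression programs across torpor datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and transferring latent expression programs across torpor datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternTransfer)
```

## The problem

Bulk RNA-seq studies of heterotherms (hibernating squirrels and bears,
brumating reptiles, aestivating amphibians) sample several tissues across
physiological states — euthermia, torpor, and the periodic interbout
arousals (IBA) of small-mammal hibernation. The measured expression of each
sample mixes several latent programs: tissue identity, the state-specific
programs the study is after, per-animal idiosyncrasies, and technical
signal such as sequencing depth. Because many of the species involved lack
reference genomes, datasets live in incompatible gene namespaces, and
cross-species comparison must pass through one-to-one ortholog maps.

This package decomposes each dataset with non-negative matrix
factorization (NMF), decides how many patterns are biologically meaningful,
and transfers the learned gene weights into other datasets and species to
test whether a program (say, a torpor program) is shared.

## The model

For a non-negative gene-by-sample matrix $X$ (TPM units), `nmf()` finds
non-negative factors minimizing the Frobenius loss

$$\min_{A \ge 0,\, P \ge 0} \; \lVert X - A P \rVert_F^2,$$

with $A$ ($G \times k$) the *amplitude* matrix — how much each gene
contributes to each pattern — and $P$ ($k \times S$) the *pattern* matrix —
how strongly each pattern is expressed in each sample. The solver is the
classical multiplicative-update scheme, which keeps both factors
non-negative elementwise and never increases the loss from one iteration to
the next. Because the loss is non-convex, `nmf()` runs several seeded
restarts (default 3) and returns the lowest-error one, with ties broken by
restart index so results are a pure function of `(X, k, seed, max_iter,
tol, n_restarts)`. Convergence is declared when the relative decrease of
the reconstruction error falls below `tol` (default `1e-6`) or after
`max_iter` (default 2000) iterations.

NMF is scale-degenerate: any pattern can be rescaled if its amplitude
column is rescaled inversely. We fix the convention that every row of $P$
has unit maximum, absorbing the inverse scale into $A$, which leaves
$A P$ unchanged and makes sample weights comparable across patterns.

The input is used as TPM without log transform, matching the practice of
feeding gene-level TPM quantifications directly to the factorizer; a
`log1p` flag exists for heavy-tailed data but defaults off.

### Split-gene consensus mode

For large gene sets, `nmf_consensus()` randomly partitions genes into
`n_sets` groups, factorizes each group independently at the same $k$,
clusters the pooled sample-weight vectors (average-linkage, distance
$1 - r$ where $r$ is the Pearson correlation between sample-weight rows)
into exactly $k$ consensus patterns, averages each cluster, rescales rows
to unit maximum, and re-solves every gene's amplitudes by non-negative
least squares (Lawson–Hanson, via `pracma::lsqnonneg`) against the
consensus $P$. With `n_sets = 1` it reduces, bit for bit, to `nmf()`.

## Choosing the number of patterns

`scan_k()` fits every $k$ in a range (each $k$ independently seeded).
Rather than picking $k$ by fit statistics — reconstruction error decreases
monotonically in $k$, so it cannot decide — the package operationalizes a
screening rule based on what drives each pattern. `classify_patterns()`
assigns one category per pattern by a cascade:

1. **technical** — the sample weights track library size:
   $|\mathrm{cor}(p_j, \text{library size})| \ge \tau_{depth}$
   (default 0.8). These are the broad depth-driven patterns seen in real
   bulk datasets; they are removed by `drop_technical_patterns()` but do
   not disqualify a $k$.
2. **sample_specific** — one sample holds at least $\tau_{dom}$
   (default 0.5) of the pattern's total weight while its tissue-by-state
   group has replicates. A pattern that singles out one replicate among
   several is noise, not biology.
3. **tissue_state / tissue / state** — the fraction of sample-weight
   variance explained by the metadata grouping (eta-squared: between-group
   sum of squares over total) reaches $\tau_{eta}$ (default 0.5).
   Interaction comes first: a pattern is `tissue_state` when the
   tissue-by-state cell grouping explains its weights while neither main
   effect alone does, one cell clearly dominates (at least 1.5 times as
   far above the floor as the runner-up), and the dominant cell's
   replicates agree (minimum at least a third of the maximum — a single
   aberrant animal inflating one cell is not an interaction program).
   Otherwise the larger qualifying main effect decides.
4. **unclassified** otherwise.

The pattern count then comes from the scan: `select_pattern_count()`
returns the largest $k$ at which *every* pattern is metadata-driven
(`tissue`, `state` or `tissue_state`; `technical` permitted). Both
replicate-splitting sample-specific patterns and diffuse unclassified
patterns disqualify a $k$ — as many patterns as all remain biologically
interpretable.

The thresholds are declared defaults, not values inferred from any
particular dataset, and all three are configurable.

## Pattern markers

`pattern_markers()` ranks genes by how exclusively they load one pattern:
amplitude columns are scaled to unit maximum and each gene's scaled row is
compared with each pattern's unit indicator vector $e_j$ by Euclidean
distance. The gene is assigned to the pattern with minimal distance (ties
to the lowest pattern index) and ranked within the pattern by ascending
distance — rank 1 is the most pattern-exclusive gene. A gene loading
exactly one pattern is always closer to that pattern's indicator than to
any other, so planted marker genes are recoverable by construction.

## Transfer across datasets and species

`restrict_to_orthologs()` aligns a source amplitude matrix and a target
expression matrix through a validated one-to-one ortholog map (only genes
with orthologs present in both datasets are kept). `project_patterns()`
then solves, per target sample, the unconstrained least-squares problem
$y \approx A s$ — no intercept, no non-negativity — so scores take both
signs; a high score means the sample's profile resembles the pattern. By
default each target gene is centered across target samples first (`center
= TRUE`), which removes baseline expression and leaves the variation the
patterns might explain; the amplitude matrix is never altered. The solver
is QR-based and agrees with the normal equations
$(A^\top A)^{-1} A^\top y$ to high precision; a rank-deficient amplitude
matrix on the shared genes is an error naming the collinear patterns.

`compare_groups()` tests one pattern's scores between two states with a
two-sided pooled-variance Student's t-test (the textbook form; Welch is
available behind `var_equal = FALSE`). Degenerate zero-variance input with
equal means yields $t = 0$, $p = 1$. Raw p-values are reported; no
correction is applied across group tests by default, though `p.adjust` can
be applied downstream.

The two-sided pooled form is the declared default because it makes no
directional assumption about which state scores higher and suits the
small, balanced group sizes typical of these designs.

## Gene-set enrichment of pattern weights

Pattern amplitudes are non-negative, so `rank_genes_by_pattern()` orders
genes by descending weight (ties broken lexicographically; identifiers can
first be converted to a reference namespace through an ortholog map).
`enrichment_score()` computes the classic weighted running-sum statistic
in a positive-only regime: hits add $w_i / \sum_{hits} w$, misses subtract
$1/(N - N_{hits})$, and the score is the maximum of the running sum floored
at zero, hence in $[0, 1]$. `gsea_pos()` builds the null per set size from
`n_perm` random same-size gene subsets (default 1000, recorded in the
result's metadata), uses the add-one estimator
$p = (1 + \#\{ES_{null} \ge ES\}) / (1 + n_{perm})$ — so
$p \in [1/(n_{perm}+1),\, 1]$ — normalizes $ES$ by the null mean to give
NES, and applies Benjamini–Hochberg across the sets of one ranking (one
pattern). Gene-label permutation is the only meaningful null here: a
preranked weight vector has no sample labels to permute.

## The synthetic torpor generator

`simulate_torpor()` emulates the structure of multi-species torpor
compendia: two species, three tissues, states euthermia / torpor / IBA,
three replicates per tissue-state group, 2000 genes per species with 80%
one-to-one orthologs. Expression is built as
$X = (A_{true} P_{true} + U)\,\odot \text{noise} \odot \text{depth}$ where

* $P_{true}$ rows are indicator-like: one pattern per tissue, one per
  non-baseline state (euthermia, the normal condition, is baseline
  expression rather than a pattern of its own), and one tissue-by-state
  program; all rows carry a small uniform jitter (at most 0.1). State
  patterns are additionally modulated per tissue by a factor drawn once
  from $U(0.8, 1.2)$ — a tissue-varying torpor response. Without this
  modulation, tissue indicators and state indicators would both sum to the
  all-ones vector and the planted factorization would not be identifiable
  at $k_{true}$.
* $A_{true}$ gives every gene a lognormal baseline (meanlog 3, sdlog 0.7,
  TPM-like scale) spread over the tissue patterns, plants 40
  pattern-exclusive marker genes per pattern at `effect_size` (default 2)
  times baseline, and lets a quarter of the remaining genes load one
  state-like pattern non-exclusively. Tissue-by-state programs span only a
  few samples, so they receive a double share of marker and responsive
  genes — every planted program then carries comparable overall signal,
  and none is trivially sacrificed by a rank-limited fit.
* $U$ is the per-animal individuality: each sample deviates coherently on
  a random 5% of genes by an amount scaled by `individual_effect *
  noise_sd` relative to the cohort's mean baseline, and a few designated
  outlier animals (default 3 per species at about 3.3 times the usual
  magnitude) deviate strongly. Real cohorts always contain this component
  — it is why over-factorized fits split replicates into sample-specific
  patterns; with purely independent noise that phenomenon cannot occur at
  all. The default magnitudes place the strongest animal's deviation
  clearly above the diffuse noise floor but below the weakest planted
  program, the regime in which the pattern-count scan is informative.
* noise is elementwise lognormal (`noise_sd`, default 0.1) and depth a
  per-sample lognormal factor (`depth_factor_sd`, default 0.15) applied
  after structural column totals are equalized (TPM-like), so library
  size tracks the planted depth factors; `library_size` in the
  annotations is the realized column sum. With `noise_sd = 0` and
  `depth_factor_sd = 0` the data equal $A_{true} P_{true}$ exactly.

Shared patterns copy their orthologous-gene amplitudes across species, so
restricting two species to the ortholog map leaves identical planted
amplitudes — the ground truth for cross-species transfer tests. Everything
is a deterministic function of the scenario seed.

What the generator does **not** emulate: count-level sampling noise
(negative binomial dispersion), isoform structure, phylogenetically
calibrated divergence of non-shared genes, batch effects beyond a scalar
depth factor, and unbalanced designs. Tests passing on this generator show
the statistical machinery recovers planted structure under realistic
magnitudes; they do not certify performance on any particular real
compendium.

## Numerical choices and degenerate inputs

* Multiplicative updates guard denominators with $10^{-12}$; entries
  driven to zero stay zero, so non-negativity is exact, and an all-zero
  input yields a zero factorization with error 0.
* Consensus clustering treats constant sample-weight vectors as maximally
  distant (correlation set to 0) rather than propagating `NaN`.
* Marker ties (identical distances) resolve to the lowest pattern index;
  within-pattern rank ties resolve by gene identifier.
* Projection refuses rank-deficient amplitude matrices and targets with
  fewer shared genes than patterns rather than silently regularizing.
* The permutation p-value uses the add-one estimator, so it can never be
  zero; NES is `NA` when the null mean is zero.
* t-tests with zero pooled variance return $t = 0, p = 1$ on equal means
  rather than erroring.

## Problem sizes used in the test suite

The shipped tests exercise the full default scenario (2000 genes, 27
samples per species) where the property under test concerns the scan and
selection behavior, and scaled-down scenarios (150–400 genes, 2 tissues
by 2 states) where the property is structural (round trips, composition,
determinism), with simulation counts chosen to keep the whole suite at a
few minutes on one core while leaving the asserted success rates far above
their thresholds. Cross-species transfer calibration uses 100 simulations
for power (at the planted effect of twice the noise sd, three samples per
group) and 200 for the null rate, matching the sizes at which the binomial
bounds in the assertions are meaningful.

## Known limitations

* The multiplicative-update NMF is a point estimator; it provides no
  uncertainty on $A$ or $P$, and pattern identity across reruns is only
  up to permutation (tests match patterns by best correlation).
* The selection rule assumes replicated tissue-state groups; designs
  without replicates cannot distinguish sample-specific from real
  patterns, and `classify_patterns()' will not call `sample_specific`
  for singleton groups.
* Technical-pattern detection needs `library_size` annotations; without
  them depth-driven patterns land in `unclassified` or a metadata
  category.
* Cross-species transfer is limited to one-to-one orthologs by design;
  paralog-rich families are invisible to it.
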