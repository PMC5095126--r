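---
title: "Fragment-filtered SWATH quantification: models, parameters and design choices"
author: "diaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-filtered SWATH quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaquant)
```

# The quantification model

`diaquant` quantifies proteins from fragment-level XIC intensities of a
two-condition SWATH experiment with a nested replicate hierarchy:
biological replicates, digestion (trypsinolysis) replicates, and injection
replicates. The pipeline runs in the order: injection-level normalization
and averaging; reliable-fragment filtering; digestion- and
within-sample-type normalization/averaging; cross-sample normalization;
log-base-*B* protein roll-up and differential testing.

## Reliable-fragment selection

The filter rests on one assumption: a clean fragment's intensity is
proportional to its precursor's, so across samples all clean fragments of
a peptide trace proportional trends, while a fragment carrying
interference from a co-eluting contaminant follows a mixture of the two
trends and falls out of proportionality. Trend vectors are the
condition-level means of linear intensities (averaging over all replicate
runs of a sample type; fragments with a wholly missing condition are set
aside as incomplete and not clustered). Similarity between two trends is
the normalized spectral contrast angle

$$\mathrm{SA}(a,b) = 1 - \frac{2}{\pi}\arccos\!\left(
  \frac{a\cdot b}{\lVert a\rVert\,\lVert b\rVert}\right) \in [0,1],$$

which is 1 exactly for positive proportionality, 0 for orthogonality, and
invariant to rescaling either vector. Clusters are grown greedily: seed
with the most similar remaining pair if its SA reaches the threshold
$\tau$; repeatedly add the fragment whose *minimum* SA to all members is
largest while it stays $\ge \tau$ (so every cluster is pairwise
$\tau$-consistent); close, remove, repeat. Clusters with at least
`minTrend` members count as reliable, and only the largest reliable
cluster of each peptide is kept, ties broken by total intensity.

* $\tau$ defaults to **0.95**. This is a package choice (the procedure
  does not determine it): 0.95 corresponds to an angular tolerance of
  4.5°, which comfortably contains the scatter that replicate-averaged
  clean fragments show at the default noise levels (their trend vectors
  share the peptide's biological/digestion noise and differ only by
  averaged injection noise) while rejecting contaminant trends of
  independent direction. Raising $\tau$ never enlarges the reliable set.
* `minTrend = 3` fragments must co-trend, and the surrounding count rules
  (≥ 3 quantified fragments per peptide before clustering, ≥ 3 reliable
  fragments after, ≥ 3 peptides per protein before and after) follow the
  published analysis this pipeline reimplements.
* Keeping only the *dominant* cluster is a deliberate resolution of an
  ambiguity: retaining several mutually inconsistent clusters of one
  peptide would mix incompatible trend estimates into one peptide value.
* A fragment counts as "quantified" for the pre-exclusion counts when it
  is present in at least half of the runs.

On small instances (≤ 8 fragments) the greedy search can be checked
exhaustively: `maxConsistentSubset()` enumerates all subsets and returns a
maximum pairwise-$\tau$-consistent one. In randomized tests the greedy
reliable set matches the exhaustive optimum in well over 95% of cases;
the test suite asserts this.

## Hierarchical normalization

"Scaling normalization" is concretized as **median-of-log equalization**:
each run in a replicate group is multiplied by the factor that moves its
median log intensity (over the rows complete in every run of the group) to
the group's mean of medians. The factors' geometric mean is 1 by
construction, the operation is idempotent, and a mean-of-log center is
available via `center = "mean"`. Groups need `minSharedRows` (default 10)
complete rows; fewer is an error rather than a silent weak estimate.

Averaging collapses one hierarchy level at a time by the mean of log
intensities (missing values ignored; a cell is missing only if all its
replicates are). Averaging in log space keeps every multiplicative model
term exact: in the noiseless limit the pipeline reproduces true fold
changes to machine precision, which the test suite asserts at 1e-9.

Cross-sample normalization between sample types assumes most proteins are
unchanged and removes the **median of per-row log differences** — the L1
minimizer of the average absolute between-sample difference, robust up to
a 50% differential fraction. With more than two samples, shifts are solved
against the first sample and re-centered to geometric mean 1. At least 10
shared rows are required ("insufficient overlap" otherwise).

Biological-replicate resolution is preserved through the within-type
stage: the same per-type factors are applied to the replicate-resolved
table so that downstream statistics keep their n.

## Protein roll-up and testing

All fragment intensities are taken to $\log_B$ with **B = 1.4** — the base
is purely a reporting convention (fold-change columns read directly in
1.4-fold units); changing B rescales `log_B_fc` by the change-of-base
factor and leaves `linear_fc` untouched. Peptide values are means of
fragment logs; protein values are the **median of the top-3 peptides**
ranked by total intensity summed over all runs (ties broken
lexicographically by sequence, for determinism).

The roll-up is applied **per biological sample**: peptide logs are first
averaged over the technical levels only (injections within digestion
samples, digestion replicates within biological samples), the top-3 median
is taken per biological replicate, and the per-sample-type abundance is
the mean of those replicate values. The alternative — averaging fragments
over biological replicates before the median — was rejected because the
between-peptide ionization offsets then dominate the within-type noise and
the median locks onto a single peptide, inflating fold-change variance by
roughly 40% in simulation; with the chosen order the reported fold change
is exactly the difference of the group means of the quantity the t-test
compares.

Differential accumulation uses two simultaneous rules: linear fold change
above `fcThreshold` (default 1.4) and a two-sided Student's (equal
variance) t-test on the per-biological-replicate $\log_B$ values below
`alpha` (default 0.05). BH-adjusted q-values are reported informationally;
the flag itself is p-based, matching the published rule. Proteins with
fewer than two replicates per group are flagged "untestable" rather than
significant. p-values are computed on log abundances (a choice, documented
here, not a claim about the original analysis).

# The synthetic-data generator

`generateTruth()` + `simulateFragmentTable()` emulate the structure of a
fragment-level XIC export:

$$I_{fr} = s_r\, A_p\, 2^{L_p [c(r)\ne \mathrm{ref}]}\, q_{pep}\, w_f\,
  e^{\varepsilon_{bio}} e^{\varepsilon_{dig}} e^{\varepsilon_{inj}}
  \;+\; s_r\, t_{f,c(r)}\, e^{\eta_{bio}+\eta_{dig}+\eta_{inj}},$$

with per-run scale $s_r$ (log-uniform in [0.5, 2]), protein base abundance
$A_p$ (log-normal, median 5×10^4), true log2 fold change $L_p$ applied in
the non-reference condition, peptide ionization factor $q$ (log-normal,
log-sd 0.5), fragment share $w$ (normalized Gamma draws), and log-normal
noise with $\sigma = \sqrt{\log(1+\mathrm{CV}^2)}$ at each level. Values
below the LOD (default 100) are censored to missing.

Design choices worth spelling out:

* **Noise placement.** Biological noise is drawn per (peptide, biological
  replicate), digestion noise per (peptide, bio, digestion replicate),
  injection noise per (fragment, run). Fragments of one peptide therefore
  share the bio/dig factors — exactly the proportionality the spectral
  angle filter exploits — and protein-level CVs across biological
  replicates land near 0.13–0.15 at the default CVs (10/15/20% for
  injection/digestion/biological), the range reported for real chloroplast
  SWATH data.
* **Interference** is additive with its own per-sample-type trend
  (magnitude 2–4× the clean signal, direction log-normal with log-sd 1.5)
  and its own replicate noise, because contaminants are co-eluting
  peptides: molecules with biological variance of their own. A
  deterministic interference term would produce artificially confident
  false calls.
* **Defaults as study conditions.** 300 proteins, 10% differential at
  linear FC ∈ {0.25, 0.5, 2, 4}, 4–8 peptides per protein, 5–8 usable
  fragments per peptide, 30% interference fragments, the published
  replication (3 biological × 3/2 digestion × 3 injections; MRM: duplicate
  injections, no digestion level), and transcripts uncoupled from the
  proteome (rho = 0) by default.
* The MRM simulator caps panels at **3 best-flyer peptides** (highest
  ionization factors) and 4 transitions, and carries no interference —
  targeted transition lists are manually reviewed before export.
* Observed-peptide identifications for emPAI are Bernoulli draws per
  observable peptide with probability $1-e^{-\mathrm{fly}\cdot A/5\times10^4}$,
  so identification counts saturate with abundance the way the emPAI index
  assumes.

What the generator does **not** emulate: retention-time structure, m/z
errors, correlated (protein-level) biological variation, batch effects,
non-log-normal heavy tails, peptide-level missingness that is informative
beyond a hard LOD, and shared peptides. Passing tests on synthetic data
therefore demonstrate the algorithm's correctness and its behavior under
the stated noise model — not performance on any particular real dataset.

# emPAI and MRM branches

The in-silico digest cleaves C-terminal to K/R except before P; observable
peptides must fall in the 300–1250 Th precursor window at charge 2 or 3
(the charge states that dominate tryptic peptides; the acquisition
selected 2–5) with length 5–30, monoisotopic masses, fixed
carbamidomethyl-Cys (+57.02146 Da). All window settings are configurable
because identification software may use a different internal window.
`empai = 10^{N_{obs}/N_{obsable}} - 1`; it is zero iff nothing was
observed, strictly monotone in both counts, and fold changes are log2
ratios flagged undefined when either side is zero.

MRM transition lists are validated against the targeted-assay constraints
(length 5–30, fully tryptic without missed cleavage, charge 2–4, ≤ 4
transitions, ≤ 3 best-flyer peptides per protein). Injection duplicates
are median-equalized at the peptide level; samples are then scale-aligned
at the protein level, each protein with ≥ 2 peptides contributing the mean
log area of its 2 most intense peptides, and the per-sample correction
taken as the **median** over proteins. The median (rather than a mean) is
deliberate: validation panels are enriched for differential proteins, and
a mean would absorb part of the signal — with the median, noiseless fold
changes are recovered exactly as long as most panel proteins are
unchanged. Protein-level MRM abundance is the mean log area of the 2 most
intense peptides (the roll-up is not dictated by the normalization rule;
this is the package's choice). Testing is Student's t across biological
replicates with BH control at FDR < 0.05.

# Transcript integration

Proteins pair with transcripts by exact identifier equality, with an
optional two-column map for namespace exceptions; ambiguous and unmatched
entries are reported, not silently dropped. The transcript call uses the
stringent two-part rule (FDR < 0.05 **and** |log2 FC| > 2); an FDR-only
mode is available via `transcriptLfc = 0`. Classes are the nine
protein × transcript combinations; class counts always sum to the number
of paired genes, and calls are invariant to the choice of B.

# Numerical choices and degenerate inputs

* Cosines are clamped to [−1, 1] before `acos`; an all-zero trend vector
  is an error (undefined angle), as are length mismatches.
* Normalization groups of one run are a warning + no-op; zero shared rows
  an error.
* t-tests on degenerate (constant) groups return NA p-values and the
  protein is reported "untestable", never silently significant.
* Ranking ties (peptide intensity) break lexicographically; cluster-size
  ties break by total intensity. All randomness flows from explicit seeds;
  identical inputs give byte-identical outputs.

# Validation strategy and problem sizes

The test suite validates each operation against independent oracles
(direct formula evaluation for the spectral angle, exhaustive subset
search for the clustering, a hand-written step-up for BH), asserts the
exactness limits (noiseless recovery ≤ 1e-9; cascade invariance ≤ 1e-6 in
log units under rescaling of any single run), and measures end-to-end
recovery on the default 300-protein study — a size chosen so the full
suite runs in well under a minute per study while keeping the
false-positive count interpretable. At those conditions the pipeline
recovers true log2 fold changes with median absolute error ≈ 0.13–0.15,
calls ≥ 90% of true ≥ 2-fold changes, rejects ≥ 90% of interference
fragments while retaining ≥ 97% of clean ones, and agrees with the MRM
branch at r ≥ 0.95.

# Known limitations

* **False-discovery behavior is tail-sensitive.** With ~30 true calls, the
  empirical FDR of the ">1.4-fold and p < 0.05" rule is driven by a
  handful of null proteins whose top-3 median locks onto one peptide
  (between-peptide ionization offsets exceed the within-type noise), and
  fluctuates between ~0 and ~0.2 across simulation seeds. A q-value-based
  rule would be more stable; the p-based rule is kept because it is the
  published one, with q-values reported alongside.
* The filter needs ≥ 3 fragments following a common trend; peptides where
  interference leaves fewer than 3 clean fragments are lost entirely.
* Cross-sample normalization assumes < 50% of rows change in one
  direction; strongly asymmetric proteomes would bias all fold changes.
* The transcript branch consumes a differential-expression table; it does
  not refit counts, and its FDR is taken at face value.
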