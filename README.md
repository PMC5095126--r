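# diaquant

Fragment-filtered label-free protein quantification for SWATH/DIA mass
spectrometry, with companion emPAI, targeted-MRM and proteome–transcriptome
concordance analyses.

## The problem

In data-independent acquisition (SWATH-MS), quantification rests on
fragment-level extracted-ion-chromatogram (XIC) intensities matched against
an ion library. Summing all fragment intensities per peptide — the vendor
default — has almost no quality control: co-eluting contaminants contribute
interference to individual transitions and corrupt the protein estimate.
`diaquant` implements a quality-controlled alternative for comparative
studies (two sample types, e.g. a stress condition against its source
tissue, with biological, digestion and injection replicates):

1. **Reliable-fragment selection.** Because each fragment's intensity is
   proportional to its precursor, the *trends* of clean fragments across
   samples are proportional to one another. Trend similarity is measured
   with the normalized spectral contrast angle,
   `SA(a,b) = 1 − 2θ/π`, `θ = arccos(a·b / |a||b|)`,
   and fragments are grouped by a greedy iterative cluster search; only the
   dominant cluster of at least 3 co-trending fragments per peptide is kept.
   Peptides with < 3 quantified fragments and proteins with < 3 quantified
   peptides are excluded.
2. **Hierarchical normalization.** Median-of-log scaling equalizes runs
   within each replicate group, followed by log-mean averaging — first over
   injections, then digestion replicates, then within sample type — and a
   final cross-sample scale normalization between sample types (median of
   per-row log differences, the L1 minimizer, under the assumption that
   most proteins do not change).
3. **Protein quantification.** Fragment intensities are taken to the
   logarithm base *B* (default 1.4), averaged per peptide, and rolled up per
   biological sample as the median of the top-3 most intense peptides. Fold
   change is the between-type difference of these values raised to the
   power *B*; differential accumulation (DAP) requires > 1.4-fold change
   and Student's t-test p < 0.05 across biological replicates.

Companion branches: **emPAI** (`10^(N_observed/N_observable) − 1` from an
in-silico tryptic digest restricted to the precursor m/z window) for
proteins identified but not quantified; **MRM** peak-area quantification
(best-flyer peptide panels, peptide/protein-level normalization,
Benjamini–Hochberg FDR) for orthogonal validation; and **concordance
classification** of protein vs transcript calls (transcript rule:
FDR < 0.05 and |log2 FPKM ratio| > 2) into the nine up/down/unchanged
combinations.

A synthetic-data generator produces fragment tables with known ground truth
(hierarchical log-normal noise, per-run scale factors, additive
interference transitions, LOD censoring), so every stage is testable
without raw instrument data.

## Worked example

```r
library(diaquant)
st <- runFullStudy(studyConfig(seed = 1))
round(st$summary, 3)
#>          n_quantified                n_daps          medae_log2fc
#>               297.000                32.000                 0.146
#>     sensitivity_2fold         empirical_fdr interference_rejected
#>                 0.933                 0.125                 0.913
#>        clean_retained           swath_mrm_r         swath_empai_r
#>                 0.974                 0.970                 0.450
#>  transcript_protein_r             median_cv
#>                 0.063                 0.146
```

Of 300 simulated proteins (10% truly changing, 30% of fragments carrying
2–4× interference), 297 are quantified; the filter removes 91% of
interference fragments while keeping 97% of clean ones; 93% of the true
≥2-fold changes are called, with median |log2 FC| error 0.146; SWATH and
MRM fold changes agree at Pearson r = 0.97 on a 60-protein validation
panel. The top of the protein table:

```r
q <- st$swath$quant
head(q[order(q$p_value),
       c("protein_id", "log_B_fc", "linear_fc", "p_value", "dap_flag")], 3)
#>    protein_id log_B_fc linear_fc  p_value dap_flag
#> 70      P0070     4.19     4.094 3.38e-05       up
#> 44      P0044     4.45     4.472 8.03e-05       up
#> 39      P0039    -4.10     0.252 9.89e-05     down
```

`log_B_fc` is on the log-1.4 scale (a value of 1 is a 1.4-fold change);
`linear_fc = 1.4^log_B_fc`. User data enter through `readIonLibrary()`,
`readFragmentTable()`, `readMrmAreas()` and `readExpressionTable()`; a thin
command-line front end lives at `inst/scripts/diaquant-cli.R`
(subcommands `simulate`, `swath`, `full`).

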