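# rloopscan

Analysis toolkit for **strand-specific R-loop maps** and the **sequence
grammar of R-loop-prone regions**, aimed at epigenomics groups studying
co-transcriptional R-loops (e.g. R-ChIP/DRIP-style data) and their impact
on gene expression.

R-loops — three-stranded structures of an RNA:DNA hybrid plus a displaced
single DNA strand — form co-transcriptionally where the non-template
strand favors them. `rloopscan` centers on a two-part grammar on the
non-template strand: an upstream **G-rich / GC-skewed cluster**
(`skew = (G−C)/(G+C)`) that licenses strand displacement, coupled with a
downstream **T-run** (a maximal poly-T tract, length `L ≥ 5`) where RNA
polymerase II stalls. The package provides:

* **`simgen`** — a synthetic-data generator: genomes + gene models from
  species profiles, planted `G^g·spacer·T^L` motifs in introns, stranded
  Poisson coverage for control/knockdown conditions, negative-binomial
  count matrices, and a full ground-truth table (`simulate_genome`,
  `plant_motifs`, `simulate_coverage`, `simulate_counts`,
  `write_dataset`).
* **`peakcall`** — stranded Poisson peak calling with local background
  `max(genome mean, 10 kb window mean)`, condition comparison
  (common/gained/lost), TSS/TTS/genebody/intergenic annotation, width
  statistics, summit metaprofiles (`call_peaks`, `compare_peak_sets`,
  `annotate_context`, `peak_length_stats`, `metaprofile`).
* **`seqfeat`** — non-template-strand features: GC skew, G%, T%, maximal
  T-run inventory, head/tail split at the summit, T-run association,
  distance to the nearest 3′ splice site, G% by T-run-length bins, k-mer
  enrichment, matched random-region samplers.
* **`rloopclf`** — an RBF-kernel SVM (in-package SMO solver; logistic
  fallback) on (GC skew, G%, T%) separating T-run-associated R-loop
  regions from random T-run regions, with stratified 5-fold CV, ROC/AUC
  (`AUC = U/(nm)` exactly), a sense-strand genome scanner and per-gene
  hit counts.
* **`expr_assoc`** — median-of-ratios normalization, a moment-matched
  negative-binomial Wald test, BH adjustment, exact/approximate
  Mann–Whitney U, gene-class association with gene length and motif
  burden, and a two-species contrast.
* **`workbench`** — `run_pipeline()` orchestrating all of the above from
  one seed, plus a CLI (`exec/rloopscan`).

## Worked example

```r
library(rloopscan)

rep <- run_pipeline(pipeline_config(seed = 42))   # defaults: 800 genes/species
rep
#> RunReport (seed 42 )
#>  peaks:
#>      set   n
#>  control 591
#>       kd 746
#>   common 591
#>   gained 155
#>     lost   0
#>  GB fractions:
#>     set gb_fraction
#>  common   0.2047377
#>  gained   0.9225806
#>  classifier:
#>  cv_accuracy    cv_auc
#>    0.8586626 0.8971647
#>  DE classes:
#>  species n_down n_up n_nochange
#>        A     11   17        772
#>        B      0    2        798
#>  species contrast:
#>  affected_ratio median_length_a median_length_b    p_len_a p_len_b
#>              14           22287          7436.5 0.07559239      NA
```

Reading the output (about 3 minutes on one CPU): knockdown adds 155
*gained* peaks on top of 591 *common* ones; gained peaks are almost all
in genebodies (92%) while common peaks are TSS-dominated (20% GB) — the
gained fraction concentrates at the planted G-cluster→T-run loci. The
classifier separates T-run-associated peaks from random T-run regions at
86% cross-validated accuracy. In the expression arm the long-intron
(human-like) profile has 14× more affected genes than the short-intron
profile; the short-intron profile has no down class at all (its length
test is reported NA). Down-class length enrichment is borderline at this
scale (p = 0.076); the acceptance suite runs the expression arm at 2,000
genes per species, where it is significant (p ≈ 0.0095).

## Documentation

`vignettes/rloopscan-methods.Rmd` documents the models and assumptions:
the synthetic world's parameters and what each one states, the coverage
kernel choice, caller/background math, classifier construction, DE test
calibration, and what a passing test suite does and does not establish.
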