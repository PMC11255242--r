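---
title: "Models and methods behind rloopscan"
author: "rloopscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rloopscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`rloopscan` implements a complete, self-contained analysis of
strand-specific R-loop mapping data and its sequence grammar: a stranded
Poisson peak caller with condition comparison and genomic-context
annotation; non-template-strand sequence features (GC skew, G%, T%,
maximal T-run inventory, head/tail partition at the summit, distance to
3' splice sites, k-mer enrichment); an SVM classifier separating
T-run-associated R-loop regions from random T-run regions, with a
genome scanner counting predicted R-loop-prone regions per gene;
negative-binomial differential-expression testing with gene-length and
motif-burden association; and a two-species contrast of those
associations. Because public R-loop datasets are large,
alignment-dependent and threshold-sensitive, the package ships a
first-class synthetic-data generator whose defaults state a fixed,
documented world; every downstream stage is validated against that
world's planted ground truth.

# The synthetic world

## Genomes and gene models

A species profile fixes gene number and the log-normal laws of exon and
intron lengths. The `human_like` profile uses intron lengths
`lognormal(meanlog 8.0, sdlog 1.0)` (median ~3 kb, heavy upper tail);
`mouse_like` uses `lognormal(7.0, 0.7)`. The reduced mouse `sdlog`
implements, not just a shorter median, but a compressed upper tail: the
biological statement that the analogues of the longest human genes are
disproportionately shorter in mouse. This choice is load-bearing for the
species contrast: with equal tail dispersion the motif-bearing mouse
genes remain strongly length-distinguished and the "length effect only
in the long-intron species" direction cannot emerge. Genes get 4-8 exons
(uniform), exon lengths `lognormal(5.0, 0.4)` (~150 bp median), random
strand, and exponential intergenic gaps; the chromosome is sized
automatically with 30% headroom. The background base composition is
A/T 29.5%, C/G 20.5% each (genome-like 41% GC).

## The planted grammar

Each planted motif is the literal sense-strand sequence
`G^g . spacer . T^L` written into an intron (reverse-complemented on the
plus strand for minus-strand genes). The spacer is drawn from the
background composition so the G cluster and T-run are unambiguous.
T-run lengths are uniform on 8-19 (the grammar's flagship runs are long;
a T5 threshold is used only for *detecting* association downstream).
G-cluster length is coupled negatively to T-run length
(`g = round(31 - 0.9 L) +/- 2`, clamped to [10, 30]): the world's
statement that a longer T-run reduces the reliance on G richness, which
downstream analysis must recover as a negative G%-vs-L trend. Motifs are
placed with probability proportional to intron length at a density of
1.5e-5 per intron bp, 100 bp clear of intron boundaries; introns too
short are skipped with a warning, never truncated.

Coverage amplitudes come in two classes: *strong* (amplitude 50,
knockdown gain 1.5) and *weak* (amplitude 5, knockdown gain 6; 60% of
motifs). The weak class sits below the caller's detection threshold in
the control condition (~4% detection) and far above it after knockdown
(~100%), which is the generator's mechanism for *gained* peaks. In
addition, 60% of genes receive a promoter peak (amplitude 50, gain 1) at
their TSS with no planted motif, so the common peak set has the
TSS-dominated composition that real R-loop maps show and the
gained-vs-common genebody contrast has something to contrast against.

## Coverage model

Per-position counts on each strand are
`Poisson(depth + sum_i A_i exp(-|x - c_i| / b))` with background depth 2
and kernel scale `b = 30` bp, anchored at each motif's G-cluster/spacer
boundary on the host gene's strand. The exponential (cusped) kernel is a
deliberate choice over a Gaussian: the caller defines the summit as the
leftmost coverage argmax, and under Poisson noise a flat-topped kernel
of any realistic amplitude cannot localize the argmax to +/-10 bp,
whereas the cusp concentrates it (measured: 98-100% of summits within
+/-10 bp at the default amplitudes). The cost is that called peak widths
(median ~130-200 bp depending on amplitude) sit slightly below the
~180-210 nt medians reported for real data; widths are reported but not
asserted. No claim is made that this kernel models the assay's physics —
the assay's signal model is not published, and the kernel is a stated
free parameter of the world.

## Counts

Gene-level counts are negative binomial with dispersion `phi = 0.1`,
baseline means `lognormal(5, 1)`, two replicates per condition. The true
knockdown effect is `log2FC = -beta min(m_g, 4)` with `beta = 0.5`,
where `m_g` is the gene's planted motif count. Compensatory upregulation
(`+1.5`) is assigned to a number of motif-free genes equal to 10% of the
motif-bearing gene count: the up class is motif-poor by construction and
its size scales with the perturbation's impact, so a species with fewer
motif targets also has fewer upregulated genes (a fixed per-gene up rate
would instead equalize the two species' affected-gene counts and erase
the cross-species contrast). With placement proportional to intron
length, `m_g`
correlates with gene length, so downregulation concentrates in long,
motif-burdened genes — the causal chain the association analysis must
recover.

# Peak calling

A position seeds a peak when its count `x` satisfies
`P(X >= x | Poisson(lambda_local)) < pval_cut`, with
`lambda_local = max(genome mean, mean over a 10 kb window)`; the max
suppresses calls inside broad elevated regions while keeping sensitivity
in flat background. Seeds separated by gaps of at most `merge_gap = 50`
bp merge; intervals narrower than `min_width = 50` bp are dropped.
Summit = leftmost argmax (deterministic tie-break); intensity = CPM
(interval coverage over total library coverage x 1e6; the read-length
equivalent cancels); the peak p-value is the Poisson upper tail of the
summit count. `fixed_lambda` overrides background estimation for
controlled experiments. The caller is verified against an independently
written brute-force scan (filter-based windows, explicit merge loop) on
1,000 random coverage vectors.

Condition comparison pairs same-strand peaks overlapping by >= 1 bp,
matching each knockdown peak to the control peak of largest overlap
(ties: leftmost). `|common| + |gained| = |kd set|` holds identically;
the control-side analogue holds when the matching is injective (two
knockdown peaks claiming one control peak is possible and is the honest
behavior of an overlap-based rule). Context labels are assigned by
summit position against same-strand genes with precedence
TSS > TTS > GB > intergenic and +/-1 kb windows in transcription
orientation.

# Sequence features

All features are computed on the sense (non-template) strand — the
displaced strand of an R-loop. GC skew is `(G - C)/(G + C)` (0 when
undefined); percentages are over the full sequence length with ambiguous
bases counted in the denominator only. T-runs are maximal runs of >= 5 T
by default; a peak is *T-run-associated* when its tail half (downstream
of the summit) contains one — encoding the grammar's geometry, G-rich
head upstream, T-run downstream. The association threshold of 5 follows
the shortest run the grammar discusses; the *scanner* (below) uses the
planted minimum of 8 instead, because background T5 runs occur in a
third of all windows and carry no signal in this world.

k-mer enrichment (k = 6 by default; 4^12 tests would not be desk-scale)
compares target k-mer counts with a background set, BH-adjusted across
all 4^k tests. Two numerical choices keep the test calibrated at desk
scale, where a naive plug-in binomial rejects a clean null in 25-35% of
runs: counting is frame-disjoint (step k), since overlapping occurrences
of self-overlapping words (homopolymers above all) clump and
overdisperse binomial counts; and the p-value is the one-sided
hypergeometric (Fisher) tail conditioned on the combined count, which
accounts for the background itself being a finite sample. So configured,
a background-drawn target is significant in 0/20 seeded runs while a
planted poly-T motif still reaches q ~ 1e-12. The procedure is a
defined, reproducible stand-in for de novo motif discovery; on head/tail
halves of T-run-associated synthetic peaks it ranks a G-rich 6-mer and
the poly-T 6-mer first, respectively.

The G%-vs-T-run-length trend is evaluated on genebody T-run-associated
peaks. Promoter peaks associated through incidental background T5 runs
have background G% at the shortest run lengths and would otherwise
dilute the planted negative trend to ~0; the published analysis this
mirrors concerns genebody-resident T-run R-loops.

# The classifier and the scanner

The classifier is a soft-margin SVM with RBF kernel on the three
standardized features (GC skew, G%, T%), `C = 1`, bandwidth
`gamma = 1/(3 x pooled feature variance)` (= 1/3 after standardization).
No SVM backend is available in the target environment, so the dual
problem is solved in-package by SMO with maximal-violating-pair
working-set selection; the solver is deterministic given the data.
A logistic-regression fallback provides a fully deterministic
alternative. Performance is reported as stratified 5-fold CV accuracy
plus the ROC/AUC of pooled CV decision scores; AUC is integrated by
trapezoid over tie-grouped thresholds, which equals the Mann-Whitney
`U/(nm)` exactly (asserted to 1e-9).

Positives are the T-run-associated called peaks; negatives are random
*T-run-containing* gene regions, length-matched to the positives. Using
unconstrained random regions instead makes the scanner's false-positive
class (T-runs without G context) invisible during training and roughly
halves scan precision.

The scanner slides a window along each gene's sense strand, skips
windows whose tail half lacks a T-run >= `min_trun`, scores the rest,
and merges overlapping positive windows into hits. The pipeline scans
with a 150 bp window (matched to called peak widths so training and
scan regions have comparable composition; with a 300 bp window the
planted G cluster is diluted by background sequence and per-gene count
recovery degrades), 50 bp step, `min_trun = 8`. Hits are attributed to
the same-strand gene containing their midpoint.

# Differential expression and association

Size factors are median-of-ratios (genes with any zero excluded from
factor estimation). The DE test is a moment-matched negative-binomial
Wald test: per-gene log2 fold-change of normalized condition means with
pseudo-count 0.5; per-gene method-of-moments dispersion shrunk toward a
`phi ~ a0 + a1/mu` trend with prior weight `df/(df + 20)` (with 2 + 2
replicates, ~91% trend); Wald z with variance `(1/mu + phi)/n` per
condition on the log2 scale; BH q-values. Under the global null (20
simulations, 2,000 genes, 2 vs 2, phi = 0.1) raw p-values are calibrated
(~5% below 0.05) and the realized false-discovery proportion at
q <= 0.05 stays within the BH guarantee plus Monte-Carlo tolerance.
This simple estimator is adequate for the 2 vs 2 synthetic design it
serves; it is not a replacement for mature DE frameworks on real data.

Classes are `down`/`up` at |log2FC| >= 1 and q <= 0.05 (configurable);
"long gene" is never dichotomized — class comparisons use full-
distribution two-tailed Mann-Whitney U tests (exact via the Wilcoxon
distribution when min(n, m) <= 8 without ties — verified against
complete enumeration — otherwise normal approximation with tie and
continuity corrections). The association report gives per-class
median/IQR box-plot summaries and down-vs-nochange, up-vs-nochange
tests on gene length and motif burden; classes with n < 3 are flagged
and skipped.

The species contrast pairs orthologs (shared gene index in synthetic
data), reports per-species affected-gene counts and their ratio, and
each species' down-vs-nochange length test. In the stated world the
human-like profile shows ~2-4x more affected genes and a significant
length effect, while the mouse-like profile's length effect is null in
most seeds; the much larger (>10-fold) count differences reported for
real cell systems also reflect cell-type and pathway differences this
generator does not model.

# What a green test does and does not establish

The generator emulates: stranded peaks with summit-anchored signal;
gained peaks arising from sub-threshold loci amplified under knockdown;
a G-cluster/T-run grammar with negative G/L coupling; motif-burden-
driven downregulation concentrated in long genes; and two species
differing in intron-length architecture. It does not emulate: read-level
noise, mappability or duplicate structure; replicate-aware peak calling;
transcription kinetics; co-transcriptional splicing; real motif
diversity (degenerate G-quadruplex contexts, interrupted runs); or
between-gene correlation of expression. Green acceptance therefore
establishes that the implementations are correct against oracles and
that the analysis recovers the stated causal structure when present —
not that the defaults are tuned to any real dataset's absolute numbers
(peak counts, the 86% accuracy figure, exact width medians are
explicitly out of reach at desk scale and are not asserted).

# Numerical and degenerate-input choices

Poisson exceedance uses the upper tail `P(X >= x)` via `ppois(x - 1)`;
empty coverage yields an empty peak set, not an error. GC skew of a
G/C-free sequence is 0 by convention. SEM of a single-region bin is NA
(flagged), empty bins report n = 0 with undefined mean. `bh_adjust`
validates p in [0, 1] and restores input order. All randomness flows
from one seed through `stage_seed(seed, stage)` (a polynomial hash into
the 31-bit range), so any stage can be regenerated independently;
`withr::with_seed` isolates the RNG so library calls never perturb user
state. Classifier model files are plain text (header plus support-vector
table) and round-trip the decision function to 1e-8.
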