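---
title: "Methods: splicing efficiency, CLIP peak context, miRNA loci and AFM stiffness"
author: "spliceclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing efficiency, CLIP peak context, miRNA loci and AFM stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceclip)
```

## What the package computes

`spliceclip` implements the quantitative core of a common class of RNA-binding
protein (RBP) studies: relate the protein's CLIP-seq binding landscape to

1. **intron splicing efficiency**, measured from junction-spanning reads;
2. **miRNA expression**, as a function of distance to CLIP peaks and of the
   host-intron context of each miR;
3. **interactome overlaps**, via the hypergeometric representation factor; and
4. **cell stiffness**, via conical-indenter (Sneddon) Hertz fits of AFM
   force-indentation maps.

All stages run end to end on synthetic data whose effects are planted by the
package's own generator, so every statistical claim the pipeline makes can be
checked against a known truth.

## Splicing efficiency from junction reads

For each intron, `ee` counts exon-exon junction-spanning reads (spliced
molecules) and `ei` counts exon-intron boundary-spanning reads (unspliced
molecules, donor- and acceptor-side pooled — the two sides are not separated,
so readers that distinguish them must sum). Splicing efficiency is

$$ SE = \frac{ee}{ee + ei} \in [0, 1], $$

1 meaning fully spliced and 0 fully retained. At the gene ("transcript")
level, counts are pooled over the gene's unique introns *before* dividing,
which weights introns by coverage. Rows with `ee + ei < min_reads`
(default 10) are flagged missing rather than zero: a ratio on a handful of
reads is noise, and imputing 0 would masquerade as full retention.

The intron set itself is built from the annotation as the *unique,
non-overlapping* intron complement of each gene's exons: candidate introns
are the gaps between consecutive exons of each transcript; candidates
identical across isoforms are emitted once; any candidate overlapping an
exon of *any* isoform of the same gene is dropped entirely (not truncated),
because a junction count for a half-intron has no clean interpretation.
Among surviving overlapping candidates, the one from the lexicographically
smallest transcript id is kept — the choice is arbitrary in principle, so it
is made deterministic. Ordinals are assigned 5'→3' on the gene strand.
Genes sharing a locus on opposite strands are processed independently.

Contrasts: `delta_splicing_efficiency()` averages SE over replicates per
condition and takes the per-intron difference of means (a difference of
medians would also be defensible; means were chosen because the replicate
count is small and the per-intron estimates are binomial means themselves).
`group_se_by_cluster_count()` bins features by the number of overlapping
CLIP clusters — default bins {0}, {1–2}, {3–5}, {≥6}, configurable since
figure-style "cluster groups" rarely print their edges — and
`compare_se_groups()` runs a tie-corrected Kruskal–Wallis test followed by
Dunn's all-paired z tests with Benjamini–Hochberg adjustment (the adjustment
is configurable; BH is the default since the all-paired test family is what
is being controlled).

## CLIP peak context

Peaks pass a significance filter of `log2fc >= 3` and adjusted
`p <= 0.001` (inclusive bounds). Each peak gets exactly one genomic
category by strand-matched overlap in a fixed priority order —
CDS exon > 5'UTR > 3'UTR > noncoding exon > protein-coding intron >
noncoding intron > intergenic — so a peak straddling an exon boundary is
called exonic. Distances to features are edge-gap distances (0 for any
overlap), with ties broken toward the smaller genomic start so results are
reproducible; whether a study measures from peak edges or centers is often
unstated, and the edge convention is the one `bedtools closest` users
expect. For motif work, the peak "position" is instead the integer midpoint
(floor), and 101-nt windows (center ± 50) are extracted and
reverse-complemented on the minus strand.

Metaprofiles:

* `exon_metaprofile()` anchors on exons: a 300-nt intronic flank on each
  side (10-nt bins) and the exon body rescaled to 100 bins, strand-oriented,
  mean ± SEM across exons. Flank length and bin scheme are conventions of
  this package (configurable), since the figure-style plots they emulate do
  not print theirs.
* `premir_metaprofile()` extends each pre-miR by 2000 nt, rescales the
  region to a common 5000-nt axis and aggregates by per-bin medians within
  a feature, then mean ± SEM across features.
* `cassette_exon_map()` profiles two windows per cassette-exon event in
  transcript orientation — 250 nt of intron before the 3' splice site plus
  50 nt of exon, and 50 nt of exon plus 250 nt of intron after the 5'
  splice site — as RPKM(IP)/RPKM(SMI) per 50-bp bin, averaged across events
  per direction class (|ΔPSI| ≥ 0.2). One read is added to each bin's IP
  and SMI totals so empty input bins cannot divide by zero; when IP and SMI
  are identical tracks the profile is exactly 1 everywhere, which is the
  unit test of the normalization.

## miRNA locus analysis

Each mature miR is assigned one of four mutually exclusive categories with
precedence *lt2kb* (closest peak at ≤ 2000 nt — the bound is taken
inclusive; whether "<2 kb" includes exactly 2000 is unstated in the style
of analysis this emulates) > host-intron context (`gt2kb` protein-coding /
noncoding intron, decided by the *mature* miR lying within a classified
intron) > *other*. Expression per miR is summarized as log2(baseMean),
baseMean being the mean of normalized counts over **all** samples.
Normalization is median-of-ratios (per-sample median of count/geometric-mean
ratios over features nonzero everywhere), rescaled to geometric mean 1.

Fold changes use the manual formula
$\log_2[(N_x + 1)/(N_y + 1)]$ with $N$ the per-condition mean of normalized
counts; the +1 stabilizes low counts and makes the formula antisymmetric in
the two conditions. The DE filter keeps features with |log2FC| ≥ 1,
padj ≤ 0.05 and baseMean ≥ 5 (miRs) or ≥ 10 (genes), all inclusive. In the
synthetic pipeline the per-feature p-values come from a two-sided
Mann–Whitney test with BH adjustment — deliberately simple, since
negative-binomial GLM machinery is out of scope here — and externally
computed DE tables with the same columns pass through the filter unchanged.
The miR–target filter keeps (miR, gene) pairs with strictly opposing,
nonzero fold changes and a target score ≥ 60.

## Hypergeometric overlap

For sets of sizes $n_1, n_2$ from a universe of size $N$ with observed
overlap $k$: expected overlap $n_1 n_2 / N$, representation factor
$k / \mathrm{expected}$, and upper tail $P(X \ge k)$ from the
hypergeometric distribution (computed by `phyper`, which is stable in log
space at extreme significance). The universe must be supplied explicitly —
a background size silently defaulted is the most common way this statistic
is abused. Note that published representation factors are not reproducible
without the universe size, which is why the package treats them as inputs
to check, not targets to match.

## AFM stiffness

Force curves follow the Sneddon cone model

$$ F = \frac{2}{\pi} \tan(\theta)\, \frac{E}{1 - \nu^2}\, \delta^2 $$

with Poisson ratio ν = 0.5 (incompressible) and half-cone angle θ = 22° by
default. The prefactor convention (2/π with tan θ) is stated explicitly
because instrument software does not always print its own.

Contact-point estimation is two-stage: a baseline (first 30% of the
approach curve) gives a coarse contact index as the first position whose
force exceeds baseline + 3 noise-SD for 5 consecutive samples; the contact
position is then refined by minimizing the residual sum of squares of the
piecewise model $F = a(z - z_0)_+^2 + c$ over $z_0$ (a 41-point grid scan
over a wide window followed by local optimization, because threshold
detection alone is systematically late on soft samples where the force
rises slowly through the noise floor). Modulus fitting restricts to
indentation depths of 150–500 nm and is ordinary least squares of
$F = a\delta^2 + c$ with the force offset free, so the estimate is exactly
invariant to a constant force shift and exactly linear in a rescaling of
the force axis.

Modulus maps assemble per-pixel fits on the acquisition grid; the height
image is derived from the piezo position at maximum force (relative height,
shifted to a zero minimum). Colony centers are the height mask above a
relative threshold (default 0.5), eroded by a configurable margin
(default 1 pixel, 8-neighborhood); on grids so small that the full margin
would empty the mask, erosion stops early with a warning rather than
returning nothing. Outlier handling is MAD normalization
$(v - \mathrm{median})/\mathrm{MAD}$ with the 1.4826 normal-consistency
constant and a 3.5 cutoff. Group comparison is Kruskal–Wallis plus
Games–Howell pairwise tests (Welch statistics, Welch–Satterthwaite degrees
of freedom, studentized-range reference via `ptukey`) — appropriate because
stiffness distributions across colonies are routinely heteroscedastic.
Whether all pixels are pooled per group or per-colony medians enter the
test is often underspecified in published figure legends; the package pools
by default and the comparison functions accept any grouping the caller
prepares.

## The synthetic-data generator

The generator is first-class, tested code. Its defaults define the study
conditions everything else is validated under:

* **Annotation**: 150 genes with 2–8 exons (100–300 nt) and introns of
  500–8000 nt on one contig; 30% noncoding genes; 30% of genes carry a
  skipped-exon second isoform to exercise the redundant-intron rules; CDS
  trimmed by 50-nt UTRs at transcript ends. 200 miRs (70-nt pre-miR, 22-nt
  mature), 60% placed inside introns, 40% flagged for peak placement.
* **Peaks**: Poisson(2) clusters per intron with donor-biased positions
  (exponential offset, 150-nt scale); one peak on or near each flagged miR
  (half overlap the miR, the rest an exponential 300-nt-scale gap,
  truncated at 1500 nt); non-intronic peaks are topped up so the planted
  intronic fraction is 0.87; 10% sub-threshold peaks exercise the filter.
* **Junction counts**: intron $i$ with binned cluster count $g(c) \in
  \{0,1,2,3\}$ and genotype dose $d \in \{0, 0.5, 1, 2\}$ has true
  $SE = \mathrm{clip}(0.8 - 0.05\,g(c) + 0.05\log_2(1+d),\ 0.01,\ 0.99)$,
  and each of 4 replicates draws $ee \sim \mathrm{Bin}(200, SE)$.
* **miR counts**: negative binomial with variance $\mu + 0.3\mu^2$, mean
  $\exp(\log 100 + 1.5\cdot[\mathrm{lt2kb}] + 0.5\cdot[\mathrm{noncoding\
  intron}])$, 16 samples in two conditions with a 4-fold change planted in
  20% of miRs (16 samples because the rank-test p-value floor at 6 samples
  cannot clear BH adjustment at 200 features — a real design consideration
  for small cohorts).
* **Force curves**: 1-nm z-sampling from 200 nm before to 600 nm past
  contact, 5% multiplicative force noise plus a 10-pN additive floor, ±20 nm
  contact jitter, per-curve force offsets, Gaussian-dome colony height;
  group moduli 1, 2.5, 3.5 and 5 kPa by default, the Argonaute-null-like
  group softest and the combined-overexpression group stiffest.
* **Interactomes**: two 100-gene lists from a 1000-gene universe with an
  exactly constructed overlap of 20.

What the generator does **not** emulate: read-level alignment artifacts,
multimapping, batch effects, library-size pathologies, annotation errors,
tip-shape deviations from an ideal cone, adhesion in the force curves, or
viscoelastic drift. Passing tests therefore demonstrate correctness of the
computations under the stated models, not robustness to every failure mode
of real data.

## Numerical choices and limitations

* All intervals live in 1-based closed coordinates inside `GRanges`; GTF
  (1-based) and BED/bedGraph (0-based half-open) conversions happen in
  `rtracklayer` at the I/O boundary. A single internal convention avoids
  off-by-one drift; the cost is that positions quoted here are 1-based.
* The Kruskal–Wallis statistic with every observation tied is defined as
  H = 0, p = 1 (no rank variation), where the textbook formula is 0/0.
* Dunn's z and Games–Howell were validated against permutation oracles and
  Tukey HSD limiting cases respectively; at group sizes below ~8 the normal
  approximation in Dunn's test is visibly loose, which is why the package
  excludes groups with fewer than 2 observations and why small categories
  are excluded from miR comparisons with a warning.
* At 0.5 kPa under the default noise model, the windowed Hertz fit operates
  at its statistical information limit: the joint Cramér–Rao bound for
  (contact, modulus, offset) allows about 4.6% median relative error even
  for a full-curve fit, and the 150–500 nm windowed fit achieves about 6%.
  Recovery below ~1 kPa should therefore be interpreted with that floor in
  mind; from 1 kPa upward the median error is under 2%.
* Problem sizes used throughout the tests (150 genes, ~600 introns, ~1500
  peaks, 200 miRs, 500 curves per modulus in recovery checks) were chosen
  as the smallest sizes at which the planted effects are comfortably
  detectable by the tests' own statistics.

## Reproducibility

Every generator consumes a single integer seed through `sim_config()`, and
`run_pipeline()` writes a summary JSON that is byte-identical across reruns
with the same configuration. The pipeline orchestrates: simulate → intron
set → splicing efficiency and cluster grouping → peak annotation and
metaprofiles → miR categories, DE and target filters → interactome overlap
→ AFM maps, colony centers and group tests.

```{r example, eval = FALSE}
summary <- run_pipeline(sim_config(seed = 7), outdir = "run7")
str(summary$splicing$bin_medians)
```
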