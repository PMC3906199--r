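---
title: "Methods: co-expression modules and network plasticity under abiotic stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules and network plasticity under abiotic stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressnet)
```

stressnet analyses time-course stress transcriptomes measured on expression
arrays: which genes respond to each stress, how responders organise into
co-expression modules, which regulator--target relationships *rewire*
between stresses, and which promoter sequences and gene classes associate
with the modules. This vignette records the statistical procedures, the
tunable parameters with their defaults, and the design decisions taken where
a choice was genuinely open. Nothing here states an empirical result that
the package's tests and acceptance script do not themselves compute.

## Study design assumed by the package

The expected input is an RMA-normalised (log2-scale) genes x arrays matrix
over four stresses (cold, heat, salt, drought) sampled at 1, 2, 5, 10 and
24 hours in biological triplicate, with matched triplicate control arrays at
every timepoint. Missing arrays are permitted (the emulated design drops the
heat 5 h replicate C array, as in the source data, PLEXDB accession BD2).
The control-array layout is not fully determined by the published design;
the package assumes matched triplicate controls at every timepoint, which is
the layout under which stress and control arrays can be "compared in a
pairwise fashion" per timepoint.

## Differential expression (SAM-style permutation test)

For each stress and timepoint, stress arrays are compared with the matched
control arrays using a two-class unpaired permutation test in the style of
Significance Analysis of Microarrays. For gene $i$,

$$d_i = \frac{\bar x_{B,i} - \bar x_{A,i}}{s_i + s_0},$$

where $s_i$ is the pooled-SD standard error of the difference and $s_0$ a
fudge factor chosen among the percentiles $\{0, 5, \dots, 95\}$ of the
$s_i$ distribution to minimise the coefficient of variation of the median
absolute deviation of $d$ across $s$-quintiles. Group labels are permuted
(100 permutations by default); for small balanced designs such as 3 vs 3,
all $\binom{6}{3} = 20$ distinct assignments are enumerated and resampled
with replacement to the requested count, so the full exchangeable space is
always covered. The sorted observed statistics $d_{(i)}$ are compared with
their expected order statistics $\bar d_{(i)}$ (means over permutations);
calls are **directional**: up where $d_{(i)} - \bar d_{(i)} \ge \delta$ in
the upper tail, down where it is $\le -\delta$ in the lower tail, with the
observed-$d$ cutoffs then closing the call sets monotonically. The median
FDR at $\delta$ is the median over permutations of the number of permuted
$d$ beyond those cutoffs, divided by the observed call count. $\delta$ is
the smallest value on a 0.01-step grid whose median FDR is at or below the
1% target; the grid step is finer than any reporting precision. No
fold-change filter is applied and no $\pi_0$ correction is used (the
procedure reports the plain median FDR).

Per-stress up and down gene sets are the unions over timepoints; a gene up
at one time and down at another appears in both sets and is flagged. The
published per-stress totals behave the same way, which is why up- and
down-counts can sum to more than the DE-gene universe. Four-way set overlap
is reported as all 15 regions of the Venn partition.

Power is bounded by the replication: with triplicates, a 3-SD mean shift
separates from the null by only about 3.7 null-SDs of the $d$ statistic, so
near-complete recovery at a 1% median FDR is mathematically out of reach at
n = 3 per group; the test suite therefore exercises the high-power property
at 8 arrays per group, where it is attainable, and verifies FDR control at
the triplicate scale.

## Co-expression network and modules

Differentially expressed genes (union over all stresses) enter an unsigned
weighted network over **all** arrays, stress and control:
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^{B}$ with soft power $B = 23$. The
topological overlap of a gene pair is

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \ne i} a_{iu},$$

and $1 - \mathrm{TOM}$ is the clustering dissimilarity. Modules come from an
average-linkage dendrogram cut **statically** at height 0.91 (the classic
`cutree`-by-height behaviour; dynamic tree cutting is deliberately not
used), with branches below 25 genes left unassigned (label 0). Exact
dissimilarity ties can leave hclust merge heights non-monotone at machine
precision; heights are clamped to their running maximum before cutting,
which only resolves floating-point noise. Tie-breaking within the linkage
itself is left to `hclust`, which is deterministic for a given input.

Each module is summarised by its eigengene: the first principal component of
the standardised member expression, sign-oriented to correlate positively
with the module mean profile (principal components are sign-ambiguous; the
orientation rule makes outputs deterministic) and scaled to unit norm.
Modules whose eigengene dissimilarity $1 - r$ falls below 0.1 are merged
iteratively, closest pair first, until no pair qualifies. Plain (signed)
correlation is used, so anticorrelated modules never merge; this matches the
default behaviour of the field's reference implementation, and merging is
idempotent.

Module stress-response profiles are the mean over member genes of the
per-gene delta (stress mean minus control mean per timepoint) with standard
errors over genes; a module is called responsive to a stress when the
maximum absolute mean delta over timepoints reaches **1 RMA unit**. Edge
lists are exported at adjacency $\ge 0.35$ with a display flag at
$\ge 0.45$, mirroring the two-stage export/display filtering used for graph
rendering.

## Network plasticity (differential correlation)

For a condition pair, every gene differentially expressed in **both**
conditions is assigned to the transcription-factor (TF) group or the target
(TG) group by the supplied TF list. All TF x TG Pearson correlations are
computed separately over each condition's stress arrays; the observed
statistic for a pair is $|\Delta r| = |r_A - r_B|$. The absolute difference
is used in both observed and null tallies because the decision thresholds
are symmetric about zero; the procedure never signs the cutoff.

The null distribution permutes each gene's profile independently
(Fisher-Yates) across **all stress arrays** (controls excluded), then draws
two **disjoint** column subsets of size N = 15 and recomputes all pairwise
correlations. Disjoint subsets mimic the comparison of two non-overlapping
condition panels. Exceedance counts are accumulated on a 0.01-step cutoff
grid over [0, 2]. The full-scale procedure uses 7,200 permutations; the
count is configurable downward (tests and the acceptance script use
200-250), which changes Monte-Carlo error but not the semantics. The heat
panel has only 14 arrays after the quality-control dropout; observed heat
correlations use those 14 arrays while the null keeps N = 15, a deliberate
fidelity-over-consistency choice that is logged as a caveat.

The $\Delta r$ cutoff is the smallest grid value $c$ at which
$$\mathrm{FDR}(c) = \frac{\text{mean null exceedances at } c}
{\text{observed exceedances at } c} \le 0.05,$$
exactly the SAM-style calibration. If no cutoff qualifies the comparison is
reported as having no signal. Genes eligible in at least one comparison
whose every TF pairing stays below the cutoff in every comparison form the
"non-plastic" set.

## Promoter element analysis

Promoters are the 500 nt immediately upstream of each gene (excluding the
first gene base), taken strand-aware from the genome and gene models; GFF3
coordinates are treated as 1-based inclusive and promoters truncated at
contig edges are flagged. All 5-8 nt words are counted on the given strand
only, overlapping occurrences included, and words spanning an N are never
counted.

Enrichment of a module's promoters against the genome-wide promoter
background uses a one-sided hypergeometric test on **promoter presence**
(the number of promoters containing the motif), not raw hit counts: the
original element-scanning software does not document its exact statistic,
and presence-based testing is robust to repeat-rich promoters; both counts
are reported so either statistic can be recomputed. P-values are
Benjamini-Hochberg corrected across the full family of all $4^k$ words for
every k in 5-8 (m = 87,040); words absent from a set carry p = 1 and cannot
displace the adjusted values of observed words. Significance is corrected
p < 0.01. Reverse complements are *not* collapsed (the published tables
list a motif and its reverse complement as separate elements), and nested
motifs (a 5-mer inside a significant 8-mer) are reported, not collapsed.
Per-module summaries count total significant elements and those unique to
the module.

## Gene-set overlap and term enrichment

Whether a gene class (e.g. calcium-binding loci, or TF loci) is over- or
under-represented among module members is tested by permutation: class-sized
subsets of the universe are drawn uniformly (10,000 draws by default; the
published analysis does not state its count, and 10,000 stabilises the SD
estimate to about 1%), the overlap with the member set recorded, and
$Z = (\mathrm{obs} - \mathrm{mean})/\mathrm{SD}$ reported with a two-tailed
normal p-value — the convention under which the published Z of -3.195 maps
to p = 0.0014. The closed-form hypergeometric mean $nK/N$ and SD are
available as a cross-check and as the exact limit of the permutation null.
The universe for these tests is the DE-gene universe; with the published
sizes (9,496 genes, 6,399 members) this reproduces the printed expected
overlaps (404.5 for the 600 TFs, 242 for the 359 calcium-binding loci).

Term enrichment is a hypergeometric tail per term with BH correction;
a term is significant only when corrected p < 0.05 **and** it maps more
than 5 genes of the set. Terms are used as flat sets exactly as supplied
(no ontology-graph propagation). Genes are classified "undefined" unless
they have an alignment at >= 70% identity over >= 70% of their length to an
informatively annotated target, or an informative domain-scan flag;
inclusive boundaries, with annotations such as "expressed protein" counted
as uninformative.

## The synthetic-data generator

`synth_dataset()` emulates the study conditions so every stage is testable
with known ground truth. The expression model is

$$x_{g,\text{array}} = \text{baseline}_g + \text{profile}(m_g, s, t) +
\varepsilon, \qquad \varepsilon \sim N(0, \sigma),\ \text{baseline}_g \sim
N(8, 2),$$

on the full 4-stress x 5-timepoint x 3-replicate design with matched
controls and the heat 5 h replicate-C dropout. Defaults are chosen once, as
the conditions the analysis assumes, and are not tuned per test:

* **22 modules** of geometrically decaying size (minimum 25) covering about
  two thirds of the universe, mirroring the published module-size spectrum.
* **Peak effect 4 RMA** (`de_effect_rma`): severe stress responses saturate
  log2 expression displays at +/-4; this amplitude is also what makes the
  published network parameters (B = 23, cut height 0.91) able to resolve
  modules at all — at peak effects near 1-2 RMA the within-module
  correlations (~0.89) collapse to adjacencies of order $10^{-1.1}$ under
  the 23rd power and every gene is left unassigned.
* **Residual SD 0.25 RMA** (`noise_sd_rma`): typical replicate-level
  variation for RMA summaries.
* Each module (and each idiosyncratically responding non-module gene)
  carries **one random temporal shape shared across its responsive
  stresses**, scaled by per-stress positive amplitudes in 0.7-1 times the
  peak effect. Sharing the shape across stresses keeps any gene pair's
  correlation consistent between conditions — so planted plastic pairs are
  the *only* systematically rewiring relationships — while distinct shapes
  keep different modules separable. The cost is a simplification: the
  generator produces no module that is up-regulated under one stress and
  down-regulated under another.
* **Plastic pairs** share a per-array latent driver whose coupling to the
  target flips sign between the two plastic conditions (drought and salt by
  default); with amplitude 1 and the default noise this gives per-condition
  correlations of about +/-0.94, a true $|\Delta r|$ of about 1.88, and the
  pairs are made differentially expressed in both conditions by a constant
  offset, which leaves their correlations untouched.
* **Promoters** are i.i.d. uniform ACGT, 500 nt, with configured motifs
  planted at recorded offsets in a configured fraction of a target module's
  promoters. Planting a motif also elevates the junction words formed where
  the insert meets its random flanks; tests treat any word sharing a core of
  five or more consecutive bases with the planted element as attributable
  to it.

What the generator does **not** emulate: probe-level effects, non-uniform
promoter composition (GC content, repeats), ontology-graph structure,
signed (up in one stress, down in another) module responses, and
inter-module correlation structure beyond chance. Passing tests therefore
demonstrate correctness of the statistical machinery under the assumed
model, not robustness to every property of real array data.

## Problem sizes and numerical choices

The test suite runs the full pipeline at a few hundred genes, 200-250 for
end-to-end determinism checks and 400 for recovery checks, with 40-200
permutations per permutation test and word sizes restricted where the check
does not need the full 5-8 range; the acceptance script uses 20,000
permutations for overlap nulls and 250 for the correlation null. These
sizes were chosen so every documented property is measurable with
comfortable Monte-Carlo margins. Degenerate inputs are defined behaviour:
empty matrices yield empty call sets, zero-variance genes are stabilised by
$s_0$ in the DE test, dropped with a warning in correlation analyses, and
rejected with a named error in network construction (where they would
poison the whole TOM row); an observed exceedance count of zero yields a
"no signal" comparison rather than a division by zero.

## Known limitations

* The plasticity null treats arrays as exchangeable per gene; real
  time-course data are autocorrelated, so the synthetic null is a
  calibration of the procedure, not of real-data false-positive rates. The
  published mean false-positive count for the drought-salt comparison
  (1368.1 at cutoff 0.97) is tied to the empirical value distributions of
  the original arrays: under an i.i.d. standard-normal null with disjoint
  15-array subsets the same statistic concentrates near 2,190 (about 0.78%
  of pairings versus the published 0.49%), and sensitivity probes with
  heavier- and lighter-tailed i.i.d. marginals, or with overlapping rather
  than disjoint subsets, bracket rather than hit the published value. The
  package reports what its stated null computes.
* Published pairing totals (e.g. 276,950 for drought-salt) are slightly
  below the TF x TG product (146 x 1,910 = 278,860); the discrepancy is
  consistent with zero-variance pair removal, so the package reports both
  raw and filtered counts.
* The element-analysis statistic is presence-based by design decision;
  published per-motif FDR values from the real data are not exact
  reproduction targets.
* With triplicate groups the DE test's power at moderate effects is
  intrinsically limited (see above); module-level calls partially
  compensate by averaging over members.
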