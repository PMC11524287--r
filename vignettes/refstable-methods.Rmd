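---
title: "Methods: reference-gene discovery, stability statistics and primer design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-gene discovery, stability statistics and primer design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstable)
```

`refstable` implements a complete protocol for mining reference genes (RGs)
from RNA-Seq count compendia and validating them by RT-qPCR. This vignette
is the package's account of the underlying models, the numerical choices
made where the design was open, and what the synthetic benchmarks do and do
not demonstrate.

## Sample quality control

Samples pass three filters, applied in a fixed order: alignment rate
strictly above 70% (a mapping-quality proxy; strict inequality by design),
total reads at or above a configurable floor (default 1,000,000 — compendia
occasionally contain well-mapped but shallow libraries, and no universal
cutoff exists, so the default is conservative and overridable), and at
least two biological replicates per group *after* the first two filters
(a lone survivor of a replicate group is uninformative about biological
variance). Filtering is idempotent and each exclusion carries a
machine-readable reason.

## Normalization methods

Four between- or within-sample scalings are implemented from their defining
formulas rather than wrapped from other packages, so the protocol is
self-contained and auditable:

* **FPKM**: `count * 1e9 / (library_size * length)`, using gene-level
  effective lengths supplied with the counts. No isoform-level
  expectation-maximization is attempted.
* **TPM**: length-normalized rates rescaled so every sample column sums to
  one million. The column-sum identity is enforced by construction and
  regression-tested; FPKM deliberately has no such constraint.
* **Median of ratios (MOR)**: the pseudo-reference of a gene is the
  geometric mean of its counts across samples, computed only over genes
  with no zero anywhere (the canonical variant; shrunken alternatives are
  not implemented); a sample's factor is the *plain* median of its
  count/reference ratios. For an even number of contributing genes this
  differs from the log-scale interpolated median used by some
  implementations by a vanishing amount; the plain median is kept because
  it matches the definition directly.
* **TMM**: reference sample = the one whose upper-quartile count fraction
  is closest to the mean of those fractions; per sample, over genes
  expressed in both sample and reference, M and A log-ratios are doubly
  rank-trimmed (30% of M ranks and 5% of A ranks from *each* tail — the
  method's canonical trim, verified to zero difference against the original
  implementation in an optional cross-check test) and the surviving M
  values are combined with inverse delta-method variance weights. Factors
  are rescaled to geometric mean 1, and TMM-normalized values are
  counts-per-million on effective library sizes. MOR factors are left
  unscaled because the pseudo-reference already anchors them.

A useful set of invariances follows and is property-tested: both factor
sets ignore gene/sample order; a global rescaling of all counts cancels in
both (the MOR pseudo-reference absorbs it); rescaling a single sample by k
multiplies its MOR factor ratio by exactly k; TMM is unchanged by pure
depth differences.

## The CV stability screen

All stability screening happens on `log2(value + 1)`: the offset keeps
zeros finite and the log compresses the dynamic range so the coefficient of
variation `cv = sd/mean` is comparable across expression levels. The
package *refuses* to compute CV on the linear scale — `gene_cv_stats()`
requires the transformed-matrix flag — because a linear-scale CV silently
changes the meaning of every downstream threshold. SD uses the n−1 sample
denominator. Genes whose transformed mean is zero get an undefined CV and
can never pass the screen (reporting 0 or ∞ would either promote silent
genes or poison summaries).

A gene is called stably expressed when its CV is at most the cutoff
(inclusive; default 0.3, stated as a fraction everywhere — percentages are
never mixed in). Candidate selection takes the k smallest CVs with
deterministic tie-breaking (smaller SD, then gene id). Method comparison
(`compare_normalizations()`) summarizes per-sample quartiles of the
transformed values and CV distributions over all genes and over a
designated set such as previously reported RGs, which is how a
normalization method is chosen for a given compendium.

## RT-qPCR stability statistics

Ct tables are assumed pre-averaged over technical replicates
(`collapse_replicates()` helps when they are not). Relative quantities use
the geNorm convention `q = E^(minCt − Ct)` with per-gene amplification
factor E (default 2.0, configurable per gene); the transform convention is
a documented choice, since only the algorithms themselves are standard.

* **ΔCt method**: a gene's score is the mean over partners of the SD (n−1)
  of the per-sample Ct difference. Pairs sharing fewer than two samples are
  skipped with a warning.
* **geNorm**: M = mean pairwise SD of `log2(q_j/q_k)`; the gene with the
  largest M is removed and M recomputed until two remain. With E = 2 the
  full-set M equals the ΔCt score — the two algorithms agree by
  construction on the first pass and differ through the iteration. The
  stepwise procedure cannot split the final pair, so the package orders
  those two by their full-set M values (then id): a deterministic
  convention that keeps the rank vector fully informative instead of
  reporting an arbitrary tie. Pairwise variation `V_{n/n+1}` (SD of
  `log2(NF_n/NF_{n+1})`, NF = geometric-mean normalization factor) is
  reported for choosing how many RGs to combine.
* **NormFinder**: the variance-decomposition form — double-center the log
  quantities (sample effect, then gene effect), take the residual variance
  per gene, subtract the mean residual variance of the other genes divided
  by G−1 (bias adjustment), floor at zero and report the square root. With
  group labels, the intra-group analysis is combined with the absolute
  inter-group deviation per gene. The exact variant used by aggregator web
  tools is unpublished; this package fixes the form above and defines
  correctness by an independent brute-force oracle in the test suite.
* **BestKeeper**: descriptive statistics on raw Ct — SD, percent CV, and
  Pearson correlation with the per-sample geometric-mean index over
  complete genes. Ranking uses SD (BestKeeper's stated stability
  yardstick); r is reported alongside. Note the deliberate asymmetry:
  adding a constant to one gene's Ct leaves ΔCt/geNorm/NormFinder scores
  and the BestKeeper SD unchanged but shifts its %CV, which is
  regression-tested.

The comprehensive rank is the geometric mean of the four rank vectors,
ties broken by the ΔCt rank then gene id. Missing Ct cells are handled
pairwise-complete for ΔCt/geNorm; genes with any missing cell are dropped
(with a warning) from the BestKeeper index and NormFinder, keeping each
estimator well-defined.

Standard curves fit `Ct = slope·log10(dilution) + intercept` by ordinary
least squares; `E = 10^(−1/slope)`, percent efficiency `(E−1)·100`,
reliable in the closed band [90, 115] (comparisons carry a 1e-9 tolerance
so exact band-edge curves survive floating point). Non-negative slopes are
flagged invalid and report no efficiency.

## Universal primer design

Ortholog selection replaces tree building with a deterministic criterion:
shared 11-mer seeding prunes unrelated sequences, a local alignment
(match 2, mismatch −3, gap open 5, extend 2) scores the rest, and the
single best hit per species passing 70% identity and 50% query coverage is
kept. Identity/coverage thresholds replace E-values deliberately: against
small in-memory databases E-values carry no extra information.

The consensus comes from a center-star multiple alignment (center = member
with the highest mean pairwise identity; pairwise global alignments merged
by gap propagation), adequate for congeneric transcripts whose pairwise
identity must exceed 60% anyway (lower identity aborts with advice to
review the ortholog set). Unanimous columns emit the base; any
disagreement emits the IUPAC code of the observed bases; per-column
conservation is the frequency of the commonest non-gap base among non-gap
members.

Primer enumeration slides every 18–27 nt window whose columns are fully
conserved, gap-free and unambiguous (degenerate windows with IUPAC
expansion ≤ 8 are an opt-in mode in which every expansion must satisfy the
Tm constraint). Melting temperatures use nearest-neighbor thermodynamics
with the unified DNA parameter table, duplex-initiation terms, an entropic
salt correction at 50 mM monovalent cation and 250 nM oligo — fixed
constants shipped in the source so Tm values are bit-reproducible. Windows
must satisfy Tm 59–63 °C and GC 0.40–0.60 (the GC band is a common design
default, configurable); pairs must produce 100–300 bp. Because several
pairs typically survive, ranking is by Tm difference, then product size
closest to 150 bp, then position — a deterministic, documented convention.
All coordinates are 0-based half-open and the reverse primer is reported
5'→3' on the minus strand, so `product_size = reverse_end − forward_start`.

In-silico PCR scans both strands of each genome for binding sites with at
most 2 IUPAC-compatible mismatches and none in the 3'-terminal 5 bases,
pairs facing sites within 5 kb, and calls a pair specific in a genome only
when exactly one amplicon is predicted; `design_universal_primers()` emits
only pairs specific in every genome. Hairpin and primer-dimer
thermodynamics are out of scope.

## Synthetic data: what it emulates, and what it does not

The simulators provide planted ground truth at the three entry points of
the pipeline.

* **Counts**: gene base means are log-normal (defaults: natural-log mean 5,
  SD 1.5 — a realistic spread from silent to highly expressed); stable
  genes keep one mean across conditions at negative-binomial dispersion
  0.01 (variance = μ + φμ²), unstable genes draw an independent log2 fold
  change per condition from Normal(0, 1) and use dispersion 0.3; per-sample
  depths are log-normal (SD 0.3) and are the true size factors. Defaults:
  5,000 genes, 60 samples in 10 condition groups, 5% stable — a desk-scale
  emulation of a multi-experiment training compendium.
* **Ct tables**: `Ct = base + group effect + Normal(0, sd_g)` with per-gene
  baselines uniform in [18, 28] (mid-range quantification cycles) and
  planted noise SDs spanning 0.05–1.5 cycles; Gaussian Ct noise is the
  standard qPCR error model, and no efficiency noise is simulated by
  default.
* **Ortholog sets**: a random root with per-species substitutions outside
  conserved windows and none inside; substitution-only evolution means the
  true alignment and consensus are known exactly.

One global seed fans out to fixed per-component child seeds, so changing
the number of genes never perturbs the sample depths, and every simulator
is a pure function of its parameters. Benchmarks on these data (performed
by the test suite and the acceptance script at sizes of a few hundred to a
few thousand genes and 24–60 samples, with the full 5,000×60 default run
once) show that MOR recovers planted depths within a few percent, the CV
screen recovers ≥ 90% of planted stable genes, and each stability
algorithm recovers a planted noise ordering at Spearman ≥ 0.9.

What passing these benchmarks does *not* show: real compendia have
correlated batch structure, GC and length biases, isoform switching and
heavy-tailed outliers that the generator deliberately omits; Ct error can
be non-Gaussian and efficiency-dependent; real orthologs diverge by indels
and rearrangements, not substitutions alone. The benchmarks validate the
statistics and their implementations, not the biology of any particular
dataset.

A practical note on resolution: the comprehensive rank separates genes
whose planted noise SDs differ by a factor of ~2 essentially always, but
distinguishing the two most stable genes of a 12-gene panel (SD 0.05 vs
0.18 at 24 samples) fails in a few percent of replicates, because the ΔCt,
geNorm and NormFinder scores are all built from pairwise differences and
err together; BestKeeper, which sees per-gene SD directly, is then the
dissenting vote. With real candidate panels the practical remedy is more
samples, or reporting the top pair rather than a single winner.

## Known limitations

Gene lengths are taken as given (no effective-length modeling); TMM/MOR
comparisons assume most genes are not differentially expressed; NormFinder
grouped mode requires ≥ 2 samples per group and complete Ct rows; the
center-star consensus is not a full progressive aligner and will be
suboptimal for indel-rich groups; the in-silico PCR scan is exact and
O(genome × primer length), intended for transcript sets and small genome
fixtures rather than gigabase genomes.
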