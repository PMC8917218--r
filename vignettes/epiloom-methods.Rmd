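---
title: "epiloom: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epiloom: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

epiloom implements an integrative 3D-epigenome analysis pipeline at desk
scale: from a binned Hi-C contact matrix and epigenomic peak/expression
tracks it derives A/B compartments, topologically associating domains
(TADs), significant chromatin loops, super-enhancers and super-silencers,
annotated loop classes, insulated-neighborhood containment statistics and
super-enhancer interaction hubs. This vignette describes each model, its
assumptions, the tunable parameters, and the design choices made where the
methods literature leaves the details open. Every empirical claim below is
recomputed by the test suite or by `scripts/acceptance.R`; none is imported
from elsewhere.

## Coordinate and container conventions

All genomic coordinates are 0-based half-open (the BED convention), for
peaks, bins, domains and anchors alike; conversion happens only at I/O
edges, and no 1-based format is in scope. Chromosome names are compared by
exact string match. The central container is the `contact_matrix`: a bin
table (uniform width per chromosome, global strictly increasing index) plus
a sparse upper-triangular count store. Symmetric and duplicate triplet
entries are folded by summation on construction, so unsorted dumps are
tolerated. A per-bin mask marks excluded bins; masked bins carry no stored
contacts.

## Matrix balancing (ICE)

Iterative correction removes multiplicative per-bin biases $b_i$ so that
$W_{ij} = T_{ij}/(b_i b_j)$ has equal row sums. Each iteration divides the
bias vector by its unit-mean-normalized marginals; convergence is declared
when the relative spread $(\max - \min)/\mathrm{mean}$ of unmasked
marginals falls below `tol` ($10^{-5}$ by default, 200 iterations
maximum). The diagonal is excluded from the marginals, standard ICE
practice. After convergence the bias vector is renormalized to geometric
mean 1, so total mass is preserved up to a single global scale factor
(reported). Bins with zero or very low coverage (marginal below 2% of the
mean, `mask_low_coverage()`) are masked first. Balancing is genome-wide
(cis and trans together), since one normalized map serves both cis and
trans loop calling downstream. Forward-constructed matrices with known
biases are recovered to a relative error below $10^{-4}$, the package's
accuracy contract for this stage.

## A/B compartments

Compartments are called at 100-kb resolution per chromosome, using the
correlation-matrix variant of compartment PCA: the balanced cis map is
normalized to observed/expected (expected = mean balanced value at each
separation, so every separation stratum of O/E has mean exactly 1), the
Pearson correlation matrix of bin profiles is formed, and its leading
eigenvector is the PC1 track. Per-chromosome computation was chosen over a
genome-wide eigenvector because compartment tracks are conventionally
displayed and interpreted per chromosome. The eigenvector sign is
arbitrary, so it is oriented per chromosome against a covariate that marks
active chromatin — GC content by default (compartment A is GC-rich); gene
density can be supplied instead. If the leading eigenvector is the trivial
all-one-sign vector (degenerate input) the next one is used, with a
message. Bins with positive oriented PC1 are labeled A, negative B; masked
bins are NA and are reported as an explicit NA fraction rather than folded
into A or B.

## TADs by insulation score

The insulation score of bin $i$ is the mean balanced contact over the
square $(i-w, i] \times (i, i+w]$, log2-normalized to its chromosome mean,
so a uniform matrix scores 0 everywhere and a global scale factor cancels.
The score is NA where the window does not fit or more than half the square
is masked. Boundaries sit at minus-to-plus zero crossings of the delta
vector (mean score just downstream minus just upstream); of the two bins
flanking a crossing, the one with the lower score is taken. Boundary
strength is the range of the delta vector around the boundary, and the
same strength functional is exposed at arbitrary positions
(`insulation_at()`) so anchors and boundaries can be compared on one
scale. Domains tile each chromosome between boundaries, a boundary bin
belonging to its downstream domain; boundaries closer than 3 bins are
pruned weakest-first so every domain spans at least 3 bins.

Defaults: 40-kb bins, 480-kb window, 120-kb delta, minimum strength 0.1.
The cited insulation-score methodology uses a 500-kb window and 100-kb
delta; those are not integer multiples of a 40-kb bin, so the package
rounds both to the nearest multiple and exposes them as config keys. A
domain is flagged repressive (H3K27me3-TAD) or heterochromatic
(H3K9me2-TAD) when merged peaks of the mark cover strictly more than half
of it — the threshold is exclusive, so exactly 50% coverage does not flag.

## Significant loops

Loops are called at 10-kb resolution with a distance-stratified binomial
model in the Fit-Hi-C tradition. The background contact probability is
estimated from the data: distances are pooled into up to 100
equal-occupancy strata (equal total contact counts per stratum, so the
count-dense short range keeps fine resolution), stratum means are made
non-increasing by weighted pool-adjacent-violators, and the fit is
interpolated log-linearly back onto integer distances. This monotone
PAVA fit deliberately replaces the original spline: same contract (a
smooth non-increasing distance prior), no extra dependency, and an exact
postcondition (monotonicity) that the tests can assert. One fitting pass
is performed; the optional refinement pass of the original method is
omitted.

Each tested cis pair (count ≥ 1, separation ≥ 2 bins — adjacent bins are
dominated by self-ligation artifacts) receives success probability
$p(d)\,b_i b_j$ renormalized to sum to 1 over all possible tested pairs,
and an upper-tail binomial p-value with $n$ equal to the total tested cis
count. Benjamini–Hochberg q-values are computed over all tested pairs,
cis and trans separately. The significance filters are exact: p-value
< 0.01, q-value < 0.01, and contact count strictly greater than 2 — a
pair with count 2 is never significant regardless of its p-value. Trans
loops use the same machinery with a uniform bias-scaled background and
$n$ = total trans count.

Bias scaling is implemented and oracle-tested, but the pipeline default is
`loop_use_bias = FALSE`: on a toy genome the ICE bias vector mainly
encodes chromosome-end coverage deficits, which are a distance effect
rather than a per-bin bias, and feeding it into the binomial probability
double-discounts end bins and produces false positives there. On the
standard synthetic conditions this choice raises mean precision from
~0.77 to ~0.82 at unchanged recall. Whether to call on raw or
bias-corrected counts is a configuration key, as is the tested distance
range. The residual false positives of the distance-only background are
TAD-corner pairs — at ~70 true loops per genome the caller runs at about
0.8 precision and ≥ 0.98 recall, and on null genomes (no focal
enrichment) the fraction of tested pairs called stays far below 5%.

## Stitched elements (ROSE)

Peaks of one mark whose gaps are at most 12.5 kb are merged transitively
into stitched elements; aggregate signal is the sum of signal × width over
constituents (total-signal ranking, not maximum). Elements are sorted by
ascending signal, rank and signal are rescaled to the unit square, and the
cutoff is the signal at the point where the discrete slope first exceeds
1 — the geometric criterion behind the familiar hockey-stick plots.
Elements strictly above the cutoff are super. Applied to H3K27ac this
yields SE/TE; to H3K27me3, super/typical repressed regions (SuReR/TyReR);
to H3K9me2, super/typical heterochromatin regions (SuHeR/TyHeR). SuReR and
SuHeR together are the super-silencers. With fewer than 3 elements or
all-equal signals nothing is super (degenerate, documented). TSS exclusion
and input subtraction, optional in the original ROSE, are off: repressive
marks have no such convention and the synthetic tracks carry no input.

Promoters are TSS ± 2 kb (TSS = `start` on the plus strand, `end − 1` on
the minus strand; the flank is a config key, 2 kb being the common
convention). Enhancers are the stitched H3K27ac elements with zero
promoter overlap — one bp of overlap excludes, and excluded elements
remain available as active-promoter evidence.

## Loop annotation

Anchors receive every label they overlap by at least one bp (the minimum
overlap is a config key). Loop classes resolve by a fixed precedence
ladder: P–P > E–P > E–E > SuReR–SuReR > SuReR–TyReR > SuHeR–SuHeR >
SuHeR–TyHeR > mixed silencer > CTCF–CTCF > other, with CTCF–CTCF assigned
only when neither anchor carries an enhancer or promoter label (insulator-
only loops). The ladder is a package decision; class reports in the
field's literature do not state how dual-label anchors resolve, and
promoter-first is the reading that keeps E–P counts conservative.
Expression tiers are TPM ≥ 10 (high), 0.1 ≤ TPM < 10 (low), TPM < 0.1
(none), boundaries belonging to the higher tier. Promoter-pair fold
changes use a 0.01 TPM pseudocount on both sides, since zero-TPM promoters
occur; promoter-to-gene assignment on shared anchors takes the nearest
TSS. Interaction density is the number of distinct loops touching a
region per 100 kb of region length — one reading of a statistic whose
normalization is rarely stated; both the unit length and the definition
live behind one function. Each cis CTCF–CTCF loop spans a candidate
insulated neighborhood from the start of its first anchor to the end of
its second; an E–P loop is contained when both anchors lie inside a single
such domain, anchors inclusive.

## Interaction networks and SE hubs

Loops of class E–P/E–E/P–P build an undirected graph with one node per
distinct element or promoter (anchor-to-node mapping: promoter gene by
nearest TSS when the anchor has a promoter label, otherwise the enhancer
with the largest overlap); duplicate loops collapse into one edge with a
multiplicity. On the subgraph restricted to SE and promoter nodes and
SE–SE/SE–P edges, a connected component is an SE interaction hub when it
has ≥ 2 SEs, ≥ 1 promoter, ≥ 1 SE–SE edge and ≥ 1 SE–P edge — the weakest
reading of "multiple SE–SE and SE–P loops" consistent with the worked
examples; stricter thresholds are config keys. Restricting components to
the SE/promoter subgraph means typical enhancers cannot bridge two hubs.
SEs with no direct promoter edge but a path through intermediate SEs are
indirect regulators, reported with their path length. Hubs are not
filtered by TAD membership.

## The synthetic genome

The generator plants every structure the pipeline is supposed to find, so
each stage can be scored against ground truth. Study conditions (the
defaults): two 20-Mb chromosomes at 10-kb bins; expected cis count
$\lambda d^{-\alpha}$ with $\lambda = 50$, $\alpha = 1$; alternating 1-Mb
A/B blocks with same-compartment multiplier $c = 1.6$; planted TADs with
within-TAD multiplier $t = 2.0$; ~60 planted loops with focal multiplier
$f = 6.0$ on a 1-bin footprint; trans mean 0.02; independent Poisson
draws (a Gamma-Poisson overdispersion flag exists, off by default so the
binomial caller's FDR behavior is exercised cleanly). One RNG stream per
artifact (structure, matrix, peaks, expression) is derived from the master
seed by fixed offsets, so regenerating one artifact does not shift the
others.

Layout choices worth knowing:

* Compartment blocks are exact 1-Mb A/B alternations aligned to bins, and
  planted TAD boundaries nest inside blocks so that every compartment edge
  is also a TAD boundary — as in real genomes, where compartment switches
  respect domain boundaries. Without this nesting, compartment edges would
  produce insulation dips scored as spurious TAD boundaries.
* TAD lengths are drawn on a 40-kb grid between 0.3 and 1.2 Mb (the grid
  matches the resolution hierarchy at which domains are called).
* Planted E/P loops span 50–150 kb and structural CTCF–CTCF loops
  200–400 kb, inside TADs, so that at $\lambda = 50$ every planted loop
  has detection power and structural loops are the longest class. Each
  active TAD's CTCF pair flanks its element cluster, so planted E–P loops
  are contained in CTCF–CTCF domains by construction. Structural-loop
  anchors carry CTCF+SMC1 peaks and no elements, making the
  insulator-only loop class recoverable by definition.
* Super-enhancers are clusters of five high-signal H3K27ac peaks
  (stitchable span ~25 kb); two SE hubs per chromosome (three SEs, one
  promoter, a triangle of SE–SE loops and one SE–P loop) plus standalone
  SE–P pairs. Typical enhancers are isolated moderate peaks. One B block
  per chromosome hosts dense H3K27me3 domains (SuReR) covering > 50% of
  their TAD, another dense H3K9me2 domains (SuHeR); scattered small
  clusters form the typical silencer classes, and one dense H3K9me2
  cluster overlaps a SuReR on odd chromosomes so the silencer-overlap
  statistic is non-trivial.
* Gene expression tiers are drawn iid at 40/40/20% (high/low/none) for
  background genes; planted genes take the tier their role implies (SE and
  E–P targets high, silencer-looped genes silent, P–P pairs one high and
  one low with one pair per chromosome below the 10-fold change). TPMs are
  drawn log-uniform within tiers.

What the generator does **not** emulate: read-level noise and mappability,
bin-level biases (GC, fragment density — hence the loop caller's default
of not bias-scaling on synthetic data), replicate structure, nested or
hierarchical TADs, compartment strength gradients, and realistic human
coordinates. Passing the planted-recovery tests therefore demonstrates
correctness of the algorithms under their stated models, not performance
on real sequencing data.

## Numerical choices and degenerate inputs

Tolerances: ICE spread $10^{-5}$ (config), eigen-decompositions via base
`eigen` on symmetric matrices, BH correction via `p.adjust`, binomial
tails via `pbinom` (oracle-checked against explicit tail sums to
$10^{-12}$). Ties: boundary crossings pick the lower-score bin; equal
aggregate signals rank by first occurrence; anchor-to-gene ties break by
nearest TSS; anchor-to-enhancer ties by largest overlap. Degenerate
cases: an all-masked matrix errors at masking; a chromosome with < 20
usable 100-kb bins yields an NA compartment track with a warning;
non-convergent ICE warns and returns the partial result with a flag;
< 3 stitched elements are all typical with a warning; empty loop sets
produce NA fractions, not errors.

## Problem sizes

The standard verification genome is 2 × 20 Mb at 10-kb bins (4,000 bins,
~0.8 M stored cis pairs), chosen so that a full simulate-and-analyze cycle
completes in well under a minute and the whole test suite, including five
planted and ten null genomes, in a few minutes. Recovery statistics quoted
above (compartment accuracy 100%, TAD boundary recall ~0.95 at zero
spurious calls, loop recall ≥ 0.98 at ~0.8 precision, SE/SuReR/SuHeR
Jaccard ~1.0, E–P containment 1.0) are what the acceptance script reports
on these conditions; they are properties of the planted-structure regime,
not claims about any real dataset.

## Known limitations

Single-resolution TAD calls (no nesting); no sub-compartments; the trans
loop model is uniform-background only; the expected model does not absorb
TAD-level enrichment, which bounds precision near 0.8 under the planted
conditions (see above); ROSE control-subtraction is reserved but
unimplemented; `.hic`/`.cool` binary interchange is out of scope.
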