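---
title: "Calling and characterizing underrepresented domains in polyploid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing underrepresented domains in polyploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urdomains)
```

## The problem

Endoreplicating cells — mouse trophoblast giant cells (TGCs) being the
canonical mammalian example — replicate their genome many times without
dividing, reaching 50–1,000 genome copies. Replication of specific large
chromosomal segments can stall or be skipped during these endocycles, so
those segments end up present in fewer copies than the rest of the genome.
In whole-genome sequencing of such a cell population against a matched
diploid control, these *underrepresented (UR) domains* appear as megabase-
scale depressions of the normalized log2 coverage ratio, typically 27–54%
depleted, hosted inside large, gene-poor, late-replicating heterochromatic
blocks. `urdomains` implements the complete read-depth analysis of this
phenomenon: track construction, domain calling, depletion quantification,
cross-sample comparison, feature enrichment, replication-timing
containment, and the paired-end test that distinguishes underreplication
from bona fide somatic deletion. A seeded generator produces synthetic data
with all of these properties plus ground truth, so every stage is testable
end to end.

## From counts to a representation track

Coverage is summarized per fixed-width bin (default **5 kb**; every domain
boundary in the published catalog is a multiple of 5 kb, which is why this
grid is the default). Each sequenced fragment is counted once, in the bin
containing its midpoint. For a test/control pair the per-bin statistic is

$$ r_i = \log_2\frac{(t_i + c_0)/T}{(c_i + c_0)/C} - m, $$

with $T$, $C$ the total unmasked counts (library-size scaling), $c_0$ a
pseudocount (default 1), and $m$ the genome-wide median of the scaled
ratios, so the neutral state is exactly 0. Median-centering was chosen over
mean-centering because the depleted fraction of the genome (~6% in the
motivating data) barely moves the median; the normalization is exactly
invariant to scaling all test counts by a constant. Bins whose control
count falls below `min_control` (default 10, about a fifth of the expected
count at 10x coverage on the 5 kb grid) are masked before any statistic is
computed — this suppresses ratio explosions in unmappable regions and is
the extension point for mappability or GC masks, which the package
deliberately does not compute itself.

## The caller

`call_ur_domains()` is the package's central fit and returns a classed
object with `print`, `summary` and `plot` methods. It implements a
neighboring-bin criterion: maximal runs of unmasked bins with
$r_i \le -0.3$ (a bin exactly at the threshold is included). A run may
bridge up to `merge_gap_bins` (default 2, i.e. 10 kb) consecutive interior
bins above threshold, provided the bridged run's mean stays at or below the
threshold; bridging is greedy, left to right, which makes the caller fully
deterministic. Runs shorter than `min_bins` (default 15 bins = 75 kb, the
smallest domain in the published catalog) are discarded.

Significance: the published analysis cites a CNV caller operating at
p = 0.01 without printing its statistical machinery, so this package
declares its own, deliberately simple, null model: bin values under no
depletion are centered at 0 with scale $\hat\sigma$ = 1.4826 x MAD of all
unmasked bins (robust to the depleted minority); a run of $n$ bins with
mean $\bar r$ gets the one-sided normal p-value
$\Phi(\bar r \sqrt{n} / \hat\sigma)$. Accepted runs (p <= 0.01) separated
by at most `merge_gap_bins` are merged and their summaries recomputed. The
z-test sits behind the `score_significance()` boundary and can be swapped
without touching the run logic. On noise-free constructed tracks the MAD
can collapse to zero; the classical SD is the declared fallback scale.

Percent depletion converts a log2 ratio $L$ to $100(1 - 2^L)$; reports
round to integer percent half-away-from-zero, which reproduces all 94
printed percent cells of the published catalog from their log2 values.
The "chromosomal median depletion" variant subtracts the chromosome-wide
median log2 from the domain median before converting — the catalog never
defines it explicitly, and this reading makes it a chromosome-normalized
version of the same statistic. Where per-sample tables are averaged (the
catalog's "Ave" columns), this package averages per-sample summaries rather
than pooling tracks; the choice is exposed, not hard-coded.

## Cross-sample structure

`consensus_domains()` groups calls from multiple samples into overlap
components (any-overlap by default; reciprocal-50 as an option — the
published analysis never states its sharing criterion, and any-overlap
reproduces its qualitative Venn logic). The consensus interval is the
intersection of the per-sample member spans: "common to all samples" is a
presence statement and the intersection is the defensible shared core; the
union is available behind a flag. `nestedness()` quantifies the observed
individual-to-individual structure (samples with fewer domains carry a
subset of the domains of samples with more). Distributional comparisons of
size and depletion between stages use the two-sided Wilcoxon rank-sum test
at alpha = 0.01 — the published box-plot comparisons state only "p < 0.01"
without naming a test, and the rank-sum test is the distribution-free
default for exactly this situation.

## Randomization enrichment

Feature sets (gene annotations, ChIP-seq peaks, gene deserts) are tested
for enrichment or depletion within UR domains against a stratified
randomization null: each feature keeps its chromosome, its length and its
TSS-distance class (boundaries 1 kb / 10 kb / 100 kb / 1 Mb), and its
midpoint is redrawn uniformly from that stratum's genomic territory. The
*features* are shuffled while the domains stay fixed — shuffling the
domains instead could not preserve the features' TSS classes, so this is
the only reading consistent with the stratification. Shuffled features may
overlap one another (the simplest null consistent with the design), and a
feature counts once if it overlaps any domain by >= 1 bp.

The p-value is a binomial test with success probability
`expected / n_features` (expected = mean over 1,000 shuffles by default),
one-sided in the observed direction and doubled. The *mid-p* tail (half
weight on the observed count) is used: with a discrete count statistic the
plain tail is conservative enough to visibly break null calibration, and
the mid-p variant restores uniform null p-values. Calibration holds exactly
when the binomial model is correct, i.e. when features share one
(chromosome, class) stratum; across heterogeneous strata the pooled
binomial is slightly conservative (the true null is Poisson-binomial with
smaller variance), which is the safe direction. The test suite verifies
uniformity on a homogeneous design and conservation invariants on a
stratified one. Printed enrichment ratios are observed/expected with
unrounded expectations — the published desert enrichments (4.96x, 3.16x)
do not equal the ratios of their rounded printed counts, so rounding
expectations is deliberately avoided.

Gene deserts are the complete 1 Mb tiles containing no annotation,
non-overlapping by default with a sliding variant behind `step`.

## Replication timing

Timing tracks use the early > 0 / late < 0 log-ratio convention of
BrdU-IP early/late designs. Segmentation is recursive binary splitting
minimizing within-segment squared error, a split being accepted when it
reduces the error by more than a BIC-like penalty (default
$2\hat\sigma^2\log n$, with $\hat\sigma$ estimated from first differences
via MAD/sqrt(2)); adjacent same-state segments are merged, so segments tile
each chromosome, alternate in state, and the procedure is idempotent on its
own reconstruction. This minimal two-state segmenter replaces the circular
binary segmentation package used in the published analysis; anything
honoring the tiling/merging contract can be swapped in.

Containment of a domain in a late segment allows a one-bin tolerance per
side (the published supplementary material itself notes one domain that
escapes strict containment by the segmenter's boundary while being entirely
late-replicating by eye); the strict count is also reported. Hosting late
segments are compared with non-hosting ones by rank-sum tests on size, gene
count and mean timing.

## Deletion versus underreplication

A somatic deletion carried by a fraction of the genome copies leaves a
paired-end signature: pairs whose unsequenced middle spans the deletion
junction map back to the reference with the deletion's length added to
their apparent span, flanking the region. Underreplicated copies produce no
such pairs — they simply contribute fewer fragments. The package counts
flanking pairs whose span exceeds `mean_insert + k * sd_insert` (defaults
500 + 4 x 50 = 700 bp for 101 bp reads) and compares the count with the
expectation under a true deletion,
$\frac{C}{2\ell}(\mu - 2\ell)f$ per junction (coverage $C$, read length
$\ell$, mean insert $\mu$, deleted fraction $f$): the verdict is "deletion"
when the observed count reaches max(2, 10% of expectation). Both the
k = 4 threshold and the verdict rule are declared package choices — the
published analysis delegated detection to an external SV caller and printed
only its conclusion. The per-sample probability of missing a true deletion
is the Poisson tail below the verdict threshold, and across $n$ independent
samples the joint non-detection probability is $(1 - p_\text{detect})^n$;
with a per-sample detection probability of 0.835 and six samples this
reproduces the published 2e-5 order of magnitude (the published text does
not show its derivation, so that value is treated as order-of-magnitude
context, not a calibration target).

## The synthetic generator

`simulate_reference()` builds the study conditions the analysis assumes:

* **Coverage**: Poisson bin counts at `lambda = 500` per 5 kb control bin —
  the count implied by 10x coverage of 101 bp reads. Poisson (no
  overdispersion) is the minimal model that makes the caller's z-test
  calibratable; the mask mechanism, not the generator, is where real-data
  messiness (mappability, GC) belongs.
* **Domains**: depletion d ~ U(0.27, 0.54) (the published mean-depletion
  span) and sizes log-normal(meanlog = log(1 Mb), sdlog = 0.9) truncated to
  75 kb – 9 Mb, resembling the published catalog's size spread. Size and
  depletion are independent in the generator so each downstream property
  can be tested in isolation; the real positive size-depletion correlation
  is exercised separately on the published catalog itself.
* **Layout**: one hosting late block per domain, 2–3x the domain's size
  (domains strictly inside, hence smaller than their blocks), plus smaller
  non-hosting late blocks; blocks are assigned to chromosomes greedily,
  largest first onto the least loaded chromosome, so heavy draws cannot
  overload one chromosome. Gene density is cut to 5% inside hosting blocks,
  and 1 Mb desert tiles concentrate there.
* **Stages**: e8.0 domains are the e9.5 domains shrunk to 0.6x their size
  around their centers with 0.8x their depletion — qualitative multipliers
  chosen to make the stage contrast detectable, not fitted to data.
* **Default scale**: 2 chromosomes x 60 Mb (24,000 bins) hosts Mb-scale
  domains and 1 Mb windows while keeping a full simulate-call-recover cycle
  in seconds. The stage-comparison preset `sim_config_stage_study()` uses
  12 chromosomes x 80 Mb with 150 domains of smaller median size: an
  unpaired rank-sum comparison of a 0.6x multiplicative size shift against
  a sdlog ~0.9 size distribution needs on the order of 150 calls per group
  to be reliably significant at p < 0.01, so the preset's size is a power
  calculation, not an arbitrary scale-up.

What the generator does **not** emulate: mappability structure, GC bias,
duplicate reads, overdispersed counts, maternal-cell contamination (a
mixing flag is deliberately out of scope), or read-level sequence. Tests
passing on synthetic data therefore demonstrate the correctness of the
algorithms under the declared statistical model, not robustness to every
artifact of real libraries.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; the published catalog's
  printed coordinates behave as half-open (stop − start equals the printed
  size in every row), and a reader flag converts 1-based inclusive input.
* Chromosome names `chr1`/`1` are normalized to the bound genome's
  convention at load.
* Only the chromosomes present in the bound genome are analyzed; building
  an autosome-only genome restricts every downstream stage.
* A bin exactly at the calling threshold is included (the criterion is
  `<=`); ties in rank-sum tests fall back to the normal approximation; a
  fully tied comparison reports p = 1.
* Windows with under 50% usable bins are dropped from correlations;
  trailing partial windows are dropped entirely.
* All stochastic entry points require an explicit seed — a missing seed is
  an error, never a silent clock seed.

## Limitations

The caller's z-test treats bins as independent; long-range autocorrelation
in real coverage would make its p-values optimistic (the run-length and
merge criteria, not the p-value, do most of the real filtering). The
binomial enrichment p is slightly conservative across heterogeneous
strata. Consensus intersection can be empty for chains of staggered
overlaps, in which case the component is flagged rather than silently
dropped. Amplification (overrepresentation) calling is out of scope, as is
aCGH segmentation — any pre-binned log2 track can be fed directly into the
caller instead.
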