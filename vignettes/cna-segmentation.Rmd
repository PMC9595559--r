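---
title: "Segmenting tumor copy-number bin data with cnaseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting tumor copy-number bin data with cnaseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnaseg)
```

## The problem

Somatic copy-number aberrations (CNAs) gain or lose large genomic segments in
tumor cells. Bulk DNA sequencing of a tumor sample measures two signals per
genomic bin (a fixed-width window, typically 50 kb): the read-depth ratio
(RDR), proportional to the total number of copies of the bin, and the
B-allele frequency (BAF) at heterozygous germline SNPs, which measures
allelic imbalance. A heterozygous diploid bin has BAF 0.5; a bin with two
copies of one allele and one of the other has BAF 1/3; three copies of a
single allele give BAF 0.

Downstream copy-number callers require a *segmentation*: an assignment of
each bin to a cluster of bins sharing a copy-number state. Two families of
methods exist. *Local* segmentation (HMMs, change-point methods) exploits
genomic adjacency — CNAs affect contiguous runs of bins — but tends to
over-segment across samples. *Global* segmentation (mixture models) pools
bins genome-wide, which is robust at low coverage but blind to focal events
and free to scatter one genomic segment over several clusters. cnaseg
implements both and their sequential combination, together with the
scripted editing, analytics, copy-state inference and evaluation tooling
needed to refine and assess a segmentation without a GUI.

## Data model

A `bin_table` holds `n` bins × `m` samples: coordinates, an `n × m` RDR
matrix, an `n × m` BAF matrix (mirrored into [0, 0.5] on load, since the
allelic-imbalance view `0.5 − BAF` presumes the minor-allele fraction), and
one integer cluster label per bin. Labels −1 (unclustered) and −2 (erased)
are reserved; erased bins are dropped on export. The TSV dialect requires
columns `CHR`, `START`, `END`, `RD`, `BAF`, optional `CLUSTER`, and obeys
three ordering rules: chromosomes grouped and position-sorted, same-position
rows grouped, and every bin present in every sample. Missing or NaN values
are rejected rather than imputed — the third rule demands complete data.

The dialect names no sample column; `cnaseg` accepts an optional `SAMPLE`
column and otherwise assigns samples by within-position row order. This
convention (not part of the dialect) keeps single-sample files minimal while
making multi-sample files deterministic. Coordinates are treated 0-based,
start-inclusive/end-exclusive; they enter only ordering, adjacency and gene
overlap, so the convention is internal. Chromosomes keep their
first-appearance order from the file — the ordering rules demand grouping,
not a karyotype order.

## The hybrid segmentation model

Each bin is a point in 2m-dimensional space,
`v_i = [RDR(1,i), …, RDR(m,i), BAF(1,i), …, BAF(m,i)]`.

**Global stage.** A k-component Gaussian mixture is fitted by EM.
Covariance is diagonal by default: RDR noise (read sampling) and BAF noise
(allele counting) live on different scales, and full covariance overfits at
the small k typical of clonal structure; full covariance remains available
as an option. Initialisation is k-means++ seeding followed by a hard
nearest-center assignment whose per-cluster moments seed the first M-step —
seeding every component at the pooled variance lets two nearby clusters
collapse symmetrically onto their midpoint, which per-cluster moments avoid.
Ten restarts are run from the user's seed and the best likelihood kept, so
fits are reproducible. Per-dimension variances are floored at 1e−6 to guard
against collapse onto duplicated points; a restart that starves a component
is discarded. Responsibility ties break toward the lower component index so
that duplicated rows always share a label. When k is not given it is chosen
by BIC over a user range; the underlying problem takes k as given, so the
criterion exists for unattended runs.

**Local stage.** The fitted components become the emission distributions of
a hidden Markov model with self-transition probability τ and uniform
off-diagonal mass (1 − τ)/(k − 1), uniform initial distribution. Viterbi
decoding runs per chromosome, so bins on different chromosomes never
constrain each other. τ defaults to 0.99 per 50-kb bin: CNAs generally
affect large genomic segments, so a switch should cost roughly
log(0.99/0.0033) ≈ 5.7 nats against the emission evidence, enough to absorb
isolated outlier bins without erasing real breakpoints. At τ = 1/k the
chain degenerates to per-bin maximum-likelihood assignment. Transitions are
fixed, not learned: with emissions pinned by the global stage, τ is a
single interpretable smoothing knob, and learning it from one genome would
confound segment length with cluster recurrence. Viterbi back-pointer ties
break toward the lower component index.

Features are clustered on their native scales by default (an optional
z-scaling flag exists): the centroid-threshold semantics of the editing
operations are stated in data units, and scaling would silently change
them.

`segment_bins()` wraps both stages and returns a classed fit with `print`,
`summary`, `coef`, `fitted` and `plot` methods; `mode = "global"` stops
after the mixture, `mode = "local"` decodes a supplied mixture.

## Editing, analytics and the operation log

The scripted editing operations mirror interactive cluster curation:
`assign_cluster`, `new_cluster` (next ID = max in use + 1, never recycling
an emptied ID), `merge_by_centroids` and `absorb_bins`. Merging flags every
cluster pair whose centroid RDR and BAF gaps are within per-sample
thresholds in *every* sample, chains flagged pairs into connected
components, and lets the largest member (most bins; ties to the lowest ID)
absorb each component. Absorption compares each donor bin's Euclidean
distance to its own and to the recipient centroids, moving it only when the
nearest is a recipient and the per-dimension gaps pass the thresholds; the
flag rule is per-dimension while nearest-candidate selection is Euclidean,
matching how the two operations are specified. A bin nearest its own
centroid is held ineligible. Centroids are frozen at entry so reassignment
cannot cascade within one call — iterate the call for repeated absorption.
Every operation appends an invertible entry to the table's log;
`replay_edit_log()` reproduces the final clustering from the initial one
and `undo_edit()` pops the last entry.

Analytics report per-cluster centroids, mean silhouette coefficients and
mean inter-cluster distances. The exact silhouette costs O(n²) — real
tables run to ~50,000 bins — so `silhouette_by_cluster()` subsamples
uniformly without replacement to a seeded cap (default 2,000); with the cap
at n it equals `silhouette_exact()` to machine precision. Singleton
clusters score 0 by convention. Inter-cluster distance averages over cross
pairs of points; a centroid-to-centroid variant is available since both
readings of "distance between clusters" are useful. Note that subsampling
is only trustworthy for clusters large enough to be represented — the tests
assert convergence on clusters of at least ten members.

## Copy-state inference

A sample of purity μ mixes tumor cells carrying state (a, b) with normal
diploid cells. The expected signals under this normal-contamination model
are

    E[BAF] = (μ·b + (1 − μ)) / (μ·(a + b) + 2·(1 − μ))
    E[RDR] = (μ·(a + b) + 2·(1 − μ)) / (μ·ρ + 2·(1 − μ))

with ρ the tumor ploidy. These closed forms are fixed by the canonical
anchors — BAF 1/3 for a (2,1) gain at μ = 1, 0 for (3,0), 0.5 for any
balanced state — and are the only mixture expectations consistent with
them. `assign_states()` matches each cluster centroid to the state
(a ≥ b ≥ 0, a + b ≤ `max_total`, default 6) minimising the summed squared
RDR/BAF gaps over samples; ties prefer the smaller total, then the larger
minor-allele count. The round trip is exact down to μ ≈ 0.3, below which
distinct states' expectations begin to collide (the tests document the
collision behaviour).

`scan_purity_ploidy()` scores a (μ, ρ) grid per sample — each sample gets
its own ranked grid using only its centroid columns, because purities
genuinely differ across samples and a joint shared-composition scan would
average away exactly the signal being estimated. A flat zero score across
purities (every cluster diploid) is flagged as unidentifiable.
`classify_gene()` classifies driver genes by total copy number against the
diploid baseline — total > 2 amplified, < 2 deleted, = 2 unaffected, so
copy-neutral LOH (2,0) counts as unaffected; the baseline is diploid
regardless of tumor ploidy, keeping the ternary interpretable without
whole-genome-duplication awareness. Mixed verdicts across a gene's bins
resolve by bin-count majority, ties to "ambiguous".

## The simulator: what it emulates and what it does not

`simulate_bins()` emulates multi-clone bulk sequencing with known ground
truth: contiguous planted segments, per-clone integer states, per-sample
mixing of clones and normal cells, and noise. Defaults are desk-scale and
were chosen once: 2 chromosomes × 250 bins of 50 kb, m = 2 samples, 2
tumor clones, 20 segments with 60% shared across clones, purities 0.6 and
0.8, RDR noise sd 0.05, 500 simulated SNP reads per bin, `max_total` 6 —
separable but nontrivial. Clone proportions split each sample's purity by
a deterministic cyclic weighting so the clone mixture differs between
samples and clone-specific segments stay distinguishable. Whole-segment
(0,0) states are excluded from the planted grid: a multi-megabase
homozygous deletion present in every cell is biologically implausible and
makes the BAF of a pure sample undefined. Each clone's ploidy is computed
from its own profile (mean total copies over equal-width bins), keeping
the RDR normalisation internally consistent. BAF noise is binomial rather
than Gaussian to respect the [0, 0.5] support and its coverage dependence;
RDR noise is truncated Gaussian. The ground-truth cluster of a bin is the
tuple of clone states at its segment, so recurrent states share a label —
the premise that makes global segmentation meaningful.

The simulator does *not* model read-level artefacts (GC bias, mappability,
wave patterns), whole-genome duplication, subclonal phylogenies deeper than
a star, or correlated noise along the genome. Passing recovery tests on
these simulations therefore demonstrates correctness of the model and
algorithms under the stated generative assumptions, not performance on
real sequencing data.

## Numerical choices

EM stops when the relative log-likelihood gain falls below 1e−8 or at 500
iterations, and asserts monotonicity each iteration. Viterbi runs entirely
in log space. All stochastic entry points take a seed and restore the
caller's RNG state. Problem sizes in the tests (500-bin genomes, 200-replicate
metric baselines, Bell(6) = 203 partitions for exhaustive pair-counting
checks) were chosen as the smallest instances that still exercise every
regime — multi-chromosome decoding, shared and clone-specific segments,
tie-breaking — while keeping the default suite fast.

## Known limitations

- The HMM transition structure is a single τ; no distance-dependent or
  learned transitions.
- Purity/ploidy scanning assumes one dominant clone per cluster signal; the
  full multi-clone factorisation of specialised callers is out of scope.
- Driver-gene classification ignores tumor ploidy (diploid baseline by
  design) and subclonal (fractional) copy numbers.
- The silhouette approximation is unreliable for clusters smaller than a
  few dozen bins at aggressive caps; use `sample_cap >= n` when feasible.
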