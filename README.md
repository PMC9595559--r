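# cnaseg

Segmentation of multi-sample tumor copy-number bin data, as a headless R
library and command-line tool.

Bulk DNA sequencing of a tumor summarises each fixed-width genomic bin by two
signals: the **read-depth ratio** (RDR), proportional to total copy number,
and the **B-allele frequency** (BAF) at heterozygous germline SNPs, which
measures allelic imbalance (0.5 means balance; a (2,1) gain gives 1/3; three
copies of one allele give 0). Copy-number callers need a *segmentation* —
an assignment of bins to clusters sharing a copy-number state. cnaseg is for
analysts who want that segmentation scriptable and reproducible: the
automated stages, the cluster-editing operations usually done by hand, and
the quality metrics, all callable from R or a shell.

## What it does

- **Hybrid segmentation.** Each bin is a point
  `v_i = [RDR(1,i),…,RDR(m,i), BAF(1,i),…,BAF(m,i)]` in 2m dimensions.
  A k-component Gaussian mixture fitted by EM (global stage) supplies the
  emission distributions of a hidden Markov model with self-transition
  probability τ, decoded per chromosome by Viterbi (local stage). The
  composition keeps recurrent copy-number states in one cluster while
  enforcing genomic contiguity. `segment_bins()` returns a classed fit with
  `print`/`summary`/`coef`/`fitted`/`plot` methods.
- **Scripted editing** with a replayable log: `assign_cluster`,
  `new_cluster`, centroid-threshold `merge_by_centroids` (flagged pairs
  chained into connected components; the largest cluster absorbs each
  component), `absorb_bins`, `undo_edit`, `replay_edit_log`.
- **Analytics**: per-cluster centroids, downsampled silhouette
  coefficients, mean inter-cluster distances, allelic imbalance.
- **Copy-state inference** under the normal-contamination model
  `E[BAF] = (μb + (1−μ)) / (μ(a+b) + 2(1−μ))`,
  `E[RDR] = (μ(a+b) + 2(1−μ)) / (μρ + 2(1−μ))`:
  per-cluster integer states `(a, b)`, purity/ploidy grid scans, and
  driver-gene classification (amplified / deleted / unaffected).
- **Evaluation**: adjusted Rand index, V-measure, exact silhouette.
- **Simulation**: a multi-clone generator with planted segments, per-sample
  purities and known ground-truth labels, so everything above is testable
  end to end.
- **I/O**: the tab-separated bin dialect (`CHR`, `START`, `END`, `RD`,
  `BAF`, optional `CLUSTER`/`SAMPLE`; reserved cluster IDs −1 unclustered
  and −2 erased; erased bins excluded from export; extra columns passed
  through), driver-gene tables, and BED-like segment export.

## Worked example

```r
library(cnaseg)

sim <- simulate_bins(simulation_config(seed = 7))   # 500 bins, 2 samples, 2 clones
k <- length(unique(sim$truth))
fit <- segment_bins(sim$table, k = k, seed = 7)
fit
#> CNA segmentation (hybrid mode): k = 17, n = 500 bins, m = 2 samples
#>   tau = 0.99
#>   26 segments over 2 chromosomes; GMM log-likelihood 3018.555

adjusted_rand_index(sim$truth, fit$clustering)  # 0.9136
v_measure(sim$truth, fit$clustering)            # 0.9575

head(fit$segments, 3)
#>   chrom   start     end cluster n_bins
#> 1  chr1       0 1100000      11     22
#> 2  chr1 1100000 2950000      15     37
#> 3  chr1 2950000 4500000      13     31

states <- assign_states(compute_centroids(fit$table),
                        purity = c(0.6, 0.8), ploidy = c(2.5, 2.5))
head(states, 4)
#>   cluster a b total   residual
#> 1       0 2 1     3 0.07753839
#> 2       1 1 0     1 0.14730804
#> 3       2 4 0     4 0.03653900
#> 4       3 3 1     4 0.03851814
```

The ARI of 0.9136 says the hybrid segmentation recovers the planted
clusters almost exactly under the default noise (RDR sd 0.05, 500 SNP reads
per bin); the V-measure of 0.9575 says the recovered clusters are both
homogeneous and complete relative to ground truth. Each row of `states` is
a cluster's inferred allele-specific state: cluster 0 is a (2,1) gain,
cluster 1 a (1,0) deletion, and the residual is the squared RDR/BAF gap
between the centroid and the state's expected signals summed over samples.

The same pipeline from a shell:

```sh
Rscript inst/cli/cnaseg.R simulate --out-dir sim --seed 7
Rscript inst/cli/cnaseg.R segment  --in sim/bins.tsv --out sim/segmented.tsv --k 17 --seed 7
Rscript inst/cli/cnaseg.R evaluate --in sim/segmented.tsv --truth sim/truth.tsv --out sim/report.tsv
```

## Documentation

The methods vignette (`vignettes/cna-segmentation.Rmd`) describes the
model, its assumptions, the tunable parameters and their defaults, what the
simulator does and does not emulate, and the package's numerical choices.
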