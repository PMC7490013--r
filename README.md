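# tecage

Computational methods for studying how the thymic stroma changes with age.
The thymus trains T cells: cortical and medullary thymic epithelial cells
(cTEC/mTEC) select thymocytes whose T cell receptors (TCRs) are useful and
delete self-reactive ones, partly by promiscuously expressing
tissue-restricted antigens (TRAs). Profiling this system across the lifespan
requires a set of bespoke computational pieces that `tecage` implements as a
tested, reusable R package:

- **TCR V(D)J rearrangement simulation.** Thymocytes assemble their receptor
  chains by randomly joining V, (D), J and C germline segments with
  untemplated junction insertions (`n ~ Poisson(lambda = 4)` per junction).
  The simulator models the beta chain's two sequential J/C cassettes
  (TRBJ1/TRBC1 then TRBJ2/TRBC2) over two alleles, allelic exclusion before
  alpha rearrangement, and calls an attempt productive when an ATG in the V
  segment opens a stop-free reading frame spanning the assembled chain.
  Sub-sampling utilities report segment-usage proportions and the Shannon
  entropy `H = -sum(f_i log2 f_i)` of CDR3 clonotypes to size sequencing
  experiments.
- **Single-cell RNA-seq preprocessing.** Plate (Smart-seq2 + ERCC) and
  droplet QC rules, size-factor normalisation with `log10(x + 1)`, and
  mean-variance highly-variable-gene selection.
- **GF-ICF clustering.** The gene frequency-inverse cell frequency transform
  `GF_ICF = log2(C + 1) * log10(N / (1 + E_x))`, shared-nearest-neighbour
  graphs, Walktrap communities, consensus robustness scoring and kNN label
  transfer between datasets.
- **Hashtag demultiplexing.** Per-sample CPM k-means, per-hashtag negative
  binomial background fits, 99th-quantile thresholds `q`, and
  Singlet/Multiplet/Dropout calls.
- **TRA atlas.** The tau tissue-specificity index
  `tau = sum_i(1 - x_i / max_j x_j) / (n - 1)` over a gene-by-tissue panel
  (TRA if `tau >= 0.8`, constitutive if `tau <= 0.4`), plus per-cell tissue
  representation counting.
- **Trajectory analysis.** Diffusion maps with local kernel bandwidths,
  diffusion pseudotime from the DC1 apex, density along pseudotime, and
  Gaussian-mixture meta-stable state assignment.
- **Age-abundance statistics.** Negative binomial regression of cell counts
  on age (edgeR quasi-likelihood or `glm.nb` likelihood-ratio engines),
  Poisson state-abundance tests with Bonferroni control, parent-offset
  models of thymocyte negative selection, and limma regression of
  expression on `log2(age)`.

Every module has a matching synthetic-data generator (`gen_germline_locus`,
`gen_sc_counts`, `gen_hto_counts`, `gen_tissue_panel`, `gen_trajectory`)
that produces inputs with known ground truth, so the full pipeline is
exercisable and testable without any external download.

## Worked example

```r
library(tecage)

locus <- gen_germline_locus(locus_spec(seed = 1))
rep <- simulate_repertoire(locus, n = 20000, seed = 42)
summary(rep)
#> Thymocytes attempted: 20000
#>   valid beta chain   : 34.9% of thymocytes
#>   valid alpha chain  : 31.1% of those reaching alpha
#>   productive pair    : 10.8% of thymocytes
#>   beta insertions    : 8.00 nt per attempt (two junctions)

sat <- saturation_stats(rep, sizes = c(10, 100, 500, 1000), n_seeds = 5)
with(subset(sat$entropy, chain == "beta"), tapply(entropy, size, mean))
#>       10      100      500     1000
#> 3.321928 6.643856 8.963384 9.962984
```

A third of thymocytes on this synthetic locus assemble a productive beta
chain within their four attempts, insertions average `2 * lambda = 8`
nucleotides per beta attempt, and clonotype diversity keeps climbing through
a 1000-cell subsample (at 10 cells every clonotype is unique, so the entropy
is exactly `log2(10) = 3.32` bits) — the saturation curve a sequencing
experiment must clear.

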