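---
title: "Models and methods in tecage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tecage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecage)
```

`tecage` packages the computational machinery needed to study the ageing
thymic stroma: a T cell receptor (TCR) rearrangement simulator, a
single-cell clustering stack built on the GF-ICF transform, a hashtag
demultiplexer, a tissue-restricted antigen (TRA) atlas, diffusion
pseudotime with meta-stable states, and a suite of age-abundance
regressions. This vignette records the models behind each piece, the
parameters that matter, and the design decisions taken where more than one
reasonable implementation existed.

## The V(D)J rearrangement model

A thymocyte's receptor is assembled by somatic recombination. The simulator
(`simulate_thymocyte()`, `simulate_repertoire()`) follows the developmental
ordering:

1. **Beta chain, up to four attempts.** On each allele, V and D segments are
   drawn uniformly; the first attempt joins a J segment from the first
   cassette (with its matched constant region, mirroring TRBJ1/TRBC1), and a
   failure is retried on the second cassette. If both attempts on allele 1
   fail, allele 2 gets the same two attempts.
2. **Allelic exclusion.** Only thymocytes with a productive beta chain
   proceed to the alpha chain: one attempt per allele, V joined directly to
   J (no D segment).
3. **Junction insertions.** Each junction (beta: V–D and VD–J; alpha: V–J)
   receives `Poisson(lambda = 4)` untemplated nucleotides with uniform base
   identity, so a beta attempt carries 8 inserted nucleotides in
   expectation. No exonucleolytic trimming is modelled; insertions are the
   only junctional diversity mechanism.
4. **Productivity.** An attempt is productive when *some* ATG inside the V
   segment (not only the first) opens a reading frame that (a) tiles the
   assembled sequence exactly — the distance from the ATG to the 3' end of
   the constant segment is a multiple of three — and (b) contains no
   in-frame stop codon before the final codon. This operationalises "a
   complete open reading frame spanning V(D)J and the constant segment";
   requiring exact tiling is the strictest sensible reading and makes the
   final codon the only position where a stop is tolerated.

Two exact consequences anchor the test suite: the probability of a valid
beta chain satisfies `P = 1 - (1 - p1)^2 (1 - p2)^2`, with `p1`, `p2` the
per-attempt productive rates on the two cassettes, and unconditional mean
insertions per beta attempt equal `2 * lambda = 8`.

**Clonotypes.** The CDR3-like clonotype of a productive attempt
(`clonotype()`) translates, in the productive frame, the codons overlapping
the junction window: the last 9 nt of V, all insertions (plus D for beta),
and the first 9 nt of J. The 9-nt flank is configurable; it is a package
definition, since CDR3 boundaries are not meaningful for synthetic
segments. Diversity is summarised by base-2 Shannon entropy over clonotype
frequencies (`shannon_entropy()`, base configurable).

**The synthetic locus.** `gen_germline_locus()` replaces the real murine
locus with a parametric emulation: uniformly composed random segments, with
an ATG planted at a configurable offset in a configurable fraction of V
segments. Two scrubbing rules keep the emulation well-behaved: incidental
ATGs are removed from V segments (so `atg_frac` exactly controls which V
segments can seed a frame), and constant segments are made stop-free in
their 3'-anchored reading frame. The latter mirrors biology — a real
constant region is coding in the productive frame — and is necessary
because every complete frame reads the constant segment at the same codon
offset: a stop there would sterilise an entire cassette for every V/D/J
combination. Default segment counts (20 V, 2 D, 12 J per chain, two beta
cassettes) and lengths (V 45–57 nt, D 10–16, J 15–21, C 24–33) were chosen
once to give non-degenerate per-attempt productivity (roughly 0.05–0.2, so
multi-attempt rescue is visible) at simulation scales of 10^4–10^5
thymocytes; they are not calibrated to any particular organism, and the
package makes no claim that absolute validity rates on synthetic loci match
murine ones. Checking those published rates requires the real C57BL/6
TRA/TRB segment sequences, which must be supplied by the user (see the
README) since reference databases cannot be redistributed.

## Single-cell preprocessing

`qc_filter()` implements two rule sets. Plate mode (Smart-seq2 with ERCC
spike-ins) removes cells with spike-in fraction > 40%, depth < 1e5 reads,
or sparsity > 97%. Droplet mode removes cells whose mitochondrial fraction
exceeds the within-sample median by more than twice the median absolute
deviation (one-sided — only *high* mitochondrial content marks damage), or
with fewer than 1000 UMIs. The MAD uses the usual normal-consistency
constant (1.4826). Plate-mode QC is idempotent; droplet mode recomputes the
MAD threshold on the filtered population, so re-filtering can in principle
remove further cells — run it once per sample.

`normalize_cells()` divides counts by per-cell size factors and stores
`log10(normalised + 1)`. Library-size factors (total over geometric mean,
so factors multiply to 1) are the built-in reference; pooled deconvolution
factors are delegated to scran when installed, since that estimator is an
established external method rather than part of this package's
contribution. `select_hvgs()` fits a loess mean–variance trend over genes
(robust `family = "symmetric"`, span 0.3) and tests each gene's variance
against its trend value with a one-sided chi-square on `n - 1` degrees of
freedom, Benjamini–Hochberg adjusted; the droplet-style default threshold
is FDR `1e-7`. A top-K fallback covers degenerate trends.

## GF-ICF clustering

The transform (`gficf_transform()`) is TF-IDF for cells: gene frequency
`G_f = log2(C + 1)` (pseudocount because raw `log2(C)` is undefined at
zero; configurable) scaled per gene by the inverse cell frequency
`ICF = log10(N / (1 + E_x))`, where `E_x` counts cells expressing gene x.
Genes expressed everywhere get a small negative weight and are retained —
clipping them to zero would silently delete ubiquitous genes.

`snn_walktrap()` builds a k-nearest-neighbour graph (Euclidean distances,
optionally in PCA space), re-weights edges by the Jaccard overlap of
neighbour sets (the shared-nearest-neighbour construction; the Jaccard
choice is ours, as edge weighting is otherwise unspecified), drops
zero-overlap edges and runs Walktrap with the default walk length of 4,
taking the maximum-modularity cut. Defaults follow the two experimental
designs: `k = 10` directly on GF-ICF values for plate data, `k = 31` on 20
principal components of highly variable genes for droplet data.

`consensus_robustness()` re-clusters under a parameter grid (with/without
GF-ICF, different k) and scores the mean off-diagonal co-clustering
frequency within the clusters of the first (reference) parameterisation.
`knn_label_transfer()` cosine-normalises both datasets on their shared
genes, optionally applies an injected batch corrector (identity and
per-dataset gene centering ship with the package; full mutual-nearest-
neighbour correction is deliberately out of scope) and takes the majority
label among the 5 nearest reference cells, breaking ties by mean distance.

## Hashtag demultiplexing

`hto_demux()` processes one sample at a time: CPM across the sample's
hashtags, k-means on CPM with k equal to the number of expected hashtags
(10 restarts, seeded), then per hashtag a background threshold fit on raw
counts after excluding that hashtag's highest-CPM partition and the top
0.5% of raw counts. Clustering on CPM but thresholding raw counts is
intentional and easy to confuse. The background is negative binomial,
fitted by maximum likelihood initialised at the method-of-moments estimate;
the likelihood step matters because a handful of signal barcodes (chiefly
doublets whose k-means partition followed their *other* hashtag) always
survive the exclusions, and raw moments are so sensitive to them that the
99th-quantile threshold `q` can triple. Sub-Poisson backgrounds fall back
to a Poisson quantile and constant backgrounds to the constant itself, both
flagged. Barcodes with counts `>= q` get the hashtag; exactly one hashtag
means Singlet, several Multiplet, none Dropout. Note the exact-threshold
convention is `>=`, so `quantile = 0` assigns everything.

The generator defaults describe the pooling design the algorithm was built
for: six hashtags per well, signal NB(mean 500, size 10), background
NB(mean 5, size 1), around 10% doublets. With only two hashtags and a 10%
doublet rate the algorithm's own geometry caps performance — every
background fit is then ~10% signal-contaminated because no k-means
partition can absorb doublets — so the package's recall claims are stated
for the six-hashtag design. Even in the clean two-hashtag case, a
99th-quantile threshold mathematically leaves about 1.6% of true singlets
above threshold on the other hashtag (discreteness of NB(1, 1)), which is
why near-perfect rather than perfect recall is the correct expectation.

## The tau TRA atlas

For a gene with expression `x_i` across `n` tissues (a panel pre-collapsed
to one value per tissue, e.g. the maximum normalised expression over the
tissue's samples with isoform means taken first),

tau = sum_i (1 - x_i / max_j x_j) / (n - 1).

Uniform profiles give 0, single-tissue profiles 1. Classification follows
the conventional thresholds (TRA `>= 0.8`, constitutive `<= 0.4`,
miscellaneous between). Each TRA is assigned its argmax tissue; exact ties
keep the first panel column and emit a message, since no principled
tie-break exists. All-zero genes are excluded with a warning, and an
optional `min_expression` floor (off by default) can exclude barely
detected genes. `count_tissue_representation()` counts, per cell and
assigned tissue, TRA genes with `log10(norm + 1) > 0` — i.e. any non-zero
normalised count — plus the per-cell percentage of expressed genes that are
TRAs, and aggregates counts over (age, replicate) for the abundance models.

## Diffusion pseudotime and meta-stable states

`diffusion_pseudotime()` uses the standard random-walk construction: a
Gaussian kernel on the union k-nearest-neighbour graph (`k = 21`, on 20
principal components by default) with per-cell bandwidth equal to the
distance to the `ceiling(k/2)`-th neighbour (local scaling, the documented
behaviour of the established diffusion-map implementations), density
normalisation, and row normalisation to a Markov matrix. Diffusion
components are the non-trivial right eigenvectors; diffusion pseudotime
between cells is the Euclidean distance of eigenvector coordinates weighted
by `lambda / (1 - lambda)` — the accumulated random-walk formulation. The
root defaults to the cell with the lowest DC1 value (the apex of a
bifurcating lineage); the DC1 sign is arbitrary, which only swaps which end
of the trajectory anchors the distances. Disconnected neighbour graphs are
refused with the component sizes named, rather than silently embedding
separate manifolds. Eigenvalues are clipped below 1 by 1e-12 to keep the
weights finite under near-disconnection.

`dpt_density()` evaluates a Gaussian KDE (Silverman bandwidth by default)
at `ceiling(0.01 * n)` points spanning the pseudotime range — a fixed 1%
evaluation rule, hence the 100-cell minimum. `assign_states()` fits a
univariate unequal-variance Gaussian mixture via mclust (2 or 3 components
in the intended analyses), assigns cells by maximum responsibility and
relabels states by increasing mean pseudotime, so state 1 is always the
earliest. mclust's model-based hierarchical initialisation makes the fit
deterministic; the `seed` argument exists for interface stability.

## Age-abundance statistics

`nb_abundance_test()` models per-replicate counts of each group as negative
binomial in age (natural week scale, matching how per-week abundance
changes are reported), with the total cells captured per replicate as an
observation weight normalised to mean one. Two engines are labelled in the
output: the edgeR quasi-likelihood F-test (groups as "genes", sharing
dispersion across groups, the default) and per-group `MASS::glm.nb` with a
likelihood-ratio test, which additionally reports a slope standard error
and falls back to Poisson on non-convergence. Quadratic age terms can be
added and are tested jointly with the linear term. BH-FDR across groups at
1% defines significance. Under all-null simulation the default engine's
family-wise any-discovery rate sits at the nominal 1%.

`poisson_state_test()` fits per-state Poisson GLMs of replicate counts on
age and Bonferroni-corrects within each lineage (threshold 0.01).
`offset_selection_test()` regresses a selection wave's counts on age with
`offset(log(parent))`, so the estimand is the log selected-fraction change
per week and joint rescaling of wave and parent leaves inference unchanged;
zero-parent rows are excluded with a warning. `age_expression_trend()`
regresses log-normalised expression on `log2(age)` — expression changes
are reported per age doubling, unlike the count models' per-week scale;
both scales are kept deliberately — with log size factor as a depth
covariate, using limma's moderated statistics.

## What the generators emulate, and what they do not

The synthetic-data module reproduces the *statistical structure* each
method assumes: discrete subtypes with marker blocks and age-shifting
composition (negative binomial counts, log-normal baselines, per-cell
log-normal capture efficiency, optional uniform dropout, ERCC rows with
cell-independent means); hashtag mixtures with known singlet/doublet/empty
identity; tissue panels with single-tissue, uniform, geometric-decay and
random profiles; one-dimensional state mixtures embedded along a smooth
curve with isotropic noise. Passing tests on these inputs demonstrates the
algorithms recover planted structure under their own model assumptions.
They do not demonstrate robustness to the pathologies of real data —
ambient RNA, batch effects beyond mean shifts, doublet transcriptomes in
the expression matrix, zero inflation beyond independent thinning,
sequence-level realism of the murine locus, or branching trajectories
(branches are taken as upstream annotation throughout, as in the intended
analyses).

## Problem sizes and numerical choices

The shipped tests run the simulator at 10^5 thymocytes (about 20 s), the
clustering stack at 500 cells x 1000 genes, demultiplexing at 2000
barcodes, mixtures at ~1200 cells, and the regression suite at 200 planted
plus 500 null simulations of a 10-group screen — sizes chosen so the whole
suite completes in a couple of minutes while keeping Monte-Carlo error well
below the asserted margins. Tolerances in tests are derived, not tuned:
binomial or Poisson standard errors at the stated n, exact discreteness
bounds for quantile thresholds, and 2–3 standard errors for estimator
recovery. Ties in k-nearest-neighbour sets follow `order()`'s stable
ordering; k-means uses 10 restarts under a caller-supplied seed; all
generators draw from one RNG seeded by `spec$seed` and restore the
caller's RNG state afterwards.
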