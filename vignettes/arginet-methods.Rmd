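---
title: "Methods: statistical pipeline for arginine-dependent giant cell multi-omics"
author: "arginet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical pipeline for arginine-dependent giant cell multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arginet)
```

# Scope

`arginet` re-implements, as tested and reusable functions, the
computational stages of a multi-omics study of arginine-dependent
multinucleated giant cell (osteoclast) formation: RANKL-driven
differentiation of myeloid precursors profiled under arginine-sufficient
and arginine-deprived conditions (arginase-mediated depletion,
arginine-free starvation, and rescue arms), with four biological
replicates per condition. The package covers the transcriptomic
differential-expression stage, a rank-sum pathway permutation test, the
label-free proteomics stage, stable-isotope tracer arithmetic, and
prize-collecting Steiner-tree network integration with a
connected-subgraph randomization null. Upstream raw-data processing (read
alignment, feature counting, peptide search and quantification) and
external-database enrichment are out of scope: the pipeline starts from
count matrices, log2 intensity matrices, gene-set files, edge lists and
isotopologue tables.

Because the deposited datasets are not downloaded, every input can be
simulated with known ground truth (`gen_design()`, `gen_counts()`,
`gen_pathways()`, `gen_proteome()`, `gen_network()`,
`gen_isotopologues()`), and all statistical claims made by the test suite
are claims about recovery of planted truth under those generative models.

# Transcriptomics

## Filtering and normalization

Genes are kept when $\log(\mathrm{CPM} + 0.25) > 0$ — equivalently
$\mathrm{CPM} > 0.75$, a rule independent of the logarithm base — in at
least three samples (`filter_expressed()`). Expression values are
$\log_2(\mathrm{CPM} + 0.25)$ (`normalize_logcpm()`); the prior constant
matches the filter's constant, keeps zero counts finite, and preserves
CPM's invariance to library-size rescaling.

## Moderated differential expression

`test_de()` computes, per gene, a two-sample $t$ statistic on log2-CPM
with empirical-Bayes variance moderation

$$ s^2_{\text{shrunk}} = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d}, \qquad
   t = \frac{\bar{x}_A - \bar{x}_B}{\sqrt{s^2_{\text{shrunk}} (1/n_A + 1/n_B)}} $$

with prior degrees of freedom $d_0 = 4$, $s_0^2$ the across-gene mean of
the pooled per-gene variances, $d = n_A + n_B - 2$, and a
$t_{d_0 + d}$ reference. P-values are Benjamini–Hochberg adjusted; a gene
is *called* when $|\log_2 \mathrm{FC}| > 1$ at FDR $< 5\%$. This is an
operational approximation of a voom/limma fit — it shares the shrinkage
idea and the calling rule, not the precision-weight machinery — and is
documented as such. Under a complete Gaussian null its p-values are
approximately uniform (Kolmogorov–Smirnov statistic below 0.05 at 2000
genes in the suite), and on negative-binomial data with planted
$|\log_2\mathrm{FC}| = 3$ at dispersion $0.05$ it recovers the planted
genes with sensitivity and precision above 0.8.

DE sets from alternative upstream counting modes (with and without
multi-mapped reads) are compared with the Jaccard coefficient
(`jaccard()`); both-empty sets return 1 by convention. Sample structure is
summarized by complete-linkage hierarchical clustering of z-scored top
fold-change genes (`cluster_top_genes()`, constant rows z-score to zero so
distances stay total) and classical MDS on Euclidean distances between
sample profiles (`mds_coordinates()`).

# Rank-sum pathway permutation test

For a pathway $G$ and two conditions with replicate sample sets $A$ and
$B$, samples are ranked per gene within $A \cup B$ (midranks for ties) and

$$ T = \sum_{g \in G} \Big| \sum_{s \in A} r_{g,s} - \sum_{s \in B} r_{g,s} \Big|. $$

The sample–condition association is randomized (default 12,000 times, the
same permutation applied to all genes) and the empirical p-value compares
$T$ to the randomization distribution; p-values are Bonferroni-corrected
across the pathways tested in one invocation.

Design choices made where the procedure was genuinely open:

* **Ranking is computed within the two compared conditions only**, since
  comparisons are pairwise; pooling all seven conditions into the ranks
  would leak between-contrast information into a pairwise test.
* **Midranks for ties** preserve $T = 0$ for constant data.
* **Add-one empirical p-values** in Monte-Carlo mode,
  $p = (1 + \#\{T^* \ge T\})/(1 + n_{\text{perm}})$, guaranteeing $p > 0$.
* **Automatic exhaustive enumeration**: a 4v4 design has only
  $\binom{8}{4} = 70$ distinct assignments, so whenever the assignment
  count does not exceed `n_perm` the test enumerates them all and reports
  the exact p-value (identity included). Sampling mode remains available
  (`mode = "sample"`).

## Discreteness and conservativeness at 4v4

The 4v4 assignment space is tiny and complement-symmetric: assignments
come in pairs with equal $T$, so exact p-values live on the grid
$\{2/70, 4/70, \dots\}$ and the smallest attainable p is
$2/70 \approx 0.029$. Consequently the test **cannot** reject at exactly
the nominal rate: at $\alpha = 0.05$ its type-I error is capped near
$0.029$ (exact mode) and, because the integer-valued rank sums tie across
assignments, the realized rate on Gaussian null data is nearer $0.02$.
This is the familiar conservativeness of small-sample permutation tests,
not an implementation artifact; type-I error control ($\le \alpha$) holds
and is asserted in the suite. Power is unaffected in the regimes of
interest: a coordinated 1.5-SD shift on a 20-gene pathway is detected in
over 90% of simulations.

# Proteomics

The stage order is fixed and mirrors the published narrative: log2
intensities → detection filter → left-censored imputation → CV filter →
z-scores → moderated test.

* `detection_filter()` keeps proteins observed in at least 3 of 4
  replicates of at least one condition.
* `impute_missing()` draws missing cells from a normal distribution
  centred on the per-sample detection limit. The detection limit is
  operationalized as the sample's observed minimum shifted down by
  `downshift` observed SDs with width `width_factor` times the observed
  SD; the default `downshift = 0` centres the imputation on the observed
  minimum itself (the most literal reading of "centred on the detection
  limit"), while Perseus-style defaults are reachable with
  `downshift = 1.8`, `width_factor = 0.3`.
* `cv_filter()` keeps proteins whose overall coefficient of variation
  strictly exceeds the CV within every condition. CV is computed on the
  linear scale ($2^{\log_2 x}$) by default because the log-scale CV is
  mean-dependent and ill-behaved near zero; `cv_scale = "log2"` is
  provided since the original scale is unstated. Note that this filter
  deliberately enriches for between-condition variation; calibration
  claims about the downstream test are therefore made on unfiltered data
  (see below).
* `sam_test()` computes the SAM-style statistic
  $d = (\bar{x}_A - \bar{x}_B)/(s_{\text{pooled SE}} + s_0)$ with
  $s_0 = 0.05$ on per-protein z-scores, builds the null of $|d|$ from
  label permutations (one shuffle applied to all proteins), and reports a
  q-value at each threshold $|d_i|$ as the median permutation
  false-positive count over the observed positive count, capped at 1 and
  monotonized to be non-increasing in $|d|$. Significance is
  $q \le 0.05$.

The synthetic proteome (`gen_proteome()`) draws per-protein baselines
$\mathcal{N}(27, 2^2)$ on the log2 scale with within-replicate SD 0.3 —
typical of label-free replicate noise — and plants $\pm 1.5$ log2 effects
on 5% of proteins by default. Missingness is left-censored: the missing
probability is logistic in (detection limit − true value), rescaled to hit
the requested overall rate. Parameter-recovery claims for the test
(sensitivity $\ge 0.7$, empirical FDR $\le 0.1$ at the 0.05 threshold) are
made on fully observed matrices: they characterize the test itself,
whereas censored-and-imputed proteins are attenuated by construction — an
expected property of detection-limit imputation, visible in the pipeline
tests, not a defect of the test.

# Tracer arithmetic

`isotopologue_fraction()` returns intensity$(m{+}k)$ over the metabolite's
summed isotopologue pool; `label_ratio()` returns
intensity$(m{+}k)$/intensity$(m{+}0)$; `normalize_to_tracer()` divides a
target isotopologue by the tracer input (e.g. m+5 ornithine over
$^{13}$C$_6$ arginine, m+4 fumarate over $^{13}$C$_4$ aspartate). All
three are invariant to uniform intensity rescaling within a sample.
Fractions are returned as proportions; display scaling by 100 is left to
the caller. Natural-abundance isotope correction is **not** applied — the
upstream workflow did not describe one — and should be hooked in before
these functions when needed. `check_mass_balance()` flags
(metabolite, sample) pools whose fractions do not sum to 1 within $10^{-9}$.

# Network integration

Hit sets come from the omics stages: the arginase-effect set is the union
of called genes and significant proteins, scored by $|\log_2\mathrm{FC}|$
and $|d|$ and tagged by layer (`recarg1_effect_set()`); the
arginine-dependent RANKL set applies the exclusive-disjunction rule —
changed with arginine present but not with arginine absent
(`arg_dependent_set()`). Prizes are $\beta \cdot$ score for hits; edge
costs are $1 - w$ clamped to $[10^{-6}, 1]$ so that even full-confidence
edges keep the tree objective strictly penalized
(`build_prizes_costs()`). Edge confidence weights are an input column (the
original BioGRID directness/assay-strength mapping is not reproduced);
`gen_network()` supplies synthetic scale-free or Erdős–Rényi interactomes
with uniform weights, retaining the largest connected component.

`pcst_heuristic()` maximizes
$\sum_{v \in T} p_v - \lambda \sum_{e \in T} c_e$ greedily: start at the
maximum-prize node; repeatedly attach the prized node whose shortest
cost-path to the tree improves the objective most, re-extracting the tree
as a minimum spanning tree of the induced subgraph after each step; stop
at the first non-improving round and prune zero-prize leaves. The greedy
trace is monotone by construction and the output is always a tree or a
singleton. `pcst_exact()` — exhaustive enumeration of connected vertex
subsets scored by induced-MST cost, feasible to 15 nodes — serves as an
independent optimum: on 50 random instances of at most 8 nodes the
heuristic matches it in $\ge 80\%$ of cases and never falls below 90% of
the optimal objective. The exact solver exists to quantify the heuristic,
never to replace it at scale.

Tree overlap significance uses `overlap_null()`: 2000 independent pairs of
connected subgraphs of the two observed tree sizes, sampled by random
neighbour expansion from a uniform start node, with add-one empirical
p-values. The expansion sampler is **not uniform** over connected
subgraphs (uniform sampling is computationally hard); on complete graphs
it reduces to uniform subset sampling, which the suite exploits to check
the hypergeometric mean $ab/n$ on $K_{10}$. Whether the original analysis
sampled pairs independently or held one tree fixed is unstated;
independent pairs were chosen as the most direct reading of "matched
size".

# Determinism and problem sizes

Every stochastic operation takes a seed; `derive_seed()` mixes a master
seed with a stage index so one integer reproduces an entire run
(`run_pipeline()`), verified bit-identical across invocations. The default
verification sizes — 2000 genes, 2000 proteins, 300–500-node networks,
1000 null pathways, 200 power replicates, 12,000 or 2000 permutations —
were chosen as the smallest scales at which the binomial error of the
measured rates is well inside the asserted margins; all are arguments, so
larger studies run unchanged.

# Known limitations

* The DE stage approximates, and does not replicate, the original
  voom/limma/edgeR fit; reproducing the study's published DE counts
  (e.g. 464 genes) requires the deposited data and the original stack.
* The synthetic generators model no batch effects, no correlated genes
  within pathways beyond planted mean shifts, and no peptide-level
  structure in the proteome.
* The PCST heuristic is a greedy approximation; its quality is measured,
  not guaranteed.
* The subgraph null inherits the non-uniformity of the expansion sampler;
  the transcription-factor inference and community-detection steps of the
  original integrative analysis are out of scope.
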