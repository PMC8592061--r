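---
title: "Group-level ROI parcellation from voxel time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level ROI parcellation from voxel time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippcluster)
```

# The problem

Functional parcellation asks whether the voxels of an anatomical structure —
here, the hippocampus — fall into subregions whose BOLD time courses are more
similar to each other than to the rest of the structure, and whether those
subregions are consistent across individuals, hemispheres and task states.
`hippcluster` implements one complete, data-driven answer to that question as
a tested pipeline:

1. **ROI definition.** A probabilistic atlas (per-voxel fraction of reference
   subjects in which the voxel belongs to the structure) is thresholded,
   inclusively, at a fraction (default 0.75). Left and right hippocampus are
   processed as entirely separate runs.
2. **Substrate construction.** Each subject's in-mask voxel time series are
   extracted, z-scored per voxel, and concatenated across subjects into the
   matrix $Z \in \mathbb{R}^{N \times p}$ ($N$ voxels, $p$ the summed
   timepoints of the $M$ subjects).
3. **Clustering.** Average-linkage (UPGMA) agglomerative clustering of the
   rows of $Z$ under Euclidean distance, followed by a cut-height search that
   maximizes the Calinski–Harabasz (CH) index.
4. **Stability.** Each subject's own clustering is compared to the group
   partition with a Jaccard-based similarity index; hemisphere and condition
   effects on these indices are tested with Greenhouse–Geisser-corrected
   repeated-measures ANOVA and Bonferroni post-hoc comparisons.
5. **Validation.** A synthetic cohort generator with known ground truth
   exercises every stage end to end.

# The model and its pieces

## Cut-height optimization

With cluster centers $C_k$ ($k = 1 \dots K$) and grand center $C$, the CH
index is

$$\mathrm{CH}(K) \;=\; \frac{B(K)/(K-1)}{W(K)/(N-K)},
\qquad W(K) = \sum_k \sum_{Z_j \in \text{cluster } k} \lVert Z_j - C_k\rVert^2 .$$

Two forms of the between-cluster term are implemented:

* `chVariant = "weighted"` (default): the classical
  $B(K) = \sum_k n_k \lVert C_k - C\rVert^2$;
* `chVariant = "printed"`: the unweighted $\sum_k \lVert C_k - C\rVert^2$,
  as the formula is sometimes written with the size factor elided.

The default matters. The unweighted form is structurally biased toward fine
partitions: for centered noise, $\lVert C_k - C\rVert^2$ scales like
$p/n_k$, so splitting clusters *increases* the numerator roughly like
$\sum_k 1/n_k$ while $W$ can only fall. In simulation this drives the cut
search to partitions with dozens of near-singleton clusters whenever the
data are noisy, which no empirical parcellation study reports. The
size-weighted form is immune (a split of a homogeneous cluster leaves
$\sum_k n_k\lVert C_k - C\rVert^2$ almost unchanged while $K-1$ grows) and
recovers planted cluster counts across the whole SNR range; it is also what
standard library implementations of the index compute. The unweighted form
stays available for comparability and is pinned by exact worked-example
tests.

The search itself: start at the root merge height $h_0$, repeatedly shrink
multiplicatively, $h \leftarrow (1 - s)\,h$ with $s = 0.01$, record
$(h, K, \mathrm{CH})$ at every visited height with $2 \le K \le N-1$, and
stop once $h$ drops below a baseline — by default the mean merge height of
the dendrogram. The reported cut maximizes CH, with ties broken toward the
larger height (fewer clusters, parsimony). Cuts are inclusive (merges with
height $\le h$ are applied), so tied merge heights collapse together.
Degenerate cases: if every merge height is zero (all rows identical — e.g.
z-scored constant series) there is no partition with $2 \le K \le N-1$ and
the search raises a classed `unstableSolutionError`; callers record the
subject as excluded. $W = 0$ with $K < N$ (perfect separation) scores
$+\infty$ and is preferred outright. A zero baseline would never terminate a
multiplicative shrink, so the smallest positive merge height acts as the
effective floor — below it no new partition can appear.

Notable consequence of the stop rule: genuinely structureless (pure noise)
data still yields a *formally* stable solution, because continuous data
gives positive, distinct merge heights and hence some valid $K$. Exclusions
therefore arise only from degenerate inputs, not from low SNR.

## Partition similarity

For partitions $\mathcal{C} = \{C_1 \dots C_m\}$ and
$\mathcal{D} = \{D_1 \dots D_n\}$ of the same voxel set, the similarity
matrix holds all blockwise Jaccard coefficients
$S_{ij} = |C_i \cap D_j| / |C_i \cup D_j|$, and the similarity index is

$$\mathrm{Sim}(\mathcal{C},\mathcal{D}) = \frac{\sum_{i \le m,\, j \le n} S_{ij}}{\max(m, n)} .$$

It lies in $[0, 1]$, is symmetric, ignores block order and labeling, and
equals 1 exactly for identical partitions. The sum runs over *all* $m \times
n$ pairs, not a matching, so unrelated partitions generally score above
zero — the index measures convergence toward identity, not chance-corrected
agreement (ARI/NMI would be the chance-corrected alternatives; they are not
pipeline outputs). Because of the $\max(m,n)$ denominator the index also
penalizes cluster-count mismatch, which makes "stability" partly a function
of whether two runs agree on $K$ — visible in simulations as a plateau when
both group and individuals lock onto the same coarse solution.

## Stability statistics

The similarity table (subject × condition × hemisphere) feeds two separate
one-way within-subject ANOVAs — hemisphere collapsed over conditions, and
condition collapsed over hemispheres, each by per-subject means — rather
than one two-way model; this matches the degrees of freedom convention of
reporting main effects separately, and keeps listwise deletion per analysis.
Greenhouse–Geisser $\hat\varepsilon$ is the Box estimate from the
double-centred sample covariance of the level scores, clamped to
$[1/(k-1), 1]$; it is exactly 1 for two levels, where the ANOVA collapses to
the squared paired $t$ test. Partial $\eta^2 = SS_\text{effect} /
(SS_\text{effect} + SS_\text{error})$, which equals
$F \cdot df_1 / (F \cdot df_1 + df_2)$ — an identity enforced by the class
validity check. Mauchly's test is not implemented (only the correction's
consequence is of interest); Huynh–Feldt is not offered.

Degenerate tables are defined conservatively: if the effect sum of squares
is zero, $F = 0$ (even when the residual also vanishes), and zero residual
level variance counts as sphericity trivially satisfied
($\hat\varepsilon = 1$).

# The synthetic cohort generator

Real 7T data of this kind are not publicly deposited, so the package ships a
generator that provides a known truth surface. In-mask voxel $v$ with
ground-truth label $k$ receives

$$x_v(t) = g_s \cdot \mathrm{snr} \cdot s_k(t) + \varepsilon_v(t),$$

with $s_k$ a standard-normal series fixed per cohort (shared across
subjects), $\varepsilon_v$ unit-variance white noise, and $g_s$ a
per-subject gain $1 + \mathcal{N}(0, 0.2^2)$ truncated at 0.1 that
multiplies signal only — the inter-subject amplitude variation that the
per-voxel z-scoring step must neutralize. The ROI is an ellipsoid inscribed
in its grid box, split into $K_\text{true}$ equal-width slabs along a chosen
anatomical axis (longitudinal, dorsoventral, or mediolateral); two such
boxes side by side form the left and right "hemispheres" of one volume. The
probabilistic atlas is by default degenerate (all subjects share the mask,
so it is exactly 1 in-mask); an `atlasJitter` option erodes each subject's
mask boundary independently to exercise sub-unit probabilities.

Deliberately absent: hemodynamic response, temporal autocorrelation (an
AR(1) flag exists, default off), motion, physiological noise, spatial
smoothness. The clustering operates on arbitrary time courses, so the
simplest model with a controllable separability knob is the right truth
surface; what passing tests show is that the *pipeline* recovers planted
structure and ranks data quality correctly — not that real hippocampal
parcellations are correct.

## Chosen constants

| parameter | default | why |
|---|---|---|
| `nTimepoints` | 100 | typical resting-state run length at TR = 3 s |
| `snr` | 0.35 | calibrated so mean individual-vs-group similarity at the reference geometry (N = 324, M = 20, T = 100) lands in the low 0.6s, the range group-parcellation studies report; at snr 1 the index saturates near 1.0 |
| `subjectGainSd` | 0.2 | 20 % amplitude spread across subjects |
| `hemiSnr` | right = 0.7 × left | the left/right stability asymmetry knob |
| `atlasThreshold` | 0.75 | the conservative "present in ≥ 28 of 37 reference subjects" convention |
| `shrink` | 0.01 | 1 % multiplicative height reduction per search step |
| reference ROI | 11 × 8 × 7 box, 324 voxels | a realistic hippocampal ROI size at ~1 mm resolution, used consistently for the simulation studies in the test suite |

The measured SNR-to-similarity curve behind the calibration (M = 20,
N = 324): snr 0.2 → 0.30, 0.3 → 0.58, 0.4 → 0.78, 0.5 → 0.86, 1.0 → 0.98.

# Numerical and design notes

* **Canonical voxel order** is ascending slice, row, column — R's
  column-major order — and every row-indexed object (series, labels,
  partitions) indexes against it; voxel indices are 1-based.
* **z-scoring before concatenation** (sample SD, $n-1$): without it,
  Euclidean distance on concatenated raw series is dominated by
  inter-subject amplitude. Constant series map to zero rows with a warning.
  A `standardize = "none"` escape hatch exists.
* **Distances/linkage** are `stats::dist` and `stats::hclust("average")`;
  UPGMA is inversion-free, so merge heights are non-decreasing and cutting
  is well-defined. Cluster labels are renumbered by each cluster's first
  member in canonical order, making outputs deterministic.
* **Unequal series lengths** across subjects are permitted; distances sum
  over columns, so the concatenation order cannot affect them (tested).
* **Atlas threshold comparison is inclusive** (≥): at 0.75 with 37 reference
  subjects the minimum supporting count is 28.
* **Determinism**: all generator seeds derive from one base seed; cohorts
  are written as uncompressed NIfTI-1, and identical configurations
  reproduce byte-identical files (tested by hash).
* **Include-all comparison**: the group solution compared against each
  subject includes that subject (no leave-one-out); with small M this
  inflates similarity slightly, and is the literal reading of the
  group-vs-individual design.
* **Per-condition cohorts**: clustering is run per condition over the
  subjects with usable data for that condition; no pooling across
  conditions.

# Problem sizes in the test suite

The suite validates at sizes a laptop handles in minutes: exact worked
examples at $N \le 5$; oracle equivalence on matrices up to $40 \times 8$;
recovery, asymmetry and monotonicity studies at the reference geometry
(324 voxels, T = 100, M = 3–20, up to 100 replicates). The asymmetry study
(100 replicates of an M = 20 two-hemisphere cohort) and the SNR-monotonicity
study (five SNR levels × 20 replicates) are the long poles at a few minutes
each.

# Known limitations

* The similarity index is not chance-corrected and penalizes cluster-count
  mismatch; interpreting it as "stability" inherits both properties.
* The formal stability criterion (existence of a valid cut) is weak:
  pure-noise data passes it. Exclusions only catch degenerate inputs.
* The printed (unweighted) CH variant over-fragments noisy data and should
  be used only to reproduce that specific formula's output.
* No spatial constraints: clusters are defined purely by time-course
  similarity and need not be spatially contiguous (on synthetic slab truth
  they come out contiguous because the signals are).
* The generator's white-noise, shared-signal model contains no realistic
  fMRI confounds; conclusions about robustness to such confounds cannot be
  drawn from these simulations.
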