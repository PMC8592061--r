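# hippcluster

Group-level functional parcellation of a region of interest — designed for
the human hippocampus — from preprocessed, co-registered fMRI. The package
is aimed at neuroimaging researchers who want a tested, reproducible
implementation of the classic voxel-time-series clustering workflow:

1. **ROI definition** — threshold a probabilistic atlas (default 0.75,
   inclusive: a voxel must be present in at least 28 of 37 reference
   subjects of a 37-subject atlas), left and right hemisphere separately.
2. **Substrate** — extract in-mask voxel time series per subject, z-score
   each voxel, and concatenate subjects into the matrix
   `Z ∈ R^(N voxels × p timepoints)`.
3. **Clustering** — average-linkage (UPGMA) agglomerative clustering of the
   rows of `Z` under Euclidean distance. The dendrogram cut height is chosen
   by an iterative search: starting at the root height, shrink by 1% per
   step, score every visited partition with the Calinski–Harabasz index

   `CH(K) = [B(K)/(K−1)] / [W(K)/(N−K)]`,

   with `B(K) = Σ_k n_k ‖C_k − C‖²` (between-cluster) and
   `W(K) = Σ_k Σ_{j∈k} ‖Z_j − C_k‖²` (within-cluster), stop at the mean
   merge height, and keep the cut with maximal CH (ties → fewer clusters).
   An unweighted variant of `B(K)` is available as
   `chVariant = "printed"`; see the methods vignette for why the weighted
   form is the default.
4. **Stability** — compare each subject's own clustering to the group
   partition with the Torres similarity index
   `Sim(C, D) = Σ_{i≤m, j≤n} Jaccard(C_i, D_j) / max(m, n)` (1 iff
   identical), then test hemisphere and condition effects on the similarity
   indices with Greenhouse–Geisser-corrected repeated-measures ANOVA,
   Bonferroni post-hoc pairwise comparisons, and partial η² effect sizes.
5. **Synthetic cohorts** — a generator writes NIfTI cohorts with known
   ground-truth parcellations (shared cluster signals + white noise, a
   per-subject gain, and a right-hemisphere SNR multiplier as a stability
   asymmetry knob), so every stage can be validated against planted truth.

Inputs are NIfTI-1 volumes (4D data, 3D probabilistic atlas); outputs are
integer NIfTI label maps, CSV similarity/descriptive/ANOVA tables, and JSON
reports.

## Worked example

Simulate a 6-subject resting-style cohort with 3 planted compartments per
hemisphere and run the full pipeline:

```r
library(hippcluster)

cfg <- SimulationConfig(nSubjects = 6, baseSeed = 11, hemiDims = c(11L, 8L, 7L),
  conditions = list(list(name = "rest", axis = "dorsoventral", KTrue = 3L)))
dir <- file.path(tempdir(), "demo")
simulateCohort(cfg, dir)
res <- runPipeline(file.path(dir, "manifest.json"), outDir = file.path(dir, "out"))

res$group$rest$left$solution
#> ClusterSolution: K = 3 clusters at cut height 34.01 (CH = 13.35; 9 heights visited)
res$group$rest$right$solution
#> ClusterSolution: K = 3 clusters at cut height 34.16 (CH = 7.293; 6 heights visited)

head(res$similarity)
#>   subject_id condition hemisphere similarity   status reason
#> 1     sub-01      rest       left  0.8829177 included
#> 2     sub-02      rest       left  0.6145602 included
#> 3     sub-03      rest       left  0.4257824 included
#> 4     sub-04      rest       left  0.3738276 included
#> 5     sub-05      rest       left  0.6548918 included
#> 6     sub-06      rest       left  0.5669693 included

aggregate(similarity ~ hemisphere, res$similarity, mean)
#>   hemisphere similarity
#> 1       left  0.5864915
#> 2      right  0.4756796

res$stats$results$hemisphere
#> Within-subject ANOVA [hemisphere]: F(1.000, 5.000) = 2.433, p_GG = 0.1796 (eps = 1.000), partial eta^2 = 0.327, n = 6
```

Both hemispheres recover the planted `K = 3`. Per-subject similarity
indices sit in the 0.4–0.9 range at the default SNR; the left hemisphere
(full SNR) is more stable on average than the right (0.7 × SNR), here 0.59
vs 0.48. With only 6 subjects the hemisphere ANOVA is not significant —
the effect needs cohort sizes closer to the 20-subject reference design
(see the asymmetry study in the test suite). Label maps
(`labels_cond-rest_hemi-left.nii`, …), similarity and descriptive CSVs, and
ANOVA reports are written under `out/`.

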