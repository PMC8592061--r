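# Orchestration: group clustering per condition x hemisphere, the
# individual-vs-group similarity table, and the stability ANOVAs, with
# standard-format outputs (integer NIfTI label maps, CSV tables, JSON
# reports). All stages are deterministic given the inputs; the only random
# stage is cohort simulation.

anovaAsRow <- function(a) {
  data.frame(effect = a@effect, F = a@F, df1 = a@df1, df2 = a@df2,
             epsilon = a@epsilon, df1GG = a@epsilon * a@df1,
             df2GG = a@epsilon * a@df2, pUncorrected = a@pUncorrected,
             pGG = a@pGG, partialEtaSq = a@partialEtaSq,
             nComplete = a@nComplete)
}

#' Group-level clustering per condition and hemisphere
#'
#' For every condition x hemisphere: thresholds the hemisphere atlas, extracts
#' and standardizes each subject's ROI series, concatenates them into the
#' group matrix, clusters with average linkage and the CH cut search, and (if
#' `outDir` is given) writes the cluster label volume plus a JSON report
#' (K, cut height, CH value, search trace, included subjects). An unstable
#' group solution is recorded in the report and no label volume is emitted.
#'
#' @param dataFiles nested list: `dataFiles[[condition]][[subjectId]]` is the
#'   path to that subject's 4D NIfTI for the condition.
#' @param atlasFiles named list: `atlasFiles[[hemisphere]]` is the path to the
#'   probabilistic atlas NIfTI for that hemisphere.
#' @param outDir optional output directory for label volumes and reports.
#' @param atlasThreshold atlas inclusion threshold (default 0.75).
#' @param standardize,shrink,baseline,chVariant clustering parameters; see
#'   [standardizeSeries()] and [optimizeCut()].
#' @return nested list `res[[condition]][[hemisphere]]` with elements `roi`,
#'   `series` (list of raw [SubjectSeries-class]), `solution` (a
#'   [ClusterSolution-class] or NULL if unstable) and `status`; clustering
#'   parameters are attached as the attribute `params`.
#' @export
runGroup <- function(dataFiles, atlasFiles, outDir = NULL,
                     atlasThreshold = 0.75, standardize = "zscore",
                     shrink = 0.01, baseline = "mean",
                     chVariant = "weighted") {
  if (!is.null(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  for (cond in names(dataFiles)) {
    res[[cond]] <- list()
    for (hemi in names(atlasFiles)) {
      roi <- thresholdAtlas(atlasFiles[[hemi]], threshold = atlasThreshold)
      series <- lapply(names(dataFiles[[cond]]), function(sid)
        extractTimeseries(dataFiles[[cond]][[sid]], roi,
                          subjectId = sid, condition = cond))
      std <- lapply(series, standardizeSeries, method = standardize)
      Z <- concatenateSubjects(std)
      sol <- tryCatch(
        optimizeCut(buildDendrogram(pairwiseEuclidean(Z)), Z,
                    shrink = shrink, baseline = baseline,
                    chVariant = chVariant),
        unstableSolutionError = function(e) NULL)
      status <- if (is.null(sol)) "unstable" else "ok"
      if (!is.null(outDir)) {
        report <- list(condition = cond, hemisphere = hemi, status = status,
                       nVoxels = nVoxels(roi),
                       includedSubjects = includedSubjects(Z),
                       atlasThreshold = atlasThreshold,
                       standardize = standardize, shrink = shrink,
                       baseline = baseline, chVariant = chVariant)
        if (status == "ok") {
          report$K <- clusterCount(sol)
          report$cutHeight <- cutHeight(sol)
          report$chValue <- chValue(sol)
          report$trace <- searchTrace(sol)
          writeLabelVolume(
            clusterLabels(sol), voxelList(roi), geometry(roi),
            file.path(outDir, sprintf("labels_cond-%s_hemi-%s.nii",
                                      cond, hemi)))
        }
        jsonlite::write_json(
          report,
          file.path(outDir, sprintf("group_cond-%s_hemi-%s.json", cond, hemi)),
          auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "columns")
      }
      res[[cond]][[hemi]] <- list(roi = roi, series = series,
                                  solution = sol, status = status)
    }
  }
  attr(res, "params") <- list(atlasThreshold = atlasThreshold,
                              standardize = standardize, shrink = shrink,
                              baseline = baseline, chVariant = chVariant)
  res
}

#' Individual-vs-group similarity table
#'
#' Computes the similarity index of every subject's own clustering against
#' the group solution for each condition x hemisphere. Subjects whose
#' individual clustering is unstable -- and every subject of a cell whose
#' group solution is unstable -- are recorded as excluded with a reason code
#' and omitted from downstream statistics.
#'
#' @param groupResults output of [runGroup()].
#' @param outDir optional directory for `similarity.csv` and
#'   `descriptives.csv`.
#' @return the similarity table (long-format data.frame with columns
#'   subject_id, condition, hemisphere, similarity, status, reason).
#' @export
runSimilarity <- function(groupResults, outDir = NULL) {
  p <- attr(groupResults, "params")
  rows <- list()
  for (cond in names(groupResults)) {
    for (hemi in names(groupResults[[cond]])) {
      cell <- groupResults[[cond]][[hemi]]
      for (s in cell$series) {
        if (cell$status != "ok") {
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = s@subjectId, condition = cond, hemisphere = hemi,
            similarity = NA_real_, status = "excluded",
            reason = "unstable_group_solution")
          next
        }
        sim <- tryCatch(
          individualVsGroup(s, cell$solution, standardize = p$standardize,
                            shrink = p$shrink, baseline = p$baseline,
                            chVariant = p$chVariant),
          unstableSolutionError = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s@subjectId, condition = cond, hemisphere = hemi,
          similarity = sim,
          status = if (is.na(sim)) "excluded" else "included",
          reason = if (is.na(sim)) "unstable_individual_solution" else "")
      }
    }
  }
  table <- do.call(rbind, rows)
  assertSimilarityTable(table)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(outDir, "similarity.csv"),
                     row.names = FALSE)
    if (any(table$status == "included")) {
      desc <- descriptiveSummary(table)
      desc$validNListwise <- attr(desc, "validNListwise")
      utils::write.csv(desc, file.path(outDir, "descriptives.csv"),
                       row.names = FALSE)
    }
  }
  table
}

#' Stability ANOVAs and post-hoc comparisons
#'
#' Runs one within-subject ANOVA per requested factor (with Greenhouse-Geisser
#' correction) and the Bonferroni-corrected pairwise comparisons, writing CSV
#' and JSON reports when `outDir` is given.
#'
#' @param table a similarity table (or a path to `similarity.csv`).
#' @param factors factors to analyse; each needs at least 2 levels.
#' @param outDir optional output directory.
#' @return list with `anova` (data.frame, one row per factor), `pairwise`
#'   (named list of data.frames) and `results` (named list of
#'   [AnovaResult-class] objects).
#' @export
runStats <- function(table, factors = c("hemisphere", "condition"),
                     outDir = NULL) {
  if (is.character(table))
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  results <- list(); pairwise <- list()
  for (f in factors) {
    results[[f]] <- rmAnova(table, f)
    pairwise[[f]] <- bonferroniPairwise(table, f)
  }
  anova <- do.call(rbind, lapply(results, anovaAsRow))
  rownames(anova) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(anova, file.path(outDir, "anova.csv"), row.names = FALSE)
    for (f in factors)
      utils::write.csv(pairwise[[f]],
                       file.path(outDir, sprintf("pairwise_%s.csv", f)),
                       row.names = FALSE)
    jsonlite::write_json(list(anova = anova, pairwise = pairwise),
                         file.path(outDir, "stats.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(anova = anova, pairwise = pairwise, results = results)
}

#' Run the full pipeline from a cohort manifest
#'
#' Convenience wrapper: reads a manifest written by [simulateCohort()] (or one
#' of the same shape pointing at real preprocessed data), then runs
#' [runGroup()], [runSimilarity()] and -- for every factor with at least two
#' levels -- [runStats()].
#'
#' @param manifest manifest list or path to `manifest.json`.
#' @param dataDir directory the manifest's relative paths resolve against;
#'   defaults to the manifest file's directory.
#' @param outDir optional output directory passed to the stages.
#' @param ... clustering parameters forwarded to [runGroup()].
#' @return list with elements `group`, `similarity` and `stats` (NULL when no
#'   factor has two levels).
#' @export
runPipeline <- function(manifest, dataDir = NULL, outDir = NULL, ...) {
  if (is.character(manifest)) {
    if (is.null(dataDir)) dataDir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  stopifnot(!is.null(dataDir))
  rel <- function(f) file.path(dataDir, f)
  dataFiles <- lapply(manifest$files$data, function(bySubj) lapply(bySubj, rel))
  atlasFiles <- lapply(manifest$files$atlas, rel)
  group <- runGroup(dataFiles, atlasFiles, outDir = outDir, ...)
  sim <- runSimilarity(group, outDir = outDir)
  factors <- c("hemisphere", "condition")
  factors <- factors[vapply(factors, function(f)
    length(unique(sim[[f]][sim$status == "included"])) >= 2L, TRUE)]
  stats <- if (length(factors)) runStats(sim, factors, outDir = outDir)
    else NULL
  list(group = group, similarity = sim, stats = stats)
}
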