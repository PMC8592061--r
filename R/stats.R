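# Stability statistics over similarity indices. The similarity table is a
# long-format data.frame with columns subject_id, condition, hemisphere,
# similarity, status ("included"/"excluded"); subjects whose clustering did
# not stabilize carry status "excluded" and are dropped from every analysis.

assertSimilarityTable <- function(table) {
  need <- c("subject_id", "condition", "hemisphere", "similarity", "status")
  if (!all(need %in% names(table)))
    stop("similarity table must have columns ",
         paste(need, collapse = ", "))
  key <- interaction(table$subject_id, table$condition, table$hemisphere)
  if (anyDuplicated(key))
    stop("at most one record per (subject, condition, hemisphere)")
  inc <- table$status == "included"
  s <- table$similarity[inc]
  if (any(!is.na(s) & (s < 0 | s > 1)))
    stop("similarities must lie in [0, 1]")
  invisible(table)
}

.includedRows <- function(table) {
  assertSimilarityTable(table)
  table[table$status == "included" & !is.na(table$similarity), , drop = FALSE]
}

# subjects with a value in every (condition x hemisphere) cell present in the
# included data
.listwiseSubjects <- function(inc) {
  cells <- interaction(inc$condition, inc$hemisphere, drop = TRUE)
  tab <- table(inc$subject_id, cells)
  rownames(tab)[apply(tab > 0, 1, all)]
}

#' Descriptive summary of similarity indices
#'
#' Per (condition, hemisphere) cell: n, minimum, maximum, mean and sample SD
#' of the included similarity indices, plus the number of listwise-complete
#' subjects across all cells (attribute `validNListwise` and one summary row).
#'
#' @param table a similarity table (long-format data.frame).
#' @return data.frame of cell statistics; single-value cells report `NA` SD.
#' @export
descriptiveSummary <- function(table) {
  inc <- .includedRows(table)
  stopifnot(nrow(inc) > 0L)
  sp <- split(inc, list(inc$condition, inc$hemisphere), drop = TRUE)
  rows <- lapply(sp, function(d) data.frame(
    condition = d$condition[1], hemisphere = d$hemisphere[1],
    n = nrow(d), minimum = min(d$similarity), maximum = max(d$similarity),
    mean = mean(d$similarity),
    sd = if (nrow(d) > 1) stats::sd(d$similarity) else NA_real_))
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$hemisphere), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validNListwise") <- length(.listwiseSubjects(inc))
  out
}

# Collapse to a subjects x levels matrix of the chosen factor, averaging over
# the other factor's available cells, then apply listwise deletion.
.levelMatrix <- function(table, factor) {
  inc <- .includedRows(table)
  fac <- match.arg(factor, c("hemisphere", "condition"))
  lv <- inc[[fac]]
  levs <- sort(unique(lv))
  if (length(levs) < 2L)
    hippStop("insufficientDataError",
             sprintf("factor '%s' needs at least 2 levels, found %d",
                     fac, length(levs)))
  agg <- stats::aggregate(similarity ~ subject_id + lv, data =
                            data.frame(subject_id = inc$subject_id, lv = lv,
                                       similarity = inc$similarity),
                          FUN = mean)
  Y <- matrix(NA_real_, nrow = length(unique(agg$subject_id)),
              ncol = length(levs),
              dimnames = list(sort(unique(agg$subject_id)), levs))
  Y[cbind(agg$subject_id, as.character(agg$lv))] <- agg$similarity
  Y[stats::complete.cases(Y), , drop = FALSE]
}

# Greenhouse-Geisser epsilon from the double-centred sample covariance of the
# level scores (Box's estimate); exactly 1 for k = 2.
ggEpsilon <- function(Y) {
  k <- ncol(Y)
  S <- stats::cov(Y)
  Sd <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  denom <- (k - 1) * sum(Sd^2)
  # zero residual level variance: sphericity is vacuously satisfied
  if (denom == 0) return(1)
  eps <- sum(diag(Sd))^2 / denom
  min(1, max(1 / (k - 1), eps))
}

#' One-way within-subject (repeated-measures) ANOVA
#'
#' Tests a single within-subject factor (hemisphere or condition) on the
#' similarity indices, collapsing over the other factor by per-subject means
#' and using listwise deletion. Reports the uncorrected F with (k - 1,
#' (n - 1)(k - 1)) degrees of freedom, the Greenhouse-Geisser epsilon and
#' corrected p value, and partial eta squared
#' (SS_effect / (SS_effect + SS_error)).
#'
#' @param table a similarity table.
#' @param factor "hemisphere" or "condition".
#' @return an [AnovaResult-class].
#' @export
rmAnova <- function(table, factor = c("hemisphere", "condition")) {
  factor <- match.arg(factor)
  Y <- .levelMatrix(table, factor)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L)
    hippStop("insufficientDataError",
             sprintf("need >= 2 listwise-complete subjects, found %d", n))
  grand <- mean(Y)
  colm <- colMeans(Y); rowm <- rowMeans(Y)
  ssEffect <- n * sum((colm - grand)^2)
  resid <- Y - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  ssError <- sum(resid^2)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  # no effect variation at all: F is 0 by convention (avoids 0/0 when the
  # residual variation also vanishes)
  Fv <- if (ssEffect == 0) 0 else (ssEffect / df1) / (ssError / df2)
  eps <- ggEpsilon(Y)
  new("AnovaResult", effect = factor, F = Fv, df1 = df1, df2 = df2,
      epsilon = eps,
      pUncorrected = stats::pf(Fv, df1, df2, lower.tail = FALSE),
      pGG = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
      partialEtaSq = if (ssEffect == 0) 0 else
        ssEffect / (ssEffect + ssError),
      nComplete = as.integer(n))
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Paired t-tests for every pair of factor levels on the listwise-complete
#' subjects, with the Bonferroni adjustment
#' `p_adj = min(1, p_raw * number_of_pairs)`.
#'
#' @param table a similarity table.
#' @param factor "hemisphere" or "condition".
#' @return data.frame with one row per level pair: `level1`, `level2`,
#'   `meanDiff` (level1 - level2), `n`, `t`, `pRaw`, `pAdjusted`. Pairs with
#'   fewer than two complete observations report `NA` statistics.
#' @export
bonferroniPairwise <- function(table, factor = c("hemisphere", "condition")) {
  factor <- match.arg(factor)
  Y <- .levelMatrix(table, factor)
  levs <- colnames(Y)
  pairs <- utils::combn(length(levs), 2)
  npairs <- ncol(pairs)
  rows <- lapply(seq_len(npairs), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    d <- Y[, i] - Y[, j]
    if (length(d) < 2L || stats::sd(d) == 0) {
      return(data.frame(level1 = levs[i], level2 = levs[j],
                        meanDiff = mean(d), n = length(d),
                        t = NA_real_, pRaw = NA_real_,
                        pAdjusted = NA_real_))
    }
    tt <- stats::t.test(Y[, i], Y[, j], paired = TRUE)
    data.frame(level1 = levs[i], level2 = levs[j],
               meanDiff = unname(tt$estimate), n = length(d),
               t = unname(tt$statistic), pRaw = tt$p.value,
               pAdjusted = min(1, tt$p.value * npairs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
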