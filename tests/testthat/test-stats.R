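simTable <- function(df) {
  df$status <- if (is.null(df$status)) "included" else df$status
  df
}

test_that("descriptive summary matches hand computation", {
  tab <- data.frame(
    subject_id = c("a", "b", "a", "b", "c"),
    condition = c("t1", "t1", "t1", "t1", "t2"),
    hemisphere = c("left", "left", "right", "right", "left"),
    similarity = c(0.5, 0.7, 0.6, 0.8, 0.4),
    status = c("included", "included", "included", "included", "included"))
  d <- descriptiveSummary(tab)
  cell <- d[d$condition == "t1" & d$hemisphere == "left", ]
  expect_equal(cell$n, 2L)
  expect_equal(cell$mean, 0.6)
  expect_equal(cell$sd, sqrt(((0.5 - 0.6)^2 + (0.7 - 0.6)^2) / 1))
  expect_equal(cell$minimum, 0.5)
  expect_equal(cell$maximum, 0.7)

  # single-value cell: SD missing
  expect_true(is.na(d[d$condition == "t2", "sd"]))

  # listwise-complete subjects across all three cells: none
  expect_equal(attr(d, "validNListwise"), 0L)

  # excluded records do not contribute
  tab2 <- tab
  tab2$status[2] <- "excluded"
  d2 <- descriptiveSummary(tab2)
  expect_equal(d2[d2$condition == "t1" & d2$hemisphere == "left", "n"], 1L)
})

test_that("two-level RM-ANOVA equals the squared paired t test", {
  set.seed(30)
  n <- 12
  tab <- data.frame(
    subject_id = rep(sprintf("s%02d", 1:n), 2),
    condition = "rest",
    hemisphere = rep(c("left", "right"), each = n),
    similarity = c(runif(n, 0.5, 0.9), runif(n, 0.3, 0.8)),
    status = "included")
  a <- rmAnova(tab, "hemisphere")
  l <- tab$similarity[tab$hemisphere == "left"]
  r <- tab$similarity[tab$hemisphere == "right"]
  tt <- t.test(l, r, paired = TRUE)
  expect_lt(abs(a@F - tt$statistic^2), 1e-9)
  expect_equal(a@epsilon, 1)
  expect_lt(abs(a@pGG - tt$p.value), 1e-9)
})

test_that("ANOVA sums of squares match the explicit-loop oracle", {
  # fixed 4 subjects x 3 levels fixture
  Y <- matrix(c(0.61, 0.55, 0.52,
                0.70, 0.62, 0.60,
                0.55, 0.50, 0.49,
                0.66, 0.58, 0.57), 4, 3, byrow = TRUE)
  tab <- data.frame(
    subject_id = rep(sprintf("s%d", 1:4), each = 3),
    condition = rep(c("c1", "c2", "c3"), 4),
    hemisphere = "left",
    similarity = as.vector(t(Y)),
    status = "included")
  a <- rmAnova(tab, "condition")
  o <- rmAnovaOracle(Y)
  expect_lt(abs(a@F - o$F), 1e-9)
  expect_lt(abs(a@partialEtaSq - o$ssEffect / (o$ssEffect + o$ssError)), 1e-9)
  expect_equal(a@df1, 2)
  expect_equal(a@df2, 6)
  # partial eta^2 identity from F and the dfs
  expect_lt(abs(a@partialEtaSq -
                  (a@F * a@df1) / (a@F * a@df1 + a@df2)), 1e-9)
  # epsilon bounds
  expect_gte(a@epsilon, 1 / 2)
  expect_lte(a@epsilon, 1)
})

test_that("degenerate and shifted tables behave as the model predicts", {
  # all levels identical per subject: F = 0
  tab <- data.frame(
    subject_id = rep(c("a", "b", "c"), each = 2),
    condition = "rest",
    hemisphere = rep(c("left", "right"), 3),
    similarity = rep(c(0.5, 0.6, 0.7), each = 2),
    status = "included")
  expect_equal(rmAnova(tab, "hemisphere")@F, 0)

  # subject-constant shifts leave F unchanged
  set.seed(31)
  base <- data.frame(
    subject_id = rep(sprintf("s%d", 1:6), each = 3),
    condition = rep(c("c1", "c2", "c3"), 6),
    hemisphere = "left",
    similarity = runif(18, 0.3, 0.7),
    status = "included")
  f0 <- rmAnova(base, "condition")@F
  shifted <- base
  shifted$similarity <- shifted$similarity +
    rep(runif(6, -0.1, 0.1), each = 3)
  expect_equal(rmAnova(shifted, "condition")@F, f0, tolerance = 1e-9)

  # fewer than two complete subjects
  expect_error(rmAnova(base[1:3, ], "condition"),
               class = "insufficientDataError")
  # single factor level
  expect_error(rmAnova(base, "hemisphere"),
               class = "insufficientDataError")
})

test_that("listwise deletion drops incomplete subjects", {
  set.seed(32)
  tab <- data.frame(
    subject_id = rep(sprintf("s%d", 1:5), each = 2),
    condition = "rest",
    hemisphere = rep(c("left", "right"), 5),
    similarity = runif(10, 0.4, 0.8),
    status = "included")
  tab$status[tab$subject_id == "s3" & tab$hemisphere == "right"] <- "excluded"
  a <- rmAnova(tab, "hemisphere")
  expect_equal(a@nComplete, 4L)
})

test_that("Bonferroni adjustment multiplies by the number of pairs", {
  set.seed(33)
  k <- 4
  tab <- data.frame(
    subject_id = rep(sprintf("s%d", 1:8), each = k),
    condition = rep(sprintf("c%d", 1:k), 8),
    hemisphere = "left",
    similarity = runif(8 * k, 0.3, 0.9),
    status = "included")
  pw <- bonferroniPairwise(tab, "condition")
  expect_equal(nrow(pw), choose(k, 2))
  expect_equal(pw$pAdjusted, pmin(1, pw$pRaw * choose(k, 2)))
  # raw p values agree with a direct paired t test
  Y <- matrix(tab$similarity, ncol = k, byrow = TRUE)
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(pw$pRaw[pw$level1 == "c1" & pw$level2 == "c2"], tt$p.value)

  # two levels: a single pair, adjusted = raw
  pw2 <- bonferroniPairwise(
    data.frame(subject_id = rep(c("a", "b", "c"), each = 2),
               condition = "rest",
               hemisphere = rep(c("left", "right"), 3),
               similarity = runif(6), status = "included"), "hemisphere")
  expect_equal(nrow(pw2), 1L)
  expect_equal(pw2$pAdjusted, pw2$pRaw)
})

test_that("hemisphere asymmetry in snr lowers right-hemisphere stability", {
  # one seeded replicate of the asymmetric-cohort design (the replicated
  # direction test lives in the acceptance suite)
  gt <- makeGroundTruth(c(11, 8, 7), 3, "longitudinal")
  rows <- list()
  for (h in c("left", "right")) {
    snr <- if (h == "left") 0.35 else 0.7 * 0.35  # generator defaults
    seed <- if (h == "left") 90 else 990  # independent signals and noise
    ser <- makeSeriesCohort(gt, M = 20, nT = 100, snr = snr, seed = seed)
    sol <- groupSolve(ser)
    for (s in ser)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s@subjectId, condition = "rest", hemisphere = h,
        similarity = individualVsGroup(s, sol), status = "included")
  }
  tab <- do.call(rbind, rows)
  a <- rmAnova(tab, "hemisphere")
  ml <- mean(tab$similarity[tab$hemisphere == "left"])
  mr <- mean(tab$similarity[tab$hemisphere == "right"])
  expect_gt(ml, mr)
  expect_lt(a@pGG, 0.05)
})
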