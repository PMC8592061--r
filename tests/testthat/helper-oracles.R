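# Independent oracles: deliberately naive explicit-loop implementations used
# only to validate the package's vectorized code.

# Calinski-Harabasz from first principles: explicit loops over clusters and
# rows. variant "printed" uses the unweighted between term.
chOracle <- function(Z, labels, variant = "printed") {
  n <- nrow(Z)
  K <- length(unique(labels))
  grand <- colMeans(Z)
  B <- 0; W <- 0
  for (k in sort(unique(labels))) {
    rows <- which(labels == k)
    ck <- colMeans(Z[rows, , drop = FALSE])
    w <- if (variant == "printed") 1 else length(rows)
    B <- B + w * sum((ck - grand)^2)
    for (r in rows) W <- W + sum((Z[r, ] - ck)^2)
  }
  list(B = B, W = W,
       CH = if (W == 0) Inf else (B / (K - 1)) / (W / (n - K)))
}

# Torres similarity with explicit set loops over the two block lists.
simOracle <- function(blocksC, blocksD) {
  total <- 0
  for (a in blocksC) for (b in blocksD) {
    p <- length(intersect(a, b))
    q <- length(union(a, b))
    total <- total + p / q
  }
  total / max(length(blocksC), length(blocksD))
}

# One-way within-subject ANOVA sums of squares with explicit loops over the
# subjects x levels table.
rmAnovaOracle <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ssEffect <- 0
  for (j in seq_len(k)) ssEffect <- ssEffect + n * (mean(Y[, j]) - grand)^2
  ssError <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ssError <- ssError +
      (Y[i, j] - mean(Y[i, ]) - mean(Y[, j]) + grand)^2
  Fv <- (ssEffect / (k - 1)) / (ssError / ((n - 1) * (k - 1)))
  list(ssEffect = ssEffect, ssError = ssError, F = Fv)
}

# Random partition of 1..n into exactly k nonempty blocks: one anchor element
# per block (so none can be empty, even for k close to n), the rest uniform.
randomPartition <- function(n, k) {
  stopifnot(k <= n)
  labs <- sample.int(k, n, replace = TRUE)
  labs[sample.int(n, k)] <- sample.int(k)
  asPartition(labs)
}
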