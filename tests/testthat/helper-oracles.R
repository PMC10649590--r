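# Independent reference implementations used as oracles. These deliberately
# use the naive O(N)-walk / textbook formulations, not the package's code
# paths.

# Weighted Kolmogorov-Smirnov running sum, walked position by position.
bruteForceES <- function(scores, members, exponent = 1) {
  stopifnot(!is.null(names(scores)))
  hit <- names(scores) %in% members
  N <- length(scores)
  w <- abs(scores)^exponent
  sw <- sum(w[hit])
  inc <- if (sw > 0) w / sw else rep(1 / sum(hit), N)
  dec <- 1 / (N - sum(hit))
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) cur + inc[i] else cur - dec
    run[i] <- cur
  }
  peak <- which(abs(run) >= max(abs(run)) - 1e-12)[1]  # earliest max |dev|
  es <- run[peak]
  le <- if (es > 0) names(scores)[hit & seq_len(N) <= peak]
        else if (es < 0) names(scores)[hit & seq_len(N) >= peak]
        else character()
  list(es = es, leading_edge = le, peak = peak)
}

# Textbook Spearman: Pearson correlation of average ranks.
spearmanOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact one-sided rank-sum p by explicit enumeration of all partitions.
rankSumEnumerate <- function(vals_in, vals_out) {
  pooled <- c(vals_in, vals_out)
  n <- length(vals_in)
  rks <- rank(pooled)
  W <- sum(rks[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  sums <- apply(combos, 2, function(ix) sum(rks[ix]))
  mean(sums >= W - 1e-9)
}

# Small helper: a made-up AnalysisSet with given matrices.
makeAset <- function(expr, tfab, groups = NULL) {
  samples <- colnames(expr)
  if (is.null(groups)) groups <- rep(c("C", "H"), length.out = length(samples))
  new("AnalysisSet", expr = expr, tfAbund = tfab, sharedSamples = samples,
      groups = groups, exprTransform = "log2cpm1")
}

randomRanking <- function(N, seed, positive = FALSE) {
  set.seed(seed)
  sc <- if (positive) sort(runif(N, 0.1, 10), decreasing = TRUE) else
    rnorm(N)
  rankedList(setNames(sc, sprintf("g%04d", seq_len(N))))
}
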