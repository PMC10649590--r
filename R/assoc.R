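## Condition association: a built-in Welch ranking statistic (an external RNK
## ranking is accepted anywhere a ranking is consumed), regulon enrichment in
## that ranking with the |NES| and adjusted-p gates, and rank-sum validation
## of a regulon against gene-level ChIP signal (exact by dynamic programming
## for small groups, tie-corrected normal approximation otherwise).

#' Welch condition-association ranking
#'
#' Per gene (row), the Welch two-sample t statistic of `case` minus
#' `control`; positive scores mean higher expression in the case group.
#' Genes whose pooled variance is zero get statistic 0 and are reported via
#' a message. The pipeline feeds `log2(CPM + 1)` expression here; any
#' externally computed RNK ranking can be used instead of this statistic.
#'
#' @param expr numeric matrix (genes x samples), typically
#'   [exprMatrix()] of an [AnalysisSet].
#' @param groups character/factor of group labels, one per column.
#' @param case,control the two group labels (defaults "H" and "C").
#' @return ranked list (named numeric vector, descending; ties in input
#'   order) with attribute `source = "builtin_welch"`.
#' @export
deStat <- function(expr, groups, case = "H", control = "C") {
  groups <- as.character(groups)
  if (!all(c(case, control) %in% groups))
    stop("both group labels must be present")
  if (length(setdiff(unique(groups), c(case, control))) > 0)
    stop("exactly two group labels expected")
  iH <- which(groups == case)
  iC <- which(groups == control)
  if (length(iH) < 2 || length(iC) < 2)
    stop("each group needs at least 2 samples")
  xH <- expr[, iH, drop = FALSE]
  xC <- expr[, iC, drop = FALSE]
  mH <- rowMeans(xH); mC <- rowMeans(xC)
  vH <- rowSums((xH - mH)^2) / (length(iH) - 1)
  vC <- rowSums((xC - mC)^2) / (length(iC) - 1)
  se <- sqrt(vH / length(iH) + vC / length(iC))
  stat <- ifelse(se == 0, 0, (mH - mC) / se)
  if (any(se == 0))
    message(sum(se == 0), " gene(s) with zero pooled variance set to 0")
  ranked <- rankedList(setNames(stat, rownames(expr)))
  attr(ranked, "source") <- "builtin_welch"
  ranked
}

#' Regulon enrichment in a condition ranking
#'
#' Tests every regulon against the signed per-gene association ranking with
#' [runGSEA()] and emits as hits the regulons passing both gates:
#' `|NES| > nes_threshold` and BH-adjusted p < `alpha`. A hit's direction is
#' `"positively_enriched"` when its NES is positive (the regulon sits among
#' genes up in the case group) and `"negatively_enriched"` otherwise.
#'
#' @param regulons data.frame from [mergeRegulons()], or a named list of
#'   gene sets.
#' @param ranking ranked list (e.g. from [deStat()] or [readRNK()]).
#' @param n_perm permutations (default 10000). Ensembles are shared across
#'   regulons of equal size, so large values cost little; the default keeps
#'   the Monte-Carlo p floor (about 1e-4) well below the `alpha` gate even
#'   after BH adjustment across a hundred regulons, where a floor of ~2e-3
#'   (1000 permutations) would sit exactly at the gate and make emission a
#'   coin flip.
#' @param seed,min_size,max_size,exponent passed to [runGSEA()].
#' @param nes_threshold |NES| gate (default 2).
#' @param alpha adjusted-p gate (default 0.05).
#' @return list with `full` (the complete per-regulon table) and `hits`
#'   (rows passing both gates, with a `direction` column).
#' @export
regulonConditionEnrichment <- function(regulons, ranking, n_perm = 10000,
                                       seed = 1, nes_threshold = 2,
                                       alpha = 0.05, min_size = 5,
                                       max_size = 500, exponent = 1) {
  sets <- if (is.data.frame(regulons)) regulonsToGeneSets(regulons)
          else regulons
  g <- runGSEA(ranking, sets, n_perm = n_perm, seed = seed,
               min_size = min_size, max_size = max_size,
               fdr_threshold = alpha, exponent = exponent)
  full <- g$results
  pass <- !full$flagged & !is.na(full$nes) &
    abs(full$nes) > nes_threshold & full$p_adjusted < alpha
  hits <- full[pass, , drop = FALSE]
  hits$direction <- ifelse(hits$nes > 0, "positively_enriched",
                           "negatively_enriched")
  rownames(hits) <- NULL
  list(full = full, hits = hits, skipped = g$skipped)
}

## Exact null distribution of the in-group rank sum by dynamic programming
## over the pooled (tie-averaged, doubled-to-integer) ranks. Returns
## P(rank sum >= w2) with w2 on the doubled scale.
.rankSumTailGE <- function(r2, n_in, w2) {
  N <- length(r2)
  smax <- sum(r2)
  f <- matrix(0, nrow = n_in + 1L, ncol = smax + 1L)  # f[j+1, s+1]
  f[1L, 1L] <- 1
  for (r in r2) {
    jmax <- min(n_in, N)
    for (j in seq.int(jmax, 1L)) {
      cols <- seq_len(smax + 1L - r)
      f[j + 1L, cols + r] <- f[j + 1L, cols + r] + f[j, cols]
    }
  }
  tail_counts <- f[n_in + 1L, ]
  sum(tail_counts[seq.int(w2 + 1L, smax + 1L)]) / choose(N, n_in)
}

#' Rank-sum validation of a regulon against ChIP signal
#'
#' One-sided Wilcoxon rank-sum (Mann-Whitney) test that genes inside the
#' regulon carry larger signal than genes outside. The null is enumerated
#' exactly (dynamic programming over tie-averaged ranks, correct with ties)
#' when both groups have at most `exact_max` observations, and approximated
#' by the tie-corrected normal with continuity correction otherwise. When
#' every signal value is identical the test is degenerate and p = 1.
#'
#' @param regulon_genes character vector of gene ids.
#' @param signal named numeric vector, gene id -> signal value.
#' @param alternative `"greater"` (default: regulon signal larger) or
#'   `"two.sided"`.
#' @param exact_max largest per-group size for exact enumeration
#'   (default 12).
#' @return list with `u_statistic`, `p_value`, `median_in`, `median_out`,
#'   `n_in`, `n_out`, `method` ("exact"/"normal") and `degenerate`.
#' @examples
#' chipValidate(c("a", "b", "c"),
#'              c(a = 4, b = 5, c = 6, d = 1, e = 2, f = 3))
#' @export
chipValidate <- function(regulon_genes, signal,
                         alternative = c("greater", "two.sided"),
                         exact_max = 12) {
  alternative <- match.arg(alternative)
  if (is.null(names(signal))) stop("signal must be a named vector")
  inside <- names(signal) %in% regulon_genes
  if (!any(inside)) stop("no regulon gene has a signal value")
  n_in <- sum(inside); n_out <- sum(!inside)
  if (n_in < 2 || n_out < 2)
    stop("need at least 2 genes with signal on each side")
  rks <- rank(signal)                     # average ranks on ties
  W <- sum(rks[inside])
  U <- W - n_in * (n_in + 1) / 2
  degenerate <- length(unique(signal)) == 1L
  N <- n_in + n_out
  if (n_in <= exact_max && n_out <= exact_max) {
    r2 <- as.integer(round(2 * rks))
    w2 <- as.integer(round(2 * W))
    p_ge <- .rankSumTailGE(r2, n_in, w2)
    if (alternative == "greater") {
      p <- p_ge
    } else {
      smax <- sum(r2)
      ## two-sided: fold around the null mean of the doubled rank sum
      mu2 <- n_in * (smax / N)
      lo2 <- as.integer(floor(2 * mu2 - w2))
      p_le <- 1 - .rankSumTailGE(r2, n_in, lo2 + 1L)
      p <- min(1, 2 * min(p_ge, p_le))
    }
    method <- "exact"
  } else {
    mu <- n_in * n_out / 2
    ties <- table(rks)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n_in * n_out / 12 * ((N + 1) - tie_term)
    if (v == 0) {
      p <- 1
    } else {
      z <- (U - mu - 0.5) / sqrt(v)
      p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE)
           else min(1, 2 * pnorm(abs(U - mu) / sqrt(v) - 0.5 / sqrt(v),
                                 lower.tail = FALSE))
    }
    method <- "normal"
  }
  if (degenerate) p <- 1
  list(u_statistic = U, p_value = p,
       median_in = stats::median(signal[inside]),
       median_out = stats::median(signal[!inside]),
       n_in = n_in, n_out = n_out, method = method, degenerate = degenerate)
}
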