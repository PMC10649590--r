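## Preranked enrichment engine: weighted Kolmogorov-Smirnov running-sum
## statistic (ES), gene-set-permutation null (NES, nominal p), BH control,
## leading edges, and the >= 50% leading-edge aggregation.
##
## The ES is evaluated in its hit-position form: with hit positions
## p_1 < ... < p_k, hit weights w_i = |s_{p_i}|^exponent and miss decrement
## 1/(N - k), the running sum immediately after hit i is
##   cumsum(w)_i / sum(w) - (p_i - i) / (N - k)
## and immediately before hit i it is the same expression with
## cumsum(w)_{i-1}. The extremum over the whole walk is attained at one of
## these 2k points (the sum only decays between hits), so the statistic is
## O(k) given the hit positions.

#' Build a ranked gene list
#'
#' Sorts scores into the non-increasing order every enrichment operation
#' expects. Ties are kept in input order (`"stable_input"`, default) or
#' broken by gene id (`"lexicographic"`).
#'
#' @param scores named numeric vector (names = unique gene ids).
#' @param tie_policy `"stable_input"` or `"lexicographic"`.
#' @return named numeric vector sorted by decreasing score.
#' @examples
#' rankedList(c(b = 1, a = 3, c = -2))
#' @export
rankedList <- function(scores, tie_policy = c("stable_input", "lexicographic")) {
  tie_policy <- match.arg(tie_policy)
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be a fully named vector")
  if (anyDuplicated(names(scores))) stop("duplicate gene ids in ranking")
  if (anyNA(scores)) stop("NA scores are not allowed in a ranking")
  ord <- if (tie_policy == "lexicographic") order(-scores, names(scores))
         else order(-scores)  # order() is stable: input order kept on ties
  scores[ord]
}

.checkRanked <- function(ranked) {
  if (is.null(names(ranked)) || anyDuplicated(names(ranked)))
    stop("ranking must have unique gene names")
  if (is.unsorted(rev(ranked)))
    stop("ranking scores must be non-increasing; use rankedList()")
  invisible(ranked)
}

## ES value only, from precomputed |score|^exponent weights and hit positions.
.esFromPositions <- function(w_all, pos, N) {
  pos <- sort.int(pos)
  k <- length(pos)
  w <- w_all[pos]
  sw <- sum(w)
  H <- if (sw > 0) cumsum(w) / sw else seq_len(k) / k  # all-zero weights: flat
  D <- (pos - seq_len(k)) / (N - k)
  top <- H - D
  bot <- c(0, H[-k]) - D
  v <- c(rbind(bot, top))
  p <- c(rbind(pos - 1L, pos))
  ## ties on |deviation| (within fp tolerance) resolve to earliest position
  cand <- which(abs(v) >= max(abs(v)) - 1e-12)
  best <- cand[which.min(p[cand])]
  list(es = v[best], peak = p[best], pos = pos)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranking; at each member ("hit") the running sum rises by
#' `|score|^exponent` normalized over all hits, at each non-member it falls
#' by `1/(N - n_hits)`. The ES is the running-sum value of maximal absolute
#' deviation (ties resolved to the earliest position). The leading edge is
#' the set of members at or before the peak for positive ES, and at or after
#' the trough for negative ES.
#'
#' @param ranked ranked list from [rankedList()] (or any named,
#'   non-increasing numeric vector).
#' @param members character vector of gene ids.
#' @param exponent hit-weighting exponent; 0 gives the classic unweighted
#'   Kolmogorov-Smirnov statistic, 1 (default) the standard weighted form.
#' @return list with `es` (in `[-1, 1]`), `leading_edge` (gene ids in
#'   ranking order) and `peak` (the 1-based ranking position of the
#'   extremum).
#' @examples
#' r <- rankedList(setNames(10:1, letters[1:10]))
#' enrichmentScore(r, "a")$es   # single hit at the top: ES = 1
#' @export
enrichmentScore <- function(ranked, members, exponent = 1) {
  .checkRanked(ranked)
  N <- length(ranked)
  pos <- which(names(ranked) %in% members)
  if (length(pos) == 0) stop("no member of the set is present in the ranking")
  if (length(pos) == N) stop("the set covers the whole ranking")
  w_all <- abs(ranked)^exponent
  r <- .esFromPositions(w_all, pos, N)
  le <- if (r$es > 0) names(ranked)[r$pos[r$pos <= r$peak]]
        else if (r$es < 0) names(ranked)[r$pos[r$pos >= r$peak]]
        else character()
  list(es = r$es, leading_edge = le, peak = r$peak)
}

## Null ES batch: ES values of n_perm random size-k gene sets drawn without
## replacement from the ranking. The distribution depends on the ranking
## only through the weight vector, so callers testing many sets against
## rankings with identical weights reuse one batch per distinct k
## (fgsea-style shared permutation ensemble).
.nullESBatch <- function(w_all, k, N, n_perm, seed) {
  set.seed(seed)
  vapply(seq_len(n_perm), function(b)
    .esFromPositions(w_all, sample.int(N, k), N)$es, numeric(1))
}

## p / NES summary of an observed ES against a null ES batch.
.permSummary <- function(es, nulls) {
  if (es == 0)
    return(list(nes = 0, p_nominal = 1, n_same_sign = 0L, flagged = TRUE))
  same <- sign(nulls) == sign(es)
  n_same <- sum(same)
  p <- (1 + sum(same & abs(nulls) >= abs(es))) / (1 + n_same)
  if (n_same < 1)
    return(list(nes = NA_real_, p_nominal = p, n_same_sign = 0L,
                flagged = TRUE))
  list(nes = es / mean(abs(nulls[same])), p_nominal = p,
       n_same_sign = n_same, flagged = FALSE)
}

#' Gene-set permutation test for one set
#'
#' Draws `n_perm` random gene sets of identical size from the ranking
#' (without replacement within each draw), forming the null ES distribution.
#' The nominal p-value uses only same-sign null values with the +1
#' correction, `p = (1 + #{|null| >= |es|}) / (1 + #same-sign)`, so it is
#' never 0; the NES divides the ES by the mean |null ES| of the same sign.
#'
#' @inheritParams enrichmentScore
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; results are reproducible given the seed.
#' @return list with `es`, `nes`, `p_nominal`, `leading_edge`,
#'   `n_same_sign` and `flagged` (`TRUE` when no same-sign null exists and
#'   the NES is undefined).
#' @export
permutationTest <- function(ranked, members, n_perm = 1000, seed = 1,
                            exponent = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  obs <- enrichmentScore(ranked, members, exponent)
  N <- length(ranked)
  k <- sum(names(ranked) %in% members)
  w_all <- abs(ranked)^exponent
  nulls <- .nullESBatch(w_all, k, N, n_perm, seed)
  s <- .permSummary(obs$es, nulls)
  list(es = obs$es, nes = s$nes, p_nominal = s$p_nominal,
       leading_edge = obs$leading_edge, n_same_sign = s$n_same_sign,
       flagged = s$flagged)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' returned in input order.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Preranked GSEA over a gene-set collection
#'
#' Restricts each set to genes present in the ranking, skips sets outside
#' `[min_size, max_size]`, computes each set's ES and evaluates it against
#' a gene-set-permutation null shared across sets of the same size (one
#' ensemble per distinct size, seeded from `seed`), adjusts nominal
#' p-values across the tested sets with [bhAdjust()] and flags sets with
#' adjusted p below `fdr_threshold`.
#'
#' @inheritParams permutationTest
#' @param collection named list of gene-id vectors.
#' @param min_size,max_size inclusive size bounds on set members present in
#'   the ranking (defaults 5 and 500).
#' @param fdr_threshold adjusted-p significance cut-off (default 0.25, the
#'   conventional preranked-GSEA exploratory level).
#' @return list with `results` (data.frame: `set_id`, `set_size_used`,
#'   `es`, `nes`, `p_nominal`, `p_adjusted`, `significant`, `flagged`,
#'   list-column `leading_edge`; sorted by `p_adjusted`, then |NES|
#'   descending) and `skipped` (data.frame: `set_id`, `set_size_used`,
#'   `reason`).
#' @export
runGSEA <- function(ranked, collection, n_perm = 1000, seed = 1,
                    min_size = 5, max_size = 500, fdr_threshold = 0.25,
                    exponent = 1) {
  if (length(collection) == 0) stop("empty gene-set collection")
  .checkRanked(ranked)
  universe <- names(ranked)
  used <- lapply(collection, intersect, x = universe)
  sizes <- lengths(used)
  in_bounds <- sizes >= min_size & sizes <= max_size & sizes < length(ranked)
  skipped <- data.frame(set_id = names(collection)[!in_bounds],
                        set_size_used = sizes[!in_bounds],
                        reason = ifelse(sizes[!in_bounds] < min_size,
                                        "below min_size",
                                        ifelse(sizes[!in_bounds] > max_size,
                                               "above max_size",
                                               "covers whole ranking")),
                        row.names = NULL, stringsAsFactors = FALSE)
  if (!any(in_bounds)) stop("no gene set passes the size bounds")
  idx <- which(in_bounds)
  ## one shared null batch per distinct set size (the null ES distribution
  ## depends on the ranking only through its weight vector)
  N <- length(ranked)
  w_all <- abs(ranked)^exponent
  nulls_by_k <- new.env(parent = emptyenv())
  null_for <- function(k) {
    key <- as.character(k)
    if (is.null(nulls_by_k[[key]]))
      nulls_by_k[[key]] <- .nullESBatch(w_all, k, N, n_perm, seed + k)
    nulls_by_k[[key]]
  }
  tests <- lapply(idx, function(i) {
    obs <- enrichmentScore(ranked, used[[i]], exponent)
    s <- .permSummary(obs$es, null_for(length(used[[i]])))
    c(obs[c("es", "leading_edge")], s)
  })
  res <- data.frame(
    set_id = names(collection)[idx],
    set_size_used = sizes[idx],
    es = vapply(tests, `[[`, numeric(1), "es"),
    nes = vapply(tests, `[[`, numeric(1), "nes"),
    p_nominal = vapply(tests, `[[`, numeric(1), "p_nominal"),
    flagged = vapply(tests, `[[`, logical(1), "flagged"),
    row.names = NULL, stringsAsFactors = FALSE)
  res$p_adjusted <- bhAdjust(res$p_nominal)
  res$significant <- res$p_adjusted < fdr_threshold
  res$leading_edge <- lapply(tests, `[[`, "leading_edge")
  ord <- order(res$p_adjusted, -abs(ifelse(is.na(res$nes), 0, res$nes)))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  list(results = res, skipped = skipped)
}

#' Leading-edge aggregation across enrichment results
#'
#' Returns the genes that appear in the leading edges of at least
#' `ceiling(fraction * n_results)` results, ordered by occurrence count
#' (descending) then gene id.
#'
#' @param results a `results` data.frame from [runGSEA()] (leading edges in
#'   the `leading_edge` list-column) or a plain list of gene-id vectors.
#' @param fraction minimum fraction of result sets a gene must support
#'   (default 0.5).
#' @return character vector of gene ids (possibly empty).
#' @export
leadingEdgeAnalysis <- function(results, fraction = 0.5) {
  edges <- if (is.data.frame(results)) results$leading_edge else results
  if (length(edges) == 0) stop("no enrichment results supplied")
  if (any(lengths(edges) == 0)) stop("every result must have a leading edge")
  counts <- table(unlist(lapply(edges, unique)))
  need <- ceiling(fraction * length(edges))
  hits <- counts[counts >= need]
  names(hits)[order(-as.integer(hits), names(hits))]
}
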