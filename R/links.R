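## TF -> gene link scoring: per-target random-forest regressions of gene
## expression on TF protein abundance, importance = impurity (variance)
## reduction summed over trees, normalized per target to sum to 1. Signs come
## from the Spearman correlation between TF abundance and target expression.

#' Infer unsigned TF-to-gene regulatory link scores
#'
#' For every expressed gene, fits a random-forest regression of its
#' expression across the shared samples on all TF protein abundances (the TF
#' itself is excluded as a predictor when the target is a TF gene), takes
#' the per-predictor impurity importance, and normalizes importances per
#' target to sum to one, so scores are comparable across targets and the
#' downstream score thresholds are scale-free. Forest defaults follow the
#' usual network-inference convention: `mtry = floor(sqrt(#TFs))`,
#' bootstrap sampling, unlimited depth.
#'
#' @param aset an [AnalysisSet].
#' @param n_trees trees per forest (default 1000).
#' @param seed integer seed; per-target seeds are derived from it, so
#'   results are reproducible and independent of evaluation order.
#' @param mtry candidate predictors per split: `"all"` (default) uses every
#'   TF at every split, which keeps importance concentrated on the true
#'   regulator when the candidate-TF panel is small; `"sqrt"` uses
#'   `floor(sqrt(#TFs))`, the classic random-forest heuristic for large
#'   regulator panels.
#' @return data.frame of links with `score > 0`: columns `tf`, `target`,
#'   `score`; ordered by target then score descending. Targets with
#'   constant expression are skipped with a warning.
#' @export
inferLinks <- function(aset, n_trees = 1000, seed = 1,
                       mtry = c("all", "sqrt")) {
  mtry <- match.arg(mtry)
  stopifnot(is(aset, "AnalysisSet"))
  tf_ab <- tfAbundance(aset)
  expr <- exprMatrix(aset)
  if (nrow(tf_ab) < 2) stop("need at least 2 TFs to infer links")
  if (length(sharedSamples(aset)) < 5) stop("need at least 5 shared samples")
  if (nrow(expr) < 1) stop("empty expression matrix")
  tf_ids <- rownames(tf_ab)
  ## canonical sample order: forests see the same rows however the caller
  ## ordered the shared samples, so scores are permutation-invariant
  ord <- order(sharedSamples(aset))
  X_all <- t(tf_ab)[ord, , drop = FALSE]
  expr <- expr[, ord, drop = FALSE]
  skipped <- character()
  out <- vector("list", nrow(expr))
  for (gi in seq_len(nrow(expr))) {
    g <- rownames(expr)[gi]
    y <- expr[gi, ]
    if (stats::var(y) == 0) {
      skipped <- c(skipped, g)
      next
    }
    preds <- setdiff(tf_ids, g)   # never a TF's own predictor
    if (length(preds) == 0) next
    X <- X_all[, preds, drop = FALSE]
    m <- if (mtry == "all") ncol(X) else max(1L, floor(sqrt(ncol(X))))
    fit <- ranger::ranger(x = X, y = y, num.trees = n_trees, mtry = m,
                          importance = "impurity", num.threads = 1,
                          seed = seed + gi)
    imp <- pmax(fit$variable.importance, 0)
    if (sum(imp) == 0) next
    sc <- imp / sum(imp)
    keep <- sc > 0
    if (!any(keep)) next
    out[[gi]] <- data.frame(tf = names(sc)[keep], target = g,
                            score = unname(sc[keep]),
                            stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped constant-expression target(s): ",
            paste(head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) " ...")
  links <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(links))
    return(data.frame(tf = character(), target = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  links <- links[order(links$target, -links$score, links$tf), , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Assign a regulation sign to each link
#'
#' The sign of a link is the sign of the Spearman rank correlation between
#' the TF's protein abundance and the target's expression over the shared
#' samples. Links whose correlation is exactly zero or undefined (constant
#' vectors) carry no direction and are dropped with a message.
#'
#' @param links data.frame from [inferLinks()].
#' @param aset the [AnalysisSet] the links were inferred from.
#' @return the links data.frame with added columns `rho` and
#'   `sign` (+1 / -1).
#' @export
assignSign <- function(links, aset) {
  stopifnot(is(aset, "AnalysisSet"))
  tf_ab <- tfAbundance(aset)
  expr <- exprMatrix(aset)
  if (!all(links$tf %in% rownames(tf_ab)))
    stop("links reference TFs absent from the analysis set")
  if (!all(links$target %in% rownames(expr)))
    stop("links reference targets absent from the analysis set")
  rho <- vapply(seq_len(nrow(links)), function(i)
    suppressWarnings(cor(tf_ab[links$tf[i], ], expr[links$target[i], ],
                         method = "spearman")),
    numeric(1))
  links$rho <- rho
  links$sign <- sign(rho)
  drop <- is.na(rho) | rho == 0
  if (any(drop))
    message(sum(drop), " link(s) dropped: zero or undefined Spearman rho")
  links <- links[!drop, , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Keep links above the score threshold
#'
#' @param links signed or unsigned links data.frame.
#' @param min_score threshold, exceeded strictly (default 0.02, the
#'   conventional cut for normalized per-target importances).
#' @return filtered links, ordered by target then score descending.
#' @export
thresholdLinks <- function(links, min_score = 0.02) {
  if (min_score < 0) stop("min_score must be nonnegative")
  links <- links[links$score > min_score, , drop = FALSE]
  links <- links[order(links$target, -links$score, links$tf), , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Write / read a links table
#'
#' TSV with columns `tf`, `target`, `score` (6 decimals), `sign`, `rho`.
#'
#' @param links signed links data.frame.
#' @param path file path.
#' @return `readLinksTSV` returns the links data.frame.
#' @export
writeLinksTSV <- function(links, path) {
  out <- links
  out$score <- sprintf("%.6f", out$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLinksTSV
#' @export
readLinksTSV <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
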