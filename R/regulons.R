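## Candidate-module construction (five schemes, sign-stratified), motif
## enrichment filtering against per-motif gene rankings, and merging into
## final up/down regulons.

.SCHEMES <- c("score002", "score005", "top50_per_tf", "top5_tf_per_gene",
              "top10_tf_per_gene")

#' Build the five candidate module families per TF
#'
#' Modules are built within each sign stratum ("up" = activating links,
#' "down" = repressive): (i) all links with score > `score_low`; (ii) score
#' > `score_high`; (iii) each TF's `top_genes` highest-scoring targets;
#' (iv)/(v) for every target its `top_tfs_small` (resp. `top_tfs_large`)
#' highest-scoring TFs are marked and a TF's module collects the targets
#' that marked it. Top-k ties break by score descending then gene/TF id
#' ascending; empty modules are discarded.
#'
#' @param links signed, thresholded links data.frame (columns `tf`,
#'   `target`, `score`, `sign`).
#' @param score_low,score_high score cut-offs of schemes (i) and (ii)
#'   (defaults 0.02 and 0.05).
#' @param top_genes per-TF target count of scheme (iii) (default 50).
#' @param top_tfs_small,top_tfs_large per-gene TF counts of schemes (iv)
#'   and (v) (defaults 5 and 10).
#' @return data.frame with columns `tf`, `sense` ("up"/"down"), `scheme`
#'   and a list-column `genes` (targets ordered by descending link score).
#' @export
buildCandidateModules <- function(links, score_low = 0.02, score_high = 0.05,
                                  top_genes = 50, top_tfs_small = 5,
                                  top_tfs_large = 10) {
  stopifnot(all(c("tf", "target", "score", "sign") %in% colnames(links)))
  out <- list()
  for (s in c(1, -1)) {
    sense <- if (s > 0) "up" else "down"
    sub <- links[links$sign == s, , drop = FALSE]
    if (nrow(sub) == 0) next
    sub <- sub[order(-sub$score, sub$target), , drop = FALSE]
    by_tf <- split(sub, sub$tf)

    add <- function(tf, scheme, genes) {
      if (length(genes) == 0) return()
      out[[length(out) + 1L]] <<- data.frame(
        tf = tf, sense = sense, scheme = scheme, stringsAsFactors = FALSE,
        genes = I(list(genes)))
    }
    for (tf in names(by_tf)) {
      d <- by_tf[[tf]]
      add(tf, "score002", d$target[d$score > score_low])
      add(tf, "score005", d$target[d$score > score_high])
      add(tf, "top50_per_tf", head(d$target, top_genes))
    }
    ## per-gene schemes: mark each target's best TFs
    by_gene <- split(sub, sub$target)
    marks5 <- do.call(rbind, lapply(by_gene, function(d)
      head(d[order(-d$score, d$tf), c("tf", "target", "score")],
           top_tfs_small)))
    marks10 <- do.call(rbind, lapply(by_gene, function(d)
      head(d[order(-d$score, d$tf), c("tf", "target", "score")],
           top_tfs_large)))
    for (tf in names(by_tf)) {
      m5 <- marks5[marks5$tf == tf, , drop = FALSE]
      m10 <- marks10[marks10$tf == tf, , drop = FALSE]
      add(tf, "top5_tf_per_gene",
          m5$target[order(-m5$score, m5$target)])
      add(tf, "top10_tf_per_gene",
          m10$target[order(-m10$score, m10$target)])
    }
  }
  if (length(out) == 0)
    return(data.frame(tf = character(), sense = character(),
                      scheme = character(), genes = I(list())))
  res <- do.call(rbind, out)
  res$scheme <- factor(res$scheme, levels = .SCHEMES)
  res <- res[order(res$tf, res$sense, res$scheme), , drop = FALSE]
  res$scheme <- as.character(res$scheme)
  rownames(res) <- NULL
  res
}

#' Filter candidate modules by TF-motif enrichment
#'
#' Every module is tested against each motif annotated to its TF: the motif
#' ranking is embedded into a preranked list and the module's genes form
#' the set of a gene-set-permutation enrichment test. The default embedding
#' scores gene `g` as `1 / rank(g)` so that, with the standard weighting
#' exponent, hit mass concentrates where motif evidence lives — the top of
#' the ranking — and the leading edge terminates sharply after the
#' high-confidence block; the alternative `"linear"` embedding
#' (`universe_size - rank + 1`) weights the whole ranking almost evenly and
#' lets the running-sum peak drift into mid-ranking positions. Nominal
#' p-values are BH-adjusted across all (module, motif) pairs of the run;
#' pairs with adjusted p < `alpha` and a positive ES (enrichment toward the
#' top of the motif ranking) are retained. Each surviving module's gene list is replaced by the union of
#' the leading edges of its retained motifs; modules of TFs with no
#' annotated motif, and modules with no retained motif, are dropped and
#' reported.
#'
#' @param modules data.frame from [buildCandidateModules()].
#' @param motifdb a [MotifDB].
#' @param n_perm permutations per (module, motif) test (default 1000).
#' @param seed integer seed.
#' @param alpha adjusted-p retention threshold (default 0.05).
#' @param exponent enrichment weighting exponent (default 1).
#' @param rank_score embedding of motif ranks into preranked scores:
#'   `"reciprocal"` (default, `1/rank`) or `"linear"`
#'   (`universe_size - rank + 1`).
#' @return list with `modules` (filtered data.frame plus list-columns
#'   `supporting_motifs` and `provenance` — per retained motif the scheme,
#'   motif id and leading-edge size), `dropped` (data.frame of dropped
#'   modules with a reason) and `tests` (the full per-pair test table).
#' @export
motifFilter <- function(modules, motifdb, n_perm = 1000, seed = 1,
                        alpha = 0.05, exponent = 1,
                        rank_score = c("reciprocal", "linear")) {
  rank_score <- match.arg(rank_score)
  stopifnot(is(motifdb, "MotifDB"))
  ann <- motifAnnotation(motifdb)
  universe <- motifUniverse(motifdb)
  N <- length(universe)
  rk <- motifRankings(motifdb)
  embed <- if (rank_score == "reciprocal") function(r) 1 / r
           else function(r) N - r + 1
  ## preranked lists per motif are reused across modules
  ranked_cache <- new.env(parent = emptyenv())
  motif_ranked <- function(m) {
    if (is.null(ranked_cache[[m]])) {
      sc <- setNames(embed(rk[m, ]), universe)
      ranked_cache[[m]] <- rankedList(sc, tie_policy = "lexicographic")
    }
    ranked_cache[[m]]
  }
  ## every motif ranking carries the same sorted weight vector, so one null
  ## ES ensemble per distinct module size serves all motifs
  w_sorted <- embed(seq_len(N))^exponent
  nulls_by_k <- new.env(parent = emptyenv())
  null_for <- function(k) {
    key <- as.character(k)
    if (is.null(nulls_by_k[[key]]))
      nulls_by_k[[key]] <- .nullESBatch(w_sorted, k, N, n_perm, seed + k)
    nulls_by_k[[key]]
  }
  tests <- list()
  dropped <- list()
  for (i in seq_len(nrow(modules))) {
    tf <- modules$tf[i]
    motifs <- names(ann)[!is.na(ann) & ann == tf]
    if (length(motifs) == 0) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        tf = tf, sense = modules$sense[i], scheme = modules$scheme[i],
        reason = "no annotated motif", stringsAsFactors = FALSE)
      next
    }
    genes <- modules$genes[[i]]
    overlap <- intersect(genes, universe)
    if (length(overlap) < length(genes) * 0.5)
      warning(sprintf(
        "motif universe misses %d/%d genes of module %s/%s/%s; testing overlap",
        length(genes) - length(overlap), length(genes), tf,
        modules$sense[i], modules$scheme[i]))
    if (length(overlap) == 0 || length(overlap) == N) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        tf = tf, sense = modules$sense[i], scheme = modules$scheme[i],
        reason = "no testable overlap with motif universe",
        stringsAsFactors = FALSE)
      next
    }
    for (m in motifs) {
      obs <- enrichmentScore(motif_ranked(m), overlap, exponent)
      s <- .permSummary(obs$es, null_for(length(overlap)))
      tests[[length(tests) + 1L]] <- data.frame(
        module = i, tf = tf, sense = modules$sense[i],
        scheme = modules$scheme[i], motif = m, es = obs$es, nes = s$nes,
        p_nominal = s$p_nominal, stringsAsFactors = FALSE,
        leading_edge = I(list(obs$leading_edge)))
    }
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(tf = character(), sense = character(), scheme = character(),
               reason = character(), stringsAsFactors = FALSE)
  if (length(tests) == 0)
    return(list(modules = modules[0, , drop = FALSE], dropped = dropped,
                tests = NULL))
  tests <- do.call(rbind, tests)
  tests$p_adjusted <- bhAdjust(tests$p_nominal)
  tests$retained <- tests$p_adjusted < alpha & tests$es > 0

  keep_rows <- list()
  for (i in unique(tests$module)) {
    ti <- tests[tests$module == i & tests$retained, , drop = FALSE]
    if (nrow(ti) == 0) {
      dropped <- rbind(dropped, data.frame(
        tf = modules$tf[i], sense = modules$sense[i],
        scheme = modules$scheme[i], reason = "no enriched motif",
        stringsAsFactors = FALSE))
      next
    }
    le_union <- unique(unlist(ti$leading_edge))
    genes <- modules$genes[[i]]
    new_genes <- genes[genes %in% le_union]   # original order, never grows
    prov <- data.frame(scheme = ti$scheme, motif = ti$motif,
                       leading_edge_size = lengths(ti$leading_edge),
                       stringsAsFactors = FALSE)
    keep_rows[[length(keep_rows) + 1L]] <- data.frame(
      tf = modules$tf[i], sense = modules$sense[i],
      scheme = modules$scheme[i], stringsAsFactors = FALSE,
      genes = I(list(new_genes)),
      supporting_motifs = I(list(unique(ti$motif))),
      provenance = I(list(prov)))
  }
  filtered <- if (length(keep_rows)) do.call(rbind, keep_rows) else
    data.frame(tf = character(), sense = character(), scheme = character(),
               genes = I(list()), supporting_motifs = I(list()),
               provenance = I(list()))
  rownames(filtered) <- NULL
  list(modules = filtered, dropped = dropped,
       tests = tests[, setdiff(colnames(tests), "leading_edge")])
}

#' Merge motif-filtered modules into final regulons
#'
#' Groups the filtered modules by (TF, sense), unions their gene lists and
#' concatenates (de-duplicated) supporting motifs and provenance records.
#'
#' @param filtered data.frame of motif-filtered modules (the `modules`
#'   element of [motifFilter()]'s result).
#' @return data.frame sorted by `tf` then `sense` with columns `tf`,
#'   `sense`, `name` ("TF_up"/"TF_down") and list-columns `genes`,
#'   `supporting_motifs`, `provenance`.
#' @export
mergeRegulons <- function(filtered) {
  if (nrow(filtered) == 0)
    return(data.frame(tf = character(), sense = character(),
                      name = character(), genes = I(list()),
                      supporting_motifs = I(list()), provenance = I(list())))
  key <- paste(filtered$tf, filtered$sense, sep = "\r")
  groups <- split(seq_len(nrow(filtered)), key)
  rows <- lapply(groups, function(ix) {
    genes <- unique(unlist(filtered$genes[ix]))
    prov <- do.call(rbind, lapply(ix, function(i) filtered$provenance[[i]]))
    prov <- unique(prov)
    data.frame(tf = filtered$tf[ix[1]], sense = filtered$sense[ix[1]],
               name = paste(filtered$tf[ix[1]], filtered$sense[ix[1]],
                            sep = "_"),
               stringsAsFactors = FALSE,
               genes = I(list(genes)),
               supporting_motifs = I(list(
                 unique(unlist(filtered$supporting_motifs[ix])))),
               provenance = I(list(prov)))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$tf, res$sense), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Convert regulons to a named gene-set list
#'
#' @param regulons data.frame from [mergeRegulons()].
#' @return named list (names "TF_up"/"TF_down") of gene-id vectors, ready
#'   for [writeGMT()] or [runGSEA()].
#' @export
regulonsToGeneSets <- function(regulons) {
  setNames(regulons$genes, regulons$name)
}
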