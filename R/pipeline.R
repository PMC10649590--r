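## Orchestration: a validated run configuration, staged execution
## (simulate -> prep -> links -> regulons -> associate) with logging and an
## md5 manifest, and recovery evaluation against planted truth.

.RUN_DEFAULTS <- list(
  out_dir = NULL,
  simulate = TRUE,
  sim = list(),            # overrides passed to simConfig()
  counts = NULL, proteins = NULL, meta = NULL, tfs = NULL,
  motif_annotation = NULL, motif_rankings = NULL, rnk = NULL,
  min_cpm = 1, min_frac = 0.10, expr_transform = "log2cpm1",
  n_trees = 1000, min_score = 0.02,
  score_low = 0.02, score_high = 0.05, top_genes = 50,
  top_tfs_small = 5, top_tfs_large = 10,
  n_perm = 1000, assoc_n_perm = 10000,
  motif_alpha = 0.05, assoc_alpha = 0.05,
  nes_threshold = 2, exponent = 1, fdr_threshold = 0.25,
  min_set_size = 5, max_set_size = 500,
  seed = 1,
  stages = c("simulate", "prep", "links", "regulons", "associate"))

#' Build and validate a pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline with its documented
#' default (link-score cut 0.02, module schemes {0.02, 0.05, 50, 5, 10},
#' motif and association alpha 0.05, |NES| gate 2, standalone-GSEA FDR
#' 0.25), plus input paths, stage toggles and the global seed. Unknown keys
#' and out-of-range values are rejected.
#'
#' @param ... named configuration entries overriding the defaults; see
#'   Details in the package vignette.
#' @return validated configuration list of class `regulomix_config`.
#' @examples
#' cfg <- runConfig(out_dir = tempfile(), sim = list(n_genes = 80,
#'   n_tfs = 4, targets_per_tf = 8), n_perm = 200, seed = 3)
#' @export
runConfig <- function(...) {
  user <- list(...)
  unknown <- setdiff(names(user), names(.RUN_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.RUN_DEFAULTS, user, keep.null = TRUE)
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  chk(cfg$min_score >= 0, "min_score must be nonnegative")
  chk(cfg$min_cpm >= 0, "min_cpm must be nonnegative")
  chk(cfg$min_frac >= 0 && cfg$min_frac <= 1, "min_frac must be in [0,1]")
  chk(cfg$expr_transform %in% c("log2cpm1", "cpm"),
      "expr_transform must be 'log2cpm1' or 'cpm'")
  chk(cfg$n_trees >= 1, "n_trees must be positive")
  chk(cfg$score_low >= 0 && cfg$score_high >= cfg$score_low,
      "need 0 <= score_low <= score_high")
  chk(cfg$top_genes >= 1 && cfg$top_tfs_small >= 1 &&
        cfg$top_tfs_large >= cfg$top_tfs_small,
      "top-k parameters must be positive with top_tfs_small <= top_tfs_large")
  chk(cfg$n_perm >= 100, "n_perm must be at least 100")
  chk(cfg$assoc_n_perm >= 100, "assoc_n_perm must be at least 100")
  for (a in c("motif_alpha", "assoc_alpha", "fdr_threshold"))
    chk(cfg[[a]] > 0 && cfg[[a]] <= 1, paste(a, "must be in (0,1]"))
  chk(cfg$nes_threshold >= 0, "nes_threshold must be nonnegative")
  chk(cfg$exponent >= 0, "exponent must be nonnegative")
  chk(all(cfg$stages %in% .RUN_DEFAULTS$stages), "unknown stage name")
  chk(is.numeric(cfg$seed) && cfg$seed == as.integer(cfg$seed),
      "seed must be an integer")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "regulomix_config"
  cfg
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys match [runConfig()] arguments.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

.md5 <- function(files) {
  h <- tools::md5sum(files)
  setNames(unname(h), basename(files))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order — simulate, prep (filtering and
#' sample alignment), links (random-forest scoring, Spearman signs, score
#' threshold), regulons (five module schemes, motif-enrichment filter,
#' merge), associate (condition ranking and regulon enrichment) — writing
#' every intermediate artifact under `out_dir`, a timestamped log, and a
#' `manifest.json` recording parameters, the seed and md5 hashes of every
#' output. Re-running with an identical configuration reproduces identical
#' hashes. A failing stage aborts the run with the stage named and leaves a
#' `FAILED` marker in `out_dir`. The global seed fans out to per-stage
#' seeds by fixed offsets so toggling one stage does not reseed another.
#'
#' @param config configuration from [runConfig()] / [readRunConfig()].
#' @return the manifest, invisibly (list with one entry per completed
#'   stage: parameters and output-file hashes).
#' @export
runAll <- function(config) {
  if (!inherits(config, "regulomix_config"))
    config <- do.call(runConfig, config)
  if (is.null(config$out_dir)) stop("config must set out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "|",
                            sprintf(...), "\n", file = log_path,
                            append = TRUE)
  manifest <- list(seed = config$seed,
                   parameters = unclass(config)[setdiff(names(config),
                                                        "out_dir")],
                   stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return()
    logf("==== stage %s ====", name)
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(fun(), error = function(e) {
      writeLines(paste("FAILED at stage:", name),
                 file.path(config$out_dir, "FAILED"))
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      stage = name,
      outputs = as.list(.md5(outputs)),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    logf("stage %s done (%d artifact(s))", name, length(outputs))
  }

  run_stage("simulate", function() {
    sim <- simulateRegulome(do.call(simConfig,
                                    c(config$sim, list(seed = config$seed))))
    state$sim <- sim
    d <- file.path(config$out_dir, "sim")
    writeSimulation(sim, d)
    list.files(d, full.names = TRUE)
  })

  run_stage("prep", function() {
    if (!is.null(state$sim)) {
      pair <- state$sim$pair
      tfs <- state$sim$tfs
      state$motifs <- state$sim$motifs
    } else {
      counts <- readMatrixTSV(config$counts)
      storage.mode(counts) <- "double"
      pair <- omicsPair(counts, readMatrixTSV(config$proteins),
                        readSampleMeta(config$meta))
      tfs <- readTFCatalog(config$tfs)
      state$motifs <- readMotifDB(config$motif_annotation,
                                  config$motif_rankings)
    }
    aset <- buildAnalysisSet(pair, tfs, config$expr_transform,
                             config$min_cpm, config$min_frac)
    state$aset <- aset
    f1 <- file.path(config$out_dir, "expr.tsv")
    f2 <- file.path(config$out_dir, "tf_abund.tsv")
    writeMatrixTSV(exprMatrix(aset), f1)
    writeMatrixTSV(tfAbundance(aset), f2)
    c(f1, f2)
  })

  run_stage("links", function() {
    raw <- inferLinks(state$aset, n_trees = config$n_trees,
                      seed = config$seed + 1000L)
    signed <- assignSign(raw, state$aset)
    state$links <- thresholdLinks(signed, config$min_score)
    f <- file.path(config$out_dir, "links.tsv")
    writeLinksTSV(state$links, f)
    f
  })

  run_stage("regulons", function() {
    mods <- buildCandidateModules(state$links, config$score_low,
                                  config$score_high, config$top_genes,
                                  config$top_tfs_small, config$top_tfs_large)
    mf <- motifFilter(mods, state$motifs, n_perm = config$n_perm,
                      seed = config$seed + 2000L, alpha = config$motif_alpha,
                      exponent = config$exponent)
    state$regulons <- mergeRegulons(mf$modules)
    f1 <- file.path(config$out_dir, "regulons.gmt")
    writeGMT(regulonsToGeneSets(state$regulons), f1)
    f2 <- file.path(config$out_dir, "regulon_provenance.tsv")
    prov <- do.call(rbind, lapply(seq_len(nrow(state$regulons)), function(i)
      cbind(name = state$regulons$name[i], state$regulons$provenance[[i]])))
    if (is.null(prov))
      prov <- data.frame(name = character(), scheme = character(),
                         motif = character(), leading_edge_size = integer())
    write.table(prov, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    f3 <- file.path(config$out_dir, "modules_dropped.tsv")
    write.table(mf$dropped, f3, sep = "\t", quote = FALSE, row.names = FALSE)
    c(f1, f2, f3)
  })

  run_stage("associate", function() {
    ranking <- if (!is.null(config$rnk)) readRNK(config$rnk)
               else deStat(exprMatrix(state$aset), sampleGroups(state$aset))
    enr <- regulonConditionEnrichment(
      state$regulons, ranking, n_perm = config$assoc_n_perm,
      seed = config$seed + 3000L, nes_threshold = config$nes_threshold,
      alpha = config$assoc_alpha, min_size = config$min_set_size,
      max_size = config$max_set_size, exponent = config$exponent)
    state$enrichment <- enr
    flat <- function(d) {
      d$leading_edge <- vapply(d$leading_edge, paste, character(1),
                               collapse = ";")
      d
    }
    f1 <- file.path(config$out_dir, "enrichment_full.tsv")
    write.table(flat(enr$full), f1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    f2 <- file.path(config$out_dir, "enrichment_hits.tsv")
    write.table(flat(enr$hits), f2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    c(f1, f2)
  })

  manifest$completed <- names(manifest$stages)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("run complete: %d stage(s)", length(manifest$completed))
  result <- list(manifest = manifest, aset = state$aset,
                 links = state$links, regulons = state$regulons,
                 enrichment = state$enrichment, sim = state$sim)
  invisible(result)
}

#' Jaccard / sign / detection report against planted truth
#'
#' Compares a run's outputs with the generator's ground truth: per
#' (TF, sense) Jaccard between regulon genes and planted same-sign targets,
#' planted-edge sign accuracy over the thresholded links (when supplied),
#' and precision/recall of programmed-TF detection from the enrichment
#' hits. A TF counts as detected when its "up" regulon is emitted as
#' positively enriched — the signature a positive condition shift of that
#' TF produces.
#'
#' @param truth `truth` element of [simulateRegulome()] output.
#' @param regulons data.frame from [mergeRegulons()].
#' @param hits `hits` table from [regulonConditionEnrichment()].
#' @param links optional signed links data.frame for sign accuracy.
#' @return list with `per_regulon` (data.frame `tf`, `sense`, `n_planted`,
#'   `n_regulon`, `jaccard`), `sign_accuracy`, `detected`, `precision`
#'   (NA when nothing is detected), `recall` (NA when no TF is programmed).
#' @export
evaluateRecovery <- function(truth, regulons, hits, links = NULL) {
  rows <- list()
  for (tf in unique(truth$edges$tf)) {
    for (sense in c("up", "down")) {
      planted <- truth$edges$target[truth$edges$tf == tf &
                                      truth$edges$sign ==
                                      (if (sense == "up") 1 else -1)]
      if (length(planted) == 0) next
      i <- which(regulons$tf == tf & regulons$sense == sense)
      reg_genes <- if (length(i)) regulons$genes[[i[1]]] else character()
      jac <- if (length(reg_genes) == 0) 0 else
        length(intersect(planted, reg_genes)) /
        length(union(planted, reg_genes))
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, sense = sense, n_planted = length(planted),
        n_regulon = length(reg_genes), jaccard = jac,
        stringsAsFactors = FALSE)
    }
  }
  per_regulon <- do.call(rbind, rows)
  sign_accuracy <- NA_real_
  if (!is.null(links) && nrow(links) > 0) {
    m <- merge(truth$edges, links, by = c("tf", "target"),
               suffixes = c("_true", "_inferred"))
    if (nrow(m) > 0)
      sign_accuracy <- mean(m$sign_true == m$sign_inferred)
  }
  detected <- character()
  if (!is.null(hits) && nrow(hits) > 0) {
    i <- match(hits$set_id, regulons$name)
    up_pos <- regulons$sense[i] == "up" & hits$nes > 0
    detected <- unique(regulons$tf[i][up_pos])
  }
  programmed <- truth$programmed_tfs
  precision <- if (length(detected) == 0) NA_real_ else
    length(intersect(detected, programmed)) / length(detected)
  recall <- if (length(programmed) == 0) NA_real_ else
    length(intersect(detected, programmed)) / length(programmed)
  list(per_regulon = per_regulon, sign_accuracy = sign_accuracy,
       detected = detected, precision = precision, recall = recall)
}

#' AUROC of link scores against planted edges
#'
#' Scores every candidate (TF, target) pair — pairs absent from the links
#' table score 0 — labels pairs by membership in the planted edge list, and
#' returns the area under the ROC curve via the rank-sum identity (average
#' ranks on ties).
#'
#' @param links links data.frame (any stage: unsigned, signed or
#'   thresholded).
#' @param truth `truth` element of [simulateRegulome()] output.
#' @param tfs TF catalog (candidate regulators).
#' @param targets candidate target universe (e.g. rownames of the analysis
#'   expression matrix).
#' @return AUROC in `[0, 1]`.
#' @export
linkAUROC <- function(links, truth, tfs, targets) {
  pairs <- expand.grid(tf = tfs, target = targets,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$tf != pairs$target, , drop = FALSE]
  key <- function(a, b) paste(a, b, sep = "\r")
  score <- setNames(rep(0, nrow(pairs)), key(pairs$tf, pairs$target))
  have <- key(links$tf, links$target)
  score[have[have %in% names(score)]] <-
    links$score[have %in% names(score)]
  label <- names(score) %in% key(truth$edges$tf, truth$edges$target)
  nP <- sum(label); nN <- sum(!label)
  if (nP == 0 || nN == 0) stop("need both planted and non-planted pairs")
  (sum(rank(score)[label]) - nP * (nP + 1) / 2) / (nP * nN)
}
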