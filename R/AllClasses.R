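#' @import methods
#' @importFrom stats cor p.adjust pnorm rnorm rpois runif setNames quantile
#' @importFrom utils head read.delim write.table
NULL

## ---- SimConfig --------------------------------------------------------------

#' Configuration of the synthetic regulome generator
#'
#' Holds every knob of the generative model used by [simulateRegulome()]:
#' cohort size, gene/TF universe, planted edge structure, noise levels, the
#' condition effect on programmed TFs, sequencing depth, proteomic
#' missingness, and the motif-database decoys. Validity enforces ranges and
#' the capacity constraint `n_tfs * targets_per_tf <= n_genes - n_tfs`
#' (targets are drawn from non-TF genes).
#'
#' @slot n_samples_per_group samples per condition group ("C" and "H").
#' @slot n_genes total genes, TF genes included.
#' @slot n_tfs number of transcription factors (`< n_genes`).
#' @slot targets_per_tf planted targets per TF.
#' @slot frac_negative share of repressive (negative-sign) planted edges.
#' @slot effect_size absolute edge weight, log2 units of target expression per
#'   log2 unit of TF abundance.
#' @slot noise_sd residual SD of target log2 expression.
#' @slot condition_shift log2 shift added to programmed-TF abundance in
#'   group "H".
#' @slot n_programmed_tfs how many TFs receive the condition shift.
#' @slot lib_size_mean mean sequencing library size (Poisson).
#' @slot protein_missing_rate independent missingness probability for protein
#'   intensities, in `[0, 1)`.
#' @slot n_decoy_motifs decoy motifs (annotated to no TF) added to the motif
#'   database.
#' @slot motif_signal_sd SD of the Gaussian perturbation of the planted
#'   motif relevance score.
#' @slot seed integer seed; equal config (seed included) gives bit-identical
#'   output.
#' @export
setClass("SimConfig", representation(
  n_samples_per_group = "integer",
  n_genes = "integer",
  n_tfs = "integer",
  targets_per_tf = "integer",
  frac_negative = "numeric",
  effect_size = "numeric",
  noise_sd = "numeric",
  condition_shift = "numeric",
  n_programmed_tfs = "integer",
  lib_size_mean = "integer",
  protein_missing_rate = "numeric",
  n_decoy_motifs = "integer",
  motif_signal_sd = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  pos_int <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 1L)
      msg <<- c(msg, sprintf("%s must be a positive integer", nm))
  }
  pos_int(object@n_samples_per_group, "n_samples_per_group")
  pos_int(object@n_genes, "n_genes")
  pos_int(object@n_tfs, "n_tfs")
  pos_int(object@targets_per_tf, "targets_per_tf")
  pos_int(object@lib_size_mean, "lib_size_mean")
  if (object@n_tfs >= object@n_genes)
    msg <- c(msg, "n_tfs must be smaller than n_genes")
  if (object@n_tfs * object@targets_per_tf > object@n_genes - object@n_tfs)
    msg <- c(msg, sprintf(
      "capacity violation: n_tfs * targets_per_tf = %d exceeds the %d non-TF genes",
      object@n_tfs * object@targets_per_tf, object@n_genes - object@n_tfs))
  if (object@frac_negative < 0 || object@frac_negative > 1)
    msg <- c(msg, "frac_negative must lie in [0, 1]")
  if (object@effect_size <= 0)
    msg <- c(msg, "effect_size must be positive")
  if (object@noise_sd < 0)
    msg <- c(msg, "noise_sd must be nonnegative")
  if (object@n_programmed_tfs < 0L || object@n_programmed_tfs > object@n_tfs)
    msg <- c(msg, "n_programmed_tfs must lie in [0, n_tfs]")
  if (object@protein_missing_rate < 0 || object@protein_missing_rate >= 1)
    msg <- c(msg, "protein_missing_rate must lie in [0, 1)")
  if (object@n_decoy_motifs < 0L)
    msg <- c(msg, "n_decoy_motifs must be nonnegative")
  if (object@motif_signal_sd < 0)
    msg <- c(msg, "motif_signal_sd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-regulome configuration
#'
#' Defaults describe the benchmark condition the package is calibrated on:
#' 20 samples in two groups, 600 genes of which 60 are TFs with 8 disjoint
#' targets each, moderate noise, and a 2-unit log2 condition shift on 5
#' programmed TFs. The TF-panel size matters: normalized per-target
#' importances spread over the candidate TFs, so fixed share thresholds
#' (0.02/0.05) are only selective when the uniform share `1/n_tfs` sits
#' well below them.
#'
#' @param n_samples_per_group,n_genes,n_tfs,targets_per_tf,n_programmed_tfs,
#'   n_decoy_motifs,lib_size_mean integer-valued scalars, see [SimConfig].
#' @param frac_negative,effect_size,noise_sd,condition_shift,
#'   protein_missing_rate,motif_signal_sd numeric scalars, see [SimConfig].
#' @param seed integer seed for all pseudo-random streams.
#' @return A validated [SimConfig] object.
#' @examples
#' cfg <- simConfig(n_genes = 100, n_tfs = 5, targets_per_tf = 10, seed = 1)
#' cfg
#' @export
simConfig <- function(n_samples_per_group = 10, n_genes = 600, n_tfs = 60,
                      targets_per_tf = 8, frac_negative = 0.3,
                      effect_size = 1.5, noise_sd = 0.2, condition_shift = 2,
                      n_programmed_tfs = min(5, n_tfs), lib_size_mean = 1e5,
                      protein_missing_rate = 0.01, n_decoy_motifs = 10,
                      motif_signal_sd = 0.5, seed = 1) {
  as_int <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x))
      stop(sprintf("'%s' must be a single integer-valued number", nm),
           call. = FALSE)
    as.integer(x)
  }
  new("SimConfig",
      n_samples_per_group = as_int(n_samples_per_group, "n_samples_per_group"),
      n_genes = as_int(n_genes, "n_genes"),
      n_tfs = as_int(n_tfs, "n_tfs"),
      targets_per_tf = as_int(targets_per_tf, "targets_per_tf"),
      frac_negative = as.numeric(frac_negative),
      effect_size = as.numeric(effect_size),
      noise_sd = as.numeric(noise_sd),
      condition_shift = as.numeric(condition_shift),
      n_programmed_tfs = as_int(n_programmed_tfs, "n_programmed_tfs"),
      lib_size_mean = as_int(lib_size_mean, "lib_size_mean"),
      protein_missing_rate = as.numeric(protein_missing_rate),
      n_decoy_motifs = as_int(n_decoy_motifs, "n_decoy_motifs"),
      motif_signal_sd = as.numeric(motif_signal_sd),
      seed = as_int(seed, "seed"))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_genes, "genes (", object@n_tfs, "TFs x",
      object@targets_per_tf, "targets ),",
      2L * object@n_samples_per_group, "samples\n")
  cat("  effect", object@effect_size, "| noise_sd", object@noise_sd,
      "| shift", object@condition_shift, "on", object@n_programmed_tfs,
      "TFs | seed", object@seed, "\n")
})

## ---- OmicsPair --------------------------------------------------------------

#' Paired transcriptome / proteome measurement
#'
#' The raw input of the pipeline: a gene-by-sample matrix of nonnegative
#' integer counts, a protein-by-sample matrix of positive intensities with
#' `NA` for missing values, and per-sample metadata carrying at least a
#' `group` column. Row and sample identifiers must be unique and every
#' sample of either matrix must be described in `sampleData`.
#'
#' @slot counts integer-valued matrix, genes x samples.
#' @slot proteins numeric matrix, proteins x samples, `NA` = missing.
#' @slot sampleData data.frame keyed by rownames = sample id, with a
#'   `group` column and optional `sex`.
#' @export
setClass("OmicsPair", representation(
  counts = "matrix",
  proteins = "matrix",
  sampleData = "data.frame"
))

setValidity("OmicsPair", function(object) {
  msg <- character()
  if (is.null(rownames(object@counts)) || is.null(colnames(object@counts)))
    msg <- c(msg, "counts must have row (gene) and column (sample) names")
  if (is.null(rownames(object@proteins)) || is.null(colnames(object@proteins)))
    msg <- c(msg, "proteins must have row (protein) and column (sample) names")
  if (anyDuplicated(rownames(object@counts)))
    msg <- c(msg, "duplicate gene ids in counts")
  if (anyDuplicated(rownames(object@proteins)))
    msg <- c(msg, "duplicate protein ids in proteins")
  if (anyDuplicated(colnames(object@counts)) ||
      anyDuplicated(colnames(object@proteins)))
    msg <- c(msg, "duplicate sample ids")
  if (any(object@counts < 0, na.rm = TRUE) || anyNA(object@counts))
    msg <- c(msg, "counts must be nonnegative and complete")
  if (any(object@proteins <= 0, na.rm = TRUE))
    msg <- c(msg, "non-missing protein intensities must be positive")
  all_samples <- union(colnames(object@counts), colnames(object@proteins))
  if (!all(all_samples %in% rownames(object@sampleData)))
    msg <- c(msg, "every sample id must appear in sampleData rownames")
  if (!"group" %in% colnames(object@sampleData))
    msg <- c(msg, "sampleData must contain a 'group' column")
  if (length(msg)) msg else TRUE
})

#' Construct an [OmicsPair]
#'
#' @param counts gene x sample matrix of nonnegative integers, dimnames set.
#' @param proteins protein x sample matrix of positive intensities with `NA`
#'   for missing entries, dimnames set.
#' @param sampleData data.frame with sample ids as rownames and a `group`
#'   column.
#' @return A validated [OmicsPair].
#' @export
omicsPair <- function(counts, proteins, sampleData) {
  new("OmicsPair", counts = counts, proteins = proteins,
      sampleData = sampleData)
}

setMethod("show", "OmicsPair", function(object) {
  cat("OmicsPair:", nrow(object@counts), "genes x", ncol(object@counts),
      "samples (counts);", nrow(object@proteins), "proteins x",
      ncol(object@proteins), "samples (intensities,",
      sum(is.na(object@proteins)), "missing)\n")
  cat("  groups:", paste(sprintf(
    "%s=%d", names(table(object@sampleData$group)),
    as.integer(table(object@sampleData$group))), collapse = " "), "\n")
})

#' Accessors for [OmicsPair] slots
#'
#' @param x an [OmicsPair].
#' @return `omicsCounts`: the count matrix; `omicsProteins`: the intensity
#'   matrix; `sampleData`: the sample metadata data.frame.
#' @export
omicsCounts <- function(x) x@counts

#' @rdname omicsCounts
#' @export
omicsProteins <- function(x) x@proteins

#' @rdname omicsCounts
#' @export
sampleData <- function(x) x@sampleData

## ---- AnalysisSet ------------------------------------------------------------

#' Aligned analysis matrices
#'
#' Output of [buildAnalysisSet()]: expression of filtered genes and complete
#' log2 TF protein abundance over the same ordered shared samples.
#'
#' @slot expr numeric matrix, filtered genes x shared samples
#'   (log2(CPM+1) or raw CPM depending on the transform chosen).
#' @slot tfAbund numeric matrix, TF proteins x shared samples, log2 scale,
#'   no missing entries.
#' @slot sharedSamples ordered character vector of sample ids.
#' @slot groups factor/character of group labels, one per shared sample.
#' @slot exprTransform `"log2cpm1"` or `"cpm"`.
#' @export
setClass("AnalysisSet", representation(
  expr = "matrix",
  tfAbund = "matrix",
  sharedSamples = "character",
  groups = "character",
  exprTransform = "character"
))

setValidity("AnalysisSet", function(object) {
  msg <- character()
  if (!identical(colnames(object@expr), object@sharedSamples))
    msg <- c(msg, "expr columns must equal sharedSamples in order")
  if (!identical(colnames(object@tfAbund), object@sharedSamples))
    msg <- c(msg, "tfAbund columns must equal sharedSamples in order")
  if (anyNA(object@tfAbund))
    msg <- c(msg, "tfAbund must have no missing entries")
  if (length(object@groups) != length(object@sharedSamples))
    msg <- c(msg, "one group label per shared sample required")
  if (!object@exprTransform %in% c("log2cpm1", "cpm"))
    msg <- c(msg, "exprTransform must be 'log2cpm1' or 'cpm'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AnalysisSet", function(object) {
  cat("AnalysisSet:", nrow(object@expr), "genes x",
      length(object@sharedSamples), "shared samples;",
      nrow(object@tfAbund), "TF proteins;",
      "expr =", object@exprTransform, "\n")
})

#' Accessors for [AnalysisSet] slots
#'
#' @param x an [AnalysisSet].
#' @return `exprMatrix`: gene expression matrix; `tfAbundance`: TF log2
#'   abundance matrix; `sharedSamples`: sample id vector; `sampleGroups`:
#'   group label vector.
#' @export
exprMatrix <- function(x) x@expr

#' @rdname exprMatrix
#' @export
tfAbundance <- function(x) x@tfAbund

#' @rdname exprMatrix
#' @export
sharedSamples <- function(x) x@sharedSamples

#' @rdname exprMatrix
#' @export
sampleGroups <- function(x) x@groups

## ---- MotifDB ----------------------------------------------------------------

#' Motif annotation and per-motif gene rankings
#'
#' Mirrors the structure of cisTarget-style resources: each motif carries a
#' total order over a fixed gene universe (rank 1 = strongest motif match),
#' and an annotation mapping motifs to the TF they represent (`NA` for
#' decoys).
#'
#' @slot annotation named character vector: motif id -> TF id or `NA`.
#' @slot rankings integer matrix, motifs x genes; `rankings[m, g]` is the
#'   rank of gene `g` under motif `m`; every row is a permutation of
#'   `1:ncol`.
#' @export
setClass("MotifDB", representation(
  annotation = "character",
  rankings = "matrix"
))

setValidity("MotifDB", function(object) {
  msg <- character()
  if (is.null(names(object@annotation)))
    msg <- c(msg, "annotation must be a named vector (motif id -> tf id)")
  if (is.null(rownames(object@rankings)) || is.null(colnames(object@rankings)))
    msg <- c(msg, "rankings must have motif rownames and gene colnames")
  if (!all(names(object@annotation) %in% rownames(object@rankings)))
    msg <- c(msg, "every annotated motif must have a ranking row")
  n <- ncol(object@rankings)
  if (n > 0 && nrow(object@rankings) > 0) {
    ok <- apply(object@rankings, 1L, function(r) identical(sort(as.integer(r)),
                                                           seq_len(n)))
    if (!all(ok))
      msg <- c(msg, "every motif ranking must be a permutation of 1..n_genes")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a [MotifDB]
#'
#' @param annotation named character vector mapping motif id to TF id
#'   (`NA` for decoy motifs).
#' @param rankings motifs x genes integer matrix of ranks (1 = best), each
#'   row a permutation of the gene universe.
#' @return A validated [MotifDB].
#' @export
motifDB <- function(annotation, rankings) {
  storage.mode(rankings) <- "integer"
  new("MotifDB", annotation = annotation, rankings = rankings)
}

setMethod("show", "MotifDB", function(object) {
  cat("MotifDB:", nrow(object@rankings), "motifs over",
      ncol(object@rankings), "genes;",
      sum(!is.na(object@annotation)), "annotated,",
      sum(is.na(object@annotation)), "decoys\n")
})

#' Accessors for [MotifDB] slots
#'
#' @param x a [MotifDB].
#' @return `motifAnnotation`: named motif -> TF vector; `motifRankings`:
#'   the rank matrix; `motifUniverse`: the gene universe (ranking columns).
#' @export
motifAnnotation <- function(x) x@annotation

#' @rdname motifAnnotation
#' @export
motifRankings <- function(x) x@rankings

#' @rdname motifAnnotation
#' @export
motifUniverse <- function(x) colnames(x@rankings)
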