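## Synthetic regulome generator.
##
## Fixed generative model (log2 scale throughout):
##   a[t,s] ~ N(mu_t, 1), mu_t ~ U(4,8); programmed TFs get +condition_shift
##     in group "H".
##   Each TF receives targets_per_tf distinct non-TF targets (disjoint across
##     TFs); edge weight w = +/- effect_size, negative with prob frac_negative.
##   Target expression x[g,s] = b0_g + sum_t w[t,g] (a[t,s] - mu_t) + eps,
##     eps ~ N(0, noise_sd); non-targets: x = b0_g + eps; b0_g ~ U(4,8).
##   Counts[g,s] ~ Poisson(L_s * 2^x[g,s] / sum_g 2^x[g,s]),
##     L_s ~ Poisson(lib_size_mean).
##   Proteins: TF rows = 2^(a + N(0, 0.25)) plus an equal number of non-TF
##     decoy protein rows; entries dropped to NA independently at
##     protein_missing_rate.
##   Motifs: one true motif per TF plus decoys; relevance(g) = 3*[g is that
##     TF's target] + N(0, motif_signal_sd); ranking = descending relevance,
##     ties broken lexicographically by gene id.
##   Gene sets: every TF's true target set plus one random set of equal size.
##
## One RNG stream per logical block (seeded seed + fixed offset) so changing
## one config field leaves unrelated blocks untouched.

.stream <- function(seed, offset) set.seed(seed + offset)
.STREAMS <- c(abund = 101L, edges = 211L, noise = 307L, counts = 331L,
              protnoise = 353L, missing = 401L, motifs = 503L,
              genesets = 601L)

.geneIds <- function(n_genes, n_tfs) {
  tf <- sprintf("TF%02d", seq_len(n_tfs))
  w <- max(3L, nchar(as.character(n_genes)))
  other <- sprintf(paste0("G%0", w, "d"), seq_len(n_genes - n_tfs))
  list(tf = tf, other = other, all = c(tf, other))
}

#' Simulate a paired-omics cohort with planted regulons
#'
#' Draws a full synthetic instance of the data the pipeline consumes: a
#' count matrix and a protein intensity matrix over shared samples in two
#' groups ("C" control, "H" condition), a TF catalog, a motif database whose
#' true motifs rank each TF's planted targets at the top, a gene-set
#' collection, and the ground truth (planted signed edges, programmed TFs,
#' motif-to-TF map). The generative model is documented in the package
#' vignette; identical `config` (seed included) yields bit-identical output.
#'
#' @param config a [SimConfig].
#' @return A list with elements `pair` ([OmicsPair]), `tfs` (character TF
#'   catalog), `motifs` ([MotifDB]), `genesets` (named list of gene-id
#'   vectors), and `truth` (list: `edges` data.frame with columns
#'   `tf`, `target`, `sign`, `weight`; `programmed_tfs`; `motif_map` named
#'   motif -> TF vector).
#' @examples
#' sim <- simulateRegulome(simConfig(n_genes = 60, n_tfs = 3,
#'                                   targets_per_tf = 5, seed = 7))
#' sim$pair
#' head(sim$truth$edges)
#' @export
simulateRegulome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n_s <- 2L * config@n_samples_per_group
  ids <- .geneIds(config@n_genes, config@n_tfs)
  samples <- sprintf("S%02d", seq_len(n_s))
  groups <- rep(c("C", "H"), each = config@n_samples_per_group)
  sexes <- rep_len(c("M", "F"), n_s)
  seed <- config@seed

  ## -- TF latent abundances (and decoy-protein latents) -----------------------
  .stream(seed, .STREAMS["abund"])
  mu <- runif(config@n_tfs, 4, 8)
  a <- matrix(rnorm(config@n_tfs * n_s, mean = mu, sd = 1),
              nrow = config@n_tfs, ncol = n_s,
              dimnames = list(ids$tf, samples))
  programmed <- ids$tf[seq_len(config@n_programmed_tfs)]
  a[programmed, groups == "H"] <- a[programmed, groups == "H"] +
    config@condition_shift
  decoy_prot_ids <- sample(ids$other, config@n_tfs)
  mu_d <- runif(config@n_tfs, 4, 8)
  d <- matrix(rnorm(config@n_tfs * n_s, mean = mu_d, sd = 1),
              nrow = config@n_tfs, ncol = n_s,
              dimnames = list(decoy_prot_ids, samples))

  ## -- planted edges -----------------------------------------------------------
  .stream(seed, .STREAMS["edges"])
  targets <- sample(ids$other, config@n_tfs * config@targets_per_tf)
  tgt_by_tf <- split(targets, rep(ids$tf, each = config@targets_per_tf))
  signs <- ifelse(runif(length(targets)) < config@frac_negative, -1, 1)
  edges <- data.frame(
    tf = rep(ids$tf, each = config@targets_per_tf),
    target = targets,
    sign = signs,
    weight = signs * config@effect_size,
    stringsAsFactors = FALSE)

  ## -- expression --------------------------------------------------------------
  .stream(seed, .STREAMS["noise"])
  b0 <- runif(config@n_genes, 4, 8)
  names(b0) <- ids$all
  x <- matrix(rep(b0, n_s), nrow = config@n_genes, ncol = n_s,
              dimnames = list(ids$all, samples))
  centered <- a - mu  # shift of programmed TFs in H carries through
  for (i in seq_len(nrow(edges))) {
    x[edges$target[i], ] <- x[edges$target[i], ] +
      edges$weight[i] * centered[edges$tf[i], ]
  }
  if (config@noise_sd > 0)
    x <- x + matrix(rnorm(length(x), sd = config@noise_sd), nrow = nrow(x))

  ## -- counts ------------------------------------------------------------------
  .stream(seed, .STREAMS["counts"])
  L <- rpois(n_s, config@lib_size_mean)
  lin <- 2^x
  frac <- sweep(lin, 2, colSums(lin), "/")
  counts <- matrix(rpois(length(frac), t(t(frac) * L)),
                   nrow = nrow(frac), dimnames = dimnames(frac))

  ## -- proteins ----------------------------------------------------------------
  .stream(seed, .STREAMS["protnoise"])
  prot_log2 <- rbind(a, d) + matrix(rnorm((2L * config@n_tfs) * n_s, sd = 0.25),
                                    nrow = 2L * config@n_tfs)
  proteins <- 2^prot_log2
  .stream(seed, .STREAMS["missing"])
  if (config@protein_missing_rate > 0) {
    drop <- runif(length(proteins)) < config@protein_missing_rate
    proteins[drop] <- NA_real_
  }

  ## -- motif database ----------------------------------------------------------
  .stream(seed, .STREAMS["motifs"])
  true_motifs <- paste0("mot_", ids$tf)
  decoy_motifs <- if (config@n_decoy_motifs > 0)
    sprintf("decoy%02d", seq_len(config@n_decoy_motifs)) else character()
  motif_ids <- c(true_motifs, decoy_motifs)
  rankings <- matrix(0L, nrow = length(motif_ids), ncol = config@n_genes,
                     dimnames = list(motif_ids, ids$all))
  for (m in seq_along(motif_ids)) {
    score <- numeric(config@n_genes)
    names(score) <- ids$all
    if (m <= config@n_tfs) score[tgt_by_tf[[ids$tf[m]]]] <- 3
    if (config@motif_signal_sd > 0)
      score <- score + rnorm(config@n_genes, sd = config@motif_signal_sd)
    ord <- order(-score, ids$all)       # ties broken lexicographically
    rankings[m, ord] <- seq_len(config@n_genes)
  }
  annotation <- c(setNames(ids$tf, true_motifs),
                  setNames(rep(NA_character_, length(decoy_motifs)),
                           decoy_motifs))
  motifs <- motifDB(annotation, rankings)

  ## -- gene sets ---------------------------------------------------------------
  .stream(seed, .STREAMS["genesets"])
  genesets <- setNames(tgt_by_tf, paste0("targets_", names(tgt_by_tf)))
  rand <- lapply(seq_len(config@n_tfs), function(i)
    sample(ids$all, config@targets_per_tf))
  names(rand) <- sprintf("random%02d", seq_len(config@n_tfs))
  genesets <- c(genesets, rand)

  meta <- data.frame(group = groups, sex = sexes, row.names = samples,
                     stringsAsFactors = FALSE)
  pair <- omicsPair(counts, proteins, meta)
  truth <- list(edges = edges, programmed_tfs = programmed,
                motif_map = setNames(ids$tf, true_motifs))
  list(pair = pair, tfs = ids$tf, motifs = motifs, genesets = genesets,
       truth = truth)
}

#' A constant miniature fixture
#'
#' Returns a hard-coded, noise-free instance: 2 TFs (`TF1`, `TF2`), 12 genes,
#' 6+6 samples, one motif per TF and no decoys. `TF1` activates `G01`, `G02`
#' and represses `G03`; `TF2` activates `G04` and represses `G05`, `G06`;
#' `G07`-`G10` are flat background. Counts are the rounded expected counts at
#' library size 100,000, so the object is identical on every call and across
#' releases.
#'
#' @return A list with elements `pair`, `tfs`, `motifs`, `truth` shaped as in
#'   [simulateRegulome()].
#' @examples
#' toy <- makeToyFixture()
#' toy$pair
#' toy$truth$edges
#' @export
makeToyFixture <- function() {
  samples <- sprintf("S%02d", 1:12)
  groups <- rep(c("C", "H"), each = 6)
  genes <- c("TF1", "TF2", sprintf("G%02d", 1:10))
  a1 <- rep(c(4, 5, 6, 7, 8, 9), 2)          # TF1 log2 abundance, mean 6.5
  a2 <- rep(c(9, 8, 7, 6, 5, 4), 2)          # TF2, anti-phased
  edges <- data.frame(
    tf = c("TF1", "TF1", "TF1", "TF2", "TF2", "TF2"),
    target = c("G01", "G02", "G03", "G04", "G05", "G06"),
    sign = c(1, 1, -1, 1, -1, -1),
    weight = c(1, 1, -1, 1, -1, -1),
    stringsAsFactors = FALSE)
  x <- matrix(6, nrow = 12, ncol = 12, dimnames = list(genes, samples))
  x["TF1", ] <- a1
  x["TF2", ] <- a2
  for (i in seq_len(nrow(edges)))
    x[edges$target[i], ] <- 6 + edges$weight[i] *
      (x[edges$tf[i], ] - 6.5)
  lin <- 2^x
  counts <- round(sweep(lin, 2, colSums(lin), "/") * 1e5)
  storage.mode(counts) <- "integer"
  proteins <- 2^rbind(TF1 = a1, TF2 = a2)
  colnames(proteins) <- samples
  meta <- data.frame(group = groups, sex = rep_len(c("M", "F"), 12),
                     row.names = samples, stringsAsFactors = FALSE)
  rankings <- matrix(0L, nrow = 2, ncol = 12,
                     dimnames = list(c("mot_TF1", "mot_TF2"), genes))
  rank_for <- function(tf_targets) {
    score <- setNames(numeric(12), genes)
    score[tf_targets] <- 3
    ord <- order(-score, genes)
    r <- integer(12); r[ord] <- 1:12
    r
  }
  rankings["mot_TF1", ] <- rank_for(c("G01", "G02", "G03"))
  rankings["mot_TF2", ] <- rank_for(c("G04", "G05", "G06"))
  motifs <- motifDB(c(mot_TF1 = "TF1", mot_TF2 = "TF2"), rankings)
  list(pair = omicsPair(counts, proteins, meta),
       tfs = c("TF1", "TF2"),
       motifs = motifs,
       truth = list(edges = edges, programmed_tfs = character(),
                    motif_map = c(mot_TF1 = "TF1", mot_TF2 = "TF2")))
}
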