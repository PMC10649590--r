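## File formats: TSV matrices (first column = row id, header = sample ids,
## empty cell = missing), GMT gene sets, RNK rankings, TF catalog (one id per
## line), motif annotation (motif \t tf-or-"-") and motif ranking long tables
## (motif \t gene \t rank).

#' Read / write a genes-by-samples TSV matrix
#'
#' First column holds row identifiers, the header row holds sample ids, and
#' an empty cell encodes a missing value.
#'
#' @param path file path.
#' @param mat numeric matrix with dimnames.
#' @return `readMatrixTSV` returns a numeric matrix with dimnames.
#' @export
readMatrixTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname readMatrixTSV
#' @export
writeMatrixTSV <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @return `readGMT` returns a named list of gene-id vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[`, character(1), 1L))
}

#' @rdname readGMT
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write RNK ranked-gene files
#'
#' Two tab-separated columns: gene id, signed score. Read back as a
#' descending-sorted named vector via [rankedList()].
#'
#' @param path file path.
#' @param ranked named numeric vector (names = gene ids).
#' @return `readRNK` returns a validated ranked list (named numeric vector,
#'   non-increasing).
#' @export
readRNK <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  rankedList(setNames(as.numeric(df[[2]]), as.character(df[[1]])))
}

#' @rdname readRNK
#' @export
writeRNK <- function(ranked, path) {
  write.table(data.frame(names(ranked), unname(ranked)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a TF catalog (one identifier per line)
#'
#' @param path file path.
#' @param tfs character vector of TF ids.
#' @return `readTFCatalog` returns a character vector of unique TF ids.
#' @export
readTFCatalog <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop("TF catalog is empty: ", path)
  if (anyDuplicated(ids)) stop("duplicate ids in TF catalog: ", path)
  ids
}

#' @rdname readTFCatalog
#' @export
writeTFCatalog <- function(tfs, path) {
  writeLines(tfs, path)
  invisible(path)
}

#' Read / write a motif database
#'
#' Two files: an annotation TSV (`motif TAB tf`, `-` marking decoys) and a
#' long ranking TSV (`motif TAB gene TAB rank`, rank 1 = best match).
#'
#' @param annotation_path,rankings_path file paths.
#' @param db a [MotifDB].
#' @param dir output directory for `writeMotifDB`.
#' @return `readMotifDB` returns a [MotifDB].
#' @export
readMotifDB <- function(annotation_path, rankings_path) {
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  long <- read.delim(rankings_path, stringsAsFactors = FALSE)
  motifs <- unique(long$motif)
  genes <- sort(unique(long$gene))
  rankings <- matrix(NA_integer_, nrow = length(motifs), ncol = length(genes),
                     dimnames = list(motifs, genes))
  rankings[cbind(match(long$motif, motifs), match(long$gene, genes))] <-
    as.integer(long$rank)
  annotation <- setNames(ifelse(ann$tf == "-", NA_character_, ann$tf),
                         ann$motif)
  motifDB(annotation, rankings)
}

#' @rdname readMotifDB
#' @export
writeMotifDB <- function(db, dir) {
  ann <- data.frame(motif = names(motifAnnotation(db)),
                    tf = ifelse(is.na(motifAnnotation(db)), "-",
                                motifAnnotation(db)))
  write.table(ann, file.path(dir, "motif_annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  r <- motifRankings(db)
  long <- data.frame(motif = rep(rownames(r), each = ncol(r)),
                     gene = rep(colnames(r), times = nrow(r)),
                     rank = as.integer(t(r)))
  write.table(long, file.path(dir, "motif_rankings.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a simulated instance to a directory
#'
#' Emits the plain-text artifacts downstream stages (and the command-line
#' interface) read back: `counts.tsv`, `proteins.tsv` (empty cell =
#' missing), `sample_meta.tsv`, `tfs.txt`, `motif_annotation.tsv`,
#' `motif_rankings.tsv`, `genesets.gmt` and `truth_edges.tsv`.
#'
#' @param sim result of [simulateRegulome()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrixTSV(omicsCounts(sim$pair), file.path(dir, "counts.tsv"))
  writeMatrixTSV(omicsProteins(sim$pair), file.path(dir, "proteins.tsv"))
  meta <- data.frame(sample = rownames(sampleData(sim$pair)),
                     sampleData(sim$pair), row.names = NULL)
  write.table(meta, file.path(dir, "sample_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeTFCatalog(sim$tfs, file.path(dir, "tfs.txt"))
  writeMotifDB(sim$motifs, dir)
  if (!is.null(sim$genesets))
    writeGMT(sim$genesets, file.path(dir, "genesets.gmt"))
  write.table(sim$truth$edges, file.path(dir, "truth_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read sample metadata written by [writeSimulation()]
#'
#' @param path TSV with columns `sample`, `group` and optionally `sex`.
#' @return data.frame with sample ids as rownames.
#' @export
readSampleMeta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  rownames(df) <- df$sample
  df$sample <- NULL
  df
}

## ---- preprocessing ----------------------------------------------------------

#' Counts per million
#'
#' Scales every column to a library of one million:
#' `cpm[g, s] = counts[g, s] / colsum_s * 1e6`.
#'
#' @param counts nonnegative count matrix, samples in columns.
#' @return numeric matrix of the same shape; every column sums to `1e6`.
#' @examples
#' cpm(matrix(c(1, 9), 2, 1, dimnames = list(c("a", "b"), "S1")))
#' @export
cpm <- function(counts) {
  libs <- colSums(counts)
  if (any(libs == 0)) {
    bad <- colnames(counts)[libs == 0]
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2, libs, "/") * 1e6
}

#' Filter lowly expressed genes
#'
#' Keeps gene `g` iff its CPM exceeds `min_cpm` (strictly) in at least
#' `ceil(min_frac * n_samples)` samples. Row order is preserved.
#'
#' @param counts count matrix.
#' @param min_cpm CPM cut-off, exceeded strictly (default 1).
#' @param min_frac minimum fraction of samples (default 0.10); the sample
#'   count threshold is `ceiling(min_frac * ncol(counts))`.
#' @return the filtered count matrix.
#' @export
filterExpression <- function(counts, min_cpm = 1, min_frac = 0.10) {
  cp <- cpm(counts)
  need <- ceiling(min_frac * ncol(counts))
  keep <- rowSums(cp > min_cpm) >= need
  counts[keep, , drop = FALSE]
}

#' Filter proteins with missing values and log2-transform
#'
#' Removes every protein row containing at least one missing value, then
#' replaces the surviving intensities by their log2.
#'
#' @param proteins intensity matrix, `NA` = missing; non-missing entries
#'   must be strictly positive.
#' @return numeric matrix of log2 intensities, complete rows only.
#' @export
filterProteins <- function(proteins) {
  bad <- which(!is.na(proteins) & proteins <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("nonpositive intensity for protein '%s' in sample '%s'",
                 rownames(proteins)[bad[1, 1]], colnames(proteins)[bad[1, 2]]))
  keep <- rowSums(is.na(proteins)) == 0
  log2(proteins[keep, , drop = FALSE])
}

#' Align filtered expression and TF abundance over shared samples
#'
#' Applies [filterExpression()] and [filterProteins()], restricts protein
#' rows to TF-catalog members, intersects the sample sets of both matrices
#' and orders both identically (count-matrix column order).
#'
#' @param pair an [OmicsPair].
#' @param tfs character TF catalog.
#' @param exprTransform `"log2cpm1"` (default; `log2(CPM + 1)`) or `"cpm"`.
#' @param min_cpm,min_frac expression-filter parameters, see
#'   [filterExpression()].
#' @return an [AnalysisSet].
#' @examples
#' toy <- makeToyFixture()
#' buildAnalysisSet(toy$pair, toy$tfs)
#' @export
buildAnalysisSet <- function(pair, tfs,
                             exprTransform = c("log2cpm1", "cpm"),
                             min_cpm = 1, min_frac = 0.10) {
  exprTransform <- match.arg(exprTransform)
  stopifnot(is(pair, "OmicsPair"), length(tfs) > 0)
  counts <- filterExpression(omicsCounts(pair), min_cpm, min_frac)
  prot <- filterProteins(omicsProteins(pair))
  tf_rows <- intersect(rownames(prot), tfs)
  if (length(tf_rows) == 0)
    stop("no TF proteins: no complete protein row matches the TF catalog")
  shared <- intersect(colnames(counts), colnames(prot))
  if (length(shared) == 0) stop("no shared samples between the two matrices")
  if (length(shared) < 3)
    stop("need at least 3 shared samples, found ", length(shared))
  cp <- cpm(counts)[, shared, drop = FALSE]
  expr <- if (exprTransform == "log2cpm1") log2(cp + 1) else cp
  groups <- as.character(sampleData(pair)[shared, "group"])
  new("AnalysisSet", expr = expr,
      tfAbund = prot[tf_rows, shared, drop = FALSE],
      sharedSamples = shared, groups = groups,
      exprTransform = exprTransform)
}
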