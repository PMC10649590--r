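fake_links <- function(tf, targets, scores, sign = 1) {
  data.frame(tf = tf, target = targets, score = scores, sign = sign,
             rho = sign * 0.5, stringsAsFactors = FALSE)
}

test_that("the five schemes implement their rules", {
  set.seed(20)
  sc <- sort(runif(60, 0.051, 0.9), decreasing = TRUE)
  links <- fake_links("T1", sprintf("g%02d", 1:60), sc)
  mods <- buildCandidateModules(links)
  get <- function(scheme) mods$genes[[which(mods$scheme == scheme)]]
  expect_length(get("score002"), 60L)
  expect_length(get("score005"), 60L)
  expect_length(get("top50_per_tf"), 50L)
  # top-50 keeps the highest-scoring 50
  expect_setequal(get("top50_per_tf"), sprintf("g%02d", 1:50))
})

test_that("per-gene schemes mark each target's best TFs", {
  set.seed(21)
  tfs <- sprintf("T%02d", 1:12)
  links <- fake_links(tfs, "gene1", sort(runif(12, 0.1, 0.9),
                                         decreasing = TRUE))
  mods <- buildCandidateModules(links)
  top5 <- mods[mods$scheme == "top5_tf_per_gene", ]
  top10 <- mods[mods$scheme == "top10_tf_per_gene", ]
  expect_equal(nrow(top5), 5L)    # gene appears in exactly 5 TFs' modules
  expect_equal(nrow(top10), 10L)
  expect_setequal(top5$tf, tfs[1:5])
  expect_setequal(top10$tf, tfs[1:10])
})

test_that("sign strata are kept apart and empty strata discarded", {
  links <- rbind(fake_links("T1", c("a", "b"), c(0.5, 0.4), sign = -1),
                 fake_links("T2", c("c"), 0.6, sign = 1))
  mods <- buildCandidateModules(links)
  expect_false(any(mods$tf == "T1" & mods$sense == "up"))
  expect_false(any(mods$tf == "T2" & mods$sense == "down"))
  expect_true(all(mods$sense[mods$tf == "T1"] == "down"))
})

test_that("scheme subset relations hold on random link tables", {
  set.seed(22)
  links <- do.call(rbind, lapply(sprintf("T%02d", 1:8), function(tf) {
    n <- sample(30:70, 1)
    fake_links(tf, sample(sprintf("g%03d", 1:150), n),
               runif(n, 0.021, 0.5),
               sign = sample(c(-1, 1), n, replace = TRUE))
  }))
  mods <- buildCandidateModules(links)
  for (tf in unique(mods$tf)) for (sense in c("up", "down")) {
    g <- function(s) {
      i <- which(mods$tf == tf & mods$sense == sense & mods$scheme == s)
      if (length(i)) mods$genes[[i]] else character()
    }
    expect_true(all(g("score005") %in% g("score002")))
    expect_true(all(g("top5_tf_per_gene") %in% g("top10_tf_per_gene")))
    expect_true(all(g("top50_per_tf") %in% g("score002")))
  }
})

## a small handmade motif database: universe of 100 genes, T1's motif ranks
## m-genes first, a decoy motif with no annotation
toy_motifdb <- function() {
  genes <- sprintf("g%03d", 1:100)
  rank1 <- seq_along(genes); names(rank1) <- genes       # identity order
  set.seed(23)
  rank2 <- sample(rank1); names(rank2) <- genes
  motifDB(c(mot1 = "T1", dec1 = NA),
          rbind(mot1 = rank1, dec1 = rank2))
}

test_that("a front-loaded module is retained with a full leading edge", {
  db <- toy_motifdb()
  genes <- motifUniverse(db)[1:20]
  mods <- data.frame(tf = "T1", sense = "up", scheme = "score002",
                     stringsAsFactors = FALSE, genes = I(list(genes)))
  out <- motifFilter(mods, db, n_perm = 1000, seed = 1)
  expect_equal(nrow(out$modules), 1L)
  expect_setequal(out$modules$genes[[1]], genes)
  expect_identical(out$modules$supporting_motifs[[1]], "mot1")
})

test_that("modules of TFs without motifs are dropped and reported", {
  db <- toy_motifdb()
  mods <- data.frame(tf = "T9", sense = "up", scheme = "score002",
                     stringsAsFactors = FALSE,
                     genes = I(list(motifUniverse(db)[1:10])))
  out <- motifFilter(mods, db, n_perm = 1000, seed = 1)
  expect_equal(nrow(out$modules), 0L)
  expect_identical(out$dropped$reason, "no annotated motif")
})

test_that("scattered modules fail the motif test", {
  db <- toy_motifdb()
  set.seed(24)
  mods <- data.frame(tf = "T1", sense = "up", scheme = "score002",
                     stringsAsFactors = FALSE,
                     genes = I(list(sample(motifUniverse(db), 15))))
  out <- motifFilter(mods, db, n_perm = 1000, seed = 1)
  expect_equal(nrow(out$modules), 0L)
})

test_that("the motif filter never adds genes", {
  db <- toy_motifdb()
  set.seed(25)
  mods <- do.call(rbind, lapply(1:5, function(i)
    data.frame(tf = "T1", sense = "up",
               scheme = regulomix:::.SCHEMES[i],
               stringsAsFactors = FALSE,
               genes = I(list(unique(c(motifUniverse(db)[1:sample(5:20, 1)],
                                       sample(motifUniverse(db), 10))))))))
  out <- motifFilter(mods, db, n_perm = 500, seed = 2)
  if (nrow(out$modules)) {
    for (i in seq_len(nrow(out$modules))) {
      orig <- mods$genes[[which(mods$scheme == out$modules$scheme[i])[1]]]
      expect_true(all(out$modules$genes[[i]] %in% orig))
    }
  }
})

test_that("merge unions genes by TF and sense", {
  f <- data.frame(tf = c("T1", "T1", "T1"), sense = c("up", "up", "down"),
                  scheme = c("score002", "score005", "score002"),
                  stringsAsFactors = FALSE,
                  genes = I(list(c("A", "B"), c("B", "C"), c("D"))),
                  supporting_motifs = I(list("m1", "m1", "m1")),
                  provenance = I(list(
                    data.frame(scheme = "score002", motif = "m1",
                               leading_edge_size = 2L),
                    data.frame(scheme = "score005", motif = "m1",
                               leading_edge_size = 2L),
                    data.frame(scheme = "score002", motif = "m1",
                               leading_edge_size = 1L))))
  regs <- mergeRegulons(f)
  expect_equal(nrow(regs), 2L)
  expect_setequal(regs$genes[[which(regs$name == "T1_up")]],
                  c("A", "B", "C"))
  expect_setequal(regs$genes[[which(regs$name == "T1_down")]], "D")
  expect_identical(regs$name, c("T1_down", "T1_up"))  # sorted tf, sense
})

test_that("regulon genes trace back to same-sign thresholded links", {
  sim <- simulateRegulome(simConfig(n_genes = 150, n_tfs = 15,
                                    targets_per_tf = 6, noise_sd = 0,
                                    protein_missing_rate = 0, seed = 30))
  aset <- buildAnalysisSet(sim$pair, sim$tfs)
  links <- suppressMessages(thresholdLinks(assignSign(
    inferLinks(aset, n_trees = 200, seed = 31), aset)))
  mods <- buildCandidateModules(links)
  out <- suppressWarnings(motifFilter(mods, sim$motifs, n_perm = 500,
                                      seed = 32))
  regs <- mergeRegulons(out$modules)
  for (i in seq_len(nrow(regs))) {
    s <- if (regs$sense[i] == "up") 1 else -1
    allowed <- links$target[links$tf == regs$tf[i] & links$sign == s]
    expect_true(all(regs$genes[[i]] %in% allowed))
  }
})
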