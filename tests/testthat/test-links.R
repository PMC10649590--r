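test_that("a copied TF abundance dominates that target's importance", {
  set.seed(10)
  S <- 20
  tfab <- matrix(rnorm(10 * S, 6), 10, S,
                 dimnames = list(sprintf("TF%02d", 1:10),
                                 sprintf("S%02d", 1:S)))
  expr <- rbind(copycat = tfab["TF01", ],
                matrix(rnorm(4 * S, 6), 4, S,
                       dimnames = list(paste0("noise", 1:4), colnames(tfab))))
  aset <- makeAset(expr, tfab)
  for (seed in 1:3) {
    links <- inferLinks(aset, n_trees = 300, seed = seed)
    l <- links[links$target == "copycat", ]
    expect_identical(l$tf[which.max(l$score)], "TF01")
    expect_gt(max(l$score), 0.5)
  }
})

test_that("per-target scores are normalized to one", {
  set.seed(11)
  S <- 12
  tfab <- matrix(rnorm(5 * S, 6), 5, S,
                 dimnames = list(paste0("TF", 1:5), paste0("S", 1:S)))
  expr <- matrix(rnorm(8 * S, 6), 8, S,
                 dimnames = list(paste0("g", 1:8), colnames(tfab)))
  links <- inferLinks(makeAset(expr, tfab), n_trees = 200, seed = 1)
  sums <- tapply(links$score, links$target, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("constant targets are skipped with a warning", {
  S <- 10
  tfab <- matrix(rnorm(3 * S, 6), 3, S,
                 dimnames = list(paste0("TF", 1:3), paste0("S", 1:S)))
  expr <- rbind(flat = rep(1, S),
                ok = rnorm(S))
  colnames(expr) <- colnames(tfab)
  expect_warning(links <- inferLinks(makeAset(expr, tfab), n_trees = 100,
                                     seed = 1),
                 "constant-expression")
  expect_false("flat" %in% links$target)
})

test_that("signs follow the Spearman correlation exactly", {
  S <- 12
  a <- seq_len(S) + 6
  tfab <- rbind(TFUP = a, TFDN = a)
  colnames(tfab) <- paste0("S", 1:S)
  expr <- rbind(mono_up = 2 * a + 1, mono_dn = -a + 40)
  colnames(expr) <- colnames(tfab)
  links <- data.frame(tf = c("TFUP", "TFDN"),
                      target = c("mono_up", "mono_dn"),
                      score = c(0.5, 0.5), stringsAsFactors = FALSE)
  signed <- assignSign(links, makeAset(expr, tfab))
  expect_equal(signed$rho, c(1, -1))
  expect_equal(signed$sign, c(1, -1))
})

test_that("zero-rho and undefined-rho links are dropped", {
  S <- 8
  tfab <- rbind(TFA = rnorm(S), TFB = rnorm(S))
  colnames(tfab) <- paste0("S", 1:S)
  expr <- rbind(const = rep(3, S))
  colnames(expr) <- colnames(tfab)
  links <- data.frame(tf = "TFA", target = "const", score = 0.5,
                      stringsAsFactors = FALSE)
  expect_message(out <- assignSign(links, makeAset(expr, tfab)), "dropped")
  expect_equal(nrow(out), 0L)
})

test_that("planted signs are recovered perfectly without noise", {
  sim <- simulateRegulome(simConfig(n_genes = 120, n_tfs = 6,
                                    targets_per_tf = 10, noise_sd = 0,
                                    protein_missing_rate = 0, seed = 21))
  aset <- buildAnalysisSet(sim$pair, sim$tfs)
  ed <- sim$truth$edges
  links <- data.frame(tf = ed$tf, target = ed$target, score = 1,
                      stringsAsFactors = FALSE)
  signed <- assignSign(links, aset)
  m <- merge(ed, signed, by = c("tf", "target"),
             suffixes = c("_true", "_got"))
  expect_equal(nrow(m), nrow(ed))
  expect_true(all(m$sign_true == m$sign_got))
})

test_that("the score threshold is strict", {
  links <- data.frame(tf = "T", target = c("a", "b", "c"),
                      score = c(0.06, 0.03, 0.01), sign = 1, rho = 0.5,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(thresholdLinks(links)), 2L)
  expect_equal(nrow(thresholdLinks(links, min_score = 0)), 3L)
  exact <- data.frame(tf = "T", target = "a", score = 0.02, sign = 1,
                      rho = 0.5, stringsAsFactors = FALSE)
  expect_equal(nrow(thresholdLinks(exact)), 0L)
  expect_error(thresholdLinks(links, min_score = -1), "nonnegative")
})

test_that("scores and signs are invariant to shared sample permutation", {
  set.seed(12)
  S <- 14
  tfab <- matrix(rnorm(4 * S, 6), 4, S,
                 dimnames = list(paste0("TF", 1:4), sprintf("S%02d", 1:S)))
  expr <- rbind(t1 = tfab["TF1", ] * 2 + rnorm(S, sd = 0.1),
                t2 = rnorm(S))
  colnames(expr) <- colnames(tfab)
  aset1 <- makeAset(expr, tfab)
  perm <- sample(S)
  aset2 <- makeAset(expr[, perm], tfab[, perm],
                    groups = rep("C", S)[perm])
  l1 <- assignSign(inferLinks(aset1, n_trees = 200, seed = 3), aset1)
  l2 <- assignSign(inferLinks(aset2, n_trees = 200, seed = 3), aset2)
  expect_equal(l1[order(l1$tf, l1$target), c("tf", "target", "score", "rho")],
               l2[order(l2$tf, l2$target), c("tf", "target", "score", "rho")],
               ignore_attr = TRUE)
})

test_that("assigned rho matches the textbook rank formula, ties included", {
  set.seed(13)
  S <- 15
  for (i in 1:20) {
    x <- sample(1:6, S, replace = TRUE) + 5        # plenty of ties
    y <- sample(1:6, S, replace = TRUE) + rnorm(S, sd = 0.3)
    tfab <- rbind(TFA = x, TFB = rnorm(S))
    colnames(tfab) <- paste0("S", 1:S)
    expr <- rbind(g = y); colnames(expr) <- colnames(tfab)
    links <- data.frame(tf = "TFA", target = "g", score = 1,
                        stringsAsFactors = FALSE)
    got <- suppressMessages(assignSign(links, makeAset(expr, tfab)))
    if (nrow(got)) expect_equal(got$rho, spearmanOracle(x, y),
                                tolerance = 1e-12)
  }
})
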