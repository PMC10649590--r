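test_that("rankedList sorts, validates and honours tie policies", {
  r <- rankedList(c(b = 1, a = 3, c = -2))
  expect_identical(names(r), c("a", "b", "c"))
  expect_error(rankedList(c(1, 2)), "named")
  expect_error(rankedList(c(a = 1, a = 2)), "duplicate")
  # stable ties keep input order; lexicographic re-sorts
  tied <- c(z = 1, m = 1, a = 1)
  expect_identical(names(rankedList(tied)), c("z", "m", "a"))
  expect_identical(names(rankedList(tied, "lexicographic")),
                   c("a", "m", "z"))
})

test_that("enrichment score matches the brute-force running sum", {
  for (i in 1:25) {
    set.seed(i)
    N <- sample(20:80, 1)
    r <- randomRanking(N, seed = i)
    k <- sample(2:(N %/% 3), 1)
    members <- sample(names(r), k)
    for (expo in c(0, 1)) {
      got <- enrichmentScore(r, members, exponent = expo)
      want <- bruteForceES(r, members, exponent = expo)
      expect_equal(got$es, want$es, tolerance = 1e-12)
      expect_setequal(got$leading_edge, want$leading_edge)
    }
  }
})

test_that("extreme sets give extreme scores", {
  r <- randomRanking(10, seed = 1, positive = TRUE)
  top <- enrichmentScore(r, names(r)[1])
  expect_equal(top$es, 1)
  expect_identical(top$leading_edge, names(r)[1])
  bottom <- enrichmentScore(r, names(r)[10])
  expect_equal(bottom$es, bruteForceES(r, names(r)[10])$es,
               tolerance = 1e-12)
  expect_lt(bottom$es, 0)
  expect_identical(bottom$leading_edge, names(r)[10])
  expect_error(enrichmentScore(r, "absent"), "no member")
  expect_error(enrichmentScore(r, names(r)), "whole ranking")
})

test_that("ES stays in [-1, 1] and negates under ranking reversal", {
  for (i in 1:20) {
    N <- 40
    set.seed(100 + i)
    sc <- sort(rnorm(N), decreasing = TRUE)          # distinct, symmetric use
    r <- rankedList(setNames(sc, sprintf("g%02d", 1:N)))
    rev_r <- rankedList(setNames(-sc, names(r)))     # reversed order
    members <- sample(names(r), 8)
    es_f <- enrichmentScore(r, members, exponent = 0)$es
    es_r <- enrichmentScore(rev_r, members, exponent = 0)$es
    expect_lte(abs(es_f), 1)
    expect_equal(abs(es_f), abs(es_r), tolerance = 1e-12)
    # sign flips unless the walk's extremes tie in magnitude, where the
    # earliest-position rule decides
    run <- bruteForceES(r, members, exponent = 0)
    hit <- names(r) %in% members
    inc <- 1 / sum(hit); dec <- 1 / (40 - sum(hit))
    walk <- cumsum(ifelse(hit, inc, -dec))
    if (abs(max(walk) + min(walk)) > 1e-9)
      expect_equal(es_f, -es_r, tolerance = 1e-12)
  }
})

test_that("permutation test is seeded, never returns p = 0, and is monotone in |ES|", {
  r <- randomRanking(200, seed = 2, positive = TRUE)
  a <- permutationTest(r, names(r)[1:10], n_perm = 500, seed = 42)
  b <- permutationTest(r, names(r)[1:10], n_perm = 500, seed = 42)
  expect_identical(a, b)
  expect_gt(a$p_nominal, 0)
  expect_gt(a$nes, 0)
  # front-loaded set has smaller p than a scattered set of the same size
  scattered <- names(r)[seq(5, 200, by = 20)]
  c <- permutationTest(r, scattered, n_perm = 500, seed = 42)
  expect_lte(a$p_nominal, c$p_nominal)
  # a perfect top-k set achieves the permutation floor
  expect_equal(a$p_nominal, 1 / (1 + a$n_same_sign))
  expect_lt(a$p_nominal, 0.005)
  expect_error(permutationTest(r, names(r)[1:5], n_perm = 50), "at least 100")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(c(1, 1)), c(1, 1))
  expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bhAdjust(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(4)
  p <- sort(runif(30))
  q <- bhAdjust(p)
  expect_true(all(diff(q) >= -1e-12))   # monotone on sorted input
  expect_true(all(q >= p))
})

test_that("runGSEA restricts, skips and orders correctly", {
  r <- randomRanking(300, seed = 5, positive = TRUE)
  coll <- list(
    strong = names(r)[1:20],
    weak = sample(names(r), 20),
    tiny = names(r)[1:2],
    with_aliens = c(names(r)[21:40], "not_in_ranking_1", "not_in_ranking_2"))
  out <- runGSEA(r, coll, n_perm = 300, seed = 1)
  expect_identical(out$skipped$set_id, "tiny")
  expect_identical(out$skipped$reason, "below min_size")
  res <- out$results
  expect_setequal(res$set_id, c("strong", "weak", "with_aliens"))
  expect_equal(res$set_size_used[res$set_id == "with_aliens"], 20L)
  expect_true(all(res$p_adjusted >= res$p_nominal))
  expect_true(!is.unsorted(res$p_adjusted))
  expect_true(res$significant[res$set_id == "strong"])
  expect_error(runGSEA(r, list(tiny = names(r)[1:2]), n_perm = 300, seed = 1),
               "size bounds")
})

test_that("leading-edge aggregation counts membership across results", {
  edges <- list(c("A", "B"), c("A", "C"), "A")
  expect_identical(leadingEdgeAnalysis(edges, fraction = 0.5), "A")
  expect_setequal(leadingEdgeAnalysis(list(c("X", "Y"))), c("X", "Y"))
  expect_length(leadingEdgeAnalysis(list(c("A"), c("B")), fraction = 1), 0L)
  # count-descending, then id order
  edges2 <- list(c("b", "a"), c("a", "b"), c("a", "c"), c("c", "b"))
  expect_identical(leadingEdgeAnalysis(edges2, fraction = 0.5),
                   c("a", "b", "c"))
  expect_error(leadingEdgeAnalysis(list(character())), "leading edge")
})

test_that("the engine agrees with fgsea on a shared instance", {
  skip_if_not_installed("fgsea")
  r <- randomRanking(500, seed = 8)
  sets <- list(s1 = names(r)[11:40], s2 = sample(names(r), 25))
  ours <- vapply(sets, function(s) enrichmentScore(r, s, exponent = 1)$es,
                 numeric(1))
  ref <- suppressWarnings(
    fgsea::fgsea(sets, stats = r, nperm = 200, gseaParam = 1))
  expect_equal(unname(ours[ref$pathway]), ref$ES, tolerance = 1e-6)
})
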