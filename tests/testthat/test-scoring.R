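# a tiny deterministic analysis setting: 3 pathways over few genes, small
# sample size so the permutation set is exhaustive, exact engine
tiny_setting <- function(seed = 5, delta = 3) {
  withr::with_seed(seed, {
    g1 <- PathwayGraph("pwA", c("A", "B", "C"),
                       data.frame(from = c("A", "B"), to = c("B", "C"),
                                  kind = "activation"))
    g2 <- PathwayGraph("pwB", c("A", "D"),
                       data.frame(from = "A", to = "D", kind = "inhibition"))
    g3 <- PathwayGraph("pwC", c("E", "F"),
                       data.frame(from = "E", to = "F", kind = "activation"))
    # pwD equalizes every gene's pathway frequency at 2, so the literal
    # frequency weight degenerates to Fn = 1 and P(A) tracks |T| alone
    g4 <- PathwayGraph("pwD", c("B", "C", "D", "E", "F"),
                       data.frame(from = "D", to = "E", kind = "activation"))
    coll <- PathwayCollection(list(g1, g2, g3, g4))
    genes <- c(geneUniverse(coll), paste0("x", 1:30))
    labels <- rep(c("control", "case"), each = 4)
    m <- matrix(rnorm(length(genes) * 8), nrow = length(genes),
                dimnames = list(genes, paste0("s", 1:8)))
    m[c("A", "B", "C"), labels == "case"] <-
      m[c("A", "B", "C"), labels == "case"] + delta
    list(coll = coll, data = ExpressionDataset(m, labels))
  })
}

test_that("the pathway score is the sum of effector reachabilities", {
  # star: A -> B, A -> C, A -> D; effectors B, C, D
  g <- PathwayGraph("star", LETTERS[1:4],
                    data.frame(from = "A", to = c("B", "C", "D"),
                               kind = "activation"))
  par <- manual_params(g, prob1 = c(0.05, 0.95, 0.95, 0.95),
                       prob_init = c(0.8, 0, 0, 0),
                       prob_active = c(0.3, 0.5, 0.7))
  sc <- pathwayScore(g, par, config = fopaConfig(engine = "exact"))
  chain <- buildChain(buildModel(g, par))
  probs <- vapply(c("B", "C", "D"), function(e)
    reachabilityExact(chain, e)$probability, numeric(1))
  expect_equal(sc$score, sum(probs), tolerance = 1e-9)
  expect_equal(sc$effector_probs, probs)
  expect_equal(sc$engine, "exact")
})

test_that("a single-effector pathway scores that effector's probability", {
  m <- two_gene_chain <- PathwayGraph("pair", c("A", "B"),
    data.frame(from = "A", to = "B", kind = "activation"))
  par <- manual_params(m, prob1 = c(0.05, 0.95), prob_init = c(0.7, 0),
                       prob_active = 0.6)
  sc <- pathwayScore(m, par, config = fopaConfig(engine = "exact"))
  expect_equal(unname(sc$score),
               reachabilityExact(buildChain(buildModel(m, par)),
                                 "B")$probability)
})

test_that("a pure cycle scores zero with a warning", {
  g <- PathwayGraph("cyc", c("A", "B"),
                    data.frame(from = c("A", "B"), to = c("B", "A"),
                               kind = "activation"))
  par <- manual_params(g, prob1 = c(0.95, 0.95), prob_init = c(0.5, 0.5),
                       prob_active = c(0.5, 0.5))
  expect_warning(sc <- pathwayScore(g, par), "no final effectors")
  expect_equal(sc$score, 0)
})

test_that("permutation p-values are deterministic and bounded", {
  ts <- tiny_setting()
  cfg <- fopaConfig(engine = "exact")
  p1 <- permutationPvalue(ts$data, ts$coll[["pwA"]], ts$coll,
                          n_perm = 40, seed = 2, config = cfg)
  p2 <- permutationPvalue(ts$data, ts$coll[["pwA"]], ts$coll,
                          n_perm = 40, seed = 2, config = cfg)
  expect_identical(p1, p2)
  expect_gte(p1, 0)
  expect_lte(p1, 1)
  expect_error(permutationPvalue(ts$data, ts$coll[["pwA"]], ts$coll,
                                 n_perm = 0), "at least 1")
})

test_that("jointly permuting samples and labels leaves score and p-value fixed", {
  # with exhaustive enumeration (choose(8,4) = 70 <= n_perm) and the exact
  # engine the whole analysis is a function of the labeled data only
  ts <- tiny_setting()
  cfg <- fopaConfig(engine = "exact")
  cfg$n_perm <- 70L
  res1 <- analyzeAll(ts$data, ts$coll, config = cfg, seed = 1)
  withr::with_seed(3, o <- sample(ncol(exprValues(ts$data))))
  d2 <- ExpressionDataset(exprValues(ts$data)[, o],
                          sampleClasses(ts$data)[o])
  res2 <- analyzeAll(d2, ts$coll, config = cfg, seed = 99)
  res2 <- res2[match(res1$pathway_id, res2$pathway_id), ]
  expect_equal(res1$score, res2$score, tolerance = 1e-12)
  expect_equal(res1$p_value, res2$p_value, tolerance = 1e-12)
})

test_that("the result table is ranked with tie-averaging", {
  ts <- tiny_setting()
  # duplicate pwC under another id: identical topology and genes gives
  # identical score and p-value, so the pair must share a mean rank
  dup <- PathwayGraph("pwC2", c("E", "F"),
                      data.frame(from = "E", to = "F", kind = "activation"))
  coll <- PathwayCollection(c(pathways(ts$coll), list(dup)))
  cfg <- fopaConfig(engine = "exact")
  cfg$n_perm <- 70L
  res <- analyzeAll(ts$data, coll, config = cfg, seed = 1)
  expect_equal(nrow(res), 5L)
  expect_true(!is.unsorted(res$p_value))
  expect_equal(sort(res$rank), res$rank)
  i <- match(c("pwC", "pwC2"), res$pathway_id)
  expect_equal(res$rank[i[1]], res$rank[i[2]])
  expect_equal(res$rank[i[1]] %% 1, 0.5)  # averaged over a 2-way tie
  expect_equal(res$rank_percentage, 100 * res$rank / 5)
  expect_error(analyzeAll(ts$data, PathwayCollection(list())), "empty")
})

test_that("duplicating an effector gene increases the score", {
  g <- PathwayGraph("one", c("A", "B"),
                    data.frame(from = "A", to = "B", kind = "activation"))
  g2 <- PathwayGraph("two", c("A", "B", "B2"),
                     data.frame(from = c("A", "A"), to = c("B", "B2"),
                                kind = "activation"))
  mk <- function(g, n) manual_params(
    g, prob1 = c(0.05, rep(0.95, n)), prob_init = c(0.7, rep(0, n)),
    prob_active = rep(0.6, n))
  s1 <- pathwayScore(g, mk(g, 1), config = fopaConfig(engine = "exact"))
  s2 <- pathwayScore(g2, mk(g2, 2), config = fopaConfig(engine = "exact"))
  expect_gt(s2$score, s1$score)
})

test_that("the permutation p-value concentrates low for a true signal", {
  ts <- tiny_setting(seed = 8, delta = 4)
  cfg <- fopaConfig(engine = "exact")
  p_sig <- permutationPvalue(ts$data, ts$coll[["pwA"]], ts$coll,
                             n_perm = 70, seed = 4, config = cfg)
  expect_lte(p_sig, 0.1)
})
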