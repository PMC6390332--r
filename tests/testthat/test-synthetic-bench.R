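test_that("random pathways respect their construction contract", {
  g0 <- randomPathway(5, 0, seed = 1)
  expect_equal(finalEffectors(g0), sort(g0@nodes))
  g1 <- randomPathway(8, 12, inhibition_fraction = 0, seed = 2)
  expect_true(all(edgePolarity(edgeTable(g1)$kind) == "activating"))
  expect_identical(edgeTable(randomPathway(8, 12, 0.25, seed = 3)),
                   edgeTable(randomPathway(8, 12, 0.25, seed = 3)))
  expect_error(randomPathway(3, 7, seed = 1), "possible directed edges")
  for (s in 1:30) {
    g <- randomPathway(7, 10, inhibition_fraction = 0.3, seed = s)
    expect_equal(nrow(edgeTable(g)), 10L)
    expect_gte(length(finalEffectors(g)), 1L)     # sink enforced
    ed <- edgeTable(g)
    expect_false(any(ed$from == ed$to))           # simple graph
    expect_false(any(duplicated(paste(ed$from, ed$to))))
    expect_equal(sum(edgePolarity(ed$kind) == "inhibiting"), 3L)
  }
})

test_that("simulated expression has the promised shape and null behavior", {
  sp <- simulationSpec(n_pathways = 5, genes_per_pathway = 6,
                       n_filler = 40, effect_size = 0, seed = 9)
  coll <- simulateCollection(sp)
  dat <- simulateExpression(sp, coll)
  expect_equal(dim(exprValues(dat)),
               c(length(geneUniverse(coll)) + 40L,
                 sp$n_control + sp$n_case))
  # no signal: raw p < 0.05 at about the nominal rate
  fr <- mean(moderatedT(dat)$p < 0.05)
  expect_lt(fr, 0.12)
  expect_identical(exprValues(simulateExpression(sp, coll)),
                   exprValues(dat))
})

test_that("an extreme shift makes every shifted target gene DE", {
  sp <- simulationSpec(n_pathways = 4, genes_per_pathway = 6,
                       de_fraction = 1, effect_size = 10, n_filler = 60,
                       seed = 3)
  hits <- vapply(1:5, function(r) {
    sp$seed <- 100 + r
    coll <- simulateCollection(sp)
    dat <- simulateExpression(sp, coll)
    tg <- coll[[sp$target_pathway_id]]@nodes
    mt <- moderatedT(dat)
    q <- adjustFDR(setNames(mt$p, mt$gene))
    mean(tg %in% flagDE(q, 0.05))
  }, numeric(1))
  expect_gte(mean(hits), 0.99)
})

test_that("decoy AUC follows the rank statistic", {
  r <- data.frame(p_value = c(0.01, 0.02), score = c(1, 1))
  d <- data.frame(p_value = c(0.5, 0.9), score = c(1, 1))
  expect_equal(decoyAUC(r, d), 1)
  expect_equal(decoyAUC(r, r), 0.5)
  # interleaved ranks 1,3 (real) vs 2,4 (decoy): 3 of 4 pairs won
  r2 <- data.frame(p_value = c(0.1, 0.3), score = 0)
  d2 <- data.frame(p_value = c(0.2, 0.4), score = 0)
  expect_equal(decoyAUC(r2, d2), 0.75)
  expect_error(decoyAUC(r2[0, ], d2), "non-empty")
})

test_that("target metrics compute the published summary formulas", {
  res <- data.frame(target_rank = c(1, 2, 3), target_p = c(0.01, 0.2, 0.5),
                    n_pathways = 100)
  tm <- targetMetrics(res)
  expect_equal(tm$median_rank_pct, 2)
  expect_equal(tm$mean_reciprocal_rank, (1 + 1 / 2 + 1 / 3) / 3)
  expect_equal(tm$median_target_p, 0.2)
  one <- targetMetrics(data.frame(target_rank = 4, target_p = 0.3,
                                  n_pathways = 10))
  expect_equal(one$median_rank_pct, 40)
  expect_equal(one$mean_reciprocal_rank, 0.25)
  expect_error(targetMetrics(res[0, ]), "empty")
})

test_that("degenerate thresholds bound the false-positive protocol", {
  ts_coll <- PathwayCollection(list(
    PathwayGraph("q1", c("A", "B"),
                 data.frame(from = "A", to = "B", kind = "activation")),
    PathwayGraph("q2", c("A", "C"),
                 data.frame(from = "A", to = "C", kind = "activation"))))
  withr::with_seed(2, {
    m <- matrix(rnorm(33 * 8), nrow = 33,
                dimnames = list(c(geneUniverse(ts_coll), paste0("f", 1:30)),
                                paste0("s", 1:8)))
    dat <- ExpressionDataset(m, rep(c("control", "case"), each = 4))
  })
  cfg <- fopaConfig(engine = "exact")
  cfg$n_perm <- 20L
  expect_equal(as.numeric(fpRateProtocol(dat, ts_coll, n_trials = 2,
                                         threshold = 0, seed = 1,
                                         config = cfg)), 0)
  expect_equal(as.numeric(fpRateProtocol(dat, ts_coll, n_trials = 2,
                                         threshold = 1.01, seed = 1,
                                         config = cfg)), 1)
})

test_that("zero perturbation reproduces the unperturbed significance call", {
  ts_coll <- PathwayCollection(list(
    PathwayGraph("r1", c("A", "B"),
                 data.frame(from = "A", to = "B", kind = "activation")),
    PathwayGraph("r2", c("B", "C"),
                 data.frame(from = "B", to = "C", kind = "activation"))))
  withr::with_seed(4, {
    m <- matrix(rnorm(23 * 8), nrow = 23,
                dimnames = list(c(geneUniverse(ts_coll), paste0("f", 1:20)),
                                paste0("s", 1:8)))
    dat <- ExpressionDataset(m, rep(c("control", "case"), each = 4))
  })
  cfg <- fopaConfig(engine = "exact")
  cfg$n_perm <- 20L
  rc <- robustnessCurve(ts_coll[["r1"]], dat, ts_coll, fractions = 0,
                        modes = "remove", n_reps = 3, seed = 7,
                        config = cfg)
  expect_equal(rc$similarity, 1)
  expect_true(all(rc$similarity >= 0 & rc$similarity <= 1))
})
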