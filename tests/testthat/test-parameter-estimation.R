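test_that("the DE-relation weight takes exactly {a, 2a, 3a}", {
  a <- 1 / 6
  expect_equal(diffTerm(FALSE, FALSE, a), 1 / 6)
  expect_equal(diffTerm(TRUE, FALSE, a), 1 / 3)
  expect_equal(diffTerm(FALSE, TRUE, a), 1 / 3)
  expect_equal(diffTerm(TRUE, TRUE, a), 1 / 2)
  expect_error(diffTerm(TRUE, TRUE, 0.5), "1/3")
  expect_error(diffTerm(TRUE, TRUE, 0), "1/3")
  # switching one gene to DE never decreases the weight
  for (aw in c(0.05, 1 / 6, 1 / 3)) {
    expect_gte(diffTerm(TRUE, FALSE, aw), diffTerm(FALSE, FALSE, aw))
    expect_gte(diffTerm(TRUE, TRUE, aw), diffTerm(TRUE, FALSE, aw))
  }
})

test_that("interaction probability counts pathways correctly", {
  # A,B co-occur in 3 pathways, activating A->B in 2 of them
  mk <- function(id, edges) PathwayGraph(id, c("A", "B", "C"), edges)
  e_act <- data.frame(from = "A", to = "B", kind = "activation")
  e_none <- data.frame(from = "A", to = "C", kind = "activation")
  coll <- PathwayCollection(list(
    mk("p1", e_act), mk("p2", e_act), mk("p3", e_none)))
  expect_equal(interactionProbability(coll, "A", "B", "activating"), 2 / 3)
  expect_equal(interactionProbability(coll, "A", "B", "inhibiting"), 0)
  solo <- PathwayCollection(list(mk("only", e_act)))
  expect_equal(interactionProbability(solo, "A", "B", "activating"), 1)
  expect_error(interactionProbability(solo, "A", "Z", "activating"),
               "co-occur in no pathway")
})

test_that("interaction probability agrees with the nested-loop oracle", {
  for (s in 1:50) {
    coll <- random_collection(s)
    uni <- geneUniverse(coll)
    pairs <- expand.grid(A = uni[1:3], B = uni[2:4],
                         stringsAsFactors = FALSE)
    for (k in seq_len(nrow(pairs))) {
      A <- pairs$A[k]; B <- pairs$B[k]
      if (A == B) next
      for (pol in c("activating", "inhibiting")) {
        oracle <- brute_interaction_prob(coll, A, B, pol)
        if (is.na(oracle)) {
          expect_error(interactionProbability(coll, A, B, pol), "co-occur")
        } else {
          expect_equal(interactionProbability(coll, A, B, pol), oracle)
        }
      }
    }
  }
})

test_that("edge parameters follow the three evidence products", {
  expect_equal(unname(edgeParameters(0.5, 0.4, 0.5, "activating")), 0.1)
  expect_equal(unname(edgeParameters(0.5, 0, 0.9, "activating")), 0)
  inh <- edgeParameters(1 / 3, 0.3, 0.8, "inhibiting")
  expect_equal(unname(inh["prob_inhibit1"]), 0.8)
  expect_equal(unname(inh["prob_inhibit2"]), 1 / 3 * 0.3 * 0.8)
})

test_that("initialization parameters mirror the DE flag", {
  expect_equal(unname(initParameters(FALSE, 0.05, 0.3)), c(0.95, 0.05, 0.3))
  expect_equal(unname(initParameters(TRUE, 0.05, 0.3)), c(0.05, 0.95, 0.3))
  expect_equal(unname(initParameters(TRUE, 0, 0.1))[1:2], c(0, 1))
  expect_error(initParameters(TRUE, 0.6), "0.5")
})

test_that("computeParameters covers every edge and node deterministically", {
  coll <- random_collection(21)
  g <- coll[["p01"]]
  stats <- data.frame(gene = geneUniverse(coll),
                      is_de = seq_along(geneUniverse(coll)) %% 3 == 0,
                      P = seq(0, 1, length.out = length(geneUniverse(coll))))
  par <- computeParameters(g, stats, coll)
  expect_equal(nrow(edgeParams(par)), nrow(edgeTable(g)))
  expect_equal(nrow(geneParams(par)), length(g@nodes))
  act <- edgeParams(par)$polarity == "activating"
  expect_true(all(!is.na(edgeParams(par)$prob_active[act])))
  expect_true(all(!is.na(edgeParams(par)$prob_inhibit1[!act])))
  expect_equal(geneParams(par)$prob1 + geneParams(par)$prob2,
               rep(1, length(g@nodes)))
  # exact identities from the evidence products
  ep <- edgeParams(par)
  P <- setNames(stats$P, stats$gene)
  expect_equal(ep$prob_active[act],
               (ep$diff * P[ep$from] * ep$p_edge)[act], ignore_attr = TRUE)
  expect_equal(ep$prob_inhibit1[!act], ep$p_edge[!act])
  expect_equal(ep$prob_inhibit2[!act],
               (ep$diff * P[ep$from] * ep$p_edge)[!act], ignore_attr = TRUE)
  # determinism
  expect_identical(computeParameters(g, stats, coll), par)
  # membership requirement
  lone <- PathwayGraph("absent", g@nodes, edgeTable(g))
  expect_error(computeParameters(lone, stats, coll), "not in the collection")
})

test_that("all emitted probabilities lie in [0,1] on random inputs", {
  for (s in 1:20) {
    coll <- random_collection(s + 100)
    uni <- geneUniverse(coll)
    stats <- withr::with_seed(s, data.frame(
      gene = uni, is_de = runif(length(uni)) < 0.3, P = runif(length(uni))))
    for (id in names(coll)) {
      par <- computeParameters(coll[[id]], stats, coll)
      ep <- edgeParams(par); gp <- geneParams(par)
      vals <- c(ep$p_edge, ep$prob_active, ep$prob_inhibit1,
                ep$prob_inhibit2, gp$prob1, gp$prob2, gp$prob_init)
      vals <- vals[!is.na(vals)]
      expect_true(all(vals >= 0 & vals <= 1))
    }
  }
})

test_that("zero gene probabilities force zero activation probabilities", {
  coll <- random_collection(33)
  g <- coll[["p02"]]
  stats <- data.frame(gene = geneUniverse(coll), is_de = FALSE, P = 0)
  par <- computeParameters(g, stats, coll)
  act <- edgeParams(par)$polarity == "activating"
  expect_true(all(edgeParams(par)$prob_active[act] == 0))
})
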