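make_dataset <- function(seed = 42, n_genes = 30, n1 = 5, n2 = 5) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * (n1 + n2)), nrow = n_genes,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n1 + n2))))
    ExpressionDataset(m, rep(c("control", "case"), c(n1, n2)))
  })
}

test_that("a constant gene gets T = 0, p = 1", {
  d <- make_dataset()
  m <- exprValues(d)
  m[1, ] <- 5
  d2 <- ExpressionDataset(m, sampleClasses(d))
  mt <- moderatedT(d2)
  expect_equal(mt$T[1], 0)
  expect_equal(mt$p[1], 1)
})

test_that("with shrinkage disabled the ordinary pooled t is recovered", {
  d <- make_dataset(7)
  mt <- moderatedT(d, prior_df = 0)
  x <- exprValues(d)
  cls <- sampleClasses(d)
  ordinary <- apply(x, 1, function(r)
    unname(t.test(r[cls == "case"], r[cls == "control"],
                  var.equal = TRUE)$statistic))
  expect_equal(mt$T, unname(ordinary), tolerance = 1e-12)
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  d <- make_dataset(seed = 123, n_genes = 60, n1 = 3, n2 = 3)
  mt <- moderatedT(d)
  design <- cbind(1, sampleClasses(d) == "case")
  fit <- limma::eBayes(limma::lmFit(exprValues(d), design))
  expect_equal(mt$T, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(mt$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 1e-6)
})

test_that("moderated t is calibrated under the null", {
  # exchangeable classes: raw p < 0.05 should occur at ~5%
  fracs <- vapply(1:20, function(s) {
    d <- make_dataset(seed = 1000 + s, n_genes = 1000, n1 = 10, n2 = 10)
    mean(moderatedT(d)$p < 0.05)
  }, numeric(1))
  expect_gte(mean(fracs), 0.03)
  expect_lte(mean(fracs), 0.07)
})

test_that("dataset construction enforces its invariants", {
  m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
  expect_error(ExpressionDataset(m, rep("control", 5)), "at least 2")
  expect_error(ExpressionDataset(m, c(rep("control", 2), rep("case", 3))[c(1, 1, 2, 3, 4)]),
               NA)
  mm <- m; mm[2, 3] <- NA
  expect_warning(ExpressionDataset(mm, rep(c("control", "case"), c(2, 3))),
                 "missing values")
  expect_error(ExpressionDataset(m, rep(c("sick", "well"), c(2, 3))), "label")
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(adjustFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustFDR(0.2), 0.2)
  expect_equal(adjustFDR(c(1, 1)), c(1, 1))
  # hand-computed: sorted p * n / rank, cummin from the right
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(adjustFDR(p),
               c(0.02, 0.053333333333333337, 0.053333333333333337, 0.8),
               tolerance = 1e-12)
  expect_error(adjustFDR(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH output is invariant under input permutation", {
  withr::with_seed(5, {
    p <- runif(40)
    for (i in 1:5) {
      o <- sample(40)
      expect_equal(sort(adjustFDR(p[o])), sort(adjustFDR(p)))
    }
  })
})

test_that("DE flagging applies the strict cutoff", {
  expect_equal(flagDE(c(g1 = 0.04, g2 = 0.06), v = 0.05), "g1")
  expect_length(flagDE(c(a = 1, b = 1)), 0L)
  expect_equal(flagDE(c(x = 0.049999)), "x")  # default v = 0.05
  expect_error(flagDE(c(0.1), v = 1.5), "\\(0, 1\\)")
})

test_that("pathway frequencies match a brute-force recount", {
  for (s in 1:10) {
    coll <- random_collection(s)
    expect_equal(geneFrequencies(coll), brute_frequencies(coll))
  }
  p1 <- PathwayGraph("a", c("X", "Y"))
  p2 <- PathwayGraph("b", c("X", "Z"))
  p3 <- PathwayGraph("c", c("Z"))
  f <- geneFrequencies(PathwayCollection(list(p1, p2, p3)))
  expect_equal(f[["X"]], 2L)
  expect_equal(f[["Z"]], 2L)
  expect_equal(f[["Y"]], 1L)
})

test_that("frequency weights hit the documented endpoints", {
  f <- c(a = 1, b = 3, c = 5)
  w <- frequencyWeight(f, "literal")
  expect_equal(unname(w), c(0, sqrt(0.5), 1))
  wi <- frequencyWeight(f, "inverted")
  expect_equal(unname(wi), c(1, sqrt(0.5), 0))
  expect_equal(unname(frequencyWeight(c(x = 2, y = 2))), c(1, 1))
})

test_that("gene probability stays in [0,1] in both scalings", {
  expect_equal(unname(geneProbability(c(A = 0), c(A = 0.9), "clip")[1]), 0)
  expect_equal(unname(geneProbability(c(A = -3), c(A = 0.5), "clip")[1]), 1)
  expect_equal(unname(geneProbability(c(A = 2, B = 5), c(A = 0.5, B = 1),
                                      "max_normalize")[1]), 0.2)
  withr::with_seed(9, for (i in 1:20) {
    T <- rnorm(15, sd = 10)
    Fn <- runif(15)
    names(T) <- names(Fn) <- paste0("g", 1:15)
    for (sc in c("max_normalize", "clip")) {
      P <- geneProbability(T, Fn, sc)
      expect_true(all(P >= 0 & P <= 1))
    }
  })
  expect_equal(unname(geneProbability(c(A = 0, B = 0), c(A = 1, B = 1))),
               c(0, 0))
})

test_that("the assembled statistic table covers pathway and measured genes", {
  coll <- random_collection(3)
  d <- make_dataset(11, n_genes = 8)
  # rename half the measured genes into the collection's universe
  m <- exprValues(d)
  uni <- geneUniverse(coll)
  rownames(m)[seq_len(4)] <- uni[seq_len(4)]
  d2 <- ExpressionDataset(m, sampleClasses(d))
  tab <- buildGeneStats(d2, coll)
  expect_setequal(tab$gene, union(rownames(m), uni))
  off <- setdiff(uni, rownames(m))
  expect_true(all(tab$T[tab$gene %in% off] == 0))
  expect_true(all(!tab$is_de[tab$gene %in% off]))
  expect_true(all(tab$q >= 0 & tab$q <= 1))
  expect_true(all(tab$Fn >= 0 & tab$Fn <= 1))
  expect_true(all(tab$P >= 0 & tab$P <= 1))
  expect_equal(tab$is_de, tab$q < 0.05)
})
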