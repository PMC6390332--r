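test_that("minimal KGML parses into nodes and a typed edge", {
  g <- parseKGML(kgml_minimal())
  expect_s4_class(g, "PathwayGraph")
  expect_setequal(g@nodes, c("hsa:10", "hsa:20"))
  expect_equal(nrow(edgeTable(g)), 1L)
  expect_equal(edgeTable(g)$kind, "activation")
  expect_equal(pathwayId(g), "path:demo01")
})

test_that("multi-gene entries expand to one node per gene with inherited edges", {
  g <- parseKGML(kgml_multi_gene())
  expect_setequal(g@nodes, c("hsa:10", "hsa:11", "hsa:20"))
  ed <- edgeTable(g)
  expect_equal(nrow(ed), 2L)
  expect_setequal(ed$from, c("hsa:10", "hsa:11"))
  expect_true(all(ed$to == "hsa:20"))
  expect_true(all(ed$kind == "activation"))
})

test_that("malformed and structurally broken KGML raise errors", {
  expect_error(parseKGML("<pathway><entry id="), "parse error")
  bad <- sub('entry1="1"', 'entry1="99"', kgml_minimal())
  expect_error(parseKGML(bad), "unknown entry id 99")
})

test_that("no-polarity relations are dropped and logged", {
  g <- parseKGML(kgml_compound())
  expect_false(any(edgeTable(g)$from == "hsa:10" & edgeTable(g)$to == "hsa:20"))
  expect_true(any(grepl("no polarity", normalizationLog(g))))
})

test_that("normalization removes non-gene nodes with sign composition", {
  g <- parseKGML(kgml_compound())
  expect_equal(nonGeneNodes(g), "cpd:C00001")
  n <- normalizeGraph(g)
  expect_length(nonGeneNodes(n), 0L)
  ed <- edgeTable(n)
  # activating hop then inhibiting hop -> net inhibition
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$from, "hsa:10")
  expect_equal(ed$to, "hsa:20")
  expect_equal(ed$kind, "inhibition")
})

test_that("normalization merges duplicate-gene entries into one node", {
  # two entries annotated with the same gene, each with an edge to C
  xml <- paste0('<?xml version="1.0"?>\n<pathway name="path:dup">\n',
    '<entry id="1" name="hsa:1" type="gene"/>\n',
    '<entry id="2" name="hsa:1" type="gene"/>\n',
    '<entry id="3" name="hsa:3" type="gene"/>\n',
    '<relation entry1="1" entry2="3" type="PPrel">',
    '<subtype name="activation"/></relation>\n',
    '<relation entry1="2" entry2="3" type="PPrel">',
    '<subtype name="activation"/></relation>\n</pathway>\n')
  g <- parseKGML(xml)
  expect_setequal(g@nodes, c("hsa:1", "hsa:3"))
  expect_true(any(grepl("merged duplicate", normalizationLog(g))))
  n <- normalizeGraph(g)
  expect_equal(nrow(edgeTable(n)), 1L)  # duplicate edge collapsed
})

test_that("normalization is idempotent and identity on clean graphs", {
  g <- chain_graph()
  n1 <- normalizeGraph(g)
  expect_equal(edgeTable(n1), edgeTable(g))
  expect_equal(n1@nodes, g@nodes)
  n2 <- normalizeGraph(n1)
  expect_equal(edgeTable(n2), edgeTable(n1))
  expect_equal(n2@nodes, n1@nodes)
})

test_that("self-edges are dropped during normalization", {
  g <- PathwayGraph("self", c("A", "B"),
                    data.frame(from = c("A", "A"), to = c("A", "B"),
                               kind = "activation"))
  n <- normalizeGraph(g)
  expect_equal(nrow(edgeTable(n)), 1L)
  expect_true(any(grepl("self-edge", normalizationLog(n))))
})

test_that("final effectors are the out-degree-0 genes, sorted", {
  expect_equal(finalEffectors(chain_graph()), "C")
  expect_equal(finalEffectors(iso_graph()), "A")
  cyc <- PathwayGraph("cyc", c("A", "B"),
                      data.frame(from = c("A", "B"), to = c("B", "A"),
                                 kind = "activation"))
  expect_warning(eff <- finalEffectors(cyc), "no out-degree-0")
  expect_length(eff, 0L)
})

test_that("decoys preserve structure and are deterministic", {
  uni <- paste0("u", 1:50)
  for (s in 1:100) {
    g <- randomPathway(6, 8, inhibition_fraction = 0.4, seed = s)
    d1 <- makeDecoy(g, uni, seed = s)
    d2 <- makeDecoy(g, uni, seed = s)
    expect_identical(edgeTable(d1), edgeTable(d2))
    expect_length(d1@nodes, length(g@nodes))
    expect_equal(nrow(edgeTable(d1)), nrow(edgeTable(g)))
    expect_equal(sort(table(edgeTable(d1)$kind)),
                 sort(table(edgeTable(g)$kind)))
    # degree sequence invariant under the relabeling
    deg <- function(x) sort(tabulate(match(
      c(edgeTable(x)$from, edgeTable(x)$to), x@nodes), length(x@nodes)))
    expect_equal(deg(d1), deg(g))
    expect_true(all(d1@nodes %in% uni))
  }
})

test_that("decoy generation rejects an undersized universe", {
  g <- chain_graph()
  expect_error(makeDecoy(g, c("x", "y"), seed = 1), "smaller than")
})

test_that("perturbation honors fraction, mode and determinism", {
  g <- randomPathway(8, 10, inhibition_fraction = 0.3, seed = 3)
  expect_identical(edgeTable(perturbGraph(g, 0, "remove", seed = 1)),
                   edgeTable(g))
  gr <- perturbGraph(g, 0.5, "remove", seed = 2)
  expect_equal(nrow(edgeTable(gr)), 5L)
  gw <- perturbGraph(g, 0.5, "rewire", seed = 2)
  expect_equal(nrow(edgeTable(gw)), 10L)
  expect_setequal(gw@nodes, g@nodes)
  expect_identical(edgeTable(perturbGraph(g, 0.5, "rewire", seed = 2)),
                   edgeTable(gw))
  expect_error(perturbGraph(g, 1.2, "remove", seed = 1), "fraction")
  # removal never increases, rewiring preserves, over many draws
  for (s in 1:25) {
    fr <- runif(1)
    expect_lte(nrow(edgeTable(perturbGraph(g, fr, "remove", seed = s))),
               nrow(edgeTable(g)))
    expect_equal(nrow(edgeTable(perturbGraph(g, fr, "rewire", seed = s))),
                 nrow(edgeTable(g)))
  }
})

test_that("TSV edge-list dialect round-trips a collection", {
  coll <- random_collection(7)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePathwayTSV(coll, f)
  back <- readPathwayTSV(f)
  expect_equal(names(back), names(coll))
  for (id in names(coll)) {
    expect_setequal(back[[id]]@nodes, coll[[id]]@nodes)
    expect_equal(edgeTable(back[[id]]), edgeTable(coll[[id]]))
  }
})
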