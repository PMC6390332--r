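# shared fixtures: tiny graphs, collections and hand-built parameter sets

chain_graph <- function(id = "chain") {
  # A -> B -| C
  PathwayGraph(id, c("A", "B", "C"),
               data.frame(from = c("A", "B"), to = c("B", "C"),
                          kind = c("activation", "inhibition"),
                          stringsAsFactors = FALSE))
}

iso_graph <- function(id = "iso", gene = "A") PathwayGraph(id, gene)

# ModelParameters built directly from probability vectors (engine tests
# need full control over every probability)
manual_params <- function(g, prob1, prob_init, prob_active = numeric(),
                          prob_inhibit1 = numeric(),
                          prob_inhibit2 = numeric(),
                          alpha_weight = 1 / 6, alpha_error = 0.05) {
  ed <- edgeTable(g)
  pol <- if (nrow(ed)) edgePolarity(ed$kind) else character()
  act <- pol == "activating"
  pa <- rep(NA_real_, nrow(ed)); pi1 <- pa; pi2 <- pa
  pa[act] <- prob_active
  pi1[!act] <- prob_inhibit1
  pi2[!act] <- prob_inhibit2
  edges <- data.frame(from = ed$from, to = ed$to, kind = ed$kind,
                      polarity = pol, diff = rep(NA_real_, nrow(ed)),
                      p_edge = rep(NA_real_, nrow(ed)),
                      prob_active = pa, prob_inhibit1 = pi1,
                      prob_inhibit2 = pi2, stringsAsFactors = FALSE)
  nodes <- g@nodes
  genes <- data.frame(gene = nodes, is_de = prob1 < 0.5,
                      prob1 = prob1, prob2 = 1 - prob1,
                      prob_init = prob_init, stringsAsFactors = FALSE)
  new("ModelParameters", edges = edges, genes = genes,
      alphaWeight = alpha_weight, alphaError = alpha_error)
}

# random pathway + random parameters, for engine cross-checks
random_model <- function(seed, n_genes = 6, n_edges = 7,
                         inhibition_fraction = 0.3) {
  g <- randomPathway(n_genes, n_edges, inhibition_fraction, seed = seed,
                     id = sprintf("rand%03d", seed))
  withr::with_seed(seed + 1000L, {
    ed <- edgeTable(g)
    act <- edgePolarity(ed$kind) == "activating"
    params <- manual_params(
      g,
      prob1 = runif(length(g@nodes)),
      prob_init = runif(length(g@nodes)),
      prob_active = runif(sum(act)),
      prob_inhibit1 = runif(sum(!act)),
      prob_inhibit2 = runif(sum(!act)))
    list(graph = g, params = params, model = buildModel(g, params))
  })
}

random_collection <- function(seed, n_pathways = 4, n_genes = 5,
                              n_edges = 6, pool = paste0("G", 1:12)) {
  withr::with_seed(seed, {
    graphs <- lapply(seq_len(n_pathways), function(k)
      randomPathway(n_genes, n_edges, inhibition_fraction = 0.4,
                    seed = sample.int(1e6, 1),
                    genes = sample(pool, n_genes),
                    id = sprintf("p%02d", k)))
    PathwayCollection(graphs)
  })
}

# independent nested-loop oracles
brute_frequencies <- function(collection) {
  uni <- geneUniverse(collection)
  out <- setNames(integer(length(uni)), uni)
  for (gene in uni)
    for (p in pathways(collection))
      if (gene %in% p@nodes) out[gene] <- out[gene] + 1L
  out
}

brute_interaction_prob <- function(collection, A, B, polarity) {
  co <- 0; hit <- 0
  for (p in pathways(collection)) {
    if (!(A %in% p@nodes) || !(B %in% p@nodes)) next
    co <- co + 1
    found <- FALSE
    ed <- edgeTable(p)
    for (i in seq_len(nrow(ed)))
      if (ed$from[i] == A && ed$to[i] == B &&
          edgePolarity(ed$kind[i]) == polarity) found <- TRUE
    if (found) hit <- hit + 1
  }
  if (co == 0) return(NA_real_)
  hit / co
}

# minimal KGML documents
kgml_minimal <- function() {
  paste0('<?xml version="1.0"?>\n',
    '<pathway name="path:demo01" org="hsa" number="01" title="Demo">\n',
    '<entry id="1" name="hsa:10" type="gene"/>\n',
    '<entry id="2" name="hsa:20" type="gene"/>\n',
    '<relation entry1="1" entry2="2" type="PPrel">',
    '<subtype name="activation" value="--&gt;"/></relation>\n',
    '</pathway>\n')
}

kgml_multi_gene <- function() {
  paste0('<?xml version="1.0"?>\n',
    '<pathway name="path:demo02">\n',
    '<entry id="1" name="hsa:10 hsa:11" type="gene"/>\n',
    '<entry id="2" name="hsa:20" type="gene"/>\n',
    '<relation entry1="1" entry2="2" type="PPrel">',
    '<subtype name="activation" value="--&gt;"/></relation>\n',
    '</pathway>\n')
}

kgml_compound <- function() {
  # A -> (compound) -| B plus a no-polarity (binding) relation
  paste0('<?xml version="1.0"?>\n',
    '<pathway name="path:demo03">\n',
    '<entry id="1" name="hsa:10" type="gene"/>\n',
    '<entry id="2" name="cpd:C00001" type="compound"/>\n',
    '<entry id="3" name="hsa:20" type="gene"/>\n',
    '<relation entry1="1" entry2="2" type="PCrel">',
    '<subtype name="activation" value="--&gt;"/></relation>\n',
    '<relation entry1="2" entry2="3" type="PCrel">',
    '<subtype name="inhibition" value="--|"/></relation>\n',
    '<relation entry1="1" entry2="3" type="PPrel">',
    '<subtype name="binding/association" value="---"/></relation>\n',
    '</pathway>\n')
}
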