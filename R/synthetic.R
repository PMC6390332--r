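#' Simulation specification
#'
#' Bundles the study conditions for the synthetic benchmark: a collection
#' of random pathways sharing genes from a common pool, and a two-class
#' expression matrix in which a designated target pathway carries the
#' differential signal.  Defaults describe the desk-scale study: 20
#' pathways of 12 genes with about 15 edges each (density 15/132), 20%
#' inhibiting edges, 30% of the target pathway's genes shifted by 1.5
#' noise SDs in cases, and 10 control vs 10 case samples.
#'
#' @param n_pathways Number of pathways in the collection.
#' @param genes_per_pathway Genes per pathway, drawn from a shared pool of
#'   `gene_pool_factor * genes_per_pathway` genes.
#' @param edge_density Fraction of the `n * (n-1)` possible directed edges.
#' @param inhibition_fraction Fraction of edges in the inhibition family.
#' @param target_pathway_id Identifier of the perturbed pathway.
#' @param de_fraction Fraction of target-pathway genes given a mean shift.
#' @param effect_size Mean shift in case samples, in units of `noise_sd`.
#' @param n_control,n_case Samples per class.
#' @param noise_sd Standard deviation of the Gaussian baseline expression.
#' @param n_filler Off-pathway filler genes added to the expression matrix.
#' @param gene_pool_factor Pool size multiplier controlling pathway
#'   overlap (hence the spread of the frequency weight Fn).
#' @param seed Integer seed.
#' @return A list of class `"fopa_sim_spec"`.
#' @export
simulationSpec <- function(n_pathways = 20L, genes_per_pathway = 12L,
                           edge_density = 15 / 132,
                           inhibition_fraction = 0.2,
                           target_pathway_id = "pw01",
                           de_fraction = 0.3, effect_size = 1.5,
                           n_control = 10L, n_case = 10L, noise_sd = 1,
                           n_filler = 500L, gene_pool_factor = 5L,
                           seed = 1L) {
  spec <- list(n_pathways = as.integer(n_pathways),
               genes_per_pathway = as.integer(genes_per_pathway),
               edge_density = edge_density,
               inhibition_fraction = inhibition_fraction,
               target_pathway_id = target_pathway_id,
               de_fraction = de_fraction, effect_size = effect_size,
               n_control = as.integer(n_control),
               n_case = as.integer(n_case),
               noise_sd = noise_sd, n_filler = as.integer(n_filler),
               gene_pool_factor = as.integer(gene_pool_factor),
               seed = as.integer(seed))
  with(spec, {
    if (n_pathways < 1L || genes_per_pathway < 1L || n_control < 2L ||
        n_case < 2L || n_filler < 0L)
      stop("counts must be positive (>= 2 samples per class)")
    if (edge_density < 0 || edge_density > 1 || inhibition_fraction < 0 ||
        inhibition_fraction > 1 || de_fraction < 0 || de_fraction > 1)
      stop("fractions must lie in [0, 1]")
    if (effect_size < 0 || noise_sd <= 0)
      stop("'effect_size' must be >= 0 and 'noise_sd' > 0")
  })
  structure(spec, class = "fopa_sim_spec")
}

#' Generate a random pathway topology
#'
#' Draws a simple directed graph without self-edges:
#' `floor(inhibition_fraction * n_edges)` edges are inhibiting, the rest
#' activating.  At least one out-degree-0 node (a final effector) is
#' guaranteed by re-orienting edges out of a chosen node when necessary.
#' Deterministic given the seed.
#'
#' @param n_genes Number of genes.
#' @param n_edges Number of edges (`<= n_genes * (n_genes - 1)`).
#' @param inhibition_fraction Fraction of inhibiting edges.
#' @param seed Integer seed.
#' @param genes Optional gene labels (default `g01 ...`).
#' @param id Pathway identifier.
#' @return A normalized [PathwayGraph-class].
#' @export
randomPathway <- function(n_genes, n_edges, inhibition_fraction = 0,
                          seed = 1L, genes = NULL,
                          id = "random_pathway") {
  if (n_edges > n_genes * (n_genes - 1L))
    stop("n_edges exceeds the number of possible directed edges")
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(n_genes))
  stopifnot(length(genes) == n_genes)
  withSeed(seed, {
    pairs <- which(matrix(TRUE, n_genes, n_genes) & !diag(n_genes) > 0)
    pairs <- cbind((pairs - 1L) %% n_genes + 1L,
                   (pairs - 1L) %/% n_genes + 1L)
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    sel <- if (n_edges > 0L) pairs[sample.int(nrow(pairs), n_edges), ,
                                   drop = FALSE]
           else pairs[integer(), , drop = FALSE]
    # guarantee a final effector: re-orient edges away from one node
    hasSink <- function(e) length(setdiff(seq_len(n_genes), unique(e[, 1]))) > 0
    while (nrow(sel) && !hasSink(sel)) {
      outdeg <- tabulate(sel[, 1], n_genes)
      v <- which.min(outdeg)
      vout <- which(sel[, 1] == v)
      for (r in vout) {
        rev <- c(sel[r, 2], v)
        dup <- any(sel[, 1] == rev[1] & sel[, 2] == rev[2])
        if (!dup && rev[1] != rev[2]) {
          sel[r, ] <- rev
        } else {
          # redraw elsewhere, keeping the edge count
          key <- sel[, 1] * (n_genes + 1L) + sel[, 2]
          free <- pairs[!(pairs[, 1] * (n_genes + 1L) + pairs[, 2]) %in% key &
                          pairs[, 1] != v, , drop = FALSE]
          if (nrow(free)) sel[r, ] <- free[sample.int(nrow(free), 1L), ]
          else sel <- sel[-r, , drop = FALSE]
        }
        if (hasSink(sel)) break
      }
    }
    n_inh <- floor(inhibition_fraction * nrow(sel))
    kind <- rep("activation", nrow(sel))
    if (n_inh > 0L) kind[sample.int(nrow(sel), n_inh)] <- "inhibition"
    PathwayGraph(id, genes,
                 data.frame(from = genes[sel[, 1]], to = genes[sel[, 2]],
                            kind = kind, stringsAsFactors = FALSE))
  })
}

#' Simulate a pathway collection
#'
#' Draws `n_pathways` random pathways whose gene sets are sampled from a
#' shared pool (`gene_pool_factor * genes_per_pathway` genes), giving the
#' collection KEGG-like gene sharing so that pathway frequencies and
#' cross-pathway interaction probabilities have spread.
#'
#' @param spec A [simulationSpec()].
#' @return A [PathwayCollection-class]; pathway ids are `pw01`, `pw02`, ...
#' @export
simulateCollection <- function(spec = simulationSpec()) {
  stopifnot(inherits(spec, "fopa_sim_spec"))
  withSeed(spec$seed, {
    pool <- sprintf("gene%03d",
                    seq_len(spec$gene_pool_factor * spec$genes_per_pathway))
    n_e <- round(spec$edge_density *
                   spec$genes_per_pathway * (spec$genes_per_pathway - 1L))
    graphs <- lapply(seq_len(spec$n_pathways), function(k) {
      genes <- sample(pool, spec$genes_per_pathway)
      randomPathway(spec$genes_per_pathway, n_e, spec$inhibition_fraction,
                    seed = drawSeed(), genes = genes,
                    id = sprintf("pw%02d", k))
    })
    PathwayCollection(graphs)
  })
}

#' Simulate a two-class expression dataset with one perturbed pathway
#'
#' Every gene (the collection's universe plus `n_filler` off-pathway
#' filler genes) gets independent Gaussian baseline expression
#' `N(0, noise_sd^2)` per sample; a randomly chosen `de_fraction` of the
#' target pathway's genes receive a mean shift of
#' `effect_size * noise_sd` in case samples.
#'
#' @param spec A [simulationSpec()].
#' @param collection The collection from [simulateCollection()] (must
#'   contain `spec$target_pathway_id`).
#' @param seed Seed for the expression draw (default `spec$seed + 1` so
#'   topology and noise are decoupled but jointly reproducible).
#' @return A `SummarizedExperiment` (see [ExpressionDataset()]) with the
#'   shifted gene set in `metadata(.)$shifted_genes`.
#' @export
simulateExpression <- function(spec, collection, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "fopa_sim_spec"))
  target <- collection[[spec$target_pathway_id]]
  if (is.null(target))
    stop("target pathway '", spec$target_pathway_id, "' not in collection")
  withSeed(seed, {
    genes <- c(geneUniverse(collection),
               if (spec$n_filler > 0L) sprintf("filler%03d",
                                               seq_len(spec$n_filler)))
    n <- spec$n_control + spec$n_case
    labels <- rep(c("control", "case"), c(spec$n_control, spec$n_case))
    x <- matrix(rnorm(length(genes) * n, sd = spec$noise_sd),
                nrow = length(genes),
                dimnames = list(genes, sprintf("s%02d", seq_len(n))))
    tg <- target@nodes
    n_shift <- round(spec$de_fraction * length(tg))
    shifted <- if (n_shift > 0L) sample(tg, n_shift) else character()
    if (length(shifted))
      x[shifted, labels == "case"] <- x[shifted, labels == "case"] +
        spec$effect_size * spec$noise_sd
    se <- ExpressionDataset(x, labels)
    S4Vectors::metadata(se)$shifted_genes <- shifted
    S4Vectors::metadata(se)$target_pathway_id <- spec$target_pathway_id
    se
  })
}
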