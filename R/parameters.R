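#' @rdname fopa-accessors
#' @export
setMethod("edgeParams", "ModelParameters", function(x) x@edges)
#' @rdname fopa-accessors
#' @export
setMethod("geneParams", "ModelParameters", function(x) x@genes)

setMethod("show", "ModelParameters", function(object) {
  cat("ModelParameters:", nrow(object@edges), "edge(s),",
      nrow(object@genes), "gene(s); alpha_weight =",
      format(object@alphaWeight), ", alpha_error =",
      format(object@alphaError), "\n")
})

#' DE-relation weight diff(A, B)
#'
#' Weights an interaction by the differential-expression status of its two
#' genes: neither DE gives \eqn{\alpha}, exactly one DE gives
#' \eqn{2\alpha}, both DE give \eqn{3\alpha}.  With
#' \eqn{\alpha \le 1/3} the weight never exceeds 1; the package default is
#' \eqn{\alpha = 1/6}.
#'
#' @param de_A,de_B Logical DE flags of the source and target gene.
#' @param alpha_weight Weight unit in (0, 1/3].
#' @return Numeric weight (vectorized over the flags).
#' @examples
#' diffTerm(TRUE, TRUE, 1/6)   # 1/2
#' @export
diffTerm <- function(de_A, de_B, alpha_weight = 1 / 6) {
  if (!is.numeric(alpha_weight) || length(alpha_weight) != 1L ||
      alpha_weight <= 0 || alpha_weight > 1 / 3)
    stop("'alpha_weight' must lie in (0, 1/3]")
  alpha_weight * (1 + as.numeric(de_A) + as.numeric(de_B))
}

#' Cross-pathway interaction probability
#'
#' Estimates how established an interaction is by counting, over the
#' collection, the pathways that contain an `A`-to-`B` edge of the given
#' polarity (any kind in that family) relative to the pathways containing
#' both `A` and `B` as nodes.
#'
#' @param collection A [PathwayCollection-class].
#' @param A,B Gene identifiers.
#' @param polarity `"activating"` or `"inhibiting"`.
#' @return A probability in \[0, 1\].
#' @export
interactionProbability <- function(collection, A, B,
                                   polarity = c("activating", "inhibiting")) {
  polarity <- match.arg(polarity)
  co <- 0L; hit <- 0L
  for (g in pathways(collection)) {
    if (!(A %in% g@nodes && B %in% g@nodes)) next
    co <- co + 1L
    ed <- g@edges
    if (nrow(ed) && any(ed$from == A & ed$to == B &
                        edgePolarity(ed$kind) == polarity))
      hit <- hit + 1L
  }
  if (co == 0L)
    stop("genes '", A, "' and '", B, "' co-occur in no pathway; ",
         "include the scored pathway in the collection")
  hit / co
}

#' Command probabilities for one edge
#'
#' Activation-family edges get
#' `prob_active = diff(A,B) * P(A) * P(A->B)`; inhibition-family edges get
#' `prob_inhibit1 = P(A-|B)` (deliberately without the diff and P(A)
#' factors) and `prob_inhibit2 = diff(A,B) * P(A) * P(A-|B)`.
#'
#' @param diff Weight from [diffTerm()].
#' @param P_A Gene probability of the source gene.
#' @param p_edge Interaction probability from [interactionProbability()].
#' @param polarity `"activating"` or `"inhibiting"`.
#' @return Named numeric vector: `prob_active` for activating edges,
#'   `prob_inhibit1`/`prob_inhibit2` for inhibiting edges.
#' @export
edgeParameters <- function(diff, P_A, p_edge,
                           polarity = c("activating", "inhibiting")) {
  polarity <- match.arg(polarity)
  if (polarity == "activating") {
    c(prob_active = diff * P_A * p_edge)
  } else {
    c(prob_inhibit1 = p_edge, prob_inhibit2 = diff * P_A * p_edge)
  }
}

#' Initialization parameters for one gene
#'
#' The six-state variable starts at -1 and is initialized to state 1
#' (expressed) or 2 (differentially expressed).  With DE-calling error
#' `alpha_error`, a non-DE gene initializes to 1 with probability
#' `1 - alpha` and to 2 with probability `alpha`; a DE gene is the mirror
#' image.  `prob_init`, the success probability of the source-activation
#' command, equals the gene probability P(A).
#'
#' @param is_de Logical DE flag.
#' @param alpha_error Error rate in \[0, 0.5); conventionally the DE
#'   cutoff v.
#' @param P Gene probability P(A).
#' @return Named vector `(prob1, prob2, prob_init)`.
#' @examples
#' initParameters(FALSE, 0.05, 0.3)   # 0.95, 0.05, 0.3
#' @export
initParameters <- function(is_de, alpha_error = 0.05, P = 0) {
  if (!is.numeric(alpha_error) || length(alpha_error) != 1L ||
      alpha_error < 0 || alpha_error >= 0.5)
    stop("'alpha_error' must lie in [0, 0.5)")
  if (isTRUE(is_de))
    c(prob1 = alpha_error, prob2 = 1 - alpha_error, prob_init = P)
  else
    c(prob1 = 1 - alpha_error, prob2 = alpha_error, prob_init = P)
}

#' Compute all model parameters for a pathway
#'
#' Aggregates the DE-relation weights, gene probabilities and
#' cross-pathway interaction probabilities into one
#' [ModelParameters-class] covering every edge and node of the pathway.
#' The pathway must be a member of the collection so that the interaction
#' probability denominators are at least one.
#'
#' @param g A normalized [PathwayGraph-class].
#' @param stats Gene statistic table from [buildGeneStats()] covering the
#'   pathway's genes.
#' @param collection A [PathwayCollection-class] containing `g`.
#' @param alpha_weight Weight unit for [diffTerm()] (default 1/6).
#' @param alpha_error Initialization error (default 0.05, the DE cutoff).
#' @param edge_probs Optional precomputed per-edge interaction
#'   probabilities (in edge-table order), to avoid recounting inside
#'   permutation loops.
#' @return A [ModelParameters-class].
#' @export
computeParameters <- function(g, stats, collection,
                              alpha_weight = 1 / 6, alpha_error = 0.05,
                              edge_probs = NULL) {
  stopifnot(is(g, "PathwayGraph"))
  if (!g@id %in% names(collection))
    stop("pathway '", g@id, "' is not in the collection; interaction ",
         "probabilities are undefined without it")
  missing <- setdiff(g@nodes, stats$gene)
  if (length(missing))
    stop("no statistics for gene(s): ", paste(missing, collapse = ", "))
  si <- match(g@nodes, stats$gene)
  is_de <- setNames(stats$is_de[si], g@nodes)
  P <- setNames(stats$P[si], g@nodes)

  ed <- g@edges
  n_e <- nrow(ed)
  pol <- if (n_e) edgePolarity(ed$kind) else character()
  if (is.null(edge_probs)) {
    edge_probs <- vapply(seq_len(n_e), function(i)
      interactionProbability(collection, ed$from[i], ed$to[i], pol[i]),
      numeric(1))
  } else if (length(edge_probs) != n_e) {
    stop("'edge_probs' must have one entry per edge")
  }
  dif <- if (n_e) diffTerm(is_de[ed$from], is_de[ed$to], alpha_weight) else numeric()
  act <- pol == "activating"
  edges <- data.frame(
    from = ed$from, to = ed$to, kind = ed$kind, polarity = pol,
    diff = unname(dif), p_edge = unname(edge_probs),
    prob_active = ifelse(act, unname(dif * P[ed$from] * edge_probs), NA_real_),
    prob_inhibit1 = ifelse(act, NA_real_, unname(edge_probs)),
    prob_inhibit2 = ifelse(act, NA_real_, unname(dif * P[ed$from] * edge_probs)),
    stringsAsFactors = FALSE, row.names = NULL)

  genes <- data.frame(
    gene = g@nodes,
    is_de = unname(is_de),
    prob1 = ifelse(is_de, alpha_error, 1 - alpha_error),
    prob2 = ifelse(is_de, 1 - alpha_error, alpha_error),
    prob_init = unname(P),
    stringsAsFactors = FALSE, row.names = NULL)

  new("ModelParameters", edges = edges, genes = genes,
      alphaWeight = alpha_weight, alphaError = alpha_error)
}

#' Write model parameters as TSV
#'
#' Dumps edge rows followed by gene rows for inspection and regression
#' testing.
#'
#' @param params A [ModelParameters-class].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
writeParametersTSV <- function(params, file) {
  con <- file(file, "w")
  on.exit(close(con))
  utils::write.table(cbind(record = "edge", params@edges), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(record = "gene", params@genes), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(file)
}
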