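#' Interaction kinds recognized on pathway edges
#'
#' Seven edge kinds are recognized.  Four form the activation family
#' (activation, phosphorylation activation, dephosphorylation activation,
#' indirect effect) and share one command semantics; three form the
#' inhibition family (inhibition, phosphorylation inhibition,
#' dephosphorylation inhibition) and share another.
#'
#' @return A data.frame with columns `kind` and `polarity`
#'   (`"activating"` or `"inhibiting"`).
#' @examples
#' interactionKinds()
#' @export
interactionKinds <- function() {
  data.frame(
    kind = c(.ACTIVATION_KINDS, .INHIBITION_KINDS),
    polarity = c(rep("activating", length(.ACTIVATION_KINDS)),
                 rep("inhibiting", length(.INHIBITION_KINDS))),
    stringsAsFactors = FALSE
  )
}

.ACTIVATION_KINDS <- c("activation", "phosphorylation_activation",
                       "dephosphorylation_activation", "indirect_effect")
.INHIBITION_KINDS <- c("inhibition", "phosphorylation_inhibition",
                       "dephosphorylation_inhibition")
.ALL_KINDS <- c(.ACTIVATION_KINDS, .INHIBITION_KINDS)

#' Polarity of an interaction kind
#'
#' @param kind Character vector of interaction kinds (see
#'   [interactionKinds()]).
#' @return Character vector, `"activating"` or `"inhibiting"`.
#' @examples
#' edgePolarity(c("activation", "phosphorylation_inhibition"))
#' @export
edgePolarity <- function(kind) {
  bad <- setdiff(kind, .ALL_KINDS)
  if (length(bad)) stop("unknown interaction kind(s): ", paste(bad, collapse = ", "))
  ifelse(kind %in% .ACTIVATION_KINDS, "activating", "inhibiting")
}

.emptyEdges <- function() {
  data.frame(from = character(), to = character(), kind = character(),
             stringsAsFactors = FALSE)
}

#' PathwayGraph: a directed, typed gene-interaction network
#'
#' One node per gene identifier; edges carry one of the seven interaction
#' kinds.  Nodes flagged as non-gene (compounds, map links) survive parsing
#' but are removed by [normalizeGraph()].
#'
#' @slot id Pathway identifier.
#' @slot nodes Character vector of unique node identifiers.
#' @slot edges data.frame with columns `from`, `to`, `kind`.
#' @slot nonGenes Subset of `nodes` flagged non-gene.
#' @slot log Character vector of provenance/normalization messages.
#' @export
setClass("PathwayGraph",
  representation(id = "character", nodes = "character", edges = "data.frame",
                 nonGenes = "character", log = "character"),
  prototype(id = "pathway", nodes = character(), edges = .emptyEdges(),
            nonGenes = character(), log = character())
)

setValidity("PathwayGraph", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "node identifiers must be unique")
  ed <- object@edges
  if (!all(c("from", "to", "kind") %in% names(ed)))
    msg <- c(msg, "'edges' must have columns from, to, kind")
  else {
    if (!all(ed$from %in% object@nodes) || !all(ed$to %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    if (!all(ed$kind %in% .ALL_KINDS))
      msg <- c(msg, "edge kinds must be recognized interaction kinds")
  }
  if (!all(object@nonGenes %in% object@nodes))
    msg <- c(msg, "'nonGenes' must be a subset of 'nodes'")
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayGraph
#'
#' @param id Pathway identifier (single string).
#' @param nodes Character vector of node identifiers.
#' @param edges data.frame with columns `from`, `to`, `kind`; see
#'   [interactionKinds()] for valid kinds.
#' @param nonGenes Nodes flagged non-gene (removed by [normalizeGraph()]).
#' @param log Provenance messages.
#' @return A [PathwayGraph-class] object.
#' @examples
#' g <- PathwayGraph("demo", c("A", "B"),
#'                   data.frame(from = "A", to = "B", kind = "activation"))
#' g
#' @export
PathwayGraph <- function(id, nodes, edges = .emptyEdges(),
                         nonGenes = character(), log = character()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$kind <- as.character(edges$kind)
  }
  rownames(edges) <- NULL
  new("PathwayGraph", id = as.character(id), nodes = as.character(nodes),
      edges = edges[, c("from", "to", "kind")], nonGenes = as.character(nonGenes),
      log = as.character(log))
}

#' PathwayCollection: a set of pathways sharing a gene universe
#'
#' The collection is the reference set over which gene pathway-frequencies
#' and pairwise interaction probabilities are counted; a pathway being
#' scored must be a member.
#'
#' @slot pathways List of [PathwayGraph-class] objects with unique ids.
#' @export
setClass("PathwayCollection", representation(pathways = "list"),
         prototype(pathways = list()))

setValidity("PathwayCollection", function(object) {
  ok <- vapply(object@pathways, is, logical(1), class2 = "PathwayGraph")
  if (!all(ok)) return("all elements must be PathwayGraph objects")
  ids <- vapply(object@pathways, function(p) p@id, character(1))
  if (anyDuplicated(ids)) return("pathway ids must be unique")
  TRUE
})

#' Construct a PathwayCollection
#'
#' @param pathways List of [PathwayGraph-class] objects (unique ids).
#' @return A [PathwayCollection-class] object.
#' @export
PathwayCollection <- function(pathways) {
  pw <- as.list(pathways)
  names(pw) <- vapply(pw, function(p) p@id, character(1))
  new("PathwayCollection", pathways = pw)
}

#' ModelParameters: every probability of a pathway's guarded-command model
#'
#' Per edge: the DE-relation weight `diff`, the cross-pathway interaction
#' probability `p_edge`, and the command probabilities
#' (`prob_active` for activation-family edges; `prob_inhibit1`,
#' `prob_inhibit2` for inhibition-family edges).  Per gene: the
#' initialization probabilities `prob1`, `prob2` and the source-activation
#' probability `prob_init`.
#'
#' @slot edges data.frame keyed by (from, to) with columns `kind`,
#'   `polarity`, `diff`, `p_edge`, `prob_active`, `prob_inhibit1`,
#'   `prob_inhibit2`.
#' @slot genes data.frame with columns `gene`, `is_de`, `prob1`, `prob2`,
#'   `prob_init`.
#' @slot alphaWeight DE-relation weight unit alpha in (0, 1/3].
#' @slot alphaError Initialization error alpha (the DE cutoff v).
#' @export
setClass("ModelParameters",
  representation(edges = "data.frame", genes = "data.frame",
                 alphaWeight = "numeric", alphaError = "numeric"))

setValidity("ModelParameters", function(object) {
  msg <- character()
  gn <- object@genes
  inrange <- function(x) all(is.na(x) | (x >= 0 & x <= 1 + 1e-12))
  if (!all(c("gene", "is_de", "prob1", "prob2", "prob_init") %in% names(gn)))
    msg <- c(msg, "'genes' missing required columns")
  else {
    if (!inrange(gn$prob1) || !inrange(gn$prob2) || !inrange(gn$prob_init))
      msg <- c(msg, "gene probabilities must lie in [0,1]")
    if (nrow(gn) && any(abs(gn$prob1 + gn$prob2 - 1) > 1e-12))
      msg <- c(msg, "prob1 + prob2 must equal 1 for every gene")
  }
  ed <- object@edges
  need <- c("from", "to", "kind", "polarity", "diff", "p_edge",
            "prob_active", "prob_inhibit1", "prob_inhibit2")
  if (!all(need %in% names(ed)))
    msg <- c(msg, "'edges' missing required columns")
  else if (nrow(ed)) {
    if (!inrange(ed$p_edge) || !inrange(ed$prob_active) ||
        !inrange(ed$prob_inhibit1) || !inrange(ed$prob_inhibit2))
      msg <- c(msg, "edge probabilities must lie in [0,1]")
  }
  if (length(object@alphaWeight) != 1L || object@alphaWeight <= 0 ||
      object@alphaWeight > 1 / 3 + 1e-12)
    msg <- c(msg, "'alphaWeight' must lie in (0, 1/3]")
  if (length(object@alphaError) != 1L || object@alphaError < 0 ||
      object@alphaError >= 0.5)
    msg <- c(msg, "'alphaError' must lie in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' GuardedModel: a probabilistic guarded-command model of one pathway
#'
#' One variable per gene over the domain \{-1, 0, 1, 2, 3, 4\}, initial
#' value -1, plus a list of probabilistic guarded commands.  Commands are
#' structured records with a `kind` in `init`, `source`, `activation`,
#' `inhibition1`, `inhibition2`; each has exactly two branches whose
#' probabilities sum to one and assigns only its target variable.
#'
#' @slot pathwayId Pathway identifier.
#' @slot genes Character vector of variables (one per gene, sorted).
#' @slot effectors Final-effector genes (reachability targets).
#' @slot deGenes Genes flagged differentially expressed.
#' @slot commands List of command records
#'   `list(kind, src, tgt, probs = c(p1, p2))`.
#' @export
setClass("GuardedModel",
  representation(pathwayId = "character", genes = "character",
                 effectors = "character", deGenes = "character",
                 commands = "list"))

.CMD_KINDS <- c("init", "source", "activation", "inhibition1", "inhibition2")

setValidity("GuardedModel", function(object) {
  msg <- character()
  if (!all(object@effectors %in% object@genes))
    msg <- c(msg, "effectors must be model genes")
  inits <- character()
  for (cmd in object@commands) {
    if (!is.list(cmd) || !all(c("kind", "src", "tgt", "probs") %in% names(cmd))) {
      msg <- c(msg, "malformed command record"); break
    }
    if (!cmd$kind %in% .CMD_KINDS)
      msg <- c(msg, paste0("unknown command kind '", cmd$kind, "'"))
    if (!cmd$tgt %in% object@genes)
      msg <- c(msg, paste0("command target '", cmd$tgt, "' is not a model gene"))
    if (cmd$kind %in% c("activation", "inhibition1", "inhibition2") &&
        !(cmd$src %in% object@genes))
      msg <- c(msg, paste0("command source '", cmd$src, "' is not a model gene"))
    if (length(cmd$probs) != 2L || any(cmd$probs < -1e-12) ||
        abs(sum(cmd$probs) - 1) > 1e-12)
      msg <- c(msg, "branch probabilities must be two values summing to 1")
    if (cmd$kind == "init") inits <- c(inits, cmd$tgt)
  }
  if (!length(msg) && (anyDuplicated(inits) ||
                       !setequal(inits, object@genes)))
    msg <- c(msg, "every variable must appear in exactly one initialization command")
  if (length(msg)) msg[1] else TRUE
})
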