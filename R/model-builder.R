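#' @rdname fopa-accessors
#' @export
setMethod("modelGenes", "GuardedModel", function(x) x@genes)
#' @rdname fopa-accessors
#' @export
setMethod("modelEffectors", "GuardedModel", function(x) x@effectors)
#' @rdname fopa-accessors
#' @export
setMethod("modelCommands", "GuardedModel", function(x) x@commands)
#' @rdname fopa-accessors
#' @export
setMethod("pathwayId", "GuardedModel", function(x) x@pathwayId)

setMethod("show", "GuardedModel", function(object) {
  cat("GuardedModel '", object@pathwayId, "': ", length(object@genes),
      " variable(s) over {-1..4}, ", length(object@commands),
      " command(s), ", length(object@effectors), " effector(s)\n", sep = "")
})

.cmd <- function(kind, src, tgt, p1) {
  list(kind = kind, src = src, tgt = tgt, probs = c(p1, 1 - p1))
}

# canonical command table: init commands (genes sorted), source-activation
# commands (sorted), then edge commands in edge-table order (inhibition
# edges contribute two commands)
.commandList <- function(genes, sources, edges, gene_par) {
  cmds <- vector("list", 0L)
  gi <- match(genes, gene_par$gene)
  for (k in seq_along(genes)) {
    cmds[[length(cmds) + 1L]] <-
      .cmd("init", NA_character_, genes[k], gene_par$prob1[gi[k]])
  }
  for (s in sources) {
    cmds[[length(cmds) + 1L]] <-
      .cmd("source", NA_character_, s, gene_par$prob_init[gi[match(s, genes)]])
  }
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    if (edges$polarity[i] == "activating") {
      cmds[[length(cmds) + 1L]] <-
        .cmd("activation", edges$from[i], edges$to[i], edges$prob_active[i])
    } else {
      cmds[[length(cmds) + 1L]] <-
        .cmd("inhibition1", edges$from[i], edges$to[i], edges$prob_inhibit1[i])
      cmds[[length(cmds) + 1L]] <-
        .cmd("inhibition2", edges$from[i], edges$to[i], edges$prob_inhibit2[i])
    }
  }
  cmds
}

#' Compile a parameterized pathway into a guarded-command model
#'
#' One six-state variable per gene (initially -1) and the following
#' commands:
#' \itemize{
#'   \item per gene, one initialization command
#'     `(A = -1) -> prob1:(A'=1) + prob2:(A'=2)`;
#'   \item per gene with no incoming edge of any kind, one
#'     source-activation command
#'     `(A=1|A=2) -> prob_init:(A'=A+2) + (1-prob_init):(A'=0)`;
#'   \item per activation-family edge, one command
#'     `A>2 & (B=1|B=2) -> prob_active:(B'=(A=3&B=1)?3:4) +
#'     (1-prob_active):(B'=0)` — the target becomes differentially
#'     activated (4) exactly when the source is in state 4 or the target
#'     was differentially expressed (2);
#'   \item per inhibition-family edge, two commands:
#'     `A<3 & (B=1|B=2) -> prob_inhibit1:(B'=B+2) + ...:(B'=0)` and
#'     `A>2 & B>2 -> prob_inhibit2:(B'=B-2) + ...:(B'=0)`.
#' }
#' A gene targeted only by inhibition edges receives no source-activation
#' command; it can still activate through the first inhibition command.
#'
#' @param g A normalized [PathwayGraph-class].
#' @param params A [ModelParameters-class] covering `g` (see
#'   [computeParameters()]).
#' @param de Optional character vector of DE genes; defaults to the flags
#'   in `params`.
#' @return A [GuardedModel-class].
#' @export
buildModel <- function(g, params, de = NULL) {
  stopifnot(is(g, "PathwayGraph"), is(params, "ModelParameters"))
  genes <- sort(g@nodes)
  gp <- params@genes
  missing <- setdiff(genes, gp$gene)
  if (length(missing))
    stop("parameters missing for gene(s): ", paste(missing, collapse = ", "))
  ed <- g@edges
  ep <- params@edges
  if (nrow(ed)) {
    key_g <- paste(ed$from, ed$to, ed$kind, sep = "\r")
    key_p <- paste(ep$from, ep$to, ep$kind, sep = "\r")
    idx <- match(key_g, key_p)
    if (anyNA(idx))
      stop("parameters missing for edge(s): ",
           paste(sprintf("%s -> %s", ed$from[is.na(idx)], ed$to[is.na(idx)]),
                 collapse = ", "))
    ep <- ep[idx, , drop = FALSE]
  } else {
    ep <- ep[integer(), , drop = FALSE]
  }
  if (is.null(de)) de <- gp$gene[gp$is_de]
  sources <- sort(setdiff(genes, unique(ed$to)))
  cmds <- .commandList(genes, sources, ep, gp)
  new("GuardedModel", pathwayId = g@id, genes = genes,
      effectors = suppressWarnings(finalEffectors(g)),
      deGenes = intersect(de, genes), commands = cmds)
}

.CMD_CODE <- c(init = 1L, source = 2L, activation = 3L,
               inhibition1 = 4L, inhibition2 = 5L)

# numeric encoding consumed by the C++ engine
.encodeCommands <- function(m) {
  genes <- m@genes
  kind <- vapply(m@commands, function(c) .CMD_CODE[[c$kind]], integer(1))
  src <- vapply(m@commands, function(c)
    if (is.na(c$src)) -1L else match(c$src, genes) - 1L, integer(1))
  tgt <- vapply(m@commands, function(c) match(c$tgt, genes) - 1L, integer(1))
  p1 <- vapply(m@commands, function(c) c$probs[1], numeric(1))
  list(kind = kind, src = src, tgt = tgt, p1 = p1,
       n_genes = length(genes), genes = genes)
}
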