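#' @rdname fopa-accessors
#' @export
setMethod("pathwayId", "PathwayGraph", function(x) x@id)
#' @rdname fopa-accessors
#' @export
setMethod("geneNodes", "PathwayGraph", function(x) setdiff(x@nodes, x@nonGenes))
#' @rdname fopa-accessors
#' @export
setMethod("edgeTable", "PathwayGraph", function(x) x@edges)
#' @rdname fopa-accessors
#' @export
setMethod("nonGeneNodes", "PathwayGraph", function(x) x@nonGenes)
#' @rdname fopa-accessors
#' @export
setMethod("normalizationLog", "PathwayGraph", function(x) x@log)

setMethod("show", "PathwayGraph", function(object) {
  np <- length(object@nodes)
  cat("PathwayGraph '", object@id, "': ", np, " node", if (np != 1) "s",
      " (", length(object@nonGenes), " non-gene), ",
      nrow(object@edges), " edge(s)\n", sep = "")
  if (nrow(object@edges)) {
    pol <- edgePolarity(object@edges$kind)
    cat("  activating:", sum(pol == "activating"),
        " inhibiting:", sum(pol == "inhibiting"), "\n")
  }
})

#' @rdname fopa-accessors
#' @export
setMethod("pathways", "PathwayCollection", function(x) x@pathways)
#' @rdname fopa-accessors
#' @export
setMethod("geneUniverse", "PathwayCollection", function(x) {
  sort(unique(unlist(lapply(x@pathways, function(p) p@nodes), use.names = FALSE)))
})

#' @export
setMethod("length", "PathwayCollection", function(x) length(x@pathways))

#' @export
setMethod("names", "PathwayCollection", function(x) names(x@pathways))

#' @param i Pathway index or id.
#' @rdname PathwayCollection-class
#' @export
setMethod("[[", "PathwayCollection", function(x, i) x@pathways[[i]])

setMethod("show", "PathwayCollection", function(object) {
  cat("PathwayCollection with", length(object@pathways), "pathway(s),",
      length(geneUniverse(object)), "genes in universe\n")
})

# sign composition when bypassing a removed non-gene node
.composePolarity <- function(pol_in, pol_out) {
  ifelse(pol_in == pol_out, "activation", "inhibition")
}

#' Normalize a pathway graph
#'
#' Performs the topology editing required before model construction:
#' (i) nodes annotated with the same gene are already keyed by identifier,
#' so duplicates cannot coexist; (ii) each non-gene node (compound, map
#' link) is removed and every parent/child pair across it is reconnected
#' with the sign product of the two hops (two activating or two inhibiting
#' hops give activation, mixed give inhibition); (iii) self-edges are
#' dropped; (iv) duplicate edges are collapsed to at most one per
#' (source, target, polarity), keeping the first-listed kind.  Every action
#' is appended to the normalization log.  The operation is idempotent.
#'
#' @param g A [PathwayGraph-class].
#' @return A normalized [PathwayGraph-class].
#' @examples
#' g <- PathwayGraph("demo", c("A", "X", "B"),
#'                   data.frame(from = c("A", "X"), to = c("X", "B"),
#'                              kind = c("activation", "inhibition")),
#'                   nonGenes = "X")
#' edgeTable(normalizeGraph(g))   # A -| B
#' @export
normalizeGraph <- function(g) {
  stopifnot(is(g, "PathwayGraph"))
  ed <- g@edges
  nodes <- g@nodes
  nong <- g@nonGenes
  log <- g@log

  # self-edges have no command semantics
  self <- which(ed$from == ed$to)
  if (length(self)) {
    log <- c(log, sprintf("dropped self-edge at '%s'", ed$from[self]))
    ed <- ed[-self, , drop = FALSE]
  }

  # remove non-gene nodes one at a time, bypassing parent -> child
  while (length(nong)) {
    m <- nong[1L]
    ins <- ed[ed$to == m & ed$from != m, , drop = FALSE]
    outs <- ed[ed$from == m & ed$to != m, , drop = FALSE]
    if (nrow(ins) && nrow(outs)) {
      for (a in seq_len(nrow(ins))) for (b in seq_len(nrow(outs))) {
        p <- ins$from[a]; c_ <- outs$to[b]
        if (p == c_) {
          log <- c(log, sprintf(
            "dropped self-edge at '%s' created by removing non-gene '%s'", p, m))
          next
        }
        kind <- .composePolarity(edgePolarity(ins$kind[a]),
                                 edgePolarity(outs$kind[b]))
        ed <- rbind(ed, data.frame(from = p, to = c_, kind = kind,
                                   stringsAsFactors = FALSE))
        log <- c(log, sprintf("reconnected '%s' -> '%s' (%s) across non-gene '%s'",
                              p, c_, kind, m))
      }
    }
    ed <- ed[ed$from != m & ed$to != m, , drop = FALSE]
    nodes <- setdiff(nodes, m)
    nong <- nong[-1L]
    log <- c(log, sprintf("removed non-gene node '%s'", m))
  }

  # de-duplicate: one edge per (source, target, polarity), first kind wins
  if (nrow(ed)) {
    key <- paste(ed$from, ed$to, edgePolarity(ed$kind), sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      log <- c(log, sprintf("collapsed duplicate edge '%s' -> '%s' (%s)",
                            ed$from[dup], ed$to[dup], ed$kind[dup]))
      ed <- ed[!dup, , drop = FALSE]
    }
  }
  PathwayGraph(g@id, nodes, ed, nonGenes = character(), log = log)
}

#' Final-effector genes of a pathway
#'
#' The final effectors are the genes assumed to trigger the cellular
#' response: operationally, the nodes with out-degree zero (KGML carries no
#' explicit effector flag, so this convention is a documented package
#' choice).  They are the reachability targets of the pathway property.
#'
#' @param g A normalized [PathwayGraph-class].
#' @return Character vector of gene identifiers, sorted; empty (with a
#'   warning) if every node has outgoing edges (pure cycle).
#' @examples
#' g <- PathwayGraph("chain", c("A", "B", "C"),
#'                   data.frame(from = c("A", "B"), to = c("B", "C"),
#'                              kind = "activation"))
#' finalEffectors(g)   # "C"
#' @export
finalEffectors <- function(g) {
  stopifnot(is(g, "PathwayGraph"))
  out <- setdiff(g@nodes, unique(g@edges$from))
  if (!length(out) && length(g@nodes))
    warning("pathway '", g@id, "' has no out-degree-0 gene (pure cycle); ",
            "no effectors")
  sort(out)
}

#' Generate a decoy pathway
#'
#' A decoy keeps the full edge structure and interaction kinds of a real
#' pathway but substitutes its gene labels with genes drawn uniformly
#' without replacement from a supplied universe.  Decoys serve as negative
#' controls: a well-calibrated method should not rank them highly.
#'
#' @param g A normalized [PathwayGraph-class].
#' @param universe Character vector of candidate gene labels
#'   (`length(universe) >= number of nodes`).
#' @param seed Integer seed; the decoy is deterministic given the seed.
#' @param id Identifier for the decoy (default `"<id>_decoy"`).
#' @return A [PathwayGraph-class] isomorphic to `g`.
#' @examples
#' g <- PathwayGraph("real", c("A", "B"),
#'                   data.frame(from = "A", to = "B", kind = "activation"))
#' makeDecoy(g, universe = paste0("g", 1:10), seed = 1)
#' @export
makeDecoy <- function(g, universe, seed, id = paste0(g@id, "_decoy")) {
  stopifnot(is(g, "PathwayGraph"))
  universe <- unique(as.character(universe))
  if (length(universe) < length(g@nodes))
    stop("universe (", length(universe), ") smaller than node count (",
         length(g@nodes), ")")
  withSeed(seed, {
    relab <- setNames(sample(universe, length(g@nodes)), g@nodes)
    ed <- g@edges
    if (nrow(ed)) {
      ed$from <- unname(relab[ed$from])
      ed$to <- unname(relab[ed$to])
    }
    PathwayGraph(id, unname(relab[g@nodes]), ed,
                 log = sprintf("decoy of '%s' (seed %d)", g@id, as.integer(seed)))
  })
}

#' Randomly remove or rewire a fraction of pathway edges
#'
#' Emulates pathway-database incompleteness (`mode = "remove"`) and noise
#' (`mode = "rewire"`).  `round(fraction * |edges|)` edges are selected
#' uniformly; removal deletes them, rewiring redraws each selected edge's
#' target uniformly from the other nodes, avoiding self-edges and existing
#' duplicates.  The node set is unchanged and the result is deterministic
#' given the seed.
#'
#' @param g A normalized [PathwayGraph-class] with at least one edge.
#' @param fraction Proportion of edges to perturb, in \[0, 1\].
#' @param mode `"remove"` or `"rewire"`.
#' @param seed Integer seed.
#' @return A perturbed [PathwayGraph-class].
#' @export
perturbGraph <- function(g, fraction, mode = c("remove", "rewire"), seed) {
  stopifnot(is(g, "PathwayGraph"))
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("'fraction' must be a single number in [0, 1]")
  ed <- g@edges
  ne <- nrow(ed)
  if (ne < 1L) stop("graph has no edges to perturb")
  k <- round(fraction * ne)
  if (k == 0L) return(g)
  withSeed(seed, {
    sel <- sample.int(ne, k)
    log <- g@log
    if (mode == "remove") {
      log <- c(log, sprintf("removed edge '%s' -> '%s'", ed$from[sel], ed$to[sel]))
      ed <- ed[-sel, , drop = FALSE]
    } else {
      pol <- edgePolarity(ed$kind)
      for (i in sel) {
        taken <- ed$to[ed$from == ed$from[i] & pol == pol[i]]
        cand <- setdiff(g@nodes, c(ed$from[i], taken))
        if (!length(cand)) {
          log <- c(log, sprintf("kept edge '%s' -> '%s' (no rewiring target)",
                                ed$from[i], ed$to[i]))
          next
        }
        newto <- if (length(cand) == 1L) cand else sample(cand, 1L)
        log <- c(log, sprintf("rewired '%s' -> '%s' to '%s' -> '%s'",
                              ed$from[i], ed$to[i], ed$from[i], newto))
        ed$to[i] <- newto
      }
    }
    PathwayGraph(g@id, g@nodes, ed, nonGenes = g@nonGenes, log = log)
  })
}
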