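#' Parse a KGML (KEGG XML) pathway document
#'
#' Reads KGML `entry` and `relation` elements into a raw
#' [PathwayGraph-class].  Gene-type entries become candidate nodes; entries
#' listing several gene identifiers are expanded to one node per gene, each
#' inheriting the entry's relations; `group` entries are expanded to their
#' component genes.  Compound and map entries are retained but flagged
#' non-gene so that [normalizeGraph()] can remove them.  Relation subtypes
#' are mapped to interaction kinds ("expression"/"repression" are treated as
#' activation/inhibition); relations carrying no activation or inhibition
#' polarity (e.g. binding/association) are dropped and logged.
#'
#' Gene identifiers are kept verbatim in the KGML namespace (e.g.
#' `"hsa:1234"`); expression data must use the same namespace or be mapped
#' beforehand.
#'
#' @param x Path to a KGML file, or a single string of KGML text.
#' @return A raw [PathwayGraph-class] (run [normalizeGraph()] before
#'   modeling).
#' @export
parseKGML <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e)
    stop("KGML parse error: ", conditionMessage(e), call. = FALSE))
  root <- xml2::xml_name(doc)
  if (root != "pathway") stop("not a KGML document (root element '", root, "')")
  pid <- xml2::xml_attr(doc, "name")
  if (is.na(pid) || !nzchar(pid)) pid <- "pathway"
  log <- character()

  entries <- xml2::xml_find_all(doc, "./entry")
  ent_id <- xml2::xml_attr(entries, "id")
  ent_type <- xml2::xml_attr(entries, "type")
  ent_name <- xml2::xml_attr(entries, "name")

  # first pass: nodes per entry
  ent_nodes <- vector("list", length(entries))
  names(ent_nodes) <- ent_id
  non_genes <- character()
  for (i in seq_along(entries)) {
    type <- ent_type[i]
    if (is.na(type)) type <- "other"
    if (type == "gene") {
      ent_nodes[[i]] <- strsplit(trimws(ent_name[i]), "\\s+")[[1]]
    } else if (type == "group") {
      comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], "./component"), "id")
      ent_nodes[[i]] <- c(group = NA_character_, comp) # resolved below
    } else {
      nm <- strsplit(trimws(ent_name[i]), "\\s+")[[1]][1]
      if (is.na(nm) || !nzchar(nm)) nm <- paste0("entry", ent_id[i])
      ent_nodes[[i]] <- nm
      non_genes <- c(non_genes, nm)
    }
  }
  # resolve groups to member genes
  for (i in seq_along(entries)) {
    v <- ent_nodes[[i]]
    if (length(v) && !is.null(names(v)) && names(v)[1] == "group") {
      comp <- v[-1]
      miss <- setdiff(comp, ent_id)
      if (length(miss))
        stop("structural error: group entry ", ent_id[i],
             " references unknown entry id(s) ", paste(miss, collapse = ", "))
      ent_nodes[[i]] <- unique(unlist(ent_nodes[match(comp, ent_id)],
                                      use.names = FALSE))
      log <- c(log, sprintf("expanded group entry %s to %d gene(s)",
                            ent_id[i], length(ent_nodes[[i]])))
    }
  }

  all_nodes <- unlist(ent_nodes, use.names = FALSE)
  dup <- unique(all_nodes[duplicated(all_nodes)])
  if (length(dup))
    log <- c(log, sprintf("merged duplicate node '%s' across entries", dup))
  nodes <- unique(all_nodes)
  non_genes <- intersect(unique(non_genes), nodes)

  # relations
  rels <- xml2::xml_find_all(doc, "./relation")
  ed <- .emptyEdges()
  for (r in rels) {
    e1 <- xml2::xml_attr(r, "entry1"); e2 <- xml2::xml_attr(r, "entry2")
    for (e in c(e1, e2)) if (!e %in% ent_id)
      stop("structural error: relation references unknown entry id ", e)
    subs <- xml2::xml_attr(xml2::xml_find_all(r, "./subtype"), "name")
    kind <- .kgmlRelationKind(subs)
    if (is.na(kind)) {
      log <- c(log, sprintf(
        "dropped relation %s -> %s with no polarity (subtypes: %s)",
        e1, e2, if (length(subs)) paste(subs, collapse = ", ") else "none"))
      next
    }
    src <- ent_nodes[[match(e1, ent_id)]]
    dst <- ent_nodes[[match(e2, ent_id)]]
    if (!length(src) || !length(dst)) next
    grid <- expand.grid(from = src, to = dst, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid$kind <- kind
    ed <- rbind(ed, grid)
  }
  PathwayGraph(pid, nodes, ed, nonGenes = non_genes, log = log)
}

# map a KGML relation subtype set to an interaction kind (NA = no polarity)
.kgmlRelationKind <- function(subs) {
  if (!length(subs)) return(NA_character_)
  subs <- tolower(subs)
  act <- any(subs %in% c("activation", "expression"))
  inh <- any(subs %in% c("inhibition", "repression"))
  if (act && inh) {  # contradictory annotation: first-listed polarity wins
    first <- subs[subs %in% c("activation", "expression",
                              "inhibition", "repression")][1]
    act <- first %in% c("activation", "expression")
    inh <- !act
  }
  phos <- "phosphorylation" %in% subs
  deph <- "dephosphorylation" %in% subs
  if (act) {
    if (phos) return("phosphorylation_activation")
    if (deph) return("dephosphorylation_activation")
    return("activation")
  }
  if (inh) {
    if (phos) return("phosphorylation_inhibition")
    if (deph) return("dephosphorylation_inhibition")
    return("inhibition")
  }
  if ("indirect effect" %in% subs) return("indirect_effect")
  NA_character_
}

#' Read a pathway collection from a TSV edge list
#'
#' The dialect is `pathway_id<TAB>source<TAB>target<TAB>kind` with a header
#' line.  Rows with `kind == "node"` declare an isolated node (the `target`
#' field is ignored); all other kinds must be recognized interaction kinds.
#'
#' @param file Path to a TSV file.
#' @return A [PathwayCollection-class].
#' @seealso [writePathwayTSV()]
#' @export
readPathwayTSV <- function(file) {
  tab <- utils::read.delim(file, header = TRUE, colClasses = "character")
  if (ncol(tab) < 4L)
    stop("expected columns: pathway_id, source, target, kind")
  names(tab)[1:4] <- c("pathway_id", "source", "target", "kind")
  graphs <- lapply(split(tab, factor(tab$pathway_id, unique(tab$pathway_id))),
    function(d) {
      isnode <- d$kind == "node"
      ed <- d[!isnode, , drop = FALSE]
      nodes <- unique(c(ed$source, ed$target, d$source[isnode]))
      PathwayGraph(d$pathway_id[1], nodes,
                   data.frame(from = ed$source, to = ed$target, kind = ed$kind,
                              stringsAsFactors = FALSE))
    })
  PathwayCollection(unname(graphs))
}

#' Write pathways as a TSV edge list
#'
#' @param x A [PathwayCollection-class] or single [PathwayGraph-class].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @seealso [readPathwayTSV()]
#' @export
writePathwayTSV <- function(x, file) {
  if (is(x, "PathwayGraph")) x <- PathwayCollection(list(x))
  stopifnot(is(x, "PathwayCollection"))
  rows <- lapply(pathways(x), function(g) {
    ed <- g@edges
    iso <- setdiff(g@nodes, unique(c(ed$from, ed$to)))
    out <- data.frame(pathway_id = rep(g@id, nrow(ed) + length(iso)),
                      source = c(ed$from, iso),
                      target = c(ed$to, rep("-", length(iso))),
                      kind = c(ed$kind, rep("node", length(iso))),
                      stringsAsFactors = FALSE)
    out
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a graph's normalization log
#'
#' @param g A [PathwayGraph-class].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
writeNormalizationLog <- function(g, file) {
  stopifnot(is(g, "PathwayGraph"))
  writeLines(g@log, file)
  invisible(file)
}
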