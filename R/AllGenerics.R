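#' @name fopa-accessors
#' @title Accessors for fopa S4 classes
#' @description Slot accessors for [PathwayGraph-class],
#'   [PathwayCollection-class], [ModelParameters-class] and
#'   [GuardedModel-class]; use these rather than `@`.
#' @param x An object of the relevant class.
#' @return `pathwayId`: a string; `geneNodes`, `nonGeneNodes`,
#'   `normalizationLog`, `modelGenes`, `modelEffectors`: character vectors;
#'   `edgeTable`, `edgeParams`, `geneParams`: data.frames;
#'   `modelCommands`: a list; `pathways`: a named list of graphs.
NULL

#' @rdname fopa-accessors
#' @export
setGeneric("pathwayId", function(x) standardGeneric("pathwayId"))
#' @rdname fopa-accessors
#' @export
setGeneric("geneNodes", function(x) standardGeneric("geneNodes"))
#' @rdname fopa-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname fopa-accessors
#' @export
setGeneric("nonGeneNodes", function(x) standardGeneric("nonGeneNodes"))
#' @rdname fopa-accessors
#' @export
setGeneric("normalizationLog", function(x) standardGeneric("normalizationLog"))
#' @rdname fopa-accessors
#' @export
setGeneric("pathways", function(x) standardGeneric("pathways"))
#' @rdname fopa-accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))
#' @rdname fopa-accessors
#' @export
setGeneric("edgeParams", function(x) standardGeneric("edgeParams"))
#' @rdname fopa-accessors
#' @export
setGeneric("geneParams", function(x) standardGeneric("geneParams"))
#' @rdname fopa-accessors
#' @export
setGeneric("modelGenes", function(x) standardGeneric("modelGenes"))
#' @rdname fopa-accessors
#' @export
setGeneric("modelEffectors", function(x) standardGeneric("modelEffectors"))
#' @rdname fopa-accessors
#' @export
setGeneric("modelCommands", function(x) standardGeneric("modelCommands"))
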