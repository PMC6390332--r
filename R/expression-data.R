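#' Build a two-class expression dataset
#'
#' Wraps a genes-by-samples matrix of (log-scale) expression values and a
#' two-class sample labeling into a
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with assay `"exprs"` and a `class` column (`"control"`/`"case"`) in the
#' column data.  Rows containing missing values are rejected with a
#' warning; each class must have at least two samples and gene identifiers
#' must be unique.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param labels Character/factor vector of per-sample classes, values
#'   `"control"` or `"case"`.
#' @param gene_ids Row identifiers (default `rownames(values)`).
#' @return A `SummarizedExperiment`.
#' @examples
#' m <- matrix(rnorm(40), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' se <- ExpressionDataset(m, rep(c("control", "case"), each = 5))
#' sampleClasses(se)
#' @export
ExpressionDataset <- function(values, labels, gene_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(gene_ids)) stop("gene identifiers are required")
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique")
  rownames(values) <- gene_ids
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("one label per sample is required")
  if (!all(labels %in% c("control", "case")))
    stop("labels must be 'control' or 'case'")
  if (sum(labels == "control") < 2L || sum(labels == "case") < 2L)
    stop("each class needs at least 2 samples")
  bad <- !stats::complete.cases(values)
  if (any(bad)) {
    warning("rejected ", sum(bad), " gene row(s) with missing values")
    values <- values[!bad, , drop = FALSE]
  }
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(class = factor(labels,
                                                  levels = c("control", "case")))
  )
}

#' @rdname ExpressionDataset
#' @param x A dataset built by `ExpressionDataset()`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @rdname ExpressionDataset
#' @export
sampleClasses <- function(x) {
  as.character(SummarizedExperiment::colData(x)$class)
}

# dataset with the same expression values under a permuted labeling
.relabel <- function(x, labels) {
  SummarizedExperiment::colData(x)$class <-
    factor(labels, levels = c("control", "case"))
  x
}

#' Read an expression matrix and label file
#'
#' The matrix file is TSV/CSV with gene identifiers in the first column and
#' a header of sample identifiers; the label file is two-column
#' `sample<TAB>class` with classes `control`/`case`.
#'
#' @param expr_file Path to the expression table.
#' @param labels_file Path to the label table.
#' @param sep Field separator (default tab).
#' @return A `SummarizedExperiment` (see [ExpressionDataset()]).
#' @export
readExpressionTSV <- function(expr_file, labels_file, sep = "\t") {
  tab <- utils::read.table(expr_file, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE)
  lab <- utils::read.table(labels_file, header = TRUE, sep = sep,
                           colClasses = "character")
  names(lab)[1:2] <- c("sample", "class")
  miss <- setdiff(colnames(tab), lab$sample)
  if (length(miss)) stop("no label for sample(s): ", paste(miss, collapse = ", "))
  ExpressionDataset(as.matrix(tab), lab$class[match(colnames(tab), lab$sample)])
}
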