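#' Empirical-Bayes moderated two-sample t-statistics
#'
#' Computes per-gene moderated t-scores between the case and control
#' classes using closed-form empirical-Bayes variance shrinkage: the
#' per-gene pooled variance \eqn{s_g^2} (with \eqn{d_g} residual df) is
#' shrunk towards a prior \eqn{s_0^2} with prior df \eqn{d_0},
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' and \eqn{T_g = (\bar x_{case} - \bar x_{control}) /
#' (\tilde s_g \sqrt{1/n_1 + 1/n_2})}.  The hyperparameters are estimated
#' by the method of moments on the log pooled variances (a scaled-F fit via
#' digamma/trigamma moments); two-sided p-values use \eqn{d_0 + d_g}
#' degrees of freedom, capped at the total residual df when \eqn{d_0} is
#' infinite.  Genes with zero pooled variance are excluded from
#' hyperparameter estimation but still receive a shrunken variance.
#'
#' @param data A dataset from [ExpressionDataset()].
#' @param prior_df Optional override of the prior df \eqn{d_0}; `0`
#'   disables shrinkage and reproduces the ordinary pooled-variance t-test.
#' @return data.frame with columns `gene`, `T`, `p`; attributes `d0` and
#'   `s02` carry the fitted hyperparameters.
#' @references Smyth, G.K. (2004) Linear models and empirical Bayes methods
#'   for assessing differential expression in microarray experiments.
#' @export
moderatedT <- function(data, prior_df = NULL) {
  x <- exprValues(data)
  cls <- sampleClasses(data)
  if (sum(cls == "control") < 2L || sum(cls == "case") < 2L)
    stop("each class needs at least 2 samples")
  core <- .moderatedTCore(x, cls == "case", prior_df = prior_df)
  out <- data.frame(gene = rownames(x), T = core$T, p = core$p,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- core$d0
  attr(out, "s02") <- core$s02
  out
}

# Newton solve of trigamma(y) = x (monotone decreasing)
.trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, clipped to \[0, 1\] and order-preserving.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values (names preserved).
#' @export
adjustFDR <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite numbers in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Flag differentially expressed genes
#'
#' @param q q-value vector (named by gene where available).
#' @param v FDR cutoff in (0, 1); default 0.05.
#' @return If `q` is named, the DE gene names; otherwise the DE indices.
#' @export
flagDE <- function(q, v = 0.05) {
  if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
    stop("'v' must be a single number in (0, 1)")
  de <- q < v
  if (!is.null(names(q))) names(q)[de] else which(de)
}

#' Per-gene pathway frequency
#'
#' `f(A)` is the number of pathways in the collection whose node set
#' contains gene `A`.
#'
#' @param collection A [PathwayCollection-class].
#' @return Named integer vector over the gene universe.
#' @export
geneFrequencies <- function(collection) {
  stopifnot(is(collection, "PathwayCollection"))
  if (!length(collection)) stop("empty collection")
  uni <- geneUniverse(collection)
  f <- setNames(integer(length(uni)), uni)
  for (g in pathways(collection)) {
    nd <- unique(g@nodes)
    f[nd] <- f[nd] + 1L
  }
  f
}

#' Frequency weight Fn
#'
#' Maps pathway frequencies to weights in \[0, 1\]:
#' `literal` uses \eqn{Fn(A) = \sqrt{(f(A) - \min f) / (\max f - \min f)}}
#' (weight grows with frequency); `inverted` flips the ratio so that
#' frequently shared genes are down-weighted and pathway-specific genes get
#' weight near 1.  The published formula and its prose description
#' disagree on the direction, so both are offered; `literal` follows the
#' formula and is the default.  When all frequencies are equal,
#' `Fn` is identically 1.  Frequencies outside the reference range (e.g. a
#' gene absent from every pathway) are clamped into \[0, 1\] before the
#' square root.
#'
#' @param f Named frequency vector from [geneFrequencies()].
#' @param mode `"literal"` or `"inverted"`.
#' @return Named numeric vector of weights in \[0, 1\].
#' @export
frequencyWeight <- function(f, mode = c("literal", "inverted")) {
  mode <- match.arg(mode)
  if (!length(f)) stop("'f' must be non-empty")
  fmin <- min(f); fmax <- max(f)
  if (fmax == fmin) return(setNames(rep(1, length(f)), names(f)))
  r <- if (mode == "literal") (f - fmin) / (fmax - fmin) else
    (fmax - f) / (fmax - fmin)
  sqrt(pmin(pmax(r, 0), 1))
}

#' Gene probability P(A)
#'
#' Combines the moderated t-score and frequency weight into the per-gene
#' probability used by the model, \eqn{P(A) = |T(A) \cdot Fn(A)|}.  Since
#' \eqn{|T|} is unbounded the raw product can exceed one; two scalings keep
#' the result a probability: `max_normalize` (default) divides \eqn{|T|}
#' by the largest \eqn{|T|} among measured genes, `clip` truncates the raw
#' product at 1.  If every t-score is zero, P is identically zero.
#'
#' @param T Named t-score vector.
#' @param Fn Named weight vector over the same genes.
#' @param scaling `"max_normalize"` or `"clip"`.
#' @return Named probability vector in \[0, 1\].
#' @export
geneProbability <- function(T, Fn, scaling = c("max_normalize", "clip")) {
  scaling <- match.arg(scaling)
  if (length(T) != length(Fn))
    stop("'T' and 'Fn' must align over the same genes")
  if (!is.null(names(T)) && !is.null(names(Fn))) {
    if (!all(names(T) == names(Fn))) Fn <- Fn[names(T)]
  }
  P <- if (scaling == "max_normalize") {
    tmax <- max(abs(T))
    if (tmax == 0) rep(0, length(T)) else (abs(T) / tmax) * Fn
  } else {
    pmin(1, abs(T * Fn))
  }
  setNames(pmin(pmax(P, 0), 1), names(T))
}

#' Assemble the per-gene statistic table
#'
#' Runs the moderated t-test, BH adjustment, DE calling, pathway-frequency
#' weighting and the gene probability P(A) over the union of measured genes
#' and the collection's gene universe.  Pathway genes absent from the
#' expression matrix are treated as expressed but non-DE (T = 0, q = 1)
#' with their frequency weight intact, so platform coverage gaps do not
#' silently shut a pathway off.
#'
#' @param data A dataset from [ExpressionDataset()].
#' @param collection A [PathwayCollection-class].
#' @param fdr_cutoff DE cutoff `v` applied to q-values (default 0.05).
#' @param freq_mode Passed to [frequencyWeight()].
#' @param scaling Passed to [geneProbability()].
#' @param stat_table Optional precomputed data.frame with columns
#'   `gene`, `T`, `q` (bypasses the moderated t-test, e.g. for externally
#'   supplied statistics).
#' @return data.frame with columns `gene`, `T`, `p`, `q`, `is_de`, `f`,
#'   `Fn`, `P`.
#' @export
buildGeneStats <- function(data = NULL, collection,
                           fdr_cutoff = 0.05,
                           freq_mode = c("literal", "inverted"),
                           scaling = c("max_normalize", "clip"),
                           stat_table = NULL) {
  freq_mode <- match.arg(freq_mode)
  scaling <- match.arg(scaling)
  f <- geneFrequencies(collection)
  if (is.null(stat_table)) {
    if (is.null(data)) stop("either 'data' or 'stat_table' is required")
    mt <- moderatedT(data)
    q <- adjustFDR(setNames(mt$p, mt$gene))
    stat <- data.frame(gene = mt$gene, T = mt$T, p = mt$p, q = unname(q),
                       stringsAsFactors = FALSE)
  } else {
    if (!all(c("gene", "T", "q") %in% names(stat_table)))
      stop("'stat_table' needs columns gene, T, q")
    stat <- data.frame(gene = as.character(stat_table$gene),
                       T = stat_table$T,
                       p = if ("p" %in% names(stat_table)) stat_table$p else NA_real_,
                       q = stat_table$q, stringsAsFactors = FALSE)
  }
  genes <- union(stat$gene, names(f))
  idx <- match(genes, stat$gene)
  T <- ifelse(is.na(idx), 0, stat$T[idx])
  p <- ifelse(is.na(idx), 1, stat$p[idx])
  q <- ifelse(is.na(idx), 1, stat$q[idx])
  fall <- setNames(integer(length(genes)), genes)
  fall[names(f)] <- f
  # the Fn reference range is the collection's universe
  fmin <- min(f); fmax <- max(f)
  Fn <- if (fmax == fmin) rep(1, length(genes)) else {
    r <- if (freq_mode == "literal") (fall - fmin) / (fmax - fmin) else
      (fmax - fall) / (fmax - fmin)
    sqrt(pmin(pmax(r, 0), 1))
  }
  P <- geneProbability(setNames(T, genes), setNames(Fn, genes), scaling)
  data.frame(gene = genes, T = T, p = p, q = q, is_de = q < fdr_cutoff,
             f = unname(fall), Fn = unname(Fn), P = unname(P),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a gene statistic table as TSV
#'
#' @param stats data.frame from [buildGeneStats()].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
writeGeneStatsTSV <- function(stats, file) {
  utils::write.table(stats, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
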