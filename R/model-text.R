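# textual model dialect: the guarded-command probabilistic-model format of
# the PRISM language (dtmc), with comment lines carrying the gene map and
# the per-effector reachability properties so that export/parse round-trips

.fmtProb <- function(p) sprintf("%.17g", p)

.varNames <- function(genes) {
  v <- paste0("v_", gsub("[^A-Za-z0-9_]", "_", genes))
  # disambiguate collisions deterministically
  while (anyDuplicated(v)) {
    d <- duplicated(v)
    v[d] <- paste0(v[d], "_")
  }
  v
}

.cmdText <- function(kind, A, B, p1, p2) {
  q1 <- .fmtProb(p1); q2 <- .fmtProb(p2)
  switch(kind,
    init = sprintf("  [] (%s=-1) -> %s:(%s'=1) + %s:(%s'=2);",
                   B, q1, B, q2, B),
    source = sprintf("  [] (%s=1|%s=2) -> %s:(%s'=%s+2) + %s:(%s'=0);",
                     B, B, q1, B, B, q2, B),
    activation = sprintf(
      "  [] (%s>2&(%s=1|%s=2)) -> %s:(%s'=(%s=3&%s=1)?3:4) + %s:(%s'=0);",
      A, B, B, q1, B, A, B, q2, B),
    inhibition1 = sprintf(
      "  [] (%s<3&(%s=1|%s=2)) -> %s:(%s'=%s+2) + %s:(%s'=0);",
      A, B, B, q1, B, B, q2, B),
    inhibition2 = sprintf(
      "  [] (%s>2&%s>2) -> %s:(%s'=%s-2) + %s:(%s'=0);",
      A, B, q1, B, B, q2, B)
  )
}

#' Export a guarded model as text
#'
#' Renders the model in the guarded-command probabilistic-model dialect of
#' the PRISM language: a `dtmc` header, one module holding every variable
#' (range `[-1..4]`, initial -1) and command, comment lines mapping
#' variables to gene identifiers, and one reachability property
#' `P=? [ F (g=4) ]` per final effector.  The rendering is deterministic
#' (genes sorted, commands in construction order) and
#' [parseModelText()] inverts it exactly.
#'
#' @param m A [GuardedModel-class].
#' @return A single text string.
#' @export
exportModelText <- function(m) {
  stopifnot(is(m, "GuardedModel"))
  genes <- m@genes
  vars <- .varNames(genes)
  vof <- function(g) vars[match(g, genes)]
  lines <- c("dtmc", "",
             sprintf("// pathway: %s", m@pathwayId),
             sprintf("// var %s gene \"%s\"", vars, genes),
             if (length(m@deGenes)) sprintf("// de %s", vof(m@deGenes)),
             "",
             sprintf("module %s", gsub("[^A-Za-z0-9_]", "_", m@pathwayId)))
  lines <- c(lines, sprintf("  %s : [-1..4] init -1;", vars))
  for (cmd in m@commands) {
    A <- if (is.na(cmd$src)) "" else vof(cmd$src)
    lines <- c(lines, .cmdText(cmd$kind, A, vof(cmd$tgt),
                               cmd$probs[1], cmd$probs[2]))
  }
  lines <- c(lines, "endmodule", "")
  for (e in m@effectors) {
    lines <- c(lines, sprintf("// effector: %s", vof(e)),
               sprintf("// property: P=? [ F (%s=4) ]", vof(e)))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse the textual model dialect
#'
#' Inverts [exportModelText()]: reconstructs the variables, guards,
#' branches and probabilities of a guarded model.  Branch probabilities of
#' every command must sum to one (tolerance 1e-9); any line outside the
#' grammar raises a parse error naming the line number.
#'
#' @param text Model text (single string or character vector of lines).
#' @return A [GuardedModel-class].
#' @export
parseModelText <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  perr <- function(i, why) stop("parse error at line ", i, ": ", why,
                                call. = FALSE)
  stripped <- trimws(lines)
  body_idx <- which(nzchar(stripped))
  if (!length(body_idx)) stop("parse error: empty model text", call. = FALSE)
  if (stripped[body_idx[1]] != "dtmc")
    perr(body_idx[1], "expected 'dtmc' header")

  pathway_id <- "pathway"
  gene_of <- character(); de_vars <- character(); eff_vars <- character()
  vars <- character(); cmds <- list()
  in_module <- FALSE; seen_module <- FALSE

  num <- "([0-9.eE+-]+)"
  ident <- "([A-Za-z_][A-Za-z0-9_]*)"
  re_var <- paste0("^", ident, " : \\[-1\\.\\.4\\] init -1;$")
  re_init <- paste0("^\\[\\] \\(", ident, "=-1\\) -> ", num, ":\\(", ident,
                    "'=1\\) \\+ ", num, ":\\(", ident, "'=2\\);$")
  re_source <- paste0("^\\[\\] \\(", ident, "=1\\|", ident, "=2\\) -> ", num,
                      ":\\(", ident, "'=", ident, "\\+2\\) \\+ ", num,
                      ":\\(", ident, "'=0\\);$")
  re_act <- paste0("^\\[\\] \\(", ident, ">2&\\(", ident, "=1\\|", ident,
                   "=2\\)\\) -> ", num, ":\\(", ident, "'=\\(", ident,
                   "=3&", ident, "=1\\)\\?3:4\\) \\+ ", num, ":\\(", ident,
                   "'=0\\);$")
  re_inh1 <- paste0("^\\[\\] \\(", ident, "<3&\\(", ident, "=1\\|", ident,
                    "=2\\)\\) -> ", num, ":\\(", ident, "'=", ident,
                    "\\+2\\) \\+ ", num, ":\\(", ident, "'=0\\);$")
  re_inh2 <- paste0("^\\[\\] \\(", ident, ">2&", ident, ">2\\) -> ", num,
                    ":\\(", ident, "'=", ident, "-2\\) \\+ ", num,
                    ":\\(", ident, "'=0\\);$")

  grab <- function(line, re) {
    mm <- regmatches(line, regexec(re, line))[[1]]
    if (length(mm)) mm[-1] else NULL
  }
  checkProbs <- function(i, p1, p2) {
    if (!is.finite(p1) || !is.finite(p2) || p1 < -1e-9 || p2 < -1e-9)
      perr(i, "invalid branch probability")
    if (abs(p1 + p2 - 1) > 1e-9)
      perr(i, sprintf("branch probabilities sum to %s, not 1",
                      format(p1 + p2)))
  }

  for (i in seq_along(stripped)) {
    ln <- stripped[i]
    if (!nzchar(ln) || ln == "dtmc") next
    if (startsWith(ln, "//")) {
      if (!is.null(g <- grab(ln, "^// pathway: (.*)$"))) pathway_id <- g[1]
      else if (!is.null(g <- grab(ln, "^// var ([A-Za-z0-9_]+) gene \"(.*)\"$")))
        gene_of[g[1]] <- g[2]
      else if (!is.null(g <- grab(ln, "^// de ([A-Za-z0-9_]+)$")))
        de_vars <- c(de_vars, g[1])
      else if (!is.null(g <- grab(ln, "^// effector: ([A-Za-z0-9_]+)$")))
        eff_vars <- c(eff_vars, g[1])
      next
    }
    if (!is.null(g <- grab(ln, "^module ([A-Za-z0-9_]+)$"))) {
      if (seen_module) perr(i, "multiple modules")
      in_module <- TRUE; seen_module <- TRUE; next
    }
    if (ln == "endmodule") {
      if (!in_module) perr(i, "'endmodule' outside module")
      in_module <- FALSE; next
    }
    if (!in_module) perr(i, "statement outside module")
    if (!is.null(g <- grab(ln, re_var))) { vars <- c(vars, g[1]); next }
    if (!is.null(g <- grab(ln, re_init))) {
      if (g[1] != g[3] || g[1] != g[5]) perr(i, "inconsistent variable in command")
      p1 <- as.numeric(g[2]); p2 <- as.numeric(g[4]); checkProbs(i, p1, p2)
      cmds[[length(cmds) + 1L]] <- list(kind = "init", src = NA_character_,
                                        tgt = g[1], probs = c(p1, p2))
      next
    }
    if (!is.null(g <- grab(ln, re_source))) {
      if (length(unique(g[c(1, 2, 4, 5, 7)])) != 1L)
        perr(i, "inconsistent variable in command")
      p1 <- as.numeric(g[3]); p2 <- as.numeric(g[6]); checkProbs(i, p1, p2)
      cmds[[length(cmds) + 1L]] <- list(kind = "source", src = NA_character_,
                                        tgt = g[1], probs = c(p1, p2))
      next
    }
    if (!is.null(g <- grab(ln, re_act))) {
      # groups: A B B p1 B A B p2 B
      if (length(unique(g[c(2, 3, 5, 7, 9)])) != 1L || g[1] != g[6])
        perr(i, "inconsistent variables in command")
      p1 <- as.numeric(g[4]); p2 <- as.numeric(g[8]); checkProbs(i, p1, p2)
      cmds[[length(cmds) + 1L]] <- list(kind = "activation", src = g[1],
                                        tgt = g[2], probs = c(p1, p2))
      next
    }
    if (!is.null(g <- grab(ln, re_inh1))) {
      if (length(unique(g[c(2, 3, 5, 6, 8)])) != 1L)
        perr(i, "inconsistent variables in command")
      p1 <- as.numeric(g[4]); p2 <- as.numeric(g[7]); checkProbs(i, p1, p2)
      cmds[[length(cmds) + 1L]] <- list(kind = "inhibition1", src = g[1],
                                        tgt = g[2], probs = c(p1, p2))
      next
    }
    if (!is.null(g <- grab(ln, re_inh2))) {
      if (length(unique(g[c(2, 4, 5, 7)])) != 1L)
        perr(i, "inconsistent variables in command")
      p1 <- as.numeric(g[3]); p2 <- as.numeric(g[6]); checkProbs(i, p1, p2)
      cmds[[length(cmds) + 1L]] <- list(kind = "inhibition2", src = g[1],
                                        tgt = g[2], probs = c(p1, p2))
      next
    }
    perr(i, paste0("unrecognized statement '", ln, "'"))
  }
  if (!seen_module) stop("parse error: no module found", call. = FALSE)
  toGene <- function(v) {
    if (!length(v)) return(character())
    g <- gene_of[v]
    unname(ifelse(is.na(g), v, g))
  }
  genes <- toGene(vars)
  cmds <- lapply(cmds, function(cmd) {
    cmd$tgt <- toGene(cmd$tgt)
    if (!is.na(cmd$src)) cmd$src <- toGene(cmd$src)
    cmd
  })
  new("GuardedModel", pathwayId = pathway_id, genes = genes,
      effectors = toGene(eff_vars), deGenes = toGene(de_vars),
      commands = cmds)
}

#' Write / read a model file
#'
#' `writeModel()` writes `exportModelText(m)` to a `.pm` file and, when
#' `properties_file` is given, one reachability query per effector to a
#' companion properties file.  `readModel()` parses such a file back.
#'
#' @param m A [GuardedModel-class].
#' @param file Model file path (conventionally `<pathway_id>.pm`).
#' @param properties_file Optional path for the property list.
#' @return Invisibly, `file`.
#' @export
writeModel <- function(m, file, properties_file = NULL) {
  cat(exportModelText(m), file = file)
  if (!is.null(properties_file)) {
    vars <- .varNames(m@genes)
    eff <- vars[match(m@effectors, m@genes)]
    writeLines(sprintf("P=? [ F (%s=4) ]", eff), properties_file)
  }
  invisible(file)
}

#' @rdname writeModel
#' @export
readModel <- function(file) parseModelText(readLines(file))
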