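# ---- internal fast pipeline ------------------------------------------------
# The permutation null recomputes the full pipeline (moderated t -> DE calls
# -> P(A) -> parameters -> model -> score) for every relabeling.  Everything
# that does not depend on the labels (pathway frequencies, Fn, cross-pathway
# interaction probabilities, command ordering and index structure) is
# computed once up front; per relabeling only the probability vector of the
# command table changes.

.precompute <- function(data, collection, config, ids = NULL) {
  ids <- ids %||% names(collection)
  f <- geneFrequencies(collection)
  fmin <- min(f); fmax <- max(f)
  x <- exprValues(data)
  measured <- rownames(x)
  genes_all <- union(measured, names(f))
  fall <- setNames(integer(length(genes_all)), genes_all)
  fall[names(f)] <- f
  Fn <- if (fmax == fmin) setNames(rep(1, length(genes_all)), genes_all) else {
    r <- if (config$freq_mode == "literal") (fall - fmin) / (fmax - fmin) else
      (fmax - fall) / (fmax - fmin)
    sqrt(pmin(pmax(r, 0), 1))
  }
  structs <- lapply(ids, function(id) {
    g <- collection[[id]]
    ed <- g@edges
    n_e <- nrow(ed)
    pol <- if (n_e) edgePolarity(ed$kind) else character()
    p_edge <- vapply(seq_len(n_e), function(i)
      interactionProbability(collection, ed$from[i], ed$to[i], pol[i]),
      numeric(1))
    genes <- sort(g@nodes)
    n_g <- length(genes)
    sources <- sort(setdiff(genes, unique(ed$to)))
    effectors <- suppressWarnings(finalEffectors(g))
    act <- pol == "activating"
    # command table skeleton (order: inits, sources, edges; inhibition
    # edges contribute a pair of commands)
    eord <- rep(seq_len(n_e), ifelse(act, 1L, 2L))
    esecond <- duplicated(eord)
    kind <- c(rep(1L, n_g), rep(2L, length(sources)),
              ifelse(act[eord], 3L, ifelse(esecond, 5L, 4L)))
    src <- c(rep(-1L, n_g + length(sources)),
             match(ed$from, genes)[eord] - 1L)
    tgt <- c(seq_len(n_g) - 1L,
             match(sources, genes) - 1L,
             match(ed$to, genes)[eord] - 1L)
    list(graph = g, id = id, genes = genes,
         gidx = match(genes, genes_all),          # rows in the stat vectors
         fidx = match(ed$from, genes_all),        # per original edge
         tidx = match(ed$to, genes_all),
         act = act, p_edge = p_edge,
         sources = sources,
         sidx = match(sources, genes_all),
         eord = eord, esecond = esecond,
         kind = kind, src = src, tgt = tgt,
         effectors = effectors,
         eff_tgt = match(effectors, genes) - 1L,
         step_cap = as.integer(10L * length(kind) * n_g))
  })
  names(structs) <- ids
  list(x = x, measured = measured, genes_all = genes_all, Fn = Fn,
       structs = structs, config = config)
}

# moderated t on a plain matrix (hot path; see moderatedT() for the
# documented interface and the hyperparameter estimation notes)
.moderatedTCore <- function(x, is_case, prior_df = NULL) {
  n2 <- sum(is_case); n1 <- length(is_case) - n2
  xc <- x[, !is_case, drop = FALSE]
  xd <- x[, is_case, drop = FALSE]
  m1 <- rowMeans(xc); m2 <- rowMeans(xd)
  v1 <- rowSums((xc - m1)^2) / (n1 - 1L)
  v2 <- rowSums((xd - m2)^2) / (n2 - 1L)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d
  if (is.null(prior_df)) {
    pos <- s2 > 0
    if (!any(pos)) stop("all genes have zero variance; cannot estimate prior")
    z <- log(s2[pos])
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- if (sum(pos) > 1L) sum((e - emean)^2) / (sum(pos) - 1L) else 0
    evar <- evar - trigamma(d / 2)
    if (evar > 0) {
      d0 <- 2 * .trigammaInverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf          # no excess dispersion: all variances shrink fully
      s02 <- mean(s2[pos])
    }
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2[s2 > 0]) else 0
  }
  s2post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2post * (1 / n1 + 1 / n2))
  T <- ifelse(se > 0, (m2 - m1) / se, 0)
  df_total <- min(d + d0, d * length(s2))
  list(T = unname(T), p = unname(2 * pt(-abs(T), df = df_total)),
       d0 = d0, s02 = s02)
}

# label-dependent gene statistics on the precomputed gene set
.statsForLabels <- function(pre, labels) {
  cfg <- pre$config
  mt <- .moderatedTCore(pre$x, labels == "case")
  q <- p.adjust(mt$p, method = "BH")
  n_extra <- length(pre$genes_all) - length(pre$measured)
  T <- c(mt$T, rep(0, n_extra))        # genes_all = measured then the rest
  qq <- c(q, rep(1, n_extra))
  de <- qq < cfg$fdr_cutoff
  P <- if (cfg$scaling == "max_normalize") {
    tmax <- max(abs(T))
    if (tmax == 0) rep(0, length(T)) else (abs(T) / tmax) * pre$Fn
  } else {
    pmin(1, abs(T * pre$Fn))
  }
  list(de = de, P = unname(P))
}

# probability column of the command table for one pathway under given stats
.commandProbs <- function(st, stats, config) {
  de <- stats$de; P <- stats$P
  aw <- config$alpha_weight; ae <- config$alpha_error
  gde <- de[st$gidx]
  p_init <- ifelse(gde, ae, 1 - ae)
  if (length(st$act)) {
    dif <- aw * (1 + as.numeric(de[st$fidx]) + as.numeric(de[st$tidx]))
    strength <- dif * P[st$fidx] * st$p_edge
    p_e <- ifelse(st$act[st$eord],
                  strength[st$eord],
                  ifelse(st$esecond, strength[st$eord], st$p_edge[st$eord]))
  } else {
    p_e <- numeric()
  }
  c(p_init, P[st$sidx], p_e)
}

# score one precomputed pathway under given gene stats
.scoreStruct <- function(st, stats, config) {
  if (!length(st$effectors)) {
    return(list(score = 0, effector_probs = setNames(numeric(0), character(0)),
                engine = "none", n = 0L, censored_fraction = 0))
  }
  p1 <- .commandProbs(st, stats, config)
  if (config$engine == "monte_carlo") {
    step_cap <- if (is.null(config$step_cap)) st$step_cap else
      as.integer(config$step_cap)
    res <- withSeed(config$mc_seed,
      mc_simulate(st$kind, st$src, st$tgt, p1, length(st$genes), st$eff_tgt,
                  config$n_traj, step_cap))
    probs <- setNames(res$successes / config$n_traj, st$effectors)
    return(list(score = sum(probs), effector_probs = probs,
                engine = "monte_carlo", n = config$n_traj,
                censored_fraction = res$censored / config$n_traj))
  }
  m <- .modelFromTable(st, p1)
  .scoreModel(m, config)
}

# materialize the GuardedModel matching a precomputed command table
.modelFromTable <- function(st, p1) {
  kindName <- names(.CMD_CODE)
  cmds <- lapply(seq_along(st$kind), function(i) {
    list(kind = kindName[st$kind[i]],
         src = if (st$src[i] < 0) NA_character_ else st$genes[st$src[i] + 1L],
         tgt = st$genes[st$tgt[i] + 1L],
         probs = c(p1[i], 1 - p1[i]))
  })
  new("GuardedModel", pathwayId = st$id, genes = st$genes,
      effectors = st$effectors, deGenes = character(), commands = cmds)
}

# reachability per effector + summed score, honoring the engine config
.scoreModel <- function(m, config) {
  eff <- m@effectors
  run_mc <- function() {
    res <- .mcMulti(m, eff, n_traj = config$n_traj,
                    step_cap = config$step_cap, seed = config$mc_seed)
    list(score = sum(res$probs), effector_probs = res$probs,
         engine = "monte_carlo", n = config$n_traj,
         censored_fraction = res$censored_fraction)
  }
  run_exact <- function() {
    chain <- buildChain(m, config$state_cap)
    probs <- vapply(eff, function(e)
      reachabilityExact(chain, e)$probability, numeric(1))
    list(score = sum(probs), effector_probs = probs, engine = "exact",
         n = nrow(chain$states), censored_fraction = 0)
  }
  switch(config$engine,
    exact = run_exact(),
    monte_carlo = run_mc(),
    auto = tryCatch(run_exact(), fopa_state_cap = function(e) run_mc()))
}

# ---- public interface ------------------------------------------------------

#' Score a pathway
#'
#' Builds the guarded-command model once, computes the reachability
#' probability `P[F (g = 4)]` for every final effector `g`, and sums them
#' into the pathway score.  Effector-rich pathways therefore have larger
#' raw scores; the permutation null (see [permutationPvalue()]) partially
#' absorbs this.
#'
#' @param g A normalized [PathwayGraph-class].
#' @param params A [ModelParameters-class] covering `g`.
#' @param de Optional DE gene set (defaults to the flags in `params`).
#' @param config A [fopaConfig()] list (engine settings).
#' @return A list of class `"fopa_score"`: `pathway_id`,
#'   `effector_probs`, `score`, `engine`, `n` (states or trajectories),
#'   `censored_fraction`.
#' @export
pathwayScore <- function(g, params, de = NULL, config = fopaConfig()) {
  m <- buildModel(g, params, de)
  if (!length(m@effectors))
    warning("pathway '", g@id, "' has no final effectors; score is 0")
  res <- if (length(m@effectors)) .scoreModel(m, config) else
    list(score = 0, effector_probs = setNames(numeric(0), character(0)),
         engine = "none", n = 0L, censored_fraction = 0)
  structure(c(list(pathway_id = g@id), res), class = "fopa_score")
}

#' @export
print.fopa_score <- function(x, ...) {
  cat(sprintf("Pathway '%s': score = %.6g over %d effector(s) [%s]\n",
              x$pathway_id, x$score, length(x$effector_probs), x$engine))
  invisible(x)
}

# class-size-preserving label permutations; exhaustive when feasible
.permutationSet <- function(labels, n_perm) {
  n <- length(labels)
  case_n <- sum(labels == "case")
  n_distinct <- choose(n, case_n)
  if (n_distinct <= n_perm) {
    sets <- combn(n, case_n)
    list(sets = lapply(seq_len(ncol(sets)), function(k) sets[, k]),
         exhaustive = TRUE)
  } else {
    list(sets = replicate(n_perm, sample.int(n, case_n), simplify = FALSE),
         exhaustive = FALSE)
  }
}

.labelsFromCase <- function(n, case_idx) {
  lab <- rep("control", n)
  lab[case_idx] <- "case"
  lab
}

#' Permutation p-value of one pathway score
#'
#' Computes the real score from the true labels, then recomputes the full
#' pipeline (moderated t, DE calls, gene probabilities, model parameters,
#' model, score) under `n_perm` class-size-preserving label permutations.
#' The p-value is the fraction of permuted scores at least as large as the
#' real score (no pseudocount unless `config$smoothing`).  When the number
#' of distinct relabelings is at most `n_perm`, they are enumerated
#' exhaustively instead of sampled.
#'
#' @param data A dataset from [ExpressionDataset()].
#' @param g A normalized [PathwayGraph-class]; it is substituted into the
#'   collection under its id (or added) so the interaction-probability
#'   denominators stay well defined.
#' @param collection A [PathwayCollection-class].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutation draw and any Monte-Carlo
#'   scoring.
#' @param config A [fopaConfig()] list.
#' @return The permutation p-value (single number in \[0, 1\]).
#' @export
permutationPvalue <- function(data, g, collection, n_perm = 200L, seed = 1L,
                              config = fopaConfig()) {
  if (n_perm < 1L) stop("'n_perm' must be at least 1")
  config$n_perm <- as.integer(n_perm)
  pws <- pathways(collection)
  pws[[g@id]] <- g
  collection <- PathwayCollection(pws)
  res <- analyzeAll(data, collection, config = config, seed = seed,
                    ids = g@id)
  res$p_value[match(g@id, res$pathway_id)]
}

#' Analyze a whole pathway collection
#'
#' Scores every pathway against the real labels and against a shared set
#' of label permutations, producing the ranked result table.  Rows are
#' sorted by permutation p-value (ascending), ties broken by score
#' (descending) then pathway id; ranks are 1-based with ties (identical
#' p-value and score) receiving their mean rank, and
#' `rank_percentage = 100 * rank / n_pathways`.
#'
#' @param data A dataset from [ExpressionDataset()].
#' @param collection A non-empty [PathwayCollection-class] (normalized
#'   pathways).
#' @param config A [fopaConfig()] list; `config$n_perm` sets the
#'   permutation count.
#' @param seed Integer seed (permutations and Monte-Carlo scoring).
#' @param ids Optional subset of pathway ids to score (the full collection
#'   still defines frequencies and interaction probabilities).
#' @return data.frame with columns `pathway_id`, `score`, `p_value`,
#'   `rank`, `rank_percentage`, `n_effectors`, `engine`,
#'   `n_states_or_traj`, sorted by rank.
#' @export
analyzeAll <- function(data, collection, config = fopaConfig(), seed = 1L,
                       ids = NULL) {
  stopifnot(is(collection, "PathwayCollection"))
  if (!length(collection)) stop("empty collection")
  withSeed(seed, {
    # common random numbers: one Monte-Carlo seed shared by the real and
    # every permuted scoring, so score comparisons are not blurred by
    # independent simulation noise
    if (is.null(config$mc_seed)) config$mc_seed <- drawSeed()
    pre <- .precompute(data, collection, config, ids)
    labels <- sampleClasses(data)
    real_stats <- .statsForLabels(pre, labels)
    real <- lapply(pre$structs, .scoreStruct, stats = real_stats,
                   config = config)
    real_scores <- vapply(real, `[[`, numeric(1), "score")

    perms <- .permutationSet(labels, config$n_perm)
    n_perm <- length(perms$sets)
    ge_count <- setNames(numeric(length(pre$structs)), names(pre$structs))
    for (ps in perms$sets) {
      plab <- .labelsFromCase(length(labels), ps)
      pstats <- .statsForLabels(pre, plab)
      pscores <- vapply(pre$structs, function(st)
        .scoreStruct(st, pstats, config)$score, numeric(1))
      ge_count <- ge_count + as.numeric(pscores >= real_scores)
    }
    p_value <- if (config$smoothing) (1 + ge_count) / (1 + n_perm) else
      ge_count / n_perm

    out <- data.frame(
      pathway_id = names(pre$structs),
      score = unname(real_scores),
      p_value = unname(p_value),
      n_effectors = vapply(pre$structs, function(s)
        length(s$effectors), integer(1)),
      engine = vapply(real, `[[`, character(1), "engine"),
      n_states_or_traj = vapply(real, function(r)
        as.integer(r$n), integer(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(out$p_value, -out$score, out$pathway_id), , drop = FALSE]
    pos <- seq_len(nrow(out))
    tie_key <- paste(format(out$p_value, digits = 15),
                     format(out$score, digits = 15))
    rank <- stats::ave(pos, tie_key, FUN = mean)
    out$rank <- rank
    out$rank_percentage <- 100 * rank / nrow(out)
    rownames(out) <- NULL
    out[, c("pathway_id", "score", "p_value", "rank", "rank_percentage",
            "n_effectors", "engine", "n_states_or_traj")]
  })
}
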