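# desk-scale implementations of the evaluation protocols: false-positive
# rate under permuted labels, decoy-pathway discrimination, target-pathway
# recovery, and robustness to topology perturbation

#' False-positive rate under permuted class labels
#'
#' For each trial the sample labels are randomly permuted (class sizes
#' preserved) before the full analysis; the fraction of pathways called
#' significant (`p_value < threshold`) is recorded and averaged over
#' trials.  On null data this should approximate the nominal threshold.
#'
#' @param data A dataset from [ExpressionDataset()].
#' @param collection A [PathwayCollection-class].
#' @param n_trials Number of label-permutation trials (>= 1).
#' @param threshold Significance threshold on the permutation p-value.
#' @param seed Integer seed.
#' @param config A [fopaConfig()] list.
#' @return Mean fraction of significant pathways over trials; the per-trial
#'   fractions are attached as attribute `"per_trial"`.
#' @export
fpRateProtocol <- function(data, collection, n_trials = 10L,
                           threshold = 0.05, seed = 1L,
                           config = fopaConfig(engine = "monte_carlo", n_traj = 4000L)) {
  if (n_trials < 1L) stop("'n_trials' must be at least 1")
  withSeed(seed, {
    labels <- sampleClasses(data)
    fr <- vapply(seq_len(n_trials), function(t) {
      plab <- sample(labels)
      res <- analyzeAll(.relabel(data, plab), collection,
                        config = config, seed = drawSeed())
      mean(res$p_value < threshold)
    }, numeric(1))
    structure(mean(fr), per_trial = fr)
  })
}

#' Real-versus-decoy discrimination AUC
#'
#' The probability that a randomly chosen real pathway outranks a randomly
#' chosen decoy, ranking by permutation p-value ascending with score
#' descending as tie-break; exact ties count one half.  This is the
#' rank-statistic (Mann-Whitney) form of the area under the ROC curve for
#' separating real from decoy pathways.
#'
#' @param real_results,decoy_results data.frames with columns `p_value`
#'   and `score` (as returned by [analyzeAll()]).
#' @return AUC in \[0, 1\].
#' @export
decoyAUC <- function(real_results, decoy_results) {
  if (!nrow(real_results) || !nrow(decoy_results))
    stop("both result sets must be non-empty")
  better <- function(p1, s1, p2, s2) {
    if (p1 < p2) 1 else if (p1 > p2) 0 else
      if (s1 > s2) 1 else if (s1 < s2) 0 else 0.5
  }
  tot <- 0
  for (i in seq_len(nrow(real_results)))
    for (j in seq_len(nrow(decoy_results)))
      tot <- tot + better(real_results$p_value[i], real_results$score[i],
                          decoy_results$p_value[j], decoy_results$score[j])
  tot / (nrow(real_results) * nrow(decoy_results))
}

#' Summaries of target-pathway placement
#'
#' Given one row per benchmark dataset (its designated target pathway's
#' rank, p-value and the pathway count), computes the sensitivity and
#' prioritization summaries: the median target p-value, the median and
#' mean rank percentage (`100 * rank / n_pathways`) and the mean
#' reciprocal rank.
#'
#' @param results data.frame with columns `target_rank`, `target_p`,
#'   `n_pathways` (one row per dataset).
#' @return A list: `median_target_p`, `median_rank_pct`, `mean_rank_pct`,
#'   `mean_reciprocal_rank`.
#' @export
targetMetrics <- function(results) {
  if (!nrow(results)) stop("empty result list")
  need <- c("target_rank", "target_p", "n_pathways")
  if (!all(need %in% names(results)))
    stop("results need columns ", paste(need, collapse = ", "))
  pct <- 100 * results$target_rank / results$n_pathways
  list(median_target_p = median(results$target_p),
       median_rank_pct = median(pct),
       mean_rank_pct = mean(pct),
       mean_reciprocal_rank = mean(1 / results$target_rank))
}

#' Robustness of the significance call to topology perturbation
#'
#' Emulates pathway-database incompleteness and noise: for each
#' perturbation fraction and mode the pathway's edges are perturbed
#' `n_reps` times and the perturbed pathway is re-analyzed; the similarity
#' is the fraction of perturbed pathways whose significance call
#' (`p_value < 0.05`, mirroring the usual convention) matches the
#' unperturbed pathway's call.
#'
#' @param g The pathway of interest (member of `collection`).
#' @param data A dataset from [ExpressionDataset()].
#' @param collection A [PathwayCollection-class].
#' @param fractions Perturbation fractions in \[0, 1\].
#' @param modes Subset of `c("remove", "rewire")`.
#' @param n_reps Replicates per (fraction, mode).
#' @param seed Integer seed.
#' @param config A [fopaConfig()] list (`config$n_perm` permutations per
#'   p-value).
#' @return data.frame with columns `fraction`, `mode`, `similarity`.
#' @export
robustnessCurve <- function(g, data, collection,
                            fractions = c(0.1, 0.2, 0.3, 0.4, 0.5),
                            modes = c("remove", "rewire"), n_reps = 10L,
                            seed = 1L,
                            config = fopaConfig(engine = "monte_carlo", n_traj = 4000L,
                                                n_perm = 100L)) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (any(fractions < 0 | fractions > 1))
    stop("'fractions' must lie in [0, 1]")
  withSeed(seed, {
    base_call <- permutationPvalue(data, g, collection,
                                   n_perm = config$n_perm,
                                   seed = drawSeed(), config = config) < 0.05
    grid <- expand.grid(fraction = fractions, mode = modes,
                        stringsAsFactors = FALSE)
    grid$similarity <- vapply(seq_len(nrow(grid)), function(k) {
      same <- vapply(seq_len(n_reps), function(r) {
        gp <- perturbGraph(g, grid$fraction[k], grid$mode[k],
                           seed = drawSeed())
        pv <- permutationPvalue(data, gp, collection,
                                n_perm = config$n_perm,
                                seed = drawSeed(), config = config)
        (pv < 0.05) == base_call
      }, logical(1))
      mean(same)
    }, numeric(1))
    grid
  })
}

#' Target-pathway recovery protocol
#'
#' The desk-scale analog of benchmarking on disease datasets with a known
#' target pathway: for each replicate a fresh collection and expression
#' dataset are simulated (the target pathway carrying the signal), the
#' whole collection is analyzed, and the target's rank and p-value are
#' recorded.  Summarize with [targetMetrics()].
#'
#' @param n_replicates Number of simulated datasets.
#' @param spec A [simulationSpec()]; each replicate re-seeds it.
#' @param n_perm Permutations per analysis.
#' @param seed Integer seed.
#' @param config A [fopaConfig()] list.
#' @return data.frame with one row per replicate: `replicate`,
#'   `target_rank`, `target_p`, `target_rank_pct`, `n_pathways`.
#' @export
targetRecoveryProtocol <- function(n_replicates = 10L,
                                   spec = simulationSpec(),
                                   n_perm = 100L, seed = 1L,
                                   config = fopaConfig(engine = "monte_carlo", n_traj = 4000L)) {
  config$n_perm <- as.integer(n_perm)
  withSeed(seed, {
    rows <- lapply(seq_len(n_replicates), function(r) {
      sp <- spec
      sp$seed <- drawSeed()
      coll <- simulateCollection(sp)
      dat <- simulateExpression(sp, coll)
      res <- analyzeAll(dat, coll, config = config, seed = drawSeed())
      i <- match(sp$target_pathway_id, res$pathway_id)
      data.frame(replicate = r, target_rank = res$rank[i],
                 target_p = res$p_value[i],
                 target_rank_pct = res$rank_percentage[i],
                 n_pathways = nrow(res))
    })
    do.call(rbind, rows)
  })
}

#' Null-calibration protocol
#'
#' Simulates exchangeable-label datasets (no signal: effect size 0) and
#' records, per replicate, the fraction of pathways with permutation
#' p-value below the threshold.  A calibrated method stays near the
#' nominal level.
#'
#' @param n_replicates Number of simulated null datasets.
#' @param spec A [simulationSpec()]; its effect size is forced to 0.
#' @param n_perm Permutations per analysis.
#' @param threshold Significance threshold (default 0.05).
#' @param seed Integer seed.
#' @param config A [fopaConfig()] list.
#' @return data.frame with columns `replicate`, `frac_significant`, plus
#'   attribute `"p_values"` holding every pathway p-value.
#' @export
nullCalibrationProtocol <- function(n_replicates = 5L,
                                    spec = simulationSpec(),
                                    n_perm = 100L, threshold = 0.05,
                                    seed = 1L,
                                    config = fopaConfig(engine = "monte_carlo", n_traj = 4000L)) {
  spec$effect_size <- 0
  config$n_perm <- as.integer(n_perm)
  withSeed(seed, {
    all_p <- numeric()
    rows <- lapply(seq_len(n_replicates), function(r) {
      sp <- spec
      sp$seed <- drawSeed()
      coll <- simulateCollection(sp)
      dat <- simulateExpression(sp, coll)
      res <- analyzeAll(dat, coll, config = config, seed = drawSeed())
      all_p <<- c(all_p, res$p_value)
      data.frame(replicate = r, frac_significant = mean(res$p_value < threshold))
    })
    structure(do.call(rbind, rows), p_values = all_p)
  })
}

#' Decoy-discrimination protocol
#'
#' Simulates one signal dataset, builds decoys of every real pathway
#' (labels resampled from the full measured gene set), analyzes the
#' combined collection and returns the real-versus-decoy AUC together
#' with the underlying result tables.
#'
#' @param spec A [simulationSpec()].
#' @param seed Integer seed.
#' @param config A [fopaConfig()] list.
#' @param n_perm Permutations per analysis.
#' @return A list: `auc`, `real`, `decoy` (result tables).
#' @export
decoyProtocol <- function(spec = simulationSpec(), seed = 1L,
                          config = fopaConfig(engine = "monte_carlo", n_traj = 4000L),
                          n_perm = 100L) {
  config$n_perm <- as.integer(n_perm)
  withSeed(seed, {
    sp <- spec
    sp$seed <- drawSeed()
    coll <- simulateCollection(sp)
    dat <- simulateExpression(sp, coll)
    universe <- rownames(exprValues(dat))
    decoys <- lapply(pathways(coll), function(g)
      makeDecoy(g, universe, seed = drawSeed()))
    combined <- PathwayCollection(c(pathways(coll), decoys))
    res <- analyzeAll(dat, combined, config = config, seed = drawSeed())
    is_decoy <- grepl("_decoy$", res$pathway_id)
    list(auc = decoyAUC(res[!is_decoy, ], res[is_decoy, ]),
         real = res[!is_decoy, ], decoy = res[is_decoy, ])
  })
}
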