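#' Analysis configuration
#'
#' Collects the tunable settings shared by the scoring pipeline.
#'
#' @param engine Reachability engine: `"auto"` (explicit-state under the
#'   state cap, Monte-Carlo beyond it), `"exact"` or `"monte_carlo"`.
#' @param state_cap Maximum explored states for the explicit engine
#'   (default 500000).
#' @param n_traj Monte-Carlo trajectories (default 20000).
#' @param step_cap Maximum steps per trajectory; `NULL` means
#'   `10 * n_commands * n_genes` of the model at hand.
#' @param mc_seed Seed used by the Monte-Carlo engine when dispatched via
#'   [reachability()]; `NULL` draws from the ambient RNG stream.
#' @param fdr_cutoff DE cutoff v for q-values (default 0.05).
#' @param alpha_weight DE-relation weight unit (default 1/6).
#' @param alpha_error Initialization error; `NULL` means `fdr_cutoff`.
#' @param freq_mode Frequency-weight mode (see [frequencyWeight()]).
#' @param scaling Gene-probability scaling (see [geneProbability()]).
#' @param n_perm Label permutations for significance (default 200).
#' @param smoothing Use the `(1 + k)/(1 + n)` pseudocount form of the
#'   permutation p-value (default `FALSE`, the literal count ratio).
#' @return A list of settings with class `"fopa_config"`.
#' @export
fopaConfig <- function(engine = c("auto", "exact", "monte_carlo"),
                       state_cap = 500000L, n_traj = 20000L, step_cap = NULL,
                       mc_seed = NULL, fdr_cutoff = 0.05, alpha_weight = 1 / 6,
                       alpha_error = NULL,
                       freq_mode = c("literal", "inverted"),
                       scaling = c("max_normalize", "clip"),
                       n_perm = 200L, smoothing = FALSE) {
  structure(list(
    engine = match.arg(engine),
    state_cap = as.integer(state_cap),
    n_traj = as.integer(n_traj),
    step_cap = step_cap,
    mc_seed = mc_seed,
    fdr_cutoff = fdr_cutoff,
    alpha_weight = alpha_weight,
    alpha_error = alpha_error %||% fdr_cutoff,
    freq_mode = match.arg(freq_mode),
    scaling = match.arg(scaling),
    n_perm = as.integer(n_perm),
    smoothing = isTRUE(smoothing)
  ), class = "fopa_config")
}

.stepCap <- function(config, enc) {
  if (!is.null(config$step_cap)) return(as.integer(config$step_cap))
  as.integer(10L * length(enc$kind) * enc$n_genes)
}

.reachResult <- function(target_gene, probability, method, std_error = 0,
                         n = NA_integer_, censored_fraction = NA_real_) {
  structure(list(target_gene = target_gene,
                 probability = min(max(probability, 0), 1),
                 method = method, std_error = std_error, n = n,
                 censored_fraction = censored_fraction),
            class = "ReachabilityResult")
}

#' @export
print.ReachabilityResult <- function(x, ...) {
  cat(sprintf("P[F (%s = 4)] = %.6g  (%s", x$target_gene, x$probability,
              x$method))
  if (x$method == "monte_carlo")
    cat(sprintf(", n_traj = %d, SE = %.3g, censored = %.3g",
                x$n, x$std_error, x$censored_fraction))
  else
    cat(sprintf(", %d states", x$n))
  cat(")\n")
  invisible(x)
}

#' Enumerate the explicit discrete-time Markov chain of a model
#'
#' Explores the reachable state space breadth-first from the
#' all-uninitialized state.  In each state the enabled commands are found
#' and the successor distribution is the uniform mixture over enabled
#' commands of their branch distributions (the standard resolution of
#' local nondeterminism for asynchronous guarded-command models); deadlock
#' states become absorbing via a self-loop.  Exploration aborts with an
#' error (condition class `fopa_state_cap`) if the reachable states exceed
#' `state_cap`.
#'
#' @param m A [GuardedModel-class].
#' @param state_cap Maximum number of states (default 500000).
#' @return A list of class `"ExplicitChain"`: `states` (integer matrix,
#'   one row per state, one column per gene), `trans` (sparse stochastic
#'   matrix), `initial` (index of the start state), `genes`.
#' @export
buildChain <- function(m, state_cap = 500000L) {
  stopifnot(is(m, "GuardedModel"))
  enc <- .encodeCommands(m)
  res <- build_chain_cpp(enc$kind, enc$src, enc$tgt, enc$p1,
                         enc$n_genes, as.integer(state_cap))
  if (isTRUE(res$capped)) {
    stop(structure(class = c("fopa_state_cap", "error", "condition"),
                   list(message = paste0(
                     "reachable state space of '", m@pathwayId,
                     "' exceeds state_cap = ", state_cap,
                     "; use the Monte-Carlo engine"), call = sys.call())))
  }
  n <- nrow(res$states)
  trans <- Matrix::sparseMatrix(i = res$i, j = res$j, x = res$x,
                                dims = c(n, n))
  colnames(res$states) <- enc$genes
  structure(list(states = res$states, trans = trans, initial = 1L,
                 genes = enc$genes), class = "ExplicitChain")
}

#' @export
print.ExplicitChain <- function(x, ...) {
  cat("ExplicitChain:", nrow(x$states), "states over",
      length(x$genes), "gene variables\n")
  invisible(x)
}

#' Exact reachability probability
#'
#' Computes `P[F (target = 4)]` on an explicit chain.  Target states get
#' probability 1; states from which the target set is graph-unreachable
#' get 0; the remaining probabilities solve the standard linear
#' reachability system by sparse LU, falling back to value iteration
#' (tolerance 1e-10, capped at 1e6 sweeps) if the direct solve fails.
#'
#' @param chain An `"ExplicitChain"` from [buildChain()].
#' @param target_gene Gene variable whose state-4 reachability is wanted.
#' @return A `"ReachabilityResult"` (probability at the initial state,
#'   `std_error` 0).
#' @export
reachabilityExact <- function(chain, target_gene) {
  gi <- match(target_gene, chain$genes)
  if (is.na(gi)) stop("unknown gene '", target_gene, "'")
  n <- nrow(chain$states)
  target <- chain$states[, gi] == 4L
  x <- numeric(n)
  if (any(target)) {
    x[target] <- 1
    # states that can reach the target set (reverse BFS over the support)
    P <- chain$trans
    can <- target
    frontier <- which(target)
    tP <- Matrix::t(P)  # columns: predecessors via t
    repeat {
      preds <- unique(Matrix::summary(tP[frontier, , drop = FALSE])$j)
      preds <- preds[!can[preds]]
      if (!length(preds)) break
      can[preds] <- TRUE
      frontier <- preds
    }
    U <- which(can & !target)
    if (length(U)) {
      Puu <- P[U, U, drop = FALSE]
      b <- as.numeric(P[U, which(target), drop = FALSE] %*%
                        rep(1, sum(target)))
      A <- Matrix::Diagonal(length(U)) - Puu
      xu <- tryCatch(
        as.numeric(Matrix::solve(A, b)),
        error = function(e) .valueIteration(Puu, b))
      x[U] <- xu
    }
  }
  .reachResult(target_gene, x[chain$initial], "exact", n = n)
}

.valueIteration <- function(Puu, b, tol = 1e-10, max_iter = 1e6L) {
  x <- numeric(length(b))
  for (it in seq_len(max_iter)) {
    xn <- as.numeric(Puu %*% x) + b
    if (max(abs(xn - x)) < tol) return(xn)
    x <- xn
  }
  warning("value iteration did not converge to ", tol)
  x
}

#' Monte-Carlo reachability estimate
#'
#' Simulates trajectories under the uniform scheduler; a trajectory counts
#' as a success on first entering a state with the target variable at 4
#' and stops on success, deadlock, or the step cap.  Trajectories cut off
#' by the step cap count as failures (a downward bias surfaced through
#' `censored_fraction`).
#'
#' @param m A [GuardedModel-class].
#' @param target_gene Gene variable of interest.
#' @param n_traj Number of trajectories (>= 1).
#' @param step_cap Maximum steps per trajectory; `NULL` means
#'   `10 * n_commands * n_genes`.
#' @param seed Integer seed (deterministic given the seed); `NULL` uses
#'   the ambient RNG stream.
#' @return A `"ReachabilityResult"` with the estimate, its standard error
#'   `sqrt(p(1-p)/n)` and the censored fraction.
#' @export
reachabilityMC <- function(m, target_gene, n_traj = 20000L, step_cap = NULL,
                           seed = NULL) {
  stopifnot(is(m, "GuardedModel"))
  if (n_traj < 1L) stop("'n_traj' must be at least 1")
  gi <- match(target_gene, m@genes)
  if (is.na(gi)) stop("unknown gene '", target_gene, "'")
  enc <- .encodeCommands(m)
  if (is.null(step_cap)) step_cap <- 10L * length(enc$kind) * enc$n_genes
  res <- withSeed(seed,
    mc_simulate(enc$kind, enc$src, enc$tgt, enc$p1, enc$n_genes,
                gi - 1L, as.integer(n_traj), as.integer(step_cap)))
  phat <- res$successes[1] / n_traj
  .reachResult(target_gene, phat, "monte_carlo",
               std_error = sqrt(phat * (1 - phat) / n_traj),
               n = as.integer(n_traj),
               censored_fraction = res$censored / n_traj)
}

# shared-trajectory estimates for several targets at once (used by the
# pathway score so one simulation pass serves every effector)
.mcMulti <- function(m, targets, n_traj, step_cap = NULL, seed = NULL) {
  enc <- .encodeCommands(m)
  if (is.null(step_cap)) step_cap <- 10L * length(enc$kind) * enc$n_genes
  gi <- match(targets, m@genes)
  res <- withSeed(seed,
    mc_simulate(enc$kind, enc$src, enc$tgt, enc$p1, enc$n_genes,
                gi - 1L, as.integer(n_traj), as.integer(step_cap)))
  list(probs = setNames(res$successes / n_traj, targets),
       censored_fraction = res$censored / n_traj)
}

#' Reachability with engine dispatch
#'
#' `engine = "exact"` builds the explicit chain and solves; `"monte_carlo"`
#' simulates with the configured trajectory count, step cap and seed;
#' `"auto"` tries the exact route under the state cap and falls back to
#' Monte Carlo with a message when the cap is exceeded.
#'
#' @param m A [GuardedModel-class].
#' @param target_gene Gene variable of interest.
#' @param config A [fopaConfig()] list.
#' @return A `"ReachabilityResult"`.
#' @export
reachability <- function(m, target_gene, config = fopaConfig()) {
  run_mc <- function() reachabilityMC(m, target_gene, n_traj = config$n_traj,
                                      step_cap = config$step_cap,
                                      seed = config$mc_seed)
  switch(config$engine,
    exact = reachabilityExact(buildChain(m, config$state_cap), target_gene),
    monte_carlo = run_mc(),
    auto = tryCatch(
      reachabilityExact(buildChain(m, config$state_cap), target_gene),
      fopa_state_cap = function(e) {
        message(conditionMessage(e), " -- falling back to Monte Carlo")
        run_mc()
      })
  )
}
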