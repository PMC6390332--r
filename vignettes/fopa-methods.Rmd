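---
title: "Scoring signaling pathways by probabilistic model checking"
author: "fopa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring signaling pathways by probabilistic model checking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fopa)
```

## The problem and the model

Pathway analysis asks which signaling pathways are most relevant to a
two-class expression contrast (say, tumor versus normal).  Simple
topology-based scores propagate per-gene statistics along signed edges;
this package instead compiles each pathway into a small *probabilistic
guarded-command program* and scores the pathway by the behavior of the
stochastic process that program induces.

Every gene in a pathway becomes a variable over six states:

| state | meaning |
|---|---|
| -1 | not yet initialized |
| 0 | not expressed |
| 1 | expressed |
| 2 | differentially expressed |
| 3 | activated |
| 4 | differentially activated |

A gene is *differentially activated* (state 4) when it is activated while
differentially expressed, or activated by an upstream gene that is itself
differentially activated — so state 4 marks the propagation of the
disease signal, not mere pathway activity.  The commands are:

* **initialization** (one per gene): from -1 the variable moves to 1 with
  probability `prob1` and to 2 with probability `prob2`.  With a
  DE-calling error of $\alpha$, a non-DE gene gets
  $(prob_1, prob_2) = (1-\alpha, \alpha)$ and a DE gene the mirror image;
  $\alpha$ is set to the FDR cutoff $v$ used for DE calling (default
  0.05), since that is the nominal rate at which DE calls are wrong.
* **source activation** (one per gene with no incoming edges): from state
  1 or 2 the gene self-activates (`+2`) with probability `prob_init`, or
  shuts off to 0.
* **activation edge** $A \to B$: when $A$ is active ($>2$) and $B$ is
  expressed (1 or 2), $B$ becomes 4 — unless $A$ is merely activated (3)
  *and* $B$ was merely expressed (1), in which case $B$ becomes 3 — with
  probability `prob_active`, else 0.  All four activation-family edge
  kinds (plain, phosphorylation, dephosphorylation, indirect effect)
  share this command.
* **inhibition edge** $A \dashv B$ (two commands): while the inhibitor is
  inactive ($A<3$), $B$ may activate with probability `prob_inhibit1`;
  when both are active, $A$ knocks $B$ back down (`-2`) with probability
  `prob_inhibit2`.  The three inhibition-family kinds share these.

The command probabilities combine three pieces of evidence:

$$prob_{active} = \mathrm{diff}(A,B) \cdot P(A) \cdot P(A \to B), \qquad
  prob_{inhibit1} = P(A \dashv B), \qquad
  prob_{inhibit2} = \mathrm{diff}(A,B) \cdot P(A) \cdot P(A \dashv B).$$

Note the deliberate asymmetry: the first inhibition command carries only
the interaction probability.  $\mathrm{diff}(A,B)$ weights the relation
by DE status ($\alpha$, $2\alpha$, $3\alpha$ for zero, one or two DE
endpoints; $\alpha \le 1/3$ keeps it a probability, default $1/6$).
$P(A) = |T(A)\,Fn(A)|$ combines the moderated t-score with a frequency
weight, and $P(A \to B)$ is the fraction of pathways containing both
genes in which the edge actually occurs, counted over the whole
collection.

The pathway score is the probability that the disease signal reaches the
pathway's output: for each *final effector* (out-degree-0 gene — KGML has
no explicit effector flag, so this operational definition is a package
choice, documented here) the engine computes the reachability probability
$P[F\,(g = 4)]$ in the induced discrete-time Markov chain, and the score
is the sum over effectors.  Significance comes from a sample-label
permutation null: the whole pipeline (moderated t, DE calls, $P(A)$,
parameters, model, score) is recomputed under class-size-preserving
relabelings and $P_F$ is the fraction of permuted scores at least as
large as the real one — no pseudocount by default, so $P_F = 0$ is
possible; a $(1+k)/(1+n)$ smoothing mode is available.

## Two design points that deserve attention

**The frequency weight.**  The published formula
$Fn(A) = \sqrt{(f(A)-\min f)/(\max f - \min f)}$ *increases* with how
often a gene appears across pathways, while its accompanying rationale
(down-weight promiscuous genes, up-weight pathway-specific ones) calls
for the opposite direction.  This package does not silently resolve the
contradiction: `freq_mode = "literal"` (default) implements the formula
as printed; `freq_mode = "inverted"` implements the prose.  Note that
under either mode the genes at one extreme of the frequency range get
weight exactly 0 and contribute nothing; in small collections this can
zero out entire pathways, which is visible in the examples of the test
suite.

**Keeping P(A) a probability.**  $|T(A)|$ is unbounded, so
$|T(A) \cdot Fn(A)|$ can exceed 1.  Two scalings are provided:
`max_normalize` (default) divides $|T|$ by the largest $|T|$ among
measured genes — scores are then comparable within one dataset, which is
all the permutation test needs — and `clip` truncates the product at 1.

## Gene statistics

The moderated t-statistic uses closed-form empirical-Bayes variance
shrinkage: per-gene pooled variances $s_g^2$ with $d_g$ df are shrunk
through $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, where
$(d_0, s_0^2)$ are estimated by the method of moments on
$\log s_g^2$ (digamma/trigamma moment equations solved by a Newton
trigamma inverse) — deterministic and dependency-free, and verified in
the tests against an independent implementation of the same published
equations to $10^{-8}$.  P-values use $d_0 + d_g$ df, capped at the total
residual df when $d_0 = \infty$ (no excess variance dispersion, in which
case $s_0^2$ is the arithmetic mean of the variances).  Genes present in
a pathway but missing from the expression matrix are treated as expressed
non-DE ($T = 0$, $q = 1$) with their frequency weight intact, so platform
coverage gaps cannot silently switch a pathway off.  DE calls are
Benjamini-Hochberg $q < v$ with $v = 0.05$ by default.

## The reachability engines

The model's local nondeterminism (several commands enabled at once) is
resolved by the *uniform scheduler*: the successor distribution is the
uniform mixture over enabled commands of their branch distributions.
This is the standard way to close an asynchronous probabilistic program
into a DTMC; no other scheduling information is available.  Deadlocked
states become absorbing through a self-loop.

* **Exact engine**: breadth-first enumeration of the reachable states
  (compiled code; states packed base-6 into 64-bit keys, so at most 24
  gene variables), then the standard linear reachability system — target
  states get 1, states that cannot reach the target get 0 by graph
  analysis, the rest solve $x = Px$ by sparse LU with a value-iteration
  fallback (tolerance $10^{-10}$, at most $10^6$ sweeps).  The default
  state cap is 500,000.
* **Monte-Carlo engine**: simulates trajectories under the same
  scheduler; a trajectory succeeds when the target variable first hits 4
  and stops on success, deadlock, or a step cap (default
  $10 \cdot |commands| \cdot |genes|$).  Censored trajectories count as
  failures — a downward bias — and the censored fraction is reported so
  callers can require it to be zero.  When one pathway has several
  effectors a single trajectory set serves all of them.  Default 20,000
  trajectories.
* **auto** tries exact under the cap, falling back to Monte Carlo.

Exact and Monte-Carlo routes cross-check each other in the tests on
random mixed-polarity pathways (closed forms on the two smallest models;
$3\,SE$ agreement at 200,000 trajectories elsewhere).

## The synthetic benchmark

The generator emulates the structure of the disease benchmarks used for
this kind of method — each dataset designates one *target pathway* that
carries the signal — without any external download.  Defaults, chosen
once as the desk-scale study conditions: 20 pathways of 12 genes drawn
from a shared pool of 60 (so pathway frequencies have KEGG-like spread,
mean ≈ 4), edge density $15/132$ (≈ 15 edges per pathway), 20% inhibiting
edges, one guaranteed sink per pathway; expression is Gaussian noise
($\sigma = 1$) over the gene universe plus 500 off-pathway filler genes,
with 30% of the target pathway's genes shifted by $1.5\sigma$ in 10 case
versus 10 control samples.  A location-shift Gaussian model is enough to
exercise every pipeline stage; what it does **not** emulate — gene-gene
correlation, heavy-tailed microarray noise, probe-level artifacts,
curated topology quality — limits how far passing benchmarks speak to
real data.  Decoy pathways (real topology, random gene labels) and
label-permutation trials provide the negative controls, and
edge-removal/rewiring curves probe robustness to database incompleteness
and noise, with the significance call fixed at $P_F < 0.05$.

At this 12-gene scale the explicit engine's state space regularly
exceeds any cap that would be practical inside a permutation loop, so
all benchmark protocols run the Monte-Carlo engine with 4,000
trajectories per scoring (per-effector standard error below 0.008) and
100 permutations per p-value; these sizes are the package's own
desk-scale choices and are printed by the protocols.  Within one
analysis the real and all permuted scorings share a single simulation
seed (common random numbers), so the permutation comparison
`score_perm >= score_real` is not blurred by independent Monte-Carlo
noise — the comparison then approximates what the exact engine would
return.  `analyzeAll()` itself defaults to `engine = "auto"`.

## Numerical and degenerate-input policy

* Branch probabilities are constructed in pairs $(p, 1-p)$, validated to
  sum to 1 within $10^{-12}$; the model-text parser enforces $10^{-9}$.
* Self-edges are dropped (the command table has no self-regulation
  semantics); relations with no activation/inhibition polarity are
  dropped and logged rather than guessed; a removed non-gene node
  reconnects its parents and children with the sign product of the two
  hops.
* A pure-cycle pathway has no effectors: its score is 0, with a warning.
* Result tables sort by $P_F$, ties by score then id; tied
  (p-value, score) pairs share their mean rank.
* With $\binom{n}{n_{case}} \le n_{perm}$ the permutation set is
  enumerated exhaustively (the identity relabeling included, as one of
  the distinct relabelings).

## Known limitations

* The raw score sums over effectors, so effector-rich pathways score
  higher; the permutation null absorbs this only partially.  Duplicating
  an effector provably increases the score (a test asserts this).
* Pathways are treated independently; cross-talk through shared genes is
  not modeled.
* The uniform scheduler is a modeling choice, not an attributed fact;
  results for models with heavy inhibition cycling depend on it.
* Monte-Carlo p-values inherit simulation noise; with 100 permutations
  the resolution of $P_F$ is 0.01.
```{r, eval = FALSE}
# the shortest complete analysis
sp <- simulationSpec()
coll <- simulateCollection(sp)
dat <- simulateExpression(sp, coll)
res <- analyzeAll(dat, coll,
                  config = fopaConfig(engine = "monte_carlo",
                                      n_traj = 4000, n_perm = 100),
                  seed = 1)
head(res)
```
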