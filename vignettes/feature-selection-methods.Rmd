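---
title: "Hybrid hunger-games feature selection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid hunger-games feature selection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dolhgs)
```

## The problem

Deep feature extractors turn each image (here, dermoscopy images of skin
lesions) into a fixed-length embedding — typically 128 numbers per sample.
Many embedding coordinates are noisy or redundant, and a k-nearest-neighbour
classifier downstream benefits from discarding them. `dolhgs` performs
*wrapper* feature selection over such tabular embeddings: candidate subsets
are scored directly by the validation error of the classifier they induce,
and a population metaheuristic searches the $2^{D}$ subset lattice.

The search operates in the continuous unit box $[0,1]^D$. A position
$x \in [0,1]^D$ decodes to a subset through a strict threshold,
$$B_j = \mathbf{1}\{x_j > 0.5\},$$
and the score to be *minimized* is
$$\mathrm{Fit}(x) = \lambda\,\gamma(B) + (1-\lambda)\,\frac{|B|}{D},$$
where $\gamma(B)$ is the misclassification fraction of a $k$-NN classifier
($k = 5$) restricted to the selected columns, and $|B|/D$ is the fraction of
features retained. An empty subset receives the sentinel score 1, the
maximum attainable value.

## The search

Three cooperating mechanisms drive the hybrid optimizer (`run_dolhgs()`):

**Hunger Games Search (HGS).** Each of the $N$ agents carries a hunger
level $H_i$. Agents matching the best-ever fitness have hunger reset to 0;
the rest accrue
$TH = 2\,\frac{\mathrm{Fit}_i - \mathrm{Fit}_b}{\mathrm{Fit}_w -
\mathrm{Fit}_b + \varepsilon}\, r\,(UB - LB)$, floored at $LH(1+r)$ when
below $LH$. Hunger feeds two weights,
$W_1 = \frac{H_i N}{SH + \varepsilon} r$ (with probability $l$, else 1) and
$W_2 = 2(1 - e^{-|H_i - SH|}) r$, with $SH = \sum_i H_i$. The position
update has three branches: with probability $l$ a self-scaled perturbation
$x(1 + z)$; otherwise attraction toward or repulsion away from the best
position $x_b$,
$$x' = W_1 x_b \mp R\, W_2\, |x_b - x|,$$
gated by comparing a fresh uniform draw with the variation control
$E = \mathrm{sech}(\mathrm{Fit}_i - \mathrm{Fit}_b) \in (0,1]$. The escape
value $R$ is uniform on $[-s, s]$ with $s = 2(1 - t/T)$, so late-stage moves
contract onto the best solution (at $t = T$ the attraction branch lands on
$W_1 x_b$ exactly).

**Particle swarm competition.** At every iteration each agent draws a gate
$\mathrm{Pr}_i$; when $\mathrm{Pr}_i > 0.5$ (strictly) it moves by HGS,
otherwise by a standard particle-swarm step
$v' = w v + c_1 r_1 (x^{p} - x) + c_2 r_2 (x^{g} - x)$, $x' = x + v'$,
with per-dimension draws, velocity clamped at $\pm V_{max}$ and inertia
decaying linearly from $w_{max}$ to $w_{min}$. The two operator families
thus compete for every agent at every iteration.

**Dynamic-opposite learning (DOL).** Opposition evaluates the mirror image
$x_o = U + L - x$ of a candidate; its dynamic generalization jumps to
$$x^{do}_j = x_j + w\, r_8 (r_9\, x^{o}_j - x_j)$$
with fresh per-dimension uniforms. DOL is applied twice. At initialization
every agent's dynamic opposite (formed against the static unit box) is
evaluated and the best $N$ of the $2N$ points survive — this can only
improve the initial best. Then once per iteration, each agent jumps with
probability 0.5, with the opposite formed against the *contracted* box
spanned per-dimension by the current population
($L_j = \min_i x_{ij}$, $U_j = \max_i x_{ij}$); the best $N$ of the union
survive greedily, ties favouring incumbents. Jumps are clamped to the
static box, which the weighted formula can leave.

The best-ever solution is archived outside the population, so the reported
best fitness is non-increasing by construction and elite selection can
never lose it.

## Parameters

| parameter | symbol | default | meaning |
|---|---|---|---|
| `n_agents` | $N$ | 50 | population size |
| `n_iterations` | $T$ | 1000 | iteration budget (the only stopping rule) |
| `lambda_weight` | $\lambda$ | 0.99 | error-vs-size balance; 1 ignores size |
| `knn_k` | $k$ | 5 | wrapper classifier neighbours |
| `hgs$l_threshold` | $l$ | 0.08 | self-perturbation branch probability |
| `hgs$hunger_floor` | $LH$ | 100 | hunger-increment floor |
| `hgs$epsilon` | $\varepsilon$ | 1e-9 | denominator guard |
| `pso$c1`, `pso$c2` | $c_1, c_2$ | 2, 2 | acceleration coefficients |
| `pso$w_max`, `pso$w_min` | — | 0.9, 0.2 | inertia schedule endpoints |
| `pso$v_max` | $V_{max}$ | 6 | velocity clamp |
| `dol$dol_weight` | $w$ | 8 | dynamic-opposite jump weight |
| `dol$jump_threshold` | — | 0.5 | per-agent jump probability |

Where the underlying publications leave a constant unstated, the default
follows the convention of the originating algorithm's literature:
$l = 0.08$ and $LH = 100$ from the original hunger-games search,
$c_1 = c_2 = 2$ as the canonical swarm choice, linear inertia decay between
the stated endpoints, and $w = 8$ as the usual dynamic-opposite weighting.
$\lambda = 0.99$ is the common wrapper-selection balance, weighting error
two orders of magnitude over subset size; any $\lambda$ near 1 behaves
similarly, and `lambda_weight` is fully configurable.

## The fitness protocol

$\gamma$ is estimated on a single seeded, stratified 80/20 split of the
training partition, fixed for the whole run, so fitness is a deterministic
function of the mask and can be memoized (`make_fitness_evaluator()`
caches by mask). The alternative — resampling the split per evaluation —
makes fitness stochastic and the elitist archive unsound. The split seed
derives deterministically from the run seed, and the exhaustive oracle
(`exhaustive_subset_search()`) uses the same derivation so that optimizer
and oracle minimize the identical function.

The KNN uses Euclidean distance on unstandardized features. Vote ties are
broken by the label of the nearest neighbour among the tied classes, and
distance ties by training-row order — both rules chosen to make prediction
fully deterministic. Held-out metrics in a `selection_report` come from
refitting the KNN on the *entire* training partition restricted to the
selected columns.

Multiclass precision/recall/F1 use support-weighted one-vs-rest averaging
(also for two classes), under which recall equals accuracy exactly — the
identity the test suite asserts. The improvement rate `pir()` implements
two conventions: the default `"table"` divides the accuracy difference by
the *new* accuracy, which is the convention under which the published
comparison values for this method reproduce; `"ratio"` is the textbook
relative improvement over the comparator.

## Randomness and reproducibility

A run uses one stream (`make_rng()`), isolated from R's global generator,
consumed in a fixed documented order: initialization draws agent-by-agent;
per iteration, hunger draws (agents in order: $r_6$, then the floor draw if
taken), weight draws per agent ($r_3$, conditionally $r_4$, then $r_5$),
then per agent the gate $\mathrm{Pr}_i$, the chosen operator's own draws,
and finally the jumping step ($\mathrm{Pr}_{DO}$ per agent, then
per-dimension pairs for jumpers). Two runs with the same configuration are
`identical()`.

`force_hgs_prob` substitutes a constant for the gate *without consuming a
draw*, and `dol = NULL` removes both DOL stages; with these, the hybrid's
trajectory coincides exactly with the standalone baselines (`run_hgs()`,
`run_pso()`), which are implemented as the degenerate gate settings of the
same engine. The swarm-only setting also skips the hunger machinery, since
no agent can take an HGS move. This makes the degeneration checks
trajectory-exact rather than merely statistical.

## Numerical and edge-case choices

- Positions are clamped to the static unit box after every move; the
  dynamic box is used only to form opposite points.
- Fitness ties always favour the incumbent (personal bests, the elitist
  archive, and elite selection), for run stability.
- A gate or jump draw exactly at 0.5 takes the "no" branch (strict
  comparisons as specified).
- $\varepsilon$ guards both the hunger-sum and fitness-range denominators,
  so a population with equal best and worst fitness is well-defined (all
  agents then tie for best and reset hunger to zero).
- An empty mask scores the sentinel 1.0 and is never refit; a run whose
  best-ever position decodes to an empty mask (never observed; it requires
  every evaluated mask to be empty) errors rather than reporting an empty
  selection.
- `n_iterations = 0` is allowed and reports the best initial agent.

## The synthetic generator

`make_embedding_dataset()` emulates what a fine-tuned convolutional
backbone emits: per-sample embedding vectors with class-conditional
structure. A random subset of `n_informative` columns carries the signal —
class $k$ is shifted by $(k-1)\cdot$`effect_size` on those columns — and
all other columns are shared $N(0, \sigma^2)$ noise. The planted indices
are recorded so tests can score recovery. Two presets mirror realistic
dermoscopy splits: a two-class, roughly 80%-benign problem with 900
training and 379 test samples at $D = 128$, and a three-class problem with
170/30 samples and 40 melanomas overall.

Default geometry (64 features, 10 informative, effect 1.5, unit noise)
makes the true subset clearly better than the full feature set while
leaving noise columns genuinely uninformative. What the generator does
*not* emulate: correlated or redundant noise structure, heavy tails,
label noise, batch effects, and the within-class manifold structure of
real embeddings. Passing tests on this generator therefore demonstrate the
search and scoring machinery, not classifier performance on real dermoscopy
data.

One property of the generator deserves emphasis because it bounds what
subset search can show: with ten planted columns each carrying effect 1.5,
the class signal is *redundant* — a handful of informative columns already
separates the classes at the wrapper's validation resolution. The fitness
optimum is then a minimal zero-error subset, which legitimately excludes
some informative columns; a better optimizer recovers *fewer* of the
planted features, not more. Recovery rates on this generator should be read
with that ceiling in mind.

## Problem sizes used in the test suite

The suite validates on deliberately small instances: an 8-feature, 200
sample problem where all 255 subsets can be enumerated (the optimizer
attains the exhaustive optimum in 5/5 seeds at $N = 30$, $T = 200$), and a
64-feature, 600-sample recovery problem at $N = 20$, $T = 100$ over five
replicates, compared against an equal-budget random-subset baseline. These
sizes exercise every operator while keeping the full suite to a couple of
minutes; the defaults ($N = 50$, $T = 1000$) match the published
experimental protocol and are intended for real use.

## Known limitations

- Wrapper fitness with a single internal split inherits that split's
  variance; a k-fold estimate would be smoother but several-fold slower and
  is not currently implemented.
- The per-agent scalar application of $W_1$, $W_2$, $R$ across dimensions
  follows one common reading of the update; drawing them per dimension is a
  known variant and would increase exploration.
- Population evaluation is sequential; the fitness cache is the main
  accelerator and pays off only when masks recur (small $D$ or late
  convergence).
- No early stopping: the iteration budget is the only stopping rule.
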