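---
title: "Multitask GEP rule induction: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask GEP rule induction: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emcgep)
```

## The model

`emcgep` learns a multi-class classifier as an ordered list of symbolic
rules. Each rule is a gene-expression-programming (GEP) individual: a
fixed-length string whose head (length $h$) may contain functions and
terminals and whose tail (length $l = h(u-1)+1$, with $u$ the maximum
arity of the function set) contains terminals only. This tail constraint
guarantees that reading the string breadth-first always yields a complete
expression tree; positions past the last consumed symbol are inert
genetic material. The function set is $\{+, -, *, /, \mathrm{Sqrt},
\mathrm{IF}\}$ and the terminals are the dataset's features plus the
constants $\{1, 2, 3, 5, 7\}$.

A rule classifies a sample $x$ as positive when its expression output is
strictly positive. An $M$-class problem is decomposed one-against-all
into $M$ binary tasks. Within a task, rules are learnt sequentially by a
covering strategy: a GEP population is evolved for a fixed budget, the
best rule is extracted, the positives it covers are removed, and the loop
repeats. Rule quality during evolution is

$$\mathrm{Fitness}(R) = \begin{cases}
  0 & \mathrm{Pre} < 0\\
  \mathrm{Pre}\cdot e^{\,\mathrm{Rec}-1} & \mathrm{Pre} \ge 0
\end{cases},
\qquad
\mathrm{Pre} = \left(\frac{TP}{TP+FP} - \frac{P}{P+N}\right)\frac{P+N}{N},$$

where $TP$ and $FP$ are counted against the *current* (shrinking)
positive set and the negatives, while $P$ and $N$ are the task's
*original* class totals. The corrected precision is 1 for a perfect
rule, 0 for a chance-level rule, and negative below chance.

Covering stops when the positive set is exhausted or when the minimum
description length criterion rejects the newest rule: with $N_c$ the
alphabet size and $L(R_i)$ each rule's valid length,

$$L_H = 0.5\,\underbrace{\log_2(N_c)\textstyle\sum_i L(R_i)}_{L_{theory}}
      + \underbrace{\log_2\binom{TP+FP}{FP} + \log_2\binom{TN+FN}{FN}}_{L_{exception}},$$

and a rule is kept only while $L_H$ strictly decreases ($L_{exception}$
is evaluated for the accumulated rule set on the task's full training
data). Finally, the rules pooled from all tasks are post-pruned into a
decision list: repeatedly re-score every rule on the remaining samples
(its own class as positives, totals recomputed from the remainder), move
the best to the list, and drop the samples it covers; the majority label
of the remainder becomes the default class. Prediction is
first-match-wins with the default as fallback.

## Multitask evolution and knowledge transfer

The $M$ binary tasks evolve simultaneously, one subpopulation each,
advancing generation-synchronously in a round-robin so that all tasks'
archives coexist in time. Each task keeps a bounded archive of successful
chromosomes: after every generation, population and archive are sorted by
fitness and archive slot $j$ is replaced by the rank-$j$ population
member with probability `arp`. Every `delta` generations a task runs a
*transfer* generation instead of self evolution, with a source archive
chosen uniformly among all tasks — possibly its own (self transfer) and
possibly that of an already-terminated task, whose archive is frozen but
remains available as donor material.

Transfer is operator-specific:

* **GA operator** (`emcgep-ga`): offspring pairs are produced by one- or
  two-point crossover (probabilities 0.4/0.4) and per-position mutation
  (0.02); in a transfer generation the second crossover parent is drawn
  uniformly from the source archive, so the donor's breadth-first prefix
  — the skeleton of its expression tree — can be transplanted.
* **DE operator** (`emcgep-de1`, `emcgep-de2`): a discrete
  current-to-best differential evolution. With random $F, CR \in [0,1]$
  and a mandatory index $k$ per individual, position $j$ mutates when
  $(\mathrm{rand} < CR \lor j = k) \land \mathrm{rand} < \phi_j$, where
  $\phi_j = 1-(1-F\,\psi(x_{best,j},x_{i,j}))(1-F\,\psi(x_{r1,j},x_{r2,j}))$
  and $\psi$ is 1 for mismatching symbols. Replacements are sampled from
  an add-one-smoothed symbol-frequency record of the population, split by
  head/tail position kind. In a transfer generation the three donors
  ($x_{best}, x_{r1}, x_{r2}$) come from the source archive (DE1); DE2
  additionally samples replacements from the archive's frequency record,
  transferring feature-usage information.

The baselines `accgep-ga` and `accgep-de` are the same engine with
transfer disabled; with a fixed seed they are bit-identical to a transfer
variant run with `delta = Inf`, which the tests assert.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `head_length` | 33 | head $h$; with $u = 3$ the total string length is $3h+1 = 100$ |
| `pop_size` | 1000 | subpopulation size per binary task |
| `generations_per_rule` | 1000 | evolution budget per covering rule |
| `p_mut` | 0.02 | per-position mutation probability (GA) |
| `p_x1`, `p_x2` | 0.4, 0.4 | one-/two-point crossover probabilities (GA) |
| `arp` | 0.8 | archive replacement probability |
| `delta` | 10 | generations between transfer events |
| `archive_capacity` | `pop_size / 5` | archive size, strictly below `pop_size` |
| constants | 1, 2, 3, 5, 7 | constant terminals, sampled like any terminal |

The full-scale defaults are intended for real datasets; the package's own
tests and the acceptance script run desk-scale budgets (population 100,
head 10, 30 generations per rule) on the synthetic fixture below, which
those budgets solve reliably.

## Design choices where the design was open

* **`IF` semantics.** `IF(a, b, c)` returns `b` when `a > 0`, else `c`
  — the standard GEP conditional, consistent with the strict
  sign-threshold rule semantics. Its arity 3 makes $u = 3$.
* **String length 100.** "Length 100" is read as the *total* length:
  $h = 33$, $l = 67$ is the unique head/tail split summing to 100 under
  $l = h(u-1)+1$ with $u = 3$.
* **Protected operators.** Division returns 1 when the denominator's
  magnitude is below $10^{-9}$; `Sqrt` acts on the absolute value; every
  intermediate value is clamped to $\pm 10^{150}$ so repeated
  multiplication cannot overflow. Outputs are therefore always finite,
  which the suite fuzz-tests.
* **Empty prediction.** When a rule predicts nothing positive
  ($TP+FP=0$) the raw-precision term is taken as 0, giving
  $\mathrm{Pre} = -P/N$: continuous with the worse-than-chance branch
  and yielding fitness 0.
* **Fixed totals.** $P$ and $N$ in the corrected precision stay at the
  task's original totals while the evaluated positive set shrinks; the
  correction exists precisely to inject that distribution information.
* **Per-rule budget.** The evolution budget is spent per covering rule,
  with a fresh random population for each rule while the task's archive
  persists across rules — this is what makes *self* transfer (drawing
  from one's own archive) informative about earlier rules.
* **DE replacement direction.** A trial replaces its parent when its
  fitness is greater *or equal* (maximisation; ties allowed so neutral
  drift can traverse plateaus).
* **Transfer "best".** Archive members keep the fitness from their home
  task; they are not re-evaluated on the target task before serving as
  the best donor, which would burn evaluations for uncertain benefit.
* **Archive initialization.** The archive starts as the top-$n$ of the
  initial random population (random content, and consistent with the
  rank-wise update rule from generation 1 on).
* **Covering stall.** If the best evolved rule covers no remaining
  positive, the task terminates with a warning rather than looping
  forever; the description-length criterion alone cannot guarantee
  termination.
* **Fitness enhancement.** Transfer diagnostics record the *signed*
  best-fitness change across a transfer generation; negative values are
  informative (a transfer can hurt) and are not floored.
* **Tie-breaks.** All fitness ties (tournaments, survivor elitism,
  post-pruning order) are broken by shorter valid length (parsimony),
  then by task and index — determinism matters more than the particular
  convention.
* **Zero-fitness rules in post-pruning.** A rule that covers remaining
  samples is eligible for selection even at fitness 0; the selection loop
  only requires coverage.
* **Degenerate remainders in post-pruning.** When the remainder contains
  no negatives for a rule's class, the corrected precision is undefined;
  the rule scores its recall-discounted maximum (precision 1) if it
  covers anything, 0 otherwise.

## The synthetic generator

`emcgep_synth()` emulates the regime the method targets — moderate
samples, few informative features among many noise features — while
keeping the ground truth expressible in the function set so recovery is
testable. Features are uniform on $[0, 4]$; classes form a threshold
chain at 2 on the informative features: class 1 has $x_{i_1} > 2$, class
$c$ has $x_{i_1..i_{c-1}} \le 2$ and $x_{i_c} > 2$, the last class has
all chain features $\le 2$. The generating rules are returned as token
strings and, evaluated through the package's own decoder, reproduce the
labels exactly at zero noise. Class sizes are balanced within one
sample; `noise_sd` adds Gaussian perturbation after labelling.

What the generator does *not* emulate: correlated features, class
imbalance, label noise away from boundaries, and the extreme
dimensionality of real transcriptomic panels (thousands of features).
Passing the recovery tests therefore demonstrates that the engine finds
threshold-expressible structure under noise-feature padding, not that it
matches any particular real-data benchmark.

## Problem sizes used by tests and the acceptance script

The acceptance script fits `emcgep-de1` on the fixture (3 classes, 200
samples, 10 features, 3 informative, noise-free) over 10 derived seeds
at the desk-scale budget, reports mean test accuracy, the fraction of
seeds reaching 0.9, the majority-class control, rule counts and transfer
diagnostics, and runs a 10-trial paired Wilcoxon signed-rank comparison
against the majority control at $\alpha = 0.1$. The test suite
additionally checks the decoder against an independent queue-simulation
oracle, the fitness/MDL formulas against brute-force recomputation over
a full contingency grid, structural closure over $10^5$ variation
applications, the archive and transfer-scheduling contracts, and
two-rule recovery of a two-cluster class.

## Known limitations

* Evolution cost is dominated by rule evaluation on the training matrix;
  the full-scale defaults (population 1000, 1000 generations per rule)
  are compute-intensive in pure R.
* The covering fitness gives no gradient to partial rules whose raw
  precision sits at the original base rate, so classes whose subgroups
  need conjunctions of several thresholds may require larger budgets.
* One-vs-all with first-match prediction resolves class overlap by rule
  order only; no calibrated probabilities are produced.
* The comparison harness re-splits the data every trial, so its paired
  tests measure pipeline variability (split + search), not search
  variability alone.
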