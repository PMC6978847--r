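# emcgep

Rule-based multi-class classification by gene expression programming
(GEP), with evolutionary-multitasking knowledge transfer between the
per-class learners.

## The problem and the method

Rule-based classifiers are attractive for tabular scientific data —
e.g. disease-subtype calls from expression panels — because each decision
is a readable symbolic expression over a handful of features. GEP evolves
such expressions as fixed-length strings: a head of length *h* holding
functions and terminals, and a terminal-only tail of length
*l = h(u−1)+1* (*u* = maximum arity), so every string decodes
breadth-first into a complete expression tree. A rule covers a sample
when its output is strictly positive.

An *M*-class problem is decomposed one-against-all into *M* binary
covering tasks. Each task repeatedly evolves a rule, scores it by

    Fitness(R) = Pre · exp(Rec − 1)   (0 when Pre < 0)
    Pre = (TP/(TP+FP) − P/(P+N)) · (P+N)/N

(raw precision centred at the class base rate, so 1 is perfect and 0 is
chance), removes the positives the accepted rule covers, and stops when a
minimum-description-length criterion `L_H = 0.5·L_theory + L_exception`
stops decreasing. The pooled rules from all tasks are post-pruned into an
ordered decision list with a default class; prediction is
first-match-wins.

The multitasking layer evolves all binary tasks simultaneously. Each task
keeps a bounded archive of successful chromosomes (refreshed rank-wise
with probability `arp`); every `delta` generations a task imports genetic
material from a uniformly chosen archive — its own or another task's,
frozen archives of finished tasks included. Five variants are provided:

| variant | operator | knowledge transfer |
|---|---|---|
| `accgep-ga` | GA (mutation + 1/2-point crossover) | none |
| `emcgep-ga` | GA | crossover against archive members |
| `accgep-de` | discrete DE (current-to-best, frequency sampling) | none |
| `emcgep-de1` | DE | DE donors drawn from the archive |
| `emcgep-de2` | DE | DE1 + the archive's symbol-frequency record |

## Worked example

```r
library(emcgep)

s  <- emcgep_synth(n_classes = 3, n_samples = 200, n_features = 10,
                   n_informative = 3, noise_sd = 0, seed = 11)
sp <- emcgep_split(s$X, s$y, 0.75, seed = 11)
model <- emcgep_fit(sp$train$X, sp$train$y, variant = "emcgep-de1",
                    seed = 11, pop_size = 100, head_length = 10,
                    generations_per_rule = 30)
model
#> EMC-GEP decision list: 3 rule(s), default class C2
#>    1. [C1] *(-(x1, 2), x9)  (fitness 1.0000)
#>    2. [C3] -(2, x7)  (fitness 1.0000)
#>    3. [C2] -(IF(x0, x7, x2), +(2, IF(-(5, 3), x1, x1)))  (fitness 0.5488)
emcgep_evaluate(model, sp$test$X, sp$test$y)$accuracy
#> [1] 1
```

The generator hid a threshold chain on features `x1` and `x7` (0-based
tokens; its ground truth for class 1 is the rule `- x1 2`, i.e.
`x1 > 2`). The fitted decision list recovers that structure: rule 1 fires
for class C1 when `x1 > 2` (the `* x9` factor is harmless since features
are positive), rule 2 catches class C3 at `x7 < 2`, and the default class
covers what remains, giving 100% test accuracy on this seed. A
`fitness` of 1 means a rule was perfect (precision 1, full recall on the
then-remaining positives) when it was selected. Transfer events are
logged in `model$diagnostics` (generation, source task, and the signed
best-fitness enhancement each transfer produced).

A command-line wrapper with `train`, `predict`, `synth` and `compare`
subcommands is installed at
`system.file("exec", "emcgep", package = "emcgep")`.

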