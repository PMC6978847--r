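Package: emcgep
Title: Evolutionary Multitasking Gene Expression Programming for
    Multi-Class Rule Induction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based multi-class classification by gene expression
    programming (GEP). An M-class problem is decomposed one-against-all
    into M binary covering tasks, each learning a set of thresholded
    symbolic rules under a minimum-description-length stopping criterion,
    and the pooled rules are post-pruned into an ordered decision list
    with a default class. The binary tasks evolve simultaneously as an
    evolutionary-multitasking problem: each task keeps a bounded archive
    of successful chromosomes and, at a fixed transfer interval, imports
    genetic material from a randomly chosen archive, either through
    crossover (canonical GEP operators) or through a discrete
    differential-evolution operator with frequency-based symbol sampling.
    Includes the single-task baseline, a synthetic multi-class data
    generator with known ground-truth rules, a train/test harness, and a
    variant-comparison tool using Wilcoxon signed-rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
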