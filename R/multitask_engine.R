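# The multitask covering engine: per-task subpopulations evolve
# generation-synchronously; each task keeps a bounded archive refreshed
# stochastically from its population; every `delta` generations a task
# imports genetic material from a uniformly chosen archive (possibly its
# own, possibly a terminated task's frozen archive). Rules accumulate per
# task under the covering strategy until the positive set is exhausted or
# the description length stops decreasing.

#' Construct a binary covering task
#'
#' One one-vs-all task: samples of \code{class_label} are the positives,
#' all others the negatives. The positive set shrinks as accepted rules
#' cover it; the totals \code{P} and \code{N} used in the
#' distribution-corrected precision stay fixed at their original values.
#'
#' @param class_label The task's positive class.
#' @param X Numeric training matrix.
#' @param y Class labels, one per row of \code{X}.
#' @return A list of class \code{"emcgep_task"}.
#' @export
new_binary_task <- function(class_label, X, y) {
  is_pos <- y == class_label
  if (!any(is_pos))
    stop("no samples of class ", class_label, call. = FALSE)
  if (all(is_pos))
    stop("task for class ", class_label, " has no negatives", call. = FALSE)
  structure(list(
    label = class_label,
    X = X,
    is_pos = is_pos,
    remaining = is_pos,        # E+ membership, shrinks as rules accept
    covered_union = rep(FALSE, nrow(X)),  # coverage of accepted rule set
    P = sum(is_pos), N = sum(!is_pos),
    H = list(),
    L_theory = 0, L_min = Inf,
    status = "active",
    t_rule_start = 0L,
    pop = NULL, archive = NULL, rng = NULL,
    log = list()
  ), class = "emcgep_task")
}

# Fitness of one chromosome on the task's current covering state.
evaluate_chrom_on_task <- function(chrom, task, cfg) {
  tree <- gep_decode(chrom, cfg)
  cov <- gep_evaluate(tree, task$X, cfg) > 0
  TP <- sum(cov & task$remaining)
  FP <- sum(cov & !task$is_pos)
  cts <- counts(TP = TP, FP = FP, TN = task$N - FP,
                FN = sum(task$remaining) - TP, P = task$P, N = task$N)
  list(fit = rule_fitness(cts), vl = tree$valid_length, cov = cov)
}

evaluate_pop_on_task <- function(mat, task, cfg) {
  n <- nrow(mat)
  fit <- numeric(n)
  vl <- integer(n)
  for (i in seq_len(n)) {
    e <- evaluate_chrom_on_task(mat[i, ], task, cfg)
    fit[i] <- e$fit
    vl[i] <- e$vl
  }
  list(fit = fit, vl = vl)
}

task_evaluator <- function(task, cfg) {
  force(task); force(cfg)
  function(mat) evaluate_pop_on_task(mat, task, cfg)
}

random_population <- function(task, cfg) {
  mat <- t(vapply(seq_len(cfg$pop_size),
                  function(i) gep_random_chromosome(cfg),
                  integer(cfg$len)))
  new_population(mat, task_evaluator(task, cfg))
}

# Archive initialization: the top-n of the freshly drawn random
# population (random content, and consistent with later rank-wise
# updates from the population).
init_archive <- function(pop, cfg) {
  ord <- pop_order(pop)[seq_len(cfg$archive_capacity)]
  list(chrom = pop$chrom[ord, , drop = FALSE],
       fit = pop$fit[ord], vl = pop$vl[ord])
}

#' Archive update
#'
#' Population and archive are sorted by fitness (descending; ties broken
#' by shorter valid length); each archive slot \code{j} is then replaced
#' by the rank-\code{j} population member with probability \code{arp}.
#' With \code{arp = 1} the archive becomes the population's top-n; with
#' \code{arp = 0} it is unchanged; in between it mixes current elites with
#' historically successful individuals.
#'
#' @param pop Evaluated population.
#' @param archive Archive (strictly smaller than the population).
#' @param arp Replacement probability in \code{[0, 1]}.
#' @return The updated archive.
#' @export
archive_update <- function(pop, archive, arp) {
  n <- nrow(archive$chrom)
  if (n >= nrow(pop$chrom))
    stop("archive capacity must be strictly smaller than population size",
         call. = FALSE)
  ao <- order(-archive$fit, archive$vl, seq_len(n))
  archive$chrom <- archive$chrom[ao, , drop = FALSE]
  archive$fit <- archive$fit[ao]
  archive$vl <- archive$vl[ao]
  po <- pop_order(pop)[seq_len(n)]
  repl <- stats::runif(n) < arp
  if (any(repl)) {
    src <- po[repl]
    archive$chrom[repl, ] <- pop$chrom[src, , drop = FALSE]
    archive$fit[repl] <- pop$fit[src]
    archive$vl[repl] <- pop$vl[src]
  }
  archive
}

#' Choose a source archive for transfer
#'
#' Uniform over all \code{M} task archives; the source may equal the
#' target (self transfer) and may belong to a terminated task, whose
#' frozen archive still serves as donor material.
#'
#' @param M Number of tasks.
#' @return A task index in \code{1..M}.
#' @export
select_source_archive <- function(M) {
  sample.int(M, 1L)
}

#' Advance one task by one generation
#'
#' When the generation counter \code{t} is divisible by the transfer
#' interval and transfer is enabled, a source archive is chosen uniformly
#' and the transfer generation runs (crossover-based for the GA operator,
#' DE1/DE2 for the DE operator); otherwise the task self-evolves. The
#' task's own archive is then refreshed. Transfer generations are logged
#' with the signed best-fitness change they produced.
#'
#' @param task An active \code{"emcgep_task"} with initialized population
#'   and archive.
#' @param archives List of all task archives (transfer sources).
#' @param t Global generation counter (starts at 1).
#' @param cfg An \code{\link{emcgep_config}}.
#' @return \code{list(task, diag)} where \code{diag} is a one-row data
#'   frame for transfer generations and \code{NULL} otherwise.
#' @export
evolve_one_generation <- function(task, archives, t, cfg) {
  if (task$status != "active") {
    warning("task '", task$label, "' is terminated; no-op", call. = FALSE)
    return(list(task = task, diag = NULL))
  }
  eval_fn <- task_evaluator(task, cfg)
  is_transfer <- cfg$transfer != "none" && (t %% cfg$delta == 0)
  diag <- NULL
  if (is_transfer) {
    k <- select_source_archive(length(archives))
    src <- archives[[k]]
    before <- max(task$pop$fit)
    task$pop <- switch(cfg$transfer,
      GA  = ga_transfer_crossover(task$pop, src, cfg, eval_fn),
      DE1 = de_transfer_generation(task$pop, src, "DE1", cfg, eval_fn),
      DE2 = de_transfer_generation(task$pop, src, "DE2", cfg, eval_fn))
    diag <- data.frame(generation = t, source_task = k,
                       best_fitness_before = before,
                       best_fitness_after = max(task$pop$fit))
    diag$enhancement <- diag$best_fitness_after - diag$best_fitness_before
  } else {
    task$pop <- if (cfg$operator == "GA") {
      ga_generation(task$pop, cfg, eval_fn)
    } else {
      de_generation(task$pop, cfg, eval_fn)
    }
  }
  task$archive <- archive_update(task$pop, task$archive, cfg$arp)
  list(task = task, diag = diag)
}

# End of a rule's evolution budget: take the population's best individual
# and run the covering/MDL bookkeeping. Accept the rule iff the rule
# set's description length still decreases; terminate otherwise, when the
# positive set empties, or when the best rule covers no remaining
# positive (covering stall).
finalize_rule <- function(task, cfg, t) {
  bi <- best_index(task$pop)
  chrom <- task$pop$chrom[bi, ]
  e <- evaluate_chrom_on_task(chrom, task, cfg)
  covered_remaining <- e$cov & task$remaining
  ri <- length(task$H) + 1L
  if (!any(covered_remaining)) {
    warning("task '", task$label,
            "': best rule covers no remaining positive; terminating",
            call. = FALSE)
    task$status <- "terminated"
    task$log[[length(task$log) + 1L]] <- data.frame(
      rule = ri, accepted = FALSE, stalled = TRUE,
      L_H = NA_real_, L_min = task$L_min,
      valid_length = e$vl, fitness = e$fit)
    return(task)
  }
  new_l_theory <- task$L_theory + mdl_l_theory(e$vl, cfg$alpha$Nc)
  union_cov <- task$covered_union | e$cov
  TP <- sum(union_cov & task$is_pos)
  FP <- sum(union_cov & !task$is_pos)
  cts <- counts(TP = TP, FP = FP, TN = task$N - FP, FN = task$P - TP,
                P = task$P, N = task$N)
  L_H <- mdl_description_length(new_l_theory, mdl_l_exception(cts))
  accepted <- L_H < task$L_min
  task$log[[length(task$log) + 1L]] <- data.frame(
    rule = ri, accepted = accepted, stalled = FALSE,
    L_H = L_H, L_min = task$L_min,
    valid_length = e$vl, fitness = e$fit)
  if (!accepted) {
    task$status <- "terminated"
    return(task)
  }
  task$H[[ri]] <- list(chrom = chrom, vl = e$vl, fitness = e$fit,
                       class = task$label, covered = e$cov)
  task$L_theory <- new_l_theory
  task$L_min <- L_H
  task$covered_union <- union_cov
  task$remaining <- task$remaining & !e$cov
  if (!any(task$remaining)) {
    task$status <- "terminated"
  } else {
    task$pop <- random_population(task, cfg)   # fresh population per rule
    task$archive <- archive_update(task$pop, task$archive, cfg$arp)
    task$t_rule_start <- t
  }
  task
}

#' Learn a single covering rule
#'
#' Runs \code{generations_per_rule} generations of self evolution on the
#' task's current covering state (a fresh random population is drawn if
#' the task has none) and returns the fittest chromosome. With a budget of
#' zero this is the best of the initial random population. Randomness
#' comes from the session RNG.
#'
#' @param task An \code{"emcgep_task"} with a non-empty remaining
#'   positive set.
#' @param cfg An \code{\link{emcgep_config}}.
#' @return \code{list(chrom, fit, vl)} for the best individual found.
#' @export
learn_rule <- function(task, cfg) {
  if (!any(task$remaining))
    stop("task has no remaining positive samples", call. = FALSE)
  if (is.null(task$pop)) task$pop <- random_population(task, cfg)
  eval_fn <- task_evaluator(task, cfg)
  for (t in seq_len(cfg$generations_per_rule)) {
    task$pop <- if (cfg$operator == "GA") {
      ga_generation(task$pop, cfg, eval_fn)
    } else {
      de_generation(task$pop, cfg, eval_fn)
    }
  }
  bi <- best_index(task$pop)
  list(chrom = task$pop$chrom[bi, ], fit = task$pop$fit[bi],
       vl = task$pop$vl[bi])
}

#' Run all binary tasks to termination
#'
#' Tasks advance generation-synchronously (round-robin, one generation
#' each) so all archives coexist in time; a terminated task's archive is
#' frozen but still serves as a transfer source. Each task consumes
#' \code{generations_per_rule} generations per covering rule and then
#' accepts or rejects the rule under the description-length criterion.
#' Each task runs on its own RNG substream derived from \code{seed}, so
#' results do not depend on scheduling order.
#'
#' @param tasks List of \code{"emcgep_task"} objects.
#' @param cfg An \code{\link{emcgep_config}}.
#' @param seed Integer seed for the run.
#' @param on_generation Optional callback \code{function(t, tasks)} invoked
#'   after every global generation (diagnostics, tests).
#' @return A list of class \code{"emcgep_run"}: \code{tasks} (all
#'   terminated, with rule sets in \code{$H}), \code{diagnostics} (one row
#'   per transfer event: generation, target and source task, best fitness
#'   before/after, signed enhancement), \code{trace} (best fitness per
#'   task per generation) and \code{rule_log}.
#' @export
run_all_tasks <- function(tasks, cfg, seed = 1L, on_generation = NULL) {
  M <- length(tasks)
  stopifnot(M >= 1L, cfg$generations_per_rule >= 1L)
  set.seed(seed)
  subseeds <- draw_subseeds(M)
  for (i in seq_len(M)) {
    st <- with_rng(rng_make(subseeds[i]), function() {
      pop <- random_population(tasks[[i]], cfg)
      list(pop = pop, archive = init_archive(pop, cfg))
    })
    tasks[[i]]$pop <- st$value$pop
    tasks[[i]]$archive <- st$value$archive
    tasks[[i]]$rng <- st$state
  }
  diagnostics <- list()
  trace <- list()
  t <- 0L
  while (any(vapply(tasks, function(x) x$status == "active", logical(1)))) {
    t <- t + 1L
    archives <- lapply(tasks, `[[`, "archive")  # generation-start snapshot
    for (i in seq_len(M)) {
      if (tasks[[i]]$status != "active") next
      res <- with_rng(tasks[[i]]$rng, function() {
        out <- evolve_one_generation(tasks[[i]], archives, t, cfg)
        if (t - out$task$t_rule_start >= cfg$generations_per_rule &&
            out$task$status == "active") {
          out$task <- finalize_rule(out$task, cfg, t)
        }
        out
      })
      tasks[[i]] <- res$value$task
      tasks[[i]]$rng <- res$state
      if (!is.null(res$value$diag)) {
        d <- res$value$diag
        d$target_task <- i
        diagnostics[[length(diagnostics) + 1L]] <- d
      }
      trace[[length(trace) + 1L]] <- data.frame(
        generation = t, task = i, best_fitness = max(tasks[[i]]$pop$fit))
    }
    if (!is.null(on_generation)) on_generation(t, tasks)
  }
  diagnostics <- if (length(diagnostics)) {
    d <- do.call(rbind, diagnostics)
    d[, c("generation", "target_task", "source_task",
          "best_fitness_before", "best_fitness_after", "enhancement")]
  } else {
    data.frame(generation = integer(), target_task = integer(),
               source_task = integer(), best_fitness_before = numeric(),
               best_fitness_after = numeric(), enhancement = numeric())
  }
  rule_log <- do.call(rbind, lapply(seq_len(M), function(i) {
    if (length(tasks[[i]]$log) == 0L) return(NULL)
    cbind(task = i, do.call(rbind, tasks[[i]]$log))
  }))
  structure(list(tasks = tasks, diagnostics = diagnostics,
                 trace = do.call(rbind, trace), rule_log = rule_log),
            class = "emcgep_run")
}

#' Covering loop for a single task
#'
#' Convenience wrapper running \code{\link{run_all_tasks}} on one task
#' (knowledge transfer, if enabled, degenerates to self transfer from the
#' task's own archive).
#'
#' @inheritParams run_all_tasks
#' @param task A single \code{"emcgep_task"}.
#' @return The terminated task, with its accepted rule set in \code{$H}.
#' @export
covering_loop <- function(task, cfg, seed = 1L) {
  run_all_tasks(list(task), cfg, seed = seed)$tasks[[1L]]
}
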