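# Post-pruning: pooled binary rules are re-scored against the remaining
# training samples, the best is appended to an ordered decision list, the
# samples it covers are removed, and the loop repeats; a default class
# handles samples no rule covers.

#' Majority label of remaining samples
#'
#' The label with most samples in \code{remaining}; ties are broken
#' uniformly at random, and an empty remainder yields a uniform draw over
#' the whole label universe.
#'
#' @param remaining Character vector of remaining sample labels.
#' @param classes The label universe.
#' @return A single class label.
#' @export
default_class <- function(remaining, classes) {
  if (length(remaining) == 0L)
    return(classes[sample.int(length(classes), 1L)])
  tab <- table(factor(remaining, levels = classes))
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
}

# Fitness of a rule on the remaining sample set: the rule's class defines
# the positives, with P and N recomputed from the remainder. When no
# negatives remain, the corrected precision degenerates; we score 1 if the
# rule makes no error possible (all covered are positive by definition)
# and still discount by recall.
prune_fitness <- function(cov, pos, remaining) {
  rem_cov <- cov & remaining
  P <- sum(pos & remaining)
  N <- sum(remaining) - P
  TP <- sum(rem_cov & pos)
  FP <- sum(rem_cov) - TP
  if (P == 0L) return(0)
  rec <- TP / P
  if (N == 0L) {
    pre <- if (TP > 0L) 1 else 0
    return(pre * exp(rec - 1))
  }
  rule_fitness(counts(TP = TP, FP = FP, TN = N - FP, FN = P - TP,
                      P = P, N = N))
}

#' Post-prune pooled rules into an ordered decision list
#'
#' Iterates Evaluation / Sorting / Selecting / Update: every remaining
#' rule is re-scored by the covering fitness against the remaining
#' training samples (its own class as positives), the best rule (ties
#' broken by shorter valid length, then task and rule index) is moved to
#' the ordered list, and the samples it covers are removed. The loop stops
#' when no remaining rule covers any remaining sample; the default class
#' is the majority label of the remainder.
#'
#' @param rules Pooled rules from all tasks: a list of lists with fields
#'   \code{chrom}, \code{class}, and optionally \code{task} and \code{vl}.
#' @param X Training matrix.
#' @param y Training labels.
#' @param cfg An \code{\link{emcgep_config}}.
#' @param classes Label universe (defaults to the sorted labels of
#'   \code{y}).
#' @return A model of class \code{"emcgep_model"}: ordered \code{rules}
#'   (each with its decoded tree, class and fitness at selection),
#'   \code{default_class}, \code{classes} and the \code{cfg} used.
#' @export
post_prune <- function(rules, X, y, cfg, classes = sort(unique(y))) {
  n <- nrow(X)
  if (n == 0L) stop("training set is empty", call. = FALSE)
  nr <- length(rules)
  meta <- NULL
  if (nr > 0L) {
    trees <- lapply(rules, function(r) gep_decode(r$chrom, cfg))
    covm <- matrix(FALSE, nr, n)
    for (i in seq_len(nr))
      covm[i, ] <- gep_evaluate(trees[[i]], X, cfg) > 0
    meta <- data.frame(
      idx = seq_len(nr),
      vl = vapply(trees, function(tr) tr$valid_length, integer(1)),
      task = vapply(rules, function(r) {
        if (is.null(r$task)) 0L else as.integer(r$task)
      }, integer(1))
    )
    posm <- vapply(rules, function(r) y == r$class, logical(n))
    if (n == 1L) posm <- matrix(posm, nrow = 1L)
  }
  remaining <- rep(TRUE, n)
  active <- seq_len(nr)
  ordered <- list()
  while (length(active) > 0L && any(remaining)) {
    covers_any <- vapply(active, function(i) any(covm[i, ] & remaining),
                         logical(1))
    active <- active[covers_any]
    if (length(active) == 0L) break
    fit <- vapply(active, function(i) {
      prune_fitness(covm[i, ], posm[, i], remaining)
    }, numeric(1))
    pick <- active[order(-fit, meta$vl[active], meta$task[active],
                         active)[1L]]
    ordered[[length(ordered) + 1L]] <- list(
      chrom = rules[[pick]]$chrom,
      tree = trees[[pick]],
      class = rules[[pick]]$class,
      fitness = fit[match(pick, active)],
      vl = meta$vl[pick])
    remaining <- remaining & !covm[pick, ]
    active <- setdiff(active, pick)
  }
  structure(list(
    rules = ordered,
    default_class = default_class(y[remaining], classes),
    classes = classes,
    cfg = cfg
  ), class = "emcgep_model")
}

#' Predict class labels with a decision list
#'
#' Rules are scanned in order; each sample receives the class of the first
#' rule that covers it, or the default class if none does.
#'
#' @param object An \code{"emcgep_model"}.
#' @param newdata Numeric matrix or data frame of feature columns.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.emcgep_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$cfg$alpha$n_features)
    stop("newdata has ", ncol(X), " features; model expects ",
         object$cfg$alpha$n_features, call. = FALSE)
  storage.mode(X) <- "double"
  out <- rep(object$default_class, nrow(X))
  unassigned <- rep(TRUE, nrow(X))
  for (r in object$rules) {
    if (!any(unassigned)) break
    cov <- gep_evaluate(r$tree, X, object$cfg) > 0
    hit <- cov & unassigned
    out[hit] <- r$class
    unassigned <- unassigned & !hit
  }
  out
}

#' @export
print.emcgep_model <- function(x, ...) {
  cat("EMC-GEP decision list:", length(x$rules), "rule(s), default class",
      x$default_class, "\n")
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    cat(sprintf("  %2d. [%s] %s  (fitness %.4f)\n", i, r$class,
                format(r$tree, x$cfg), r$fitness))
  }
  invisible(x)
}

#' Write / read a model as JSON
#'
#' Rules are stored as plain-text token strings together with the class
#' labels, the default class and the alphabet configuration needed to
#' rebuild them.
#'
#' @param model An \code{"emcgep_model"}.
#' @param path File path.
#' @return \code{write_model} returns \code{path} invisibly;
#'   \code{read_model} returns the model.
#' @export
write_model <- function(model, path) {
  cfg <- model$cfg
  doc <- list(
    format = "emcgep-model",
    classes = as.character(model$classes),
    default_class = as.character(model$default_class),
    rules = lapply(model$rules, function(r) list(
      tokens = chromosome_to_tokens(r$chrom, cfg),
      class = as.character(r$class),
      fitness = r$fitness,
      valid_length = r$vl)),
    config = list(
      n_features = cfg$alpha$n_features,
      feature_names = cfg$alpha$feature_names,
      head_length = cfg$h,
      constants = cfg$alpha$const[!is.na(cfg$alpha$const)],
      variant = model$variant %||% NA,
      seed = model$seed %||% NA
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- emcgep_config(n_features = doc$config$n_features,
                       feature_names = doc$config$feature_names,
                       head_length = doc$config$head_length,
                       constants = doc$config$constants)
  rules <- lapply(doc$rules, function(r) {
    chrom <- tokens_to_chromosome(r$tokens, cfg)
    list(chrom = chrom, tree = gep_decode(chrom, cfg), class = r$class,
         fitness = r$fitness, vl = r$valid_length)
  })
  structure(list(rules = rules, default_class = doc$default_class,
                 classes = doc$classes, cfg = cfg),
            class = "emcgep_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
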