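# End-to-end classifier API: one-against-all decomposition, the five
# method variants, dataset I/O, stratified splitting, the synthetic
# multi-class generator, and the Wilcoxon comparison harness.

EMCGEP_VARIANTS <- list(
  "accgep-ga"  = list(operator = "GA", transfer = "none"),
  "emcgep-ga"  = list(operator = "GA", transfer = "GA"),
  "accgep-de"  = list(operator = "DE", transfer = "none"),
  "emcgep-de1" = list(operator = "DE", transfer = "DE1"),
  "emcgep-de2" = list(operator = "DE", transfer = "DE2")
)

#' Map a method variant name to its operator/transfer pair
#'
#' The baseline variants (\code{accgep-*}) evolve each binary task in
#' isolation; the multitasking variants add archive-based knowledge
#' transfer: \code{emcgep-ga} via crossover against archive members,
#' \code{emcgep-de1} via archive donors in the DE operator, and
#' \code{emcgep-de2} additionally via the archive's symbol-frequency
#' record.
#'
#' @param variant One of \code{"accgep-ga"}, \code{"emcgep-ga"},
#'   \code{"accgep-de"}, \code{"emcgep-de1"}, \code{"emcgep-de2"}.
#' @return List with \code{operator} and \code{transfer}.
#' @export
variant_params <- function(variant) {
  v <- EMCGEP_VARIANTS[[match.arg(variant, names(EMCGEP_VARIANTS))]]
  v
}

#' Read a tabular classification dataset from CSV
#'
#' Expects a header row, one sample per row, numeric feature columns and a
#' label column (by default the last column). Missing values are rejected.
#'
#' @param file CSV path.
#' @param label_col Name of the label column; default: last column.
#' @return List with \code{X} (numeric matrix), \code{y} (character
#'   labels) and \code{feature_names}.
#' @export
read_dataset <- function(file, label_col = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (is.null(label_col)) label_col <- names(df)[ncol(df)]
  if (!label_col %in% names(df))
    stop("label column '", label_col, "' not found", call. = FALSE)
  y <- as.character(df[[label_col]])
  Xdf <- df[setdiff(names(df), label_col)]
  X <- as.matrix(Xdf)
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(y))
    stop("dataset contains missing values", call. = FALSE)
  list(X = X, y = y, feature_names = colnames(X))
}

#' Decompose a dataset into one-vs-all binary tasks
#'
#' One task per class (in sorted label order): the class's samples are the
#' positives, all others the negatives.
#'
#' @param X Numeric training matrix.
#' @param y Class labels.
#' @return List of \code{"emcgep_task"} objects.
#' @export
one_vs_all_tasks <- function(X, y) {
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2L)
    stop("need at least 2 classes", call. = FALSE)
  yc <- as.character(y)
  lapply(classes, function(cl) new_binary_task(cl, X, yc))
}

#' Fit an EMC-GEP / AccGEP multi-classifier
#'
#' Decomposes the training data one-against-all, runs the multitask
#' covering engine for the chosen variant, pools every task's accepted
#' rules and post-prunes them into an ordered decision list with a default
#' class. All randomness derives from \code{seed}.
#'
#' @param X Numeric training matrix (samples in rows).
#' @param y Class labels.
#' @param variant Method variant name (see \code{\link{variant_params}}),
#'   or \code{"majority"} for the rule-free default-class baseline.
#' @param seed Integer seed.
#' @param ... Engine parameters passed to \code{\link{emcgep_config}}
#'   (e.g. \code{pop_size}, \code{head_length},
#'   \code{generations_per_rule}, \code{delta}, \code{arp}).
#' @return An \code{"emcgep_model"} with the engine run's
#'   \code{diagnostics}, \code{trace} and \code{rule_log} attached.
#' @export
emcgep_fit <- function(X, y, variant = "emcgep-de1", seed = 1L, ...) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.character(y)
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  classes <- sort(unique(y))
  if (variant == "majority") {
    cfg <- emcgep_config(n_features = ncol(X),
                         feature_names = colnames(X), ...)
    set.seed(seed)
    model <- post_prune(list(), X, y, cfg, classes)
    model$variant <- "majority"
    model$seed <- seed
    return(model)
  }
  vp <- variant_params(variant)
  cfg <- emcgep_config(n_features = ncol(X), feature_names = colnames(X),
                       operator = vp$operator, transfer = vp$transfer, ...)
  set.seed(seed)
  seeds <- draw_subseeds(2L)
  tasks <- one_vs_all_tasks(X, y)
  run <- run_all_tasks(tasks, cfg, seed = seeds[1L])
  pool <- list()
  for (i in seq_along(run$tasks)) {
    for (r in run$tasks[[i]]$H) {
      r$task <- i
      pool[[length(pool) + 1L]] <- r
    }
  }
  set.seed(seeds[2L])
  model <- post_prune(pool, X, y, cfg, classes)
  model$variant <- variant
  model$seed <- seed
  model$diagnostics <- run$diagnostics
  model$trace <- run$trace
  model$rule_log <- run$rule_log
  model
}

#' Accuracy and confusion matrix on a test set
#'
#' @param model An \code{"emcgep_model"}.
#' @param X Test matrix.
#' @param y True labels.
#' @return List with \code{accuracy} in \code{[0, 1]} and a
#'   \code{confusion} matrix (true classes in rows).
#' @export
emcgep_evaluate <- function(model, X, y) {
  y <- as.character(y)
  pred <- predict(model, X)
  lev <- sort(unique(c(model$classes, y)))
  confusion <- table(true = factor(y, levels = lev),
                     predicted = factor(pred, levels = lev))
  list(accuracy = mean(pred == y), confusion = confusion)
}

#' Stratified train/test split
#'
#' Each class is split at \code{train_fraction} independently so that
#' small classes are preserved in both partitions; a class with a single
#' sample goes entirely to the training set with a warning.
#'
#' @param X Feature matrix.
#' @param y Labels.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.75).
#' @param seed Integer seed.
#' @return List with \code{train} and \code{test}, each \code{list(X, y)}.
#' @export
emcgep_split <- function(X, y, train_fraction = 0.75, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  X <- as.matrix(X)
  y <- as.character(y)
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    if (length(idx) < 2L) {
      warning("class '", cl, "' has fewer than 2 samples; ",
              "assigning all to the training set", call. = FALSE)
      train_idx <- c(train_idx, idx)
      next
    }
    k <- round(length(idx) * train_fraction)
    k <- max(1L, min(length(idx) - 1L, k))
    train_idx <- c(train_idx, sample(idx, k))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  list(train = list(X = X[train_idx, , drop = FALSE], y = y[train_idx]),
       test = list(X = X[test_idx, , drop = FALSE], y = y[test_idx]))
}

# --- synthetic data -------------------------------------------------------

# Build a breadth-first token string from a nested (tok, kids) node.
bfs_linearize <- function(node) {
  out <- character(0)
  queue <- list(node)
  while (length(queue)) {
    nd <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, nd$tok)
    queue <- c(queue, nd$kids)
  }
  out
}

synth_truth_rules <- function(n_classes, informative) {
  leaf <- function(tok) list(tok = tok, kids = list())
  nd <- function(tok, ...) list(tok = tok, kids = list(...))
  feat <- function(j) leaf(paste0("x", informative[j] - 1L))
  neg <- nd("-", leaf("1"), leaf("3"))               # constant -2: never covers
  cond_le <- function(j) nd("-", leaf("2"), feat(j)) # > 0 iff x_j < 2
  cond_gt <- function(j) nd("-", feat(j), leaf("2")) # > 0 iff x_j > 2
  build <- function(conds, then) {
    node <- then
    for (cond in rev(conds)) node <- nd("IF", cond, node, neg)
    node
  }
  rules <- vector("list", n_classes)
  for (c in seq_len(n_classes)) {
    prior <- if (c > 1L) lapply(seq_len(c - 1L), cond_le) else list()
    then <- if (c < n_classes) cond_gt(c) else leaf("1")
    rules[[c]] <- paste(bfs_linearize(build(prior, then)), collapse = " ")
  }
  names(rules) <- paste0("C", seq_len(n_classes))
  rules
}

#' Generate a synthetic multi-class dataset with known rules
#'
#' Class boundaries are axis-aligned thresholds at 2 on a chain of
#' informative features drawn uniformly on \code{[0, 4]}: class 1 has
#' \code{x_(i1) > 2}; class c has \code{x_(i1..i(c-1)) <= 2} and
#' \code{x_(ic) > 2}; the last class has all chain features \code{<= 2}.
#' Each boundary is expressible in the GEP function set
#' \{+, -, *, /, Sqrt, IF\} with the constant terminals, and the
#' generating rules are returned as token strings so recovery can be
#' tested exactly. Remaining features are i.i.d. noise on \code{[0, 4]};
#' \code{noise_sd} adds Gaussian perturbation to the informative features
#' after labelling (labels keep their region of origin). Class sizes are
#' balanced within one sample.
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_samples Total sample count.
#' @param n_features Total feature count.
#' @param n_informative Number of informative features; must be at least
#'   \code{n_classes - 1} (the chain length) and at most \code{n_features}.
#' @param noise_sd Standard deviation of Gaussian feature noise.
#' @param seed Integer seed.
#' @return List with \code{X}, \code{y} (labels \code{C1..CM}),
#'   \code{informative} (feature indices, the first
#'   \code{n_classes - 1} of which form the decision chain) and
#'   \code{truth_rules} (one breadth-first token string per class).
#' @export
emcgep_synth <- function(n_classes = 3L, n_samples = 200L,
                         n_features = 10L, n_informative = 3L,
                         noise_sd = 0, seed = 1L) {
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  if (n_informative > n_features)
    stop("n_informative exceeds n_features", call. = FALSE)
  if (n_informative < n_classes - 1L)
    stop("the threshold-chain rule family needs n_informative >= ",
         "n_classes - 1", call. = FALSE)
  set.seed(seed)
  informative <- sort(sample.int(n_features, n_informative))
  sizes <- rep(n_samples %/% n_classes, n_classes)
  extra <- n_samples %% n_classes
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  X <- matrix(stats::runif(n_samples * n_features, 0, 4),
              n_samples, n_features)
  y <- character(n_samples)
  row <- 0L
  for (c in seq_len(n_classes)) {
    rows <- row + seq_len(sizes[c])
    for (j in seq_len(min(n_classes - 1L, n_informative))) {
      f <- informative[j]
      X[rows, f] <- if (j < c) {
        stats::runif(sizes[c], 0, 2)
      } else if (j == c) {
        stats::runif(sizes[c], 2, 4)
      } else {
        stats::runif(sizes[c], 0, 4)
      }
    }
    y[rows] <- paste0("C", c)
    row <- row + sizes[c]
  }
  if (noise_sd > 0)
    X[, informative] <- X[, informative] +
      stats::rnorm(n_samples * n_informative, 0, noise_sd)
  perm <- sample.int(n_samples)
  X <- X[perm, , drop = FALSE]
  y <- y[perm]
  colnames(X) <- paste0("x", seq_len(n_features) - 1L)
  list(X = X, y = y, informative = informative,
       truth_rules = synth_truth_rules(n_classes, informative))
}

# --- comparison harness ---------------------------------------------------

#' Compare method variants over repeated trials
#'
#' Runs each variant over \code{n_trials} independent stratified
#' train/test splits, reports mean accuracy and ranks, and performs
#' pairwise Wilcoxon signed-rank tests on the paired per-trial accuracies.
#' In the significance matrix, entry (i, j) is \code{"+"} when variant i
#' is significantly better than variant j at level \code{alpha},
#' \code{"-"} when significantly worse, and \code{"="} otherwise.
#'
#' @param X Feature matrix.
#' @param y Labels.
#' @param variants Character vector of variant names
#'   (\code{\link{variant_params}} names, plus \code{"majority"} for the
#'   default-class control).
#' @param n_trials Number of independent trials (>= 2); each trial
#'   re-splits the data.
#' @param seed Integer seed.
#' @param train_fraction Train fraction per trial.
#' @param alpha Significance level for the signed-rank tests.
#' @param ... Engine parameters forwarded to \code{\link{emcgep_fit}}.
#' @return List with \code{accuracy} (trials x variants matrix),
#'   \code{table} (mean accuracy and rank per variant), \code{p_values}
#'   and \code{significance} (pairwise matrices).
#' @export
compare_variants <- function(X, y, variants = c("accgep-de", "emcgep-de1"),
                             n_trials = 30L, seed = 1L,
                             train_fraction = 0.75, alpha = 0.1, ...) {
  stopifnot(n_trials >= 2L)
  set.seed(seed)
  split_seeds <- draw_subseeds(n_trials)
  fit_seeds <- matrix(draw_subseeds(n_trials * length(variants)),
                      n_trials, length(variants))
  acc <- matrix(NA_real_, n_trials, length(variants),
                dimnames = list(NULL, variants))
  for (tr in seq_len(n_trials)) {
    sp <- emcgep_split(X, y, train_fraction, seed = split_seeds[tr])
    for (v in seq_along(variants)) {
      model <- emcgep_fit(sp$train$X, sp$train$y, variant = variants[v],
                          seed = fit_seeds[tr, v], ...)
      acc[tr, v] <- emcgep_evaluate(model, sp$test$X, sp$test$y)$accuracy
    }
  }
  k <- length(variants)
  pv <- matrix(NA_real_, k, k, dimnames = list(variants, variants))
  sig <- matrix("=", k, k, dimnames = list(variants, variants))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    d <- acc[, i] - acc[, j]
    pv[i, j] <- if (all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(acc[, i], acc[, j],
                                          paired = TRUE)$p.value)
    if (!is.na(pv[i, j]) && pv[i, j] < alpha)
      sig[i, j] <- if (mean(d) > 0) "+" else "-"
  }
  means <- colMeans(acc)
  tab <- data.frame(variant = variants, mean_accuracy = means,
                    rank = rank(-means, ties.method = "average"),
                    row.names = NULL)
  list(accuracy = acc, table = tab, p_values = pv, significance = sig)
}
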