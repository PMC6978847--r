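# Independent oracles used across the suite. These deliberately use
# different mechanisms from the package implementation.

# Queue-simulation decoder: builds the tree with explicit node objects and
# a FIFO of parents awaiting children, consuming symbols one at a time.
# Returns nested nodes list(sym, kids) plus the number of consumed symbols.
oracle_decode <- function(chrom, cfg) {
  ar <- cfg$alpha$arity
  nodes <- list(list(sym = chrom[1L], kids = integer(0)))
  consumed <- 1L
  parents <- integer(0)
  remain <- integer(0)
  if (ar[chrom[1L]] > 0L) {
    parents <- 1L
    remain <- ar[chrom[1L]]
  }
  qi <- 1L
  while (qi <= length(parents)) {
    p <- parents[qi]
    for (s in seq_len(remain[qi])) {
      consumed <- consumed + 1L
      id <- chrom[consumed]
      nodes[[consumed]] <- list(sym = id, kids = integer(0))
      nodes[[p]]$kids <- c(nodes[[p]]$kids, consumed)
      if (ar[id] > 0L) {
        parents <- c(parents, consumed)
        remain <- c(remain, ar[id])
      }
    }
    qi <- qi + 1L
  }
  nest <- function(i) {
    list(sym = nodes[[i]]$sym, kids = lapply(nodes[[i]]$kids, nest))
  }
  list(tree = nest(1L), valid_length = consumed)
}

# Convert the package's flat gep_tree into the oracle's nested form.
tree_to_nested <- function(tr) {
  f <- function(i) {
    kids <- lapply(seq_len(tr$arity[i]) - 1L,
                   function(j) f(tr$child_start[i] + j))
    list(sym = tr$sym[i], kids = kids)
  }
  f(1L)
}

# Recursive evaluator on the oracle's nested tree, with the same
# protection rules, written scalar-first.
oracle_eval <- function(node, x, cfg) {
  a <- cfg$alpha
  id <- node$sym
  if (a$arity[id] == 0L) {
    if (a$feat[id] > 0L) return(x[a$feat[id]])
    return(a$const[id])
  }
  k <- lapply(node$kids, oracle_eval, x = x, cfg = cfg)
  tok <- a$token[id]
  v <- switch(tok,
    "+" = k[[1]] + k[[2]],
    "-" = k[[1]] - k[[2]],
    "*" = k[[1]] * k[[2]],
    "/" = if (abs(k[[2]]) < 1e-9) 1 else k[[1]] / k[[2]],
    "Sqrt" = sqrt(abs(k[[1]])),
    "IF" = if (k[[1]] > 0) k[[2]] else k[[3]])
  min(max(v, -1e150), 1e150)
}

# Straight-line recomputation of the corrected precision and fitness.
oracle_precision <- function(TP, FP, P, N) {
  raw <- if (TP + FP == 0) 0 else TP / (TP + FP)
  base <- P / (P + N)
  (raw - base) * (P + N) / N
}

oracle_fitness <- function(TP, FP, P, N) {
  pre <- oracle_precision(TP, FP, P, N)
  if (pre < 0) return(0)
  pre * exp(TP / P - 1)
}

# Exception bits via R's exact-ish binomial coefficient (choose), not the
# log-gamma route the implementation uses.
oracle_l_exception <- function(TP, FP, TN, FN) {
  log2(choose(TP + FP, FP)) + log2(choose(TN + FN, FN))
}

# Small default configs for unit tests.
test_cfg <- function(n_features = 4, head_length = 6, pop_size = 20,
                     generations_per_rule = 5, ...) {
  emcgep_config(n_features = n_features, head_length = head_length,
                pop_size = pop_size,
                generations_per_rule = generations_per_rule, ...)
}

# Binary-only alphabet (u = 2) matching classic worked GEP examples.
binary_cfg <- function(n_features = 2, head_length = 3) {
  fs <- data.frame(token = c("+", "-", "*", "/"), arity = 2L,
                   stringsAsFactors = FALSE)
  alpha <- gep_alphabet(n_features, constants = numeric(0),
                        function_set = fs)
  l <- gep_tail_length(head_length, alpha$u)
  list(alpha = alpha, h = as.integer(head_length), l = l,
       len = as.integer(head_length) + l)
}

chrom_of <- function(tokens, cfg, pad = TRUE) {
  tokens_to_chromosome(tokens, cfg, pad = pad)
}

# Two-cluster binary task fixture: cluster A sits at x0 < 1, cluster B at
# x1 > 3 (with x0 > 1); negatives fill x0 > 1, x1 < 3. Each cluster is
# coverable by a one-threshold rule on its own feature, but covering the
# union in a single rule needs a genuine disjunction.
two_cluster_task <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  X <- rbind(
    cbind(runif(n_per, 0, 1), runif(n_per, 0, 4)),        # cluster A
    cbind(runif(n_per, 1, 4), runif(n_per, 3, 4)),        # cluster B
    cbind(runif(2 * n_per, 1, 4), runif(2 * n_per, 0, 3)) # negatives
  )
  colnames(X) <- c("x0", "x1")
  y <- rep(c("pos", "neg"), each = 2 * n_per)
  new_binary_task("pos", X, y)
}
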