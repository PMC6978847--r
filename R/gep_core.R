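# GEP chromosome representation: fixed-length integer vectors indexing a
# symbol alphabet, decoded breadth-first into expression trees.

FUNCTION_SET <- data.frame(
  token = c("+", "-", "*", "/", "Sqrt", "IF"),
  arity = c(2L, 2L, 2L, 2L, 1L, 3L),
  stringsAsFactors = FALSE
)

#' Tail length of a GEP chromosome
#'
#' The head of a GEP chromosome (length \code{h}) may hold functions and
#' terminals; the tail holds terminals only. A tail of length
#' \code{h * (u - 1) + 1}, where \code{u} is the maximum arity in the
#' function set, guarantees that breadth-first decoding always yields a
#' complete expression tree regardless of head content.
#'
#' @param h Head length, a positive integer.
#' @param u Maximum function arity, an integer >= 1.
#' @return The tail length \code{h * (u - 1) + 1}.
#' @export
#' @examples
#' gep_tail_length(10, 2) # 11
#' gep_tail_length(33, 3) # 67
gep_tail_length <- function(h, u) {
  if (length(h) != 1L || !is.finite(h) || h < 1 || h != floor(h))
    stop("`h` must be a positive integer", call. = FALSE)
  if (length(u) != 1L || !is.finite(u) || u < 1 || u != floor(u))
    stop("`u` must be an integer >= 1", call. = FALSE)
  as.integer(h) * (as.integer(u) - 1L) + 1L
}

# Symbol alphabet: functions first, then feature terminals x0..x{d-1},
# then numeric constants. Stored as parallel vectors for fast indexing.
gep_alphabet <- function(n_features, feature_names = NULL,
                         constants = c(1, 2, 3, 5, 7),
                         function_set = FUNCTION_SET) {
  if (n_features < 1 && length(constants) < 1)
    stop("terminal set is empty: need at least one feature or constant",
         call. = FALSE)
  nf <- nrow(function_set)
  feat_tok <- paste0("x", seq_len(n_features) - 1L)
  if (is.null(feature_names)) feature_names <- feat_tok
  token <- c(function_set$token, feat_tok, as.character(constants))
  arity <- c(function_set$arity, integer(n_features + length(constants)))
  op    <- c(seq_len(nf), integer(n_features + length(constants)))
  feat  <- c(integer(nf), seq_len(n_features), integer(length(constants)))
  const <- c(rep(NA_real_, nf + n_features), as.numeric(constants))
  list(token = token, arity = arity, op = op, feat = feat, const = const,
       n_fun = nf, n_features = n_features, feature_names = feature_names,
       fun_ids = seq_len(nf),
       term_ids = nf + seq_len(n_features + length(constants)),
       all_ids = seq_along(token),
       u = max(function_set$arity),
       Nc = length(token))
}

#' Engine and chromosome configuration
#'
#' Bundles the GEP alphabet (function set \{+, -, *, /, Sqrt, IF\}, the
#' dataset's feature terminals, and constant terminals) with the structural
#' and evolutionary parameters. Defaults follow the full-scale study
#' settings: total chromosome length 100 (head 33 with maximum arity 3),
#' population 1000, 1000 generations per rule, mutation 0.02, one- and
#' two-point crossover 0.4 each, archive replacement probability 0.8 and
#' transfer interval 10.
#'
#' @param n_features Number of feature columns in the training data.
#' @param feature_names Optional character vector of feature names.
#' @param head_length Head length \code{h}; tail length follows from the
#'   maximum arity of the function set.
#' @param pop_size Subpopulation size per binary task.
#' @param generations_per_rule Evolution budget spent on each covering rule.
#' @param p_mut Per-position mutation probability.
#' @param p_x1,p_x2 One-point and two-point crossover probabilities
#'   (must sum to at most 1).
#' @param arp Archive replacement probability.
#' @param delta Transfer interval in generations; transfer fires when the
#'   generation counter is divisible by \code{delta}. May be \code{Inf}.
#' @param operator Base variation operator, \code{"GA"} or \code{"DE"}.
#' @param transfer Knowledge-transfer mode: \code{"none"}, \code{"GA"}
#'   (crossover against an archive member), \code{"DE1"} (DE donors from
#'   the archive) or \code{"DE2"} (DE1 plus the archive's symbol-frequency
#'   record).
#' @param archive_capacity Archive size; must be strictly smaller than
#'   \code{pop_size}. Defaults to \code{max(3, pop_size %/% 5)}.
#' @param constants Numeric constant terminals.
#' @return A list of class \code{"emcgep_config"}.
#' @export
emcgep_config <- function(n_features, feature_names = NULL,
                          head_length = 33L, pop_size = 1000L,
                          generations_per_rule = 1000L,
                          p_mut = 0.02, p_x1 = 0.4, p_x2 = 0.4,
                          arp = 0.8, delta = 10,
                          operator = c("GA", "DE"),
                          transfer = c("none", "GA", "DE1", "DE2"),
                          archive_capacity = NULL,
                          constants = c(1, 2, 3, 5, 7)) {
  operator <- match.arg(operator)
  transfer <- match.arg(transfer)
  if (transfer == "GA" && operator != "GA")
    stop("crossover-based transfer requires operator = 'GA'", call. = FALSE)
  if (transfer %in% c("DE1", "DE2") && operator != "DE")
    stop("DE-based transfer requires operator = 'DE'", call. = FALSE)
  stopifnot(p_mut >= 0, p_mut <= 1, p_x1 >= 0, p_x2 >= 0, p_x1 + p_x2 <= 1,
            arp >= 0, arp <= 1, delta >= 1, pop_size >= 2)
  alpha <- gep_alphabet(n_features, feature_names, constants)
  h <- as.integer(head_length)
  l <- gep_tail_length(h, alpha$u)
  if (is.null(archive_capacity)) archive_capacity <- max(3L, pop_size %/% 5L)
  if (archive_capacity >= pop_size)
    stop("archive_capacity must be strictly smaller than pop_size",
         call. = FALSE)
  structure(list(
    alpha = alpha, h = h, l = l, len = h + l,
    pop_size = as.integer(pop_size),
    generations_per_rule = as.integer(generations_per_rule),
    p_mut = p_mut, p_x1 = p_x1, p_x2 = p_x2,
    arp = arp, delta = delta,
    operator = operator, transfer = transfer,
    archive_capacity = as.integer(archive_capacity)
  ), class = "emcgep_config")
}

#' Draw a random chromosome
#'
#' Head positions are drawn uniformly from functions and terminals, tail
#' positions uniformly from terminals only.
#'
#' @param cfg An \code{\link{emcgep_config}}.
#' @return Integer vector of symbol ids, length \code{h + l}.
#' @export
gep_random_chromosome <- function(cfg) {
  a <- cfg$alpha
  c(a$all_ids[sample.int(length(a$all_ids), cfg$h, replace = TRUE)],
    a$term_ids[sample.int(length(a$term_ids), cfg$l, replace = TRUE)])
}

# Check the structural invariants; used by tests and on deserialization.
gep_validate <- function(chrom, cfg) {
  if (length(chrom) != cfg$len)
    stop("chromosome length must be h + l = ", cfg$len, call. = FALSE)
  if (cfg$l != gep_tail_length(cfg$h, cfg$alpha$u))
    stop("tail length violates l = h(u-1)+1", call. = FALSE)
  tail_ids <- chrom[(cfg$h + 1L):cfg$len]
  if (any(cfg$alpha$arity[tail_ids] != 0L))
    stop("tail positions must hold terminals", call. = FALSE)
  invisible(TRUE)
}

#' Decode a chromosome breadth-first into an expression tree
#'
#' Symbols are read left to right and attached level by level: each
#' function node claims the next \code{arity} unread positions as its
#' children, queue-style. The head/tail constraint guarantees the tree
#' completes within the string; trailing unused symbols are ignored.
#'
#' @param chrom Integer chromosome.
#' @param cfg An \code{\link{emcgep_config}}.
#' @return A list of class \code{"gep_tree"} with elements \code{sym}
#'   (consumed symbol ids, in consumption order), \code{arity},
#'   \code{child_start} (index of each node's first child within
#'   \code{sym}) and \code{valid_length}, the number of chromosome
#'   positions consumed.
#' @export
gep_decode <- function(chrom, cfg) {
  ar <- cfg$alpha$arity[chrom]
  # open slot count after reading i symbols is 1 + sum(arity) - i;
  # the tree is complete at the first i where it hits zero
  vl <- match(-1L, cumsum(ar - 1L))
  if (is.na(vl))
    stop("chromosome does not decode to a complete tree", call. = FALSE)
  idx <- seq_len(vl)
  ar <- ar[idx]
  structure(list(
    sym = chrom[idx], arity = ar,
    child_start = 2L + c(0L, cumsum(ar))[idx],
    valid_length = vl
  ), class = "gep_tree")
}

#' Valid length of a chromosome
#'
#' Number of string positions consumed during breadth-first decoding; the
#' size term of the rule in the description-length criterion.
#'
#' @inheritParams gep_decode
#' @return A positive integer, at most \code{h + l}.
#' @export
gep_valid_length <- function(chrom, cfg) {
  vl <- match(-1L, cumsum(cfg$alpha$arity[chrom] - 1L))
  if (is.na(vl))
    stop("chromosome does not decode to a complete tree", call. = FALSE)
  vl
}

GEP_CLAMP <- 1e150
GEP_DIV_EPS <- 1e-9

#' Evaluate an expression tree on samples
#'
#' Bottom-up evaluation with protected operators: division returns 1 when
#' the denominator magnitude is below 1e-9, \code{Sqrt(x)} is
#' \code{sqrt(abs(x))}, \code{IF(a, b, c)} yields \code{b} where
#' \code{a > 0} and \code{c} otherwise, and every intermediate value is
#' clamped to +/- 1e150, so the output is always finite on finite inputs.
#'
#' @param tree A \code{"gep_tree"} from \code{\link{gep_decode}}, or an
#'   integer chromosome (decoded on the fly).
#' @param X Numeric matrix (samples in rows) or a single feature vector.
#' @param cfg An \code{\link{emcgep_config}}.
#' @return Numeric vector of one output per sample.
#' @export
gep_evaluate <- function(tree, X, cfg) {
  if (!inherits(tree, "gep_tree")) tree <- gep_decode(tree, cfg)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) < cfg$alpha$n_features)
    stop("input has ", ncol(X), " features; alphabet expects ",
         cfg$alpha$n_features, call. = FALSE)
  a <- cfg$alpha
  n <- nrow(X)
  vals <- vector("list", tree$valid_length)
  for (i in rev(seq_len(tree$valid_length))) {
    id <- tree$sym[i]
    if (tree$arity[i] == 0L) {
      f <- a$feat[id]
      vals[[i]] <- if (f > 0L) X[, f] else rep.int(a$const[id], n)
    } else {
      s <- tree$child_start[i]
      v <- switch(a$op[id],
        vals[[s]] + vals[[s + 1L]],                     # +
        vals[[s]] - vals[[s + 1L]],                     # -
        vals[[s]] * vals[[s + 1L]],                     # *
        {                                               # protected /
          den <- vals[[s + 1L]]
          r <- vals[[s]] / den
          r[abs(den) < GEP_DIV_EPS] <- 1
          r
        },
        sqrt(abs(vals[[s]])),                           # protected Sqrt
        {                                               # IF(a, b, c)
          r <- vals[[s + 2L]]
          sel <- vals[[s]] > 0
          r[sel] <- vals[[s + 1L]][sel]
          r
        })
      vals[[i]] <- pmin.int(pmax.int(v, -GEP_CLAMP), GEP_CLAMP)
    }
  }
  vals[[1L]]
}

#' Chromosome/token-string conversion
#'
#' Chromosomes serialize to space-separated token strings: function names,
#' features as \code{x<i>} (0-based), constants as literals.
#'
#' @param chrom Integer chromosome.
#' @param cfg An \code{\link{emcgep_config}}.
#' @return A single string.
#' @export
chromosome_to_tokens <- function(chrom, cfg) {
  paste(cfg$alpha$token[chrom], collapse = " ")
}

#' @rdname chromosome_to_tokens
#' @param tokens A token string or character vector of tokens.
#' @param pad If TRUE, a token prefix shorter than \code{h + l} is padded
#'   to full length with the first constant terminal (useful to embed a
#'   hand-written tree in a structurally valid chromosome).
#' @export
tokens_to_chromosome <- function(tokens, cfg, pad = FALSE) {
  if (length(tokens) == 1L && grepl(" ", tokens))
    tokens <- strsplit(trimws(tokens), "\\s+")[[1]]
  ids <- match(tokens, cfg$alpha$token)
  if (anyNA(ids))
    stop("unknown token(s): ", paste(tokens[is.na(ids)], collapse = ", "),
         call. = FALSE)
  if (pad && length(ids) < cfg$len) {
    filler <- cfg$alpha$term_ids[cfg$alpha$n_features + 1L]
    if (is.na(filler)) filler <- cfg$alpha$term_ids[1L]
    ids <- c(ids, rep.int(filler, cfg$len - length(ids)))
  }
  ids <- as.integer(ids)
  gep_validate(ids, cfg)
  ids
}

#' @export
format.gep_tree <- function(x, cfg, ...) {
  fmt <- function(i) {
    tok <- cfg$alpha$token[x$sym[i]]
    if (x$arity[i] == 0L) return(tok)
    kids <- vapply(seq_len(x$arity[i]) - 1L,
                   function(j) fmt(x$child_start[i] + j), character(1))
    paste0(tok, "(", paste(kids, collapse = ", "), ")")
  }
  fmt(1L)
}
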