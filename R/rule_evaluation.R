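# Binary rule semantics, distribution-corrected precision, the covering
# fitness, and MDL description-length terms.

#' Does a rule cover samples?
#'
#' A rule covers a sample iff its GEP output is strictly positive;
#' an output of exactly zero does not cover.
#'
#' @param rule A \code{"gep_tree"} or integer chromosome.
#' @param X Numeric matrix of samples (rows) or a single feature vector.
#' @param cfg An \code{\link{emcgep_config}}.
#' @return Logical vector, one entry per sample.
#' @export
rule_covers <- function(rule, X, cfg) {
  gep_evaluate(rule, X, cfg) > 0
}

#' Contingency counts of a rule on a binary task
#'
#' TP/FN are counted over the supplied (possibly shrunken) positive set,
#' FP/TN over the negatives. \code{P} and \code{N} are the original task
#' totals, which the covering loop keeps fixed while the evaluated
#' positive set shrinks, so \code{TP + FN <= P}.
#'
#' @param rule A \code{"gep_tree"} or chromosome.
#' @param X_pos,X_neg Matrices of current positive / negative samples.
#' @param P,N Original totals of positives and negatives in the task's
#'   training set. Default to the supplied set sizes.
#' @param cfg An \code{\link{emcgep_config}}.
#' @return A list of class \code{"emcgep_counts"} with fields
#'   \code{TP, FP, TN, FN, P, N}.
#' @export
rule_contingency <- function(rule, X_pos, X_neg, cfg,
                             P = nrow(X_pos), N = nrow(X_neg)) {
  if (is.null(dim(X_pos))) X_pos <- matrix(X_pos, nrow = 1L)
  if (is.null(dim(X_neg)) && length(X_neg)) X_neg <- matrix(X_neg, nrow = 1L)
  if (NROW(X_neg) == 0L)
    stop("negative set is empty: N would be zero", call. = FALSE)
  if (!inherits(rule, "gep_tree")) rule <- gep_decode(rule, cfg)
  cov_p <- if (nrow(X_pos)) rule_covers(rule, X_pos, cfg) else logical(0)
  cov_n <- rule_covers(rule, X_neg, cfg)
  counts(TP = sum(cov_p), FN = sum(!cov_p),
         FP = sum(cov_n), TN = sum(!cov_n), P = P, N = N)
}

counts <- function(TP, FP, TN, FN, P, N) {
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN, P = P, N = N),
            class = "emcgep_counts")
}

#' Distribution-corrected precision
#'
#' \code{(TP/(TP+FP) - P/(P+N)) * (P+N)/N}: the raw precision of the rule,
#' centred at the task's positive base rate and rescaled so that a perfect
#' rule scores exactly 1 and a chance-level rule scores 0. May be negative
#' for rules worse than chance. When the rule predicts nothing positive
#' (\code{TP + FP = 0}) the raw-precision term is taken as 0, giving
#' \code{-P/N}, continuous with the worse-than-chance branch.
#'
#' @param c An \code{"emcgep_counts"} object.
#' @return Precision (unbounded below, at most 1).
#' @export
rule_precision <- function(c) {
  if (c$N < 1) stop("precision undefined for N = 0", call. = FALSE)
  raw <- if (c$TP + c$FP == 0) 0 else c$TP / (c$TP + c$FP)
  (raw - c$P / (c$P + c$N)) * (c$P + c$N) / c$N
}

#' Covering fitness of a rule
#'
#' \code{Pre * exp(Rec - 1)} when the corrected precision \code{Pre} is
#' non-negative, else 0, with recall \code{Rec = TP/P}. Maximised during
#' rule learning.
#'
#' @param c An \code{"emcgep_counts"} object.
#' @return Fitness in \code{[0, 1]} for counts with \code{Pre <= 1}.
#' @export
rule_fitness <- function(c) {
  if (c$P < 1) stop("fitness undefined for P = 0", call. = FALSE)
  pre <- rule_precision(c)
  if (pre < 0) 0 else pre * exp(c$TP / c$P - 1)
}

#' Exception coding length (bits)
#'
#' \code{log2 C(TP+FP, FP) + log2 C(TN+FN, FN)}: bits to single out the
#' false positives among the samples the rule set predicts positive and
#' the false negatives among those predicted negative. Computed via
#' log-gamma so large counts do not overflow.
#'
#' @param c An \code{"emcgep_counts"} object.
#' @return Non-negative bits.
#' @export
mdl_l_exception <- function(c) {
  (lchoose(c$TP + c$FP, c$FP) + lchoose(c$TN + c$FN, c$FN)) / log(2)
}

#' Theory coding length (bits)
#'
#' \code{log2(Nc) * sum(L(R_i))} where \code{Nc} is the number of distinct
#' symbols available to GEP and \code{L(R_i)} the valid length of rule i.
#'
#' @param valid_lengths Integer vector of rule valid lengths (may be empty).
#' @param Nc Alphabet size, at least 2.
#' @return Non-negative bits.
#' @export
mdl_l_theory <- function(valid_lengths, Nc) {
  if (Nc < 2) stop("Nc must be >= 2", call. = FALSE)
  if (length(valid_lengths) == 0L) return(0)
  if (any(valid_lengths < 1)) stop("valid lengths must be positive",
                                   call. = FALSE)
  log2(Nc) * sum(valid_lengths)
}

#' Description length of a rule set
#'
#' The pruning criterion \code{0.5 * L_theory + L_exception}; covering
#' stops as soon as adding the newly learnt rule no longer decreases it.
#'
#' @param l_theory,l_exception Bits, both non-negative.
#' @return \code{0.5 * l_theory + l_exception}.
#' @export
mdl_description_length <- function(l_theory, l_exception) {
  0.5 * l_theory + l_exception
}
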