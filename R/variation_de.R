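# Discrete DE/current-to-best/1 operator for GEP strings: symbol
# mismatches between donors induce a per-position mutation probability;
# replacements are drawn from a smoothed symbol-frequency record.

#' Symbol matching operator
#'
#' Returns 1 where two symbols differ and 0 where they match; the discrete
#' analogue of a DE difference vector. Vectorised over positions.
#'
#' @param a,b Symbol ids (or tokens); equal-length vectors.
#' @return Integer 0/1 vector.
#' @export
de_psi <- function(a, b) {
  as.integer(a != b)
}

#' Per-position mutation probability
#'
#' \code{phi = 1 - (1 - F * psi(xbest, xi)) * (1 - F * psi(xr1, xr2))}:
#' a position is under mutation pressure when the individual disagrees
#' with the best donor or the two random donors disagree with each other,
#' scaled by the factor \code{F}.
#'
#' @param F Scale factor in \code{[0, 1]}.
#' @param xbest,xi,xr1,xr2 Donor symbols at the position (vectorised).
#' @return Probabilities in \code{[0, 1]}.
#' @export
de_mutation_prob <- function(F, xbest, xi, xr1, xr2) {
  stopifnot(F >= 0, F <= 1)
  1 - (1 - F * de_psi(xbest, xi)) * (1 - F * de_psi(xr1, xr2))
}

#' Symbol-frequency record of a population or archive
#'
#' Counts every symbol occurrence, bucketed by position kind (head or
#' tail), then applies add-one smoothing over the legal alphabet of each
#' kind so no symbol's sampling weight is ever zero. Tail weights are zero
#' for function symbols.
#'
#' @param source A population/archive (list with a \code{chrom} matrix) or
#'   a chromosome matrix.
#' @param cfg An \code{\link{emcgep_config}}.
#' @return List with raw counts (\code{head}, \code{tail}) and smoothed
#'   sampling weights (\code{w_head}, \code{w_tail}) over symbol ids.
#' @export
de_frequency_record <- function(source, cfg) {
  mat <- if (is.list(source)) source$chrom else source
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  if (nrow(mat) == 0L)
    stop("cannot build a frequency record from an empty source",
         call. = FALSE)
  nsym <- cfg$alpha$Nc
  head_raw <- tabulate(mat[, seq_len(cfg$h)], nbins = nsym)
  tail_raw <- tabulate(mat[, (cfg$h + 1L):cfg$len], nbins = nsym)
  w_head <- head_raw + 1
  w_tail <- numeric(nsym)
  w_tail[cfg$alpha$term_ids] <- tail_raw[cfg$alpha$term_ids] + 1
  list(head = head_raw, tail = tail_raw, w_head = w_head, w_tail = w_tail)
}

#' Frequency-based symbol sampling
#'
#' Draws symbol ids proportional to the smoothed counts of the record;
#' tail draws only ever yield terminals.
#'
#' @param freq A record from \code{\link{de_frequency_record}}.
#' @param kind \code{"head"} or \code{"tail"}.
#' @param n Number of draws.
#' @return Integer vector of symbol ids.
#' @export
de_sample_symbol <- function(freq, kind = c("head", "tail"), n = 1L) {
  kind <- match.arg(kind)
  w <- if (kind == "head") freq$w_head else freq$w_tail
  sample.int(length(w), n, replace = TRUE, prob = w)
}

# Shared inner loop. donor = NULL means self evolution (best/r1/r2 from
# the evolving population itself); otherwise all three come from `donor`.
de_step <- function(pop, cfg, eval_fn, freq, donor = NULL) {
  n <- nrow(pop$chrom)
  if (n < 4L)
    stop("DE needs a population of at least 4", call. = FALSE)
  self <- is.null(donor)
  if (!self) {
    db <- order(-donor$fit, donor$vl)[1L]
    best_chrom <- donor$chrom[db, ]
    nd <- nrow(donor$chrom)
  } else {
    best_chrom <- pop$chrom[best_index(pop), ]
  }
  pos <- seq_len(cfg$len)
  is_head <- pos <= cfg$h
  for (i in seq_len(n)) {
    F  <- stats::runif(1L)
    CR <- stats::runif(1L)
    k  <- sample.int(cfg$len, 1L)
    if (self) {
      cand <- seq_len(n)[-i]
      rr <- cand[sample.int(n - 1L, 2L)]
      r1 <- pop$chrom[rr[1L], ]; r2 <- pop$chrom[rr[2L], ]
    } else {
      rr <- sample.int(nd, 2L)
      r1 <- donor$chrom[rr[1L], ]; r2 <- donor$chrom[rr[2L], ]
    }
    x <- pop$chrom[i, ]
    phi <- de_mutation_prob(F, best_chrom, x, r1, r2)
    mask <- (stats::runif(cfg$len) < CR | pos == k) &
      stats::runif(cfg$len) < phi
    if (!any(mask)) next
    u <- x
    mh <- mask & is_head
    mt <- mask & !is_head
    if (any(mh)) u[mh] <- de_sample_symbol(freq, "head", sum(mh))
    if (any(mt)) u[mt] <- de_sample_symbol(freq, "tail", sum(mt))
    ev <- eval_fn(matrix(u, nrow = 1L))
    if (ev$fit[1L] >= pop$fit[i]) {   # maximisation; ties allow drift
      pop$chrom[i, ] <- u
      pop$fit[i] <- ev$fit[1L]
      pop$vl[i] <- ev$vl[1L]
    }
  }
  pop
}

#' One DE generation (self evolution)
#'
#' For each individual, scale factor \code{F}, replacement probability
#' \code{CR} and a mandatory index \code{k} are drawn uniformly; donors
#' are the population's best and two distinct random members. A position
#' is replaced by a frequency-record draw when
#' \code{(rand < CR or j == k) and rand < phi}; the trial replaces the
#' individual iff its fitness is not worse.
#'
#' @param pop Evaluated population (size at least 4).
#' @param cfg An \code{\link{emcgep_config}}.
#' @param eval_fn Function taking a chromosome matrix and returning
#'   \code{list(fit, vl)}.
#' @param freq Optional frequency record; built from \code{pop} when
#'   \code{NULL}.
#' @return The next population.
#' @export
de_generation <- function(pop, cfg, eval_fn, freq = NULL) {
  if (is.null(freq)) freq <- de_frequency_record(pop, cfg)
  de_step(pop, cfg, eval_fn, freq)
}

#' One DE transfer generation
#'
#' As \code{\link{de_generation}}, but the best donor and both random
#' donors come from the source archive (the individual itself still from
#' the target population). Variant \code{"DE1"} keeps the population's own
#' frequency record for replacement sampling; \code{"DE2"} additionally
#' uses the archive's record. Archives with fewer than 3 members fall
#' back to self evolution with a warning.
#'
#' @inheritParams de_generation
#' @param archive Source archive.
#' @param variant \code{"DE1"} or \code{"DE2"}.
#' @return The next population.
#' @export
de_transfer_generation <- function(pop, archive, variant = c("DE1", "DE2"),
                                   cfg, eval_fn) {
  variant <- match.arg(variant)
  if (nrow(archive$chrom) < 3L) {
    warning("source archive has fewer than 3 members: ",
            "falling back to self evolution", call. = FALSE)
    return(de_generation(pop, cfg, eval_fn))
  }
  freq <- if (variant == "DE2") de_frequency_record(archive, cfg)
          else de_frequency_record(pop, cfg)
  de_step(pop, cfg, eval_fn, freq, donor = archive)
}
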