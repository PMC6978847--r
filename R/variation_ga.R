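# Canonical GEP variation: per-position mutation, one- and two-point
# crossover, tournament survivor selection, and the crossover-based
# knowledge-transfer generation (parent 2 drawn from a source archive).

# Populations are lists: chrom (pop x len integer matrix), fit, vl.
new_population <- function(chrom, eval_fn) {
  ev <- eval_fn(chrom)
  list(chrom = chrom, fit = ev$fit, vl = ev$vl)
}

# Rank individuals: fitness desc, then shorter valid length (parsimony),
# then earlier index. Used for elitism, sorting and tie-breaks.
pop_order <- function(pop) order(-pop$fit, pop$vl, seq_along(pop$fit))

best_index <- function(pop) pop_order(pop)[1L]

# Binary tournament over a (possibly merged) pool.
tournament_pick <- function(fit, vl) {
  n <- length(fit)
  ij <- if (n >= 2L) sample.int(n, 2L) else c(1L, 1L)
  i <- ij[1L]; j <- ij[2L]
  if (fit[i] > fit[j]) return(i)
  if (fit[j] > fit[i]) return(j)
  if (vl[i] < vl[j]) i else if (vl[j] < vl[i]) j else min(i, j)
}

#' Mutate a chromosome
#'
#' Each position is independently resampled with probability \code{p_mut};
#' head positions resample from functions and terminals, tail positions
#' from terminals only, so the head/tail structure is preserved.
#'
#' @param chrom Integer chromosome.
#' @param cfg An \code{\link{emcgep_config}}.
#' @param p_mut Per-position mutation probability (default from \code{cfg}).
#' @return A mutated chromosome of identical length.
#' @export
ga_mutate <- function(chrom, cfg, p_mut = cfg$p_mut) {
  mask <- stats::runif(cfg$len) < p_mut
  if (any(mask)) {
    a <- cfg$alpha
    head <- seq_along(chrom) <= cfg$h
    mh <- mask & head
    mt <- mask & !head
    if (any(mh))
      chrom[mh] <- a$all_ids[sample.int(length(a$all_ids), sum(mh),
                                        replace = TRUE)]
    if (any(mt))
      chrom[mt] <- a$term_ids[sample.int(length(a$term_ids), sum(mt),
                                         replace = TRUE)]
  }
  chrom
}

#' One-point crossover
#'
#' The cut index \code{k} is uniform in \code{[1, h+l-1]}; offspring swap
#' suffixes after position \code{k}. Because the swap is position-aligned
#' the head/tail typing of every position is preserved. The leading
#' segment carries the breadth-first skeleton of the donor's expression
#' tree, which is the transferable unit in crossover-based transfer.
#'
#' @param a,b Parent chromosomes of identical structure.
#' @param k Optional cut index; drawn uniformly when \code{NULL}.
#' @return List of two offspring chromosomes.
#' @export
ga_crossover_one_point <- function(a, b, k = NULL) {
  len <- length(a)
  if (length(b) != len)
    stop("parents must share the same chromosome structure", call. = FALSE)
  if (is.null(k)) k <- sample.int(len - 1L, 1L)
  stopifnot(k >= 1L, k <= len - 1L)
  tail_idx <- (k + 1L):len
  c1 <- a; c1[tail_idx] <- b[tail_idx]
  c2 <- b; c2[tail_idx] <- a[tail_idx]
  list(c1, c2)
}

#' Two-point crossover
#'
#' Two cut indices \code{0 <= k1 <= k2 <= h+l} are drawn; the middle
#' segments (positions \code{k1+1 .. k2}) are exchanged, which can cut an
#' intermediate section out of the donor string.
#'
#' @param a,b Parent chromosomes of identical structure.
#' @param k1,k2 Optional cut indices; drawn uniformly when \code{NULL}.
#' @return List of two offspring chromosomes.
#' @export
ga_crossover_two_point <- function(a, b, k1 = NULL, k2 = NULL) {
  len <- length(a)
  if (length(b) != len)
    stop("parents must share the same chromosome structure", call. = FALSE)
  if (is.null(k1) || is.null(k2)) {
    ks <- sort(sample.int(len + 1L, 2L, replace = TRUE) - 1L)
    k1 <- ks[1L]; k2 <- ks[2L]
  }
  stopifnot(k1 >= 0L, k2 >= k1, k2 <= len)
  if (k1 == k2) return(list(a, b))
  mid <- (k1 + 1L):k2
  c1 <- a; c1[mid] <- b[mid]
  c2 <- b; c2[mid] <- a[mid]
  list(c1, c2)
}

#' Survivor selection
#'
#' Binary tournaments over the merged parent + offspring pool, with a
#' one-elite guarantee: the single best individual of the pool (ties
#' broken by shorter valid length, then earlier index) always survives.
#' Output size equals the parent population size.
#'
#' @param parents,offspring Evaluated populations of equal size.
#' @return A population of the parents' size.
#' @export
ga_select_survivors <- function(parents, offspring) {
  if (anyNA(parents$fit) || anyNA(offspring$fit))
    stop("all individuals must be evaluated before selection", call. = FALSE)
  pool <- list(chrom = rbind(parents$chrom, offspring$chrom),
               fit = c(parents$fit, offspring$fit),
               vl = c(parents$vl, offspring$vl))
  n_out <- nrow(parents$chrom)
  keep <- integer(n_out)
  keep[1L] <- best_index(pool)
  for (i in seq_len(n_out - 1L))
    keep[i + 1L] <- tournament_pick(pool$fit, pool$vl)
  list(chrom = pool$chrom[keep, , drop = FALSE],
       fit = pool$fit[keep], vl = pool$vl[keep])
}

#' One GA generation, with optional archive-based transfer
#'
#' Offspring are produced in pairs: parent 1 by binary tournament from the
#' population and parent 2 likewise, except in a transfer generation where
#' parent 2 is drawn uniformly from the source \code{archive}. Each pair
#' undergoes one-point crossover with probability \code{p_x1}, two-point
#' with probability \code{p_x2}, and is cloned otherwise; mutation is then
#' applied to every offspring; survivors are selected from the merged
#' pool by \code{\link{ga_select_survivors}}.
#'
#' @param pop Evaluated population.
#' @param cfg An \code{\link{emcgep_config}}.
#' @param eval_fn Function taking a chromosome matrix and returning
#'   \code{list(fit, vl)}.
#' @param archive Optional source archive for transfer; an empty archive
#'   falls back to self evolution with a warning.
#' @return The next population.
#' @export
ga_generation <- function(pop, cfg, eval_fn, archive = NULL) {
  if (!is.null(archive) && nrow(archive$chrom) == 0L) {
    warning("empty source archive: falling back to self evolution",
            call. = FALSE)
    archive <- NULL
  }
  n <- nrow(pop$chrom)
  off <- matrix(0L, n, cfg$len)
  i <- 1L
  while (i <= n) {
    p1 <- pop$chrom[tournament_pick(pop$fit, pop$vl), ]
    p2 <- if (is.null(archive)) {
      pop$chrom[tournament_pick(pop$fit, pop$vl), ]
    } else {
      archive$chrom[sample.int(nrow(archive$chrom), 1L), ]
    }
    r <- stats::runif(1L)
    pair <- if (r < cfg$p_x1) {
      ga_crossover_one_point(p1, p2)
    } else if (r < cfg$p_x1 + cfg$p_x2) {
      ga_crossover_two_point(p1, p2)
    } else {
      list(p1, p2)
    }
    off[i, ] <- ga_mutate(pair[[1L]], cfg)
    if (i + 1L <= n) off[i + 1L, ] <- ga_mutate(pair[[2L]], cfg)
    i <- i + 2L
  }
  ga_select_survivors(pop, new_population(off, eval_fn))
}

#' Crossover-based knowledge transfer
#'
#' A transfer generation for the canonical operator: identical to
#' \code{\link{ga_generation}} except that the second crossover parent is
#' drawn uniformly from the source archive.
#'
#' @inheritParams ga_generation
#' @param archive Source archive (non-empty).
#' @return The next population.
#' @export
ga_transfer_crossover <- function(pop, archive, cfg, eval_fn) {
  ga_generation(pop, cfg, eval_fn, archive = archive)
}
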