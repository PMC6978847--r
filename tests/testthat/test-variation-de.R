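test_that("the matching operator and mutation probability follow the
           current-to-best form", {
  expect_identical(de_psi(3L, 3L), 0L)
  expect_identical(de_psi(3L, 5L), 1L)
  expect_identical(de_psi(c(1L, 2L), c(1L, 3L)), c(0L, 1L))
  # symmetry
  set.seed(4)
  a <- sample(1:10, 50, TRUE); b <- sample(1:10, 50, TRUE)
  expect_identical(de_psi(a, b), de_psi(b, a))

  expect_equal(de_mutation_prob(0.7, 1L, 1L, 2L, 2L), 0)
  expect_equal(de_mutation_prob(0.5, 1L, 2L, 1L, 2L), 0.75)
  expect_equal(de_mutation_prob(1, 1L, 2L, 3L, 3L), 1)
  for (F in c(0, 0.25, 0.5, 1)) {
    expect_equal(de_mutation_prob(F, 1L, 2L, 1L, 2L), 1 - (1 - F)^2)
    expect_equal(de_mutation_prob(F, 1L, 1L, 2L, 2L), 0)
  }
  # always a probability
  set.seed(6)
  for (i in 1:200) {
    F <- runif(1)
    phi <- de_mutation_prob(F, sample(3, 1), sample(3, 1),
                            sample(3, 1), sample(3, 1))
    expect_true(phi >= 0 && phi <= 1)
  }
})

test_that("frequency records count symbols by position kind with
           add-one smoothing", {
  cfg <- test_cfg(n_features = 3, head_length = 5)
  set.seed(10)
  ch <- gep_random_chromosome(cfg)
  mat <- rbind(ch, ch)
  fr <- de_frequency_record(mat, cfg)
  # conservation: raw counts sum to pop * positions of each kind
  expect_identical(sum(fr$head), 2L * cfg$h)
  expect_identical(sum(fr$tail), 2L * cfg$l)
  # identical chromosomes: counts proportional to the symbol multiset
  expect_identical(fr$head, 2L * tabulate(ch[1:cfg$h], cfg$alpha$Nc))
  # smoothing leaves no legal symbol at zero weight
  expect_true(all(fr$w_head > 0))
  expect_true(all(fr$w_tail[cfg$alpha$term_ids] > 0))
  expect_true(all(fr$w_tail[cfg$alpha$fun_ids] == 0))
  expect_error(de_frequency_record(matrix(0L, 0, cfg$len), cfg), "empty")

  # a large uniform population gives near-uniform head frequencies
  set.seed(12)
  big <- t(vapply(1:1000, function(i) gep_random_chromosome(cfg),
                  integer(cfg$len)))
  fr2 <- de_frequency_record(big, cfg)
  expected <- 1000 * cfg$h / cfg$alpha$Nc
  sigma <- sqrt(1000 * cfg$h * (1 / cfg$alpha$Nc) * (1 - 1 / cfg$alpha$Nc))
  expect_true(all(abs(fr2$head - expected) < 4 * sigma))
})

test_that("frequency-based sampling follows the record and never puts a
           function in the tail", {
  cfg <- test_cfg(n_features = 3, head_length = 5)
  # concentrated record: always the single nonzero symbol (smoothing off)
  fr <- list(w_head = numeric(cfg$alpha$Nc), w_tail = numeric(cfg$alpha$Nc))
  target <- cfg$alpha$term_ids[1]
  fr$w_head[target] <- 5
  fr$w_tail[target] <- 5
  set.seed(3)
  expect_true(all(de_sample_symbol(fr, "head", 100) == target))
  # uniform record: chi-squared test on draws
  fru <- list(w_head = rep(1, cfg$alpha$Nc),
              w_tail = as.numeric(seq_len(cfg$alpha$Nc) %in%
                                    cfg$alpha$term_ids))
  set.seed(31)
  draws <- de_sample_symbol(fru, "head", 10000)
  p <- chisq.test(tabulate(draws, cfg$alpha$Nc))$p.value
  expect_gt(p, 0.001)
  tail_draws <- de_sample_symbol(fru, "tail", 2000)
  expect_true(all(cfg$alpha$arity[tail_draws] == 0L))
})

test_that("DE generation honours its fixed points and elitist replacement", {
  cfg <- test_cfg(n_features = 3, head_length = 5, pop_size = 8)
  ev <- function(mat) {
    n <- nrow(mat)
    list(fit = rep(0, n),
         vl = vapply(seq_len(n),
                     function(i) gep_valid_length(mat[i, ], cfg),
                     integer(1)))
  }
  set.seed(40)
  ch <- gep_random_chromosome(cfg)
  clones <- new_population(matrix(rep(ch, each = 8), 8), ev)
  # identical population: all phi = 0, nothing can change
  out <- de_generation(clones, cfg, ev)
  expect_identical(out$chrom, clones$chrom)
  expect_error(de_generation(new_population(matrix(rep(ch, each = 3), 3),
                                            ev), cfg, ev),
               "at least 4")

  # fitness never decreases across a DE generation
  set.seed(41)
  mat <- t(vapply(1:12, function(i) gep_random_chromosome(cfg),
                  integer(cfg$len)))
  ev2 <- function(m) {
    n <- nrow(m)
    list(fit = vapply(seq_len(n), function(i) sum(m[i, ]) %% 7, numeric(1)),
         vl = vapply(seq_len(n),
                     function(i) gep_valid_length(m[i, ], cfg),
                     integer(1)))
  }
  pop <- new_population(mat, ev2)
  for (rep in 1:10) {
    before <- pop$fit
    pop <- de_generation(pop, cfg, ev2)
    expect_true(all(pop$fit >= before - 1e-12))
    apply(pop$chrom, 1, function(ch) gep_validate(ch, cfg))
  }
})

test_that("DE transfer draws donors and (for DE2) the record from the
           archive", {
  cfg <- test_cfg(n_features = 3, head_length = 5, pop_size = 8)
  ev <- function(mat) {
    n <- nrow(mat)
    list(fit = rep(1, n),  # every trial accepted: replacement always happens
         vl = vapply(seq_len(n),
                     function(i) gep_valid_length(mat[i, ], cfg),
                     integer(1)))
  }
  set.seed(50)
  pop <- new_population(t(vapply(1:8, function(i)
    gep_random_chromosome(cfg), integer(cfg$len))), ev)
  pop$fit <- rep(1, 8)
  # archive of identical chromosomes equal to each individual: phi = 0
  clones_pop <- new_population(matrix(rep(pop$chrom[1, ], each = 8), 8), ev)
  arch <- list(chrom = matrix(rep(pop$chrom[1, ], each = 3), 3),
               fit = rep(1, 3), vl = rep(clones_pop$vl[1], 3))
  out <- de_transfer_generation(clones_pop, arch, "DE1", cfg, ev)
  expect_identical(out$chrom, clones_pop$chrom)
  # under-sized archive falls back to self evolution
  small <- list(chrom = pop$chrom[1:2, ], fit = rep(0, 2), vl = pop$vl[1:2])
  expect_warning(de_transfer_generation(pop, small, "DE1", cfg, ev),
                 "fewer than 3")

  # DE2 with an archive record concentrated on one terminal: replaced
  # positions overwhelmingly carry it
  target <- cfg$alpha$term_ids[1]
  arch2 <- list(chrom = matrix(rep(target, 3 * cfg$len), 3),
                fit = rep(2, 3), vl = rep(1L, 3))
  set.seed(51)
  pop2 <- new_population(t(vapply(1:8, function(i)
    gep_random_chromosome(cfg), integer(cfg$len))), ev)
  pop2$fit <- rep(0, 8)   # trials (fit 1) always accepted
  out2 <- de_transfer_generation(pop2, arch2, "DE2", cfg, ev)
  replaced <- out2$chrom[out2$chrom != pop2$chrom]
  expect_gt(mean(replaced == target), 0.6)
})
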