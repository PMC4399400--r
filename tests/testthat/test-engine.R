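# Phase-level behaviour of the generation engine.

test_that("extinction empties cells at the configured probability", {
  cfg <- tiny_config()
  g <- init_grid(cfg)
  g0 <- apply_extinction(g, 0)
  expect_length(wfgrid:::occupied_cells(g0), 4)
  g1 <- apply_extinction(g, 1)
  expect_length(wfgrid:::occupied_cells(g1), 0)

  # binomial mean: 16 occupied cells, e = 0.3, repeated phase executions
  cfg16 <- build_config(list(grid_rows = 4, grid_cols = 4,
                             genome_length = 1000, n_generations = 1,
                             initial_size = 5, carrying_capacity = 5,
                             rng_seed = 3))
  base <- init_grid(cfg16)
  reps <- 3000
  counts <- integer(reps)
  g <- base
  for (i in seq_len(reps)) {
    g2 <- apply_extinction(g, 0.3)
    counts[i] <- length(attr(g2, "extinct"))
    g <- base
    g$rng <- g2$rng
  }
  se <- sqrt(16 * 0.3 * 0.7 / reps)
  expect_lt(abs(mean(counts) - 16 * 0.3), 3 * se)
})

test_that("migration conserves individuals and respects rates", {
  cfg <- tiny_config(initial_size = 25, migration_rate = 0)
  g <- init_grid(cfg)
  g2 <- apply_migration(g, cfg$migration)
  expect_equal(wfgrid:::pop_sizes(g2), wfgrid:::pop_sizes(g))

  cfg2 <- tiny_config(initial_size = 25, migration_rate = 0.5)
  g <- init_grid(cfg2)
  for (i in 1:20) {
    g <- apply_migration(g, cfg2$migration)
    expect_equal(sum(wfgrid:::pop_sizes(g)), 100)
    tr <- attr(g, "migration_trace")
    expect_true(all(tr$emigrants >= 0))
  }
})

test_that("migrants found new populations on empty cells", {
  cfg <- tiny_config(grid_rows = 1, grid_cols = 2,
                     initial_size = c(40, 0), migration_rate = 1)
  g <- init_grid(cfg)
  g2 <- apply_migration(g, cfg$migration)
  expect_equal(wfgrid:::pop_sizes(g2), c(0L, 40L))
})

test_that("explicit-matrix migration follows per-pair rates", {
  rm <- matrix(0, 4, 4)
  rm[1, 4] <- 0.5   # only flow: cell 1 -> cell 4
  cfg <- tiny_config(initial_size = c(100, 0, 0, 0),
                     carrying_capacity = 100,
                     migration_mode = "explicit_matrix",
                     migration_matrix = rm)
  base <- init_grid(cfg)
  reps <- 2000
  moved <- integer(reps)
  g <- base
  for (i in seq_len(reps)) {
    g2 <- apply_migration(g, cfg$migration)
    tr <- attr(g2, "migration_trace")
    expect_equal(sum(tr$immigrants[-4]), 0)
    moved[i] <- tr$emigrants[1]
    g <- base
    g$rng <- g2$rng
  }
  se <- sqrt(100 * 0.5 * 0.5 / reps)
  expect_lt(abs(mean(moved) - 50), 3 * se)
})

test_that("mutation adds unique positions at the Poisson rate", {
  cfg <- tiny_config(mutation_rate = 0)
  g <- init_grid(cfg)
  g2 <- apply_mutation(g, 0, cfg$selection)
  expect_equal(nrow(g2$loci), 0)

  # lambda = mu * g * N = 1e-4 * 100 * 50 = 0.5 per cell; positions unique
  # even on a short genome where collisions are frequent
  cfg2 <- tiny_config(grid_rows = 1, grid_cols = 1, genome_length = 100,
                      mutation_rate = 1e-4, initial_size = 50,
                      carrying_capacity = 50)
  g <- init_grid(cfg2)
  for (i in 1:60) g <- apply_mutation(g, cfg2$mutation_rate, cfg2$selection)
  expect_gt(nrow(g$loci), 5)
  expect_false(anyDuplicated(g$loci$position) > 0)
  expect_true(all(g$loci$position >= 0 & g$loci$position < 100))
  # every new site enters as exactly one derived copy
  expect_true(all(colSums(g$pops[[1]]$geno) >= 1))

  counts <- mutation_phase_draws(N = 100, mu = 1e-5, g = 1e4, reps = 20000,
                                 cells = 50, seed = 7)
  lam <- 1e-5 * 1e4 * 100
  se <- sqrt(lam / length(counts))
  expect_lt(abs(mean(counts) - lam), 3 * se)
})

test_that("selection coefficients follow the configured model", {
  expect_equal(draw_selection_coefficient(list(kind = "neutral"), 5),
               rep(0, 5))
  expect_equal(
    draw_selection_coefficient(list(kind = "fixed", fixed_s = 0.01), 3),
    rep(0.01, 3))
  set.seed(11)
  gm <- list(kind = "gamma", gamma_shape = 2, gamma_scale = 0.005,
             sign_negative = FALSE)
  draws <- draw_selection_coefficient(gm, 1e5)
  se <- sqrt(2 * 0.005^2 / 1e5)   # var of gamma = shape * scale^2
  expect_lt(abs(mean(draws) - 0.01), 3 * se)
  gm$sign_negative <- TRUE
  expect_true(all(draw_selection_coefficient(gm, 100) < 0))
  expect_true(all(draw_selection_coefficient(gm, 100) > -1))
})

test_that("growth targets follow the logistic equation with Allee term", {
  g <- init_grid(tiny_config(initial_size = 10, carrying_capacity = 100))
  # r deterministic 0: target = current size
  gr <- apply_growth(g, 100, 0, 0)
  expect_equal(gr$target, gr$n)
  # N = K: logistic equilibrium regardless of r
  gK <- init_grid(tiny_config(initial_size = 100, carrying_capacity = 100))
  grK <- apply_growth(gK, 100, 0.8, 0)
  expect_equal(grK$target, rep(100L, 4))
  # N < A: Allee decline (sign of N - A); r large enough that the negative
  # increment survives rounding
  grA <- apply_growth(g, 100, 8, 0, allee = 20)
  expect_true(all(grA$target < grA$n))
  # growth toward K from below without Allee
  grUp <- apply_growth(g, 100, 0.5, 0)
  expect_equal(grUp$target, rep(as.integer(round(10 + 0.5 * 10 * 0.9)), 4))
  # override replaces the computed target
  grO <- apply_growth(g, 100, 0.5, 0,
                      overrides = stats::setNames(55L, "1"))
  expect_equal(grO$target[grO$cell == 1], 55L)
  # strong decline clamps at zero
  grZ <- apply_growth(g, 100, -20, 0)
  expect_true(all(grZ$target >= 0))
})

test_that("fitness is multiplicative with genotype weights 1, 1+hs, 1+s", {
  geno <- matrix(c(0L, 1L, 2L, 2L,
                   0L, 0L, 0L, 2L), ncol = 2)
  w <- compute_fitness(geno, c(0.1, 0.2), ploidy = 2, h = 0.5)
  expect_equal(w, c(1, 1.05, 1.1, 1.1 * 1.2))
  expect_equal(compute_fitness(geno, c(0, 0), 2, 0.5), rep(1, 4))
  wh <- compute_fitness(matrix(c(0L, 1L), 2, 1), 0.3, ploidy = 1)
  expect_equal(wh, c(1, 1.3))
  expect_error(compute_fitness(matrix(2L, 1, 1), -1.5, 2, 0.5,
                               positions = 42L), "42")
})

test_that("reproduction keeps fixed alleles fixed and is a martingale", {
  geno_fixed <- matrix(2L, 20, 1)
  off <- apply_reproduction(geno_fixed, 30L, rep(1, 20), 2)
  expect_equal(dim(off), c(30, 1))
  expect_true(all(off == 2L))

  # neutral martingale: E[offspring copies] = parental copies
  set.seed(21)
  N <- 100
  geno <- matrix(0L, N, 1)
  geno[1:25, 1] <- 2L
  geno[26:75, 1] <- 1L   # 100 derived copies, p = 0.5
  reps <- 4000
  tot <- replicate(reps, sum(apply_reproduction(geno, N, rep(1, N), 2)))
  se <- sqrt(2 * N * 0.5 * 0.5 / reps)
  expect_lt(abs(mean(tot) - 100), 3 * se)

  # one haploid carrier with enormous advantage sweeps immediately
  ghap <- matrix(0L, 50, 1); ghap[7, 1] <- 1L
  w <- compute_fitness(ghap, 1e9, 1)
  offh <- apply_reproduction(ghap, 50L, w, 1)
  expect_true(all(offh == 1L))
})

test_that("reproduction matches the genotype-count law used by the
           single-locus samplers", {
  # engine offspring derived-copy moments vs the multinomial law with
  # transmission probability p* = (0.5 n1 w1 + n2 w2) / sum n_g w_g
  set.seed(31)
  N <- 60; n1 <- 20; n2 <- 10; s <- 0.3; h <- 0.5
  geno <- matrix(0L, N, 1)
  geno[seq_len(n1), 1] <- 1L
  geno[n1 + seq_len(n2), 1] <- 2L
  w <- compute_fitness(geno, s, 2, h)
  pstar <- (0.5 * n1 * (1 + h * s) + n2 * (1 + s)) /
    ((N - n1 - n2) + n1 * (1 + h * s) + n2 * (1 + s))
  reps <- 4000
  tot <- replicate(reps, sum(apply_reproduction(geno, N, w, 2)))
  se_mean <- sqrt(2 * N * pstar * (1 - pstar) / reps)
  expect_lt(abs(mean(tot) - 2 * N * pstar), 3 * se_mean)
  # variance of a Binomial(2N, p*) total
  expect_lt(abs(var(tot) - 2 * N * pstar * (1 - pstar)),
            4 * 2 * N * pstar * (1 - pstar) / sqrt(reps) * 2)
})

test_that("site bookkeeping drops lost sites and promotes fixed ones", {
  genos <- list(
    cbind(rep(0L, 4), rep(2L, 4), c(1L, 0L, 2L, 0L)),
    cbind(rep(0L, 3), rep(2L, 3), c(0L, 1L, 1L))
  )
  g <- manual_grid(genos, nrow = 1, ncol = 2)
  before <- allele_frequencies(g)
  g2 <- prune_and_promote_sites(g)
  expect_equal(nrow(g2$loci), 1)          # only the polymorphic site stays
  expect_equal(g2$loci$position, 2L)
  expect_equal(nrow(g2$fixed), 1)         # globally fixed site promoted
  expect_equal(g2$fixed$position, 1L)
  after <- allele_frequencies(g2)
  expect_equal(after$freq,
               before$freq[before$position == 2])
})

test_that("run_simulation honours trivial limits and stays deterministic", {
  cfg0 <- tiny_config(n_generations = 0)
  res0 <- run_simulation(cfg0)
  expect_equal(res0$state$generation, 0L)
  expect_equal(res0$state, init_grid(cfg0))

  # all rates zero: sizes constant, no sites ever
  cfgz <- tiny_config(n_generations = 15)
  resz <- run_simulation(cfgz)
  expect_equal(resz$status, "completed")
  expect_true(all(resz$trace$n_end == 10))
  expect_equal(nrow(resz$state$loci), 0)
  expect_equal(nrow(resz$state$fixed), 0)

  cfg <- tiny_config(mutation_rate = 1e-5, migration_rate = 0.1,
                     extinction_prob = 0.01, growth_rate_mean = 0.5,
                     growth_rate_var = 0.01, n_generations = 25,
                     rng_seed = 17)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$state, r2$state)
  expect_identical(r1$trace, r2$trace)
})

test_that("a fully extinct grid terminates early with partial trace", {
  cfg <- tiny_config(extinction_prob = 1, n_generations = 50)
  res <- run_simulation(cfg)
  expect_equal(res$status, "extinct")
  expect_equal(max(res$trace$generation), 1)
  expect_length(wfgrid:::occupied_cells(res$state), 0)
})

test_that("scheduled events change sizes and rates at their generation", {
  cfg <- tiny_config(
    grid_rows = 1, grid_cols = 2, initial_size = 100,
    carrying_capacity = 100, n_generations = 10,
    events = data.frame(
      generation = c(3, 5),
      kind = c("step_size_change", "set_migration"),
      row = c(1, NA), col = c(1, NA), value = c(50, 0.4)))
  res <- run_simulation(cfg)
  tr <- res$trace
  expect_equal(tr$n_end[tr$generation == 3 & tr$col == 1], 50)
  expect_equal(sum(tr$emigrants[tr$generation < 5]), 0)
  expect_gt(sum(tr$emigrants[tr$generation >= 5]), 0)
})

test_that("neutral reproduction is a martingale across whole generations", {
  # with a polymorphic starting SNP and no mutation/migration, the mean
  # frequency over replicate runs stays at its initial value
  freqs <- numeric(200)
  for (i in seq_along(freqs)) {
    cfg <- tiny_config(grid_rows = 1, grid_cols = 1, initial_size = 50,
                       carrying_capacity = 50, n_generations = 5,
                       init_snps = data.frame(position = 0, freq = 0.5,
                                              s = 0),
                       rng_seed = 1000 + i)
    res <- run_simulation(cfg)
    f <- allele_frequencies(res$state)
    freqs[i] <- if (nrow(f)) f$freq else
      if (nrow(res$state$fixed)) 1 else 0
  }
  # SE of the mean of 200 replicate final frequencies (var <= p(1-p))
  expect_lt(abs(mean(freqs) - 0.5), 3 * sqrt(0.25 * (1 + 5 / 50) / 200))
})
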