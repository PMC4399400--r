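# Summary statistics and their closed-form expectations.

test_that("allele frequencies count derived copies exactly", {
  # one copy in one of 100 diploids -> 1/200 there, 0 elsewhere
  g1 <- matrix(0L, 100, 1); g1[5, 1] <- 1L
  g2 <- matrix(0L, 100, 1)
  g <- manual_grid(list(g1, g2), nrow = 1, ncol = 2)
  f <- allele_frequencies(g)
  expect_equal(f$freq[f$col == 1], 1 / 200)
  expect_equal(f$freq[f$col == 2], 0)

  # 3 of 10 haploids -> 0.3
  gh <- manual_grid(list(matrix(c(rep(1L, 3), rep(0L, 7)), 10, 1)),
                    ploidy = 1)
  expect_equal(allele_frequencies(gh)$freq, 0.3)

  # a site at dosage ploidy everywhere reads 1.0 in every occupied cell
  gfix <- manual_grid(list(matrix(2L, 6, 1), matrix(2L, 9, 1)),
                      nrow = 1, ncol = 2)
  expect_equal(allele_frequencies(gfix)$freq, c(1, 1))
})

test_that("expected heterozygosity and its decay law", {
  expect_equal(expected_heterozygosity(c(0, 1)), c(0, 0))
  expect_equal(expected_heterozygosity(0.5), 0.5)
  expect_equal(expected_heterozygosity(c(0.2, 0.5), aggregate = "sum"),
               2 * 0.2 * 0.8 + 0.5)
  # frozen closed-form value: 0.5 * (1 - 1/200)^200
  expect_equal(theory_het_decay(0.5, 100, 200), 0.1834789, tolerance = 1e-6)
  # infinite-population limit: no decay
  expect_equal(theory_het_decay(0.5, 1e12, 500), 0.5, tolerance = 1e-6)
  expect_equal(theory_het_decay(0.3, 50, 0), 0.3)
})

test_that("Fst matches hand-computed components and stays in [0, 1]", {
  expect_equal(fst(matrix(c(0.3, 0.3), 1, 2)), 0)
  expect_equal(fst(matrix(c(1, 0), 1, 2)), 1)
  # p1 = 0.2, p2 = 0.8: H_S = 0.32, H_T = 0.5 -> 0.36
  expect_equal(fst(matrix(c(0.2, 0.8), 1, 2)), 0.36)
  expect_warning(v <- fst(matrix(0, 2, 2)), "undefined")
  expect_true(is.na(v))

  set.seed(13)
  for (i in 1:25) {
    fr <- matrix(runif(20), 10, 2)
    v <- fst(fr)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(fst(cbind(fr[, 1], fr[, 1])), 0)
  }
})

test_that("island-model expectations are consistent and monotone", {
  expect_equal(theory_island_fst(50, 0.02, 2), 1 / (1 + 16))
  vals <- sapply(c(0.25, 1, 4) / 50, function(m) theory_island_fst(50, m, 2))
  expect_true(all(diff(vals) < 0))
  # the exact two-deme recursion approaches the island formula as u -> 0
  for (nm in c(0.5, 1, 2)) {
    exact <- theory_two_deme_gst(50, nm / 50, 1e-9)
    expect_equal(exact, theory_island_fst(50, nm / 50, 2), tolerance = 0.06)
  }
})

test_that("fixation probability theory: neutral, Kimura, continuity", {
  expect_equal(theory_fixation_prob(50, 0), 0.01)
  expect_equal(theory_fixation_prob(10, 0, ploidy = 1), 0.1)
  expect_equal(theory_fixation_prob(500, 0.02), 0.03921056,
               tolerance = 1e-6)
  # s -> 0 recovers 1/(2N)
  expect_equal(theory_fixation_prob(100, 1e-10), 1 / 200,
               tolerance = 1e-4)
  # strong-selection regime approaches 2s
  expect_equal(theory_fixation_prob(5000, 0.05), 2 * 0.05, tolerance = 0.06)
  expect_equal(fixation_outcome(c(0.1, 0.7, 1)), "fixed")
  expect_equal(fixation_outcome(0), "lost")
  expect_equal(fixation_outcome(0.42), "segregating")
})

test_that("drift replicates are a martingale with the right variance", {
  set.seed(41)
  traj <- wf_drift_replicates(N = 50, p0 = 0.5, generations = 10,
                              reps = 4000)
  expect_equal(dim(traj), c(4000, 11))
  expect_true(all(traj[, 1] == 0.5))
  p10 <- traj[, 11]
  expect_lt(abs(mean(p10) - 0.5), 3 * sd(p10) / sqrt(4000))
  # Var(p_t) = p0(1-p0) (1 - (1-1/(2N))^t)
  vtheory <- 0.25 * (1 - (1 - 1 / 100)^10)
  expect_lt(abs(var(p10) - vtheory), 4 * vtheory / sqrt(4000) * 2)
})

test_that("full-engine fixation of single new mutations matches 1/(2N)", {
  # 800 replicate engine runs, N = 20 diploids: expect ~1/40 to fix
  N <- 20L
  reps <- 800
  fixed <- 0L
  for (i in seq_len(reps)) {
    cfg <- build_config(list(grid_rows = 1, grid_cols = 1,
                             genome_length = 1000, n_generations = 40,
                             initial_size = N, carrying_capacity = N,
                             rng_seed = 5000 + i))
    g <- init_grid(cfg)
    g$loci <- data.frame(position = 0L, origin_generation = 0L,
                         origin_row = 1L, origin_col = 1L, s = 0)
    g$pops[[1]]$geno <- matrix(c(1L, rep(0L, N - 1)), N, 1)
    repeat {
      res <- run_simulation(cfg, initial = list(state = g))
      g <- res$state
      if (nrow(g$loci) == 0) break
    }
    fixed <- fixed + nrow(g$fixed)
  }
  p <- 1 / (2 * N)
  se <- sqrt(p * (1 - p) / reps)
  expect_lt(abs(fixed / reps - p), 3 * se)
})

test_that("reduced fixation sampler agrees with theory for haploids too", {
  set.seed(51)
  res <- wf_fixation_replicates(N = 40, s = 0, ploidy = 1, reps = 8000)
  p <- 1 / 40
  expect_lt(abs(res$fraction_fixed - p), 3 * sqrt(p * (1 - p) / 8000))
  expect_equal(res$fixed + res$lost, 8000)
})
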