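# Observed summary statistics and their closed-form expectations.

#' Per-site, per-cell derived-allele frequencies
#'
#' @param grid A `wfgrid_state`.
#' @return Data frame with one row per segregating site per occupied cell:
#'   `generation`, `position`, `row`, `col`, `count` (derived copies), `n`
#'   (individuals) and `freq` = count / (ploidy * n).
#' @export
allele_frequencies <- function(grid) {
  occ <- occupied_cells(grid)
  S <- n_sites(grid)
  if (!length(occ) || S == 0L) {
    return(data.frame(generation = integer(), position = integer(),
                      row = integer(), col = integer(), count = integer(),
                      n = integer(), freq = numeric()))
  }
  out <- lapply(occ, function(i) {
    rc <- cell_rc(grid, i)
    cnt <- colSums(grid$pops[[i]]$geno)
    n <- nrow(grid$pops[[i]]$geno)
    data.frame(generation = grid$generation, position = grid$loci$position,
               row = rc[["row"]], col = rc[["col"]],
               count = as.integer(cnt), n = n,
               freq = cnt / (grid$ploidy * n))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sites x cells matrix of derived-allele frequencies
#'
#' @param grid A `wfgrid_state`.
#' @return Numeric matrix, one row per segregating site (named by position),
#'   one column per occupied cell (named `"row_col"`).
#' @export
allele_frequency_matrix <- function(grid) {
  occ <- occupied_cells(grid)
  S <- n_sites(grid)
  m <- matrix(numeric(0), S, length(occ))
  cn <- character(length(occ))
  for (k in seq_along(occ)) {
    i <- occ[k]
    rc <- cell_rc(grid, i)
    n <- nrow(grid$pops[[i]]$geno)
    m <- if (k == 1) matrix(0, S, length(occ)) else m
    if (S > 0) m[, k] <- colSums(grid$pops[[i]]$geno) / (grid$ploidy * n)
    cn[k] <- paste0(rc[["row"]], "_", rc[["col"]])
  }
  dimnames(m) <- list(as.character(grid$loci$position), cn)
  m
}

#' Expected heterozygosity of biallelic sites
#'
#' `H = 2 p (1 - p)` per site, optionally aggregated.
#'
#' @param p Vector (or matrix) of derived-allele frequencies.
#' @param aggregate `"none"` (per entry), `"mean"` or `"sum"` over entries.
#' @return Heterozygosities, aggregated as requested.
#' @export
expected_heterozygosity <- function(p, aggregate = c("none", "mean", "sum")) {
  aggregate <- match.arg(aggregate)
  h <- 2 * p * (1 - p)
  switch(aggregate, none = h, mean = mean(h), sum = sum(h))
}

#' Theoretical decay of expected heterozygosity under drift
#'
#' `H_t = H_0 (1 - 1/(ploidy * N))^t` for an isolated constant-size
#' population.
#'
#' @param H0 Initial expected heterozygosity.
#' @param N Population size (individuals).
#' @param t Generations (vectorised).
#' @param ploidy 1 or 2.
#' @return `H_t`.
#' @export
theory_het_decay <- function(H0, N, t, ploidy = 2) {
  stopifnot(N >= 1, all(t >= 0))
  H0 * (1 - 1 / (ploidy * N)) ^ t
}

#' Multi-site Fst (G_ST, ratio of sums)
#'
#' `Fst = (sum_l H_T(l) - sum_l mean H_S(l)) / sum_l H_T(l)` over sites,
#' with `H_S` the per-deme expected heterozygosity and `H_T` the expected
#' heterozygosity at the unweighted mean frequency.
#'
#' @param freqs Sites x demes matrix of derived-allele frequencies (for a
#'   grid, see [allele_frequency_matrix()]; select columns for a subset of
#'   cells).
#' @return Fst in \[0, 1\], or `NA` with a warning when `H_T` sums to zero
#'   (no variation, Fst undefined).
#' @export
fst <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) < 2) stop("Fst needs at least two demes")
  comp <- fst_components(freqs)
  if (comp[["ht"]] == 0) {
    warning("Fst undefined: no variation (H_T = 0)")
    return(NA_real_)
  }
  (comp[["ht"]] - comp[["hs"]]) / comp[["ht"]]
}

#' Summed Fst components (for pooling across samples)
#'
#' @param freqs Sites x demes frequency matrix.
#' @return Named vector `c(ht = sum H_T, hs = sum mean H_S)`; pooling these
#'   sums over replicate samples before taking the ratio gives a
#'   lower-variance multi-sample Fst.
#' @export
fst_components <- function(freqs) {
  freqs <- as.matrix(freqs)
  hs <- rowMeans(2 * freqs * (1 - freqs))
  pbar <- rowMeans(freqs)
  ht <- 2 * pbar * (1 - pbar)
  c(ht = sum(ht), hs = sum(hs))
}

#' Finite-island-model equilibrium Fst
#'
#' `Fst = 1 / (1 + 4 N m (d/(d-1))^2)` for `d` demes of `N` diploid
#' individuals exchanging migrants at per-individual rate `m`.
#'
#' @param N Deme size (individuals).
#' @param m Per-individual per-generation migration probability.
#' @param d Number of demes.
#' @return Expected equilibrium Fst.
#' @export
theory_island_fst <- function(N, m, d) {
  stopifnot(N >= 1, m >= 0, d >= 2)
  1 / (1 + 4 * N * m * (d / (d - 1))^2)
}

#' Exact two-deme equilibrium G_ST with mutation
#'
#' Stationary solution of the identity-by-descent recursions for two demes
#' of `N` diploids exchanging migrants at rate `m` with per-gene-copy
#' infinite-alleles mutation rate `u`: with `f0` (`f1`) the equilibrium
#' identity of two genes within (between) demes, the expected
#' heterozygosities are `E[H_S] = (1 - 1/(2N)) (1 - f0)` and
#' `E[H_T] = E[H_S]/2 + (1 - f1)/2`, and G_ST = 1 - E\[H_S\]/E\[H_T\].
#' Unlike [theory_island_fst()] this keeps finite-size and mutation terms,
#' so it is the sharper reference for simulated two-deme equilibria.
#'
#' @param N Deme size (diploid individuals).
#' @param m Per-individual migration probability.
#' @param u Per-gene-copy per-generation mutation rate.
#' @return Expected equilibrium G_ST.
#' @export
theory_two_deme_gst <- function(N, m, u) {
  c2 <- (1 - m)^2 + m^2   # pair in same deme: both parent genes same deme
  c1 <- 2 * m * (1 - m)   # pair in different demes: parents same deme
  v <- (1 - u)^2
  A <- matrix(c(v * c2 * (1 - 1 / (2 * N)) - 1, v * (1 - c2),
                v * c1 * (1 - 1 / (2 * N)),     v * (1 - c1) - 1),
              2, 2, byrow = TRUE)
  b <- c(-v * c2 / (2 * N), -v * c1 / (2 * N))
  f <- solve(A, b)
  EhS <- (1 - 1 / (2 * N)) * (1 - f[1])
  EhT <- 0.5 * EhS + 0.5 * (1 - f[2])
  1 - EhS / EhT
}

#' Classify the fate of a tracked site
#'
#' @param freq Global derived-allele frequency (final value, or a trajectory
#'   whose last value is used).
#' @return `"fixed"`, `"lost"` or `"segregating"`.
#' @export
fixation_outcome <- function(freq) {
  f <- freq[length(freq)]
  if (f >= 1) "fixed" else if (f <= 0) "lost" else "segregating"
}

#' Theoretical fixation probability of a single new mutation
#'
#' Neutral: `1/(ploidy * N)`. Selected (diploid, Kimura's diffusion
#' approximation for additive selection):
#' `(1 - exp(-2 s)) / (1 - exp(-4 N s))`, where `s` is the heterozygote
#' advantage — genotype fitnesses 1, `1 + s`, `1 + 2s`. In the engine's
#' `1 / 1 + h s' / 1 + s'` weights this corresponds to `s' = 2 s` with
#' `h = 0.5`.
#'
#' @param N Population size (individuals).
#' @param s Heterozygote selective advantage of the derived allele.
#' @param ploidy 1 or 2.
#' @return Fixation probability.
#' @export
theory_fixation_prob <- function(N, s = 0, ploidy = 2) {
  stopifnot(N >= 1)
  if (s == 0) return(1 / (ploidy * N))
  if (ploidy != 2) {
    stop("selected fixation probability implemented for diploids only")
  }
  (1 - exp(-2 * s)) / (1 - exp(-4 * N * s))
}

#' Single-locus Wright-Fisher fixation replicates
#'
#' Vectorised simulation of the fate of a single new mutation (one copy in
#' one individual) in an isolated population of constant size `N`, under the
#' same reproduction law as the engine: each offspring's two alleles are
#' independent Bernoulli draws with success probability equal to the
#' fitness-weighted transmission probability
#' `p* = (0.5 n_het w_het + n_hom w_hom) / sum(n_g w_g)`
#' (weights 1, 1+h*s, 1+s), so offspring genotype counts are multinomial.
#' This is the exact marginal law of [apply_reproduction()] for one unlinked
#' site; it simply tracks genotype counts instead of individuals, which lets
#' tens of thousands of replicates run as vector operations.
#'
#' @param N Population size (individuals).
#' @param s Selection coefficient (derived allele).
#' @param h Dominance coefficient (diploid only).
#' @param ploidy 1 or 2.
#' @param reps Number of replicate mutations.
#' @param max_generations Safety cap per replicate (default `1e6`).
#' @return List: `fixed` and `lost` counts, `fraction_fixed`, `reps`.
#' @export
wf_fixation_replicates <- function(N, s = 0, h = 0.5, ploidy = 2, reps,
                                   max_generations = 1e6) {
  stopifnot(N >= 1, reps >= 1, s > -1)
  if (ploidy == 2L) {
    n1 <- rep(1L, reps)  # heterozygote carriers
    n2 <- rep(0L, reps)  # derived homozygotes
    fixed <- 0L; lost <- 0L
    w1 <- 1 + h * s; w2 <- 1 + s
    gen <- 0L
    while (length(n1) && gen < max_generations) {
      gen <- gen + 1L
      n0 <- N - n1 - n2
      tot <- n0 + n1 * w1 + n2 * w2
      pstar <- (0.5 * n1 * w1 + n2 * w2) / tot
      n2new <- stats::rbinom(length(n1), N, pstar^2)
      phet <- ifelse(pstar < 1, 2 * pstar / (1 + pstar), 0)
      n1new <- stats::rbinom(length(n1), N - n2new, phet)
      copies <- n1new + 2L * n2new
      done_lost <- copies == 0L
      done_fixed <- copies == 2L * N
      lost <- lost + sum(done_lost)
      fixed <- fixed + sum(done_fixed)
      keep <- !(done_lost | done_fixed)
      n1 <- n1new[keep]; n2 <- n2new[keep]
    }
  } else {
    cc <- rep(1L, reps)
    fixed <- 0L; lost <- 0L
    gen <- 0L
    while (length(cc) && gen < max_generations) {
      gen <- gen + 1L
      p <- cc * (1 + s) / (cc * (1 + s) + (N - cc))
      cc <- stats::rbinom(length(cc), N, p)
      done_lost <- cc == 0L
      done_fixed <- cc == N
      lost <- lost + sum(done_lost)
      fixed <- fixed + sum(done_fixed)
      cc <- cc[!(done_lost | done_fixed)]
    }
  }
  list(fixed = fixed, lost = lost, fraction_fixed = fixed / reps, reps = reps)
}

#' Neutral single-locus drift trajectories
#'
#' Replicate frequency trajectories of a neutral site in an isolated
#' population of constant size `N`: derived-copy counts follow
#' `Binomial(ploidy*N, p)` each generation, the exact neutral marginal of
#' the engine's reproduction phase.
#'
#' @param N Population size (individuals).
#' @param p0 Initial derived-allele frequency.
#' @param generations Number of generations to iterate.
#' @param reps Number of replicate populations.
#' @param ploidy 1 or 2.
#' @return `reps` x `(generations + 1)` matrix of frequencies (column 1 is
#'   generation 0 at exactly `p0`).
#' @export
wf_drift_replicates <- function(N, p0 = 0.5, generations, reps, ploidy = 2) {
  M <- ploidy * N
  c0 <- as.integer(round(M * p0))
  out <- matrix(NA_real_, reps, generations + 1L)
  cc <- rep(c0, reps)
  out[, 1] <- cc / M
  for (t in seq_len(generations)) {
    cc <- stats::rbinom(reps, M, cc / M)
    out[, t + 1L] <- cc / M
  }
  out
}
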