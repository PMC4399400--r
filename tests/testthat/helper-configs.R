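# Small configuration builders shared across test files.

tiny_config <- function(...) {
  over <- list(...)
  base <- list(grid_rows = 2, grid_cols = 2, ploidy = 2,
               genome_length = 10000, mutation_rate = 0,
               n_generations = 5, initial_size = 10,
               carrying_capacity = 10, rng_seed = 1)
  base[names(over)] <- over
  build_config(base)
}

# a grid built by hand around a given dosage matrix (single occupied cell
# unless more are supplied); positions default to 0, 1, 2, ...
manual_grid <- function(genos, ploidy = 2, s = NULL, genome_length = 10000,
                        nrow = 1, ncol = length(genos), seed = 1) {
  S <- ncol(genos[[which(!vapply(genos, is.null, logical(1)))[1]]])
  loci <- if (S > 0) {
    data.frame(position = seq_len(S) - 1L, origin_generation = 0L,
               origin_row = NA_integer_, origin_col = NA_integer_,
               s = if (is.null(s)) rep(0, S) else s,
               stringsAsFactors = FALSE)
  } else {
    data.frame(position = integer(), origin_generation = integer(),
               origin_row = integer(), origin_col = integer(), s = numeric(),
               stringsAsFactors = FALSE)
  }
  pops <- lapply(genos, function(g) {
    if (is.null(g)) NULL else {
      storage.mode(g) <- "integer"
      list(geno = g)
    }
  })
  structure(list(
    nrow = nrow, ncol = ncol, ploidy = as.integer(ploidy),
    genome_length = as.integer(genome_length), generation = 0L,
    pops = pops, loci = loci,
    fixed = loci[0, ],
    rng = wfgrid:::rng_make_streams(seed)
  ), class = "wfgrid_state")
}
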