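# Population grid state.
#
# A `wfgrid_state` holds the whole simulator state: one optional population
# per grid cell, a single locus table shared by every cell, the generation
# counter, and the named RNG stream states. Genotypes are stored per cell as
# an integer dosage matrix (individuals x segregating sites, values
# 0..ploidy). With free recombination between sites (no linkage) the
# per-copy phase carries no information: transmission probabilities and
# genotype fitness depend on the dosage only, so this representation is a
# lossless statistical reduction of the per-copy array.

new_locus_table <- function() {
  data.frame(position = integer(), origin_generation = integer(),
             origin_row = integer(), origin_col = integer(),
             s = numeric(), stringsAsFactors = FALSE)
}

cell_index <- function(grid, row, col) (row - 1L) * grid$ncol + col

cell_rc <- function(grid, idx) {
  c(row = ((idx - 1L) %/% grid$ncol) + 1L,
    col = ((idx - 1L) %% grid$ncol) + 1L)
}

occupied_cells <- function(grid) {
  which(!vapply(grid$pops, is.null, logical(1)))
}

pop_size <- function(grid, idx) {
  if (is.null(grid$pops[[idx]])) 0L else nrow(grid$pops[[idx]]$geno)
}

pop_sizes <- function(grid) {
  vapply(seq_along(grid$pops), function(i) pop_size(grid, i), integer(1))
}

n_sites <- function(grid) nrow(grid$loci)

#' Initialise the population grid from a configuration
#'
#' Occupies every cell with nonzero `initial_size`, seeds the per-phase RNG
#' streams from `rng_seed`, and, if `init_snps` is set, draws starting
#' genotypes binomially per gene copy at the requested frequencies.
#'
#' @param config A `wfgrid_config` from [build_config()].
#' @return Object of class `wfgrid_state` at generation 0.
#' @examples
#' cfg <- build_config(list(grid_rows = 2, grid_cols = 2, genome_length = 1e4,
#'                          n_generations = 5, initial_size = 10,
#'                          carrying_capacity = 10))
#' g <- init_grid(cfg)
#' sum(pop_sizes(g))
#' @export
init_grid <- function(config) {
  stopifnot(inherits(config, "wfgrid_config"))
  rows <- config$grid_rows
  cols <- config$grid_cols
  snps <- config$init_snps
  s0 <- if (is.null(snps)) 0L else nrow(snps)

  grid <- structure(list(
    nrow = rows, ncol = cols, ploidy = config$ploidy,
    genome_length = config$genome_length,
    generation = 0L,
    pops = vector("list", rows * cols),
    loci = new_locus_table(),
    fixed = new_locus_table(),
    rng = rng_make_streams(config$rng_seed)
  ), class = "wfgrid_state")

  if (s0 > 0) {
    grid$loci <- data.frame(position = as.integer(snps$position),
                            origin_generation = 0L,
                            origin_row = NA_integer_, origin_col = NA_integer_,
                            s = as.numeric(snps$s), stringsAsFactors = FALSE)
  }

  sizes <- config$initial_size
  res <- rng_with(grid$rng, "init", function() {
    pops <- vector("list", rows * cols)
    for (r in seq_len(rows)) {
      for (cc in seq_len(cols)) {
        n <- sizes[r, cc]
        if (n > 0) {
          geno <- matrix(0L, n, s0)
          if (s0 > 0) {
            for (j in seq_len(s0)) {
              geno[, j] <- stats::rbinom(n, config$ploidy, snps$freq[j])
            }
          }
          pops[[(r - 1L) * cols + cc]] <- list(geno = geno)
        }
      }
    }
    pops
  })
  grid$rng <- res$streams
  grid$pops <- res$value
  grid
}

#' @export
print.wfgrid_state <- function(x, ...) {
  occ <- occupied_cells(x)
  cat(sprintf(
    "wfgrid state: %d x %d grid, generation %d\n  %d occupied cell(s), %d individuals, %d segregating + %d fixed sites\n",
    x$nrow, x$ncol, x$generation, length(occ), sum(pop_sizes(x)),
    nrow(x$loci), nrow(x$fixed)))
  invisible(x)
}

# In-grid von Neumann (4-)neighbourhood of a cell index, no wraparound.
cell_neighbors <- function(grid, idx) {
  rc <- cell_rc(grid, idx)
  out <- integer(0)
  if (rc["row"] > 1L) out <- c(out, cell_index(grid, rc["row"] - 1L, rc["col"]))
  if (rc["row"] < grid$nrow) out <- c(out, cell_index(grid, rc["row"] + 1L, rc["col"]))
  if (rc["col"] > 1L) out <- c(out, cell_index(grid, rc["row"], rc["col"] - 1L))
  if (rc["col"] < grid$ncol) out <- c(out, cell_index(grid, rc["row"], rc["col"] + 1L))
  out
}
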