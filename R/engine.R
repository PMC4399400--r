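# The generation cycle.
#
# Each generation passes through ordered phases:
#   1. extinction  2. migration  3. mutation (with selection-coefficient
#   assignment)  4. logistic growth / scheduled size changes
#   5. fitness-weighted Wright-Fisher reproduction,
# followed by locus bookkeeping (dropping globally lost sites, promoting
# globally fixed ones). Every phase draws from its own named RNG stream.

#' Apply the extinction phase
#'
#' Each occupied cell independently becomes extinct (is emptied) with its
#' per-cell probability. Emptied cells are unoccupied and can be recolonised
#' by later migration.
#'
#' @param grid A `wfgrid_state`.
#' @param e Per-cell extinction probability: scalar or rows x cols matrix.
#' @return Updated grid, with attribute `"extinct"` holding the indices of
#'   cells emptied this call.
#' @export
apply_extinction <- function(grid, e) {
  e <- per_cell(e, grid$nrow, grid$ncol, "extinction_prob")
  check_prob(e, "extinction_prob")
  occ <- occupied_cells(grid)
  extinct <- integer(0)
  if (length(occ)) {
    res <- rng_with(grid$rng, "extinction", function() {
      stats::runif(length(occ))
    })
    grid$rng <- res$streams
    probs <- vapply(occ, function(i) {
      rc <- cell_rc(grid, i); e[rc["row"], rc["col"]]
    }, numeric(1))
    extinct <- occ[res$value < probs]
    for (i in extinct) grid$pops[i] <- list(NULL)
  }
  attr(grid, "extinct") <- extinct
  grid
}

#' Apply the migration phase
#'
#' For each occupied source cell of size N the emigrant count is drawn from
#' Binomial(N, total outgoing rate); emigrants are chosen uniformly without
#' replacement. In `adjacent_uniform` mode each emigrant moves to a uniformly
#' chosen in-grid 4-neighbour; in `explicit_matrix` mode destinations follow
#' the per-ordered-pair rates. All draws use pre-migration sizes (synchronous
#' update); migrants arriving at an empty cell found a new population.
#'
#' @param grid A `wfgrid_state`.
#' @param migration Migration specification, as in a `wfgrid_config`
#'   (`list(mode, rate, rate_matrix)`).
#' @return Updated grid, with attribute `"migration_trace"`: a data frame of
#'   per-cell emigrant and immigrant counts.
#' @export
apply_migration <- function(grid, migration) {
  occ <- occupied_cells(grid)
  ncell <- grid$nrow * grid$ncol
  emig <- integer(ncell)
  immig <- integer(ncell)
  moves <- list()  # per source: list(ids = individual rows, dest = cell idx)

  if (length(occ)) {
    res <- rng_with(grid$rng, "migration", function() {
      out <- vector("list", length(occ))
      names(out) <- as.character(occ)
      for (k in seq_along(occ)) {
        i <- occ[k]
        n <- nrow(grid$pops[[i]]$geno)
        if (migration$mode == "adjacent_uniform") {
          rc <- cell_rc(grid, i)
          m <- migration$rate[rc["row"], rc["col"]]
          nb <- cell_neighbors(grid, i)
          if (m <= 0 || n == 0 || length(nb) == 0) next
          nmig <- stats::rbinom(1L, n, m)
          if (nmig == 0) next
          ids <- sample.int(n, nmig)
          dest <- nb[sample.int(length(nb), nmig, replace = TRUE)]
        } else {
          rates <- migration$rate_matrix[i, ]
          tot <- sum(rates)
          if (tot <= 0 || n == 0) next
          nmig <- stats::rbinom(1L, n, tot)
          if (nmig == 0) next
          ids <- sample.int(n, nmig)
          dest <- sample.int(ncell, nmig, replace = TRUE, prob = rates)
        }
        out[[k]] <- list(ids = ids, dest = dest)
      }
      out
    })
    grid$rng <- res$streams
    moves <- res$value
  }

  # apply removals and arrivals after all draws (pre-migration state rule);
  # arrivals are accumulated as row chunks and bound once per destination
  arrivals <- vector("list", ncell)
  for (k in seq_along(moves)) {
    mv <- moves[[k]]
    if (is.null(mv)) next
    i <- occ[k]
    rows_out <- grid$pops[[i]]$geno[mv$ids, , drop = FALSE]
    emig[i] <- length(mv$ids)
    for (d in unique(mv$dest)) {
      sel <- which(mv$dest == d)
      arrivals[[d]] <- c(arrivals[[d]], list(rows_out[sel, , drop = FALSE]))
      immig[d] <- immig[d] + length(sel)
    }
    keep <- setdiff(seq_len(nrow(grid$pops[[i]]$geno)), mv$ids)
    if (length(keep)) {
      grid$pops[[i]]$geno <- grid$pops[[i]]$geno[keep, , drop = FALSE]
    } else {
      grid$pops[i] <- list(NULL)
    }
  }
  for (d in which(lengths(arrivals) > 0)) {
    inc <- do.call(rbind, arrivals[[d]])
    if (is.null(grid$pops[[d]])) {
      grid$pops[[d]] <- list(geno = inc)
    } else {
      grid$pops[[d]]$geno <- rbind(grid$pops[[d]]$geno, inc)
    }
  }
  attr(grid, "migration_trace") <- data.frame(
    cell = seq_len(ncell), emigrants = emig, immigrants = immig)
  grid
}

#' Draw one selection coefficient for a new mutation
#'
#' Neutral model: 0. Fixed model: the configured coefficient. Gamma model: a
#' Gamma(shape, scale) draw, negated when `sign_negative` (deleterious
#' alleles); draws <= -1 are rejected and redrawn (at most 100 attempts).
#' Uses the calling session's RNG; the engine wraps it in the "selection"
#' stream.
#'
#' @param model Selection specification (`list(kind, fixed_s, gamma_shape,
#'   gamma_scale, sign_negative, ...)`).
#' @param n Number of coefficients to draw.
#' @return Numeric vector of length `n`, each entry > -1.
#' @export
draw_selection_coefficient <- function(model, n = 1L) {
  if (n == 0) return(numeric(0))
  switch(model$kind,
    neutral = rep(0, n),
    fixed = rep(model$fixed_s, n),
    gamma = {
      draw1 <- function() {
        for (attempt in seq_len(100L)) {
          s <- stats::rgamma(1L, shape = model$gamma_shape,
                             scale = model$gamma_scale)
          if (model$sign_negative) s <- -s
          if (s > -1) return(s)
        }
        stop("could not draw a selection coefficient > -1 in 100 attempts")
      }
      vapply(seq_len(n), function(i) draw1(), numeric(1))
    },
    stop("unknown selection kind: ", model$kind))
}

#' Apply the mutation phase (infinitely many sites)
#'
#' Per occupied cell the number of new mutations is Poisson with rate
#' `mu * g * N` (`N` = individuals, or gene copies if the configuration says
#' so). Each mutation picks a uniform carrier, a uniform genomic position not
#' yet used by any segregating or fixed site, and a selection coefficient
#' from the selection model.
#'
#' @param grid A `wfgrid_state`.
#' @param mu Per-site per-generation mutation rate.
#' @param selection Selection specification (see [draw_selection_coefficient()]).
#' @param count_scale `"individuals"` or `"gene_copies"`.
#' @return Updated grid, with attribute `"mutation_trace"`: per-cell new
#'   mutation counts.
#' @export
apply_mutation <- function(grid, mu, selection,
                           count_scale = c("individuals", "gene_copies")) {
  count_scale <- match.arg(count_scale)
  stopifnot(mu >= 0)
  occ <- occupied_cells(grid)
  ncell <- grid$nrow * grid$ncol
  counts <- integer(ncell)
  if (mu > 0 && length(occ)) {
    sizes <- vapply(occ, function(i) nrow(grid$pops[[i]]$geno), integer(1))
    lam <- mu * grid$genome_length * sizes
    if (count_scale == "gene_copies") lam <- lam * grid$ploidy
    res <- rng_with(grid$rng, "mutation", function() {
      k <- stats::rpois(length(occ), lam)
      used <- c(grid$loci$position, grid$fixed$position)
      recs <- NULL
      if (sum(k) > 0) {
        if (length(used) >= grid$genome_length) {
          stop("genome exhausted: every position already carries a site")
        }
        cell <- rep(occ, k)
        carrier <- integer(length(cell))
        pos <- integer(length(cell))
        for (t in seq_along(cell)) {
          carrier[t] <- sample.int(sizes[match(cell[t], occ)], 1L)
          repeat {
            p <- sample.int(grid$genome_length, 1L) - 1L
            if (!p %in% used) break
          }
          pos[t] <- p
          used <- c(used, p)
        }
        recs <- data.frame(cell = cell, carrier = carrier, position = pos)
      }
      recs
    })
    grid$rng <- res$streams
    recs <- res$value
    if (!is.null(recs)) {
      sres <- rng_with(grid$rng, "selection", function() {
        draw_selection_coefficient(selection, nrow(recs))
      })
      grid$rng <- sres$streams
      s_new <- sres$value
      kk <- nrow(recs)
      for (i in occ) {
        n <- nrow(grid$pops[[i]]$geno)
        grid$pops[[i]]$geno <- cbind(grid$pops[[i]]$geno,
                                     matrix(0L, n, kk))
      }
      for (t in seq_len(kk)) {
        i <- recs$cell[t]
        grid$pops[[i]]$geno[recs$carrier[t], n_sites(grid) + t] <- 1L
      }
      rcs <- t(vapply(recs$cell, function(i) cell_rc(grid, i), integer(2)))
      grid$loci <- rbind(grid$loci, data.frame(
        position = recs$position,
        origin_generation = grid$generation + 1L,
        origin_row = rcs[, 1], origin_col = rcs[, 2],
        s = s_new, stringsAsFactors = FALSE))
      counts <- tabulate(recs$cell, nbins = ncell)
    }
  }
  attr(grid, "mutation_trace") <- counts
  grid
}

#' Logistic growth targets with optional Allee effect
#'
#' For each occupied cell a growth rate r is drawn from
#' Normal(growth_rate_mean, growth_rate_var) and the target size is
#' `round(N + r * N * (1 - N/K) * a)` with `a = (N - A)/K` when an Allee
#' threshold A is set for the cell and `a = 1` otherwise, clamped at 0.
#' Rounding is round-half-to-even. A `step_size_change` override replaces
#' the computed target.
#'
#' @param grid A `wfgrid_state`.
#' @param K Per-cell carrying capacity (scalar or matrix).
#' @param r_mean,r_var Mean and variance of the growth-rate distribution.
#' @param allee Optional per-cell Allee threshold (`NULL`/`NA` = disabled).
#' @param overrides Optional named integer vector: cell index -> forced size.
#' @return Data frame with columns `cell`, `n`, `r`, `target`.
#' @export
apply_growth <- function(grid, K, r_mean, r_var, allee = NULL,
                         overrides = NULL) {
  K <- per_cell(K, grid$nrow, grid$ncol, "carrying_capacity")
  if (!is.null(allee)) {
    allee <- per_cell(allee, grid$nrow, grid$ncol, "allee", allow_na = TRUE)
  }
  occ <- occupied_cells(grid)
  if (!length(occ)) {
    return(data.frame(cell = integer(), n = integer(), r = numeric(),
                      target = integer()))
  }
  res <- rng_with(grid$rng, "growth", function() {
    stats::rnorm(length(occ), mean = r_mean, sd = sqrt(r_var))
  })
  grid_rng_updated <- res$streams
  r <- res$value
  n <- vapply(occ, function(i) nrow(grid$pops[[i]]$geno), integer(1))
  target <- numeric(length(occ))
  for (k in seq_along(occ)) {
    rc <- cell_rc(grid, occ[k])
    kk <- K[rc["row"], rc["col"]]
    a <- 1
    if (!is.null(allee) && !is.na(allee[rc["row"], rc["col"]])) {
      a <- (n[k] - allee[rc["row"], rc["col"]]) / kk
    }
    target[k] <- max(0, round(n[k] + r[k] * n[k] * (1 - n[k] / kk) * a))
  }
  target <- as.integer(target)
  if (!is.null(overrides) && length(overrides)) {
    hit <- match(as.integer(names(overrides)), occ)
    ok <- !is.na(hit)
    target[hit[ok]] <- as.integer(overrides[ok])
  }
  out <- data.frame(cell = occ, n = n, r = r, target = target)
  attr(out, "rng") <- grid_rng_updated
  out
}

#' Per-individual multiplicative fitness
#'
#' Diploid per-locus weights are 1 (ancestral homozygote), `1 + h*s`
#' (heterozygote) and `1 + s` (derived homozygote); haploid weights are 1 and
#' `1 + s`. Individual fitness is the product over segregating sites, with
#' `s` the locus coefficient times the cell's spatial multiplier.
#'
#' @param geno Integer dosage matrix (individuals x sites).
#' @param s_eff Effective per-site selection coefficients at this cell.
#' @param ploidy 1 or 2.
#' @param h Dominance coefficient (diploid heterozygote weight `1 + h*s`).
#' @param positions Optional site positions, used in error messages.
#' @return Numeric vector of per-individual fitnesses (all > 0).
#' @export
compute_fitness <- function(geno, s_eff, ploidy, h = 0.5, positions = NULL) {
  n <- nrow(geno)
  sel <- which(s_eff != 0)
  if (!length(sel) || n == 0) return(rep(1, n))
  s <- s_eff[sel]
  bad <- if (ploidy == 2L) (1 + h * s <= 0) | (1 + s <= 0) else (1 + s <= 0)
  if (any(bad)) {
    lab <- if (!is.null(positions)) positions[sel][bad][1] else which(bad)[1]
    stop("nonpositive fitness at locus ", lab)
  }
  G <- geno[, sel, drop = FALSE]
  if (ploidy == 2L) {
    logw <- (G == 1L) %*% log1p(h * s) + (G == 2L) %*% log1p(s)
  } else {
    logw <- (G == 1L) %*% log1p(s)
  }
  as.vector(exp(logw))
}

#' Wright-Fisher reproduction of one population
#'
#' Produces `target_size` offspring: each offspring draws its parent(s)
#' independently with probability proportional to fitness (diploid: two
#' independent draws, selfing allowed; haploid: one). At every site,
#' independently of all other sites (free recombination), the offspring
#' receives one uniformly chosen allele copy from each parent. Offspring
#' replace the parents entirely (non-overlapping generations). Uses the
#' calling session's RNG; the engine wraps it in the "reproduction" stream.
#'
#' @param geno Parental dosage matrix (individuals x sites).
#' @param target_size Number of offspring.
#' @param fitness Per-parent fitness vector.
#' @param ploidy 1 or 2.
#' @return Offspring dosage matrix (`target_size` x sites).
#' @export
apply_reproduction <- function(geno, target_size, fitness, ploidy) {
  n <- nrow(geno)
  S <- ncol(geno)
  if (target_size == 0L) return(geno[0, , drop = FALSE])
  stopifnot(n >= 1)
  if (ploidy == 2L) {
    p1 <- sample.int(n, target_size, replace = TRUE, prob = fitness)
    p2 <- sample.int(n, target_size, replace = TRUE, prob = fitness)
    if (S == 0L) return(matrix(0L, target_size, 0))
    h1 <- matrix(stats::rbinom(target_size * S, 1L,
                               as.vector(geno[p1, , drop = FALSE] / 2)),
                 target_size, S)
    h2 <- matrix(stats::rbinom(target_size * S, 1L,
                               as.vector(geno[p2, , drop = FALSE] / 2)),
                 target_size, S)
    off <- h1 + h2
  } else {
    p <- sample.int(n, target_size, replace = TRUE, prob = fitness)
    off <- geno[p, , drop = FALSE]
  }
  storage.mode(off) <- "integer"
  off
}

#' Drop globally lost sites, promote globally fixed ones
#'
#' A site absent from every occupied cell is deleted from the locus table; a
#' site at frequency 1 in every occupied cell is moved to the fixed-site
#' registry and removed from the genotype arrays. Frequencies of remaining
#' sites are unchanged.
#'
#' @param grid A `wfgrid_state`.
#' @return Updated grid.
#' @export
prune_and_promote_sites <- function(grid) {
  occ <- occupied_cells(grid)
  S <- n_sites(grid)
  if (!length(occ) || S == 0L) return(grid)
  counts <- rep(0, S)
  total <- 0L
  for (i in occ) {
    counts <- counts + colSums(grid$pops[[i]]$geno)
    total <- total + nrow(grid$pops[[i]]$geno)
  }
  copies <- grid$ploidy * total
  lost <- counts == 0
  fixd <- counts == copies
  if (any(fixd)) {
    grid$fixed <- rbind(grid$fixed, grid$loci[fixd, , drop = FALSE])
    rownames(grid$fixed) <- NULL
  }
  drop <- lost | fixd
  if (any(drop)) {
    keep <- which(!drop)
    grid$loci <- grid$loci[keep, , drop = FALSE]
    rownames(grid$loci) <- NULL
    for (i in occ) {
      grid$pops[[i]]$geno <- grid$pops[[i]]$geno[, keep, drop = FALSE]
    }
  }
  grid
}

# One full generation step. `params` carries the currently active (possibly
# event-modified) per-cell parameters; `overrides` are this generation's
# step_size_change events as a named vector (cell index -> size).
step_generation <- function(grid, config, params, overrides = NULL) {
  ncell <- grid$nrow * grid$ncol
  n_start <- pop_sizes(grid)

  grid <- apply_extinction(grid, params$extinction)
  extinct <- attr(grid, "extinct")

  grid <- apply_migration(grid, params$migration)
  mtr <- attr(grid, "migration_trace")

  grid <- apply_mutation(grid, config$mutation_rate, config$selection,
                         config$mutation_count_scale)
  mut <- attr(grid, "mutation_trace")

  gr <- apply_growth(grid, config$carrying_capacity, config$growth_rate_mean,
                     config$growth_rate_var, config$allee, overrides)
  if (!is.null(attr(gr, "rng"))) grid$rng <- attr(gr, "rng")

  # reproduction: per occupied cell, fitness-weighted resampling to target
  if (nrow(gr)) {
    res <- rng_with(grid$rng, "reproduction", function() {
      pops <- grid$pops
      for (k in seq_len(nrow(gr))) {
        i <- gr$cell[k]
        if (gr$target[k] == 0L) {
          pops[i] <- list(NULL)
          next
        }
        rc <- cell_rc(grid, i)
        mult <- params$sel_multiplier[rc["row"], rc["col"]]
        w <- compute_fitness(pops[[i]]$geno, grid$loci$s * mult,
                             grid$ploidy, config$selection$dominance_h,
                             grid$loci$position)
        pops[[i]]$geno <- apply_reproduction(pops[[i]]$geno, gr$target[k], w,
                                             grid$ploidy)
      }
      pops
    })
    grid$rng <- res$streams
    grid$pops <- res$value
  }

  grid <- prune_and_promote_sites(grid)
  grid$generation <- grid$generation + 1L

  r_vec <- rep(NA_real_, ncell); r_vec[gr$cell] <- gr$r
  t_vec <- rep(NA_integer_, ncell); t_vec[gr$cell] <- gr$target
  rc <- t(vapply(seq_len(ncell), function(i) cell_rc(grid, i), integer(2)))
  trace <- data.frame(
    generation = grid$generation, row = rc[, 1], col = rc[, 2],
    n_start = n_start, extinct = seq_len(ncell) %in% extinct,
    emigrants = mtr$emigrants, immigrants = mtr$immigrants,
    mutations = mut, r = r_vec, target = t_vec, n_end = pop_sizes(grid))
  attr(grid, "trace") <- trace
  grid
}

#' Run a full simulation
#'
#' Initialises the grid from the configuration (or resumes from a
#' checkpoint) and applies the generation cycle `n_generations` times.
#' Scheduled events take effect at the start of their generation;
#' `step_size_change` events override that generation's growth target.
#' If every population goes extinct the run terminates early (migrants can
#' only come from occupied cells, so recovery is impossible) with status
#' `"extinct"` and the partial trace is returned.
#'
#' @param config A `wfgrid_config`.
#' @param initial Optional checkpoint (from [read_checkpoint()]) to resume
#'   from; its grid dimensions, ploidy and genome length must match `config`
#'   unless `allow_structure_change = TRUE`. `n_generations` then counts
#'   additional generations and event generations refer to the absolute
#'   generation counter.
#' @param out_dir Optional directory: final state (and snapshots every
#'   `snapshot_every` generations) are written there in the configured
#'   output formats, together with a run manifest.
#' @param record_frequencies If `TRUE`, per-generation per-cell allele
#'   frequencies of all segregating sites are accumulated (memory grows with
#'   sites x cells x generations; meant for demonstration-scale runs).
#' @param allow_structure_change Permit resuming from a checkpoint whose
#'   grid structure differs from `config`.
#' @return Object of class `wfgrid_result`: `list(state, trace, status,
#'   config, frequencies)` where `status` is `"completed"` or `"extinct"`.
#' @examples
#' cfg <- build_config(list(grid_rows = 2, grid_cols = 2, genome_length = 1e4,
#'                          mutation_rate = 1e-5, n_generations = 20,
#'                          initial_size = 20, carrying_capacity = 20,
#'                          migration_rate = 0.05, rng_seed = 42))
#' res <- run_simulation(cfg)
#' res$status
#' @export
run_simulation <- function(config, initial = NULL, out_dir = NULL,
                           record_frequencies = FALSE,
                           allow_structure_change = FALSE) {
  stopifnot(inherits(config, "wfgrid_config"))
  if (is.null(initial)) {
    grid <- init_grid(config)
  } else {
    grid <- initial$state
    stopifnot(inherits(grid, "wfgrid_state"))
    if (!allow_structure_change &&
        (grid$nrow != config$grid_rows || grid$ncol != config$grid_cols ||
         grid$ploidy != config$ploidy ||
         grid$genome_length != config$genome_length)) {
      stop("checkpoint structure (grid dims, ploidy, genome length) does not ",
           "match the new configuration; pass allow_structure_change = TRUE ",
           "to override")
    }
  }

  params <- list(extinction = config$extinction_prob,
                 migration = config$migration,
                 sel_multiplier = config$selection$multiplier)
  events <- config$events
  start_gen <- grid$generation
  end_gen <- start_gen + config$n_generations

  apply_param_events <- function(params, evs) {
    for (k in seq_len(nrow(evs))) {
      ev <- evs[k, ]
      set_cells <- function(m, value) {
        if (is.na(ev$row)) m[, ] <- value else m[ev$row, ev$col] <- value
        m
      }
      if (ev$kind == "set_extinction_prob") {
        params$extinction <- set_cells(params$extinction, ev$value)
      } else if (ev$kind == "set_migration") {
        if (params$migration$mode != "adjacent_uniform") {
          stop("set_migration events require adjacent_uniform mode")
        }
        params$migration$rate <- set_cells(params$migration$rate, ev$value)
      } else if (ev$kind == "set_selection_multiplier") {
        params$sel_multiplier <- set_cells(params$sel_multiplier, ev$value)
      }
    }
    params
  }
  params <- apply_param_events(params,
                               events[events$generation == start_gen &
                                        events$kind != "step_size_change", ,
                                      drop = FALSE])

  traces <- vector("list", config$n_generations)
  freqs <- if (record_frequencies) list(allele_frequencies(grid)) else NULL
  status <- "completed"

  gen_i <- 0L
  while (grid$generation < end_gen) {
    gen <- grid$generation + 1L
    evs <- events[events$generation == gen, , drop = FALSE]
    params <- apply_param_events(params,
                                 evs[evs$kind != "step_size_change", ,
                                     drop = FALSE])
    sz <- evs[evs$kind == "step_size_change", , drop = FALSE]
    overrides <- NULL
    if (nrow(sz)) {
      idx <- ifelse(is.na(sz$row), NA_integer_,
                    (sz$row - 1L) * grid$ncol + sz$col)
      if (anyNA(idx)) {  # "all" cells
        all_sz <- sz$value[which(is.na(idx))[1]]
        overrides <- stats::setNames(rep(all_sz, grid$nrow * grid$ncol),
                                     seq_len(grid$nrow * grid$ncol))
      } else {
        overrides <- stats::setNames(sz$value, idx)
      }
    }
    grid <- step_generation(grid, config, params, overrides)
    gen_i <- gen_i + 1L
    traces[[gen_i]] <- attr(grid, "trace")
    if (record_frequencies) freqs[[length(freqs) + 1L]] <- allele_frequencies(grid)
    if (!is.null(out_dir) && !is.null(config$snapshot_every) &&
        grid$generation %% config$snapshot_every == 0L &&
        grid$generation < end_gen) {
      write_checkpoint(grid, config,
                       file.path(out_dir, sprintf("snapshot_gen%06d.json",
                                                  grid$generation)))
    }
    if (!length(occupied_cells(grid))) {
      status <- "extinct"
      break
    }
  }

  for (a in c("trace", "extinct", "migration_trace", "mutation_trace")) {
    attr(grid, a) <- NULL
  }
  result <- structure(list(
    state = grid,
    trace = do.call(rbind, traces[seq_len(gen_i)]),
    status = status,
    config = config,
    frequencies = if (record_frequencies) do.call(rbind, freqs) else NULL
  ), class = "wfgrid_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_outputs(result, out_dir)
  }
  result
}

#' @export
print.wfgrid_result <- function(x, ...) {
  cat(sprintf("wfgrid result: status %s after %d generation(s)\n",
              x$status, x$state$generation))
  print(x$state)
  invisible(x)
}
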