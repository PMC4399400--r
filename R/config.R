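# Simulation configuration: construction, validation, (de)serialisation.

#' Build and validate a simulation configuration
#'
#' Assembles a complete, validated configuration for [run_simulation()] from
#' a flat key-value list (for example one read with [read_config_file()]).
#' Unspecified keys take documented defaults; scalar per-cell parameters are
#' broadcast to every cell of the grid.
#'
#' @param params Named list. Recognised keys:
#' \describe{
#'   \item{grid_rows, grid_cols}{Grid dimensions (positive integers). Default 1.}
#'   \item{ploidy}{1 (haploid) or 2 (diploid). Default 2.}
#'   \item{genome_length}{Number of base pairs `g` (positive integer).}
#'   \item{mutation_rate}{Per-site per-generation mutation rate `mu` (>= 0).}
#'   \item{n_generations}{Number of generations to simulate (positive integer).}
#'   \item{initial_size}{Per-cell starting size; scalar or rows x cols matrix
#'     (row-major vector also accepted). 0 marks an initially empty cell.}
#'   \item{carrying_capacity}{Per-cell carrying capacity `K` (>= 1 wherever a
#'     population can occur); scalar or matrix.}
#'   \item{growth_rate_mean, growth_rate_var}{Mean and variance of the normal
#'     distribution from which the logistic growth rate `r` is drawn each
#'     generation for each population. Defaults 0 (constant size).}
#'   \item{allee}{Optional per-cell Allee threshold `A` (`NA` disables the
#'     Allee term for that cell; default disabled everywhere). Must satisfy
#'     `A < K` wherever set.}
#'   \item{extinction_prob}{Per-cell per-generation extinction probability in
#'     \[0, 1\]. Default 0.}
#'   \item{migration_mode}{`"adjacent_uniform"` (default) or `"explicit_matrix"`.}
#'   \item{migration_rate}{Per-cell per-individual emigration probability
#'     (adjacent_uniform mode); scalar or matrix. Default 0.}
#'   \item{migration_matrix}{ncell x ncell matrix of per-ordered-pair rates
#'     (explicit_matrix mode); cells indexed row-major. Row sums must be <= 1.}
#'   \item{selection_kind}{`"neutral"` (default), `"fixed"` or `"gamma"`.}
#'   \item{fixed_s}{Selection coefficient for `"fixed"` (> -1). Default 0.}
#'   \item{gamma_shape, gamma_scale}{Gamma parameters for `"gamma"` (> 0).}
#'   \item{sign_negative}{If `TRUE`, gamma draws are negated (deleterious).}
#'   \item{dominance_h}{Dominance coefficient `h`. Default 0.5 (semidominant).}
#'   \item{selection_multiplier}{Optional per-cell multiplier on selection
#'     coefficients (spatially varying selection); scalar or matrix. Default 1.}
#'   \item{events}{Data frame (or list of records) with columns `generation`,
#'     `kind` (one of `step_size_change`, `set_extinction_prob`,
#'     `set_migration`, `set_selection_multiplier`), `row`, `col` (`NA` = all
#'     cells) and `value`.}
#'   \item{init_snps}{Optional data frame of starting SNPs with columns
#'     `position` (0-based, unique), `freq` (initial derived frequency applied
#'     to every occupied cell) and `s`. Genotypes are drawn binomially per
#'     gene copy at initialisation.}
#'   \item{mutation_count_scale}{`"individuals"` (default; `N` in the Poisson
#'     rate `mu * g * N` counts individuals) or `"gene_copies"`.}
#'   \item{rng_seed}{Integer master seed. Default 1.}
#'   \item{output_formats}{Subset of `c("genepop", "plink", "geneland",
#'     "checkpoint")`. Default `"checkpoint"`.}
#'   \item{snapshot_every}{Optional positive integer: write intermediate
#'     checkpoints every that many generations.}
#' }
#' @return Object of class `wfgrid_config`.
#' @examples
#' cfg <- build_config(list(grid_rows = 2, grid_cols = 2, genome_length = 1e4,
#'                          mutation_rate = 1e-6, n_generations = 10,
#'                          initial_size = 20, carrying_capacity = 20))
#' cfg$ploidy
#' @export
build_config <- function(params = list()) {
  stopifnot(is.list(params))
  known <- c("grid_rows", "grid_cols", "ploidy", "genome_length",
             "mutation_rate", "n_generations", "initial_size",
             "carrying_capacity", "growth_rate_mean", "growth_rate_var",
             "allee", "extinction_prob", "migration_mode", "migration_rate",
             "migration_matrix", "selection_kind", "fixed_s", "gamma_shape",
             "gamma_scale", "sign_negative", "dominance_h",
             "selection_multiplier", "events", "init_snps",
             "mutation_count_scale", "rng_seed", "output_formats",
             "snapshot_every")
  unknown <- setdiff(names(params), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  get_par <- function(key, default) {
    if (!is.null(params[[key]])) params[[key]] else default
  }

  rows <- check_count(get_par("grid_rows", 1L), "grid_rows")
  cols <- check_count(get_par("grid_cols", 1L), "grid_cols")
  ploidy <- as.integer(get_par("ploidy", 2L))
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  g <- check_count(get_par("genome_length", NULL), "genome_length")
  mu <- get_par("mutation_rate", 0)
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu < 0) {
    stop("mutation_rate must be a nonnegative number")
  }
  ngen <- check_count(get_par("n_generations", NULL), "n_generations",
                      allow_zero = TRUE)

  init_n <- per_cell(get_par("initial_size", 0), rows, cols, "initial_size")
  if (any(init_n < 0) || any(init_n != round(init_n))) {
    stop("initial_size must be nonnegative integers")
  }
  storage.mode(init_n) <- "integer"
  K <- per_cell(get_par("carrying_capacity", pmax(init_n, 1L)), rows, cols,
                "carrying_capacity")
  if (any(K < 1) || any(K != round(K))) {
    stop("carrying_capacity must be integers >= 1")
  }
  storage.mode(K) <- "integer"

  r_mean <- as.numeric(get_par("growth_rate_mean", 0))
  r_var <- as.numeric(get_par("growth_rate_var", 0))
  if (length(r_mean) != 1 || length(r_var) != 1 || is.na(r_var) || r_var < 0) {
    stop("growth_rate_var must be a nonnegative number")
  }

  allee <- get_par("allee", NULL)
  if (!is.null(allee)) {
    allee <- per_cell(allee, rows, cols, "allee", allow_na = TRUE)
    bad <- !is.na(allee) & (allee < 0 | allee >= K)
    if (any(bad)) stop("allee must satisfy 0 <= A < K wherever set")
  }

  e <- per_cell(get_par("extinction_prob", 0), rows, cols, "extinction_prob")
  check_prob(e, "extinction_prob")

  migration <- build_migration(
    mode = match.arg(get_par("migration_mode", "adjacent_uniform"),
                     c("adjacent_uniform", "explicit_matrix")),
    rate = get_par("migration_rate", 0),
    rate_matrix = get_par("migration_matrix", NULL),
    rows = rows, cols = cols)

  selection <- build_selection(
    kind = match.arg(get_par("selection_kind", "neutral"),
                     c("neutral", "fixed", "gamma")),
    fixed_s = get_par("fixed_s", 0),
    gamma_shape = get_par("gamma_shape", NULL),
    gamma_scale = get_par("gamma_scale", NULL),
    sign_negative = isTRUE(get_par("sign_negative", FALSE)),
    dominance_h = as.numeric(get_par("dominance_h", 0.5)),
    multiplier = per_cell(get_par("selection_multiplier", 1), rows, cols,
                          "selection_multiplier"))

  events <- build_events(get_par("events", NULL), rows, cols, ngen)

  init_snps <- get_par("init_snps", NULL)
  if (!is.null(init_snps)) {
    init_snps <- as.data.frame(init_snps)
    req <- c("position", "freq", "s")
    if (!all(req %in% names(init_snps))) {
      stop("init_snps needs columns position, freq, s")
    }
    init_snps <- init_snps[req]
    init_snps$position <- as.integer(init_snps$position)
    if (anyDuplicated(init_snps$position) ||
        any(init_snps$position < 0 | init_snps$position >= g)) {
      stop("init_snps positions must be unique integers in [0, genome_length)")
    }
    check_prob(init_snps$freq, "init_snps$freq")
    if (any(init_snps$s <= -1)) stop("init_snps s must be > -1")
  }

  scale <- match.arg(get_par("mutation_count_scale", "individuals"),
                     c("individuals", "gene_copies"))
  seed <- get_par("rng_seed", 1L)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("rng_seed must be a single integer")
  }
  formats <- get_par("output_formats", "checkpoint")
  bad_fmt <- setdiff(formats, c("genepop", "plink", "geneland", "checkpoint"))
  if (length(bad_fmt)) stop("unknown output format(s): ",
                            paste(bad_fmt, collapse = ", "))
  snap <- get_par("snapshot_every", NULL)
  if (!is.null(snap)) snap <- check_count(snap, "snapshot_every")

  structure(list(
    grid_rows = rows, grid_cols = cols, ploidy = ploidy,
    genome_length = g, mutation_rate = mu, n_generations = ngen,
    initial_size = init_n, carrying_capacity = K,
    growth_rate_mean = r_mean, growth_rate_var = r_var, allee = allee,
    extinction_prob = e, migration = migration, selection = selection,
    events = events, init_snps = init_snps, mutation_count_scale = scale,
    rng_seed = as.integer(seed), output_formats = formats,
    snapshot_every = snap
  ), class = "wfgrid_config")
}

# Broadcast a scalar (or row-major vector / matrix) to a rows x cols matrix.
per_cell <- function(x, rows, cols, field, allow_na = FALSE) {
  if (is.null(x)) stop("missing per-cell parameter: ", field)
  x <- as.numeric(unlist(x))
  if (!allow_na && anyNA(x)) stop(field, " contains NA")
  if (length(x) == 1) {
    matrix(x, rows, cols)
  } else if (is.matrix(x) && all(dim(x) == c(rows, cols))) {
    x
  } else if (length(x) == rows * cols) {
    matrix(x, rows, cols, byrow = TRUE)
  } else {
    stop(field, " must be a scalar or have one value per grid cell")
  }
}

check_prob <- function(x, field) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(field, " must lie in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, allow_zero = FALSE) {
  if (is.null(x)) stop("missing required parameter: ", field)
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) ||
      x < if (allow_zero) 0 else 1) {
    stop(field, " must be a ", if (allow_zero) "nonnegative" else "positive",
         " integer")
  }
  as.integer(x)
}

build_migration <- function(mode, rate, rate_matrix, rows, cols) {
  ncell <- rows * cols
  if (mode == "adjacent_uniform") {
    rate <- per_cell(rate, rows, cols, "migration_rate")
    check_prob(rate, "migration_rate")
    list(mode = mode, rate = rate, rate_matrix = NULL)
  } else {
    if (is.null(rate_matrix)) {
      stop("migration_matrix is required in explicit_matrix mode")
    }
    m <- if (is.matrix(rate_matrix)) {
      if (!all(dim(rate_matrix) == ncell)) {
        stop("migration_matrix must be ", ncell, " x ", ncell)
      }
      matrix(as.numeric(rate_matrix), ncell, ncell)
    } else {
      # flat vectors (config files) are row-major: source cells as rows
      matrix(as.numeric(unlist(rate_matrix)), ncell, ncell, byrow = TRUE)
    }
    check_prob(m, "migration_matrix")
    if (any(diag(m) != 0)) stop("migration_matrix diagonal must be 0")
    if (any(rowSums(m) > 1 + 1e-12)) {
      stop("migration_matrix row sums (total outgoing rate) must be <= 1")
    }
    list(mode = mode, rate = NULL, rate_matrix = m)
  }
}

build_selection <- function(kind, fixed_s, gamma_shape, gamma_scale,
                            sign_negative, dominance_h, multiplier) {
  fixed_s <- as.numeric(fixed_s)
  if (kind == "fixed" && (length(fixed_s) != 1 || fixed_s <= -1)) {
    stop("fixed_s must be a single value > -1")
  }
  if (kind == "gamma") {
    if (is.null(gamma_shape) || is.null(gamma_scale) ||
        gamma_shape <= 0 || gamma_scale <= 0) {
      stop("gamma_shape and gamma_scale must be positive for gamma selection")
    }
  }
  list(kind = kind, fixed_s = fixed_s,
       gamma_shape = if (is.null(gamma_shape)) NULL else as.numeric(gamma_shape),
       gamma_scale = if (is.null(gamma_scale)) NULL else as.numeric(gamma_scale),
       sign_negative = sign_negative, dominance_h = dominance_h,
       multiplier = multiplier)
}

build_events <- function(events, rows, cols, ngen) {
  if (is.null(events) || (is.data.frame(events) && nrow(events) == 0)) {
    return(data.frame(generation = integer(), kind = character(),
                      row = integer(), col = integer(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!is.data.frame(events)) {
    events <- do.call(rbind, lapply(events, function(ev) {
      as.data.frame(ev[c("generation", "kind", "row", "col", "value")])
    }))
  }
  req <- c("generation", "kind", "row", "col", "value")
  if (!all(req %in% names(events))) {
    stop("events need columns generation, kind, row, col, value")
  }
  events <- as.data.frame(events)[req]
  events$generation <- as.integer(events$generation)
  events$row <- as.integer(events$row)
  events$col <- as.integer(events$col)
  events$value <- as.numeric(events$value)
  events$kind <- as.character(events$kind)
  kinds <- c("step_size_change", "set_extinction_prob", "set_migration",
             "set_selection_multiplier")
  if (!all(events$kind %in% kinds)) {
    stop("event kind must be one of: ", paste(kinds, collapse = ", "))
  }
  if (any(events$generation < 0 | events$generation > ngen)) {
    stop("event generations must lie in [0, n_generations]")
  }
  in_grid <- (is.na(events$row) & is.na(events$col)) |
    (events$row >= 1 & events$row <= rows & events$col >= 1 &
       events$col <= cols)
  if (any(!in_grid)) stop("event cell outside the grid")
  if (any(events$kind == "set_extinction_prob" &
          (events$value < 0 | events$value > 1))) {
    stop("set_extinction_prob value must lie in [0, 1]")
  }
  if (any(events$kind == "set_migration" &
          (events$value < 0 | events$value > 1))) {
    stop("set_migration value must lie in [0, 1]")
  }
  if (any(events$kind == "step_size_change" &
          (events$value < 0 | events$value != round(events$value)))) {
    stop("step_size_change value must be a nonnegative integer")
  }
  events[order(events$generation), , drop = FALSE]
}

#' @export
print.wfgrid_config <- function(x, ...) {
  cat(sprintf("wfgrid configuration: %d x %d grid, ploidy %d\n",
              x$grid_rows, x$grid_cols, x$ploidy))
  cat(sprintf("  genome %d bp, mu = %g, %d generations, seed %d\n",
              x$genome_length, x$mutation_rate, x$n_generations, x$rng_seed))
  cat(sprintf("  migration: %s; selection: %s; events: %d\n",
              x$migration$mode, x$selection$kind, nrow(x$events)))
  invisible(x)
}

#' Flatten a configuration to a plain serialisable list
#'
#' Inverse of [build_config()] up to equality: per-cell matrices that are
#' constant collapse back to scalars, otherwise they are emitted as row-major
#' vectors; `build_config(config_to_list(cfg))` reproduces `cfg`.
#'
#' @param config A `wfgrid_config`.
#' @return Named list suitable for [write_config_file()] or JSON.
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "wfgrid_config"))
  flat_cell <- function(m) {
    if (is.null(m)) return(NULL)
    v <- as.vector(t(m))
    if (length(unique(v[!is.na(v)])) <= 1 && !anyNA(v)) v[1] else v
  }
  out <- list(
    grid_rows = config$grid_rows, grid_cols = config$grid_cols,
    ploidy = config$ploidy, genome_length = config$genome_length,
    mutation_rate = config$mutation_rate,
    n_generations = config$n_generations,
    initial_size = flat_cell(config$initial_size),
    carrying_capacity = flat_cell(config$carrying_capacity),
    growth_rate_mean = config$growth_rate_mean,
    growth_rate_var = config$growth_rate_var,
    extinction_prob = flat_cell(config$extinction_prob),
    migration_mode = config$migration$mode,
    selection_kind = config$selection$kind,
    fixed_s = config$selection$fixed_s,
    sign_negative = config$selection$sign_negative,
    dominance_h = config$selection$dominance_h,
    selection_multiplier = flat_cell(config$selection$multiplier),
    mutation_count_scale = config$mutation_count_scale,
    rng_seed = config$rng_seed,
    output_formats = config$output_formats
  )
  if (!is.null(config$allee)) out$allee <- flat_cell(config$allee)
  if (config$migration$mode == "adjacent_uniform") {
    out$migration_rate <- flat_cell(config$migration$rate)
  } else {
    out$migration_matrix <- as.vector(t(config$migration$rate_matrix))
  }
  if (!is.null(config$selection$gamma_shape)) {
    out$gamma_shape <- config$selection$gamma_shape
    out$gamma_scale <- config$selection$gamma_scale
  }
  if (nrow(config$events)) out$events <- config$events
  if (!is.null(config$init_snps)) out$init_snps <- config$init_snps
  if (!is.null(config$snapshot_every)) out$snapshot_every <- config$snapshot_every
  out
}

#' Read a flat YAML configuration file
#'
#' @param path Path to a YAML file whose keys match [build_config()].
#' @param overrides Named list applied on top of the file (CLI flags).
#' @return A validated `wfgrid_config`.
#' @export
read_config_file <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  for (k in c("events", "init_snps")) {
    if (!is.null(raw[[k]])) {
      raw[[k]] <- do.call(rbind, lapply(raw[[k]], function(rec) {
        as.data.frame(lapply(rec, function(v) if (is.null(v)) NA else v))
      }))
    }
  }
  raw[names(overrides)] <- overrides
  build_config(raw)
}

#' Write a configuration to a flat YAML file
#'
#' @param config A `wfgrid_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_file <- function(config, path) {
  lst <- config_to_list(config)
  for (k in c("events", "init_snps")) {
    if (!is.null(lst[[k]])) {
      df <- lst[[k]]
      lst[[k]] <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    }
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}
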