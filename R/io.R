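# Output formats: GENEPOP, PLINK text (.ped/.map), Geneland, and lossless
# JSON checkpoints. Allele coding is stable across formats: ancestral is
# 01/A/1, derived is 02/T/2. Site positions are 0-based internally and
# 1-based in every output file.

#' Assemble an export sample from the grid
#'
#' @param grid A `wfgrid_state`.
#' @param cells Optional two-column matrix/data frame of (row, col) cells to
#'   export; default all occupied cells.
#' @param n_per_cell Optional number of individuals drawn uniformly without
#'   replacement per cell (default: all individuals). Uses the grid's
#'   "sampling" RNG stream.
#' @param include_fixed If `TRUE`, globally fixed sites are appended as
#'   monomorphic derived columns (excluded by default: monomorphic loci are
#'   uninformative for downstream consumers).
#' @return Object of class `wfgrid_sample`: `list(ploidy, loci, cells)` where
#'   `cells` is a list of `list(row, col, geno)`.
#' @export
make_export_sample <- function(grid, cells = NULL, n_per_cell = NULL,
                               include_fixed = FALSE) {
  occ <- occupied_cells(grid)
  if (!length(occ)) stop("cannot export: no occupied cells")
  if (is.null(cells)) {
    idx <- occ
  } else {
    cells <- as.matrix(cells)
    idx <- cell_index(grid, as.integer(cells[, 1]), as.integer(cells[, 2]))
    if (!all(idx %in% occ)) stop("requested cell is unoccupied")
  }
  loci <- grid$loci
  take <- vector("list", length(idx))
  if (!is.null(n_per_cell)) {
    res <- rng_with(grid$rng, "sampling", function() {
      lapply(idx, function(i) {
        n <- nrow(grid$pops[[i]]$geno)
        if (n_per_cell > n) stop("n_per_cell exceeds cell size")
        sort(sample.int(n, n_per_cell))
      })
    })
    take <- res$value
  } else {
    take <- lapply(idx, function(i) seq_len(nrow(grid$pops[[i]]$geno)))
  }
  out_cells <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    rc <- cell_rc(grid, i)
    geno <- grid$pops[[i]]$geno[take[[k]], , drop = FALSE]
    if (include_fixed && nrow(grid$fixed)) {
      geno <- cbind(geno, matrix(grid$ploidy, nrow(geno), nrow(grid$fixed)))
    }
    out_cells[[k]] <- list(row = rc[["row"]], col = rc[["col"]], geno = geno)
  }
  if (include_fixed && nrow(grid$fixed)) loci <- rbind(loci, grid$fixed)
  structure(list(ploidy = grid$ploidy, loci = loci, cells = out_cells),
            class = "wfgrid_sample")
}

locus_names <- function(loci) paste0("L", loci$position + 1L)

#' Write a GENEPOP file
#'
#' Title line, one locus name per line (`L<1-based position>`), then one
#' `POP` block per cell with lines `"<row>_<col>_<id> ,  <genotypes>"`.
#' Alleles are 2-digit coded: 01 ancestral, 02 derived; diploids get 4-digit
#' genotypes (heterozygote `0102`), haploids 2-digit.
#'
#' @param sample A `wfgrid_sample` from [make_export_sample()].
#' @param path Output path.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(sample, path, title = "wfgrid simulation export") {
  check_sample(sample)
  lines <- c(title, locus_names(sample$loci))
  code <- function(d) {
    if (sample$ploidy == 2L) c("0101", "0102", "0202")[d + 1L]
    else c("01", "02")[d + 1L]
  }
  for (cell in sample$cells) {
    lines <- c(lines, "POP")
    for (i in seq_len(nrow(cell$geno))) {
      gt <- vapply(cell$geno[i, ], code, character(1))
      lines <- c(lines, paste0(cell$row, "_", cell$col, "_", i, " ,  ",
                               paste(gt, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write PLINK text files (.ped / .map)
#'
#' `.map`: `chromosome locus-id genetic-distance position` per site, with
#' chromosome 1, id `L<1-based position>`, distance 0, 1-based position.
#' `.ped`: family id `<row>_<col>`, individual id, father 0, mother 0, sex 0,
#' phenotype -9, then two allele columns per site coded A (ancestral) /
#' T (derived); heterozygotes are written `A T` (unphased).
#'
#' @param sample A diploid `wfgrid_sample`.
#' @param basepath Output path without extension; writes `<basepath>.ped`
#'   and `<basepath>.map`.
#' @return `basepath`, invisibly.
#' @export
write_plink <- function(sample, basepath) {
  check_sample(sample)
  if (sample$ploidy != 2L) {
    stop("PLINK .ped export is diploid-only; use GENEPOP or Geneland for ",
         "haploid data")
  }
  map <- sprintf("1 %s 0 %d", locus_names(sample$loci),
                 sample$loci$position + 1L)
  writeLines(map, paste0(basepath, ".map"))
  alleles <- c("A A", "A T", "T T")
  ped <- character(0)
  for (cell in sample$cells) {
    fid <- paste0(cell$row, "_", cell$col)
    for (i in seq_len(nrow(cell$geno))) {
      gt <- alleles[cell$geno[i, ] + 1L]
      ped <- c(ped, paste(fid, paste0(fid, "_", i), "0 0 0 -9",
                          paste(gt, collapse = " ")))
    }
  }
  writeLines(ped, paste0(basepath, ".ped"))
  invisible(basepath)
}

#' Write Geneland genotype and coordinates files
#'
#' Space-delimited genotype matrix without header: one row per individual,
#' two columns per locus for diploids (allele codes 1 ancestral / 2 derived,
#' missing `NA`), one column per locus for haploids. The companion
#' coordinates file has one `x y` = `col row` line per individual (cell
#' centres).
#'
#' @param sample A `wfgrid_sample`.
#' @param geno_path Genotype file path.
#' @param coord_path Coordinates file path.
#' @return `geno_path`, invisibly.
#' @export
write_geneland <- function(sample, geno_path, coord_path) {
  check_sample(sample)
  glines <- character(0)
  clines <- character(0)
  for (cell in sample$cells) {
    for (i in seq_len(nrow(cell$geno))) {
      d <- cell$geno[i, ]
      fields <- if (sample$ploidy == 2L) {
        as.vector(rbind(ifelse(d >= 1, ifelse(d == 2, "2", "1"), "1"),
                        ifelse(d >= 1, "2", "1")))
      } else {
        as.character(d + 1L)
      }
      glines <- c(glines, paste(fields, collapse = " "))
      clines <- c(clines, paste(cell$col, cell$row))
    }
  }
  writeLines(glines, geno_path)
  writeLines(clines, coord_path)
  invisible(geno_path)
}

check_sample <- function(sample) {
  stopifnot(inherits(sample, "wfgrid_sample"))
  if (!length(sample$cells) ||
      all(vapply(sample$cells, function(x) nrow(x$geno), integer(1)) == 0)) {
    stop("empty sample: no individuals to export")
  }
  if (nrow(sample$loci) == 0) {
    stop("empty sample: no sites to export (grid has no segregating sites)")
  }
  invisible(sample)
}

# ---- minimal independent parsers (round-trip verification) ----------------

#' Parse a GENEPOP file back to dosage matrices
#'
#' Minimal independent reader used to verify [write_genepop()] round trips;
#' it shares no code with the writer.
#'
#' @param path GENEPOP file.
#' @param ploidy 1 or 2 (GENEPOP genotype fields are 2 or 4 digits).
#' @return `list(loci = <names>, pops = <list of dosage matrices>)`.
#' @export
read_genepop <- function(path, ploidy = 2) {
  lines <- readLines(path)
  pop_at <- which(toupper(trimws(lines)) == "POP")
  stopifnot(length(pop_at) >= 1)
  loci <- trimws(lines[2:(pop_at[1] - 1)])
  bounds <- c(pop_at, length(lines) + 1L)
  pops <- vector("list", length(pop_at))
  for (b in seq_along(pop_at)) {
    block <- lines[seq(bounds[b] + 1L, bounds[b + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    geno <- matrix(NA_integer_, length(block), length(loci))
    for (i in seq_along(block)) {
      parts <- strsplit(block[i], ",", fixed = TRUE)[[1]]
      gts <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
      stopifnot(length(gts) == length(loci))
      for (j in seq_along(gts)) {
        codes <- substring(gts[j], seq(1, nchar(gts[j]), 2),
                           seq(2, nchar(gts[j]), 2))
        stopifnot(length(codes) == ploidy)
        geno[i, j] <- sum(codes == "02")
      }
    }
    pops[[b]] <- geno
  }
  list(loci = loci, pops = pops)
}

#' Parse PLINK text files back to a dosage matrix
#'
#' @param basepath Path without extension (expects `.ped` and `.map`).
#' @return `list(map = <data frame>, fid = <family ids>, geno = <dosage
#'   matrix>)`.
#' @export
read_plink <- function(basepath) {
  map <- utils::read.table(paste0(basepath, ".map"),
                           col.names = c("chr", "id", "cm", "pos"))
  ped <- utils::read.table(paste0(basepath, ".ped"),
                           colClasses = "character")
  stopifnot(ncol(ped) == 6 + 2 * nrow(map))
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  stopifnot(all(al %in% c("A", "T")))
  tcount <- al == "T"
  geno <- tcount[, seq(1, ncol(al), 2), drop = FALSE] +
    tcount[, seq(2, ncol(al), 2), drop = FALSE]
  storage.mode(geno) <- "integer"
  list(map = map, fid = ped[[1]], geno = geno)
}

#' Parse Geneland genotype and coordinates files
#'
#' @param geno_path,coord_path Paths written by [write_geneland()].
#' @param ploidy 1 or 2.
#' @return `list(geno = <dosage matrix>, coords = <data frame x, y>)`.
#' @export
read_geneland <- function(geno_path, coord_path, ploidy = 2) {
  g <- as.matrix(utils::read.table(geno_path))
  coords <- utils::read.table(coord_path, col.names = c("x", "y"))
  stopifnot(nrow(g) == nrow(coords))
  if (ploidy == 2L) {
    geno <- (g[, seq(1, ncol(g), 2), drop = FALSE] == 2) +
      (g[, seq(2, ncol(g), 2), drop = FALSE] == 2)
  } else {
    geno <- g == 2
  }
  storage.mode(geno) <- "integer"
  list(geno = geno, coords = coords)
}

# ---- checkpointing ---------------------------------------------------------

CHECKPOINT_FORMAT <- "wfgrid-checkpoint"
CHECKPOINT_VERSION <- 1L

#' Write a lossless simulator checkpoint
#'
#' Serialises the full configuration and state (including the per-phase RNG
#' stream states and the fixed-site registry) to versioned JSON, so a later
#' run can resume exactly where this one stopped — the mechanism for
#' temporally varying parameters across chained runs.
#'
#' @param grid A `wfgrid_state`.
#' @param config The `wfgrid_config` that produced it.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(grid, config, path) {
  stopifnot(inherits(grid, "wfgrid_state"), inherits(config, "wfgrid_config"))
  pops <- lapply(grid$pops, function(p) {
    if (is.null(p)) NULL
    else list(n = nrow(p$geno), geno = as.vector(p$geno))
  })
  obj <- list(
    format = CHECKPOINT_FORMAT,
    version = CHECKPOINT_VERSION,
    config = config_to_list(config),
    state = list(
      nrow = grid$nrow, ncol = grid$ncol, ploidy = grid$ploidy,
      genome_length = grid$genome_length, generation = grid$generation,
      n_sites = n_sites(grid),
      loci = grid$loci, fixed = grid$fixed,
      pops = pops,
      rng = lapply(grid$rng, as.integer)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "columns")
  invisible(path)
}

#' Read a checkpoint
#'
#' @param path File written by [write_checkpoint()].
#' @return `list(state = <wfgrid_state>, config = <wfgrid_config>)`, directly
#'   usable as the `initial` argument of [run_simulation()].
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$format, CHECKPOINT_FORMAT)) {
    stop("not a wfgrid checkpoint: ", path)
  }
  if (!identical(as.integer(obj$version), CHECKPOINT_VERSION)) {
    stop("unsupported checkpoint version: ", obj$version)
  }
  cfg_list <- obj$config
  for (k in c("events", "init_snps")) {
    if (!is.null(cfg_list[[k]]) && !is.data.frame(cfg_list[[k]])) {
      cfg_list[[k]] <- as.data.frame(cfg_list[[k]])
    }
  }
  config <- build_config(cfg_list)
  st <- obj$state
  fix_loci <- function(df) {
    if (is.null(df) || (is.data.frame(df) && nrow(df) == 0) ||
        (is.list(df) && !length(df))) {
      return(new_locus_table())
    }
    df <- as.data.frame(df)
    for (col in c("position", "origin_generation", "origin_row",
                  "origin_col")) {
      df[[col]] <- as.integer(df[[col]])
    }
    df$s <- as.numeric(df$s)
    df[c("position", "origin_generation", "origin_row", "origin_col", "s")]
  }
  loci <- fix_loci(st$loci)
  S <- nrow(loci)
  pops <- lapply(st$pops, function(p) {
    if (is.null(p)) return(NULL)
    geno <- matrix(as.integer(unlist(p$geno)), nrow = p$n, ncol = S)
    list(geno = geno)
  })
  grid <- structure(list(
    nrow = as.integer(st$nrow), ncol = as.integer(st$ncol),
    ploidy = as.integer(st$ploidy),
    genome_length = as.integer(st$genome_length),
    generation = as.integer(st$generation),
    pops = pops, loci = loci, fixed = fix_loci(st$fixed),
    rng = lapply(st$rng, as.integer)
  ), class = "wfgrid_state")
  list(state = grid, config = config)
}

#' Write all configured outputs for a finished run
#'
#' @param result A `wfgrid_result`.
#' @param out_dir Directory (created if needed).
#' @param basename File name stem, default `"final"`.
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(result, out_dir, basename = "final") {
  stopifnot(inherits(result, "wfgrid_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- result$state
  config <- result$config
  files <- character(0)
  genotype_formats <- intersect(config$output_formats,
                                c("genepop", "plink", "geneland"))
  if (length(genotype_formats) && length(occupied_cells(grid)) &&
      n_sites(grid) > 0) {
    sample <- make_export_sample(grid)
    for (fmt in genotype_formats) {
      if (fmt == "genepop") {
        f <- file.path(out_dir, paste0(basename, ".gen"))
        write_genepop(sample, f)
        files <- c(files, f)
      } else if (fmt == "plink") {
        base <- file.path(out_dir, basename)
        write_plink(sample, base)
        files <- c(files, paste0(base, c(".ped", ".map")))
      } else {
        f <- file.path(out_dir, paste0(basename, "_geneland.txt"))
        fc <- file.path(out_dir, paste0(basename, "_coords.txt"))
        write_geneland(sample, f, fc)
        files <- c(files, f, fc)
      }
    }
  }
  if ("checkpoint" %in% config$output_formats) {
    f <- file.path(out_dir, paste0(basename, "_checkpoint.json"))
    write_checkpoint(grid, config, f)
    files <- c(files, f)
  }
  invisible(files)
}
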