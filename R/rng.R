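# Named per-phase RNG streams derived from one master seed.
#
# Each stochastic phase of the generation cycle (extinction, migration,
# mutation, selection-coefficient assignment, growth, reproduction, plus
# grid initialisation and output sampling) draws from its own L'Ecuyer-CMRG
# stream. Streams are derived deterministically from the master seed with
# parallel::nextRNGStream(), so adding draws in one phase never perturbs
# another phase's sequence, and the full set of stream states is a plain
# list of integer vectors that serialises losslessly into checkpoints.

RNG_PHASES <- c("init", "extinction", "migration", "mutation", "selection",
                "growth", "reproduction", "sampling")

#' Create named per-phase RNG streams from a master seed
#'
#' @param seed Integer master seed.
#' @return Named list of L'Ecuyer-CMRG `.Random.seed` states, one per phase.
#' @keywords internal
rng_make_streams <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", length(RNG_PHASES))
  names(streams) <- RNG_PHASES
  for (p in RNG_PHASES) {
    s <- parallel::nextRNGStream(s)
    streams[[p]] <- s
  }
  streams
}

rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

rng_restore <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate a function under one named stream, advancing it
#'
#' Runs `fn()` with `.Random.seed` set to the stream `phase`, captures the
#' advanced state back into the stream list, and restores the caller's RNG.
#'
#' @param streams Named list from [rng_make_streams()].
#' @param phase Stream name.
#' @param fn Zero-argument function performing the random draws.
#' @return `list(streams = <updated streams>, value = fn())`.
#' @keywords internal
rng_with <- function(streams, phase, fn) {
  if (!phase %in% names(streams)) {
    stop("unknown RNG stream: ", phase)
  }
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  assign(".Random.seed", streams[[phase]], envir = globalenv())
  value <- fn()
  streams[[phase]] <- get(".Random.seed", envir = globalenv())
  list(streams = streams, value = value)
}
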