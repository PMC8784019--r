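#' Reproducible random-number streams for simulation cells
#'
#' The experiment derives one independent L'Ecuyer-CMRG stream per scenario
#' cell from a single master seed, and one substream per replicate within a
#' cell. Any single replicate is therefore reproducible in isolation without
#' re-running the replicates before it in a different cell.
#'
#' @param seed Master seed (single integer).
#' @return A `.Random.seed`-compatible integer vector for the master stream.
#' @keywords internal
master_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old_kind <- RNGkind()
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(as.integer(seed))
  get(".Random.seed", envir = globalenv())
}

#' Stream for the `index`-th scenario cell (1-based)
#' @keywords internal
cell_stream <- function(master, index) {
  stopifnot(index >= 1L)
  s <- master
  for (i in seq_len(index)) s <- parallel::nextRNGStream(s)
  s
}

#' Substream for the `rep`-th replicate within a cell stream (1-based)
#'
#' O(rep); loops advance incrementally instead, this accessor exists so a
#' single replicate can be reconstructed on its own.
#' @keywords internal
replicate_stream <- function(cell, rep) {
  stopifnot(rep >= 1L)
  s <- cell
  for (i in seq_len(rep)) s <- parallel::nextRNGSubStream(s)
  s
}

#' Evaluate code with the global RNG state set to `state`, then restore
#' @keywords internal
with_rng_state <- function(state, code) {
  old_kind <- RNGkind()
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  assign(".Random.seed", state, envir = globalenv())
  code
}
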