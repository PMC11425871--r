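# Shared constants and small helpers.

#' The 20 canonical amino-acid one-letter codes
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Derive a stage seed from a master seed
#'
#' Per-stage seeds are derived deterministically from one master seed so a
#' whole run is reproducible while stages stay independently re-runnable.
#' The result always fits in a 32-bit signed integer.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(master_seed)) * 10007 + h) %% 2147483647L)
}

#' Run an expression with a locally seeded RNG
#'
#' Saves and restores `.Random.seed` so package functions never perturb the
#' caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent prefix for input-contract violations
abort_input <- function(...) stop(..., call. = FALSE)
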