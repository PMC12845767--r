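#' Derive a reproducible child seed for a named random stream
#'
#' One master seed drives a whole simulation run; each sampled input variable
#' gets its own child stream keyed by name, so adding or removing a variable
#' never perturbs the draws of the others, and the lower-bound and upper-bound
#' scenarios share identical draws under a common master seed.
#'
#' The child seed is a 31-bit polynomial string hash of the stream name folded
#' together with the master seed (both reduced modulo 2^31 - 1).
#'
#' @param master Integer master seed.
#' @param name Character stream name, e.g. `"BAF"` or `"intake_rice"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' child_seed(42, "BAF")
#' child_seed(42, "intake_rice")
#' @export
child_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name),
            length(name) == 1L, nzchar(name))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- abs(as.numeric(master)) %% m
  for (ch in utf8ToInt(name)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# evaluate expr under a named child stream of `master`, restoring RNG state
with_stream <- function(master, name, expr) {
  withr::with_seed(child_seed(master, name), expr)
}
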