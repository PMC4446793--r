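#' Derive a labelled RNG stream seed from a master seed
#'
#' Every stochastic operation in the package draws its randomness from a
#' stream seeded by `derive_seed(master, label)`, where `label` names the
#' operation. Adding a new operation (a new label) therefore never perturbs
#' the output of existing ones run under the same master seed.
#'
#' The derivation is a small polynomial rolling hash of the label folded
#' with the master seed, reduced modulo 2^31 - 1; all intermediate products
#' stay below 2^53 so the arithmetic is exact in double precision.
#'
#' @param master integer master seed.
#' @param label character scalar naming the stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  s <- (h * 31 + (as.double(master) %% m)) %% m
  # avoid the degenerate seeds 0 and m-1
  as.integer(s %% (m - 2L) + 1L)
}

# Run `expr` with a temporary RNG state seeded from (master, label).
with_stream <- function(master, label, expr) {
  withr::with_seed(derive_seed(master, label), expr)
}
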