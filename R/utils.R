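# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All stochastic stages draw their seed through this function so that one
#' master seed fully determines a run while stages stay decoupled (adding a
#' stage does not perturb the streams of the others).  The result is always
#' a valid 32-bit integer seed.
#'
#' @param seed integer master seed.
#' @param salt character label of the consuming stage.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(salt))
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  # multiplicative congruential mix, kept below 2^31 - 1; the product is
  # at most (2^31)(48271) < 2^53, exact in double arithmetic
  m <- 2147483647
  as.integer((((abs(seed) %% m) * 48271) %% m + h) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_winsig <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "winsig_error")))
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_winsig(sprintf("`%s` must be a positive integer scalar", name),
                "winsig_bad_argument")
  as.numeric(x)
}
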