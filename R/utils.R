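# internal helpers shared across modules

# logistic gate steady state; k > 0 activates with depolarization,
# k < 0 activates with hyperpolarization
sigmoid_inf <- function(v, v_half, k) 1 / (1 + exp((v_half - v) / k))

# derive a child seed from a master seed and an index path; stays < 2^31
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
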