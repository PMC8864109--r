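# internal helpers shared across modules

# locale-independent ordering so outputs are byte-identical across machines
sort_ids <- function(x) {
  if (length(x) == 0) return(character(0))
  sort(x, method = "radix")
}

order_ids <- function(...) order(..., method = "radix")

# variance-stabilized scale for the moderated tests
log2p1 <- function(x) log2(x + 1)

# unbounded log scale for correlations: abundances are positive, zeros are
# guarded by a tiny floor instead of a +1 pseudo-count (which would compress
# low-abundance features and attenuate strong correlations)
log2_safe <- function(x) log2(pmax(x, 2^-20))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
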