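# shared helpers

# clamp a vector or matrix to per-coordinate box bounds (scalars recycle)
clip_box <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

# derive a child seed from a base seed and a stream index; stays < 2^31
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(stream)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
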