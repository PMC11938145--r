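`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot() with a readable message
.check <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

.is_num <- function(x) is.numeric(x) && all(is.finite(x))

# seeds derived from a master seed stay below 2^31
.derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}
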