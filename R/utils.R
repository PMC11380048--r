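# Internal helpers: classed conditions and scoped RNG.

stop_config <- function(msg, field = NULL, call. = FALSE) {
  stop(errorCondition(msg, class = c("resistseq_config_error", "resistseq_error"),
                      field = field))
}

stop_data <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("resistseq_data_error", "resistseq_error")))
}

stop_training <- function(msg) {
  stop(errorCondition(msg, class = c("resistseq_training_error", "resistseq_error")))
}

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage/per-model seed derivation, kept inside 32-bit range.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (o in offs) s <- (s * 69069 + as.double(o) + 1) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log2_tpm <- function(tpm) log2(tpm + 1)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == floor(x)
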