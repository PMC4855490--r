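# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!(is.numeric(seed) && length(seed) == 1L && is.finite(seed)))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_positive <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0))
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0))
    stop(sprintf("`%s` must be a single non-negative number", name),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) &&
        x >= min && x == as.integer(x)))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
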