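# Internal helpers: typed error conditions and seeded evaluation.

stop_value <- function(msg, ...) {
  stop(structure(
    class = c("cellrisk_value_error", "cellrisk_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_schema <- function(msg, ...) {
  stop(structure(
    class = c("cellrisk_schema_error", "cellrisk_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_integrity <- function(msg, ...) {
  stop(structure(
    class = c("cellrisk_integrity_error", "cellrisk_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ordinal disease-state coding used throughout: ND=0, preT2D=1, T2D=2.
STATE_LEVELS <- c(ND = 0L, preT2D = 1L, T2D = 2L)

state_label <- function(code) names(STATE_LEVELS)[match(code, STATE_LEVELS)]
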