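# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-unit RNG substream seed from a master seed; stays a valid
# 32-bit integer so adding units never perturbs earlier ones.
substream_seed <- function(master_seed, index, stream = 0L) {
  base <- (as.numeric(master_seed) + 9973 * as.numeric(index) +
             7919 * as.numeric(stream)) %% (.Machine$integer.max - 1)
  as.integer(base) + 1L
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_not_count <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a single positive integer.", name))
  }
  invisible(as.integer(x))
}

stop_not_scalar <- function(x, name, lo = -Inf, hi = Inf,
                            lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1 && is.numeric(x) && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) abort(sprintf("`%s` must be a finite scalar in the valid range.", name))
  invisible(as.numeric(x))
}

# Machine-parseable log line: <ISO timestamp>\t<LEVEL>\t<stage>\t<message>
log_line <- function(stage, msg, level = "INFO", verbose = TRUE) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  ts <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  message(sprintf("%s\t%s\t%s\t%s", ts, level, stage, msg))
  invisible(NULL)
}
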