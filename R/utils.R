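# Internal validation helpers. All user-facing errors are classed so the
# pipeline can distinguish configuration errors from stage failures.

stop_config <- function(msg, ...) {
  abort(msg, class = "proxitome_config_error", ...)
}

stop_value <- function(msg, ...) {
  abort(msg, class = "proxitome_value_error", ...)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_value(sprintf("`%s` must be a single non-missing number.", name))
  }
  low_ok <- if (strict_min) x > min else x >= min
  if (!low_ok || x > max) {
    stop_value(sprintf("`%s` = %g is out of range.", name, x))
  }
  invisible(x)
}

# Deterministic 32-bit sub-seed derived from a master seed and a stream
# label, so independent generators never share an RNG stream.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 10007 + h) %% 2147483647)
}

`%||%` <- rlang::`%||%`

# Evaluates `code` under `seed` and restores the caller's RNG state, so
# seeded generators never perturb the global random stream.
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
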