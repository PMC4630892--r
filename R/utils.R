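# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  rlang::abort(paste0(...), class = "gencor_config_error")
}

stop_structure <- function(...) {
  rlang::abort(paste0(...), class = "gencor_structure_error")
}

stop_numeric <- function(...) {
  rlang::abort(paste0(...), class = "gencor_numeric_error")
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop_config("`", name, "` must be a single integer >= ", min, ".")
  }
  as.integer(x)
}

check_proportion <- function(x, name, lo = 0, hi = 1,
                             lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_config("`", name, "` must be a single number in ",
                if (lo_open) "(" else "[", lo, ", ", hi,
                if (hi_open) ")" else "]", ".")
  }
  as.numeric(x)
}

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so simulators do not perturb the session stream.
with_seed_preserved <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# zero-padded id labels: id_labels("BB_C", 3) -> "BB_C001" ...
id_labels <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(3L, nchar(as.character(n))), seq_len(n))
}
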