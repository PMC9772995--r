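#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards. seed = NULL runs
# `code` under the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Counter-based derivation: the master seed and any number of integer
#' keys (year, repetition, stage code, ...) are folded through a
#' multiplicative congruential hash modulo 2^31 - 1, so child streams
#' are decoupled and adding keys later in the sequence does not change
#' earlier children. Deterministic and platform-independent.
#'
#' @param seed master seed (integer) or NULL (returns NULL: free-running RNG).
#' @param ... further integer keys.
#' @return an integer seed in [1, 2^31 - 2], or NULL.
#' @export
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  keys <- c(seed, ...)
  h <- 0
  for (k in keys) {
    h <- (h * 69069 + (as.numeric(k) %% 2147483646) + 1) %% 2147483647
  }
  as.integer(h + 1)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_config(field, "must be TRUE or FALSE")
  }
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_number <- function(x, field, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_min) x > min else x >= min) &&
    (if (strict_max) x < max else x <= max)
  if (!ok) {
    stop_config(field, sprintf("must be a single number in %s%g, %g%s",
                               if (strict_min) "(" else "[", min, max,
                               if (strict_max) ")" else "]"))
  }
  as.numeric(x)
}
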