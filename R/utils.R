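#' @keywords internal
"_PACKAGE"

# Shared input checks and seed plumbing.

stop_invalid <- function(...) {
  stop(structure(
    class = c("lodlamp_invalid_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(name, " must be a single finite number")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_invalid(name, " = ", format(x), " outside the allowed range [",
                 lower, ", ", upper, "]",
                 if (strict_lower || strict_upper) " (open bound)" else "")
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(name, " must be TRUE or FALSE")
  }
  invisible(x)
}

#' Derive a deterministic child seed from a master seed
#'
#' A single global seed fans out to per-module seeds so that modules stay
#' independently reproducible. The derivation is a fixed affine map modulo
#' a Mersenne prime, keeping every child strictly below 2^31.
#'
#' @param master_seed single integer master seed.
#' @param stream integer stream index (0, 1, 2, ...).
#' @return a single integer seed in [1, 2^31 - 2].
#' @export
child_seed <- function(master_seed, stream) {
  check_number(master_seed, "master_seed")
  check_number(stream, "stream", lower = 0)
  m <- 2147483647               # 2^31 - 1
  s <- (as.double(master_seed) %% m) + 1
  ((s * 48271 + as.double(stream) * 10007) %% (m - 1)) + 1
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
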