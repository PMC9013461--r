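## Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library functions taking a
#' `seed` argument do not disturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Stage- and antenna-level seeds are derived by hashing the key into
#' the master seed so stages can be re-run independently yet
#' reproducibly. The result is kept strictly below 2^31.
#'
#' @param seed integer master seed.
#' @param key character scalar (stage name, antenna id, ...).
#' @return integer in `[0, 2^31)`.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

## near-equality tolerant comparison for time-grid arithmetic
.time_eps <- 1e-9

stop_config <- function(...) {
  stop(structure(class = c("eag_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
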