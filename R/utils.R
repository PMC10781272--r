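# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' `.Random.seed` afterwards, so seeded package internals never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Mix a base seed with extra integer components into a single seed < 2^31.
# Deterministic, order-sensitive, overflow-safe (double arithmetic).
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  acc <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    acc <- (acc * 69069 + v + 1) %% 2147483647
  }
  as.integer(acc)
}

stop_config <- function(...) {
  stop(structure(class = c("moodcast_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("moodcast_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# round-half-away-from-zero (base round() is round-half-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
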