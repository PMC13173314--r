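#' @keywords internal
"_PACKAGE"

# Run expr with a temporarily seeded RNG, restoring global RNG state after.
# All generators funnel randomness through here so that identical
# (params, seed) pairs give identical outputs without disturbing the caller.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("drusenmorph_invalid", "error")))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid("`", name, "` must be a single positive finite number")
  }
  invisible(x)
}

# Fractional position -> 0-based pixel index, round-half-down.
# round_half_down(0.5) == 0, round_half_down(1.5) == 1.
round_half_down <- function(x) as.integer(ceiling(round(x, 9) - 0.5))

# Sampling rule shared by reslicing and in-plane line positions:
# fractional positions 0.05, 0.15, ..., 0.95 of `n` pixels.
grid_indices <- function(n) {
  if (n < 10L) stop_invalid("need at least 10 pixels along a sampled axis, got ", n)
  fr <- seq(0.05, 0.95, by = 0.10)
  idx <- round_half_down(fr * n)
  pmin(pmax(idx, 0L), n - 1L)
}
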