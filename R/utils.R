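# internal helpers shared across modules

# Deterministic per-stage seed derived from a user seed and a stage tag, kept
# below 2^31 so it is always a valid R integer seed.
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 131 + h) %% 2147483629)
}

# p-values below the double underflow range are clamped rather than printed
# as 0 (real summary statistics contain such rows).
P_CLAMP <- 1e-300

clamp_p <- function(p) pmin(pmax(p, P_CLAMP), 1)

# two-sided normal p from a z score, clamped into (0, 1]
z_to_p <- function(z) clamp_p(2 * pnorm(-abs(z)))

# |z| from a two-sided p-value
p_to_z <- function(p) qnorm(clamp_p(p) / 2, lower.tail = FALSE)

fail <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    fail("`%s` must be a single finite number", name)
  }
  lo <- if (open_left) x > 0 else x >= 0
  hi <- if (open_right) x < 1 else x <= 1
  if (!lo || !hi) fail("`%s` out of range: %g", name, x)
  invisible(x)
}
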