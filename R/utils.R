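#' @keywords internal
"_PACKAGE"

# Validation helper: stop with the caller's message when a condition fails.
abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

#' Derive a reproducible stage seed from a global seed
#'
#' A single pipeline seed fans out to per-stage, per-subject seeds through a
#' small integer hash, so any stage can be re-run in isolation and still
#' produce the bytes it produced inside the full run. Results stay below
#' 2^31 - 1 so they are always representable as R integers.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label (e.g. "cohort", "train").
#' @param index Optional integer index (e.g. subject number) within the stage.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  abort_if(!is.numeric(seed) || length(seed) != 1L || !is.finite(seed),
           "`seed` must be a single finite number")
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  val <- (abs(as.numeric(seed)) %% 1e6) * 1021 + h * 7919 + as.numeric(index) * 104729
  as.integer(val %% (2^31 - 1))
}

# von Mises sampler (Best & Fisher 1979 rejection algorithm).
# kappa = 0 gives uniform on (-pi, pi]; kappa = Inf gives exactly mu.
rvonmises <- function(n, mu = 0, kappa = 1) {
  abort_if(!is.finite(kappa) && !is.infinite(kappa), "kappa must be >= 0")
  abort_if(kappa < 0, "kappa must be >= 0")
  if (is.infinite(kappa)) return(rep(mu, n))
  if (kappa == 0) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  wrap_phase(out)
}

# Wrap angles into (-pi, pi].
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
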