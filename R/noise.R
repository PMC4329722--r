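#' Ornstein-Uhlenbeck noise configuration
#'
#' The background input noise is an OU process
#' `d xi/dt = -xi/tau + (sqrt(2 D)/tau) * xi_w(t)` with unit-intensity
#' Gaussian white noise `xi_w`. Under this amplitude convention the
#' stationary standard deviation is `sqrt(D / tau)`.
#'
#' @param D Noise intensity (Hz). `D = 0` switches the noise off.
#' @param tau Correlation time (s), > 0.
#' @return An object of class `ou_config`.
#' @export
#' @examples
#' ou_stationary_std(ou_config(D = 350, tau = 0.15)) # about 48.3 Hz
ou_config <- function(D = 350, tau = 0.15) {
  if (!is.finite(D) || D < 0) stop("noise intensity D must be >= 0")
  if (!is.finite(tau) || tau <= 0) stop("correlation time tau must be > 0")
  structure(list(D = D, tau = tau), class = "ou_config")
}

#' Stationary standard deviation of the OU noise
#'
#' @param cfg An [ou_config()] object.
#' @return `sqrt(D / tau)` (Hz).
#' @export
ou_stationary_std <- function(cfg) {
  sqrt(cfg$D / cfg$tau)
}

#' One stochastic Heun update of the OU noise
#'
#' Advances the OU process by one step of size `h` with white-noise draw `w`
#' (standard normal), using the same predictor-corrector scheme as the
#' network integrator: the predictor is an Euler step, the corrector averages
#' the drift at both ends, and the identical noise increment enters both
#' stages.
#'
#' @param xi Current noise value (Hz). Vectorized.
#' @param cfg An [ou_config()] object.
#' @param h Step size (s), > 0.
#' @param w Standard normal draw(s), same length as `xi`.
#' @return Updated noise value(s) (Hz).
#' @export
ou_step <- function(xi, cfg, h, w) {
  if (h <= 0) stop("step size must be positive")
  cn <- sqrt(2 * cfg$D) / cfg$tau * sqrt(h)
  xi_p <- xi - h * xi / cfg$tau + cn * w
  xi - 0.5 * h * (xi + xi_p) / cfg$tau + cn * w
}

#' Simulate an OU noise path
#'
#' Generates `n` Heun steps of the OU process. The update is linear, so the
#' whole path is computed by a recursive filter. The initial value defaults
#' to a draw from the stationary distribution.
#'
#' @param n Number of steps.
#' @param cfg An [ou_config()] object.
#' @param h Step size (s).
#' @param seed Integer seed; ignored when `w` is supplied.
#' @param xi0 Initial value (Hz); `NULL` draws from the stationary
#'   distribution.
#' @param w Optional vector of `n` standard normal draws.
#' @return Numeric vector of length `n + 1` (including the initial value).
#' @export
ou_path <- function(n, cfg, h = 0.001, seed = 1, xi0 = NULL, w = NULL) {
  if (is.null(w)) {
    w <- with_local_seed(seed, rnorm(n))
  }
  if (is.null(xi0)) {
    xi0 <- with_local_seed(seed + 1L, rnorm(1, 0, ou_stationary_std(cfg)))
  }
  q <- h / cfg$tau
  alpha <- 1 - q + q^2 / 2
  beta <- sqrt(2 * cfg$D) / cfg$tau * sqrt(h) * (1 - q / 2)
  path <- stats::filter(beta * w, alpha, method = "recursive",
                        init = xi0)
  c(xi0, as.numeric(path))
}

#' Derive a per-column RNG seed
#'
#' Stable splitting rule used to give every column an independent white-noise
#' stream: `(seed + 1000003 * i) mod (2^31 - 1)`. A column's noise therefore
#' depends only on the master seed and its own index, not on `N`.
#'
#' @param seed Master integer seed.
#' @param i Column index (1-based).
#' @return Integer seed for column `i`.
#' @export
column_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483647)
}

#' Matrix of white-noise increments for a network run
#'
#' One column of standard normal draws per cortical column, each generated
#' from its [column_seed()] substream.
#'
#' @param nsteps Number of integration steps.
#' @param N Number of columns.
#' @param seed Master seed.
#' @param shared If `TRUE`, every column receives the same stream (a test
#'   mode in which identically initialized columns stay identical forever).
#' @return `nsteps x N` numeric matrix.
#' @export
white_noise_matrix <- function(nsteps, N, seed, shared = FALSE) {
  W <- matrix(0, nsteps, N)
  for (i in seq_len(N)) {
    s <- if (shared) column_seed(seed, 1L) else column_seed(seed, i)
    W[, i] <- with_local_seed(s, rnorm(nsteps))
  }
  W
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
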