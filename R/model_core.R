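#' Sigmoid firing-rate function
#'
#' Maps the mean membrane potential of a population to its mean firing rate,
#' `2 * e0 / (1 + exp(r * (v0 - y)))`. The rate is bounded in `(0, 2 e0)`,
#' strictly increasing, and equals `e0` at `y = v0`.
#'
#' @param y Membrane potential(s), mV. Vectorized.
#' @param params A [jr_params()] object.
#' @return Firing rate(s), 1/s.
#' @export
sigmoid <- function(y, params = jr_params()) {
  if (any(!is.finite(y))) stop("sigmoid input must be finite")
  2 * params$e0 / (1 + exp(params$r * (params$v0 - y)))
}

#' Derivative of the sigmoid rate function
#'
#' `Sigm'(y) = r * Sigm(y) * (1 - Sigm(y) / (2 e0))`; used by the analytic
#' Jacobian of the column equations.
#'
#' @inheritParams sigmoid
#' @return Rate derivative(s), 1/(s mV).
#' @export
sigmoid_deriv <- function(y, params = jr_params()) {
  s <- sigmoid(y, params)
  params$r * s * (1 - s / (2 * params$e0))
}

#' Time derivative of a single column state
#'
#' Evaluates the six-dimensional first-order form of the column equations:
#' the pyramidal feedback potential `y0`, the excitatory and inhibitory
#' potentials `y1`, `y2` entering the pyramidal population, and their
#' derivatives `z0`, `z1`, `z2`. `p_exc` is the full excitatory input to the
#' pyramidal population (constant + coupling + periodic + noise); it may be
#' negative, no rectification is applied.
#'
#' @param state Numeric vector of length 6: `c(y0, y1, y2, z0, z1, z2)`.
#' @param p_exc Total excitatory pyramidal input (Hz).
#' @param params A [jr_params()] object.
#' @return Numeric vector of length 6: the time derivative of `state`.
#' @export
column_derivatives <- function(state, p_exc, params = jr_params()) {
  if (length(state) != 6 || any(!is.finite(state))) {
    stop("state must be 6 finite values (y0,y1,y2,z0,z1,z2)")
  }
  if (!is.finite(p_exc)) stop("p_exc must be finite")
  y0 <- state[1]; y1 <- state[2]; y2 <- state[3]
  z0 <- state[4]; z1 <- state[5]; z2 <- state[6]
  with(params, c(
    z0, z1, z2,
    A * a * sigmoid(y1 - y2, params) - 2 * a * z0 - a^2 * y0,
    A * a * (p_exc + C2 * sigmoid(C1 * y0, params)) - 2 * a * z1 - a^2 * y1,
    B * b * C4 * sigmoid(C3 * y0, params) - 2 * b * z2 - b^2 * y2
  ))
}

#' Inter-column coupling inputs
#'
#' Excitatory firing-rate input each column receives from the others,
#' normalized by the number of afferent connections:
#' `coup_i = (1/(N-1)) * sum_{j != i} K[j, i] * Sigm(y1_j - y2_j)`.
#' For a single column the coupling is zero.
#'
#' @param state A [jr_state()] object or a `6 x N` state matrix.
#' @param net A [jr_network()] object.
#' @param params A [jr_params()] object.
#' @return Numeric vector of length `N`, coupling input per column (Hz).
#' @export
coupling_inputs <- function(state, net, params = jr_params()) {
  cols <- if (inherits(state, "jr_state")) state$columns else as.matrix(state)
  N <- ncol(cols)
  if (N != net$N) stop("state and network configuration disagree on N")
  if (N == 1) return(0)
  rates <- sigmoid(cols[2, ] - cols[3, ], params)
  as.numeric(crossprod(net$K, rates)) / (N - 1)
}

#' Total excitatory pyramidal input
#'
#' Sum of the constant component, the inter-column coupling, the deterministic
#' periodic drive evaluated at time `t`, and the column's OU noise value. This
#' is the `p_exc` fed to [column_derivatives()].
#'
#' @param t Time (s).
#' @param i Column index.
#' @param state A [jr_state()] object.
#' @param net A [jr_network()] object.
#' @param drive A [drive_spec()] object.
#' @param params A [jr_params()] object.
#' @return Total input (Hz).
#' @export
total_pyramidal_input <- function(t, i, state, net, drive = drive_spec("none"),
                                  params = jr_params()) {
  net$p_const + coupling_inputs(state, net, params)[i] +
    drive_signal(drive, t) + state$noise[i]
}

#' EEG observable
#'
#' The model's EEG proxy: per column the difference between the excitatory and
#' inhibitory postsynaptic potentials of the pyramidal population,
#' `y1 - y2`, and their unweighted average across columns (the electrode-like
#' aggregate signal).
#'
#' @param state A [jr_state()] object or `6 x N` state matrix.
#' @return A list with `per_column` (mV, length `N`) and `average` (mV).
#' @export
eeg_observable <- function(state) {
  cols <- if (inherits(state, "jr_state")) state$columns else as.matrix(state)
  v <- cols[2, ] - cols[3, ]
  list(per_column = as.numeric(v), average = mean(v))
}
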