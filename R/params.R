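#' Jansen-Rit column parameters
#'
#' Constructs the shared parameter set of a cortical column: postsynaptic
#' potential amplitudes, inverse synaptic time constants, intra-column
#' connectivity constants, and the sigmoid rate function parameters. Defaults
#' are the canonical Jansen-Rit values.
#'
#' @param A Maximum excitatory postsynaptic potential amplitude (mV).
#' @param B Maximum inhibitory postsynaptic potential amplitude (mV).
#' @param a Excitatory inverse synaptic time constant (1/s).
#' @param b Inhibitory inverse synaptic time constant (1/s).
#' @param C1,C2,C3,C4 Dimensionless intra-column connectivity constants.
#' @param e0 Half of the maximum population firing rate (1/s); the sigmoid
#'   saturates at `2 * e0`.
#' @param v0 Membrane potential at which the firing rate is half-maximal (mV).
#' @param r Sigmoid steepness (1/mV).
#'
#' @return An object of class `jr_params` (a named list).
#' @export
#' @examples
#' p <- jr_params()
#' sigmoid(p$v0, p) # half the maximum rate, e0
jr_params <- function(A = 3.25, B = 22, a = 100, b = 50,
                      C1 = 135, C2 = 0.8 * 135, C3 = 0.25 * 135,
                      C4 = 0.25 * 135, e0 = 2.5, v0 = 6, r = 0.56) {
  p <- list(A = A, B = B, a = a, b = b, C1 = C1, C2 = C2, C3 = C3, C4 = C4,
            e0 = e0, v0 = v0, r = r)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all Jansen-Rit parameters must be finite and strictly positive")
  }
  if (C2 > C1) {
    warning("C2 > C1 departs from the canonical parameterization")
  }
  if (abs(C3 - C4) > 1e-12 * max(C3, C4)) {
    warning("C3 != C4 departs from the canonical parameterization")
  }
  structure(p, class = "jr_params")
}

#' Network configuration
#'
#' Describes a homogeneous all-to-all network of identical columns: its size,
#' the inter-column connectivity matrix, and the constant component of the
#' external pyramidal input.
#'
#' @param N Number of columns (integer, >= 1).
#' @param K Either a single nonnegative coupling strength (expanded to a
#'   homogeneous all-to-all matrix with zero diagonal) or a full `N x N`
#'   nonnegative matrix with zero diagonal. Entry `K[j, i]` scales the input
#'   from column `j` to column `i`.
#' @param p_const Constant external input component (Hz, >= 0).
#'
#' @return An object of class `jr_network`.
#' @export
#' @examples
#' net <- jr_network(N = 4, K = 15, p_const = 75)
jr_network <- function(N = 4, K = 15, p_const = 75) {
  N <- as.integer(N)
  if (is.na(N) || N < 1) stop("N must be an integer >= 1")
  if (is.matrix(K)) {
    if (nrow(K) != N || ncol(K) != N) {
      stop("K matrix dimensions must match N")
    }
    Kmat <- K
  } else {
    if (length(K) != 1) stop("K must be a scalar or an N x N matrix")
    Kmat <- matrix(K, N, N)
  }
  diag(Kmat) <- 0
  if (any(Kmat < 0)) stop("coupling strengths must be nonnegative")
  if (!is.finite(p_const) || p_const < 0) stop("p_const must be >= 0")
  structure(list(N = N, K = Kmat, p_const = p_const), class = "jr_network")
}

#' Network state
#'
#' Bundles the instantaneous state of the network: one six-dimensional column
#' state per column (three mean postsynaptic potentials and their time
#' derivatives), one Ornstein-Uhlenbeck noise value per column, and the time.
#'
#' @param columns `6 x N` numeric matrix; rows are `y0, y1, y2, z0, z1, z2`
#'   (potentials in mV, derivatives in mV/s), one column per cortical column.
#' @param noise Numeric vector of length `N`: the OU noise values (Hz).
#' @param t Time (s).
#'
#' @return An object of class `jr_state`.
#' @export
jr_state <- function(columns, noise = numeric(ncol(columns)), t = 0) {
  columns <- as.matrix(columns)
  if (nrow(columns) != 6) stop("columns must have 6 rows (y0,y1,y2,z0,z1,z2)")
  if (length(noise) != ncol(columns)) {
    stop("noise length must equal the number of columns")
  }
  if (any(!is.finite(columns)) || any(!is.finite(noise))) {
    stop("state values must be finite")
  }
  rownames(columns) <- c("y0", "y1", "y2", "z0", "z1", "z2")
  structure(list(columns = columns, noise = as.numeric(noise), t = t),
            class = "jr_state")
}

#' Zero network state
#'
#' All potentials, derivatives, and noise values set to zero.
#'
#' @param N Number of columns.
#' @return A [jr_state()] object.
#' @export
jr_state_zero <- function(N = 1) {
  jr_state(matrix(0, 6, N), numeric(N), t = 0)
}
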