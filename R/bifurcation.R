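#' Equilibria of the deterministic single column
#'
#' At an equilibrium the column equations reduce to a scalar fixed-point
#' problem in `y = y1 - y2`:
#' `y = (A/a) (p_exc + C2 Sigm(C1 y0)) - (B/b) C4 Sigm(C3 y0)` with
#' `y0 = (A/a) Sigm(y)`. Roots are located by a dense sign-change scan over
#' `y_range` followed by bisection, then lifted to the full six-dimensional
#' state (derivatives zero) and polished.
#'
#' @param p_exc Constant pyramidal input (Hz).
#' @param params A [jr_params()] object.
#' @param y_range Search interval for `y1 - y2` (mV).
#' @param n_grid Number of scan points.
#' @return A list of equilibria; each has `state` (length-6 vector), `p_exc`,
#'   `y` (`y1 - y2` at the equilibrium), and `eigenvalues` (the six Jacobian
#'   eigenvalues, sorted by decreasing real part).
#' @export
fixed_points <- function(p_exc, params = jr_params(), y_range = c(-50, 50),
                         n_grid = 10000) {
  g <- function(y) {
    y0 <- params$A / params$a * sigmoid(y, params)
    params$A / params$a * (p_exc + params$C2 * sigmoid(params$C1 * y0,
                                                       params)) -
      params$B / params$b * params$C4 * sigmoid(params$C3 * y0, params) - y
  }
  ys <- seq(y_range[1], y_range[2], length.out = n_grid)
  gv <- g(ys)
  sgn <- sign(gv)
  idx <- which(sgn[-1] * sgn[-n_grid] < 0)
  if (length(idx) == 0 && all(gv != 0)) {
    stop("no equilibrium found in the search bracket")
  }
  roots <- vapply(idx, function(j) {
    uniroot(g, c(ys[j], ys[j + 1]), tol = 1e-13)$root
  }, numeric(1))
  roots <- c(roots, ys[gv == 0])
  lapply(sort(roots), function(y) {
    y0 <- params$A / params$a * sigmoid(y, params)
    y1 <- params$A / params$a *
      (p_exc + params$C2 * sigmoid(params$C1 * y0, params))
    y2 <- params$B / params$b * params$C4 * sigmoid(params$C3 * y0, params)
    state <- c(y0, y1, y2, 0, 0, 0)
    ev <- jacobian_eigenvalues(state, params)
    list(state = state, p_exc = p_exc, y = y, eigenvalues = ev)
  })
}

#' Analytic Jacobian of the single-column system
#'
#' Linearization of the six-dimensional column equations at a state, using
#' the closed-form sigmoid derivative
#' `Sigm'(y) = r Sigm(y) (1 - Sigm(y) / (2 e0))`.
#'
#' @param state Length-6 state vector `(y0, y1, y2, z0, z1, z2)`.
#' @param params A [jr_params()] object.
#' @return A `6 x 6` Jacobian matrix.
#' @export
jr_jacobian <- function(state, params = jr_params()) {
  y0 <- state[1]; y1 <- state[2]; y2 <- state[3]
  sp_y <- sigmoid_deriv(y1 - y2, params)
  sp_1 <- sigmoid_deriv(params$C1 * y0, params)
  sp_3 <- sigmoid_deriv(params$C3 * y0, params)
  J <- matrix(0, 6, 6)
  J[1:3, 4:6] <- diag(3)
  with(params, {
    J[4, 1] <<- -a^2
    J[4, 2] <<- A * a * sp_y
    J[4, 3] <<- -A * a * sp_y
    J[4, 4] <<- -2 * a
    J[5, 1] <<- A * a * C2 * C1 * sp_1
    J[5, 2] <<- -a^2
    J[5, 5] <<- -2 * a
    J[6, 1] <<- B * b * C4 * C3 * sp_3
    J[6, 3] <<- -b^2
    J[6, 6] <<- -2 * b
  })
  J
}

#' Eigenvalues of the linearization at an equilibrium
#'
#' @param eq An equilibrium from [fixed_points()] or a length-6 state vector.
#' @param params A [jr_params()] object.
#' @return Six complex eigenvalues sorted by decreasing real part.
#' @export
jacobian_eigenvalues <- function(eq, params = jr_params()) {
  state <- if (is.list(eq)) eq$state else eq
  ev <- eigen(jr_jacobian(state, params), only.values = TRUE)$values
  ev <- as.complex(ev)
  ev[order(Re(ev), decreasing = TRUE)]
}

# Leading real part among eigenvalues with nonzero imaginary part, tracking
# the equilibrium branch continuous with y_prev (Hopf detection follows the
# complex pair, not a real eigenvalue). Without a previous point the upper
# branch (largest y) is taken: it exists for every input level and carries
# the Hopf points delimiting the alpha regime.
branch_leading_pair <- function(p, params, y_prev = NULL) {
  eqs <- fixed_points(p, params)
  yv <- vapply(eqs, `[[`, numeric(1), "y")
  pick <- if (!is.null(y_prev)) which.min(abs(yv - y_prev)) else
    which.max(yv)
  eq <- eqs[[pick]]
  cplx <- eq$eigenvalues[abs(Im(eq$eigenvalues)) > 1e-8]
  if (length(cplx) == 0) {
    return(list(re = -Inf, im = NA_real_, y = eq$y))
  }
  lead <- cplx[which.max(Re(cplx))]
  list(re = Re(lead), im = abs(Im(lead)), y = eq$y)
}

#' Locate Hopf bifurcations along the equilibrium branch
#'
#' Scans the constant input `p` over `[p_lo, p_hi]`, follows the equilibrium
#' branch, and bisects every sign change of the real part of the leading
#' complex eigenvalue pair down to tolerance `tol`. The imaginary part at the
#' crossing gives the frequency of the emerging cycle.
#'
#' @param p_lo,p_hi Scan interval for the constant input (Hz).
#' @param params A [jr_params()] object.
#' @param tol Bisection tolerance on `p` (Hz).
#' @param n_grid Number of initial scan points.
#' @return A data frame with one row per Hopf point: `p` (Hz), `im`
#'   (imaginary part at crossing, rad/s), and `frequency` (`im / 2 pi`, Hz).
#'   Zero rows when no crossing exists in the interval.
#' @export
hopf_scan <- function(p_lo, p_hi, params = jr_params(), tol = 0.01,
                      n_grid = 41) {
  if (p_lo >= p_hi) stop("need p_lo < p_hi")
  ps <- seq(p_lo, p_hi, length.out = n_grid)
  y_prev <- NULL
  info <- vector("list", n_grid)
  for (i in seq_along(ps)) {
    info[[i]] <- branch_leading_pair(ps[i], params, y_prev)
    y_prev <- info[[i]]$y
  }
  res <- vapply(info, `[[`, numeric(1), "re")
  found <- list()
  for (i in seq_len(n_grid - 1)) {
    if (is.finite(res[i]) && is.finite(res[i + 1]) &&
        res[i] * res[i + 1] < 0) {
      lo <- ps[i]; hi <- ps[i + 1]
      re_lo <- res[i]
      y_here <- info[[i]]$y
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        bp <- branch_leading_pair(mid, params, y_here)
        y_here <- bp$y
        if (sign(bp$re) == sign(re_lo)) {
          lo <- mid; re_lo <- bp$re
        } else {
          hi <- mid
        }
      }
      p_star <- (lo + hi) / 2
      bp <- branch_leading_pair(p_star, params, y_here)
      found[[length(found) + 1]] <- data.frame(p = p_star, im = bp$im,
                                               frequency = bp$im / (2 * pi))
    }
  }
  if (length(found) == 0) {
    return(data.frame(p = numeric(0), im = numeric(0),
                      frequency = numeric(0)))
  }
  do.call(rbind, found)
}

#' Classify a deterministic trajectory
#'
#' Labels the attractor reached by a deterministic run of the EEG observable:
#' `fixed_point` when the peak-to-peak excursion is below `eps_fp`;
#' otherwise `spiky_cycle` when the dominant spectral frequency is below
#' `f_split` *and* the peak-to-peak amplitude exceeds `A_split` (the spiky
#' cycle is slower and much larger than the alpha cycle); otherwise
#' `alpha_cycle`.
#'
#' @param x Trajectory of the EEG observable (mV), transient removed.
#' @param fs Sampling rate (Hz).
#' @param eps_fp Fixed-point peak-to-peak threshold (mV).
#' @param f_split Frequency split between spiky and alpha cycles (Hz).
#' @param A_split Amplitude split (mV, peak-to-peak).
#' @return A list with `label`, `dominant_frequency` (Hz, `NA` for a fixed
#'   point), and `peak_to_peak` (mV).
#' @export
classify_attractor <- function(x, fs, eps_fp = 0.1, f_split = 6,
                               A_split = 8) {
  if (length(x) / fs < 10) {
    stop("trajectory shorter than 10 s: too few cycles to classify")
  }
  p2p <- diff(range(x))
  if (p2p < eps_fp) {
    return(list(label = "fixed_point", dominant_frequency = NA_real_,
                peak_to_peak = p2p))
  }
  seg <- min(10, floor(length(x) / fs / 2))
  psd <- welch_psd(x, fs, spectral_config(segment = seg, overlap = seg / 2))
  sel <- psd$freq >= 0.5
  domf <- psd$freq[sel][which.max(psd$density[sel])]
  label <- if (domf < f_split && p2p > A_split) "spiky_cycle" else
    "alpha_cycle"
  list(label = label, dominant_frequency = domf, peak_to_peak = p2p)
}

# Deterministic single-column run from a given length-6 state; returns the
# classified attractor and the terminal state.
probe_attractor <- function(p_exc, init_state, params, t_total = 40,
                            t_settle = 15, h = 1e-3, ...) {
  ts <- simulate_network(
    net = jr_network(N = 1, K = 0, p_const = p_exc), params = params,
    ou = ou_config(D = 0, tau = 0.15), drive = drive_spec("none"),
    sim = sim_config(h = h, duration = t_total, transient = t_settle,
                     seed = 1),
    init = jr_state(matrix(init_state, 6, 1), 0)
  )
  cls <- classify_attractor(ts$average, ts$fs, ...)
  cls$final_state <- ts$final_state$columns[, 1]
  cls
}

# Initial-condition library at input p: every equilibrium plus +/-2 and
# +/-10 mV perturbations of y1, plus the zero state.
ic_library <- function(p_exc, params) {
  eqs <- fixed_points(p_exc, params)
  ics <- list(numeric(6))
  for (eq in eqs) {
    ics[[length(ics) + 1]] <- eq$state
    for (d in c(-10, -2, 2, 10)) {
      s <- eq$state
      s[2] <- s[2] + d
      ics[[length(ics) + 1]] <- s
    }
  }
  ics
}

#' Attractor inventory at one input level
#'
#' Runs deterministic single-column simulations from a library of initial
#' conditions (equilibria, perturbed equilibria, the origin, and any supplied
#' continuation states) and collects the distinct attractor labels reached.
#'
#' @param p_exc Constant input (Hz).
#' @param params A [jr_params()] object.
#' @param extra_inits Optional list of additional length-6 initial states
#'   (e.g. continuation states from a nearby input level).
#' @param t_total,t_settle Run length and settling span per probe (s).
#' @return A list with `labels` (character vector, one per probe), `spiky`
#'   (logical: any probe classified spiky), and `spiky_state` (terminal state
#'   of the first spiky probe, or `NULL`).
#' @export
attractor_inventory <- function(p_exc, params = jr_params(),
                                extra_inits = list(), t_total = 40,
                                t_settle = 15) {
  ics <- c(extra_inits, ic_library(p_exc, params))
  labels <- character(length(ics))
  spiky_state <- NULL
  for (i in seq_along(ics)) {
    pr <- probe_attractor(p_exc, ics[[i]], params, t_total, t_settle)
    labels[i] <- pr$label
    if (is.null(spiky_state) && pr$label == "spiky_cycle") {
      spiky_state <- pr$final_state
    }
  }
  list(labels = labels, spiky = any(labels == "spiky_cycle"),
       spiky_state = spiky_state)
}

#' Existence window of the spiky attractor
#'
#' Locates the onset and offset of the high-amplitude, low-frequency (spiky)
#' limit cycle of the deterministic single column by simulation-based
#' bisection. A probe input is first confirmed to support the spiky
#' attractor; the boundary search then continues the spiky orbit from
#' neighboring input levels (continuation initial conditions find the branch
#' reliably near its fold) on top of the standard initial-condition library.
#'
#' @param params A [jr_params()] object.
#' @param p_probe Input level expected to lie inside the window (Hz).
#' @param p_lower Input level below the window (no spiky attractor, Hz).
#' @param p_upper Input level above the window (Hz).
#' @param tol Bisection tolerance (Hz).
#' @return A list with `onset` and `offset` (Hz).
#' @export
coexistence_boundaries <- function(params = jr_params(), p_probe = 125,
                                   p_lower = 100, p_upper = 150, tol = 0.1) {
  inv <- attractor_inventory(p_probe, params)
  if (!inv$spiky) {
    stop(sprintf(
      "no spiky attractor found at probe input %g Hz (labels: %s)",
      p_probe, paste(unique(inv$labels), collapse = ", ")))
  }
  bisect_edge <- function(p_no, p_yes, state_yes) {
    while (abs(p_yes - p_no) > tol) {
      mid <- (p_no + p_yes) / 2
      inv <- attractor_inventory(mid, params,
                                 extra_inits = list(state_yes))
      if (inv$spiky) {
        p_yes <- mid
        state_yes <- inv$spiky_state
      } else {
        p_no <- mid
      }
    }
    (p_no + p_yes) / 2
  }
  low <- attractor_inventory(p_lower, params, list(inv$spiky_state))
  if (low$spiky) stop("spiky attractor still present at p_lower")
  high <- attractor_inventory(p_upper, params, list(inv$spiky_state))
  if (high$spiky) stop("spiky attractor still present at p_upper")
  list(onset = bisect_edge(p_lower, p_probe, inv$spiky_state),
       offset = bisect_edge(p_upper, p_probe, inv$spiky_state))
}

#' Bifurcation report of the single column
#'
#' Assembles the equilibrium branch table, detected Hopf points, and (when
#' requested) the spiky/alpha coexistence window, and optionally writes the
#' report as JSON.
#'
#' @param params A [jr_params()] object.
#' @param p_grid Input grid for the branch table (Hz).
#' @param hopf_ranges List of `c(lo, hi)` intervals scanned for Hopf points.
#' @param window If `TRUE`, also run [coexistence_boundaries()].
#' @param path Optional output file; the report is written as JSON.
#' @return A list with `branch` (data frame: `p`, `y`, `max_re`), `hopf`
#'   (data frame), and optionally `window`.
#' @export
bifurcation_report <- function(params = jr_params(),
                               p_grid = seq(0, 350, by = 5),
                               hopf_ranges = list(c(80, 100), c(300, 330)),
                               window = FALSE, path = NULL) {
  branch <- do.call(rbind, lapply(p_grid, function(p) {
    eqs <- fixed_points(p, params)
    do.call(rbind, lapply(eqs, function(eq) {
      data.frame(p = p, y = eq$y, max_re = max(Re(eq$eigenvalues)))
    }))
  }))
  hopf <- do.call(rbind, lapply(hopf_ranges, function(rg) {
    hopf_scan(rg[1], rg[2], params)
  }))
  rep <- list(branch = branch, hopf = hopf)
  if (window) rep$window <- coexistence_boundaries(params)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  rep
}
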