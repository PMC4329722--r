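#' Simulation settings
#'
#' @param h Integration step (s), default 0.001.
#' @param duration Total simulated time (s).
#' @param transient Initial span discarded from the returned series (s).
#' @param seed Master integer seed; per-column noise substreams are derived
#'   from it with [column_seed()].
#' @param record_stride Output decimation factor (integer >= 1); the output
#'   sampling rate is `1 / (h * record_stride)`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(h = 0.001, duration = 1010, transient = 10, seed = 1,
                       record_stride = 1L) {
  if (h <= 0) stop("h must be > 0")
  if (!(duration > transient && transient >= 0)) {
    stop("need duration > transient >= 0")
  }
  record_stride <- as.integer(record_stride)
  if (record_stride < 1) stop("record_stride must be >= 1")
  structure(list(h = h, duration = duration, transient = transient,
                 seed = as.integer(seed), record_stride = record_stride),
            class = "sim_config")
}

#' Simulate the stochastic network
#'
#' Advances the coupled column/noise system with the stochastic Heun scheme
#' (Euler predictor, trapezoidal corrector, identical white-noise increment in
#' both stages), discards the configured transient, and returns the recorded
#' EEG observable per column plus the column average. Identical seeds give
#' bit-identical outputs.
#'
#' @param net A [jr_network()] object.
#' @param params A [jr_params()] object.
#' @param ou An [ou_config()] object.
#' @param drive A [drive_spec()] object.
#' @param sim A [sim_config()] object.
#' @param init Optional [jr_state()] initial condition. Default: all column
#'   potentials and derivatives zero; OU values drawn from the stationary
#'   distribution.
#' @param record_coupling If `TRUE`, also record the per-column coupling
#'   input time series (needed for effective-input statistics).
#' @param shared_noise Test mode: feed every column the same white-noise
#'   stream and the same initial OU value.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation in plain R; identical output, much slower).
#' @return An object of class `jr_timeseries`: a list with `time` (s), `fs`
#'   (Hz), `eeg` (samples x N, mV), `average` (mV), optionally `coupling`
#'   (Hz), the final [jr_state()], and the full configuration as provenance.
#' @export
simulate_network <- function(net = jr_network(), params = jr_params(),
                             ou = ou_config(), drive = drive_spec("none"),
                             sim = sim_config(), init = NULL,
                             record_coupling = FALSE, shared_noise = FALSE,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  N <- net$N
  nsteps <- round(sim$duration / sim$h)
  times_all <- seq(0, by = sim$h, length.out = nsteps + 1)
  posc <- drive_signal(drive, times_all)

  if (is.null(init)) {
    noisy <- ou$D > 0
    xi0 <- if (!noisy) {
      numeric(N)
    } else if (shared_noise) {
      rep(with_local_seed(column_seed(sim$seed, 0L),
                          rnorm(1, 0, ou_stationary_std(ou))), N)
    } else {
      with_local_seed(column_seed(sim$seed, 0L),
                      rnorm(N, 0, ou_stationary_std(ou)))
    }
    init <- jr_state(matrix(0, 6, N), xi0)
  }
  if (ncol(init$columns) != N) stop("initial state and network disagree on N")

  W <- if (ou$D > 0) {
    white_noise_matrix(nsteps, N, sim$seed, shared = shared_noise)
  } else {
    matrix(0, 0, 0)
  }

  raw <- if (engine == "cpp") {
    heun_simulate_cpp(init$columns, init$noise, unclass(params), net$K,
                      net$p_const, posc, W, ou$D, ou$tau, sim$h,
                      sim$record_stride, record_coupling)
  } else {
    heun_simulate_r(init, params, net, posc, W, ou, sim$h,
                    sim$record_stride, record_coupling)
  }

  fs <- 1 / (sim$h * sim$record_stride)
  nrec <- nrow(raw$eeg)
  ts <- structure(list(
    time = seq(0, by = 1 / fs, length.out = nrec),
    fs = fs,
    eeg = raw$eeg,
    average = rowMeans(raw$eeg),
    coupling = if (record_coupling) raw$coupling else NULL,
    final_state = jr_state(raw$final_state, raw$final_xi,
                           t = nsteps * sim$h),
    config = list(net = net, params = params, ou = ou, drive = drive,
                  sim = sim, shared_noise = shared_noise)
  ), class = "jr_timeseries")
  discard_transient(ts, sim$transient)
}

# Plain-R Heun stepper over the whole run; mirrors the compiled kernel and is
# used to cross-validate it on short runs.
heun_simulate_r <- function(init, params, net, posc, W, ou, h, record_stride,
                            record_coupling) {
  N <- net$N
  nsteps <- length(posc) - 1
  x <- init$columns
  xi <- init$noise
  nrec <- nsteps %/% record_stride + 1
  eeg <- matrix(0, nrec, N)
  coup_rec <- if (record_coupling) matrix(0, nrec, N) else NULL
  irec <- 1
  eeg[irec, ] <- x[2, ] - x[3, ]
  if (record_coupling) coup_rec[irec, ] <- coupling_inputs(x, net, params)
  cn <- sqrt(2 * ou$D) / ou$tau * sqrt(h)
  for (k in seq_len(nsteps)) {
    w <- if (ou$D > 0) W[k, ] else numeric(N)
    step <- heun_step(x, xi, k - 1, h, params, net, ou,
                      posc[k], posc[k + 1], w)
    x <- step$columns
    xi <- step$noise
    if (k %% record_stride == 0) {
      irec <- irec + 1
      eeg[irec, ] <- x[2, ] - x[3, ]
      if (record_coupling) coup_rec[irec, ] <- coupling_inputs(x, net, params)
    }
  }
  out <- list(eeg = eeg, final_state = x, final_xi = xi)
  if (record_coupling) out$coupling <- coup_rec
  out
}

network_drift <- function(x, p_exc, params) {
  vapply(seq_len(ncol(x)),
         function(i) column_derivatives(x[, i], p_exc[i], params),
         numeric(6))
}

#' One stochastic Heun step of the full network
#'
#' Applies the predictor-corrector update jointly to all column equations and
#' the OU noise, using the same white-noise increment in both stages. With
#' `D = 0` the update reduces to the deterministic Heun method.
#'
#' @param x `6 x N` state matrix.
#' @param xi OU noise values, length `N`.
#' @param k Step index (0-based), so the step spans `t = k h` to `(k+1) h`.
#' @param h Step size (s).
#' @param params,net,ou Model configuration objects.
#' @param posc0,posc1 Deterministic drive at the start and end of the step.
#' @param w Standard normal draws, length `N`.
#' @return List with updated `columns` and `noise`.
#' @export
heun_step <- function(x, xi, k, h, params, net, ou, posc0 = 0, posc1 = 0,
                      w = numeric(length(xi))) {
  cn <- sqrt(2 * ou$D) / ou$tau * sqrt(h)
  coup0 <- coupling_inputs(x, net, params)
  f0 <- network_drift(x, net$p_const + coup0 + posc0 + xi, params)
  xp <- x + h * f0
  xip <- xi - h * xi / ou$tau + cn * w
  coup1 <- coupling_inputs(xp, net, params)
  f1 <- network_drift(xp, net$p_const + coup1 + posc1 + xip, params)
  list(columns = x + 0.5 * h * (f0 + f1),
       noise = xi - 0.5 * h * (xi + xip) / ou$tau + cn * w)
}

#' Drop the initial transient of a recorded series
#'
#' Removes all samples with `t < t_cut` and re-zeroes the time axis origin at
#' the first retained sample. With `t_cut = 0` the series is unchanged.
#'
#' @param ts A `jr_timeseries`.
#' @param t_cut Span to discard (s), measured from the start of the series.
#' @return The trimmed `jr_timeseries`; the cut is noted in the provenance.
#' @export
discard_transient <- function(ts, t_cut) {
  if (t_cut == 0) return(ts)
  if (t_cut >= ts$time[length(ts$time)]) {
    stop("t_cut must be smaller than the series duration")
  }
  keep <- ts$time >= t_cut - 1e-12
  ts$time <- ts$time[keep] - ts$time[keep][1]
  ts$eeg <- ts$eeg[keep, , drop = FALSE]
  ts$average <- ts$average[keep]
  if (!is.null(ts$coupling)) ts$coupling <- ts$coupling[keep, , drop = FALSE]
  ts$config$transient_cut <- c(ts$config$transient_cut, t_cut)
  ts
}

#' @export
print.jr_timeseries <- function(x, ...) {
  cat(sprintf("jr_timeseries: %d columns, %.1f s at fs = %g Hz\n",
              ncol(x$eeg), x$time[length(x$time)], x$fs))
  cat(sprintf("  average EEG range: [%.3f, %.3f] mV\n",
              min(x$average), max(x$average)))
  invisible(x)
}

#' Write a recorded series as columnar plain text
#'
#' Tab-separated table (time, per-column EEG, average, optional coupling
#' inputs) with a `#`-prefixed header carrying the sampling rate. Values are
#' written with full double precision, so [read_timeseries()] round-trips
#' bit-exactly.
#'
#' @param ts A `jr_timeseries`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  N <- ncol(ts$eeg)
  tab <- cbind(ts$time, ts$eeg, ts$average)
  nms <- c("time", sprintf("eeg_%d", seq_len(N)), "average")
  if (!is.null(ts$coupling)) {
    tab <- cbind(tab, ts$coupling)
    nms <- c(nms, sprintf("coupling_%d", seq_len(N)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# jrnet timeseries fs=%.17g n_columns=%d", ts$fs, N),
               paste(nms, collapse = "\t")), con)
  utils::write.table(format(tab, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a series written by [write_timeseries()]
#'
#' @param path File produced by [write_timeseries()].
#' @return A `jr_timeseries` (without provenance beyond the sampling rate).
#' @export
read_timeseries <- function(path) {
  header <- readLines(path, n = 2)
  fs <- as.numeric(sub(".*fs=([^ ]+).*", "\\1", header[1]))
  N <- as.integer(sub(".*n_columns=([0-9]+).*", "\\1", header[1]))
  tab <- utils::read.table(path, skip = 2, sep = "\t")
  names(tab) <- strsplit(header[2], "\t")[[1]]
  eeg <- as.matrix(tab[, sprintf("eeg_%d", seq_len(N)), drop = FALSE])
  dimnames(eeg) <- NULL
  coupling <- NULL
  if (any(grepl("^coupling_", names(tab)))) {
    coupling <- as.matrix(tab[, sprintf("coupling_%d", seq_len(N)),
                              drop = FALSE])
    dimnames(coupling) <- NULL
  }
  structure(list(time = tab$time, fs = fs, eeg = eeg,
                 average = tab$average, coupling = coupling,
                 final_state = NULL, config = list(fs = fs)),
            class = "jr_timeseries")
}
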