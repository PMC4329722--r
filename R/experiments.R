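#' Stationary (undriven) reference experiment
#'
#' Simulates the model without periodic drive and returns the recorded series
#' together with the Welch PSD of the column-average EEG observable. The two
#' scenarios reproduce the standard configurations: a single column with
#' `p_const = 90` Hz, or the coupled four-column network with `K = 15` and
#' `p_const = 75` Hz.
#'
#' @param scenario `"single_column"` or `"coupled_stationary"`.
#' @param duration,transient Simulated time and discarded transient (s).
#' @param seed Master seed.
#' @param ou An [ou_config()] object.
#' @param params A [jr_params()] object.
#' @param net Optional [jr_network()] overriding the scenario default.
#' @param spectral A [spectral_config()] object.
#' @param record_coupling Record per-column coupling inputs (default: yes for
#'   the coupled scenario).
#' @return A list with `ts` (`jr_timeseries`) and `psd` (`jr_psd` of the
#'   column-average signal).
#' @export
run_stationary <- function(scenario = c("single_column",
                                        "coupled_stationary"),
                           duration = 300, transient = 10, seed = 1,
                           ou = ou_config(), params = jr_params(),
                           net = NULL, spectral = spectral_config(),
                           record_coupling = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(net)) {
    net <- if (scenario == "single_column") {
      jr_network(N = 1, K = 0, p_const = 90)
    } else {
      jr_network(N = 4, K = 15, p_const = 75)
    }
  }
  if (is.null(record_coupling)) record_coupling <- net$N > 1
  ts <- simulate_network(net = net, params = params, ou = ou,
                         drive = drive_spec("none"),
                         sim = sim_config(duration = duration,
                                          transient = transient,
                                          seed = seed),
                         record_coupling = record_coupling)
  list(ts = ts, psd = welch_psd(ts$average, ts$fs, spectral))
}

#' Mean effective pyramidal input of a coupled run
#'
#' Time- and column-averaged total input `p_const + coupling`, together with
#' the mean, standard deviation, and coefficient of variation of the coupling
#' input itself. Requires a run recorded with `record_coupling = TRUE` and
#' more than one column.
#'
#' @param ts A `jr_timeseries` from [simulate_network()] with coupling
#'   recorded.
#' @return A list with `mean_total` (Hz), `coupling_mean`, `coupling_sd`
#'   (Hz), and `coupling_cv`.
#' @export
mean_effective_input <- function(ts) {
  if (ncol(ts$eeg) < 2) stop("effective input needs a coupled run (N >= 2)")
  if (is.null(ts$coupling)) {
    stop("run was not recorded with record_coupling = TRUE")
  }
  cm <- mean(ts$coupling)
  csd <- sd(as.numeric(ts$coupling))
  list(mean_total = ts$config$net$p_const + cm, coupling_mean = cm,
       coupling_sd = csd, coupling_cv = csd / cm)
}

#' Driven-versus-stationary experiment
#'
#' Runs the coupled network without drive, with a pure sine drive, and with
#' the power-matched composed multi-sine drive, over an ensemble of noise
#' seeds (the composed condition additionally varies the random phases per
#' ensemble member). Matched seeds are used across the three conditions so
#' the same noise realization underlies each comparison. Returned PSDs are
#' ensemble averages of the column-average observable.
#'
#' @param duration,transient Per-run simulated time and transient (s).
#' @param seed Base master seed; member `r` uses `seed + r - 1`.
#' @param n_realizations Ensemble size (phase realizations for the composed
#'   drive), default 10.
#' @param amplitude,frequency Sine drive parameters (Hz).
#' @param f_min,f_max,f_step Composed drive grid (Hz).
#' @param net,params,ou,spectral Model configuration objects.
#' @return A list with averaged `psd_stationary`, `psd_sine`, `psd_composed`,
#'   the pointwise ensemble statistics `composed_stats`
#'   (see [psd_ensemble_stats()]), and the calibrated composed amplitude.
#' @export
run_driven <- function(duration = 210, transient = 10, seed = 1,
                       n_realizations = 10, amplitude = 45,
                       frequency = 0.25, f_min = 0.05, f_max = 4,
                       f_step = 0.05, net = jr_network(),
                       params = jr_params(), ou = ou_config(),
                       spectral = spectral_config()) {
  amp_comp <- calibrate_composed_amplitude(amplitude, f_min, f_max, f_step)
  one <- function(drv, s) {
    ts <- simulate_network(net = net, params = params, ou = ou, drive = drv,
                           sim = sim_config(duration = duration,
                                            transient = transient,
                                            seed = s))
    welch_psd(ts$average, ts$fs, spectral)
  }
  seeds <- seed + seq_len(n_realizations) - 1
  stat_psds <- lapply(seeds, function(s) one(drive_spec("none"), s))
  sine_psds <- lapply(seeds, function(s) {
    one(drive_spec("sine", amplitude = amplitude, frequency = frequency), s)
  })
  comp_psds <- lapply(seq_along(seeds), function(r) {
    drv <- drive_spec("composed", amplitude = amplitude,
                      amplitude_composed = amp_comp, f_min = f_min,
                      f_max = f_max, f_step = f_step,
                      phase_seed = seed + 1000 + r)
    one(drv, seeds[r])
  })
  avg <- function(psds) {
    st <- psd_ensemble_stats(psds)
    structure(list(freq = st$freq, density = st$mean,
                   n_segments = sum(vapply(psds, `[[`, numeric(1),
                                           "n_segments")),
                   fs = psds[[1]]$fs, config = psds[[1]]$config),
              class = "jr_psd")
  }
  list(psd_stationary = avg(stat_psds), psd_sine = avg(sine_psds),
       psd_composed = avg(comp_psds),
       composed_stats = psd_ensemble_stats(comp_psds),
       amplitude_composed = amp_comp)
}

#' Relative spectral-change response map
#'
#' For each value of the swept parameter (drive amplitude, drive frequency,
#' or network size), simulates a driven and a stationary run with matched
#' noise seeds and assembles the per-frequency relative change
#' `10 log10(PSD_driven / PSD_stat)` into a matrix (sweep values x
#' frequencies).
#'
#' @param sweep One of `"amplitude"`, `"frequency"`, `"size"`.
#' @param values Sweep grid. Defaults: amplitudes `c(0, 15, 30, 45, 60, 90)`
#'   Hz, frequencies `c(0.1, 0.25, 0.5, 1, 2, 5, 10, 15, 20, 25)` Hz, sizes
#'   `c(2, 4, 8, 16)`.
#' @param duration,transient Per-run simulated time and transient (s).
#' @param seed Master seed (shared between the driven and stationary run of
#'   each cell).
#' @param amplitude,frequency Drive parameters held fixed while the other
#'   axis is swept (Hz).
#' @param net,params,ou,spectral Model configuration objects; `net` is
#'   rebuilt per value for the size sweep.
#' @return An object of class `jr_response_map`: list with `sweep`, `values`,
#'   `freq`, `db` (matrix, `NA` rows mark cells whose simulation blew up),
#'   and provenance.
#' @export
run_response_map <- function(sweep = c("amplitude", "frequency", "size"),
                             values = NULL, duration = 110, transient = 10,
                             seed = 1, amplitude = 45, frequency = 0.25,
                             net = jr_network(), params = jr_params(),
                             ou = ou_config(),
                             spectral = spectral_config()) {
  sweep <- match.arg(sweep)
  if (is.null(values)) {
    values <- switch(sweep,
      amplitude = c(0, 15, 30, 45, 60, 90),
      frequency = c(0.1, 0.25, 0.5, 1, 2, 5, 10, 15, 20, 25),
      size = c(2, 4, 8, 16))
  }
  db <- NULL
  freq <- NULL
  for (v in values) {
    cell_net <- net
    amp <- amplitude
    freq_drive <- frequency
    if (sweep == "amplitude") amp <- v
    if (sweep == "frequency") freq_drive <- v
    if (sweep == "size") {
      cell_net <- jr_network(N = v, K = net$K[2, 1], p_const = net$p_const)
    }
    cell <- tryCatch({
      sim <- sim_config(duration = duration, transient = transient,
                        seed = seed)
      drv <- drive_spec("sine", amplitude = amp, frequency = freq_drive)
      ts_d <- simulate_network(cell_net, params, ou, drv, sim)
      ts_s <- simulate_network(cell_net, params, ou, drive_spec("none"), sim)
      p_d <- welch_psd(ts_d$average, ts_d$fs, spectral)
      p_s <- welch_psd(ts_s$average, ts_s$fs, spectral)
      list(freq = p_s$freq, db = relative_change_db(p_d, p_s))
    }, error = function(e) NULL)
    if (!is.null(cell)) {
      freq <- cell$freq
      db <- rbind(db, cell$db)
    } else {
      db <- rbind(db, rep(NA_real_, if (is.null(freq)) 1 else length(freq)))
    }
  }
  rownames(db) <- NULL
  structure(list(sweep = sweep, values = values, freq = freq, db = db,
                 config = list(amplitude = amplitude, frequency = frequency,
                               net = net, ou = ou, duration = duration,
                               seed = seed)),
            class = "jr_response_map")
}

#' Band-averaged relative change from a response map
#'
#' Mean dB change over a frequency band, one value per sweep point, with
#' optional notched sub-intervals (e.g. the drive line).
#'
#' @param map A `jr_response_map`.
#' @param f_lo,f_hi Band edges (Hz).
#' @param exclude Optional list of `c(lo, hi)` intervals to notch out.
#' @return Numeric vector, one mean dB value per sweep value.
#' @export
map_band_db <- function(map, f_lo, f_hi, exclude = NULL) {
  sel <- map$freq >= f_lo & map$freq <= f_hi
  if (!is.null(exclude)) {
    for (ex in exclude) sel <- sel & !(map$freq >= ex[1] & map$freq <= ex[2])
  }
  apply(map$db[, sel, drop = FALSE], 1, mean, na.rm = TRUE)
}

#' Run a configured experiment
#'
#' Dispatches on the `scenario` field of a configuration list (as returned by
#' [read_model_config()] plus an `experiment` block) to the corresponding
#' pipeline. This is the engine behind the command-line `experiment`
#' subcommand.
#'
#' @param cfg Configuration list with components `net`, `params`, `ou`,
#'   `sim`, `drive`, and `experiment` (fields `scenario`, optional `values`,
#'   `n_realizations`).
#' @return The scenario's result object.
#' @export
run_experiment <- function(cfg) {
  sc <- cfg$experiment$scenario
  dur <- cfg$sim$duration
  trans <- cfg$sim$transient
  seed <- cfg$sim$seed
  switch(sc,
    single_column = run_stationary("single_column", duration = dur,
                                   transient = trans, seed = seed,
                                   ou = cfg$ou, params = cfg$params),
    coupled_stationary = run_stationary("coupled_stationary", duration = dur,
                                        transient = trans, seed = seed,
                                        ou = cfg$ou, params = cfg$params,
                                        net = cfg$net),
    sine_driven = ,
    composed_driven = run_driven(duration = dur, transient = trans,
                                 seed = seed,
                                 n_realizations =
                                   cfg$experiment$n_realizations %||% 10,
                                 amplitude = cfg$drive$amplitude,
                                 frequency = cfg$drive$frequency,
                                 net = cfg$net, params = cfg$params,
                                 ou = cfg$ou),
    response_map_amplitude = run_response_map("amplitude",
                                              values = cfg$experiment$values,
                                              duration = dur,
                                              transient = trans, seed = seed,
                                              net = cfg$net,
                                              params = cfg$params,
                                              ou = cfg$ou),
    response_map_frequency = run_response_map("frequency",
                                              values = cfg$experiment$values,
                                              duration = dur,
                                              transient = trans, seed = seed,
                                              net = cfg$net,
                                              params = cfg$params,
                                              ou = cfg$ou),
    response_map_size = run_response_map("size",
                                         values = cfg$experiment$values,
                                         duration = dur, transient = trans,
                                         seed = seed, net = cfg$net,
                                         params = cfg$params, ou = cfg$ou),
    stop(sprintf("unknown scenario '%s'", sc))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
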