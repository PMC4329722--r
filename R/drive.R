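#' Deterministic driving specification
#'
#' Describes the periodic component of the pyramidal input shared by all
#' columns: none, a pure sine `amplitude * sin(2 pi frequency t)`, or a
#' composed multi-sine with exponentially decaying component weights on the
#' grid `f_min, f_min + f_step, ..., f_max` and random phases.
#'
#' @param mode One of `"none"`, `"sine"`, `"composed"`.
#' @param amplitude Sine amplitude (Hz).
#' @param frequency Sine frequency (Hz).
#' @param amplitude_composed Composed-signal amplitude (Hz). `NULL` calibrates
#'   it with [calibrate_composed_amplitude()] so the composed signal delivers
#'   the same mean power as the pure sine of `amplitude`.
#' @param f_min,f_max,f_step Composed frequency grid (Hz).
#' @param phases Numeric vector of phases in `[0, 1)`, one per grid component;
#'   `NULL` samples them with [sample_phases()] using `phase_seed`.
#' @param phase_seed Seed used when `phases` is `NULL`.
#' @return An object of class `drive_spec`.
#' @export
#' @examples
#' drive_spec("sine", amplitude = 45, frequency = 0.25)
drive_spec <- function(mode = c("none", "sine", "composed"),
                       amplitude = 45, frequency = 0.25,
                       amplitude_composed = NULL,
                       f_min = 0.05, f_max = 4, f_step = 0.05,
                       phases = NULL, phase_seed = 1) {
  mode <- match.arg(mode)
  spec <- list(mode = mode, amplitude = amplitude, frequency = frequency)
  if (mode == "composed") {
    idx <- composed_indices(f_min, f_max, f_step)
    n_comp <- idx$n_max - idx$n_min + 1
    if (is.null(phases)) {
      phases <- sample_phases(n_comp, phase_seed)
    }
    if (length(phases) != n_comp) {
      stop(sprintf("composed drive needs %d phases, got %d", n_comp,
                   length(phases)))
    }
    if (any(phases < 0 | phases >= 1)) stop("phases must lie in [0, 1)")
    if (is.null(amplitude_composed)) {
      amplitude_composed <- calibrate_composed_amplitude(amplitude, f_min,
                                                         f_max, f_step)
    }
    spec <- c(spec, list(amplitude_composed = amplitude_composed,
                         f_min = f_min, f_max = f_max, f_step = f_step,
                         n_min = idx$n_min, n_max = idx$n_max,
                         phases = phases))
  }
  structure(spec, class = "drive_spec")
}

# Component indices n_min = f_min/f_step, n_max = f_max/f_step, rounded to
# nearest integer with relative tolerance 1e-6.
composed_indices <- function(f_min, f_max, f_step) {
  if (f_step <= 0) stop("f_step must be > 0")
  if (f_min > f_max) stop("f_min must not exceed f_max")
  ratio <- c(f_min, f_max) / f_step
  n <- round(ratio)
  off <- abs(ratio - n) / pmax(ratio, 1)
  if (any(off > 1e-6)) {
    stop("f_min and f_max must be integer multiples of f_step")
  }
  list(n_min = as.integer(n[1]), n_max = as.integer(n[2]))
}

# Exponentially decaying component weights 10^(-(n f_step - f_min)/(f_max -
# f_min)); all ones in the degenerate single-frequency case f_max == f_min.
composed_weights <- function(f_min, f_max, f_step) {
  idx <- composed_indices(f_min, f_max, f_step)
  n <- idx$n_min:idx$n_max
  if (f_max == f_min) return(rep(1, length(n)))
  10^(-(n * f_step - f_min) / (f_max - f_min))
}

#' Pure sine drive
#'
#' @param t Time(s), s. Vectorized.
#' @param amplitude Amplitude (Hz).
#' @param frequency Frequency (Hz).
#' @return `amplitude * sin(2 pi frequency t)` (Hz).
#' @export
sine_drive <- function(t, amplitude = 45, frequency = 0.25) {
  amplitude * sin(2 * pi * frequency * t)
}

#' Composed multi-sine drive
#'
#' Evaluates
#' `A' * sum_n 10^(-(n f_step - f_min)/(f_max - f_min)) *
#' sin(2 pi (n f_step t + X_n))` over the component grid.
#'
#' @param t Time(s), s. Vectorized.
#' @param spec A [drive_spec()] with `mode = "composed"`.
#' @return Drive value(s) (Hz).
#' @export
composed_drive <- function(t, spec) {
  if (!inherits(spec, "drive_spec") || spec$mode != "composed") {
    stop("spec must be a composed drive_spec")
  }
  n <- spec$n_min:spec$n_max
  wts <- composed_weights(spec$f_min, spec$f_max, spec$f_step)
  freq <- n * spec$f_step
  # outer product: time points x components
  ph <- outer(t, freq) + rep(spec$phases, each = length(t))
  as.numeric(spec$amplitude_composed * (sin(2 * pi * ph) %*% wts))
}

#' Evaluate a drive specification
#'
#' @param spec A [drive_spec()] object.
#' @param t Time(s), s.
#' @return Drive value(s) (Hz); zero for `mode = "none"`.
#' @export
drive_signal <- function(spec, t) {
  switch(spec$mode,
    none = rep(0, length(t)),
    sine = sine_drive(t, spec$amplitude, spec$frequency),
    composed = composed_drive(t, spec)
  )
}

#' Power-matched composed-signal amplitude
#'
#' Returns the amplitude `A'` for which the phase-averaged mean power of the
#' composed multi-sine equals the mean power `A^2 / 2` of a pure sine of
#' amplitude `A`: `A' = A / sqrt(sum_n w_n^2)` with the exponentially decaying
#' weights `w_n`.
#'
#' @param amplitude Reference sine amplitude `A` (Hz).
#' @param f_min,f_max,f_step Composed frequency grid (Hz).
#' @return Calibrated amplitude `A'` (Hz).
#' @export
#' @examples
#' calibrate_composed_amplitude(45, 0.05, 4, 0.05) # 10.76 Hz
calibrate_composed_amplitude <- function(amplitude, f_min = 0.05, f_max = 4,
                                         f_step = 0.05) {
  wts <- composed_weights(f_min, f_max, f_step)
  if (length(wts) == 0) stop("empty component set")
  amplitude / sqrt(sum(wts^2))
}

#' Sample random phases
#'
#' Uniform draws on `[0, 1)`, reproducible for a fixed seed; the caller's RNG
#' state is untouched.
#'
#' @param count Number of phases (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of `count` phases in `[0, 1)`.
#' @export
sample_phases <- function(count, seed = 1) {
  if (count < 1) stop("count must be >= 1")
  with_local_seed(seed, runif(count))
}
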