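#' Welch estimation settings
#'
#' @param segment Segment length (s), default 20.
#' @param overlap Overlap between consecutive segments (s), default 10.
#' @param detrend Remove each segment's mean before windowing (default TRUE).
#' @return An object of class `spectral_config`. The window is a periodic
#'   Hann window; the estimate is one-sided.
#' @export
spectral_config <- function(segment = 20, overlap = 10, detrend = TRUE) {
  if (overlap >= segment) stop("overlap must be smaller than segment length")
  structure(list(segment = segment, overlap = overlap, detrend = detrend),
            class = "spectral_config")
}

#' Welch power spectral density
#'
#' Averaged modified periodogram over Hann-windowed, overlapping segments.
#' The one-sided density is normalized per Hz so that its integral over
#' frequency approximates the signal variance (Parseval).
#'
#' @param x Signal (regular sampling).
#' @param fs Sampling rate (Hz).
#' @param cfg A [spectral_config()] object.
#' @return An object of class `jr_psd`: list with `freq` (Hz), `density`
#'   (signal-units^2 / Hz), `n_segments`, `fs`, and `config`.
#' @export
welch_psd <- function(x, fs, cfg = spectral_config()) {
  L <- round(cfg$segment * fs)
  S <- round((cfg$segment - cfg$overlap) * fs)
  n <- length(x)
  if (n < L) {
    stop(sprintf("signal too short for Welch: %d samples, need >= %d", n, L))
  }
  k <- 0:(L - 1)
  win <- 0.5 * (1 - cos(2 * pi * k / L)) # periodic Hann
  wnorm <- fs * sum(win^2)
  nseg <- (n - L) %/% S + 1
  nfreq <- L %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1) * S + 1):((s - 1) * S + L)]
    if (cfg$detrend) seg <- seg - mean(seg)
    spec <- abs(fft(seg * win)[1:nfreq])^2 / wnorm
    # one-sided: double all bins except DC (and Nyquist for even L)
    spec[2:(nfreq - 1)] <- 2 * spec[2:(nfreq - 1)]
    if (L %% 2 == 1) spec[nfreq] <- 2 * spec[nfreq]
    acc <- acc + spec
  }
  structure(list(freq = (0:(nfreq - 1)) * fs / L, density = acc / nseg,
                 n_segments = as.integer(nseg), fs = fs, config = cfg),
            class = "jr_psd")
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) stop("need at least two points to integrate")
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Band power from a PSD
#'
#' Trapezoidal integral of the one-sided density over `[f_lo, f_hi]`,
#' optionally excluding notched sub-intervals (e.g. a +/- 0.1 Hz notch around
#' a driving line).
#'
#' @param psd A `jr_psd`.
#' @param f_lo,f_hi Band edges (Hz), `f_lo < f_hi`.
#' @param exclude Optional list of `c(lo, hi)` intervals removed from the
#'   integration grid.
#' @return Band power (signal-units^2).
#' @export
band_power <- function(psd, f_lo, f_hi, exclude = NULL) {
  if (f_lo >= f_hi) stop("need f_lo < f_hi")
  sel <- psd$freq >= f_lo & psd$freq <= f_hi
  if (!is.null(exclude)) {
    for (ex in exclude) {
      sel <- sel & !(psd$freq >= ex[1] & psd$freq <= ex[2])
    }
  }
  if (sum(sel) < 2) stop("band contains fewer than two frequency bins")
  trapz(psd$freq[sel], psd$density[sel])
}

#' Relative spectral change in decibels
#'
#' Pointwise `10 log10(PSD_driven / PSD_stat)`. Frequencies where the
#' stationary density is zero yield `NA` (flagged, never infinite).
#'
#' @param psd_driven,psd_stat `jr_psd` objects on identical frequency grids.
#' @return Numeric vector of dB values on the common grid.
#' @export
relative_change_db <- function(psd_driven, psd_stat) {
  if (length(psd_driven$freq) != length(psd_stat$freq) ||
      any(abs(psd_driven$freq - psd_stat$freq) > 1e-9)) {
    stop("PSDs must share an identical frequency grid")
  }
  out <- rep(NA_real_, length(psd_stat$freq))
  ok <- psd_stat$density > 0
  out[ok] <- 10 * log10(psd_driven$density[ok] / psd_stat$density[ok])
  out
}

#' Pointwise mean and spread of a PSD ensemble
#'
#' @param psds List of at least two `jr_psd` objects on a common grid.
#' @return A list with `freq`, `mean`, and `sd` (pointwise standard
#'   deviation), plus `n`.
#' @export
psd_ensemble_stats <- function(psds) {
  if (length(psds) < 2) stop("need at least two PSDs")
  f0 <- psds[[1]]$freq
  for (p in psds[-1]) {
    if (length(p$freq) != length(f0) || any(abs(p$freq - f0) > 1e-9)) {
      stop("PSDs must share an identical frequency grid")
    }
  }
  m <- vapply(psds, `[[`, numeric(length(f0)), "density")
  list(freq = f0, mean = rowMeans(m), sd = apply(m, 1, sd), n = length(psds))
}

#' Write / read a PSD as two-column plain text
#'
#' @param psd A `jr_psd`.
#' @param path Output file.
#' @return `path` invisibly; `read_psd()` returns the `jr_psd` back.
#' @export
write_psd <- function(psd, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# jrnet psd fs=%.17g n_segments=%d", psd$fs,
                       psd$n_segments), "freq\tdensity"), con)
  utils::write.table(format(cbind(psd$freq, psd$density), digits = 17,
                            scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_psd
#' @export
read_psd <- function(path) {
  header <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*fs=([^ ]+).*", "\\1", header))
  nseg <- as.integer(sub(".*n_segments=([0-9]+).*", "\\1", header))
  tab <- utils::read.table(path, skip = 2, sep = "\t")
  structure(list(freq = tab[[1]], density = tab[[2]], n_segments = nseg,
                 fs = fs, config = NULL), class = "jr_psd")
}
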