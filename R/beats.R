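#' Peak detection on the derivative-sign criterion
#'
#' A sample is a peak when the first discrete difference changes from positive
#' to non-positive and the local second difference is negative.
#'
#' @param x numeric sequence, length >= 3.
#' @return Integer sample indices of peaks (possibly empty).
#' @export
detect_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  d <- diff(x)
  cand <- which(d[-(n - 1)] > 0 & d[-1] <= 0) + 1L
  d2 <- x[cand + 1L] - 2 * x[cand] + x[cand - 1L]
  cand[d2 < 0]
}

#' Select the IMF with the most regular envelope peaks
#'
#' For each of the first IMFs of a 4-s window, an envelope is drawn through
#' the IMF's detected peaks, the envelope's own peaks are detected, and the
#' standard deviation of the resulting peak-to-peak intervals (PPIs) is
#' computed. The IMF minimizing this SD carries the clearest cardiac rhythm;
#' ties go to the lowest (highest-frequency) IMF index.
#'
#' The envelope is the cubic spline through the IMF's own peaks, low-passed
#' (zero-phase) at `env_smooth_hz` so that envelope peaks track valve-event
#' bursts rather than sample-level noise wiggle; envelope peaks below the
#' mean envelope level are discarded as noise-floor fluctuation. IMFs whose
#' envelope yields fewer than three peaks (fewer than two PPIs, so the SD is
#' undefined) are excluded.
#'
#' @param decomp an `imf_decomposition` of the window.
#' @param max_imfs number of leading IMFs considered.
#' @param fs sampling rate (Hz).
#' @param env_smooth_hz low-pass cutoff applied to each IMF envelope before
#'   peak detection.
#' @return A list with `imf_index` and `peaks` (envelope peak indices within
#'   the window), or `NULL` when no IMF qualifies.
#' @export
select_optimal_imf <- function(decomp, max_imfs = 4L, fs = 4000,
                               env_smooth_hz = 15) {
  stopifnot(inherits(decomp, "imf_decomposition"))
  n_try <- min(max_imfs, length(decomp$imfs))
  if (n_try < 1) return(NULL)
  bf <- signal::butter(4, min(env_smooth_hz / (fs / 2), 0.99))
  best <- NULL
  best_sd <- Inf
  for (k in seq_len(n_try)) {
    imf <- decomp$imfs[[k]]
    pk <- detect_peaks(imf)
    if (length(pk) < 2) next
    env <- as.numeric(signal::filtfilt(bf, spline_envelope(imf, pk)))
    epk <- detect_peaks(env)
    epk <- epk[env[epk] > mean(env)]
    if (length(epk) < 3) next
    sdv <- sd(diff(epk))
    if (sdv < best_sd) {
      best_sd <- sdv
      best <- list(imf_index = k, peaks = epk)
    }
  }
  best
}

#' Beat sequence constructor
#'
#' @param beat_samples strictly increasing beat locations (sample units at the
#'   working rate; fractional values allowed after interval correction).
#' @param fs sampling rate (Hz).
#' @param source_imf optional per-window chosen IMF index.
#' @return An object of class `dus_beats` with fields `beat_samples`, `ppis`,
#'   `fs`, `source_imf`.
#' @export
dus_beats <- function(beat_samples, fs = 4000, source_imf = integer()) {
  beat_samples <- as.numeric(beat_samples)
  if (is.unsorted(beat_samples, strictly = TRUE))
    stop("beat samples must be strictly increasing", call. = FALSE)
  structure(list(beat_samples = beat_samples, ppis = diff(beat_samples),
                 fs = fs, source_imf = source_imf),
            class = "dus_beats")
}

#' @export
print.dus_beats <- function(x, ...) {
  cat(sprintf("%d beats; median PPI %.1f samples (%.0f bpm)\n",
              length(x$beat_samples), median(x$ppis),
              60 * x$fs / median(x$ppis)))
  invisible(x)
}

#' Merge per-window peak lists across overlapping windows
#'
#' Windows advance by `window_s - overlap_s`, so adjacent windows share an
#' overlap in which a beat may be found twice. Peaks closer than 0.2 x the
#' local median PPI to an already-accepted peak are treated as duplicates and
#' dropped (the earlier detection is kept); peaks seen by only one window are
#' kept.
#'
#' @param window_peaks list of numeric vectors of global sample indices, one
#'   per window, in window order.
#' @return Strictly increasing merged peak indices.
#' @export
stitch_windows <- function(window_peaks) {
  merged <- numeric()
  for (pk in window_peaks) {
    pk <- sort(pk)
    if (!length(pk)) next
    if (!length(merged)) { merged <- pk; next }
    tail_m <- merged[max(1, length(merged) - 20):length(merged)]
    local <- sort(unique(c(tail_m, pk)))
    med_ppi <- if (length(local) > 1) median(diff(local)) else Inf
    thr <- 0.2 * med_ppi
    for (p in pk) {
      if (!length(merged) || min(abs(merged - p)) >= thr) merged <- c(merged, p)
    }
    merged <- sort(unique(merged))
  }
  merged
}

#' Five-interval median-window correction of peak-to-peak intervals
#'
#' Slides a 5-PPI window left to right; when the middle PPI differs from the
#' mean of the other four by more than 20 % of that mean it is replaced by
#' that mean (using already-corrected values, i.e. a causal in-place update).
#' Beat locations are rebuilt by cumulative summation from the first beat.
#'
#' @param beats a [dus_beats()] object.
#' @return A corrected [dus_beats()]; returned unchanged with a warning when
#'   fewer than 5 PPIs are available.
#' @export
correct_ppis <- function(beats) {
  stopifnot(inherits(beats, "dus_beats"))
  ppis <- beats$ppis
  if (length(ppis) < 5) {
    warning("fewer than 5 PPIs; interval correction skipped")
    return(beats)
  }
  for (i in 3:(length(ppis) - 2)) {
    m <- mean(ppis[c(i - 2, i - 1, i + 1, i + 2)])
    if (abs(ppis[i] - m) > 0.2 * m) ppis[i] <- m
  }
  dus_beats(beats$beat_samples[1] + c(0, cumsum(ppis)),
            fs = beats$fs, source_imf = beats$source_imf)
}

# iteratively drop the later peak of any interval shorter than the
# physiological minimum (bpm above `bpm_max`), e.g. double detections of the
# two valve events within one cycle
gate_min_ppi <- function(peaks, fs, bpm_max = 210) {
  min_ppi <- fs * 60 / bpm_max
  out <- numeric()
  for (p in sort(peaks)) {
    if (!length(out) || p - out[length(out)] >= min_ppi) out <- c(out, p)
  }
  out
}

#' Detect beats in a recording via windowed EMD
#'
#' Runs the sifting decomposition over 4-s windows advancing by 3 s (1-s
#' overlap), selects the optimal IMF per window by the PPI-SD criterion,
#' stitches the per-window envelope peaks, removes sub-physiological
#' intervals, and applies the 5-PPI correction.
#'
#' @param rec a [dus_recording()] at the working rate.
#' @param config a [dus_config()].
#' @return A [dus_beats()] object, or `NULL` when no window yields beats.
#' @export
detect_beats <- function(rec, config = dus_config()) {
  stopifnot(inherits(rec, "dus_recording"))
  fs <- rec$fs
  n <- length(rec$samples)
  wlen <- round(config$beat_window_s * fs)
  step <- round((config$beat_window_s - config$beat_overlap_s) * fs)
  if (n < wlen) stop("recording shorter than one beat-detection window", call. = FALSE)
  starts <- seq(0, n - wlen, by = step)
  if (starts[length(starts)] + wlen < n) starts <- c(starts, n - wlen)

  window_peaks <- list()
  source_imf <- integer()
  for (s0 in starts) {
    w <- rec$samples[s0 + seq_len(wlen)]
    dec <- sift(w, max_imfs = config$emd_max_imfs,
                sd_stop = config$emd_sd_stop, max_iter = config$emd_max_sift)
    sel <- select_optimal_imf(dec, max_imfs = config$emd_max_imfs, fs = fs,
                              env_smooth_hz = config$imf_env_smooth_hz)
    if (is.null(sel)) {
      window_peaks[[length(window_peaks) + 1L]] <- numeric()
      source_imf <- c(source_imf, NA_integer_)
      next
    }
    window_peaks[[length(window_peaks) + 1L]] <- s0 + sel$peaks
    source_imf <- c(source_imf, sel$imf_index)
  }
  peaks <- stitch_windows(window_peaks)
  peaks <- gate_min_ppi(peaks, fs, config$bpm_max)
  if (length(peaks) < 2) return(NULL)
  beats <- dus_beats(peaks, fs = fs, source_imf = source_imf)
  if (length(beats$ppis) >= 5) beats <- correct_ppis(beats)
  beats
}

#' Continuous wavelet transform magnitude in the valve-motion band
#'
#' Convolves the signal with an order-2 complex Gaussian mother wavelet at a
#' single scale and returns the coefficient magnitude. At the 4 kHz working
#' rate the default scale of 8 samples concentrates the response on the
#' sub-1 kHz band carrying fetal valve and wall motion. The signal is
#' processed in 25-s windows (reflect-padded at the seams) and the magnitudes
#' concatenated.
#'
#' @param x numeric signal at the working rate.
#' @param fs sampling rate (Hz).
#' @param scale wavelet scale in samples.
#' @param window_s processing window length in seconds.
#' @return Numeric vector of CWT magnitudes, same length as `x`.
#' @export
cwt_valve_band <- function(x, fs = 4000, scale = 8, window_s = 25) {
  x <- as.numeric(x)
  n <- length(x)
  psi <- cgau2_wavelet(scale)
  half <- (length(psi) - 1L) %/% 2L
  wlen <- round(window_s * fs)
  if (n <= wlen) return(cwt_window_mag(x, psi, half))
  starts <- seq(1L, n, by = wlen)
  out <- numeric(n)
  for (s0 in starts) {
    e0 <- min(s0 + wlen - 1L, n)
    p0 <- max(1L, s0 - half)
    p1 <- min(n, e0 + half)
    seg <- cwt_window_mag(x[p0:p1], psi, half)
    out[s0:e0] <- seg[(s0 - p0 + 1L):(s0 - p0 + (e0 - s0 + 1L))]
  }
  out
}

# order-2 complex Gaussian wavelet psi(t) = C (4t^2 + 4it - 3) exp(-t^2 - it),
# unit L2 norm, sampled at integer lags for the given scale with support
# |t/scale| <= 8; includes the 1/sqrt(scale) CWT normalization
cgau2_wavelet <- function(scale) {
  half <- ceiling(8 * scale)
  u <- (-half:half) / scale
  psi <- (4 * u^2 + 4i * u - 3) * exp(-u^2 - 1i * u)
  # continuous unit-norm constant: integral |psi0|^2 dt evaluated densely
  ug <- seq(-8, 8, length.out = 32768)
  p0 <- (4 * ug^2 + 4i * ug - 3) * exp(-ug^2 - 1i * ug)
  c0 <- sqrt(sum(Mod(p0)^2) * (ug[2] - ug[1]))
  psi / c0 / sqrt(scale)
}

cwt_window_mag <- function(x, psi, half) {
  n <- length(x)
  nfft <- 2^ceiling(log2(n + length(psi) - 1))
  X <- fft(c(x, numeric(nfft - n)))
  P <- fft(c(Conj(rev(psi)), numeric(nfft - length(psi))))
  full <- fft(X * P, inverse = TRUE) / nfft
  # correlation with the wavelet centered on each sample
  Mod(full[half + seq_len(n)])
}

#' Per-cycle normalized envelopes of the CWT magnitude
#'
#' The envelope of the CWT magnitude is obtained by cubic-spline
#' interpolation through its local maxima, smoothed with a zero-phase 4th
#' order Butterworth low-pass, then cut at the beat locations; every
#' beat-to-beat excerpt is normalized to zero mean and unit SD. Cycles with
#' zero variance are dropped with a warning.
#'
#' Because the smoothed envelope is band-limited at `smooth_cutoff_hz`, it is
#' stored at the decimated `envelope_fs` rate (default 200 Hz, an 8x
#' oversampling of the default 25 Hz cutoff): template correlations are
#' unaffected while the downstream warping costs shrink quadratically. Cycle
#' onsets are kept in working-rate sample units.
#'
#' @param cwt_mag CWT magnitude sequence (see [cwt_valve_band()]).
#' @param beats a [dus_beats()] object.
#' @param fs sampling rate (Hz).
#' @param smooth_cutoff_hz low-pass cutoff for envelope smoothing (Hz).
#' @param envelope_fs storage rate of the smoothed envelope (Hz; must divide
#'   `fs`).
#' @return A list of `dus_cycle` objects (`values` at `envelope_fs`,
#'   `onset_sample` at `fs`, `length_samples` in envelope samples, `env_fs`),
#'   with the full decimated envelope attached as attribute `"envelope"`.
#' @export
cycle_envelopes <- function(cwt_mag, beats, fs = 4000, smooth_cutoff_hz = 25,
                            envelope_fs = 200) {
  stopifnot(inherits(beats, "dus_beats"))
  env <- smooth_envelope(cwt_mag, fs, smooth_cutoff_hz)
  dec <- max(1L, round(fs / envelope_fs))
  env_d <- env[seq(1L, length(env), by = dec)]
  nd <- length(env_d)
  b <- round(beats$beat_samples)
  bd <- pmax(1L, round((b - 1L) / dec) + 1L)
  cycles <- list()
  dropped <- 0L
  for (i in seq_len(length(b) - 1L)) {
    i0 <- bd[i]
    i1 <- min(nd, bd[i + 1L] - 1L)
    if (i1 - i0 < 1L) next
    v <- env_d[i0:i1]
    if (sd(v) == 0) { dropped <- dropped + 1L; next }
    cycles[[length(cycles) + 1L]] <- structure(
      list(values = (v - mean(v)) / sd(v), onset_sample = b[i],
           length_samples = i1 - i0 + 1L, env_fs = fs / dec),
      class = "dus_cycle")
  }
  if (dropped > 0) warning(dropped, " zero-variance cycle(s) dropped")
  attr(cycles, "envelope") <- env_d
  attr(cycles, "env_fs") <- fs / dec
  cycles
}

smooth_envelope <- function(cwt_mag, fs, smooth_cutoff_hz) {
  pk <- local_maxima(cwt_mag)
  env <- if (length(pk) >= 2) spline_envelope(cwt_mag, pk) else cwt_mag
  bf <- signal::butter(4, smooth_cutoff_hz / (fs / 2))
  as.numeric(signal::filtfilt(bf, env))
}
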