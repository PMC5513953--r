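#' Sample entropy
#'
#' Negative log conditional probability that sequences matching for `m`
#' points (Chebyshev distance within tolerance `r`) also match for `m + 1`
#' points. Pair counts follow the standard convention: the `N - m` template
#' vectors are compared pairwise with self-matches excluded, the same index
#' range serving both pattern lengths.
#'
#' @param x numeric series of length `N >= m + 2`.
#' @param m pattern length.
#' @param r_frac tolerance as a fraction of `sd(x)`.
#' @return Entropy in nats. A constant series returns the degenerate sentinel
#'   0 with a warning; when no `m + 1` match exists (`A = 0`) the value is
#'   capped at `log(B * (N - m - 1))`.
#' @export
sample_entropy <- function(x, m = 2L, r_frac = 0.1) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < m + 2) stop("series too short for pattern length m", call. = FALSE)
  s <- sd(x)
  if (s == 0) {
    warning("degenerate input (zero variance); sample entropy set to 0")
    return(0)
  }
  cnt <- sampen_counts_cpp(x, as.integer(m), r_frac * s)
  A <- cnt$A; B <- cnt$B
  if (B == 0) {
    warning("no length-m matches; sample entropy capped")
    return(log(N - m - 1))
  }
  if (A == 0) return(log(B * (N - m - 1)))
  -log(A / B)
}

#' Welch averaged-periodogram power spectral density
#'
#' Hann-tapered segments of `window_s` seconds with fractional `overlap`,
#' periodograms averaged. A signal shorter than one window is estimated with
#' a single whole-signal taper.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param window_s segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return List with `freq` (Hz, one-sided) and `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  n <- length(x)
  nw <- min(n, round(window_s * fs))
  hop <- max(1L, round(nw * (1 - overlap)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))   # Hann
  starts <- seq(1L, n - nw + 1L, by = hop)
  acc <- numeric(nw)
  for (s0 in starts) {
    seg <- x[s0 + seq_len(nw) - 1L] * win
    acc <- acc + Mod(fft(seg))^2
  }
  p <- acc / (length(starts) * sum(win^2) * fs)
  half <- floor(nw / 2)
  list(freq = (0:half) * fs / nw, psd = p[1:(half + 1L)])
}

#' Fraction of spectral power inside the Doppler cardiac band
#'
#' Power in `band` divided by the total power above DC, from the Welch
#' estimator. A 4 kHz segment with its energy at fetal valve/wall velocities
#' concentrates in the default 160-660 Hz band.
#'
#' @param x a `dus_segment` or numeric signal at the working rate.
#' @param band two-element band in Hz.
#' @param fs sampling rate (Hz, ignored when `x` is a segment).
#' @param window_s,overlap Welch estimator settings.
#' @return Ratio in \[0, 1\]; 0 with a warning for a zero-power input.
#' @export
psd_ratio <- function(x, band = c(160, 660), fs = 4000, window_s = 1,
                      overlap = 0.5) {
  if (inherits(x, "dus_segment")) { fs <- x$fs; x <- x$samples }
  w <- welch_psd(x, fs, window_s, overlap)
  total <- sum(w$psd[w$freq > 0])
  if (total == 0) {
    warning("zero-power input; PSD ratio set to 0")
    return(0)
  }
  sum(w$psd[w$freq >= band[1] & w$freq <= band[2]]) / total
}

#' 1-D earth mover's (Wasserstein-1) distance between empirical samples
#'
#' Computed in closed form as the integral of the absolute difference of the
#' two empirical CDFs.
#'
#' @param a,b non-empty numeric sample sets.
#' @return Non-negative scalar.
#' @export
earth_movers_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both sample sets must be non-empty", call. = FALSE)
  grid <- sort(c(a, b))
  k <- length(grid)
  if (k < 2) return(0)
  fa <- ecdf(a)(grid[-k])
  fb <- ecdf(b)(grid[-k])
  sum(abs(fa - fb) * diff(grid))
}

#' Grid search for the most discriminative power band
#'
#' For every candidate (low, high) band-edge pair, computes the PSD-ratio
#' distributions of the good- and poor-quality segments and their earth
#' mover's distance; returns the pair with the largest distance. Ties go to
#' the widest band (then the lowest low edge).
#'
#' @param good,poor lists of `dus_segment` (or numeric vectors at `fs`).
#' @param lo_range,hi_range two-element ranges (Hz) for the low and high band
#'   edges.
#' @param step grid step in Hz.
#' @param fs sampling rate (Hz).
#' @return List with `lo`, `hi` (Hz) and the `distance` achieved.
#' @export
optimize_band <- function(good, poor, lo_range = c(80, 400),
                          hi_range = c(580, 900), step = 20, fs = 4000) {
  if (length(good) < 2 || length(poor) < 2)
    stop("need at least 2 segments per class", call. = FALSE)
  if (step <= 0 || lo_range[2] < lo_range[1] || hi_range[2] < hi_range[1])
    stop("empty band grid", call. = FALSE)
  los <- seq(lo_range[1], lo_range[2], by = step)
  his <- seq(hi_range[1], hi_range[2], by = step)

  spectra <- function(segs) lapply(segs, function(s) {
    if (inherits(s, "dus_segment")) { x <- s$samples; f <- s$fs } else { x <- s; f <- fs }
    welch_psd(x, f)
  })
  sp_g <- spectra(good)
  sp_p <- spectra(poor)
  band_ratio <- function(w, lo, hi) {
    tot <- sum(w$psd[w$freq > 0])
    if (tot == 0) 0 else sum(w$psd[w$freq >= lo & w$freq <= hi]) / tot
  }
  best <- NULL
  for (lo in los) for (hi in his) {
    rg <- vapply(sp_g, band_ratio, numeric(1), lo = lo, hi = hi)
    rp <- vapply(sp_p, band_ratio, numeric(1), lo = lo, hi = hi)
    d <- earth_movers_distance(rg, rp)
    if (is.null(best) || d > best$distance + 1e-12 ||
        (abs(d - best$distance) <= 1e-12 &&
         (hi - lo > best$hi - best$lo ||
          (hi - lo == best$hi - best$lo && lo < best$lo)))) {
      best <- list(lo = lo, hi = hi, distance = d)
    }
  }
  best
}

feature_names <- c("sqi1", "sqi2", "sqi3", "sqi4", "h_s", "psd_ratio")

#' Assemble the six-feature vector of a segment
#'
#' Median template SQIs over the segment's beats, sample entropy of the raw
#' 4 kHz segment, and the Doppler-band PSD ratio, in the fixed order
#' (SQI1, SQI2, SQI3, SQI4, H_s, PSD ratio).
#'
#' @param segment a `dus_segment`.
#' @param beat_sqis per-beat score table from [compute_beat_sqis()]; `NULL`
#'   (no detected beats) scores the four SQIs 0.
#' @param config a [dus_config()].
#' @return One-row data frame: `subject_id`, `record_id`, `start_s`, the six
#'   features, `label`.
#' @export
build_feature_vector <- function(segment, beat_sqis = NULL, config = dus_config()) {
  stopifnot(inherits(segment, "dus_segment"))
  sq <- if (is.null(beat_sqis) || !nrow(beat_sqis)) {
    c(sqi1 = 0, sqi2 = 0, sqi3 = 0, sqi4 = 0)
  } else {
    segment_sqis(segment, beat_sqis, fs = segment$fs)
  }
  hs <- sample_entropy(segment$samples, m = config$entropy_m,
                       r_frac = config$entropy_r_frac)
  pr <- psd_ratio(segment, band = config$psd_band, fs = segment$fs,
                  window_s = config$welch_window_s, overlap = config$welch_overlap)
  data.frame(subject_id = segment$subject_id, record_id = segment$record_id,
             start_s = segment$start_time,
             sqi1 = unname(sq[1]), sqi2 = unname(sq[2]),
             sqi3 = unname(sq[3]), sqi4 = unname(sq[4]),
             h_s = hs, psd_ratio = pr, label = segment$label)
}

#' End-to-end feature extraction for one recording
#'
#' Resamples to the working rate if needed, detects beats by windowed EMD,
#' derives the CWT valve-band envelope and per-cycle templates, scores every
#' beat with the four SQIs, cuts the recording into 3.75-s segments (labelled
#' by annotator consensus when tracks are given), and assembles one feature
#' row per segment.
#'
#' @param rec a [dus_recording()].
#' @param annotations optional list of three annotation tracks (see
#'   [read_annotations()]).
#' @param config a [dus_config()].
#' @return Data frame with one row per segment (see
#'   [build_feature_vector()]).
#' @export
extract_features <- function(rec, annotations = NULL, config = dus_config()) {
  stopifnot(inherits(rec, "dus_recording"))
  if (rec$fs != config$target_fs)
    rec <- resample_to_working_rate(rec, target_fs = config$target_fs,
                                    order = config$antialias_order,
                                    cutoff_frac = config$antialias_cutoff_frac)
  beats <- tryCatch(detect_beats(rec, config), error = function(e) NULL)
  beat_sqis <- NULL
  if (!is.null(beats) && length(beats$beat_samples) >= 2) {
    cwt <- cwt_valve_band(rec$samples, fs = rec$fs, scale = config$cwt_scale,
                          window_s = config$cwt_window_s)
    cycles <- cycle_envelopes(cwt, beats, fs = rec$fs,
                              smooth_cutoff_hz = config$smooth_cutoff_hz,
                              envelope_fs = config$envelope_fs)
    if (length(cycles) >= 2) {
      templates <- build_templates(cycles, length(rec$samples), fs = rec$fs,
                                   config = config)
      beat_sqis <- compute_beat_sqis(cycles, templates, fs = rec$fs, config = config)
    }
  }
  segs <- segment_recording(rec, seg_len = config$seg_len_s,
                            stride = config$seg_stride_s)
  if (!length(segs)) return(NULL)
  if (!is.null(annotations))
    segs <- lapply(segs, assign_consensus_label, tracks = annotations)
  do.call(rbind, lapply(segs, build_feature_vector, beat_sqis = beat_sqis,
                        config = config))
}
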