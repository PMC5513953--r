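#' Specification of a synthetic Doppler recording
#'
#' The generator emulates the statistics of 1-D Doppler ultrasound of the
#' fetal heart at the 4 kHz working rate: quasi-periodic cardiac cycles at a
#' mean fetal heart rate with Gaussian beat-to-beat jitter, two
#' Gaussian-windowed bursts of band-limited carrier noise per cycle (the
#' valve events), broadband additive noise at a set SNR, and optional
#' dropout/transient artifacts. Three simulated annotators label every
#' second by thresholding a shared latent quality score with
#' annotator-specific offsets, so intermediate consensus classes arise at
#' intermediate SNR.
#'
#' @param duration_s recording length in seconds (>= 15 so template windows
#'   exist).
#' @param fhr_bpm mean fetal heart rate (90-210 bpm).
#' @param fhr_sd_bpm beat-to-beat heart-rate SD (bpm).
#' @param valve_band_hz two-element carrier band (Hz).
#' @param n_bursts_per_cycle valve-event bursts per cardiac cycle.
#' @param snr_db broadband signal-to-noise ratio (dB).
#' @param artifact_rate_per_min expected dropouts/transients per minute.
#' @param seed RNG seed; the same spec is byte-reproducible.
#' @return An object of class `dus_synthspec`.
#' @export
synth_spec <- function(duration_s = 60, fhr_bpm = 140, fhr_sd_bpm = 3.5,
                       valve_band_hz = c(160, 660), n_bursts_per_cycle = 2L,
                       snr_db = 10, artifact_rate_per_min = 0, seed = 1L) {
  if (fhr_bpm < 90 || fhr_bpm > 210)
    stop("fhr_bpm must lie in [90, 210]", call. = FALSE)
  if (duration_s < 15)
    stop("duration_s must be at least 15 s", call. = FALSE)
  structure(list(duration_s = duration_s, fhr_bpm = fhr_bpm,
                 fhr_sd_bpm = fhr_sd_bpm, valve_band_hz = valve_band_hz,
                 n_bursts_per_cycle = as.integer(n_bursts_per_cycle),
                 snr_db = snr_db, artifact_rate_per_min = artifact_rate_per_min,
                 seed = as.integer(seed)),
            class = "dus_synthspec")
}

#' Generate a synthetic Doppler recording with ground truth
#'
#' @param spec a [synth_spec()].
#' @param subject_id,record_id identity metadata for the recording.
#' @return List with `recording` (a [dus_recording()] at 4 kHz) and `truth`:
#'   `beat_samples` (true cycle onsets, sample units), `annotations` (three
#'   simulated per-second tracks usable by [assign_consensus_label()]),
#'   `latent_quality` (per-second score) and `artifact_seconds`.
#' @export
synth_recording <- function(spec, subject_id = "synth", record_id = "synth-1") {
  stopifnot(inherits(spec, "dus_synthspec"))
  set.seed(spec$seed)
  fs <- 4000
  n <- round(spec$duration_s * fs)
  n_sec <- floor(spec$duration_s)

  # beat onsets: instantaneous rate drawn per beat, converted to intervals
  mean_ppi <- 60 / spec$fhr_bpm
  onsets <- numeric()
  t <- 0.05
  while (t < spec$duration_s) {
    onsets <- c(onsets, t)
    bpm <- rnorm(1, spec$fhr_bpm, spec$fhr_sd_bpm)
    bpm <- min(max(bpm, 60), 240)
    t <- t + 60 / bpm
  }
  beat_samples <- round(onsets * fs) + 1

  # band-limited carrier shared by all bursts
  carrier <- bandlimited_noise(n, fs, spec$valve_band_hz)
  env <- numeric(n)
  burst_frac <- seq(0, by = 0.4, length.out = spec$n_bursts_per_cycle)
  burst_gain <- 0.7^(seq_len(spec$n_bursts_per_cycle) - 1)
  tt <- (seq_len(n) - 1) / fs
  ppis <- c(diff(onsets), mean_ppi)
  for (i in seq_along(onsets)) {
    width <- 0.045 * ppis[i]
    for (bi in seq_len(spec$n_bursts_per_cycle)) {
      ctr <- onsets[i] + burst_frac[bi] * ppis[i]
      lo <- max(1L, floor((ctr - 4 * width) * fs))
      hi <- min(n, ceiling((ctr + 4 * width) * fs))
      if (hi <= lo) next
      idx <- lo:hi
      env[idx] <- env[idx] + burst_gain[bi] * exp(-(tt[idx] - ctr)^2 / (2 * width^2))
    }
  }
  sig <- carrier * env
  p_sig <- mean(sig^2)
  noise <- rnorm(n, 0, sqrt(p_sig / 10^(spec$snr_db / 10)))
  x <- sig + noise

  # artifacts: half dropouts (flat-line), half large low-frequency transients
  n_art <- rpois(1, spec$artifact_rate_per_min * spec$duration_s / 60)
  artifact_seconds <- integer()
  if (n_art > 0) {
    for (a in seq_len(n_art)) {
      at <- runif(1, 0, spec$duration_s - 1)
      i0 <- round(at * fs) + 1
      i1 <- min(n, i0 + round(0.5 * fs))
      if (runif(1) < 0.5) {
        x[i0:i1] <- 0
      } else {
        tau <- (0:(i1 - i0)) / fs
        x[i0:i1] <- x[i0:i1] + 10 * sqrt(p_sig) * sin(2 * pi * 15 * tau) * exp(-tau / 0.2)
      }
      artifact_seconds <- union(artifact_seconds, floor(at):min(n_sec - 1, floor((i1 - 1) / fs)))
    }
  }
  x <- x / max(abs(x), 1e-12) * 0.9

  # latent per-second quality on the logit scale; annotators threshold it
  # with fixed offsets, producing disagreement at intermediate SNR
  latent <- (spec$snr_db - 3) / 2.5 + rnorm(n_sec, 0, 0.6)
  latent[artifact_seconds + 1] <- -10
  offsets <- c(-0.5, 0, 0.5)
  annotations <- lapply(seq_along(offsets), function(a) {
    list(annotator_id = paste0("ann", a),
         labels = as.integer(latent > offsets[a]))
  })

  list(recording = dus_recording(x, fs, subject_id, record_id),
       truth = list(beat_samples = beat_samples, annotations = annotations,
                    latent_quality = latent, artifact_seconds = artifact_seconds,
                    spec = spec))
}

# white noise confined to `band` with a 257-tap FIR bandpass (difference of
# least-squares low-pass prototypes), applied by FFT convolution
bandlimited_noise <- function(n, fs, band) {
  h_hi <- ls_lowpass_fir(256, band[2] / fs)
  h_lo <- ls_lowpass_fir(256, band[1] / fs)
  h <- h_hi - h_lo
  w <- rnorm(n + 256)
  y <- conv_full(w, h)
  y <- y[128 + seq_len(n)]
  y / sd(y)
}

#' Generate a labelled multi-subject synthetic dataset
#'
#' Draws per-subject generator settings from ranges, synthesizes one or more
#' recordings per subject, and returns the recordings together with their
#' simulated annotation tracks and consensus-labelled segments (via the same
#' ingestion path as real data).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param records_per_subject recordings per subject.
#' @param spec_ranges named list of two-element ranges overriding
#'   [synth_spec()] defaults, e.g. `list(fhr_bpm = c(120, 160),
#'   snr_db = c(-5, 15))`; scalar entries are held fixed.
#' @param duration_s recording length (s).
#' @param seed master seed; per-record seeds are derived from it.
#' @return List with `recordings`, `truths`, and `segments` (consensus
#'   labelled `dus_segment` list across all records).
#' @export
make_dataset <- function(n_subjects, records_per_subject = 1,
                         spec_ranges = list(), duration_s = 60, seed = 1) {
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  set.seed(seed)
  draw <- function(key, default) {
    rng <- spec_ranges[[key]]
    if (is.null(rng)) default
    else if (length(rng) == 1) rng
    else runif(1, rng[1], rng[2])
  }
  recordings <- list(); truths <- list(); segments <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    # heart rate is a subject trait; SNR and artifacts vary per acquisition
    fhr <- draw("fhr_bpm", 140)
    fhr_sd <- draw("fhr_sd_bpm", 3.5)
    for (r in seq_len(records_per_subject)) {
      rid <- sprintf("%s-R%02d", sid, r)
      snr <- draw("snr_db", 10)
      art <- draw("artifact_rate_per_min", 0)
      sp <- synth_spec(duration_s = duration_s, fhr_bpm = fhr,
                       fhr_sd_bpm = fhr_sd, snr_db = snr,
                       artifact_rate_per_min = art,
                       seed = (seed + 1013 * s + r) %% .Machine$integer.max)
      out <- synth_recording(sp, subject_id = sid, record_id = rid)
      recordings[[rid]] <- out$recording
      truths[[rid]] <- out$truth
      segs <- segment_recording(out$recording)
      segs <- lapply(segs, assign_consensus_label, tracks = out$truth$annotations)
      segments <- c(segments, segs)
    }
  }
  list(recordings = recordings, truths = truths, segments = segments)
}
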