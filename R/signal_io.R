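#' Recording constructor
#'
#' A recording is a mono Doppler-ultrasound waveform with its sampling rate
#' and subject/record identity.
#'
#' @param samples numeric vector of finite amplitudes (non-empty).
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id,record_id opaque identifier strings.
#' @return An object of class `dus_recording`.
#' @export
dus_recording <- function(samples, fs, subject_id = "unknown", record_id = "unknown") {
  samples <- as.numeric(samples)
  if (!length(samples)) stop("samples must be non-empty", call. = FALSE)
  if (!all(is.finite(samples))) stop("samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar", call. = FALSE)
  structure(list(samples = samples, fs = fs,
                 subject_id = as.character(subject_id),
                 record_id = as.character(record_id)),
            class = "dus_recording")
}

#' @export
print.dus_recording <- function(x, ...) {
  cat(sprintf("DUS recording '%s' (subject %s): %.2f s at %g Hz\n",
              x$record_id, x$subject_id, length(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Load a mono WAV recording
#'
#' Reads a RIFF/WAVE file (PCM 16-bit or IEEE float 32-bit). Multi-channel
#' files are rejected: the pipeline is defined for single-transducer audio.
#' PCM samples are scaled to \[-1, 1).
#'
#' @param path WAV file path.
#' @param subject_id,record_id identity metadata; `record_id` defaults to the
#'   file name without extension.
#' @return A [dus_recording()].
#' @export
load_recording <- function(path, subject_id = "unknown",
                           record_id = sub("\\.[Ww][Aa][Vv]$", "", basename(path))) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path, call. = FALSE)
  if (fmt$n_channels != 1)
    stop("multi-channel WAV not supported (", fmt$n_channels, " channels): ", path, call. = FALSE)

  if (fmt$audio_format == 1 && fmt$bits == 16) {
    samples <- readBin(data_raw, "integer", length(data_raw) %/% 2, 2,
                       signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    samples <- readBin(data_raw, "double", length(data_raw) %/% 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ", fmt$bits, " bit)", call. = FALSE)
  }
  dus_recording(samples, fmt$sample_rate, subject_id, record_id)
}

#' Write a recording to a 16-bit PCM WAV file
#'
#' Amplitudes are clipped to \[-1, 1\] before quantization.
#'
#' @param rec a [dus_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "dus_recording"))
  q <- as.integer(pmax(-32768, pmin(32767, round(rec$samples * 32768))))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")                    # PCM, mono
  writeBin(as.integer(rec$fs), con, 4, endian = "little")
  writeBin(as.integer(rec$fs * 2), con, 4, endian = "little")       # byte rate
  writeBin(c(2L, 16L), con, 2, endian = "little")                   # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(q, con, 2, endian = "little")
  invisible(path)
}

#' Resample a recording to the working rate
#'
#' Applies a least-squares linear-phase FIR anti-aliasing low-pass (truncated
#' ideal impulse response, the L2-optimal linear-phase design) with zero-phase
#' compensation, then samples the filtered waveform on the target grid. Only
#' downsampling is supported; the working rate for the pipeline is 4 kHz.
#'
#' @param rec a [dus_recording()] with `fs >= target_fs`.
#' @param target_fs target rate in Hz.
#' @param order FIR order (taps - 1).
#' @param cutoff_frac anti-alias cutoff as a fraction of the target Nyquist.
#' @return A [dus_recording()] at `target_fs` with
#'   `round(n * target_fs / fs)` samples.
#' @export
resample_to_working_rate <- function(rec, target_fs = 4000, order = 512,
                                     cutoff_frac = 0.9) {
  stopifnot(inherits(rec, "dus_recording"))
  if (rec$fs < target_fs)
    stop("upsampling not supported (fs ", rec$fs, " < target ", target_fs, ")", call. = FALSE)
  n <- length(rec$samples)
  m <- round(n * target_fs / rec$fs)
  if (rec$fs == target_fs) return(rec)

  # least-squares design: unit passband up to the cutoff, zero stopband from
  # the target Nyquist, transition band left unconstrained
  h <- ls_fir_lowpass(order, cutoff_frac * target_fs / 2 / rec$fs,
                      target_fs / 2 / rec$fs)
  half <- order %/% 2
  # reflect-pad so the zero-phase trim has full support at the edges
  pad_l <- rev(rec$samples[seq_len(min(half, n - 1)) + 1])
  pad_r <- rev(rec$samples[n - seq_len(min(half, n - 1))])
  y <- conv_full(c(pad_l, rec$samples, pad_r), h)
  y <- y[(length(pad_l) + half) + seq_len(n)]

  t_new <- (seq_len(m) - 1) / target_fs
  out <- approx(x = (seq_len(n) - 1) / rec$fs, y = y, xout = t_new, rule = 2)$y
  dus_recording(out, target_fs, rec$subject_id, rec$record_id)
}

# impulse response of the ideal low-pass truncated to `order`+1 taps
# (normalized cutoff wc in cycles/sample); L2-optimal brickwall
# approximation, used where edge ripple is harmless
ls_lowpass_fir <- function(order, wc) {
  k <- seq(-order %/% 2, order %/% 2)
  h <- ifelse(k == 0, 2 * wc, sin(2 * pi * wc * k) / (pi * k))
  h / sum(h)
}

# linear-phase (type I) low-pass minimizing the squared frequency-response
# error over passband [0, fp] (gain 1) and stopband [fst, 0.5] (gain 0),
# with [fp, fst] as unconstrained transition; frequencies in cycles/sample
ls_fir_lowpass <- function(order, fp, fst) {
  M <- order %/% 2
  f <- seq(0, 0.5, length.out = 2048)
  f <- f[f <= fp | f >= fst]
  D <- as.numeric(f <= fp)
  X <- cos(2 * pi * outer(f, 0:M))
  a <- as.numeric(qr.solve(crossprod(X), crossprod(X, D)))
  c(rev(a[-1] / 2), a[1], a[-1] / 2)
}

# linear convolution via FFT
conv_full <- function(x, h) {
  nfft <- 2^ceiling(log2(length(x) + length(h) - 1))
  Re(fft(fft(c(x, numeric(nfft - length(x)))) *
           fft(c(h, numeric(nfft - length(h)))), inverse = TRUE))[
             seq_len(length(x) + length(h) - 1)] / nfft
}

#' Cut a recording into overlapping fixed-length segments
#'
#' Segments of `seg_len` seconds are taken every `stride` seconds from the
#' start of the recording; the sample count of every segment is fixed at
#' `seg_len * fs` to avoid off-by-one drift across overlaps.
#'
#' @param rec a [dus_recording()] at the working rate.
#' @param seg_len segment duration in seconds.
#' @param stride hop between segment starts in seconds.
#' @return A list of `dus_segment` objects (label `"unlabeled"`); empty, with
#'   a warning, when the recording is shorter than `seg_len`.
#' @export
segment_recording <- function(rec, seg_len = 3.75, stride = 3.0) {
  stopifnot(inherits(rec, "dus_recording"))
  fs <- rec$fs
  dur <- length(rec$samples) / fs
  n_seg_samp <- round(seg_len * fs)
  if (dur < seg_len) {
    warning("recording shorter than one segment (", signif(dur, 4), " s); no segments")
    return(list())
  }
  starts <- seq(0, dur - seg_len, by = stride)
  lapply(starts, function(s) {
    i0 <- round(s * fs)
    dus_segment(rec$samples[i0 + seq_len(n_seg_samp)], start_time = s,
                duration = seg_len, fs = fs, label = "unlabeled",
                subject_id = rec$subject_id, record_id = rec$record_id)
  })
}

quality_classes <- c("good", "mostly_clean", "mostly_noisy", "poor", "rejected", "unlabeled")

#' @rdname segment_recording
#' @param samples segment samples at the working rate.
#' @param start_time offset from the record start (s).
#' @param duration segment duration (s).
#' @param fs sampling rate (Hz).
#' @param label one of good, mostly_clean, mostly_noisy, poor, rejected,
#'   unlabeled.
#' @param subject_id,record_id identity metadata.
#' @export
dus_segment <- function(samples, start_time, duration = 3.75, fs = 4000,
                        label = "unlabeled", subject_id = "unknown",
                        record_id = "unknown") {
  label <- match.arg(label, quality_classes)
  structure(list(samples = as.numeric(samples), start_time = start_time,
                 duration = duration, fs = fs, label = label,
                 subject_id = as.character(subject_id),
                 record_id = as.character(record_id)),
            class = "dus_segment")
}

#' Consensus quality label for a segment from three annotation tracks
#'
#' Each annotator labels whole seconds of a recording as good (1) or poor (0).
#' A segment spans seconds `floor(start)` through `floor(start + duration)`
#' (exclusive of an exact boundary); the partial trailing fraction inherits
#' the label of the second containing it. An annotator whose labels are not
#' constant over that span makes the segment `rejected`; otherwise the number
#' of annotators voting good maps 3/2/1/0 to
#' good / mostly_clean / mostly_noisy / poor.
#'
#' @param segment a `dus_segment`.
#' @param tracks list of three annotation tracks, each a list with
#'   `annotator_id` and `labels` (per-second 0/1 vector from time 0).
#' @return The segment with its `label` field set.
#' @export
assign_consensus_label <- function(segment, tracks) {
  stopifnot(inherits(segment, "dus_segment"))
  if (length(tracks) != 3) stop("exactly three annotation tracks required", call. = FALSE)
  eps <- 1e-9
  secs <- seq(floor(segment$start_time + eps),
              floor(segment$start_time + segment$duration - eps))
  votes <- 0L
  rejected <- FALSE
  for (tr in tracks) {
    lab <- tr$labels
    if (!all(lab %in% c(0, 1))) stop("annotation labels must be 0/1", call. = FALSE)
    if (max(secs) + 1 > length(lab))
      stop("annotation track '", tr$annotator_id, "' does not cover second ",
           max(secs), call. = FALSE)
    span <- lab[secs + 1]
    if (length(unique(span)) > 1) rejected <- TRUE else votes <- votes + span[1]
  }
  segment$label <- if (rejected) "rejected"
  else c("poor", "mostly_noisy", "mostly_clean", "good")[votes + 1]
  segment
}

#' Read and write per-second annotation tracks
#'
#' The on-disk dialect is one CSV per record with columns `second_index`
#' (0-based), `annotator_id` and `label` (`good`/`poor`).
#'
#' @param path CSV file path.
#' @return `read_annotations`: a list of tracks (one per annotator, ordered by
#'   id), each with `annotator_id` and a 0/1 `labels` vector.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("second_index", "annotator_id", "label")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(df$label %in% c("good", "poor")))
    stop("annotation labels must be 'good' or 'poor'", call. = FALSE)
  lapply(sort(unique(df$annotator_id)), function(a) {
    sub <- df[df$annotator_id == a, ]
    sub <- sub[order(sub$second_index), ]
    if (!identical(sub$second_index, seq_len(nrow(sub)) - 1L) &&
        !identical(as.integer(sub$second_index), seq_len(nrow(sub)) - 1L))
      stop("annotator '", a, "': second_index must be contiguous from 0", call. = FALSE)
    list(annotator_id = as.character(a), labels = as.integer(sub$label == "good"))
  })
}

#' @rdname read_annotations
#' @param tracks list of annotation tracks as returned by `read_annotations`.
#' @export
write_annotations <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(second_index = seq_along(tr$labels) - 1L,
               annotator_id = tr$annotator_id,
               label = ifelse(tr$labels == 1, "good", "poor"))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Export a segment index as CSV
#'
#' @param segments list of `dus_segment`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment_index <- function(segments, path) {
  df <- data.frame(
    record_id = vapply(segments, `[[`, character(1), "record_id"),
    start_s   = vapply(segments, `[[`, numeric(1), "start_time"),
    label     = vapply(segments, `[[`, character(1), "label")
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
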