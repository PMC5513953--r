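#' Template constructor
#'
#' A template is the running prototype envelope of one 15-s window: the
#' pointwise mean of onset-aligned normalized cycle envelopes, of length L =
#' rounded mean beat-to-beat interval of the window.
#'
#' @param values prototype sequence of length `L` (or `NULL` when invalid).
#' @param L template length in samples.
#' @param window_index 1-based 15-s window index.
#' @param valid logical validity flag.
#' @param support_count number of cycles averaged.
#' @return An object of class `dus_template`.
#' @export
dus_template <- function(values, L, window_index = 1L, valid = TRUE,
                         support_count = 0L) {
  structure(list(values = values, L = L, window_index = window_index,
                 valid = valid, support_count = support_count),
            class = "dus_template")
}

# trim to L or zero-pad at the tail (cycles are onset-aligned)
fit_length <- function(v, L) {
  if (length(v) >= L) v[seq_len(L)] else c(v, numeric(L - length(v)))
}

# Pearson correlation with degenerate inputs scored 0, negatives clipped to 0
clipped_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  max(0, cor(a, b))
}

#' Initial template of a 15-s window
#'
#' @param cycles list of `dus_cycle` envelopes whose onsets fall in the
#'   window (at least 2 for a valid template).
#' @param window_index window identifier stored on the template.
#' @return A [dus_template()]; invalid (with `support_count` 0) when fewer
#'   than two cycles are available.
#' @export
initial_template <- function(cycles, window_index = 1L) {
  if (length(cycles) < 2)
    return(dus_template(NULL, L = NA_integer_, window_index = window_index,
                        valid = FALSE, support_count = 0L))
  btbis <- vapply(cycles, `[[`, numeric(1), "length_samples")
  L <- as.integer(round(mean(btbis)))
  mat <- vapply(cycles, function(cy) fit_length(cy$values, L), numeric(L))
  dus_template(rowMeans(mat), L = L, window_index = window_index,
               valid = TRUE, support_count = length(cycles))
}

#' Correlation-gated template update with neighbor fallback
#'
#' Each cycle (fitted to length L) is correlated with the initial template;
#' if at least `validity_fraction` of the cycles reach
#' `r >= corr_threshold`, the template is replaced by the mean of those
#' qualifying cycles. Otherwise the window's template is invalid and the
#' previous window's template is used; if that is also invalid, the next
#' window's. When both neighbors are invalid the window is template-less
#' (`valid = FALSE`, `values = NULL`) and its beats score 0.
#'
#' @param t initial [dus_template()] of the window.
#' @param cycles the window's `dus_cycle` list.
#' @param prev,nxt neighboring windows' own templates (or `NULL`).
#' @param corr_threshold per-cycle correlation gate (inclusive).
#' @param validity_fraction minimum fraction of qualifying cycles (inclusive).
#' @return An updated [dus_template()].
#' @export
update_template <- function(t, cycles, prev = NULL, nxt = NULL,
                            corr_threshold = 0.6, validity_fraction = 0.2) {
  stopifnot(inherits(t, "dus_template"))
  own <- if (t$valid && length(cycles)) {
    rs <- vapply(cycles, function(cy) {
      a <- fit_length(cy$values, t$L)
      if (sd(a) == 0 || sd(t$values) == 0) -Inf else cor(a, t$values)
    }, numeric(1))
    keep <- rs >= corr_threshold
    if (mean(keep) >= validity_fraction) {
      mat <- vapply(cycles[keep], function(cy) fit_length(cy$values, t$L),
                    numeric(t$L))
      mat <- matrix(mat, nrow = t$L)
      dus_template(rowMeans(mat), L = t$L, window_index = t$window_index,
                   valid = TRUE, support_count = sum(keep))
    } else NULL
  } else NULL
  if (!is.null(own)) return(own)
  for (nb in list(prev, nxt)) {
    if (!is.null(nb) && isTRUE(nb$valid))
      return(dus_template(nb$values, L = nb$L, window_index = t$window_index,
                          valid = TRUE, support_count = nb$support_count))
  }
  dus_template(NULL, L = t$L, window_index = t$window_index,
               valid = FALSE, support_count = 0L)
}

#' Direct-matching SQI (no time normalization)
#'
#' The cycle is truncated to the template length L (or zero-padded at the
#' tail when shorter) and Pearson-correlated with the template; negative
#' correlations are clipped to 0.
#'
#' @param cycle a `dus_cycle` (or numeric vector).
#' @param t a valid [dus_template()].
#' @return Score in \[0, 1\].
#' @export
sqi1_direct <- function(cycle, t) {
  v <- cycle_values(cycle)
  stopifnot(isTRUE(t$valid))
  clipped_cor(fit_length(v, t$L), t$values)
}

#' Linear-resampling SQI
#'
#' The full cycle is linearly stretched or compressed to exactly L points
#' before correlation with the template.
#'
#' @inheritParams sqi1_direct
#' @return Score in \[0, 1\].
#' @export
sqi2_linear <- function(cycle, t) {
  v <- cycle_values(cycle)
  stopifnot(isTRUE(t$valid), length(v) >= 2)
  y <- approx(seq_along(v), v, xout = seq(1, length(v), length.out = t$L))$y
  clipped_cor(y, t$values)
}

#' Dynamic time warping alignment
#'
#' Aligns `seq` onto `ref` with a monotone, continuous, boundary-anchored
#' warping path (steps down/right/diagonal) minimizing the summed weighted
#' squared difference `w(|i-j|) * (seq[i] - ref[j])^2`. The warped output has
#' one value per `ref` index: the mean of the `seq` values matched to it.
#'
#' @param seq,ref numeric sequences, lengths >= 2.
#' @param weights `NULL` for classical (uniform-weight) DTW, or a function of
#'   the absolute index phase lag `d` returning a non-negative weight.
#' @return Numeric vector of `length(ref)` with the optimal path cost in
#'   attribute `"cost"`.
#' @export
dtw_align <- function(seq, ref, weights = NULL) {
  seq <- as.numeric(seq); ref <- as.numeric(ref)
  if (length(seq) < 2 || length(ref) < 2)
    stop("both sequences need length >= 2", call. = FALSE)
  d <- 0:(max(length(seq), length(ref)) - 1)
  w <- if (is.null(weights)) rep(1, length(d)) else as.numeric(weights(d))
  res <- dtw_align_cpp(seq, ref, w)
  structure(res$aligned, cost = res$cost)
}

# logistic phase-penalty weight used by the weighted-DTW SQI: midpoint at
# L/2, unit ceiling; g = 0 gives a constant 1/2 (classical DTW path)
wdtw_weight <- function(g, L) {
  function(d) 1 / (1 + exp(-g * (d - L / 2)))
}

#' DTW and weighted-DTW SQIs
#'
#' The cycle is warped onto the template by [dtw_align()] and the warped
#' sequence Pearson-correlated with the template (negatives clipped). `sqi3`
#' uses uniform weights; `sqi4` penalizes matches with large index phase lag
#' `d` through the logistic weight `1 / (1 + exp(-g (d - L/2)))`.
#'
#' @inheritParams sqi1_direct
#' @param g phase-penalty parameter of the weighted variant.
#' @return Score in \[0, 1\].
#' @export
sqi3_dtw <- function(cycle, t) {
  v <- cycle_values(cycle)
  stopifnot(isTRUE(t$valid))
  if (sd(v) == 0) return(0)
  clipped_cor(dtw_align(v, t$values), t$values)
}

#' @rdname sqi3_dtw
#' @export
sqi4_wdtw <- function(cycle, t, g = 0.02) {
  v <- cycle_values(cycle)
  stopifnot(isTRUE(t$valid))
  if (sd(v) == 0) return(0)
  clipped_cor(dtw_align(v, t$values, weights = wdtw_weight(g, t$L)), t$values)
}

cycle_values <- function(cycle) {
  if (inherits(cycle, "dus_cycle")) cycle$values else as.numeric(cycle)
}

# 1-based 15-s window index of a sample position
window_of_sample <- function(sample, fs, window_s = 15) {
  as.integer(floor((sample - 1) / (window_s * fs))) + 1L
}

#' Build per-window templates for a recording
#'
#' Tiles the recording into contiguous 15-s windows from t = 0, assigns each
#' cycle to the window containing its onset, computes the initial template of
#' every window and applies the correlation-gated update with
#' previous/next-window fallback.
#'
#' @param cycles list of `dus_cycle` from [cycle_envelopes()].
#' @param n_samples recording length in samples.
#' @param fs sampling rate (Hz).
#' @param config a [dus_config()].
#' @return A list of [dus_template()], one per window.
#' @export
build_templates <- function(cycles, n_samples, fs = 4000, config = dus_config()) {
  n_win <- max(1L, ceiling(n_samples / (config$template_window_s * fs)))
  onsets <- vapply(cycles, `[[`, numeric(1), "onset_sample")
  win <- window_of_sample(onsets, fs, config$template_window_s)
  by_win <- lapply(seq_len(n_win), function(w) cycles[win == w])

  initial <- lapply(seq_len(n_win), function(w) initial_template(by_win[[w]], w))
  # each window's own updated template (no fallback), then fallback resolution
  own <- lapply(seq_len(n_win), function(w) {
    update_template(initial[[w]], by_win[[w]],
                    corr_threshold = config$corr_threshold,
                    validity_fraction = config$validity_fraction)
  })
  lapply(seq_len(n_win), function(w) {
    if (isTRUE(own[[w]]$valid)) return(own[[w]])
    prev <- if (w > 1) own[[w - 1]] else NULL
    nxt <- if (w < n_win) own[[w + 1]] else NULL
    update_template(initial[[w]], by_win[[w]], prev = prev, nxt = nxt,
                    corr_threshold = config$corr_threshold,
                    validity_fraction = config$validity_fraction)
  })
}

#' Score every cycle against its window template
#'
#' @param cycles list of `dus_cycle`.
#' @param templates per-window templates from [build_templates()].
#' @param fs sampling rate (Hz).
#' @param config a [dus_config()].
#' @return A data frame with one row per cycle: `beat_index`, `onset_sample`,
#'   `window_index`, `sqi1`..`sqi4`. Cycles in template-less windows score 0.
#' @export
compute_beat_sqis <- function(cycles, templates, fs = 4000, config = dus_config()) {
  rows <- lapply(seq_along(cycles), function(i) {
    cy <- cycles[[i]]
    w <- window_of_sample(cy$onset_sample, fs, config$template_window_s)
    t <- if (w <= length(templates)) templates[[w]] else NULL
    if (is.null(t) || !isTRUE(t$valid)) {
      s <- c(0, 0, 0, 0)
    } else {
      s <- c(sqi1_direct(cy, t), sqi2_linear(cy, t), sqi3_dtw(cy, t),
             sqi4_wdtw(cy, t, g = config$wdtw_g))
    }
    data.frame(beat_index = i, onset_sample = cy$onset_sample, window_index = w,
               sqi1 = s[1], sqi2 = s[2], sqi3 = s[3], sqi4 = s[4])
  })
  do.call(rbind, rows)
}

#' Segment-level SQIs as medians over the segment's beats
#'
#' @param segment a `dus_segment`.
#' @param beat_sqis per-beat score table from [compute_beat_sqis()].
#' @param fs sampling rate (Hz).
#' @return Named numeric vector `(sqi1, sqi2, sqi3, sqi4)`; all zeros when no
#'   beat onset falls inside the segment.
#' @export
segment_sqis <- function(segment, beat_sqis, fs = 4000) {
  stopifnot(inherits(segment, "dus_segment"))
  i0 <- segment$start_time * fs
  i1 <- (segment$start_time + segment$duration) * fs
  sel <- beat_sqis$onset_sample >= i0 & beat_sqis$onset_sample < i1
  if (!any(sel)) {
    message("segment at ", segment$start_time, " s overlaps no scored beat; SQIs set to 0")
    return(c(sqi1 = 0, sqi2 = 0, sqi3 = 0, sqi4 = 0))
  }
  vapply(c("sqi1", "sqi2", "sqi3", "sqi4"),
         function(k) median(beat_sqis[[k]][sel]), numeric(1))
}
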