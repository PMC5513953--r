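test_that("derivative-criterion peak detection finds isolated and periodic peaks", {
  expect_equal(detect_peaks(c(0, 1, 0)), 2L)
  expect_length(detect_peaks(1:50), 0)
  # 2 Hz over 2 s: one maximum per 0.5-s period, first at t = 0.125 s
  x <- sin(2 * pi * 2 * (0:7999) / 4000)
  pk <- detect_peaks(x)
  expect_length(pk, 4)
  expect_true(all(abs(pk - c(501, 2501, 4501, 6501)) <= 1))
})

make_decomp <- function(imfs) {
  structure(list(imfs = imfs, residual = numeric(length(imfs[[1]])),
                 n_sift_iters = rep(1L, length(imfs))),
            class = "imf_decomposition")
}

burst_imf <- function(centers, fs = 4000, n = 16000, f0 = 300, width = 0.03) {
  t <- (0:(n - 1)) / fs
  env <- rowSums(sapply(centers, function(ctr) exp(-(t - ctr)^2 / (2 * width^2))))
  sin(2 * pi * f0 * t) * env
}

test_that("the IMF with the most regular envelope peaks is selected", {
  set.seed(7)
  regular <- seq(0.3, 3.7, by = 0.45)
  jit1 <- regular + runif(length(regular), -0.08, 0.08)
  jit2 <- regular + runif(length(regular), -0.12, 0.12)
  dec <- make_decomp(list(burst_imf(jit1, f0 = 700), burst_imf(regular, f0 = 300),
                          burst_imf(jit2, f0 = 120)))
  sel <- select_optimal_imf(dec)
  expect_equal(sel$imf_index, 2)
  expect_equal(length(sel$peaks), length(regular))

  # single qualifying IMF is returned; flat IMFs are excluded
  dec1 <- make_decomp(list(numeric(16000), burst_imf(regular)))
  expect_equal(select_optimal_imf(dec1)$imf_index, 2)

  # exact tie in PPI SD resolves to the lowest IMF index
  dec_tie <- make_decomp(list(burst_imf(regular), burst_imf(regular)))
  expect_equal(select_optimal_imf(dec_tie)$imf_index, 1)
})

test_that("window stitching deduplicates seam peaks by the 0.2 x PPI rule", {
  expect_equal(stitch_windows(list(c(1000, 2600, 4200), c(4200, 5800))),
               c(1000, 2600, 4200, 5800))
  # a peak seen only by the later window survives
  expect_equal(stitch_windows(list(c(1000, 2600), c(4200, 5800))),
               c(1000, 2600, 4200, 5800))
  # 10 ms apart with a 400 ms local PPI: merged, earlier kept
  merged <- stitch_windows(list(c(1000, 2600, 4200, 5800), c(5840, 7400, 9000)))
  expect_equal(merged, c(1000, 2600, 4200, 5800, 7400, 9000))
  expect_true(all(diff(merged) > 0))
})

test_that("5-PPI correction replaces only >20 % deviations and is idempotent", {
  mk <- function(ppis) dus_beats(cumsum(c(10000, ppis)))
  out <- correct_ppis(mk(c(500, 500, 700, 500, 500)))
  expect_equal(out$ppis, rep(500, 5))
  expect_equal(correct_ppis(mk(rep(500, 6)))$ppis, rep(500, 6))
  # 16 % deviation is tolerated
  expect_equal(correct_ppis(mk(c(500, 500, 580, 500, 500)))$ppis,
               c(500, 500, 580, 500, 500))
  expect_warning(correct_ppis(mk(c(500, 510))), "fewer than 5")

  set.seed(3)
  ppis <- rnorm(60, 1700, 30)
  ppis[c(12, 30, 31, 48)] <- c(900, 2600, 950, 2900)
  once <- correct_ppis(mk(ppis))
  twice <- correct_ppis(once)
  expect_equal(twice$ppis, once$ppis)
})

test_that("valve-band CWT magnitude behaves like a sub-kHz band-pass", {
  fs <- 4000
  t <- (0:(4 * fs - 1)) / fs
  m_in <- mean(cwt_valve_band(sin(2 * pi * 500 * t), fs))
  m_out <- mean(cwt_valve_band(sin(2 * pi * 1500 * t), fs))
  expect_gt(m_in / m_out, 2)
  expect_equal(max(cwt_valve_band(numeric(8000), fs)), 0)
  imp <- numeric(8000); imp[4000] <- 1
  expect_lt(abs(sum(cwt_valve_band(imp, fs)^2) - 1), 0.01)
  # windowed processing (> 25 s) matches the whole-signal transform away
  # from seams
  x <- random_smooth_signal(30 * fs, seed = 4)
  w_win <- cwt_valve_band(x, fs, window_s = 25)
  w_all <- cwt_valve_band(x, fs, window_s = 40)
  expect_lt(max(abs(w_win - w_all)) / max(w_all), 1e-6)
})

test_that("cycle envelopes are normalized and keep within-cycle morphology", {
  fs <- 4000
  n <- 20 * fs
  t <- (0:(n - 1)) / fs
  onsets <- seq(0.2, 19.4, by = 0.45)
  bumps <- rowSums(sapply(onsets, function(o) {
    exp(-(t - o)^2 / (2 * 0.03^2)) + 0.7 * exp(-(t - o - 0.18)^2 / (2 * 0.03^2))
  }))
  cwt_mag <- abs(sin(2 * pi * 300 * t)) * bumps
  # cut slightly ahead of the first burst so both bursts are cycle-interior
  beats <- dus_beats(round((onsets - 0.06) * fs) + 1, fs = fs)
  cycles <- cycle_envelopes(cwt_mag, beats, fs = fs)
  expect_gt(length(cycles), 30)
  for (cy in cycles) {
    expect_lt(abs(mean(cy$values)), 1e-9)
    expect_lt(abs(sd(cy$values) - 1), 1e-9)
  }
  # two valve bursts per cycle survive smoothing and decimation
  two_max <- vapply(cycles, function(cy) {
    length(detect_peaks(cy$values)) >= 2
  }, logical(1))
  expect_gt(mean(two_max), 0.9)
})

test_that("envelope smoothing suppresses out-of-band ripple by > 20 dB", {
  fs <- 4000
  n <- 16 * fs
  t <- (0:(n - 1)) / fs
  slow <- 2 + sin(2 * pi * 3 * t)
  rippled <- slow + 0.3 * sin(2 * pi * 500 * t)
  beats <- dus_beats(seq(1000, n - 2000, by = 1800), fs = fs)
  cycles <- cycle_envelopes(rippled, beats, fs = fs, envelope_fs = fs)
  env <- attr(cycles, "envelope")
  band_power <- function(x) {
    p <- Mod(fft(x - mean(x)))^2
    f <- (0:(length(x) - 1)) * fs / length(x)
    sum(p[f >= 480 & f <= 520])
  }
  expect_lt(band_power(env) / band_power(rippled), 10^(-20 / 10))
})

test_that("beats are recovered from synthetic recordings at moderate SNR", {
  for (seed in c(21, 22, 23)) {
    out <- synth_recording(synth_spec(duration_s = 60, snr_db = 12, seed = seed))
    beats <- detect_beats(out$recording)
    tb <- out$truth$beat_samples
    recall <- mean(vapply(tb, function(b)
      min(abs(beats$beat_samples - b)) <= 0.05 * 4000, logical(1)))
    expect_gte(recall, 0.95)
    bpm <- 60 * 4000 / beats$ppis
    expect_true(all(bpm >= 90 & bpm <= 215))
  }
})
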