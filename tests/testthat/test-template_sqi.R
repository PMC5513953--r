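triangle <- function(L) {
  v <- c(seq_len(ceiling(L / 2)), rev(seq_len(floor(L / 2))))
  as.numeric(scale(v[seq_len(L)]))
}

test_that("initial template averages onset-aligned cycles at length L", {
  v <- triangle(100)
  cycles <- lapply(1:5, function(i) make_cycle(v))
  t <- initial_template(cycles, window_index = 1L)
  expect_true(t$valid)
  expect_equal(t$L, 100L)
  expect_equal(t$values, make_cycle(v)$values)
  expect_equal(t$support_count, 5L)

  mixed <- list(make_cycle(rnorm(400)), make_cycle(rnorm(420)), make_cycle(rnorm(380)))
  expect_equal(initial_template(mixed)$L, 400L)

  single <- initial_template(list(make_cycle(v)))
  expect_false(single$valid)
  expect_equal(single$support_count, 0L)
})

test_that("template update keeps correlated cycles and falls back by neighbor", {
  v <- triangle(80)
  cycles <- lapply(1:6, function(i) make_cycle(v))
  t0 <- initial_template(cycles)
  up <- update_template(t0, cycles)
  expect_true(up$valid)
  expect_equal(up$support_count, 6L)
  expect_equal(up$values, t0$values)

  # 1 of 10 matching (10 % < 20 %) invalidates; previous window's template used
  set.seed(1)
  noise_cycles <- c(list(make_cycle(v)),
                    lapply(1:9, function(i) make_cycle(rnorm(80))))
  t_noise <- initial_template(noise_cycles)
  prev <- dus_template(triangle(70), L = 70L, window_index = 0L,
                       valid = TRUE, support_count = 4L)
  fb <- update_template(t_noise, noise_cycles, prev = prev)
  expect_true(fb$valid)
  expect_equal(fb$values, prev$values)
  expect_equal(fb$window_index, t_noise$window_index)

  # previous invalid -> next window's template
  nxt <- dus_template(triangle(90), L = 90L, window_index = 2L,
                      valid = TRUE, support_count = 3L)
  bad_prev <- dus_template(NULL, L = 80L, valid = FALSE)
  fb2 <- update_template(t_noise, noise_cycles, prev = bad_prev, nxt = nxt)
  expect_equal(fb2$values, nxt$values)

  # both neighbors invalid -> template-less window
  fb3 <- update_template(t_noise, noise_cycles, prev = bad_prev, nxt = NULL)
  expect_false(fb3$valid)
  expect_null(fb3$values)
})

test_that("the 20 % validity boundary is inclusive at r = 0.6", {
  L <- 60
  base <- triangle(L)
  t0 <- dus_template(base, L = as.integer(L), valid = TRUE, support_count = 2L)
  # construct cycles with an exact known correlation to the template:
  # mix base with an orthogonal unit vector
  set.seed(5)
  orth <- as.numeric(scale(residuals(lm(rnorm(L) ~ base))))
  at_r <- function(r) make_cycle(r * base + sqrt(1 - r^2) * orth)
  cyc <- c(lapply(1:2, function(i) at_r(0.6000001)),
           lapply(1:8, function(i) at_r(-0.5)))
  up <- update_template(t0, cyc)
  expect_true(up$valid)       # exactly 2 of 10 = 20 % at r >= 0.6
  expect_equal(up$support_count, 2L)
})

test_that("self-correlation gives 1 and anti-correlation clips to 0 for all SQIs", {
  v <- triangle(90)
  t <- dus_template(make_cycle(v)$values, L = 90L, valid = TRUE)
  cy <- make_cycle(v)
  expect_equal(sqi1_direct(cy, t), 1)
  expect_equal(sqi2_linear(cy, t), 1)
  expect_equal(sqi3_dtw(cy, t), 1)
  expect_equal(sqi4_wdtw(cy, t), 1)
  anti <- make_cycle(-v)
  expect_equal(sqi1_direct(anti, t), 0)
  expect_equal(sqi2_linear(anti, t), 0)
})

test_that("short cycles are tail-padded for the direct SQI per the Pearson formula", {
  tpl_v <- triangle(100)
  t <- dus_template(tpl_v, L = 100L, valid = TRUE)
  part <- tpl_v[1:80]
  cy <- make_cycle(part)
  padded <- c((part - mean(part)) / sd(part), numeric(20))
  mx <- mean(padded); my <- mean(tpl_v)
  expected <- sum((padded - mx) * (tpl_v - my)) /
    sqrt(sum((padded - mx)^2) * sum((tpl_v - my)^2))
  expect_equal(sqi1_direct(cy, t), max(0, expected))
})

test_that("linear-resampling SQI round-trips an upsampled template", {
  tpl_v <- as.numeric(scale(sin(seq(0, 2 * pi, length.out = 120))))
  t <- dus_template(tpl_v, L = 120L, valid = TRUE)
  up2 <- approx(seq_len(120), tpl_v, n = 240)$y
  expect_gt(sqi2_linear(make_cycle(up2), t), 0.99)
})

test_that("white-noise cycles score near zero on the linear-resampling SQI", {
  t <- dus_template(triangle(50), L = 50L, valid = TRUE)
  set.seed(10)
  raw <- replicate(1000, {
    v <- rnorm(40)
    y <- approx(seq_along(v), v, xout = seq(1, 40, length.out = 50))$y
    cor(y, t$values)   # unclipped null distribution
  })
  expect_lt(abs(mean(raw)), 0.1)
})

test_that("DTW alignment matches exhaustive path enumeration", {
  expect_equal(as.numeric(dtw_align(1:5, 1:5)), as.numeric(1:5))
  expect_equal(attr(dtw_align(1:5, 1:5), "cost"), 0)
  s <- c(1, 3, 3, 5); r <- c(1, 3, 5)
  al <- dtw_align(s, r)
  expect_equal(as.numeric(al), r)
  expect_equal(attr(al, "cost"), 0)

  set.seed(8)
  for (i in 1:60) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    s <- rnorm(n); r <- rnorm(m)
    bf <- brute_force_dtw(s, r)
    al <- dtw_align(s, r)
    expect_equal(attr(al, "cost"), bf$cost, tolerance = 1e-12)
    expect_equal(as.numeric(al), bf$aligned, tolerance = 1e-12)
  }
})

test_that("zero phase penalty makes weighted DTW coincide with classical DTW", {
  t <- dus_template(triangle(45), L = 45L, valid = TRUE)
  set.seed(2)
  for (i in 1:10) {
    cy <- make_cycle(cumsum(rnorm(38)))
    expect_equal(sqi4_wdtw(cy, t, g = 0), sqi3_dtw(cy, t))
  }
})

test_that("a larger penalty never cheapens phase lag relative to in-phase matches", {
  # the logistic weight rescales globally with g, so the meaningful monotone
  # quantity is the optimal cost measured in units of the in-phase weight
  # w(0): every path's relative cost is non-decreasing in g, hence so is the
  # optimum
  set.seed(6)
  for (i in 1:20) {
    s <- rnorm(12); r <- rnorm(10)
    costs <- vapply(c(0, 0.02, 0.1, 0.5, 2), function(g) {
      w <- function(d) 1 / (1 + exp(-g * (d - length(r) / 2)))
      attr(dtw_align(s, r, weights = w), "cost") / w(0)
    }, numeric(1))
    expect_true(all(diff(costs) >= -1e-9))
  }
})

test_that("time normalization cannot reduce the median template fit", {
  set.seed(3)
  draws <- replicate(300, {
    tpl <- dus_template(as.numeric(scale(cumsum(rnorm(50)))), L = 50L, valid = TRUE)
    cy <- make_cycle(cumsum(rnorm(40)))
    c(sqi1_direct(cy, tpl), sqi2_linear(cy, tpl), sqi3_dtw(cy, tpl))
  })
  med <- apply(draws, 1, median)
  expect_gte(med[3], med[2])
  expect_gte(med[2], med[1])
})

test_that("segment SQIs are per-beat medians using each beat's own window template", {
  sq <- data.frame(beat_index = 1:3, onset_sample = c(4100, 8200, 12000),
                   window_index = 1L,
                   sqi1 = c(0.5, 0.4, 0.3), sqi2 = c(0.9, 0.8, 0.2),
                   sqi3 = c(1, 1, 0), sqi4 = c(0.2, 0.6, 0.4))
  seg <- dus_segment(rnorm(15000), start_time = 1)
  got <- segment_sqis(seg, sq)
  expect_equal(unname(got), c(0.4, 0.8, 1, 0.4))
  one <- segment_sqis(dus_segment(rnorm(15000), start_time = 2.5),
                      sq[sq$onset_sample >= 10000, ])
  expect_equal(unname(one), c(0.3, 0.2, 0, 0.4))
  expect_message(none <- segment_sqis(dus_segment(rnorm(15000), start_time = 10), sq),
                 "no scored beat")
  expect_equal(unname(none), c(0, 0, 0, 0))

  # beats spanning two 15-s windows are scored against their own templates
  set.seed(9)
  shape_a <- as.numeric(scale(sin(seq(0, pi, length.out = 80))))
  shape_b <- as.numeric(scale(sin(seq(0, 6 * pi, length.out = 80))))
  cyc <- c(lapply(seq(1000, 55000, by = 6000), function(o) {
            cy <- make_cycle(shape_a); cy$onset_sample <- o; cy
          }),
          lapply(seq(61000, 115000, by = 6000), function(o) {
            cy <- make_cycle(shape_b); cy$onset_sample <- o; cy
          }))
  templates <- build_templates(cyc, n_samples = 120000, fs = 4000)
  tab <- compute_beat_sqis(cyc, templates)
  expect_true(all(tab$sqi1[tab$window_index == 1] > 0.99))
  expect_true(all(tab$sqi1[tab$window_index == 2] > 0.99))
  # cross-check: shape_a against window-2's template scores poorly
  t2 <- templates[[2]]
  expect_lt(sqi1_direct(make_cycle(shape_a), t2), 0.5)
})
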