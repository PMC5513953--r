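# well-separated two-class feature set with subject structure: each subject
# contributes segments of both classes so subject-stratified folds stay mixed
make_separable <- function(n_per_class = 150, n_subjects = 10, gap = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * 3, gap), ncol = 3),
             matrix(rnorm(n_per_class * 3, 0), ncol = 3))
  colnames(x) <- c("f1", "f2", "f3")
  y <- rep(c("good", "poor"), each = n_per_class)
  subjects <- paste0("S", rep_len(seq_len(n_subjects), 2 * n_per_class))
  list(x = x, y = y, subjects = subjects)
}

test_that("the RBF kernel matches its closed form and is symmetric", {
  v <- rnorm(6)
  expect_equal(rbf_kernel(v, v, sigma = 2), 1)
  a <- c(1, 0); b <- c(1 + sqrt(2) * 0.7, 0)  # squared distance = 2 sigma^2
  expect_equal(rbf_kernel(a, b, sigma = 0.7), exp(-1))
  set.seed(3)
  for (i in 1:10) {
    p <- rnorm(4); q <- rnorm(4)
    expect_equal(rbf_kernel(p, q, 1.3), rbf_kernel(q, p, 1.3))
  }
  expect_error(rbf_kernel(p, q, sigma = 0), "positive")
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1), "equal length")
})

test_that("subject split alternates by ranked good counts with a balance rule", {
  # equal counts: ranking falls back to id order, running totals tie after
  # 16 assignments, and the 17th subject balances the sides to 9/8
  counts <- setNames(rep(10, 17), sprintf("P%02d", 1:17))
  sp <- split_train_test(counts)
  expect_length(sp$train, 9)
  expect_length(sp$test, 8)
  expect_true(all(c("P01", "P03") %in% sp$train))
  expect_setequal(c(sp$train, sp$test), sprintf("P%02d", 1:17))

  # with unequal counts the last subject goes to the lighter side, here test
  sp2 <- split_train_test(setNames(c(40, 35, 30, 28, 25, 22, 20, 18, 15, 12,
                                     10, 9, 8, 7, 6, 5, 4), sprintf("Q%02d", 1:17)))
  expect_length(sp2$train, 8)
  expect_length(sp2$test, 9)
  expect_true("Q17" %in% sp2$test)

  two <- split_train_test(c(a = 5, b = 3))
  expect_length(two$train, 1)
  expect_length(two$test, 1)

  # last subject goes to the side with the smaller running total
  four <- split_train_test(c(w = 10, x = 9, y = 8, z = 7))
  expect_equal(sort(four$test), c("x", "z"))
  expect_error(split_train_test(c(only = 3)), "at least 2")
})

test_that("grid search returns single-point grids directly and prefers small C", {
  d <- make_separable(40, 4, gap = 4)
  one <- grid_search(d$x, d$y, C_grid = 2, sigma_grid = 0.5)
  expect_equal(one$C, 2)
  expect_equal(one$sigma, 0.5)

  gs <- grid_search(d$x, d$y, C_grid = 2^c(-1, 1, 3), sigma_grid = 2^c(0, 1), seed = 7)
  expect_equal(gs$C, 2^-1)   # separable data: every C works, tie -> smallest
  expect_equal(gs$sigma, 2)  # then the largest sigma
  expect_gt(gs$accuracy, 0.95)
})

test_that("bootstrap CV recovers separable labels and is seed-reproducible", {
  d <- make_separable(120, 8, gap = 3.5, seed = 2)
  cv <- bootstrap_cv(d$x, d$y, d$subjects, n_folds = 5, per_class = 40,
                     n_reps = 5, seed = 3, C_grid = 2, sigma_grid = 1)
  expect_gte(cv$median_accuracy, 98)
  cv2 <- bootstrap_cv(d$x, d$y, d$subjects, n_folds = 5, per_class = 40,
                      n_reps = 5, seed = 3, C_grid = 2, sigma_grid = 1)
  expect_identical(cv$accuracies, cv2$accuracies)
  expect_identical(cv$audit, cv2$audit)

  set.seed(99)
  y_shuf <- sample(d$y)
  cv0 <- bootstrap_cv(d$x, y_shuf, d$subjects, n_folds = 5, per_class = 40,
                      n_reps = 5, seed = 3, C_grid = 2, sigma_grid = 1)
  expect_gte(cv0$median_accuracy, 40)
  expect_lte(cv0$median_accuracy, 60)
})

test_that("balanced bootstrap folds satisfy accuracy = (sens + spec) / 2 exactly", {
  d <- make_separable(80, 6, gap = 1.2, seed = 5)
  cv <- bootstrap_cv(d$x, d$y, d$subjects, n_folds = 5, per_class = 30,
                     n_reps = 3, seed = 1, C_grid = 2, sigma_grid = 1)
  for (rep_a in cv$audit) for (f in rep_a) {
    expect_equal(f$accuracy, (f$sensitivity + f$specificity) / 2)
  }
})

test_that("CV audits prove subject-disjoint folds and training-only scaling", {
  d <- make_separable(60, 6, gap = 2, seed = 8)
  cv <- bootstrap_cv(d$x, d$y, d$subjects, n_folds = 3, per_class = 25,
                     n_reps = 4, seed = 2, C_grid = 2, sigma_grid = 1)
  audit <- audit_cv(cv, d$x, d$subjects)
  expect_true(audit$subject_disjoint)
  expect_true(audit$train_only_scaling)
})

test_that("probability predictions are calibrated, monotone and thresholded", {
  d <- make_separable(100, 5, gap = 3, seed = 4)
  model <- train_quality_svm(d$x, d$y, C = 2, sigma = 1)
  far_good <- matrix(rep(3, 3) + 1, nrow = 1)
  far_poor <- matrix(rep(0, 3) - 1, nrow = 1)
  expect_gt(predict_with_probability(model, far_good)$p_good, 0.9)
  expect_lt(predict_with_probability(model, far_poor)$p_good, 0.5)
  expect_equal(predict_with_probability(model, far_poor)$class, "poor")

  # calibration is monotone in the decision value
  set.seed(6)
  pts <- matrix(rnorm(60 * 3, 1.5), ncol = 3)
  dv <- dusqi:::decision_values(model, pts)
  p <- predict_with_probability(model, pts)$p_good
  expect_true(all(diff(p[order(dv)]) * sign(model$platt[2]) >= 0) ||
              all(diff(p[order(dv)]) * sign(model$platt[2]) <= 0))
  expect_equal(order(p), order(model$platt[2] * dv))

  # resubstitution accuracy is at least the CV median (optimistic bound)
  cv <- bootstrap_cv(d$x, d$y, d$subjects, n_folds = 5, per_class = 30,
                     n_reps = 3, seed = 1, C_grid = 2, sigma_grid = 1)
  resub <- 100 * mean(predict_with_probability(model, d$x)$class == d$y)
  expect_gte(resub, cv$median_accuracy - 1e-9)
})

test_that("intermediate mixtures score between the pure classes", {
  d <- make_separable(100, 5, gap = 3, seed = 9)
  model <- train_quality_svm(d$x, d$y, C = 2, sigma = 1)
  set.seed(10)
  n <- 60
  good_like <- matrix(rnorm(n * 3, 3), ncol = 3)
  poor_like <- matrix(rnorm(n * 3, 0), ncol = 3)
  lam <- runif(n)
  mix_clean <- 0.75 * good_like + 0.25 * poor_like
  mix_noisy <- 0.25 * good_like + 0.75 * poor_like
  ev <- evaluate_intermediate(model, list(good = good_like, mostly_clean = mix_clean,
                                          mostly_noisy = mix_noisy, poor = poor_like))
  fr <- ev$fraction_above
  expect_gt(fr[["good"]], 0.9)
  expect_lt(fr[["poor"]], 0.1)
  expect_true(fr[["good"]] >= fr[["mostly_clean"]])
  expect_true(fr[["mostly_clean"]] >= fr[["mostly_noisy"]])
  expect_true(fr[["mostly_noisy"]] >= fr[["poor"]])
  empty <- evaluate_intermediate(model, list(mostly_clean = NULL))
  expect_true(is.na(empty$fraction_above[["mostly_clean"]]))
})

test_that("models survive a JSON round trip with identical predictions", {
  d <- make_separable(60, 4, gap = 2, seed = 11)
  model <- train_quality_svm(d$x, d$y, C = 2, sigma = 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  p1 <- predict_with_probability(model, d$x)
  p2 <- predict_with_probability(back, d$x)
  expect_equal(p2$p_good, p1$p_good, tolerance = 1e-12)
  expect_identical(p2$class, p1$class)
})

test_that("feature-subset search ranks by accuracy then specificity", {
  set.seed(12)
  n <- 120
  x <- cbind(inform = c(rnorm(n, 2.5), rnorm(n, 0)),
             noise = rnorm(2 * n))
  y <- rep(c("good", "poor"), each = n)
  subjects <- paste0("S", rep_len(1:6, 2 * n))
  tab <- feature_subset_search(x, y, subjects, n_folds = 3, per_class = 30,
                               n_reps = 2, seed = 1)
  expect_equal(nrow(tab), 3)
  expect_true(grepl("inform", tab$features[1]))
  expect_true(all(diff(tab$accuracy) <= 0))
})
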