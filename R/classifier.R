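#' Gaussian radial basis function kernel
#'
#' `k(x_i, x_j) = exp(-||x_i - x_j||^2 / (2 sigma^2))`.
#'
#' @param x_i,x_j equal-length numeric vectors.
#' @param sigma kernel width (> 0).
#' @return Scalar in (0, 1\].
#' @export
rbf_kernel <- function(x_i, x_j, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a positive scalar", call. = FALSE)
  if (length(x_i) != length(x_j)) stop("vectors must have equal length", call. = FALSE)
  exp(-sum((x_i - x_j)^2) / (2 * sigma^2))
}

# kernel matrix between rows of A and rows of B
rbf_kernel_matrix <- function(A, B, sigma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Ranked alternating subject split
#'
#' Subjects are ranked by their number of good-quality segments in
#' descending order (ties broken lexicographically by id) and assigned
#' alternately to the training and test sides, starting with training. The
#' last subject instead joins the side with the smaller running segment
#' total, which balances the split when the subject count is odd.
#'
#' @param good_counts named numeric vector: good-segment count per subject.
#' @return List with character vectors `train` and `test`.
#' @export
split_train_test <- function(good_counts) {
  if (length(good_counts) < 2) stop("need at least 2 subjects", call. = FALSE)
  ord <- order(-good_counts, names(good_counts))
  ids <- names(good_counts)[ord]
  cnt <- unname(good_counts[ord])
  train <- character(); test <- character()
  t_train <- 0; t_test <- 0
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    if (i %% 2 == 1) { train <- c(train, ids[i]); t_train <- t_train + cnt[i] }
    else { test <- c(test, ids[i]); t_test <- t_test + cnt[i] }
  }
  if (t_train <= t_test) train <- c(train, ids[n]) else test <- c(test, ids[n])
  list(train = train, test = test)
}

# scale columns by training statistics; constant columns get unit scale
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

#' Train the RBF-SVM quality classifier
#'
#' Normalizes features with training-set statistics, fits a soft-margin SVM
#' with the Gaussian kernel, calibrates a logistic (Platt-style) map from
#' decision values to the probability of the good class, and derives the
#' good-class probability threshold maximizing balanced accuracy on the
#' training set.
#'
#' @param x numeric feature matrix (rows = segments).
#' @param y factor or character labels with values `"good"` / `"poor"`.
#' @param C soft-margin constant.
#' @param sigma kernel width (libsvm `gamma = 1 / (2 sigma^2)`).
#' @return An object of class `dus_svm` holding the support vectors and
#'   coefficients, the scaler, the calibration coefficients and
#'   `prob_threshold`.
#' @export
train_quality_svm <- function(x, y, C, sigma) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("good", "poor"))
  if (any(is.na(y))) stop("labels must be 'good' or 'poor'", call. = FALSE)
  if (nlevels(droplevels(y)) < 2) stop("both classes required", call. = FALSE)
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  fit <- e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                    gamma = 1 / (2 * sigma^2), cost = C, scale = FALSE)
  model <- structure(list(
    sv = unname(as.matrix(fit$SV)), coefs = as.numeric(fit$coefs),
    rho = fit$rho, sigma = sigma, C = C, scaler = scaler,
    feature_names = colnames(x), platt = c(0, 1), prob_threshold = 0.5
  ), class = "dus_svm")
  dv <- decision_values(model, x)
  # Platt-style logistic calibration of p(good | decision value)
  cal <- suppressWarnings(glm((y == "good") ~ dv, family = binomial()))
  model$platt <- unname(coef(cal))
  p <- plogis(model$platt[1] + model$platt[2] * dv)
  model$prob_threshold <- best_threshold(p, y)
  model
}

# decision value of the fitted SVM in the model's own kernel expansion
# (positive side = libsvm's first training class)
decision_values <- function(model, x) {
  xs <- apply_scaler(as.matrix(x), model$scaler)
  K <- rbf_kernel_matrix(xs, model$sv, model$sigma)
  as.numeric(K %*% model$coefs - model$rho)
}

# threshold on p_good maximizing sensitivity + specificity on training data;
# ties resolved towards the candidate closest to 0.5
best_threshold <- function(p, y) {
  cand <- sort(unique(c(0.5, p)))
  bal <- vapply(cand, function(t) {
    pred_good <- p >= t
    sens <- mean(pred_good[y == "good"])
    spec <- mean(!pred_good[y == "poor"])
    sens + spec
  }, numeric(1))
  top <- which(bal >= max(bal) - 1e-12)
  cand[top[which.min(abs(cand[top] - 0.5))]]
}

#' @export
print.dus_svm <- function(x, ...) {
  cat(sprintf("RBF-SVM quality classifier: C = %g, sigma = %g, %d support vectors, p(good) threshold %.4f\n",
              x$C, x$sigma, nrow(x$sv), x$prob_threshold))
  invisible(x)
}

#' Predict quality class and good-class probability
#'
#' @param model a fitted `dus_svm`.
#' @param x feature matrix or single feature vector.
#' @return Data frame with `class` (`"good"` iff `p_good >=` the model's
#'   probability threshold) and `p_good`.
#' @export
predict_with_probability <- function(model, x) {
  if (!inherits(model, "dus_svm")) stop("model must be a fitted dus_svm", call. = FALSE)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  dv <- decision_values(model, x)
  p <- plogis(model$platt[1] + model$platt[2] * dv)
  data.frame(class = ifelse(p >= model$prob_threshold, "good", "poor"), p_good = p)
}

#' Hyperparameter grid search by inner five-fold cross-validation
#'
#' Evaluates every (C, sigma) pair by stratified five-fold CV accuracy on the
#' training set and returns the maximizer; ties prefer the smallest C, then
#' the largest sigma (simpler margin, smoother kernel). A single-point grid
#' is returned directly.
#'
#' @param x feature matrix.
#' @param y labels (`"good"` / `"poor"`).
#' @param C_grid,sigma_grid numeric candidate vectors.
#' @param n_folds inner fold count.
#' @param seed RNG seed for the fold assignment.
#' @return List with `C`, `sigma` and the inner-CV `accuracy` (NA for a
#'   single-point grid).
#' @export
grid_search <- function(x, y, C_grid = 2^c(-3, -1, 1, 3, 5),
                        sigma_grid = 2^c(-5, -2, 1, 2), n_folds = 5, seed = 1) {
  if (!length(C_grid) || !length(sigma_grid)) stop("grids must be non-empty", call. = FALSE)
  if (length(C_grid) == 1 && length(sigma_grid) == 1)
    return(list(C = C_grid, sigma = sigma_grid, accuracy = NA_real_))
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("good", "poor"))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  best <- NULL
  for (C in sort(C_grid)) for (s in sort(sigma_grid, decreasing = TRUE)) {
    accs <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2 || !any(!tr)) return(NA_real_)
      scaler <- fit_scaler(x[tr, , drop = FALSE])
      fit <- e1071::svm(apply_scaler(x[tr, , drop = FALSE], scaler), y[tr],
                        type = "C-classification", kernel = "radial",
                        gamma = 1 / (2 * s^2), cost = C, scale = FALSE)
      mean(predict(fit, apply_scaler(x[!tr, , drop = FALSE], scaler)) == y[!tr])
    }, numeric(1))
    a <- mean(accs, na.rm = TRUE)
    if (is.null(best) || a > best$accuracy + 1e-12) best <- list(C = C, sigma = s, accuracy = a)
  }
  best
}

#' Subject-stratified bootstrap cross-validation
#'
#' Per repetition, subjects (never individual segments) are partitioned into
#' `n_folds` folds; in every fold, `per_class` segments per class are drawn
#' with replacement from the fold's own segments (so each subject contributes
#' in proportion to its segment count). Each fold in turn is the evaluation
#' fold: the classifier is fitted on the concatenated bootstrap samples of
#' the other folds with (C, sigma) chosen by [grid_search()] on that training
#' sample, features are normalized with training statistics only, and
#' accuracy, sensitivity (good recall) and specificity (poor recall) are
#' measured on the fold's bootstrap sample. The per-repetition value is the
#' median over folds; the summary value the median over repetitions.
#'
#' @param x feature matrix of good/poor segments.
#' @param y labels (`"good"` / `"poor"`).
#' @param subjects subject id per row (folds are subject-disjoint).
#' @param n_folds,per_class,n_reps validation design.
#' @param seed master seed; per-repetition streams are derived from it.
#' @param C_grid,sigma_grid hyperparameter grids (single-point grids skip the
#'   inner search).
#' @return An object of class `dus_cvresult`: per-repetition `accuracies`,
#'   `sensitivities`, `specificities` (in %), chosen `C`/`sigma`, overall
#'   medians, and an `audit` record of fold compositions and scaler
#'   statistics for [audit_cv()].
#' @export
bootstrap_cv <- function(x, y, subjects, n_folds = 5, per_class = 60,
                         n_reps = 100, seed = 1,
                         C_grid = 2^c(-3, -1, 1, 3, 5),
                         sigma_grid = 2^c(-5, -2, 1, 2)) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("good", "poor"))
  subjects <- as.character(subjects)
  stopifnot(nrow(x) == length(y), length(y) == length(subjects))
  uniq_subj <- sort(unique(subjects))
  if (length(uniq_subj) < n_folds)
    stop("need at least as many subjects as folds", call. = FALSE)

  acc <- sens <- spec <- numeric(n_reps)
  chosen_C <- chosen_sigma <- numeric(n_reps)
  audit <- vector("list", n_reps)

  for (rep_i in seq_len(n_reps)) {
    set.seed((seed * 1009 + rep_i * 7919) %% .Machine$integer.max)
    fold_of <- assign_subject_folds(uniq_subj, subjects, y, n_folds)
    boot_idx <- lapply(seq_len(n_folds), function(f) {
      subj_f <- uniq_subj[fold_of == f]
      rows_f <- which(subjects %in% subj_f)
      unlist(lapply(levels(y), function(cl) {
        pool <- rows_f[y[rows_f] == cl]
        sample(pool, per_class, replace = TRUE)
      }))
    })
    f_acc <- f_sens <- f_spec <- f_C <- f_sigma <- numeric(n_folds)
    f_audit <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      tr_idx <- unlist(boot_idx[-f])
      te_idx <- boot_idx[[f]]
      gs <- grid_search(x[tr_idx, , drop = FALSE], y[tr_idx],
                        C_grid = C_grid, sigma_grid = sigma_grid,
                        seed = (seed * 104729 + rep_i * 131 + f) %% .Machine$integer.max)
      scaler <- fit_scaler(x[tr_idx, , drop = FALSE])
      fit <- e1071::svm(apply_scaler(x[tr_idx, , drop = FALSE], scaler),
                        y[tr_idx], type = "C-classification", kernel = "radial",
                        gamma = 1 / (2 * gs$sigma^2), cost = gs$C, scale = FALSE)
      pred <- predict(fit, apply_scaler(x[te_idx, , drop = FALSE], scaler))
      truth <- y[te_idx]
      f_acc[f] <- 100 * mean(pred == truth)
      f_sens[f] <- 100 * mean(pred[truth == "good"] == "good")
      f_spec[f] <- 100 * mean(pred[truth == "poor"] == "poor")
      f_C[f] <- gs$C; f_sigma[f] <- gs$sigma
      f_audit[[f]] <- list(
        test_subjects = sort(unique(subjects[te_idx])),
        train_subjects = sort(unique(subjects[tr_idx])),
        train_rows = tr_idx, center = scaler$center, scale = scaler$scale,
        accuracy = f_acc[f], sensitivity = f_sens[f], specificity = f_spec[f])
    }
    acc[rep_i] <- median(f_acc); sens[rep_i] <- median(f_sens); spec[rep_i] <- median(f_spec)
    mode_i <- which.max(tabulate(match(paste(f_C, f_sigma), unique(paste(f_C, f_sigma)))))
    chosen_C[rep_i] <- f_C[match(unique(paste(f_C, f_sigma))[mode_i], paste(f_C, f_sigma))]
    chosen_sigma[rep_i] <- f_sigma[match(unique(paste(f_C, f_sigma))[mode_i], paste(f_C, f_sigma))]
    audit[[rep_i]] <- f_audit
  }
  structure(list(
    accuracies = acc, sensitivities = sens, specificities = spec,
    chosen_C = chosen_C, chosen_sigma = chosen_sigma,
    median_accuracy = median(acc), median_sensitivity = median(sens),
    median_specificity = median(spec),
    n_folds = n_folds, per_class = per_class, n_reps = n_reps, seed = seed,
    audit = audit
  ), class = "dus_cvresult")
}

# partition subjects into folds with every fold containing both classes;
# retries the random assignment when a fold misses a class
assign_subject_folds <- function(uniq_subj, subjects, y, n_folds, max_tries = 100) {
  for (try_i in seq_len(max_tries)) {
    fold_of <- rep_len(seq_len(n_folds), length(uniq_subj))[sample(length(uniq_subj))]
    ok <- all(vapply(seq_len(n_folds), function(f) {
      rows <- subjects %in% uniq_subj[fold_of == f]
      all(c("good", "poor") %in% unique(as.character(y[rows])))
    }, logical(1)))
    if (ok) return(fold_of)
    if (try_i == 1) message("fold assignment missing a class; resampling")
  }
  stop("could not form folds containing both classes", call. = FALSE)
}

#' @export
print.dus_cvresult <- function(x, ...) {
  cat(sprintf("Bootstrap CV (%d folds, %d/class, %d reps): median accuracy %.1f %%, sensitivity %.1f %%, specificity %.1f %%\n",
              x$n_folds, x$per_class, x$n_reps, x$median_accuracy,
              x$median_sensitivity, x$median_specificity))
  invisible(x)
}

#' Audit a cross-validation result for validation hygiene
#'
#' Verifies, for every repetition and fold, that no subject appears on both
#' the training and evaluation side, and that the stored normalization
#' statistics equal the mean/SD recomputed from the training rows alone.
#'
#' @param cv a `dus_cvresult` from [bootstrap_cv()].
#' @param x,subjects the feature matrix and subject ids passed to
#'   [bootstrap_cv()].
#' @return List with logicals `subject_disjoint` and `train_only_scaling`.
#' @export
audit_cv <- function(cv, x, subjects) {
  stopifnot(inherits(cv, "dus_cvresult"))
  x <- as.matrix(x)
  disjoint <- TRUE; scaling <- TRUE
  for (rep_a in cv$audit) for (f in rep_a) {
    if (length(intersect(f$train_subjects, f$test_subjects))) disjoint <- FALSE
    sc <- fit_scaler(x[f$train_rows, , drop = FALSE])
    if (max(abs(sc$center - f$center)) > 1e-10 ||
        max(abs(sc$scale - f$scale)) > 1e-10) scaling <- FALSE
  }
  list(subject_disjoint = disjoint, train_only_scaling = scaling)
}

#' Probability behaviour on intermediate-quality segments
#'
#' Applies a classifier trained on good/poor segments to held-out classes
#' and reports, per class, the fraction of segments whose good-class
#' probability exceeds the model threshold, plus a smoothed density summary
#' of the probabilities.
#'
#' @param model a fitted `dus_svm`.
#' @param class_features named list of feature matrices, e.g.
#'   `list(good = ..., mostly_clean = ..., mostly_noisy = ..., poor = ...)`.
#' @return List with `fraction_above` (named, NA for an empty class) and
#'   `densities` (per-class [stats::density()] objects or `NULL`).
#' @export
evaluate_intermediate <- function(model, class_features) {
  fr <- sapply(class_features, function(m) {
    if (is.null(m) || !NROW(m)) return(NA_real_)
    mean(predict_with_probability(model, m)$p_good >= model$prob_threshold)
  })
  dens <- lapply(class_features, function(m) {
    if (is.null(m) || NROW(m) < 2) return(NULL)
    density(predict_with_probability(model, m)$p_good, from = 0, to = 1)
  })
  list(fraction_above = fr, densities = dens, threshold = model$prob_threshold)
}

#' Exhaustive feature-subset search
#'
#' Runs [bootstrap_cv()] for every non-empty subset of the feature columns
#' and ranks subsets by median accuracy, breaking ties by median specificity.
#'
#' @inheritParams bootstrap_cv
#' @return Data frame, one row per subset, sorted best first: `features`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
feature_subset_search <- function(x, y, subjects, n_folds = 5, per_class = 60,
                                  n_reps = 10, seed = 1,
                                  C_grid = 2, sigma_grid = 1) {
  x <- as.matrix(x)
  p <- ncol(x)
  subsets <- lapply(seq_len(2^p - 1), function(m) which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
  rows <- lapply(subsets, function(cols) {
    cv <- bootstrap_cv(x[, cols, drop = FALSE], y, subjects, n_folds = n_folds,
                       per_class = per_class, n_reps = n_reps, seed = seed,
                       C_grid = C_grid, sigma_grid = sigma_grid)
    data.frame(features = paste(colnames(x)[cols], collapse = "+"),
               accuracy = cv$median_accuracy,
               sensitivity = cv$median_sensitivity,
               specificity = cv$median_specificity)
  })
  out <- do.call(rbind, rows)
  out[order(-out$accuracy, -out$specificity), ]
}

#' Save / load a trained classifier as portable JSON
#'
#' The file stores the support vectors and coefficients, kernel parameters,
#' feature scaler, calibration coefficients and probability threshold, so a
#' model can be reloaded without refitting.
#'
#' @param model a `dus_svm`.
#' @param path JSON file path.
#' @return `save_model`: `path` invisibly; `load_model`: the `dus_svm`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dus_svm"))
  obj <- list(sv = model$sv, coefs = model$coefs, rho = model$rho,
              sigma = model$sigma, C = model$C,
              center = model$scaler$center, scale = model$scaler$scale,
              feature_names = model$feature_names, platt = model$platt,
              prob_threshold = model$prob_threshold)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    sv = matrix(as.numeric(obj$sv), nrow = nrow(obj$sv)),
    coefs = as.numeric(obj$coefs), rho = obj$rho, sigma = obj$sigma, C = obj$C,
    scaler = list(center = setNames(as.numeric(obj$center), obj$feature_names),
                  scale = setNames(as.numeric(obj$scale), obj$feature_names)),
    feature_names = obj$feature_names, platt = as.numeric(obj$platt),
    prob_threshold = obj$prob_threshold
  ), class = "dus_svm")
}
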