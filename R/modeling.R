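# Integrated predictive models: ordinary least squares for BMI on the
# selected expression profiles plus the genetic risk score, a pairwise
# interaction scan, and a cross-validated SVM for binary weight status.

#' Fit the linear BMI model
#'
#' Ordinary least squares regression of BMI on the admitted gene
#' expression profiles and, optionally, the genetic risk score:
#' `BMI_i = a0 + sum_k a_k E_ik + b G_i + e_i`. Per-term two-sided t
#' tests, the overall F test, and the adjusted R-squared are reported.
#' With `prune_insignificant = TRUE`, predictors are dropped backward —
#' at each step the largest-p predictor with p >= `prune_p` is removed
#' and the model refitted — until every remaining predictor is
#' significant (or one predictor remains).
#'
#' @param cohort An aligned `cohort` with expression and phenotype.
#' @param genes A `feature_set` or character vector of gene IDs.
#' @param grs Optional `grs_result` supplying the per-sample score.
#' @param prune_insignificant Backward-drop predictors at `prune_p`
#'   (default `FALSE`: keep the full selected set).
#' @param prune_p Significance cutoff used when pruning (default 0.05).
#' @return An object of class `bmi_model`: list with `terms`,
#'   `estimates`, `std_errors`, `t_stats`, `p_values`, `r2`,
#'   `adjusted_r2`, `model_p`, `n`, `residuals`, `fitted`, `dropped`
#'   (pruned terms) and the underlying `lm` fit.
#' @export
fit_bmi_model <- function(cohort, genes, grs = NULL,
                          prune_insignificant = FALSE, prune_p = 0.05) {
  df <- .model_frame(cohort, genes, grs)
  preds <- setdiff(names(df), "bmi")
  if (length(preds) == 0L) stop("no predictors supplied", call. = FALSE)
  dropped <- character(0)
  repeat {
    fit <- .ols_fit(df, preds)
    if (!prune_insignificant || length(preds) <= 1L) break
    pv <- fit$p_values[preds]
    worst <- names(which.max(pv))
    if (pv[worst] < prune_p) break
    dropped <- c(dropped, worst)
    preds <- setdiff(preds, worst)
  }
  fit$dropped <- dropped
  fit
}

# Core OLS fit + inference on a model frame with response 'bmi'.
.ols_fit <- function(df, preds) {
  n <- nrow(df)
  if (n <= length(preds) + 1L) {
    stop("need n > number of predictors + 1", call. = FALSE)
  }
  const <- preds[vapply(preds, function(p) stats::sd(df[[p]]) == 0,
                        logical(1))]
  if (length(const)) {
    stop("predictor(s) with zero variance: ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  fm <- stats::reformulate(sprintf("`%s`", preds), response = "bmi")
  fit <- stats::lm(fm, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(gsub("`", "", bad), collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  term_names <- c("(Intercept)", preds)
  fstat <- sm$fstatistic
  structure(
    list(terms = term_names,
         estimates = stats::setNames(ct[, 1L], term_names),
         std_errors = stats::setNames(ct[, 2L], term_names),
         t_stats = stats::setNames(ct[, 3L], term_names),
         p_values = stats::setNames(ct[, 4L], term_names),
         r2 = sm$r.squared,
         adjusted_r2 = adjusted_r2(sm$r.squared, n, length(preds)),
         model_p = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                    lower.tail = FALSE)),
         n = n,
         residuals = stats::residuals(fit),
         fitted = stats::fitted(fit),
         lm = fit),
    class = "bmi_model"
  )
}

#' @export
print.bmi_model <- function(x, ...) {
  cat(sprintf(
    "linear BMI model: %d predictors, n = %d, R2 = %.3f, adj R2 = %.3f (model p = %.3g)\n",
    length(x$terms) - 1L, x$n, x$r2, x$adjusted_r2, x$model_p))
  invisible(x)
}

#' @export
summary.bmi_model <- function(object, ...) {
  tab <- data.frame(term = object$terms,
                    estimate = unname(object$estimates),
                    std_error = unname(object$std_errors),
                    t = unname(object$t_stats),
                    p = unname(object$p_values),
                    stringsAsFactors = FALSE)
  out <- list(coefficients = tab, r2 = object$r2,
              adjusted_r2 = object$adjusted_r2,
              model_p = object$model_p, n = object$n,
              dropped = object$dropped)
  class(out) <- "summary.bmi_model"
  out
}

#' @export
print.summary.bmi_model <- function(x, ...) {
  print(x$coefficients, digits = 4)
  cat(sprintf("R2 %.4f | adjusted R2 %.4f | model p %.3g | n %d\n",
              x$r2, x$adjusted_r2, x$model_p, x$n))
  if (length(x$dropped)) {
    cat("pruned:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.bmi_model <- function(object, ...) object$estimates

#' @export
residuals.bmi_model <- function(object, ...) object$residuals

#' Predict BMI from a fitted linear model
#'
#' Evaluates the linear predictor `a0 + sum_k a_k E_k + b G` on new
#' feature values. Every slope term of the fit must be present as a
#' column.
#'
#' @param fit A `bmi_model`.
#' @param new_features Data frame or matrix whose columns cover the
#'   fit's predictor terms.
#' @return Numeric vector of predicted BMI values.
#' @export
predict_bmi <- function(fit, new_features) {
  stopifnot(inherits(fit, "bmi_model"))
  new_features <- as.data.frame(new_features, check.names = FALSE)
  preds <- setdiff(fit$terms, "(Intercept)")
  missing_terms <- setdiff(preds, names(new_features))
  if (length(missing_terms)) {
    stop("missing feature term(s): ",
         paste(missing_terms, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(new_features[, preds, drop = FALSE])
  drop(fit$estimates["(Intercept)"] +
         x %*% fit$estimates[preds])
}

#' @export
predict.bmi_model <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  predict_bmi(object, newdata)
}

#' Scan all pairwise interactions among the model predictors
#'
#' For each unordered pair of predictors (admitted genes plus the
#' genetic risk score), refits the main-effects BMI model with that
#' single product term added and records the product term's p-value;
#' p-values are BH-adjusted across the testable pairs. Pairs whose
#' product is collinear with the main effects are reported untestable.
#'
#' @inheritParams fit_bmi_model
#' @return Data frame with `term_pair`, `interaction_p`, `adjusted_p`,
#'   `testable`.
#' @export
interaction_scan <- function(cohort, genes, grs = NULL) {
  df <- .model_frame(cohort, genes, grs)
  preds <- setdiff(names(df), "bmi")
  if (length(preds) < 2L) stop("need at least two predictors",
                               call. = FALSE)
  pairs <- utils::combn(preds, 2L)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]
    b <- pairs[2L, k]
    df2 <- df
    inter <- ".interaction."
    df2[[inter]] <- df[[a]] * df[[b]]
    p_int <- tryCatch({
      fit <- .ols_fit(df2, c(preds, inter))
      fit$p_values[[inter]]
    }, error = function(e) NA_real_)
    rows[[k]] <- data.frame(term_pair = paste(a, b, sep = ":"),
                            interaction_p = p_int,
                            testable = !is.na(p_int),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  out$adjusted_p[out$testable] <- bh_adjust(out$interaction_p[out$testable])
  out[, c("term_pair", "interaction_p", "adjusted_p", "testable")]
}

#' Cross-validated SVM classification of weight status
#'
#' Dichotomizes BMI at `bmi_threshold` (overweight iff BMI >= threshold)
#' and classifies the binary status from the admitted gene expression
#' profiles plus the genetic risk score with a soft-margin support vector
#' machine (LibSVM via e1071). Folds are stratified by class and derived
#' deterministically from `seed`; features are standardized using
#' training-fold statistics only. Reports the pooled held-out accuracy
#' (correct / total over all folds) and the per-fold accuracies.
#'
#' @inheritParams fit_bmi_model
#' @param n_folds Number of cross-validation folds (default 5).
#' @param kernel `"linear"` (default), `"rbf"` or `"polynomial"`.
#' @param seed Integer seed controlling fold assignment.
#' @param cost Soft-margin cost parameter C (default 1).
#' @param bmi_threshold Overweight cutoff (default 25 kg/m^2).
#' @return An object of class `cv_classification`: list with `accuracy`
#'   (pooled), `mean_fold_accuracy`, `fold_accuracies`, `n_folds`,
#'   `kernel`, `confusion_counts` (2x2, truth in rows), `seed`, `n`.
#' @export
cv_classify_weight_status <- function(cohort, genes, grs = NULL,
                                      n_folds = 5L,
                                      kernel = c("linear", "rbf",
                                                 "polynomial"),
                                      seed = 1L, cost = 1,
                                      bmi_threshold = 25) {
  kernel <- match.arg(kernel)
  df <- .model_frame(cohort, genes, grs)
  y <- dichotomize_bmi(cohort$phenotype, bmi_threshold)
  x <- as.matrix(df[, setdiff(names(df), "bmi"), drop = FALSE])
  n <- nrow(x)
  if (nlevels(droplevels(y)) < 2L) {
    stop("both weight-status classes must be present", call. = FALSE)
  }
  if (n < n_folds) stop("need n >= n_folds", call. = FALSE)

  fold_id <- integer(n)
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold_id[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  fold_acc <- numeric(n_folds)
  svm_kernel <- c(linear = "linear", rbf = "radial",
                  polynomial = "polynomial")[[kernel]]
  for (f in seq_len(n_folds)) {
    test_i <- fold_id == f
    train_i <- !test_i
    if (nlevels(droplevels(y[train_i])) < 2L) {
      stop("a training fold contains one class; use fewer folds",
           call. = FALSE)
    }
    mu <- colMeans(x[train_i, , drop = FALSE])
    sdv <- apply(x[train_i, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1  # constant feature: leave centered, unscaled
    xs_train <- scale(x[train_i, , drop = FALSE], mu, sdv)
    xs_test <- scale(x[test_i, , drop = FALSE], mu, sdv)
    model <- e1071::svm(x = xs_train, y = droplevels(y[train_i]),
                        kernel = svm_kernel, cost = cost,
                        scale = FALSE)
    ph <- stats::predict(model, xs_test)
    pred[test_i] <- as.character(ph)
    fold_acc[f] <- mean(ph == y[test_i])
  }
  structure(
    list(accuracy = mean(pred == y),
         mean_fold_accuracy = mean(fold_acc),
         fold_accuracies = fold_acc,
         n_folds = n_folds,
         kernel = kernel,
         confusion_counts = table(truth = y, predicted = pred),
         seed = seed,
         n = n),
    class = "cv_classification"
  )
}

#' @export
print.cv_classification <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV %s SVM: pooled accuracy %.1f%% (mean fold %.1f%%, n = %d)\n",
    x$n_folds, x$kernel, 100 * x$accuracy, 100 * x$mean_fold_accuracy,
    x$n))
  invisible(x)
}
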