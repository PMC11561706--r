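#' Inverse Train-Test Procedure, case 1 (verifiable)
#'
#' Diagnoses whether two labeled datasets are interchangeable for clock
#' training. Step 1 trains model 1 on the training set and scores its
#' predictions on the test set against the test set's own ages. Step 2
#' trains model 2 — from the same model family, a cross-validated Lasso —
#' on the test features paired with model 1's predictions (at full
#' floating precision), then scores model 2's predictions of the original
#' training ages. Both steps passing the R-squared threshold means the
#' datasets can predict each other: interchangeable. Step 2 alone passing
#' means the test set still contains the information needed to predict the
#' training set (one-way). Anything else is not interchangeable.
#'
#' @param train,test [methylation_dataset()] objects with ages; they are
#'   restricted to their common CpG universe before any fit.
#' @param seed integer seed for both model fits.
#' @param threshold R-squared above which a step counts as satisfactory
#'   (default 0.25).
#' @param folds CV folds for the Lasso fits.
#' @return An object of class `ittp_report`.
#' @export
ittp_case1 <- function(train, test, seed = 1, threshold = 0.25, folds = 5) {
  require_ages(train, "ittp_case1")
  require_ages(test, "ittp_case1")
  pair <- intersect_cpgs(train, test)
  train <- pair$a; test <- pair$b

  model1 <- fit_lasso_clock(train, folds = folds, seed = stage_seed(seed, "ittp_m1"))
  yhat_te <- apply_clock(model1, test)$mu
  step1 <- regression_metrics(test$age, yhat_te)

  step2_of <- fit_step2(test, yhat_te, train, seed, folds)
  verdict <- ittp_verdict(case = 1, step1 = step1, step2 = step2_of$metrics,
                          threshold = threshold, reason = step2_of$reason)
  new_ittp_report(case = 1, step1 = step1, step2 = step2_of$metrics,
                  model1 = model1, model2 = step2_of$model,
                  threshold = threshold, verdict = verdict$verdict,
                  reason = verdict$reason, seed = seed)
}

#' Inverse Train-Test Procedure, case 2 (unverifiable)
#'
#' The query dataset carries no trustworthy ages (the reprogramming case:
#' the biological age of reprogrammed cells is unknown). Model 1 is
#' trained on the labeled training set and produces intermediary
#' predictions for the unlabeled features; model 2 is trained on those
#' features paired with the intermediary predictions and scored against
#' the original training ages. Only the step-2 metrics exist; the verdict
#' rests on them alone. Constant intermediary predictions (a collapsed
#' model 1) short-circuit to not interchangeable.
#'
#' @param train labeled [methylation_dataset()].
#' @param unlabeled query `methyl_dataset`; any ages it carries are ignored.
#' @param seed,threshold,folds as in [ittp_case1()].
#' @return An object of class `ittp_report` with `step1_metrics = NULL`.
#' @export
ittp_case2 <- function(train, unlabeled, seed = 1, threshold = 0.25, folds = 5) {
  require_ages(train, "ittp_case2")
  pair <- intersect_cpgs(train, unlabeled)
  train <- pair$a; unlabeled <- pair$b

  model1 <- fit_lasso_clock(train, folds = folds, seed = stage_seed(seed, "ittp_m1"))
  yhat_rep <- apply_clock(model1, unlabeled)$mu
  if (stats::sd(yhat_rep) <= 1e-8 * max(1, abs(mean(yhat_rep)))) {
    return(new_ittp_report(
      case = 2, step1 = NULL, step2 = NULL, model1 = model1, model2 = NULL,
      threshold = threshold, verdict = "not_interchangeable",
      reason = "degenerate intermediary predictions", seed = seed
    ))
  }
  step2_of <- fit_step2(unlabeled, yhat_rep, train, seed, folds)
  verdict <- ittp_verdict(case = 2, step1 = NULL, step2 = step2_of$metrics,
                          threshold = threshold, reason = step2_of$reason)
  new_ittp_report(case = 2, step1 = NULL, step2 = step2_of$metrics,
                  model1 = model1, model2 = step2_of$model,
                  threshold = threshold, verdict = verdict$verdict,
                  reason = verdict$reason, seed = seed)
}

# Step 2 shared by both cases: train on (features of the query set,
# intermediary predictions), score on the original training ages.
fit_step2 <- function(query, yhat, train, seed, folds) {
  pseudo <- query
  pseudo$age <- yhat
  out <- tryCatch({
    model2 <- fit_lasso_clock(pseudo, folds = folds,
                              seed = stage_seed(seed, "ittp_m2"))
    metrics <- regression_metrics(train$age, apply_clock(model2, train)$mu)
    list(model = model2, metrics = metrics, reason = NULL)
  }, error = function(e) {
    list(model = NULL, metrics = NULL,
         reason = paste("step-2 fit failed:", conditionMessage(e)))
  })
  out
}

#' Re-derive the ITTP verdict from recorded metrics
#'
#' The verdict is a pure function of the step metrics and the threshold:
#' case 1 requires both steps' R-squared above the threshold for
#' `interchangeable`, step 2 alone gives `one_way`; case 2 uses step 2
#' alone. Degenerate fits give `not_interchangeable` with a reason.
#'
#' @param case 1 or 2.
#' @param step1,step2 [regression_metrics()] objects (or NULL).
#' @param threshold R-squared threshold.
#' @param reason optional failure reason carried through.
#' @return list with `verdict` and `reason`.
#' @export
ittp_verdict <- function(case, step1, step2, threshold, reason = NULL) {
  if (is.null(step2)) {
    return(list(verdict = "not_interchangeable",
                reason = reason %||% "missing step-2 metrics"))
  }
  pass2 <- is.finite(step2$r2) && step2$r2 > threshold
  if (case == 1) {
    pass1 <- !is.null(step1) && is.finite(step1$r2) && step1$r2 > threshold
    verdict <- if (pass1 && pass2) "interchangeable"
    else if (!pass1 && pass2) "one_way"
    else "not_interchangeable"
  } else {
    verdict <- if (pass2) "interchangeable" else "not_interchangeable"
  }
  list(verdict = verdict, reason = reason)
}

new_ittp_report <- function(case, step1, step2, model1, model2, threshold,
                            verdict, reason, seed) {
  structure(
    list(case = case, step1_metrics = step1, step2_metrics = step2,
         model1 = summarize_clock(model1), model2 = summarize_clock(model2),
         threshold = threshold, verdict = verdict, reason = reason,
         seed = seed),
    class = "ittp_report"
  )
}

summarize_clock <- function(clock) {
  if (is.null(clock)) return(NULL)
  list(support_size = length(clock$coefficients), alpha = clock$alpha,
       intercept = clock$intercept, n_train = clock$n_train)
}

#' @export
print.ittp_report <- function(x, ...) {
  cat(sprintf("<ittp_report> case %d, verdict: %s (R2 threshold %g)\n",
              x$case, x$verdict, x$threshold))
  if (!is.null(x$step1_metrics)) {
    cat(sprintf("  step 1: R2=%.3f MAE=%.3f\n",
                x$step1_metrics$r2, x$step1_metrics$mae))
  }
  if (!is.null(x$step2_metrics)) {
    cat(sprintf("  step 2: R2=%.3f MAE=%.3f\n",
                x$step2_metrics$r2, x$step2_metrics$mae))
  }
  if (!is.null(x$reason)) cat(sprintf("  reason: %s\n", x$reason))
  invisible(x)
}
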