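#' Two-prediction z-test
#'
#' Compares two single age predictions that carry variances:
#' `z = (mu2 - mu1) / sqrt(v1 + v2)` with a two-sided normal p-value.
#' If both variances are zero and the means differ, the comparison is
#' degenerate and reported with p = 0 and the `degenerate` flag.
#'
#' @param p1,p2 single predictions: one-row data.frames (as returned by
#'   [predict_gpr()]) or lists with elements `mu` and `variance`.
#' @return An object of class `group_comparison` with the effect
#'   (`p2 - p1`), standard error, statistic, and two-sided p-value.
#' @export
z_test_two_predictions <- function(p1, p2) {
  g1 <- as_pred(p1); g2 <- as_pred(p2)
  effect <- g2$mu - g1$mu
  se <- sqrt(g1$variance + g2$variance)
  if (se == 0) {
    degenerate <- TRUE
    z <- if (effect == 0) 0 else sign(effect) * Inf
    p <- if (effect == 0) 1 else 0
  } else {
    degenerate <- FALSE
    z <- effect / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_group_comparison(effect = effect, se = se, statistic = z, p_value = p,
                       tau2 = NA_real_, method = "z", degenerate = degenerate)
}

as_pred <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1, all(c("mu", "variance") %in% names(p)))
    list(mu = p$mu, variance = p$variance)
  } else {
    stopifnot(all(c("mu", "variance") %in% names(p)))
    list(mu = p$mu, variance = p$variance)
  }
}

#' Variance-aware meta-regression comparison of two prediction groups
#'
#' Random-effects meta-regression of the predicted ages on an intercept
#' plus a binary group indicator, weighting each prediction by the inverse
#' of `variance_i + tau2`. The between-observation heterogeneity `tau2` is
#' estimated by REML via Fisher scoring with non-negativity projection
#' (converged when the step falls below `tol` or after `max_iter`
#' iterations); `tau2` can instead be pinned to a fixed value. Inference
#' on the indicator coefficient is a two-sided Wald z-test. With exactly
#' one prediction per group the model is saturated and the comparison
#' falls back to [z_test_two_predictions()] with a warning.
#'
#' @param groupA,groupB prediction data.frames with `mu` and `variance`
#'   columns (e.g. [predict_gpr()] output split by group).
#' @param tau2 `NULL` to estimate by REML (default) or a fixed value >= 0.
#' @param aggregate collapse each group to its mean prediction (with the
#'   variance of the mean) before regression; off by default — per-sample
#'   rows retain the within-group information.
#' @param max_iter,tol REML iteration controls.
#' @return An object of class `group_comparison`; the effect is group B
#'   minus group A.
#' @export
meta_regression_groups <- function(groupA, groupB, tau2 = NULL,
                                   aggregate = FALSE, max_iter = 100,
                                   tol = 1e-8) {
  stopifnot(is.data.frame(groupA), is.data.frame(groupB),
            nrow(groupA) > 0, nrow(groupB) > 0)
  if (aggregate) {
    groupA <- aggregate_preds(groupA)
    groupB <- aggregate_preds(groupB)
  }
  if (nrow(groupA) == 1 && nrow(groupB) == 1) {
    warning("one prediction per group: falling back to the z-test")
    return(z_test_two_predictions(groupA, groupB))
  }
  y <- c(groupA$mu, groupB$mu)
  v <- c(groupA$variance, groupB$variance)
  if (any(v < 0)) stop("prediction variances must be >= 0", call. = FALSE)
  X <- cbind(1, c(rep(0, nrow(groupA)), rep(1, nrow(groupB))))

  if (is.null(tau2)) {
    est <- reml_tau2(y, v, X, max_iter = max_iter, tol = tol)
    tau2_hat <- est$tau2
    converged <- est$converged
    n_iter <- est$n_iter
    if (!converged) {
      stop(sprintf(
        "REML estimation of tau2 did not converge in %d iterations (trace: %s)",
        max_iter, paste(sprintf("%.3g", utils::tail(est$trace, 5)),
                        collapse = " -> ")), call. = FALSE)
    }
  } else {
    if (tau2 < 0) stop("fixed tau2 must be >= 0", call. = FALSE)
    tau2_hat <- tau2
    converged <- TRUE
    n_iter <- 0L
  }

  w <- 1 / (v + tau2_hat)
  XtWX <- crossprod(X * w, X)
  b <- solve(XtWX, crossprod(X * w, y))
  vb <- solve(XtWX)
  effect <- b[2, 1]
  se <- sqrt(vb[2, 2])
  z <- effect / se
  new_group_comparison(effect = effect, se = se, statistic = z,
                       p_value = 2 * stats::pnorm(-abs(z)), tau2 = tau2_hat,
                       method = "meta_reml", degenerate = FALSE,
                       n_iter = n_iter)
}

aggregate_preds <- function(g) {
  data.frame(mu = mean(g$mu), variance = mean(g$variance) / nrow(g))
}

# REML estimation of the heterogeneity variance by Fisher scoring with
# projection onto tau2 >= 0. Score and expected information follow the
# standard restricted-likelihood derivatives for the weighted linear model.
reml_tau2 <- function(y, v, X, max_iter = 100, tol = 1e-8) {
  b_ols <- stats::lm.fit(X, y)$coefficients
  tau2 <- max(0, stats::var(y - X %*% b_ols) - mean(v))
  trace <- numeric(0)
  for (i in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    XtWX <- crossprod(X * w, X)
    b <- solve(XtWX, crossprod(X * w, y))
    r <- as.vector(y - X %*% b)
    P_corr <- sum(diag(solve(XtWX, crossprod(X * w^2, X))))
    score <- -0.5 * sum(w) + 0.5 * sum(w^2 * r^2) + 0.5 * P_corr
    info <- 0.5 * sum(w^2)
    step <- score / info
    tau2_new <- max(0, tau2 + step)
    trace <- c(trace, tau2_new)
    if (abs(tau2_new - tau2) < tol) {
      return(list(tau2 = tau2_new, converged = TRUE, n_iter = i, trace = trace))
    }
    tau2 <- tau2_new
  }
  list(tau2 = tau2, converged = FALSE, n_iter = max_iter, trace = trace)
}

#' Two-sided Mann-Whitney U comparison of two groups of values
#'
#' Rank-based comparison used for point-estimate clocks, which carry no
#' per-prediction variance. Exact p-values for small samples without
#' ties; normal approximation with tie correction otherwise (the
#' behavior of [stats::wilcox.test()]).
#'
#' @param groupA,groupB numeric vectors (e.g. `mu` columns of two
#'   prediction groups).
#' @return An object of class `group_comparison`; the effect is reported
#'   as the difference of medians (B - A), the statistic is U for group A.
#' @export
mann_whitney <- function(groupA, groupB) {
  stopifnot(length(groupA) > 0, length(groupB) > 0)
  wt <- suppressWarnings(stats::wilcox.test(groupA, groupB,
                                            alternative = "two.sided"))
  new_group_comparison(effect = stats::median(groupB) - stats::median(groupA),
                       se = NA_real_, statistic = unname(wt$statistic),
                       p_value = wt$p.value, tau2 = NA_real_, method = "mww",
                       degenerate = FALSE)
}

new_group_comparison <- function(effect, se, statistic, p_value, tau2,
                                 method, degenerate = FALSE,
                                 n_iter = NA_integer_) {
  structure(
    list(effect = effect, se = se, statistic = statistic, p_value = p_value,
         tau2 = tau2, method = method, degenerate = degenerate,
         n_iter = n_iter),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> method=%s  effect=%.4g", x$method, x$effect))
  if (!is.na(x$se)) cat(sprintf("  se=%.4g", x$se))
  cat(sprintf("  statistic=%.4g  p=%.4g", x$statistic, x$p_value))
  if (!is.na(x$tau2)) cat(sprintf("  tau2=%.4g", x$tau2))
  if (x$degenerate) cat("  [degenerate]")
  cat("\n")
  invisible(x)
}
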