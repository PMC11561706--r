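#' Construct a linear aging clock from a coefficient table
#'
#' A linear clock is a sparse coefficient vector over CpG ids plus an
#' intercept; prediction is the plain dot product
#' `mu = intercept + sum_i w_i * beta_i`. Published clocks supplied as
#' coefficient tables are applied through this same container (nonlinear
#' age transforms are out of scope).
#'
#' @param coefficients named numeric vector, names are CpG ids. Zero
#'   entries are dropped.
#' @param intercept intercept in age units.
#' @param alpha regularization strength used in training, if any.
#' @param cv_folds number of CV folds used to choose `alpha`, if any.
#' @param age_unit `"years"` or `"months"`.
#' @param tissue,n_train,seed optional training metadata.
#' @return An object of class `linear_clock`.
#' @export
linear_clock <- function(coefficients, intercept, alpha = NA_real_,
                         cv_folds = NA_integer_,
                         age_unit = c("years", "months"), tissue = NULL,
                         n_train = NA_integer_, seed = NA_integer_) {
  age_unit <- match.arg(age_unit)
  coefficients <- coefficients[coefficients != 0]
  if (length(coefficients) > 0 &&
      (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))) {
    stop("every coefficient must be named by a nonempty CpG id", call. = FALSE)
  }
  structure(
    list(coefficients = coefficients, intercept = as.numeric(intercept),
         alpha = alpha, cv_folds = cv_folds, age_unit = age_unit,
         tissue = tissue, n_train = n_train, seed = seed),
    class = "linear_clock"
  )
}

#' @export
print.linear_clock <- function(x, ...) {
  cat(sprintf("<linear_clock> %d CpGs, intercept %.3f %s",
              length(x$coefficients), x$intercept, x$age_unit))
  if (!is.na(x$alpha)) cat(sprintf(", alpha %.4g", x$alpha))
  cat("\n")
  invisible(x)
}

#' Fit a Lasso aging clock with cross-validated regularization
#'
#' Trains an L1-penalized linear regression of age on beta values. The
#' regularization strength is chosen to minimize the mean cross-validated
#' squared error over an automatic grid of 100 log-spaced values spanning
#' three decades down from the smallest penalty that empties the support;
#' the final model is refit on all training data at the chosen penalty.
#' Features are not standardized: beta values already share the \[0, 1\]
#' scale.
#'
#' @param train a [methylation_dataset()] with ages.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @param alpha optional fixed penalty; when given, cross-validation is
#'   skipped and the model is fit directly at this value.
#' @param nlambda,lambda_min_ratio grid size and span of the automatic
#'   penalty grid.
#' @return A [linear_clock()] with `alpha`, support and CV metadata filled.
#' @export
fit_lasso_clock <- function(train, folds = 5, seed = 1, alpha = NULL,
                            nlambda = 100, lambda_min_ratio = 1e-3) {
  stopifnot(inherits(train, "methyl_dataset"))
  require_ages(train, "fit_lasso_clock")
  y <- train$age
  x <- train$beta
  if (stats::sd(y) == 0) stop("constant age target; nothing to fit", call. = FALSE)
  if (!is.null(alpha)) {
    fit <- glmnet::glmnet(x, y, alpha = 1, lambda = alpha,
                          standardize = FALSE)
    chosen <- alpha
    folds_used <- NA_integer_
  } else {
    if (n_samples(train) < folds) {
      stop(sprintf("need at least %d samples for %d-fold CV", folds, folds),
           call. = FALSE)
    }
    chosen <- with_seed(seed, {
      foldid <- sample(rep(seq_len(folds), length.out = length(y)))
      cv <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                              standardize = FALSE, nlambda = nlambda,
                              lambda.min.ratio = lambda_min_ratio)
      cv$lambda.min
    })
    fit <- glmnet::glmnet(x, y, alpha = 1, lambda = chosen,
                          standardize = FALSE)
    folds_used <- as.integer(folds)
  }
  co <- as.matrix(stats::coef(fit))[, 1]
  linear_clock(co[-1], intercept = co[1], alpha = chosen,
               cv_folds = folds_used, age_unit = train$age_unit,
               tissue = train$tissue, n_train = n_samples(train),
               seed = as.integer(seed))
}

#' Apply a linear clock to a dataset
#'
#' @param clock a [linear_clock()].
#' @param data a [methylation_dataset()] containing every support CpG.
#' @return A data.frame of age predictions: `sample_id`, `mu`
#'   (predicted age), `group` (NA when the dataset carries no labels).
#'   No variance is attached — point-estimate clocks cannot provide one.
#' @export
apply_clock <- function(clock, data) {
  stopifnot(inherits(clock, "linear_clock"), inherits(data, "methyl_dataset"))
  support <- names(clock$coefficients)
  missing <- setdiff(support, cpg_ids(data))
  if (length(missing) > 0) {
    stop(sprintf("clock CpGs absent from data (%d of %d): %s",
                 length(missing), length(support),
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  mu <- rep(clock$intercept, n_samples(data))
  if (length(support) > 0) {
    mu <- mu + as.vector(data$beta[, support, drop = FALSE] %*%
                           clock$coefficients)
  }
  data.frame(sample_id = sample_ids(data), mu = mu,
             group = if (is.null(data$group)) NA_character_ else data$group,
             stringsAsFactors = FALSE)
}

#' Regression performance metrics
#'
#' MAE, median absolute error, R-squared (`1 - SS_res / SS_tot`), and
#' Pearson's correlation with its two-sided p-value. A constant prediction
#' vector leaves Pearson's r undefined; it is reported as `NA` with the
#' `degenerate` flag set while the other metrics are still returned.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return An object of class `regression_metrics`: list with `mae`,
#'   `medae`, `r2`, `pearson_r`, `pearson_p`, `n`, `degenerate`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    stop("y_true and y_pred must have equal length >= 2", call. = FALSE)
  }
  e <- y_pred - y_true
  ss_res <- sum(e^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  degenerate <- stats::sd(y_pred) == 0
  if (degenerate) {
    r <- NA_real_; rp <- NA_real_
  } else {
    ct <- stats::cor.test(y_true, y_pred, method = "pearson")
    r <- unname(ct$estimate); rp <- ct$p.value
  }
  structure(
    list(mae = mean(abs(e)), medae = stats::median(abs(e)),
         r2 = 1 - ss_res / ss_tot, pearson_r = r, pearson_p = rp,
         n = length(y_true), degenerate = degenerate),
    class = "regression_metrics"
  )
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("<regression_metrics> n=%d  MAE=%.3f  MedAE=%.3f  R2=%.3f  r=%s\n",
              x$n, x$mae, x$medae, x$r2,
              if (is.na(x$pearson_r)) "undefined" else sprintf("%.3f", x$pearson_r)))
  invisible(x)
}

#' Mean predicted-age difference between two time points
#'
#' `mean(mu | group == t1) - mean(mu | group == t0)`; a negative value is
#' read as rejuvenation.
#'
#' @param predictions a prediction data.frame (from [apply_clock()] or
#'   [predict_gpr()]) with `mu` and `group` columns.
#' @param t0,t1 group labels of the earlier and later time point.
#' @return Numeric delta in age units.
#' @export
rejuvenation_delta <- function(predictions, t0, t1) {
  g <- as.character(predictions$group)
  m0 <- predictions$mu[g == as.character(t0)]
  m1 <- predictions$mu[g == as.character(t1)]
  if (length(m0) == 0 || length(m1) == 0) {
    stop(sprintf("group '%s' or '%s' absent from predictions", t0, t1),
         call. = FALSE)
  }
  mean(m1) - mean(m0)
}

#' Built-in regressor families
#'
#' A regressor family is a pluggable contract: a list with a `name`, a
#' `fit(x, y, seed)` returning a fitted object, and a `predict(model, x)`
#' returning numeric predictions. Each family tunes its own hyperparameters
#' by grid-search cross-validation on the mean squared error. Two families
#' ship built in — the penalized linear clock and a k-nearest-neighbors
#' regressor; other off-the-shelf families (random forests, SVR, boosting)
#' can be plugged in through the same contract.
#'
#' @param folds CV folds for internal tuning.
#' @param k_grid candidate neighborhood sizes for the k-NN family.
#' @return A regressor-family list.
#' @export
lasso_family <- function(folds = 5) {
  list(
    name = "lasso",
    fit = function(x, y, seed = 1) {
      d <- methylation_dataset(x, age = y)
      fit_lasso_clock(d, folds = folds, seed = seed)
    },
    predict = function(model, x) {
      apply_clock(model, methylation_dataset(x))$mu
    }
  )
}

#' @rdname lasso_family
#' @export
knn_family <- function(k_grid = c(3, 5, 7, 10), folds = 5) {
  list(
    name = "knn",
    fit = function(x, y, seed = 1) {
      with_seed(seed, {
        foldid <- sample(rep(seq_len(folds), length.out = length(y)))
        cv_mse <- vapply(k_grid, function(k) {
          errs <- vapply(seq_len(folds), function(f) {
            tr <- foldid != f
            m <- caret::knnreg(x[tr, , drop = FALSE], y[tr], k = k)
            mean((stats::predict(m, x[!tr, , drop = FALSE]) - y[!tr])^2)
          }, numeric(1))
          mean(errs)
        }, numeric(1))
        best_k <- k_grid[which.min(cv_mse)]
        list(model = caret::knnreg(x, y, k = best_k), k = best_k)
      })
    },
    predict = function(model, x) {
      as.numeric(stats::predict(model$model, x))
    }
  )
}

#' Compare aging-clock model families on one training set
#'
#' Trains each regressor family on the same training data (each family
#' tunes itself by grid-search CV), evaluates it on the held-out test set,
#' and — when a time-course dataset is supplied — computes its
#' rejuvenation delta between `t0` and `t1`. Disagreement between the
#' deltas of equally well-fitting families is the model-choice component
#' of epistemic uncertainty.
#'
#' @param train,test [methylation_dataset()] objects with ages, on one
#'   CpG universe.
#' @param course optional unlabeled time-course `methyl_dataset` with
#'   `group` labels containing `t0` and `t1`.
#' @param families list of regressor families (see [lasso_family()]).
#' @param t0,t1 course group labels for the delta.
#' @param seed integer seed fanned out to each family.
#' @return A data.frame with one row per family: `family`, test metrics,
#'   `delta` (NA without a course), `failed`.
#' @export
compare_model_families <- function(train, test, course = NULL,
                                   families = list(lasso_family(), knn_family()),
                                   t0 = NULL, t1 = NULL, seed = 1) {
  require_ages(train, "compare_model_families")
  require_ages(test, "compare_model_families")
  rows <- lapply(families, function(fam) {
    out <- tryCatch({
      model <- fam$fit(train$beta, train$age, seed = seed)
      m <- regression_metrics(test$age, fam$predict(model, test$beta))
      delta <- NA_real_
      if (!is.null(course) && !is.null(t0) && !is.null(t1)) {
        mu <- fam$predict(model, course$beta)
        preds <- data.frame(sample_id = sample_ids(course), mu = mu,
                            group = course$group, stringsAsFactors = FALSE)
        delta <- rejuvenation_delta(preds, t0, t1)
      }
      data.frame(family = fam$name, mae = m$mae, medae = m$medae, r2 = m$r2,
                 pearson_r = m$pearson_r, delta = delta, failed = FALSE,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(family = fam$name, mae = NA_real_, medae = NA_real_,
                 r2 = NA_real_, pearson_r = NA_real_, delta = NA_real_,
                 failed = TRUE, stringsAsFactors = FALSE)
    })
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Serialize / deserialize a linear clock
#'
#' The coefficient table is TSV (`cpg_id`, `weight`); intercept and
#' metadata go to a JSON sidecar.
#'
#' @param clock a [linear_clock()].
#' @param path path of the coefficient TSV; the sidecar is `path` + ".json".
#' @return `path` ([write_clock()]) or a `linear_clock` ([read_clock()]).
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "linear_clock"))
  tab <- data.frame(cpg_id = names(clock$coefficients),
                    weight = formatC(unname(clock$coefficients),
                                     format = "g", digits = 17),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  header <- list(intercept = clock$intercept, alpha = clock$alpha,
                 cv_folds = clock$cv_folds, age_unit = clock$age_unit,
                 tissue = clock$tissue, n_train = clock$n_train,
                 seed = clock$seed)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  co <- as.numeric(tab$weight)
  names(co) <- tab$cpg_id
  linear_clock(co, intercept = header$intercept,
               alpha = header$alpha %||% NA_real_,
               cv_folds = header$cv_folds %||% NA_integer_,
               age_unit = header$age_unit %||% "years",
               tissue = header$tissue,
               n_train = header$n_train %||% NA_integer_,
               seed = header$seed %||% NA_integer_)
}
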