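#' Kernel hyperparameters for the GP clock
#'
#' @param s2 signal variance (age-units squared); also the ceiling that the
#'   predictive variance approaches for samples far outside the training
#'   distribution.
#' @param l length scale in feature space.
#' @param sigma2 white-noise (observation) variance, age-units squared;
#'   the aleatoric component.
#' @return An object of class `kernel_params`. All three must be > 0.
#' @export
kernel_params <- function(s2, l, sigma2) {
  if (any(c(s2, l, sigma2) <= 0) || any(!is.finite(c(s2, l, sigma2)))) {
    stop("s2, l and sigma2 must all be strictly positive and finite",
         call. = FALSE)
  }
  structure(list(s2 = s2, l = l, sigma2 = sigma2), class = "kernel_params")
}

#' Radial basis function kernel
#'
#' `k(xi, xj) = s2 * exp(-||xi - xj||^2 / (2 l^2))`. With matrix inputs,
#' returns the Gram matrix between the rows of `x1` and `x2`; entries lie
#' in (0, s2], with s2 attained at zero distance.
#'
#' @param x1 numeric matrix (rows are samples) or vector (one sample).
#' @param x2 like `x1`; defaults to `x1`.
#' @param params a [kernel_params()] (`sigma2` is ignored here; the white
#'   noise term enters only on the Gram diagonal during training).
#' @return Covariance matrix of dimension `nrow(x1)` x `nrow(x2)`.
#' @export
rbf_kernel <- function(x1, x2 = NULL, params) {
  stopifnot(inherits(params, "kernel_params"))
  if (is.vector(x1)) x1 <- matrix(x1, nrow = 1)
  if (is.null(x2)) x2 <- x1
  if (is.vector(x2)) x2 <- matrix(x2, nrow = 1)
  if (ncol(x1) != ncol(x2)) {
    stop("feature dimensions differ between x1 and x2", call. = FALSE)
  }
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), `+`) - 2 * tcrossprod(x1, x2)
  d2 <- pmax(d2, 0)  # guard tiny negative values from cancellation
  params$s2 * exp(-d2 / (2 * params$l^2))
}

# Cholesky of K = rbf(X, X) + sigma2*I with escalating diagonal jitter
# (1e-10 growing tenfold up to 1e-6) before declaring failure.
chol_gram <- function(X, params, jitter0 = 1e-10, jitter_max = 1e-6) {
  K <- rbf_kernel(X, NULL, params)
  diag(K) <- diag(K) + params$sigma2
  jitter <- jitter0
  repeat {
    L <- tryCatch(t(chol(K + diag(jitter, nrow(K)))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jitter))
    if (jitter >= jitter_max) {
      stop("Cholesky factorization failed even after jitter escalation",
           call. = FALSE)
    }
    jitter <- jitter * 10
  }
}

#' Log marginal likelihood of centered targets under the GP prior
#'
#' The zero-mean GP with RBF + white-noise composite kernel views the
#' target vector as `y ~ N(0, Sigma + sigma2 * I)`; this evaluates that
#' log density through a Cholesky factorization with diagonal jitter.
#'
#' @param X numeric matrix of features (rows are samples).
#' @param y_centered numeric target vector, already centered.
#' @param params a [kernel_params()].
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(X, y_centered, params) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (nrow(X) != length(y_centered)) {
    stop("X and y_centered are not aligned", call. = FALSE)
  }
  f <- chol_gram(X, params)
  a <- forwardsolve(f$L, y_centered)
  -0.5 * sum(a^2) - sum(log(diag(f$L))) - 0.5 * length(y_centered) * log(2 * pi)
}

#' Construct a GP clock at fixed hyperparameters
#'
#' Builds the cached training solve for given kernel parameters. The
#' zero-mean GP convention is realized by centering the targets on their
#' training mean and adding it back at prediction time (ages are positive,
#' so a raw zero-mean prior would bias predictions); `center = FALSE`
#' keeps the targets as given, for fully manual control.
#'
#' @param x training feature matrix (samples x features) or a
#'   [methylation_dataset()] (its beta matrix and ages are used).
#' @param y training targets; ignored when `x` is a dataset.
#' @param params a [kernel_params()].
#' @param center center targets on their mean (default TRUE).
#' @return An object of class `gpr_clock` with the Cholesky factor and the
#'   solve of `(Sigma + sigma2 I)` against the centered targets cached.
#' @export
gpr_clock <- function(x, y = NULL, params, center = TRUE) {
  if (inherits(x, "methyl_dataset")) {
    require_ages(x, "gpr_clock")
    y <- x$age
    feature_names <- cpg_ids(x)
    age_unit <- x$age_unit
    x <- x$beta
  } else {
    if (is.vector(x)) x <- matrix(x, ncol = 1)
    feature_names <- colnames(x)
    age_unit <- NULL
  }
  stopifnot(inherits(params, "kernel_params"), nrow(x) == length(y))
  y_offset <- if (center) mean(y) else 0
  yc <- y - y_offset
  f <- chol_gram(x, params)
  alpha <- backsolve(t(f$L), forwardsolve(f$L, yc))
  structure(
    list(X = x, y_centered = yc, y_offset = y_offset, params = params,
         L = f$L, alpha = alpha, jitter = f$jitter,
         feature_names = feature_names, age_unit = age_unit,
         lml = -0.5 * sum(forwardsolve(f$L, yc)^2) - sum(log(diag(f$L))) -
           0.5 * length(yc) * log(2 * pi),
         fit_info = NULL),
    class = "gpr_clock"
  )
}

#' Fit a GP aging clock by maximizing the log marginal likelihood
#'
#' Multi-start L-BFGS-B over the log-parameters (s2, l, sigma2) within
#' box bounds: one heuristic start (s2 = target variance, l = median
#' pairwise feature distance, sigma2 = a tenth of the target variance)
#' plus `restarts` seeded log-uniform draws. The best restart is kept;
#' identical seeds give identical fits.
#'
#' @param x training features (matrix or [methylation_dataset()]).
#' @param y targets; ignored when `x` is a dataset.
#' @param bounds named list of length-2 ranges for `s2`, `l`, `sigma2`.
#' @param restarts number of random restarts beyond the heuristic start.
#' @param seed integer seed for the restart draws.
#' @return A `gpr_clock` with `fit_info` (per-restart log marginal
#'   likelihoods, convergence codes, chosen start).
#' @export
fit_gpr <- function(x, y = NULL,
                    bounds = list(s2 = c(1e-2, 1e5), l = c(1e-2, 1e3),
                                  sigma2 = c(1e-4, 1e4)),
                    restarts = 5, seed = 1) {
  if (inherits(x, "methyl_dataset")) {
    require_ages(x, "fit_gpr")
    dataset <- x
    X <- x$beta
    y <- x$age
  } else {
    dataset <- NULL
    if (is.vector(x)) x <- matrix(x, ncol = 1)
    X <- x
  }
  if (nrow(X) < 3) stop("need at least 3 training samples", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant age target; nothing to fit", call. = FALSE)
  yc <- y - mean(y)
  lb <- log(c(bounds$s2[1], bounds$l[1], bounds$sigma2[1]))
  ub <- log(c(bounds$s2[2], bounds$l[2], bounds$sigma2[2]))

  nll <- function(logp) {
    p <- kernel_params(exp(logp[1]), exp(logp[2]), exp(logp[3]))
    -log_marginal_likelihood(X, yc, p)
  }
  clamp <- function(v) pmin(pmax(v, lb), ub)

  starts <- with_seed(seed, {
    med_d <- stats::median(stats::dist(
      X[sample.int(nrow(X), min(nrow(X), 100)), , drop = FALSE]))
    if (!is.finite(med_d) || med_d <= 0) med_d <- 1
    c(list(clamp(log(c(stats::var(yc), med_d, 0.1 * stats::var(yc)))),
           # pure-noise hypothesis, so the iid explanation always competes
           clamp(log(c(1e-2, med_d, stats::var(yc))))),
      lapply(seq_len(restarts), function(i) lb + stats::runif(3) * (ub - lb)))
  })

  fits <- lapply(starts, function(s0) {
    tryCatch(
      stats::optim(s0, nll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 200)),
      error = function(e) NULL
    )
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop(sprintf("all %d optimizer starts failed", length(fits)), call. = FALSE)
  }
  vals <- vapply(fits, function(f) if (is.null(f)) Inf else f$value, numeric(1))
  # A short length scale makes the RBF kernel mimic white noise, so the
  # likelihood can be flat along a signal/noise ridge; among near-tied
  # optima the noise explanation (larger sigma2) is preferred.
  tied <- which(vals - min(vals) < 1e-4)
  best <- tied[which.max(vapply(tied, function(i) fits[[i]]$par[3],
                                numeric(1)))]
  p <- exp(fits[[best]]$par)
  params <- kernel_params(p[1], p[2], p[3])
  clock <- gpr_clock(dataset %||% X, y = if (is.null(dataset)) y else NULL,
                     params = params)
  clock$fit_info <- list(
    restarts = length(starts), chosen_start = best, seed = seed,
    log_marginal_likelihoods = -vals,
    convergence = vapply(fits, function(f)
      if (is.null(f)) NA_integer_ else f$convergence, integer(1))
  )
  clock
}

#' Posterior predictions with credible intervals from a GP clock
#'
#' Closed-form GP posterior for each query point:
#' `mu* = k*' (Sigma + sigma2 I)^-1 y` (plus the training-mean offset) and
#' latent variance `(sigma*)^2 = k(x*, x*) - k*' (Sigma + sigma2 I)^-1 k*`,
#' clamped at zero (clamping events are counted in the `clamped`
#' attribute). The reported interval is `mu +/- 2 sqrt(variance)`, a
#' credible interval of two standard deviations. By default the variance
#' is latent-only, whose ceiling for far-away queries is the signal
#' variance s2; `include_noise = TRUE` adds sigma2 for observation-level
#' intervals.
#'
#' @param clock a `gpr_clock`.
#' @param newdata query features: matrix or [methylation_dataset()]. When
#'   the clock was trained on a dataset, query CpGs are matched by id.
#' @param include_noise add the white-noise variance to the predictive
#'   variance (default FALSE).
#' @return data.frame: `sample_id`, `mu`, `variance`, `lower`, `upper`,
#'   `group`; attribute `clamped` counts negative-variance clamps.
#' @export
predict_gpr <- function(clock, newdata, include_noise = FALSE) {
  stopifnot(inherits(clock, "gpr_clock"))
  group <- NA_character_
  if (inherits(newdata, "methyl_dataset")) {
    ids <- sample_ids(newdata)
    if (!is.null(newdata$group)) group <- newdata$group
    if (!is.null(clock$feature_names)) {
      missing <- setdiff(clock$feature_names, cpg_ids(newdata))
      if (length(missing) > 0) {
        stop(sprintf("clock CpGs absent from query data: %s",
                     paste(utils::head(missing, 5), collapse = ", ")),
             call. = FALSE)
      }
      Xn <- newdata$beta[, clock$feature_names, drop = FALSE]
    } else {
      Xn <- newdata$beta
    }
  } else {
    if (is.vector(newdata)) newdata <- matrix(newdata, ncol = ncol(clock$X))
    Xn <- newdata
    ids <- rownames(Xn) %||% sprintf("q%04d", seq_len(nrow(Xn)))
  }
  if (ncol(Xn) != ncol(clock$X)) {
    stop("query feature dimension does not match the training matrix",
         call. = FALSE)
  }
  kstar <- rbf_kernel(clock$X, Xn, clock$params)      # n_train x n_query
  mu <- clock$y_offset + as.vector(crossprod(kstar, clock$alpha))
  v <- forwardsolve(clock$L, kstar)
  var_latent <- clock$params$s2 - colSums(v^2)
  clamped <- sum(var_latent < 0)
  var_latent <- pmax(var_latent, 0)
  variance <- if (include_noise) var_latent + clock$params$sigma2 else var_latent
  sd2 <- 2 * sqrt(variance)
  out <- data.frame(sample_id = ids, mu = mu, variance = variance,
                    lower = mu - sd2, upper = mu + sd2,
                    group = group, stringsAsFactors = FALSE)
  attr(out, "clamped") <- clamped
  out
}

#' @export
print.gpr_clock <- function(x, ...) {
  cat(sprintf(
    "<gpr_clock> n=%d, d=%d | s2=%.4g l=%.4g sigma2=%.4g | lml=%.2f\n",
    nrow(x$X), ncol(x$X), x$params$s2, x$params$l, x$params$sigma2, x$lml))
  invisible(x)
}
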