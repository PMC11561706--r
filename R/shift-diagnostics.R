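#' Select the CpGs most correlated with age
#'
#' Ranks CpGs by the absolute Pearson correlation of their beta values with
#' chronological age and returns the top `k`, ties broken by CpG id
#' lexicographic order. Zero-variance CpGs are excluded before ranking.
#' This is the surrogate for a published clock's CpG set: any accurate
#' age-predicting subset suffices for shift diagnostics.
#'
#' @param dataset a [methylation_dataset()] with ages.
#' @param k number of CpGs to select (>= 1).
#' @return Character vector of `k` CpG ids.
#' @export
select_age_correlated_cpgs <- function(dataset, k) {
  stopifnot(inherits(dataset, "methyl_dataset"))
  require_ages(dataset, "select_age_correlated_cpgs")
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  sds <- apply(dataset$beta, 2, stats::sd)
  usable <- cpg_ids(dataset)[sds > 0]
  if (k > length(usable)) {
    stop(sprintf("k = %d exceeds the %d CpGs with nonzero variance",
                 k, length(usable)), call. = FALSE)
  }
  r <- abs(as.vector(stats::cor(dataset$beta[, usable, drop = FALSE],
                                dataset$age)))
  ord <- order(-r, usable)  # ties broken lexicographically by id
  usable[ord][seq_len(k)]
}

#' PCA embedding of a merged dataset pair
#'
#' Fits principal components on the row-bound, column-mean-centered beta
#' matrix of both datasets (no unit-variance scaling: beta values already
#' share the \[0, 1\] scale) and returns per-sample scores labeled by
#' source dataset, plus explained-variance ratios. A visual covariate
#' shift shows up as separated score clouds.
#'
#' @param a,b [methylation_dataset()] objects on a common CpG universe
#'   (they are intersected internally if they differ).
#' @param n_components number of components to return (default 2).
#' @return A list with `scores` (data.frame: `sample_id`, `dataset`,
#'   `PC1`, ...) and `explained_variance_ratio`.
#' @export
pca_embed <- function(a, b, n_components = 2) {
  pair <- intersect_cpgs(a, b)
  merged <- rbind(pair$a$beta, pair$b$beta)
  if (nrow(merged) < n_components) {
    stop("fewer samples than requested components", call. = FALSE)
  }
  keep <- apply(merged, 2, stats::sd) > 0
  merged <- merged[, keep, drop = FALSE]
  if (ncol(merged) == 0) stop("all CpGs have zero variance", call. = FALSE)
  fit <- stats::prcomp(merged, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  scores <- as.data.frame(fit$x[, seq_len(k), drop = FALSE])
  scores <- cbind(
    data.frame(sample_id = rownames(merged),
               dataset = rep(c("a", "b"), c(n_samples(pair$a), n_samples(pair$b))),
               stringsAsFactors = FALSE),
    scores
  )
  rownames(scores) <- NULL
  evr <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = scores, explained_variance_ratio = evr[seq_len(k)])
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: after sorting ascending,
#' `p'_(i) = min_{j >= i} (p_(j) * m / j)` capped at 1 and mapped back to
#' the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-CpG two-sample Kolmogorov-Smirnov shift test
#'
#' For each tested CpG, compares its beta-value distribution between the
#' two datasets with a two-sided two-sample KS test (exact p-values where
#' the sample sizes permit and there are no ties, asymptotic otherwise),
#' then applies the Benjamini-Hochberg correction across the tested set.
#' A CpG is flagged as shifted iff its adjusted p-value is below `q`.
#' The rejected fraction is the headline covariate-shift summary and is
#' accompanied by a Wilson 95% interval (an honesty extension over a bare
#' percentage).
#'
#' @param a,b [methylation_dataset()] objects, each with >= 3 samples.
#' @param cpgs CpG ids to test; defaults to the full common CpG set.
#'   In practice pass a clock-CpG subset or
#'   [select_age_correlated_cpgs()] output.
#' @param q FDR threshold for flagging a CpG as shifted (default 0.01).
#' @return An object of class `shift_report`: list with `per_cpg`
#'   (data.frame: `cpg_id`, `statistic`, `p_value`, `adjusted_p`,
#'   `shifted`), `rejected_fraction`, `rejected_ci`, `q`, `n_a`, `n_b`.
#' @export
ks_shift_test <- function(a, b, cpgs = NULL, q = 0.01) {
  stopifnot(inherits(a, "methyl_dataset"), inherits(b, "methyl_dataset"))
  if (n_samples(a) < 3 || n_samples(b) < 3) {
    stop("each dataset needs at least 3 samples for the KS test", call. = FALSE)
  }
  if (is.null(cpgs)) cpgs <- intersect(cpg_ids(a), cpg_ids(b))
  missing_a <- setdiff(cpgs, cpg_ids(a))
  missing_b <- setdiff(cpgs, cpg_ids(b))
  if (length(missing_a) > 0 || length(missing_b) > 0) {
    stop(sprintf("CpGs absent from a dataset: %s",
                 paste(utils::head(unique(c(missing_a, missing_b)), 5),
                       collapse = ", ")), call. = FALSE)
  }
  if (length(cpgs) == 0) stop("no CpGs to test", call. = FALSE)

  res <- vapply(cpgs, function(cg) {
    kt <- suppressWarnings(stats::ks.test(a$beta[, cg], b$beta[, cg],
                                          alternative = "two.sided"))
    c(unname(kt$statistic), kt$p.value)
  }, numeric(2))
  per_cpg <- data.frame(
    cpg_id = cpgs,
    statistic = res[1, ],
    p_value = res[2, ],
    stringsAsFactors = FALSE
  )
  per_cpg$adjusted_p <- bh_adjust(per_cpg$p_value)
  per_cpg$shifted <- per_cpg$adjusted_p < q
  rownames(per_cpg) <- NULL
  n_rej <- sum(per_cpg$shifted)
  structure(
    list(per_cpg = per_cpg,
         rejected_fraction = n_rej / nrow(per_cpg),
         rejected_ci = wilson_interval(n_rej, nrow(per_cpg)),
         q = q, n_a = n_samples(a), n_b = n_samples(b)),
    class = "shift_report"
  )
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("<shift_report> %d CpGs tested (n = %d vs %d)\n",
              nrow(x$per_cpg), x$n_a, x$n_b))
  cat(sprintf("  rejected at q = %g: %.1f%% [Wilson 95%%: %.1f%%, %.1f%%]\n",
              x$q, 100 * x$rejected_fraction,
              100 * x$rejected_ci[["lower"]], 100 * x$rejected_ci[["upper"]]))
  invisible(x)
}
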