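#' Methylation dataset container
#'
#' The universal carrier for all cohorts handled by clockshift: a numeric
#' matrix of beta values (samples in rows, CpG sites in columns, values in
#' \[0, 1\]) plus per-sample metadata. Ages may be absent, which is the
#' normal state for reprogramming or embryo-like cohorts whose biological
#' age is unknown; operations that need ages fail only when invoked.
#'
#' @param beta numeric matrix, samples x CpGs, all values in \[0, 1\].
#'   Row names are sample ids, column names CpG ids (generated when absent).
#' @param age optional numeric vector of per-sample ages, in `age_unit`.
#' @param group optional per-sample categorical label (reprogramming day,
#'   cohort, treatment, ...), coerced to character.
#' @param tissue optional single string naming the tissue.
#' @param age_unit `"years"` (human datasets) or `"months"` (mouse datasets).
#'   Carried as metadata and never converted implicitly.
#' @param age_cpgs optional character vector of CpG ids with a true age
#'   dependence. Only synthetic data can know this; used for
#'   support-recovery checks and absent for real data.
#' @param shifted_cpgs optional character vector of CpG ids that received an
#'   artificial covariate shift (synthetic data only).
#'
#' @return An object of class `methyl_dataset`.
#' @export
methylation_dataset <- function(beta, age = NULL, group = NULL, tissue = NULL,
                                age_unit = c("years", "months"),
                                age_cpgs = NULL, shifted_cpgs = NULL) {
  age_unit <- match.arg(age_unit)
  beta <- as.matrix(beta)
  if (!is.numeric(beta)) {
    stop("`beta` must be a numeric matrix of methylation values", call. = FALSE)
  }
  if (is.null(rownames(beta))) {
    rownames(beta) <- sprintf("s%04d", seq_len(nrow(beta)))
  }
  if (is.null(colnames(beta))) {
    colnames(beta) <- sprintf("cg%05d", seq_len(ncol(beta)))
  }
  if (anyDuplicated(rownames(beta)) > 0) {
    stop("sample ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(colnames(beta)) > 0) {
    stop("CpG ids must be unique", call. = FALSE)
  }
  if (anyNA(beta)) {
    bad <- which(is.na(beta), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("missing beta value at sample '%s', CpG '%s'",
                 rownames(beta)[bad[1]], colnames(beta)[bad[2]]), call. = FALSE)
  }
  check_beta_bounds(beta)
  if (!is.null(age)) {
    age <- as.numeric(age)
    if (length(age) != nrow(beta)) {
      stop("`age` must have one value per sample", call. = FALSE)
    }
    if (anyNA(age)) stop("`age` must not contain missing values", call. = FALSE)
  }
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != nrow(beta)) {
      stop("`group` must have one value per sample", call. = FALSE)
    }
  }
  structure(
    list(beta = beta, age = age, group = group, tissue = tissue,
         age_unit = age_unit, age_cpgs = age_cpgs, shifted_cpgs = shifted_cpgs),
    class = "methyl_dataset"
  )
}

check_beta_bounds <- function(beta) {
  out <- beta < 0 | beta > 1
  if (any(out)) {
    bad <- which(out, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf(
      "beta value %.6g outside [0, 1] at sample '%s', CpG '%s'",
      beta[bad[1], bad[2]], rownames(beta)[bad[1]], colnames(beta)[bad[2]]
    ), call. = FALSE)
  }
  invisible(beta)
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat(sprintf("<methyl_dataset> %d samples x %d CpGs\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  ages: %s\n",
              if (is.null(x$age)) "absent" else
                sprintf("%.1f-%.1f %s", min(x$age), max(x$age), x$age_unit)))
  if (!is.null(x$group)) {
    cat(sprintf("  groups: %s\n", paste(unique(x$group), collapse = ", ")))
  }
  if (!is.null(x$tissue)) cat(sprintf("  tissue: %s\n", x$tissue))
  if (!is.null(x$age_cpgs)) {
    cat(sprintf("  synthetic: %d true age-CpGs recorded\n", length(x$age_cpgs)))
  }
  invisible(x)
}

#' Number of samples / CpGs in a dataset
#' @param dataset a `methyl_dataset`.
#' @return integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$beta)

#' @rdname n_samples
#' @export
n_cpgs <- function(dataset) ncol(dataset$beta)

#' @rdname n_samples
#' @export
cpg_ids <- function(dataset) colnames(dataset$beta)

#' @rdname n_samples
#' @export
sample_ids <- function(dataset) rownames(dataset$beta)

require_ages <- function(dataset, what) {
  if (is.null(dataset$age)) {
    stop(sprintf("%s requires per-sample ages, but the dataset has none", what),
         call. = FALSE)
  }
  invisible(dataset)
}

#' Subset a dataset by samples or CpGs, keeping metadata aligned
#'
#' @param dataset a `methyl_dataset`.
#' @param idx integer or logical index over samples.
#' @param ids character vector of CpG ids (all must be present).
#' @return The restricted `methyl_dataset`.
#' @export
subset_samples <- function(dataset, idx) {
  d <- dataset
  d$beta <- d$beta[idx, , drop = FALSE]
  if (!is.null(d$age)) d$age <- d$age[idx]
  if (!is.null(d$group)) d$group <- d$group[idx]
  d
}

#' @rdname subset_samples
#' @export
subset_cpgs <- function(dataset, ids) {
  missing <- setdiff(ids, cpg_ids(dataset))
  if (length(missing) > 0) {
    stop(sprintf("CpGs absent from dataset: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  d <- dataset
  d$beta <- d$beta[, ids, drop = FALSE]
  if (!is.null(d$age_cpgs)) d$age_cpgs <- intersect(d$age_cpgs, ids)
  if (!is.null(d$shifted_cpgs)) d$shifted_cpgs <- intersect(d$shifted_cpgs, ids)
  d
}
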