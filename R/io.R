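#' Read a methylation beta matrix with sample metadata
#'
#' The beta matrix is delimited text with the sample id in the first column
#' and CpG ids in the header row (samples x CpGs orientation; a transposed
#' file must be transposed explicitly by the caller — auto-detection is
#' refused because silent transposition is a classic methylation-data bug).
#' Metadata is a delimited table with columns `sample_id`, and optionally
#' `age`, `group`, `tissue`; rows are matched to the matrix by `sample_id`.
#'
#' @param path path to the beta matrix (TSV/CSV, separator auto from
#'   extension: `.csv` comma, otherwise tab).
#' @param metadata_path optional path to the metadata table.
#' @param age_unit unit of the `age` column, `"years"` or `"months"`.
#' @return A [methylation_dataset()].
#' @export
read_beta_matrix <- function(path, metadata_path = NULL,
                             age_unit = c("years", "months")) {
  age_unit <- match.arg(age_unit)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(tab) < 2) stop("beta matrix needs a sample-id column plus CpGs",
                          call. = FALSE)
  ids <- tab[[1]]
  beta <- as.matrix(tab[, -1, drop = FALSE])
  cpgs <- colnames(beta)
  num <- suppressWarnings(matrix(as.numeric(beta), nrow(beta), ncol(beta)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-numeric beta value '%s' at sample '%s', CpG '%s'",
                 beta[bad[1], bad[2]], ids[bad[1]], cpgs[bad[2]]),
         call. = FALSE)
  }
  dimnames(num) <- list(ids, cpgs)

  age <- NULL; group <- NULL; tissue <- NULL
  if (!is.null(metadata_path)) {
    msep <- if (grepl("\\.csv$", metadata_path, ignore.case = TRUE)) "," else "\t"
    meta <- utils::read.table(metadata_path, header = TRUE, sep = msep,
                              check.names = FALSE, stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(meta)) {
      stop("metadata must contain a 'sample_id' column", call. = FALSE)
    }
    unmatched <- setdiff(ids, meta$sample_id)
    if (length(unmatched) > 0) {
      stop(sprintf("samples missing from metadata: %s",
                   paste(utils::head(unmatched, 5), collapse = ", ")),
           call. = FALSE)
    }
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
    if ("age" %in% colnames(meta) && !all(is.na(meta$age))) {
      age <- as.numeric(meta$age)
    }
    if ("group" %in% colnames(meta)) group <- as.character(meta$group)
    if ("tissue" %in% colnames(meta)) tissue <- meta$tissue[1]
  }
  methylation_dataset(num, age = age, group = group, tissue = tissue,
                      age_unit = age_unit)
}

#' Write a methylation dataset to delimited text
#'
#' Beta values are printed with 17 significant digits so that
#' `read_beta_matrix(write_beta_matrix(d))` round-trips bit-identically.
#'
#' @param dataset a [methylation_dataset()].
#' @param path output path for the beta matrix (TSV).
#' @param metadata_path optional output path for the metadata table.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(dataset, path, metadata_path = NULL) {
  stopifnot(inherits(dataset, "methyl_dataset"))
  b <- dataset$beta
  chr <- matrix(formatC(b, format = "g", digits = 17), nrow(b), ncol(b))
  out <- cbind(sample_id = rownames(b), as.data.frame(chr))
  colnames(out) <- c("sample_id", colnames(b))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    meta <- data.frame(
      sample_id = rownames(b),
      age = if (is.null(dataset$age)) NA else
        formatC(dataset$age, format = "g", digits = 17),
      group = if (is.null(dataset$group)) NA else dataset$group,
      tissue = if (is.null(dataset$tissue)) NA else dataset$tissue,
      stringsAsFactors = FALSE
    )
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Restrict two datasets to their common CpG universe
#'
#' Both datasets are reduced to the intersection of their CpG ids, in the
#' same column order, so that downstream models see one feature universe.
#'
#' @param a,b [methylation_dataset()] objects.
#' @return A list with elements `a` and `b`, both restricted.
#' @export
intersect_cpgs <- function(a, b) {
  stopifnot(inherits(a, "methyl_dataset"), inherits(b, "methyl_dataset"))
  common <- intersect(cpg_ids(a), cpg_ids(b))
  if (length(common) == 0) {
    stop("datasets share no CpGs; cannot intersect", call. = FALSE)
  }
  list(a = subset_cpgs(a, common), b = subset_cpgs(b, common))
}

#' Filter CpGs by sequencing coverage
#'
#' Retains a CpG iff the number of samples with coverage >= `min_cov` is at
#' least `ceiling(min_frac * n_samples)` — with the defaults, the standard
#' RRBS rule of at least 5-fold coverage in no less than 90% of samples.
#' CpGs whose id encodes a sex chromosome are dropped when
#' `autosomal_only` (id conventions are platform-specific, so the pattern
#' is configurable).
#'
#' @param dataset a [methylation_dataset()].
#' @param coverage integer matrix of read counts with the same dimnames as
#'   `dataset$beta`.
#' @param min_cov minimum per-sample coverage (default 5).
#' @param min_frac minimum fraction of samples meeting `min_cov` (default 0.9).
#' @param autosomal_only drop sex-chromosome CpGs (default TRUE).
#' @param sex_regex regex identifying sex-chromosome CpG ids.
#' @return The filtered `methyl_dataset`.
#' @export
filter_by_coverage <- function(dataset, coverage, min_cov = 5, min_frac = 0.9,
                               autosomal_only = TRUE,
                               sex_regex = "^(chr[XY][:_])|^cg[XY]_") {
  stopifnot(inherits(dataset, "methyl_dataset"))
  coverage <- as.matrix(coverage)
  if (!identical(dim(coverage), dim(dataset$beta)) ||
      !identical(colnames(coverage), cpg_ids(dataset)) ||
      !identical(rownames(coverage), sample_ids(dataset))) {
    stop("coverage matrix axes do not match the beta matrix", call. = FALSE)
  }
  if (any(coverage < 0)) stop("coverage counts must be >= 0", call. = FALSE)
  need <- ceiling(min_frac * n_samples(dataset))
  keep <- colSums(coverage >= min_cov) >= need
  if (autosomal_only) {
    keep <- keep & !grepl(sex_regex, cpg_ids(dataset))
  }
  kept <- cpg_ids(dataset)[keep]
  if (length(kept) == 0) {
    d <- dataset
    d$beta <- d$beta[, 0, drop = FALSE]
    d$age_cpgs <- character(0)
    return(d)
  }
  subset_cpgs(dataset, kept)
}

#' Randomly split a dataset into training and testing subsets
#'
#' @param dataset a [methylation_dataset()].
#' @param test_frac fraction of samples set aside for testing, in (0, 1).
#' @param seed integer seed; the same seed reproduces the same index sets.
#' @return A list with elements `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(dataset, test_frac, seed = 1) {
  stopifnot(inherits(dataset, "methyl_dataset"))
  if (test_frac <= 0 || test_frac >= 1) {
    stop("test_frac must be in (0, 1)", call. = FALSE)
  }
  n <- n_samples(dataset)
  n_test <- round(test_frac * n)
  if (n_test == 0 || n_test == n) {
    stop("split would leave an empty side; adjust test_frac", call. = FALSE)
  }
  with_seed(seed, {
    test_idx <- sort(sample.int(n, n_test))
    list(train = subset_samples(dataset, setdiff(seq_len(n), test_idx)),
         test = subset_samples(dataset, test_idx))
  })
}
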