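#' Configuration for the synthetic aging-methylation generator
#'
#' Describes a cohort in which a subset of CpGs tracks chronological age
#' linearly on the beta scale while the remainder is age-independent noise.
#' This is the statistical skeleton that penalized linear clocks assume;
#' it makes every downstream stage testable without external downloads.
#'
#' @param n_samples number of samples.
#' @param n_cpgs total number of CpG sites.
#' @param n_age_cpgs number of CpGs with a true linear age dependence
#'   (must not exceed `n_cpgs`).
#' @param age_range length-2 numeric, the (non-degenerate) uniform sampling
#'   interval for ages, in `age_unit`.
#' @param slope_range length-2 positive numeric, range of absolute per-unit-age
#'   beta change for age-CpGs; each CpG draws a magnitude uniformly from this
#'   interval and a random sign.
#' @param noise_sd standard deviation of the additive Gaussian noise on the
#'   beta scale (>= 0).
#' @param age_unit `"years"` or `"months"`.
#' @param seed integer seed making the generator a pure function of its config.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples, n_cpgs, n_age_cpgs,
                              age_range = c(20, 80),
                              slope_range = c(0.002, 0.008),
                              noise_sd = 0.03,
                              age_unit = c("years", "months"),
                              seed = 1) {
  age_unit <- match.arg(age_unit)
  if (n_samples < 1 || n_cpgs < 1 || n_age_cpgs < 0) {
    stop("counts must be positive (n_age_cpgs may be zero)", call. = FALSE)
  }
  if (n_age_cpgs > n_cpgs) {
    stop("n_age_cpgs must not exceed n_cpgs", call. = FALSE)
  }
  if (length(age_range) != 2 || diff(age_range) <= 0) {
    stop("age_range must be a non-degenerate increasing interval", call. = FALSE)
  }
  if (length(slope_range) != 2 || any(slope_range < 0) || diff(slope_range) < 0) {
    stop("slope_range must be a non-negative increasing interval", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples), n_cpgs = as.integer(n_cpgs),
         n_age_cpgs = as.integer(n_age_cpgs), age_range = as.numeric(age_range),
         slope_range = as.numeric(slope_range), noise_sd = noise_sd,
         age_unit = age_unit, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate an aging methylation cohort
#'
#' Ages are drawn uniformly on `age_range`. Each age-linked CpG i follows
#' `beta = clip(b0_i + slope_i * age + eps, 0, 1)` with
#' `eps ~ Normal(0, noise_sd^2)`; the baseline `b0_i` is chosen so that the
#' noiseless line stays inside \[0, 1\] over the age range (clipping then
#' only acts on noise excursions). Age-independent CpGs fluctuate around a
#' random baseline with the same noise. The identities of the true age-CpGs
#' are recorded in the returned dataset — information only synthetic data
#' can carry, used for support-recovery checks.
#'
#' @param config a [simulation_config()].
#' @return A [methylation_dataset()] with ages, `age_cpgs` metadata filled in.
#' @export
simulate_aging_methylation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  geom <- draw_cpg_geometry(config)
  with_seed(stage_seed(config$seed, "aging_samples"), {
    n <- config$n_samples
    p <- config$n_cpgs
    k <- config$n_age_cpgs
    ages <- stats::runif(n, config$age_range[1], config$age_range[2])
    mid <- mean(config$age_range)

    beta <- matrix(NA_real_, n, p,
                   dimnames = list(sprintf("s%04d", seq_len(n)),
                                   sprintf("cg%05d", seq_len(p))))
    for (j in seq_len(k)) {
      beta[, j] <- geom$centre[j] + geom$slope[j] * (ages - mid)
    }
    if (p > k) {
      beta[, (k + 1):p] <- matrix(geom$base, n, p - k, byrow = TRUE)
    }
    if (config$noise_sd > 0) {
      beta <- beta + matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
    }
    beta <- clip01(beta)
    methylation_dataset(beta, age = ages, age_unit = config$age_unit,
                        age_cpgs = colnames(beta)[seq_len(k)])
  })
}

# Per-CpG geometry (slopes, noiseless-line centres, age-independent
# baselines) is a pure function of the config, drawn under a sub-seed of
# its own. Generators that emulate cohorts from the same underlying
# process (an aging cohort and the day-0 state of a reprogramming course)
# share a geometry by sharing a base config.
draw_cpg_geometry <- function(config) {
  with_seed(stage_seed(config$seed, "cpg_geometry"), {
    k <- config$n_age_cpgs
    p <- config$n_cpgs
    half <- diff(config$age_range) / 2
    slope <- if (k > 0) {
      stats::runif(k, config$slope_range[1], config$slope_range[2]) *
        sample(c(-1, 1), k, replace = TRUE)
    } else {
      numeric(0)
    }
    # keep the noiseless line within [margin, 1 - margin] across age_range
    span <- abs(slope) * half
    centre <- if (k > 0) {
      stats::runif(k, pmin(0.05 + span, 0.5), pmax(0.95 - span, 0.5))
    } else {
      numeric(0)
    }
    base <- if (p > k) stats::runif(p - k, 0.05, 0.95) else numeric(0)
    list(slope = slope, centre = centre, base = base)
  })
}

#' Specify a covariate and/or response shift
#'
#' A covariate shift perturbs the beta-value distribution of a fraction of
#' CpGs (what a batch effect or platform difference does to P(X)); a
#' response shift adds a constant to the ages (what a strain difference can
#' do to P(Y)). Offset 0 together with response offset 0 is the identity.
#'
#' @param offset fixed beta-scale offset applied to every shifted CpG
#'   (mutually exclusive with `offset_sd`).
#' @param offset_sd draw a per-CpG offset from Normal(0, offset_sd^2) instead.
#' @param fraction_shifted proportion of CpGs shifted, in \[0, 1\].
#' @param direction `"signed"` adds the offset as given; `"toward_extremes"`
#'   moves each shifted CpG by `|offset|` toward its nearer of \{0, 1\}
#'   (judged by its cohort mean), mimicking pluripotency-associated
#'   hyper/hypomethylation without modeling biology.
#' @param response_offset additive age bias, in the dataset's age unit.
#' @return An object of class `shift_spec`.
#' @export
shift_spec <- function(offset = NULL, offset_sd = NULL, fraction_shifted = 1,
                       direction = c("signed", "toward_extremes"),
                       response_offset = 0) {
  direction <- match.arg(direction)
  if (!is.null(offset) && !is.null(offset_sd)) {
    stop("give either `offset` or `offset_sd`, not both", call. = FALSE)
  }
  if (is.null(offset) && is.null(offset_sd)) offset <- 0
  if (fraction_shifted < 0 || fraction_shifted > 1) {
    stop("fraction_shifted must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(offset = offset, offset_sd = offset_sd,
         fraction_shifted = fraction_shifted, direction = direction,
         response_offset = response_offset),
    class = "shift_spec"
  )
}

#' Apply a covariate (and optional response) shift to a dataset
#'
#' A random `fraction_shifted` of CpG columns receives the specified beta
#' offset, clipped back into \[0, 1\]; unshifted columns are bitwise
#' untouched. Shifted CpG identities are recorded in `shifted_cpgs`. A CpG
#' driven to a constant column by saturation is permitted but flagged with
#' a warning (it carries no distributional signal any more).
#'
#' @param dataset a [methylation_dataset()].
#' @param spec a [shift_spec()].
#' @param seed integer seed controlling which CpGs are shifted and the
#'   per-CpG offsets when `offset_sd` is used.
#' @return The shifted `methyl_dataset`.
#' @export
apply_covariate_shift <- function(dataset, spec, seed = 1) {
  stopifnot(inherits(dataset, "methyl_dataset"), inherits(spec, "shift_spec"))
  if (n_samples(dataset) == 0 || n_cpgs(dataset) == 0) {
    stop("dataset must be nonempty", call. = FALSE)
  }
  with_seed(seed, {
    p <- n_cpgs(dataset)
    n_shift <- round(spec$fraction_shifted * p)
    idx <- sort(sample.int(p, n_shift))
    d <- dataset
    if (n_shift > 0) {
      off <- if (!is.null(spec$offset_sd)) {
        stats::rnorm(n_shift, 0, spec$offset_sd)
      } else {
        rep(spec$offset, n_shift)
      }
      if (spec$direction == "toward_extremes") {
        towards <- ifelse(colMeans(d$beta[, idx, drop = FALSE]) >= 0.5, 1, -1)
        off <- abs(off) * towards
      }
      shifted <- clip01(sweep(d$beta[, idx, drop = FALSE], 2, off, `+`))
      d$beta[, idx] <- shifted
      sat <- colnames(shifted)[apply(shifted, 2, function(x) diff(range(x)) == 0)]
      if (length(sat) > 0) {
        warning(sprintf("shift saturated %d CpG(s) to a constant column: %s",
                        length(sat), paste(utils::head(sat, 5), collapse = ", ")))
      }
    }
    if (spec$response_offset != 0) {
      require_ages(d, "response_offset")
      d$age <- d$age + spec$response_offset
    }
    d$shifted_cpgs <- colnames(dataset$beta)[idx]
    d
  })
}

#' Simulate a reprogramming time course
#'
#' Day-0 samples are drawn from the base aging process at a fixed donor
#' age. On later days a fraction of CpGs drifts monotonically toward its
#' nearer extreme of \{0, 1\} (judged by the day-0 column mean) by
#' `drift_per_day * day`, clipped into \[0, 1\] — an idealization of the
#' genome-wide hyper/hypomethylation that accompanies induced
#' pluripotency. The course carries group labels (the day) but no ages:
#' the biological age of reprogrammed cells is the unknown this framework
#' is about.
#'
#' @param base a [simulation_config()]; `n_samples` is the per-day cohort size.
#' @param days sorted non-negative numeric vector of time points.
#' @param drift_per_day beta-scale drift magnitude per day (>= 0).
#' @param fraction_drifting proportion of CpGs that drift (default all).
#' @param age_drift_multiplier extra drift factor for the age-linked CpGs
#'   (default 2): the age signal is erased ahead of the bulk methylome,
#'   mirroring the observation that epigenetic age resets during the early
#'   maturation phase of reprogramming, before somatic identity is fully
#'   lost. Set to 1 for uniform drift.
#' @param donor_age fixed chronological age of the donor; defaults to the
#'   midpoint of `base$age_range`.
#' @param seed integer seed.
#' @return A `methyl_dataset` with `group` = day as character, no ages.
#' @export
simulate_reprogramming_course <- function(base, days, drift_per_day,
                                          fraction_drifting = 1,
                                          age_drift_multiplier = 2,
                                          donor_age = NULL, seed = 1) {
  stopifnot(inherits(base, "simulation_config"))
  if (is.unsorted(days)) stop("days must be sorted ascending", call. = FALSE)
  if (drift_per_day < 0) stop("drift_per_day must be >= 0", call. = FALSE)
  donor_age <- donor_age %||% mean(base$age_range)
  geom <- draw_cpg_geometry(base)
  with_seed(seed, {
    n <- base$n_samples
    p <- base$n_cpgs
    mid <- mean(base$age_range)

    # day-0 state: the base aging process evaluated at the donor age,
    # with the same CpG geometry the aging generator would use
    base_level <- c(geom$centre + geom$slope * (donor_age - mid), geom$base)
    drifting <- sort(sample.int(p, round(fraction_drifting * p)))
    towards <- ifelse(base_level >= 0.5, 1, -1)
    rate <- rep(drift_per_day, p)
    if (base$n_age_cpgs > 0) {
      rate[seq_len(base$n_age_cpgs)] <- drift_per_day * age_drift_multiplier
    }

    blocks <- lapply(days, function(day) {
      b <- matrix(base_level, n, p, byrow = TRUE)
      if (base$noise_sd > 0) {
        b <- b + matrix(stats::rnorm(n * p, 0, base$noise_sd), n, p)
      }
      if (length(drifting) > 0 && day > 0) {
        b[, drifting] <- sweep(b[, drifting, drop = FALSE], 2,
                               (towards * rate)[drifting] * day, `+`)
      }
      clip01(b)
    })
    beta <- do.call(rbind, blocks)
    rownames(beta) <- sprintf("d%g_s%04d", rep(days, each = n),
                              rep(seq_len(n), length(days)))
    colnames(beta) <- sprintf("cg%05d", seq_len(p))
    methylation_dataset(beta, group = as.character(rep(days, each = n)),
                        age_unit = base$age_unit)
  })
}

#' Default growth-curve parameters for the anthropometric toy cohorts
#'
#' Smooth saturating height and roughly linear weight means over age in
#' months (0-276, i.e. birth to 23 years), with age-dependent SDs and a
#' height-weight correlation of 0.7. The `shifted` cohort has systematically
#' lower height means (a short-stature phenotype) with near-normal weight,
#' which is what makes a height+weight clock trained on controls
#' under-predict its ages.
#'
#' @return A list with `control` and `shifted` entries, each containing
#'   functions `height_mean`, `weight_mean`, `height_sd`, `weight_sd` of age
#'   (months) and a scalar `cor`.
#' @export
default_growth_params <- function() {
  list(
    control = list(
      height_mean = function(a) 50 + 126 * (1 - exp(-a / 84)),
      weight_mean = function(a) 3.5 + 0.26 * a,
      height_sd = function(a) 2.5 + 0.015 * a,
      weight_sd = function(a) 0.8 + 0.03 * a,
      cor = 0.7
    ),
    shifted = list(
      height_mean = function(a) 47 + 83 * (1 - exp(-a / 84)),
      weight_mean = function(a) 3.3 + 0.24 * a,
      height_sd = function(a) 2.5 + 0.015 * a,
      weight_sd = function(a) 0.8 + 0.03 * a,
      cor = 0.7
    ),
    age_range = c(0, 276)
  )
}

#' Simulate anthropometric control and shifted cohorts
#'
#' Ages are sampled uniformly over the configured range; (height, weight)
#' are drawn jointly normal with the per-age mean vector and covariance
#' given by the growth parameters. Defaults to 1000 samples per cohort.
#'
#' @param growth_params as returned by [default_growth_params()].
#' @param n_per_cohort samples per cohort (default 1000).
#' @param seed integer seed.
#' @return A data.frame with columns `sample_id`, `age` (months), `height`
#'   (cm), `weight` (kg), `cohort` (`"control"` / `"shifted"`).
#' @export
simulate_anthropometric_cohorts <- function(growth_params = default_growth_params(),
                                            n_per_cohort = 1000, seed = 1) {
  if (n_per_cohort < 1) stop("n_per_cohort must be positive", call. = FALSE)
  rng <- growth_params$age_range %||% c(0, 276)
  with_seed(seed, {
    one_cohort <- function(pars, label) {
      a <- stats::runif(n_per_cohort, rng[1], rng[2])
      hm <- pars$height_mean(a); wm <- pars$weight_mean(a)
      hs <- pars$height_sd(a); ws <- pars$weight_sd(a)
      if (any(hs <= 0) || any(ws <= 0)) {
        stop("growth-curve SDs must be positive at all sampled ages",
             call. = FALSE)
      }
      # bivariate normal via Cholesky of the per-age covariance
      z1 <- stats::rnorm(n_per_cohort)
      z2 <- stats::rnorm(n_per_cohort)
      h <- hm + hs * z1
      w <- wm + ws * (pars$cor * z1 + sqrt(1 - pars$cor^2) * z2)
      data.frame(sample_id = sprintf("%s_%04d", label, seq_len(n_per_cohort)),
                 age = a, height = h, weight = w, cohort = label,
                 stringsAsFactors = FALSE)
    }
    out <- rbind(one_cohort(growth_params$control, "control"),
                 one_cohort(growth_params$shifted, "shifted"))
    if (any(out$height <= 0) || any(out$weight <= 0)) {
      stop("generated non-positive height or weight; check growth parameters",
           call. = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}
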