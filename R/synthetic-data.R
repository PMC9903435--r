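#' Synthetic cohort configuration
#'
#' Parameters of the synthetic multimodal NSCLC cohort: covariate
#' distributions and true log-hazard coefficients mirror a large
#' real-world NSCLC cohort (mean age 67.95 +/- 9.63, 74.6% male, overall
#' stage proportions 22.1/10.0/31.1/36.7%, 69.3% ever-smokers, ~31%
#' censoring), a Weibull baseline with mild aging hazard (shape 1.2)
#' scaled so the median survival at the centered linear predictor is
#' ~400 days, and an image-borne latent prognostic factor with weight
#' `gamma` entering the true log hazard independently of the clinical
#' covariates.  Distant metastasis is tied to overall stage (M1 if and
#' only if stage IV), as in TNM staging.
#'
#' @param n_subjects cohort size.
#' @param gamma weight of the standardized latent image factor in the
#'   true log hazard (0 = images carry no prognostic signal).
#' @param age_mean,age_sd age distribution (years).
#' @param p_male probability of male sex.
#' @param p_histology,p_stage,p_t,p_n named probability vectors for the
#'   categorical blocks (must each sum to 1).
#' @param p_ever probability of ever-smoking; never-smokers have zero
#'   pack-years.
#' @param smoke_mean_ever,smoke_shape gamma distribution of pack-years
#'   among ever-smokers.
#' @param beta named true log-hazard coefficients per design column.
#' @param baseline_family `"weibull"` or `"exponential"`.
#' @param baseline_shape Weibull shape (ignored for exponential).
#' @param target_median uncensored median survival (days) at the
#'   centered linear predictor; sets the baseline scale.
#' @param censoring_target target censoring fraction (NULL disables
#'   censoring).
#' @param admin_horizon administrative censoring horizon (days).
#' @param vol_shape volume extents (LR, AP, IS).
#' @param vol_background,vol_noise_sd background intensity level and
#'   white-noise sd of the volumes.
#' @param seed master seed; sub-draws (clinical, image factor, survival,
#'   volumes) use fixed offsets from it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 400, gamma = 1,
                          age_mean = 67.95, age_sd = 9.63,
                          p_male = 2005 / 2687,
                          p_histology = c(NOS = 109, adenocarcinoma = 1501,
                                          large_cell = 39,
                                          squamous = 1038) / 2687,
                          p_stage = c(I = 595, II = 269, III = 836,
                                      IV = 987) / 2687,
                          p_t = c(T1 = 575, T2 = 1066, T3 = 544,
                                  T4 = 502) / 2687,
                          p_n = c(N0 = 930, N1 = 329, N2 = 709,
                                  N3 = 719) / 2687,
                          p_ever = 1861 / 2687,
                          smoke_mean_ever = 42.5, smoke_shape = 3.5,
                          beta = NULL,
                          baseline_family = c("weibull", "exponential"),
                          baseline_shape = 1.2, target_median = 400,
                          censoring_target = 830 / 2687,
                          admin_horizon = 2557,
                          vol_shape = c(32, 32, 64),
                          vol_background = 0.2, vol_noise_sd = 0.05,
                          seed = 1) {
  baseline_family <- match.arg(baseline_family)
  for (p in list(p_histology, p_stage, p_t, p_n)) {
    if (abs(sum(p) - 1) > 1e-8) stop("categorical proportions must sum to 1")
  }
  if (!is.null(censoring_target)) {
    stopifnot(censoring_target > 0, censoring_target < 1)
  }
  stopifnot(gamma >= 0, n_subjects >= 1)
  if (is.null(beta)) {
    beta <- c(age = 0.03, smoking_amount = 0,
              sex_male = 0.48,
              histology_adenocarcinoma = -0.19,
              histology_large_cell = -0.05,
              histology_squamous = -0.70,
              t_stage_T2 = 0.10, t_stage_T3 = 0.21, t_stage_T4 = 0.28,
              n_stage_N1 = 0.07, n_stage_N2 = 0.20, n_stage_N3 = 0.53,
              m_stage_M1 = 0.39,
              overall_stage_II = 0.58, overall_stage_III = 1.09,
              overall_stage_IV = 1.36,
              smoking_history_never = -0.06)
  }
  shape <- if (baseline_family == "exponential") 1 else baseline_shape
  out <- list(n_subjects = n_subjects, gamma = gamma,
              age_mean = age_mean, age_sd = age_sd, p_male = p_male,
              p_histology = p_histology, p_stage = p_stage, p_t = p_t,
              p_n = p_n, p_ever = p_ever,
              smoke_mean_ever = smoke_mean_ever, smoke_shape = smoke_shape,
              beta = beta, baseline_family = baseline_family,
              baseline_shape = shape,
              baseline_scale = target_median / log(2)^(1 / shape),
              censoring_target = censoring_target,
              admin_horizon = admin_horizon,
              vol_shape = as.integer(vol_shape),
              vol_background = vol_background, vol_noise_sd = vol_noise_sd,
              seed = seed)
  class(out) <- "cohort_config"
  out
}

# Expected design-column values implied by the config; used to center
# the true linear predictor.
expected_design <- function(config) {
  c(age = config$age_mean,
    smoking_amount = config$p_ever * config$smoke_mean_ever,
    sex_male = config$p_male,
    histology_adenocarcinoma = unname(config$p_histology["adenocarcinoma"]),
    histology_large_cell = unname(config$p_histology["large_cell"]),
    histology_squamous = unname(config$p_histology["squamous"]),
    t_stage_T2 = unname(config$p_t["T2"]),
    t_stage_T3 = unname(config$p_t["T3"]),
    t_stage_T4 = unname(config$p_t["T4"]),
    n_stage_N1 = unname(config$p_n["N1"]),
    n_stage_N2 = unname(config$p_n["N2"]),
    n_stage_N3 = unname(config$p_n["N3"]),
    m_stage_M1 = unname(config$p_stage["IV"]),
    overall_stage_II = unname(config$p_stage["II"]),
    overall_stage_III = unname(config$p_stage["III"]),
    overall_stage_IV = unname(config$p_stage["IV"]),
    smoking_history_never = 1 - config$p_ever)
}

#' Generate clinical covariates with a known linear predictor
#'
#' Samples the covariate table from the configured distributions and
#' returns, alongside, the true clinical linear predictor
#' `lp_clin = beta . x` (centered at its expectation) for oracle
#' evaluation.
#'
#' @param config a [cohort_config()].
#' @param seed seed (defaults to `config$seed`).
#' @return List with `features` (covariate data frame), `design`
#'   (encoded matrix), `lp_clin` (centered), and `beta`.
#' @export
generate_clinical <- function(config, seed = config$seed) {
  n <- config$n_subjects
  sch <- clinical_schema()
  features <- with_seed(seed, {
    stage <- sample(names(config$p_stage), n, TRUE, config$p_stage)
    ever <- rbinom(n, 1, config$p_ever) == 1
    amount <- ifelse(
      ever,
      rgamma(n, shape = config$smoke_shape,
             scale = config$smoke_mean_ever / config$smoke_shape),
      0)
    data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = pmax(rnorm(n, config$age_mean, config$age_sd), 20),
      sex = factor(ifelse(rbinom(n, 1, config$p_male) == 1, "male",
                          "female"), levels = sch$levels$sex),
      histology = factor(sample(names(config$p_histology), n, TRUE,
                                config$p_histology),
                         levels = sch$levels$histology),
      t_stage = factor(sample(names(config$p_t), n, TRUE, config$p_t),
                       levels = sch$levels$t_stage),
      n_stage = factor(sample(names(config$p_n), n, TRUE, config$p_n),
                       levels = sch$levels$n_stage),
      m_stage = factor(ifelse(stage == "IV", "M1", "M0"),
                       levels = sch$levels$m_stage),
      overall_stage = factor(stage, levels = sch$levels$overall_stage),
      smoking_history = factor(ifelse(ever, "ever", "never"),
                               levels = sch$levels$smoking_history),
      smoking_amount = amount,
      stringsAsFactors = FALSE)
  })
  design <- encode_design(features)
  beta <- config$beta[colnames(design)]
  lp <- as.vector(design %*% beta) - sum(expected_design(config) * beta)
  list(features = features, design = design, lp_clin = lp, beta = beta)
}

#' Generate survival outcomes from a proportional-hazards model
#'
#' Event times are drawn by inverse-CDF from the configured Weibull (or
#' exponential) baseline with hazard multiplier `exp(lp)`.  Censoring is
#' the minimum of the administrative horizon and an independent
#' exponential time whose rate is tuned (on the drawn event times) so
#' the expected censoring fraction equals the target.
#'
#' @param lp true log relative hazards (finite), one per subject.
#' @param config a [cohort_config()].
#' @param seed seed (defaults to `config$seed + 2`).
#' @param subject_id optional identifiers.
#' @return A [surv_records] with attributes `true_event_times` and
#'   `censoring_rate_used`.
#' @export
generate_survival <- function(lp, config, seed = config$seed + 2,
                              subject_id = NULL) {
  stopifnot(all(is.finite(lp)))
  n <- length(lp)
  if (is.null(subject_id)) subject_id <- sprintf("S%05d", seq_len(n))
  with_seed(seed, {
    u <- runif(n)
    t_event <- config$baseline_scale *
      (-log(u) * exp(-lp))^(1 / config$baseline_shape)
    if (is.null(config$censoring_target)) {
      rec <- surv_records(subject_id, t_event, rep(1, n))
      attr(rec, "true_event_times") <- t_event
      attr(rec, "censoring_rate_used") <- 0
      rec
    } else {
      h <- config$admin_horizon
      frac_cens <- function(rate) {
        mean(ifelse(t_event >= h, 1, 1 - exp(-rate * t_event)))
      }
      lo <- frac_cens(0)
      if (config$censoring_target <= lo) {
        stop(sprintf(
          "unattainable censoring target %.3f: administrative censoring alone gives %.3f (feasible range (%.3f, 1))",
          config$censoring_target, lo, lo))
      }
      rate <- uniroot(function(r) frac_cens(r) - config$censoring_target,
                      lower = 1e-12, upper = 1, extendInt = "upX",
                      tol = 1e-12)$root
      c_exp <- -log(runif(n)) / rate
      c_time <- pmin(c_exp, h)
      time <- pmin(t_event, c_time)
      event <- as.numeric(t_event <= c_time)
      rec <- surv_records(subject_id, time, event)
      attr(rec, "true_event_times") <- t_event
      attr(rec, "censoring_rate_used") <- rate
      rec
    }
  })
}

#' Generate lesion-bearing synthetic PET volumes
#'
#' Each volume is smooth background noise plus 1-4 ellipsoidal
#' Gaussian-profile blobs whose count, peak intensity and radius all
#' increase monotonically with the subject's latent image factor, so
#' total lesion burden encodes the image-borne prognostic signal.
#'
#' @param image_factor standardized latent factors (mean ~0, sd ~1),
#'   one per subject.
#' @param config a [cohort_config()].
#' @param seed seed (defaults to `config$seed + 3`).
#' @return Object of class `volume_set`: matrix with one flattened
#'   volume per row (positions column-major) and attributes `dims` and
#'   `spacing`.
#' @export
generate_volumes <- function(image_factor, config, seed = config$seed + 3) {
  dims <- config$vol_shape
  max_rad <- 4 * 1.2   # largest semi-axis the factor mapping can produce
  if (any(dims < 2 * ceiling(max_rad + 1) + 2)) {
    stop(sprintf("volume shape (%s) too small for the configured blobs",
                 paste(dims, collapse = "x")))
  }
  n <- length(image_factor)
  p <- prod(dims)
  vols <- matrix(0, n, p)
  with_seed(seed, {
    for (i in seq_len(n)) {
      u <- pnorm(image_factor[i])
      k <- 1 + floor(u * 3.9999)
      peak <- 1.5 + 2.5 * u
      rad <- 2 + 2 * u
      v <- array(rnorm(p, config$vol_background, config$vol_noise_sd),
                 dim = dims)
      for (b in seq_len(k)) {
        semi <- rad * runif(3, 0.8, 1.2)
        # keep centers a core-radius inside the field of view; Gaussian
        # tails may clip at the boundary, as peripheral lesions do
        ctr <- vapply(1:3, function(a) {
          runif(1, semi[a] + 1, dims[a] - semi[a] - 1)
        }, 1)
        lo <- pmax(floor(ctr - 3 * semi), 1)
        hi <- pmin(ceiling(ctr + 3 * semi), dims)
        gx <- exp(-0.5 * ((lo[1]:hi[1] - ctr[1]) / semi[1])^2)
        gy <- exp(-0.5 * ((lo[2]:hi[2] - ctr[2]) / semi[2])^2)
        gz <- exp(-0.5 * ((lo[3]:hi[3] - ctr[3]) / semi[3])^2)
        blob <- peak * outer(outer(gx, gy), gz)
        v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
          v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blob
      }
      vols[i, ] <- pmax(as.vector(v), 0)
    }
  })
  attr(vols, "dims") <- dims
  attr(vols, "spacing") <- c(1, 1, 1)
  class(vols) <- c("volume_set", class(vols))
  vols
}

#' Extract one volume from a volume set
#'
#' @param vols a [generate_volumes()] result.
#' @param i subject index.
#' @return A [pet_volume()].
#' @export
get_volume <- function(vols, i) {
  dims <- attr(vols, "dims")
  pet_volume(array(vols[i, ], dim = dims), spacing = attr(vols, "spacing"))
}

#' Generate a full multimodal synthetic cohort
#'
#' Orchestrates [generate_clinical()], the latent image factor,
#' [generate_survival()] on the combined true log hazard
#' `lp_clin + gamma * z`, and [generate_volumes()], and assembles the
#' network inputs (design matrix, flattened volumes, coronal MIPs).
#'
#' @param config a [cohort_config()].
#' @param with_volumes generate volumes (set `FALSE` for clinical-only
#'   studies; much faster).
#' @return List with `features`, `design`, `records`, `lp_clin`,
#'   `image_factor`, `lp_total`, `volumes` (or NULL), `inputs`
#'   (a [model_inputs()]), and `config`.
#' @export
generate_cohort <- function(config, with_volumes = TRUE) {
  cl <- generate_clinical(config)
  z <- with_seed(config$seed + 1, rnorm(config$n_subjects))
  z <- (z - mean(z)) / sd(z)
  lp_total <- cl$lp_clin + config$gamma * z
  records <- generate_survival(lp_total, config,
                               subject_id = cl$features$subject_id)
  vols <- NULL
  mips <- NULL
  mip_dims <- NULL
  if (with_volumes) {
    vols <- generate_volumes(z, config)
    dims <- attr(vols, "dims")
    mip_dims <- dims[c(1, 3)]
    mips <- t(apply(vols, 1, function(v) {
      as.vector(apply(array(v, dims), c(1, 3), max))
    }))
  }
  inputs <- model_inputs(design = unclass(cl$design)[, , drop = FALSE],
                         volumes = if (with_volumes) unclass(vols) else NULL,
                         vol_dims = if (with_volumes) attr(vols, "dims"),
                         mips = mips, mip_dims = mip_dims)
  list(features = cl$features, design = cl$design, records = records,
       lp_clin = cl$lp_clin, image_factor = z, lp_total = lp_total,
       volumes = vols, inputs = inputs, config = config)
}

#' Write a synthetic cohort to disk
#'
#' Writes the clinical table as CSV (covariates plus `os_days` and
#' `event`), one uncompressed NIfTI volume per subject, and a JSON
#' manifest recording the config, seed, true coefficients and true
#' per-subject linear predictors for downstream oracle evaluation.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param with_volumes write volumes.
#' @return List of paths: `clinical`, `volumes` (directory), `manifest`.
#' @export
simulate_cohort <- function(config, out_dir, with_volumes = TRUE) {
  cohort <- generate_cohort(config, with_volumes = with_volumes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  clin <- cohort$features
  clin$os_days <- cohort$records$time
  clin$event <- cohort$records$event
  clin_path <- file.path(out_dir, "clinical.csv")
  utils::write.csv(clin, clin_path, row.names = FALSE, quote = FALSE)
  vol_dir <- NULL
  if (with_volumes) {
    vol_dir <- file.path(out_dir, "volumes")
    dir.create(vol_dir, showWarnings = FALSE)
    for (i in seq_len(config$n_subjects)) {
      RNifti::writeNifti(
        array(cohort$volumes[i, ], dim = attr(cohort$volumes, "dims")),
        file.path(vol_dir, paste0(cohort$features$subject_id[i], ".nii")))
    }
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(config = config[setdiff(names(config),
                                 c("p_histology", "p_stage", "p_t", "p_n"))],
         proportions = list(histology = as.list(config$p_histology),
                            stage = as.list(config$p_stage),
                            t = as.list(config$p_t), n = as.list(config$p_n)),
         beta = as.list(cohort$config$beta),
         subjects = data.frame(subject_id = cohort$features$subject_id,
                               lp_clin = cohort$lp_clin,
                               image_factor = cohort$image_factor,
                               lp_total = cohort$lp_total)),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(clinical = clin_path, volumes = vol_dir, manifest = manifest_path)
}

#' Read a simulated cohort directory
#'
#' Counterpart of [simulate_cohort()]: reads the clinical CSV and the
#' per-subject NIfTI volumes and assembles the [model_inputs()].
#'
#' @param dir cohort directory.
#' @param with_volumes load volumes.
#' @return List with `features`, `records`, `inputs`.
#' @export
read_cohort <- function(dir, with_volumes = TRUE) {
  tab <- read_clinical_table(file.path(dir, "clinical.csv"))
  inputs_design <- encode_design(tab$features)
  vols <- NULL
  mips <- NULL
  dims <- NULL
  if (with_volumes) {
    vol_dir <- file.path(dir, "volumes")
    paths <- file.path(vol_dir, paste0(tab$features$subject_id, ".nii"))
    first <- load_volume(paths[1])
    dims <- dim(first$data)
    vols <- matrix(0, length(paths), prod(dims))
    for (i in seq_along(paths)) {
      vols[i, ] <- as.vector(load_volume(paths[i])$data)
    }
    mips <- t(apply(vols, 1, function(v) {
      as.vector(apply(array(v, dims), c(1, 3), max))
    }))
  }
  inputs <- model_inputs(design = unclass(inputs_design)[, , drop = FALSE],
                         volumes = vols, vol_dims = dims,
                         mips = mips,
                         mip_dims = if (with_volumes) dims[c(1, 3)])
  list(features = tab$features, records = tab$records, inputs = inputs)
}
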