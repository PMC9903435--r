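#' Clinical covariate schema
#'
#' The covariate schema used throughout the package: age (years), sex,
#' histology, T/N/M stage, overall stage, smoking history and smoking
#' amount (pack-years), plus overall-survival time in days (`os_days`)
#' and the event indicator (`event`).
#'
#' @return Named list of the categorical levels (first level = the
#'   reference level dropped by [encode_design()]) and the required CSV
#'   column names.
#' @export
clinical_schema <- function() {
  list(
    levels = list(
      sex = c("female", "male"),
      histology = c("NOS", "adenocarcinoma", "large_cell", "squamous"),
      t_stage = c("T1", "T2", "T3", "T4"),
      n_stage = c("N0", "N1", "N2", "N3"),
      m_stage = c("M0", "M1"),
      overall_stage = c("I", "II", "III", "IV"),
      smoking_history = c("ever", "never")),
    columns = c("subject_id", "age", "sex", "histology", "t_stage",
                "n_stage", "m_stage", "overall_stage", "smoking_history",
                "smoking_amount", "os_days", "event"))
}

#' Read and validate a clinical table
#'
#' Reads a delimited clinical table with the schema of
#' [clinical_schema()], validates every row (categorical values against
#' their enumerations, `age > 0`, `smoking_amount >= 0`, never-smokers
#' with zero pack-years, `os_days > 0`, `event` in 0/1), and excludes
#' rows with any missing or invalid field, reporting them with their
#' line numbers.
#'
#' @param path path to a CSV file with a header.
#' @return List with `features` (validated covariate data frame),
#'   `records` (a [surv_records]) and `rejected` (data frame of excluded
#'   rows: `line`, `subject_id`, `reason`).
#' @export
read_clinical_table <- function(path) {
  sch <- clinical_schema()
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(sch$columns, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  reasons <- character(n)
  num <- function(x) suppressWarnings(as.numeric(x))
  age <- num(raw$age); amt <- num(raw$smoking_amount)
  osd <- num(raw$os_days); ev <- num(raw$event)
  add_reason <- function(bad, why) {
    bad <- which(bad)
    reasons[bad] <<- ifelse(nzchar(reasons[bad]),
                            paste(reasons[bad], why, sep = "; "), why)
  }
  for (v in names(sch$levels)) {
    add_reason(is.na(raw[[v]]) | !(raw[[v]] %in% sch$levels[[v]]),
               sprintf("invalid %s", v))
  }
  add_reason(is.na(age) | age <= 0, "invalid age")
  add_reason(is.na(amt) | amt < 0, "invalid smoking_amount")
  add_reason(!is.na(amt) & amt > 0 & raw$smoking_history %in% "never",
             "never-smoker with nonzero smoking_amount")
  add_reason(is.na(osd) | osd <= 0, "invalid os_days")
  add_reason(is.na(ev) | !(ev %in% c(0, 1)), "invalid event")
  keep <- !nzchar(reasons)
  rejected <- data.frame(line = which(!keep) + 1L,  # +1 for the header
                         subject_id = raw$subject_id[!keep],
                         reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    message(sprintf("read_clinical_table: excluded %d row(s): %s",
                    nrow(rejected),
                    paste(sprintf("line %d (%s)", rejected$line,
                                  rejected$reason), collapse = "; ")))
  }
  features <- data.frame(
    subject_id = raw$subject_id[keep],
    age = age[keep],
    sex = factor(raw$sex[keep], levels = sch$levels$sex),
    histology = factor(raw$histology[keep], levels = sch$levels$histology),
    t_stage = factor(raw$t_stage[keep], levels = sch$levels$t_stage),
    n_stage = factor(raw$n_stage[keep], levels = sch$levels$n_stage),
    m_stage = factor(raw$m_stage[keep], levels = sch$levels$m_stage),
    overall_stage = factor(raw$overall_stage[keep],
                           levels = sch$levels$overall_stage),
    smoking_history = factor(raw$smoking_history[keep],
                             levels = sch$levels$smoking_history),
    smoking_amount = amt[keep],
    stringsAsFactors = FALSE)
  records <- surv_records(raw$subject_id[keep], osd[keep], ev[keep])
  list(features = features, records = records, rejected = rejected)
}

#' One-hot design matrix for the clinical covariates
#'
#' Encodes the covariates with fixed reference levels (female, NOS
#' histology, T1, N0, M0, overall stage I, ever-smoker dropped); age and
#' smoking amount pass through as continuous columns.  Column order is
#' deterministic: the 2 continuous columns, then each categorical block.
#'
#' @param features covariate data frame as returned by
#'   [read_clinical_table()] or [generate_clinical()].
#' @return Numeric matrix (17 columns for the full schema) with
#'   attributes `column_names` and `reference_levels`.
#' @export
encode_design <- function(features) {
  stopifnot(nrow(features) > 0)
  sch <- clinical_schema()
  cols <- list(age = features$age, smoking_amount = features$smoking_amount)
  refs <- list()
  for (v in names(sch$levels)) {
    lv <- sch$levels[[v]]
    x <- as.character(features[[v]])
    if (any(!x %in% lv)) {
      stop(sprintf("unseen level in %s: %s", v,
                   paste(unique(setdiff(x, lv)), collapse = ", ")))
    }
    refs[[v]] <- lv[1]
    for (l in lv[-1]) cols[[paste(v, l, sep = "_")]] <- as.numeric(x == l)
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  attr(m, "column_names") <- names(cols)
  attr(m, "reference_levels") <- refs
  m
}

#' Reconstruct categorical levels from a design matrix
#'
#' Inverse of the one-hot block of [encode_design()]: rows with all-zero
#' indicators for a variable map back to its reference level.
#'
#' @param design matrix produced by [encode_design()].
#' @return Data frame of the categorical covariates (character columns)
#'   plus the continuous `age` and `smoking_amount`.
#' @export
decode_design <- function(design) {
  refs <- attr(design, "reference_levels")
  stopifnot(!is.null(refs))
  sch <- clinical_schema()
  out <- data.frame(age = design[, "age"],
                    smoking_amount = design[, "smoking_amount"])
  for (v in names(refs)) {
    lv <- sch$levels[[v]]
    block <- design[, paste(v, lv[-1], sep = "_"), drop = FALSE]
    lab <- rep(refs[[v]], nrow(design))
    for (j in seq_along(lv[-1])) lab[block[, j] == 1] <- lv[-1][j]
    out[[v]] <- lab
  }
  out
}

#' Load a PET volume from NIfTI
#'
#' Reads a 3D volume, clips negative intensities to zero (with a logged
#' count) and attaches axis labels and voxel spacing.  Arrays are stored
#' in (left-right, anterior-posterior, inferior-superior) order.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param axes axis labels of the stored array order.
#' @return Object of class `pet_volume`: list with `data` (3D array),
#'   `axes`, `spacing` (mm per axis).
#' @export
load_volume <- function(path, axes = c("LR", "AP", "IS")) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) {
    stop(sprintf("expected a 3D volume, got %d dims", length(dim(arr))))
  }
  n_neg <- sum(arr < 0)
  if (n_neg > 0) {
    message(sprintf("load_volume: clipped %d negative voxel(s) to 0", n_neg))
    arr[arr < 0] <- 0
  }
  pd <- attr(img, "pixdim")
  spacing <- if (!is.null(pd) && length(pd) >= 3) as.numeric(pd[1:3]) else
    c(1, 1, 1)
  pet_volume(arr, axes = axes, spacing = spacing)
}

#' Construct a PET volume object
#'
#' @param data nonnegative 3D array.
#' @param axes ordered axis labels; must contain "AP" (the
#'   anterior-posterior axis) for [coronal_mip()].
#' @param spacing voxel spacing in mm per axis.
#' @return Object of class `pet_volume`.
#' @export
pet_volume <- function(data, axes = c("LR", "AP", "IS"),
                       spacing = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3, length(axes) == 3, length(spacing) == 3)
  if (any(!is.finite(data))) stop("volume intensities must be finite")
  if (any(data < 0)) stop("volume intensities must be nonnegative")
  out <- list(data = data, axes = axes, spacing = as.numeric(spacing))
  class(out) <- "pet_volume"
  out
}

#' Normalize volume intensities
#'
#' Default method clips intensities at a ceiling and scales to \[0, 1\]
#' per volume.  When `clip_max` is `NULL` the volume maximum is used.
#' The method and parameters are recorded in the `provenance` attribute.
#'
#' @param vol a [pet_volume()].
#' @param method only `"clip_scale"` is implemented.
#' @param clip_max intensity ceiling; `NULL` for the per-volume maximum.
#' @return A normalized `pet_volume` with intensities in \[0, 1\].
#' @export
normalize_volume <- function(vol, method = "clip_scale", clip_max = NULL) {
  stopifnot(inherits(vol, "pet_volume"))
  method <- match.arg(method, "clip_scale")
  mx <- max(vol$data)
  if (mx == 0) stop("all-zero volume cannot be normalized")
  ceiling_used <- if (is.null(clip_max)) mx else clip_max
  x <- pmin(vol$data, ceiling_used) / ceiling_used
  out <- pet_volume(x, axes = vol$axes, spacing = vol$spacing)
  attr(out, "provenance") <- list(method = method, clip_max = ceiling_used)
  out
}

#' Coronal maximum intensity projection
#'
#' Projects a 3D volume onto the coronal plane by taking the voxel-wise
#' maximum along the anterior-posterior axis, the standard whole-body
#' PET display transform.
#'
#' @param vol a [pet_volume()] whose `axes` contain "AP".
#' @return 2D matrix with dims (left-right extent, inferior-superior
#'   extent).
#' @export
coronal_mip <- function(vol) {
  stopifnot(inherits(vol, "pet_volume"))
  ap <- which(vol$axes == "AP")
  if (length(ap) != 1) stop("axes metadata must identify the AP axis")
  apply(vol$data, setdiff(1:3, ap), max)
}

#' Stratified train/test split
#'
#' Splits subjects into train and test index sets, preserving the
#' proportions of a stratification variable (by default the event
#' indicator) within each part.
#'
#' @param records a [surv_records] data frame.
#' @param fraction training fraction (default 0.8, an 80/20 split).
#' @param stratify_on vector to stratify on, one value per record;
#'   defaults to `records$event`.
#' @param seed integer seed; the split is reproducible given the seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(records, fraction = 0.8, stratify_on = NULL,
                         seed = 1) {
  assert_records(records)
  stopifnot(fraction > 0, fraction < 1)
  if (is.null(stratify_on)) stratify_on <- records$event
  stopifnot(length(stratify_on) == nrow(records))
  test <- integer(0)
  with_seed(seed, {
    for (s in unique(stratify_on)) {
      idx <- which(stratify_on == s)
      n_test <- round(length(idx) * (1 - fraction))
      test <- c(test, sample(idx, n_test))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_len(nrow(records)), test), test = test)
}

#' Stratified k-fold partition
#'
#' Partitions subjects into k disjoint, exhaustive folds with the
#' stratification variable balanced across folds (fold counts within
#' each stratum differ by at most one).
#'
#' @inheritParams split_cohort
#' @param k number of folds (>= 2).
#' @return List of length `k`; element i is a list with `train` and
#'   `test` integer index vectors for fold i.  Attributes `seed` and
#'   `strata` record the construction.
#' @export
stratified_kfold <- function(records, k = 5, stratify_on = NULL, seed = 1) {
  assert_records(records)
  stopifnot(k >= 2)
  if (is.null(stratify_on)) stratify_on <- records$event
  stopifnot(length(stratify_on) == nrow(records))
  fold_of <- integer(nrow(records))
  with_seed(seed, {
    for (s in unique(stratify_on)) {
      idx <- which(stratify_on == s)
      if (length(idx) < k) {
        stop(sprintf("stratum '%s' has %d member(s), fewer than k = %d",
                     s, length(idx), k))
      }
      idx <- sample(idx)
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  out <- lapply(seq_len(k), function(i) {
    list(train = which(fold_of != i), test = which(fold_of == i))
  })
  attr(out, "seed") <- seed
  attr(out, "strata") <- stratify_on
  out
}

#' Write a fold manifest as JSON
#'
#' Records subject ids per fold with the seed and stratification used,
#' so a split can be audited and replayed.
#'
#' @param folds output of [stratified_kfold()] or [split_cohort()].
#' @param records the [surv_records] the folds index into.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(folds, records, path) {
  ids <- records$subject_id
  if (!is.null(folds$train)) {
    payload <- list(kind = "train_test",
                    train = ids[folds$train], test = ids[folds$test])
  } else {
    payload <- list(kind = "kfold",
                    seed = attr(folds, "seed"),
                    folds = lapply(folds, function(f) {
                      list(train = ids[f$train], test = ids[f$test])
                    }))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(code))
}
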