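test_that("clinical table reading validates and excludes bad rows", {
  path <- tiny_clinical_csv(tempfile(fileext = ".csv"))
  out <- read_clinical_table(path)
  expect_equal(nrow(out$features), 3)
  expect_equal(nrow(out$rejected), 0)
  expect_s3_class(out$records, "surv_records")
  # enumeration violation: stage "V"
  bad <- tiny_clinical_csv(tempfile(fileext = ".csv"), rows = c(
    "P1,62,male,adenocarcinoma,T2,N1,M0,II,ever,30,410,1",
    "P2,71,female,squamous,T3,N2,M0,V,never,0,820,0"))
  expect_message(out2 <- read_clinical_table(bad), "excluded 1 row")
  expect_equal(nrow(out2$features), 1)
  expect_equal(out2$rejected$line, 3L)
  expect_match(out2$rejected$reason, "overall_stage")
  # missing smoking_amount: that row excluded, others kept
  miss <- tiny_clinical_csv(tempfile(fileext = ".csv"), rows = c(
    "P1,62,male,adenocarcinoma,T2,N1,M0,II,ever,,410,1",
    "P2,71,female,squamous,T3,N2,M0,III,never,0,820,0",
    "P3,55,male,NOS,T1,N0,M1,IV,ever,45,150,1"))
  expect_message(out3 <- read_clinical_table(miss), "smoking_amount")
  expect_equal(out3$features$subject_id, c("P2", "P3"))
  # missing column is a schema error
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,age", "P1,62"), tmp)
  expect_error(read_clinical_table(tmp), "missing required column")
})

test_that("design encoding drops the documented reference levels", {
  # reference subject: only the continuous columns are nonzero
  ref <- reference_subject()
  d_ref <- encode_design(ref)
  onehot <- d_ref[, setdiff(colnames(d_ref), c("age", "smoking_amount"))]
  expect_true(all(onehot == 0))
  # single deviation: male, T2 -> exactly two nonzero one-hot entries
  subj <- reference_subject()
  subj$sex <- factor("male", levels(ref$sex))
  subj$t_stage <- factor("T2", levels(ref$t_stage))
  d <- encode_design(subj)
  onehot <- d[, setdiff(colnames(d), c("age", "smoking_amount"))]
  expect_equal(sum(onehot != 0), 2)
  expect_equal(unname(d[, "sex_male"]), 1)
  expect_equal(unname(d[, "t_stage_T2"]), 1)
  # full column count: 2 continuous + 1+3+3+3+1+3+1 one-hot = 17
  expect_equal(ncol(d), 17)
  expect_error(encode_design(transform(ref, sex = "other")), "unseen level")
})

test_that("design encoding round-trips through its reference metadata", {
  cfg <- cohort_config(n_subjects = 40, seed = 2)
  cl <- generate_clinical(cfg)
  dec <- decode_design(cl$design)
  for (v in c("sex", "histology", "t_stage", "n_stage", "m_stage",
              "overall_stage", "smoking_history")) {
    expect_equal(dec[[v]], as.character(cl$features[[v]]), label = v)
  }
  expect_equal(dec$age, cl$features$age)
})

test_that("volumes load from NIfTI with negative-intensity clipping", {
  arr <- array(runif(8 * 8 * 8), c(8, 8, 8))
  arr[1, 1, 1] <- -3
  path <- tempfile(fileext = ".nii")
  RNifti::writeNifti(arr, path)
  expect_message(vol <- load_volume(path), "clipped 1 negative")
  expect_equal(vol$data[1, 1, 1], 0)
  expect_equal(dim(vol$data), c(8, 8, 8))
  # non-3D input is rejected
  p2 <- tempfile(fileext = ".nii")
  RNifti::writeNifti(array(1, c(4, 4)), p2)
  expect_error(load_volume(p2), "3D")
})

test_that("volume normalization clips, scales, and is deterministic", {
  v <- pet_volume(array(2, c(4, 4, 4)))
  expect_true(all(normalize_volume(v)$data == 1))
  arr <- array(1, c(4, 4, 4)); arr[2, 2, 2] <- 50
  v2 <- pet_volume(arr)
  nv <- normalize_volume(v2, clip_max = 10)
  expect_equal(nv$data[2, 2, 2], 1)
  expect_equal(nv$data[1, 1, 1], 0.1)
  expect_identical(normalize_volume(v2)$data, normalize_volume(v2)$data)
  expect_error(normalize_volume(pet_volume(array(0, c(2, 2, 2)))),
               "all-zero")
})

test_that("coronal MIP is the max over the anterior-posterior axis", {
  arr <- array(0, c(5, 6, 7))
  arr[3, 4, 2] <- 9
  m <- coronal_mip(pet_volume(arr))
  expect_equal(dim(m), c(5, 7))
  expect_equal(m[3, 2], 9)
  expect_equal(sum(m == 9), 1)
  # constant volume projects to a constant plane
  expect_true(all(coronal_mip(pet_volume(array(2.5, c(4, 4, 4)))) == 2.5))
  # AP extent of 1: projection returns the same plane
  thin <- array(runif(5 * 1 * 7), c(5, 1, 7))
  expect_equal(coronal_mip(pet_volume(thin)), thin[, 1, ])
  # random volumes vs the triple-loop oracle
  for (seed in 1:20) {
    set.seed(seed)
    a <- array(runif(6 * 5 * 4), c(6, 5, 4))
    expect_equal(coronal_mip(pet_volume(a)), oracle_mip(a))
  }
  expect_error(coronal_mip(pet_volume(arr, axes = c("LR", "XX", "IS"))),
               "AP axis")
})

test_that("stratified splits balance events and are reproducible", {
  set.seed(3)
  rec <- surv_records(1:100, rexp(100) + 1,
                      rep(c(1, 0), c(30, 70)))
  folds <- stratified_kfold(rec, k = 5, seed = 9)
  # disjoint and exhaustive
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:100)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(tests[[i]], tests[[j]]), 0)
  }
  # 30 events over 5 folds: exactly 6 per fold
  for (f in folds) expect_equal(sum(rec$event[f$test]), 6)
  # reproducible under the same seed
  folds2 <- stratified_kfold(rec, k = 5, seed = 9)
  expect_identical(lapply(folds, `[[`, "test"),
                   lapply(folds2, `[[`, "test"))
  # tiny stratum is reported by name
  rec_s <- surv_records(1:6, 1:6, c(1, 0, 0, 0, 0, 0))
  expect_error(stratified_kfold(rec_s, k = 5), "stratum '1'")
})

test_that("80/20 split reproduces the cohort's event allocation", {
  set.seed(4)
  rec <- surv_records(1:2687, rexp(2687) + 1,
                      rep(c(1, 0), c(1857, 830)))
  sp <- split_cohort(rec, fraction = 0.8, seed = 5)
  expect_equal(length(sp$train) + length(sp$test), 2687)
  expect_length(intersect(sp$train, sp$test), 0)
  # test-fold deaths close to the proportional count of 372
  expect_lte(abs(sum(rec$event[sp$test]) - 372), 2)
  # event-rate balance within 2 percentage points
  expect_lt(abs(mean(rec$event[sp$test]) - mean(rec$event)), 0.02)
})

test_that("fold manifests serialize subject ids with the seed", {
  rec <- surv_records(sprintf("S%03d", 1:40), rexp(40) + 1,
                      rep(c(1, 0), 20))
  folds <- stratified_kfold(rec, k = 4, seed = 2)
  path <- tempfile(fileext = ".json")
  write_split_manifest(folds, rec, path)
  got <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(got$kind, "kfold")
  expect_equal(got$seed, 2L)
  expect_equal(sort(unlist(lapply(got$folds, function(f) unlist(f$test)))),
               sort(rec$subject_id))
})
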