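# Small cohort and fixture builders shared across test files.

tiny_clinical_csv <- function(path, rows = NULL) {
  header <- paste("subject_id,age,sex,histology,t_stage,n_stage,m_stage",
                  "overall_stage,smoking_history,smoking_amount,os_days,event",
                  sep = ",")
  if (is.null(rows)) {
    rows <- c(
      "P1,62,male,adenocarcinoma,T2,N1,M0,II,ever,30,410,1",
      "P2,71,female,squamous,T3,N2,M0,III,never,0,820,0",
      "P3,55,male,NOS,T1,N0,M1,IV,ever,45,150,1")
  }
  writeLines(c(header, rows), path)
  path
}

# Reference-level subject: female, NOS, T1, N0, M0, stage I, ever-smoker.
reference_subject <- function(age = 60, smoking_amount = 10) {
  data.frame(subject_id = "R1", age = age,
             sex = factor("female", c("female", "male")),
             histology = factor("NOS", c("NOS", "adenocarcinoma",
                                         "large_cell", "squamous")),
             t_stage = factor("T1", paste0("T", 1:4)),
             n_stage = factor("N0", paste0("N", 0:3)),
             m_stage = factor("M0", c("M0", "M1")),
             overall_stage = factor("I", c("I", "II", "III", "IV")),
             smoking_history = factor("ever", c("ever", "never")),
             smoking_amount = smoking_amount,
             stringsAsFactors = FALSE)
}

# Simple proportional-hazards simulation with an explicit design, for
# fitter recovery tests (independent of the package generator).
simulate_ph <- function(n, beta, censor_frac = 0.3, seed = 1,
                        rate = 1 / 500) {
  set.seed(seed)
  x <- matrix(rnorm(n * length(beta)), n)
  colnames(x) <- paste0("x", seq_along(beta))
  lp <- as.vector(x %*% beta)
  t_event <- rexp(n, rate) * exp(-lp)
  if (censor_frac > 0) {
    cens <- rexp(n, rate * censor_frac / (1 - censor_frac))
    time <- pmin(t_event, cens)
    event <- as.numeric(t_event <= cens)
  } else {
    time <- t_event
    event <- rep(1, n)
  }
  list(design = x, records = surv_records(seq_len(n), time, event),
       lp = lp)
}
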