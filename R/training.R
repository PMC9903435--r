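#' Training configuration
#'
#' Optimization settings for Cox-loss training.  Defaults follow the
#' reference setup: Adam with learning rate 1e-4, batch size 6 for
#' volume inputs and 125 for clinical-only models, early stopping with
#' a patience of 3 epochs on the validation Cox loss.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size (>= 2; Cox risk sets need at least
#'   two subjects).  `NULL` selects 6 for models with an image branch
#'   and 125 for clinical-only models.
#' @param patience early-stopping patience in epochs.
#' @param max_epochs epoch cap.
#' @param l2_weight L2 penalty weight on the network weights.
#' @param seed integer seed controlling initialization-independent
#'   randomness inside [train()] (validation split, batch order).
#' @param validation_fraction fraction of the training set held out,
#'   event-stratified, to monitor the validation Cox loss.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = NULL,
                         patience = 3, max_epochs = 200, l2_weight = 1e-4,
                         seed = 1, validation_fraction = 0.2) {
  stopifnot(learning_rate > 0, patience >= 1, max_epochs >= 1,
            l2_weight >= 0, validation_fraction >= 0,
            validation_fraction < 1)
  if (!is.null(batch_size)) stopifnot(batch_size >= 2)
  out <- list(learning_rate = learning_rate, batch_size = batch_size,
              patience = patience, max_epochs = max_epochs,
              l2_weight = l2_weight, seed = seed,
              validation_fraction = validation_fraction)
  class(out) <- "train_config"
  out
}

default_batch_size <- function(model) {
  if (model$kind %in% c("mlp")) 125 else 6
}

# Adam optimizer state over all (layer, parameter) pairs of a model.
adam_state <- function(model) {
  refs <- list()
  for (ly in model_layer_list(model)) {
    for (nm in names(ly$params)) {
      refs[[length(refs) + 1]] <- list(ly = ly, nm = nm)
    }
  }
  list(refs = refs,
       m = lapply(refs, function(r) r$ly$params[[r$nm]] * 0),
       v = lapply(refs, function(r) r$ly$params[[r$nm]] * 0),
       t = 0L)
}

adam_update <- function(opt, lr, l2_weight, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1t <- beta1^opt$t
  b2t <- beta2^opt$t
  for (i in seq_along(opt$refs)) {
    r <- opt$refs[[i]]
    l2 <- if (r$nm %in% r$ly$decay) l2_weight else 0
    adam_step_inplace(r$ly$params[[r$nm]], r$ly$grads[[r$nm]],
                      opt$m[[i]], opt$v[[i]],
                      lr, beta1, beta2, eps, b1t, b2t, l2)
  }
  opt
}

param_norm_sq <- function(model) {
  s <- 0
  for (ly in model_layer_list(model)) {
    for (nm in ly$decay) s <- s + sum(ly$params[[nm]]^2)
  }
  s
}

# Partition a permuted index vector into minibatches, then repair
# event-free batches by swapping in an event subject from the
# event-richest batch.
make_batches <- function(idx, event, batch_size) {
  n <- length(idx)
  n_batches <- max(1L, n %/% batch_size)
  grp <- rep(seq_len(n_batches), each = batch_size, length.out = n)
  batches <- split(idx, grp)
  ev_counts <- vapply(batches, function(b) sum(event[b]), 1)
  for (j in which(ev_counts == 0)) {
    donor <- which.max(ev_counts)
    if (ev_counts[donor] < 2) next  # nothing to give; caller resamples
    d_ev <- batches[[donor]][event[batches[[donor]]] == 1]
    give <- d_ev[sample.int(length(d_ev), 1)]
    take_pos <- sample.int(length(batches[[j]]), 1)
    take <- batches[[j]][take_pos]
    batches[[j]][take_pos] <- give
    batches[[donor]][batches[[donor]] == give] <- take
    ev_counts[j] <- 1
    ev_counts[donor] <- ev_counts[donor] - 1
  }
  batches[vapply(batches, function(b) sum(event[b]) > 0, TRUE)]
}

#' Train a risk network with the Cox partial-likelihood loss
#'
#' Minibatch Adam optimization of [coxnll()]; risk sets are formed
#' within each minibatch (batches are sorted by time and guaranteed at
#' least one event, with event-free batches repaired by swapping).
#' Early stopping monitors the validation Cox loss on an internal
#' event-stratified split and restores the best weights.  Deterministic
#' given the config seed on a single device.
#'
#' @param model a `petsurv_model` (mutated in place and also returned).
#' @param records training [surv_records].
#' @param inputs training [model_inputs()], rows aligned with `records`.
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return List with `model`, `history` (data frame: epoch, train_loss,
#'   val_loss), `best_epoch`, and `config`.
#' @export
train <- function(model, records, inputs, config = train_config(),
                  verbose = FALSE) {
  assert_records(records)
  stopifnot(inherits(model, "petsurv_model"))
  if (sum(records$event) < 2) stop("training set must contain >= 2 events")
  if (!is.null(inputs$design) && is.null(model$scaler) &&
      model$kind %in% c("mlp", "multimodal")) {
    model$scaler <- fit_design_scaler(inputs$design)
  }
  batch_size <- if (is.null(config$batch_size)) default_batch_size(model)
    else config$batch_size
  n <- nrow(records)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, epoch = 0L, state = NULL)
  opt <- adam_state(model)
  with_seed(config$seed, {
    if (config$validation_fraction > 0) {
      sp <- split_cohort(records, fraction = 1 - config$validation_fraction,
                         stratify_on = records$event,
                         seed = sample.int(.Machine$integer.max, 1))
      tr_idx <- sp$train
      va_idx <- sp$test
      if (sum(records$event[va_idx]) == 0) {
        va_idx <- integer(0)
        tr_idx <- seq_len(n)
      }
    } else {
      tr_idx <- seq_len(n)
      va_idx <- integer(0)
    }
    patience_left <- config$patience
    for (epoch in seq_len(config$max_epochs)) {
      perm <- tr_idx[sample.int(length(tr_idx))]
      batches <- make_batches(perm, records$event, batch_size)
      batch_losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        b <- b[order(records$time[b])]
        risks <- model_forward(model, inputs, b, training = TRUE)
        brec <- records[b, , drop = FALSE]
        nll <- coxnll(risks, brec)
        if (!is.finite(nll)) {
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d batch %d",
            epoch, bi))
        }
        batch_losses[bi] <- nll
        model_backward(model, coxnll_grad(risks, brec))
        opt <- adam_update(opt, config$learning_rate, config$l2_weight)
      }
      monitor <- if (length(va_idx) > 0) {
        va_risks <- predict_risk(model, subset_inputs(inputs, va_idx))
        coxnll(va_risks, records[va_idx, , drop = FALSE])
      } else mean(batch_losses)
      history[epoch, ] <- list(epoch, mean(batch_losses), monitor)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        mean(batch_losses), monitor))
      }
      if (monitor < best$loss) {
        best <- list(loss = monitor, epoch = epoch,
                     state = model_state(model))
        patience_left <- config$patience
      } else {
        patience_left <- patience_left - 1
        if (patience_left <= 0) break
      }
    }
  })
  if (!is.null(best$state)) set_model_state(model, best$state)
  list(model = model, history = history, best_epoch = best$epoch,
       config = config)
}

#' Build a model from a spec against concrete inputs
#'
#' @param spec a [model_spec()].
#' @param inputs a [model_inputs()] (used for the clinical input width).
#' @param seed initialization seed.
#' @param f64 double-precision kernel path.
#' @return A `petsurv_model`.
#' @export
build_model <- function(spec, inputs, seed = 1, f64 = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  switch(spec$kind,
    mlp = build_mlp(ncol(inputs$design), spec$hidden_width, seed = seed,
                    f64 = f64),
    resnet2d = build_resnet2d(spec$layers, spec$in_channels, seed = seed,
                              f64 = f64),
    resnet3d = build_resnet3d(spec$layers, spec$in_channels, seed = seed,
                              f64 = f64),
    multimodal = build_multimodal(
      ncol(inputs$design),
      resnet3d_spec = spec$resnet3d[setdiff(names(spec$resnet3d), "kind")],
      mlp_spec = spec$mlp[setdiff(names(spec$mlp), "kind")],
      seed = seed, f64 = f64))
}

#' Stratified k-fold cross-validation of one model configuration
#'
#' For each fold: trains on the other k-1 folds (with an internal
#' validation split for early stopping), fits the Breslow baseline
#' hazard on the training-fold risk scores only, predicts median
#' survival times for the held-out fold, and computes the full metric
#' bundle.  The summary reports mean and sd per metric across folds.
#'
#' @param spec a [model_spec()].
#' @param records cohort [surv_records].
#' @param inputs cohort [model_inputs()], rows aligned with `records`.
#' @param k number of folds.
#' @param config a [train_config()]; fold i trains with seed
#'   `config$seed + i`.
#' @param horizon prediction cap in days for [predict_median_times()].
#' @return Object of class `cv_result`: list with `folds` (per-fold
#'   results: metrics, history, baseline, test indices, predicted
#'   times), `summary` (mean/sd table), `k`.
#' @export
cross_validate <- function(spec, records, inputs, k = 5,
                           config = train_config(), horizon = 3650) {
  assert_records(records)
  folds <- stratified_kfold(records, k = k, stratify_on = records$event,
                            seed = config$seed)
  results <- vector("list", k)
  for (i in seq_len(k)) {
    results[[i]] <- tryCatch({
      tr <- folds[[i]]$train
      te <- folds[[i]]$test
      fold_config <- config
      fold_config$seed <- config$seed + i
      model <- build_model(spec, inputs, seed = fold_config$seed,
                           f64 = FALSE)
      fit <- train(model, records[tr, , drop = FALSE],
                   subset_inputs(inputs, tr), fold_config)
      train_risks <- predict_risk(model, subset_inputs(inputs, tr))
      baseline <- breslow_baseline(train_risks,
                                   records[tr, , drop = FALSE])
      test_risks <- predict_risk(model, subset_inputs(inputs, te))
      pred <- predict_median_times(baseline, test_risks, horizon = horizon)
      list(fold = i, metrics = metric_bundle(records[te, , drop = FALSE],
                                             pred$time),
           history = fit$history, best_epoch = fit$best_epoch,
           baseline = baseline, test_idx = te,
           predicted_times = pred$time, test_risks = test_risks)
    }, error = function(e) {
      message(sprintf("fold %d failed: %s", i, conditionMessage(e)))
      list(fold = i, error = conditionMessage(e))
    })
  }
  ok <- !vapply(results, function(r) is.null(r$metrics), TRUE)
  summary <- if (any(ok)) {
    metric_table(lapply(results[ok], `[[`, "metrics"))
  } else NULL
  out <- list(folds = results, summary = summary, k = k, config = config)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds\n", x$k))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Pooled out-of-fold predicted times from a cross-validation result
#'
#' @param cv a [cross_validate()] result.
#' @param n cohort size.
#' @return Numeric vector of length `n` (NA for subjects in failed
#'   folds).
#' @export
oof_predictions <- function(cv, n) {
  out <- rep(NA_real_, n)
  for (f in cv$folds) {
    if (!is.null(f$predicted_times)) out[f$test_idx] <- f$predicted_times
  }
  out
}

#' Stage-wise subgroup analysis of predictions
#'
#' Compares predictions with the ground truth within overall-stage
#' subgroups: the early stages (I-III) pooled, the advanced stage (IV),
#' and each individual stage.  Reports the MAE over uncensored subjects
#' and a log-rank test between the ground-truth survival distribution
#' and the distribution of predicted times (taken as exact).
#'
#' @param predicted_times numeric vector aligned with `records` (e.g.
#'   [oof_predictions()]); NA entries are dropped.
#' @param records cohort [surv_records].
#' @param overall_stage factor/character vector of stages I-IV aligned
#'   with `records`.
#' @return Data frame: `group`, `n`, `n_uncensored`, `mae_days`,
#'   `logrank_chisq`, `logrank_p`.
#' @export
stage_subgroup_analysis <- function(predicted_times, records,
                                    overall_stage) {
  assert_aligned(records, predicted_times, "predicted times")
  stopifnot(length(overall_stage) == nrow(records))
  stage <- as.character(overall_stage)
  groups <- list(early = c("I", "II", "III"), advanced = "IV",
                 I = "I", II = "II", III = "III", IV = "IV")
  rows <- list()
  for (g in names(groups)) {
    sel <- stage %in% groups[[g]] & !is.na(predicted_times)
    if (!any(sel)) {
      message(sprintf("stage group '%s' is empty; skipped", g))
      next
    }
    rec_g <- records[sel, , drop = FALSE]
    pred_g <- predicted_times[sel]
    mae <- mae_uncensored(rec_g, pred_g)
    lr <- if (sum(rec_g$event) > 0) {
      log_rank_test(rec_g,
                    surv_records(paste0("pred_", seq_along(pred_g)),
                                 pred_g, rep(1, length(pred_g))))
    } else list(statistic = NA_real_, p_value = NA_real_)
    rows[[g]] <- data.frame(group = g, n = sum(sel),
                            n_uncensored = mae$n_uncensored,
                            mae_days = mae$mae_days,
                            logrank_chisq = lr$statistic,
                            logrank_p = lr$p_value)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
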