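# The parameter-recovery training run shared by the recovery and
# localization checks: 400 synthetic records (anomaly contrast 0.5,
# pixel noise 0.1), 64-px input, small preset, 30 epochs, fixed seed.
# Trained once per session and memoised.

recovery_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_records = 400, lesion_contrast = 0.5,
                              noise_sd = 0.1, seed = 11)
      rs <- generate_dataset(cfg)
      sp <- split_records(rs, 0.8, seed = 11)
      ps <- dataset_psize_stats(rs)$chosen_global_size
      tr <- prepare_inputs(sp$train, 64, ps)
      va <- prepare_inputs(sp$val, 64, ps, with_masks = TRUE)
      model <- build_model(model_config(), seed = 11)
      fit <- train_model(model, tr, va, schedule_config(), epochs = 30,
                         seed = 11)
      cache <<- list(fit = fit, va = va)
    }
    cache
  }
})

# Median own- and cross-mask localization over correctly classified
# positive validation records of one task branch.
localization_medians <- function(fit, va, task) {
  y <- if (task == "m") va$label_m else va$label_p
  idx <- which(y == 1 & fit$best_val[[task]]$prob >= 0.5)
  own <- numeric(0); other <- numeric(0)
  for (k in idx) {
    mk <- if (task == "m") va$mask_m[[k]] else va$mask_p[[k]]
    ok <- if (task == "m") va$mask_p[[k]] else va$mask_m[[k]]
    cam <- grad_cam(fit$model, va$x[, , , k], task = task)
    own <- c(own, localization_score(cam, mk))
    if (!is.null(ok)) other <- c(other, localization_score(cam, ok))
  }
  list(n = length(own), own = stats::median(own),
       other = stats::median(other))
}
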