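#' Desk-scale model-versus-interpolation comparison experiment
#'
#' Runs the full pipeline end to end at CPU scale: a seeded phantom cohort is
#' split at the subject level into a train+validation pool and a held-out
#' test set, a reduced network is trained on the pooled maps, and the model
#' is compared against nearest-neighbor and cubic-spline interpolation on
#' every held-out map (MSE/RMSE/PSNR/SSIM, pairwise Mann-Whitney U tests).
#'
#' Defaults: 60 subjects (42 train+validation / 18 test), two slices per
#' subject, sampled tumor values, the `"reduced"` network preset, and at most
#' 20 epochs of Adam at learning rate 3e-3 with 0.95 per-epoch decay, batch
#' size 8, and stochastic weight averaging over the final epochs — a
#' short-budget schedule chosen for this small regime (the full-scale
#' protocol uses 1e-5 over 100 epochs at batch 24). The model is evaluated
#' with its geometric self-ensemble.
#'
#' @param seed Root seed for every random stream.
#' @param n_subjects Cohort size.
#' @param n_slices Slices per subject.
#' @param test_fraction Fraction of subjects held out for testing.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param config An [srnet_config()]; default the reduced preset.
#' @param verbose Print progress.
#' @return A list with `records`, `report`, `model`, and the train/test
#'   subject counts.
#' @export
run_comparison_experiment <- function(seed = 1L, n_subjects = 60L,
                                      n_slices = 2L, test_fraction = 0.3,
                                      epochs = 20L, learning_rate = 3e-3,
                                      config = NULL, verbose = FALSE) {
  if (is.null(config))
    config <- srnet_config(preset = "reduced", seed = derive_seed(seed, "model"))
  cohort <- generate_cohort(n_subjects, seed = derive_seed(seed, "cohort"),
                            grade_mix = 0.5, n_slices = n_slices)
  n_test <- round(test_fraction * n_subjects)
  test_idx <- with_seed(derive_seed(seed, "testsplit"),
                        sample.int(n_subjects, n_test))
  table <- concentration_table()
  trainval <- build_dataset(cohort[-test_idx], table, mode = "sampled",
                            seed = derive_seed(seed, "conc"))
  test <- build_dataset(cohort[test_idx], table, mode = "sampled",
                        seed = derive_seed(seed, "conc"))
  control <- train_control(batch_size = 8L, learning_rate = learning_rate,
                           epochs = epochs, val_fraction = 0.30,
                           augment = TRUE, seed = derive_seed(seed, "train"),
                           lr_decay = 0.95, val_every = 5L,
                           swa_from = max(1L, epochs - 7L), verbose = verbose)
  model <- srnet_fit(trainval, config, control)
  records <- evaluate_methods(test, methods = c("model", "nearest", "spline"),
                              model = model, self_ensemble = TRUE)
  report <- summarize_evaluation(records)
  list(records = records, report = report, model = model,
       n_train_subjects = n_subjects - n_test, n_test_subjects = n_test,
       n_test_maps = length(test))
}

#' Single-batch memorization check
#'
#' Trains the reduced network on one fixed batch of phantom examples (train
#' and validation are the same batch, no augmentation) until the training
#' loss falls below `target` or the step budget runs out — a capacity and
#' optimizer sanity check: a functioning model memorizes a single batch.
#'
#' @param seed Root seed.
#' @param n_examples Batch size (default 8).
#' @param max_steps Maximum optimization steps.
#' @param target Training-loss target.
#' @param learning_rate Adam learning rate.
#' @return A list with the trained `model` and `final_loss`.
#' @export
run_overfit_check <- function(seed = 1L, n_examples = 8L, max_steps = 340L,
                              target = 1e-4, learning_rate = 3e-3) {
  cohort <- generate_cohort(2L, seed = derive_seed(seed, "cohort"),
                            n_slices = 1L)
  ds <- build_dataset(cohort, mode = "deterministic")
  idx <- seq_len(min(n_examples, length(ds)))
  batch <- structure(list(examples = ds$examples[idx],
                          manifest = ds$manifest[idx, , drop = FALSE]),
                     class = "sr_dataset")
  model <- build_srnet(srnet_config(preset = "reduced",
                                    seed = derive_seed(seed, "model")))
  control <- train_control(batch_size = n_examples,
                           learning_rate = learning_rate, epochs = max_steps,
                           augment = FALSE, seed = derive_seed(seed, "train"),
                           lr_decay = 0.995, val_every = 50L,
                           stop_train_loss = target)
  model <- fit_srnet_on(model, batch, batch, control)
  list(model = model,
       final_loss = model$history$train_loss[nrow(model$history)])
}
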