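#' Run the full augmentation study end to end
#'
#' The three-stage workflow on simulated data: (1) simulate the multi-cycle
#' fermentation study and impute failed channels; (2) train the convolutional
#' VAE on all original experiments (min-max normalized) and sample a pool of
#' synthetic experiments; (3) evaluate the ethanol soft sensor under the
#' Original / Augmented10 / Augmented100 regimes over repeated
#' leave-one-experiment-out splits and assemble the statistical comparison.
#' Additionally scores the anomalous-sensor case: every regime is trained
#' with the offset-capacitance experiment held out and tested on it.
#'
#' All randomness derives hierarchically from `seed`.
#'
#' @param seed Integer study seed.
#' @param params A [ferm_sim_params()].
#' @param n_experiments Number of simulated cycles.
#' @param fault_plan List of [fault_spec()]s (default: one missing-redox and
#'   one offset-capacitance experiment).
#' @param n_synthetic_pool Size of the generated synthetic pool.
#' @param vae A [vae_config()] (its seed is re-derived from `seed`).
#' @param fnn A [fnn_config()] template.
#' @param n_iter Repeated-split iterations per regime.
#' @param k_impute Neighbours for KNN imputation.
#' @return List with `study`, `imputed`, `normalizer`, `vae`, `synthetic`,
#'   `dists` (per-regime [repeated_evaluation()] results), `comparison`
#'   (the [comparison_table()]) and `case_anomalous` (per-regime `r2`/`rmse`
#'   on the offset-capacitance experiment).
#' @export
run_augmentation_study <- function(seed = 1L,
                                   params = ferm_sim_params(),
                                   n_experiments = 11L,
                                   fault_plan = default_fault_plan(),
                                   n_synthetic_pool = 100L,
                                   vae = vae_config(),
                                   fnn = fnn_config(),
                                   n_iter = 100L,
                                   k_impute = 5L) {
  study <- simulate_study(params, n_experiments, fault_plan,
                          seed = derive_seed(seed, "simulate"))
  imputed <- impute_missing_channels(study, k = k_impute)

  normalizer <- fit_normalizer(imputed, scheme = "minmax")
  vae$seed <- derive_seed(seed, "vae")
  model <- train_vae(to_vae_tensor(apply_normalizer(imputed, normalizer)),
                     vae)
  synthetic <- generate_synthetic(model, n_synthetic_pool, normalizer,
                                  seed = derive_seed(seed, "generate"),
                                  time = study[[1]]$time)

  eval_seed <- derive_seed(seed, "evaluate")
  dists <- list(
    Original = repeated_evaluation(imputed, NULL, regime_spec("Original"),
                                   n_iter, eval_seed, fnn),
    Augmented10 = repeated_evaluation(imputed, synthetic,
                                      regime_spec("Augmented10"),
                                      n_iter, eval_seed, fnn),
    Augmented100 = repeated_evaluation(imputed, synthetic,
                                       regime_spec("Augmented100"),
                                       n_iter, eval_seed, fnn)
  )
  comparison <- comparison_table(dists$Original, dists$Augmented10,
                                 dists$Augmented100)

  case_anomalous <- anomalous_case_scores(imputed, synthetic, fnn,
                                          seed = derive_seed(seed, "case"))

  list(study = study, imputed = imputed, normalizer = normalizer,
       vae = model, synthetic = synthetic, dists = dists,
       comparison = comparison, case_anomalous = case_anomalous)
}

## Locate the offset-channel experiment injected by the fault plan.
find_offset_experiment <- function(collection) {
  hits <- which(vapply(collection$experiments, function(e) {
    any(startsWith(e$faults, "offset_channel:"))
  }, logical(1)))
  if (!length(hits)) stop("no offset-channel experiment in the collection")
  hits[1]
}

## Train each regime with the anomalous experiment held out and score the
## prediction on it (normalized target space).
anomalous_case_scores <- function(imputed, synthetic, fnn, seed = 1L) {
  idx <- find_offset_experiment(imputed)
  train_orig <- imputed[setdiff(seq_len(length(imputed)), idx)]
  test_series <- imputed[[idx]]
  normalizer <- fit_normalizer(train_orig, scheme = "minmax")

  score <- function(regime_name) {
    regime <- regime_spec(regime_name)
    training <- compose_regime(regime, train_orig, synthetic,
                               seed = derive_seed(seed, "case-compose"))
    arrays <- to_regression_arrays(apply_normalizer(training, normalizer))
    fnn$seed <- derive_seed(seed, paste0("case-", regime_name))
    model <- train_soft_sensor(arrays$features, arrays$targets, fnn)
    res <- prediction_overlay(model, test_series, normalizer)
    data.frame(regime = regime_name, r2 = res$r2, rmse = res$rmse)
  }
  out <- do.call(rbind, lapply(c("Original", "Augmented10", "Augmented100"),
                               score))
  out$test_id <- test_series$id
  out
}
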