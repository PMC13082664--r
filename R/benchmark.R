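# Scaled-down end-to-end benchmark on synthetic data: the full pipeline
# (simulate -> label -> windows -> train -> evaluate) at a size that runs on
# one CPU in a few minutes. The full-scale protocol (80 epochs, tuned widths
# and learning rates, real recordings) is out of desk reach; these profiles
# shrink widths and epochs while keeping the architectures and the protocol
# (subject-wise split, balanced training pool, untouched validation/test).

desk_profile <- function(type) {
  switch(type,
         cnn = list(
           build = function(seed) build_cnn(cnn_config(n_filters = 16L, dense_units = 32L), seed),
           train = function(seed) train_config(epochs = 10L, learning_rate = 1e-3,
                                               seed = seed, max_val_samples = 4096L)),
         hybrid = list(
           build = function(seed) build_hybrid(hybrid_config(24L, 24L, 32L, 32L), seed),
           train = function(seed) train_config(epochs = 3L, seed = seed,
                                               max_val_samples = 4096L)),
         transformer = list(
           build = function(seed) build_transformer(
             transformer_config(d_model = 32L, n_heads = 1L, n_layers = 2L, d_ff = 64L), seed),
           train = function(seed) train_config(epochs = 3L, learning_rate = 1e-4,
                                               batch_size = 128L, seed = seed,
                                               max_val_samples = 4096L)),
         stop("unknown model type: ", type, call. = FALSE))
}

#' Scaled-down end-to-end benchmark on synthetic gait data
#'
#' Simulates 12 subjects x 2 trials x 60 s at 200 Hz, resamples to 100 Hz,
#' splits subject-wise (8 train / 4 test subjects, one validation session
#' per training subject), standardizes with training statistics, builds
#' w = 20 one-step-ahead windows, balances the training pool, then trains
#' and evaluates each requested architecture at reduced width (<= 10
#' epochs). Validation loss is monitored on a fixed seeded subsample of at
#' most 4096 windows; test evaluation always uses every test window.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param models which architectures to run.
#' @param verbose print progress lines.
#' @return list with `dataset` (sizes and subject allocation) and one
#'   element per model: the [eval_report()], the loss `history` and the
#'   elapsed training time in seconds.
#' @export
run_synthetic_benchmark <- function(seed = 1L,
                                    models = c("cnn", "hybrid", "transformer"),
                                    verbose = TRUE) {
  models <- match.arg(models, several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  params <- gait_sim_params(n_subjects = 12L, trials_per_subject = 2L,
                            trial_duration = 60, seed = child_seed(seed, "bench_sim"))
  say("[benchmark] simulating %d trials ...", params$n_subjects * params$trials_per_subject)
  trials <- generate_dataset(params)
  bundle <- build_dataset(trials, fs_out = 100, w = 20L, offset = 1L,
                          n_test_subjects = 4L,
                          split_seed = child_seed(seed, "bench_split"),
                          balance_seed = child_seed(seed, "bench_balance"))
  say("[benchmark] windows: train %d (balanced), val %d, test %d",
      length(bundle$train$targets), length(bundle$val$targets),
      length(bundle$test$targets))
  out <- list(dataset = list(n_train = length(bundle$train$targets),
                             n_val = length(bundle$val$targets),
                             n_test = length(bundle$test$targets),
                             train_subjects = bundle$spec$train_subjects,
                             test_subjects = bundle$spec$test_subjects))
  for (type in models) {
    prof <- desk_profile(type)
    t0 <- Sys.time()
    fit <- train_model(prof$build(child_seed(seed, paste0("init_", type))),
                       bundle$train, bundle$val,
                       prof$train(child_seed(seed, paste0("train_", type))))
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    rep <- evaluate_model(fit$model, bundle$test)
    say("[benchmark] %s: %.0f s, test ACC %.2f%%, macro F1 %.2f%%, val loss %.3f -> %.3f",
        type, elapsed, rep$acc, rep$macro_f1,
        fit$history$val_loss[1L], utils::tail(fit$history$val_loss, 1L))
    out[[type]] <- list(report = rep, history = fit$history, train_seconds = elapsed)
  }
  out
}
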