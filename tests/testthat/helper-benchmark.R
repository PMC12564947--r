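# Shared end-to-end fixture: the seeded 64x64 transplanted-anomaly phantom
# benchmark (200 training frames, 40 test frames, 30 epochs per variant).
# Trained once per test run and reused by the trainer, segmenter, and
# acceptance tests.
.bench_env <- new.env(parent = emptyenv())

get_benchmark <- function(seed = 1L) {
  key <- paste0("bench_", seed)
  if (is.null(.bench_env[[key]])) {
    .bench_env[[key]] <- run_phantom_benchmark(seed = seed)
  }
  .bench_env[[key]]
}

# A small, fast training setup for unit-level trainer tests: 16x16 phantom,
# narrow model.
tiny_train_setup <- function(n_frames = 12L, use_pe = TRUE, seed = 5L) {
  spec <- phantom_spec(height = 16L, width = 16L, n_blobs = 2L, seed = seed)
  ds <- generate_phantom_dataset(spec, n_train = n_frames, n_test_clean = 0L,
                                 n_test_anom = 0L, seed = seed)
  x <- boluseg:::stack_inputs(encode_frames(ds$frames, use_pe = use_pe))
  set.seed(seed)
  model <- build_autoencoder(model_config(
    in_channels = if (use_pe) 5L else 3L, encoder_widths = c(2L, 3L, 4L)))
  list(spec = spec, ds = ds, x = x, model = model)
}
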