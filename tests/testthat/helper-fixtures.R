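# Shared fixtures, generated programmatically.

# small noise-free phantom dataset on disk, built once per test session
phantom_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(n_train = 6, n_val = 2, n_test = 2, image_size = 64, noise_sd = 0,
           seed = 1) {
    key <- paste(n_train, n_val, n_test, image_size, noise_sd, seed, sep = "_")
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("cesynth_fix_", key))
      p <- phantom_params(image_size = image_size, noise_sd = noise_sd, seed = seed)
      suppressWarnings(make_dataset(n_train, n_val, n_test, p, dir))
      cache[[key]] <- list(dir = dir, params = p,
                           manifest = load_manifest(file.path(dir, "manifest.csv")))
    }
    cache[[key]]
  }
})

expect_same_matrix <- function(a, b, tol = 1e-12) {
  expect_true(max(abs(a - b)) <= tol)
}
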