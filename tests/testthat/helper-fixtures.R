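# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Separable synthetic benchmark: 40 trials/class -> 120 GASF images,
# stratified into 90 train / 30 test. The generator defaults ARE the
# benchmark conditions; only the sizes and seeds are fixed here.
sep_fixture <- function() {
  if (!is.null(.fixture_cache$parts)) return(.fixture_cache$parts)
  rec <- generate_recording(sim_config(n_trials_per_class = 40, seed = 11))
  eps <- extract_epochs(bandpass(rec))
  eps <- lapply(eps, baseline_correct)
  ch <- select_channel(eps)
  ds <- gasf_dataset(lapply(eps, encode_epoch, channel = ch), "train")
  parts <- split_dataset(ds, n_test = 30, seed = 5)
  parts$channel <- ch
  .fixture_cache$parts <- parts
  parts
}

# Small, fast toy GASF datasets built directly from class-distinct series
# (no signal pipeline): RHT an early bump, LHT a late broad bump, FT a
# narrow early dip. Used where only image-level mechanics are under test.
toy_images <- function(n_per_class, seed = 1, noise = 0.05) {
  t28 <- seq(0, 1, length.out = 28)
  shapes <- list(
    RHT = exp(-((t28 - 0.25) / 0.12)^2),
    LHT = exp(-((t28 - 0.65) / 0.2)^2),
    FT  = -exp(-((t28 - 0.2) / 0.07)^2)
  )
  withr::with_seed(seed, {
    images <- unlist(lapply(names(shapes), function(l) {
      lapply(seq_len(n_per_class), function(i) {
        series <- shapes[[l]] + rnorm(28, sd = noise)
        to_image(gasf(rescale_unit(series)), l)
      })
    }), recursive = FALSE)
  })
  gasf_dataset(images, "train")
}

# Minimal hand-built recording for filter/epoch unit tests.
make_recording <- function(hbo, hbr = hbo, fs = 10, onsets = numeric(0),
                           labels = character(0), durations = 10) {
  structure(list(
    hbo = hbo, hbr = hbr, sampling_rate = fs,
    channel_side = rep(c("left", "right"), each = nrow(hbo) / 2),
    events = tibble::tibble(onset = onsets,
                            duration = rep(durations, length.out = length(onsets)),
                            label = task_label(labels))
  ), class = "nirs_recording")
}

# Nearest-centroid oracle classifier in pixel space, fit on real images.
nearest_centroid_fit <- function(ds) {
  labs <- dataset_labels(ds)
  arr <- vapply(ds$images, function(im) as.vector(im$pixels), numeric(784))
  centroids <- vapply(levels(labs), function(l)
    rowMeans(arr[, labs == l, drop = FALSE]), numeric(784))
  function(images) {
    a <- vapply(images, function(im) as.vector(im$pixels), numeric(784))
    lab_idx <- apply(a, 2, function(v) which.min(colSums((centroids - v)^2)))
    task_label(levels(labs)[lab_idx])
  }
}
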