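# Analytic magnitude of the digital Butterworth design at frequency f (Hz);
# the zero-phase pass squares it.
butter_mag2 <- function(f, fs = 10, low = 0.01, high = 0.1, order = 3) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  w <- 2 * pi * f / fs
  e <- exp(-1i * w * (seq_along(bf$b) - 1))
  abs(sum(bf$b * e) / sum(bf$a * e))^2
}

# Least-squares amplitude of a sinusoid at f in the central half of y.
fitted_amp <- function(y, f, fs = 10) {
  t <- (seq_along(y) - 1) / fs
  mid <- seq(round(length(y) * 0.3), round(length(y) * 0.7))
  X <- cbind(sin(2 * pi * f * t[mid]), cos(2 * pi * f * t[mid]))
  co <- stats::coef(stats::lm(y[mid] ~ X - 1))
  list(amp = sqrt(sum(co^2)), phase = atan2(co[2], co[1]))
}

one_channel_rec <- function(x, fs = 10) {
  make_recording(rbind(x, x), fs = fs)
}

test_that("zero-phase band-pass rejects DC and stopband tones and passes the band without lag", {
  t <- (0:2999) / 10
  # DC: constant 5 -> essentially zero
  rec <- one_channel_rec(rep(5, 3000))
  out <- bandpass(rec)
  expect_lt(max(abs(out$hbo)), 5 * 1e-6)

  # passband 0.05 Hz: amplitude in [0.9, 1], zero phase, zero lag
  y <- bandpass(one_channel_rec(sin(2 * pi * 0.05 * t)))$hbo[1, ]
  fit <- fitted_amp(y, 0.05)
  expect_gte(fit$amp, 0.9)
  expect_lte(fit$amp, 1 + 1e-6)
  expect_lt(abs(fit$phase), 0.01)
  # analytic oracle: measured amplitude matches the squared Butterworth gain
  expect_equal(fit$amp, butter_mag2(0.05), tolerance = 1e-2)
  cc <- stats::ccf(y[500:2500], sin(2 * pi * 0.05 * t)[500:2500],
                   lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # cardiac 1.2 Hz: forward-backward squares the attenuation
  y2 <- bandpass(one_channel_rec(sin(2 * pi * 1.2 * t)))$hbo[1, ]
  a2 <- fitted_amp(y2, 1.2)$amp
  expect_lt(a2, 0.001)
  expect_equal(a2, butter_mag2(1.2), tolerance = 1e-4)
  # >= 40 dB at 1.2 Hz and at near-DC for the squared response
  expect_gt(-20 * log10(a2), 40)
  expect_gt(-10 * log10(butter_mag2(0.001)^2), 40)

  expect_error(bandpass(rec, low = 0.1, high = 6), "Nyquist")
  expect_error(bandpass(rec, low = 0.2, high = 0.1), "Nyquist|low")
  expect_error(bandpass(one_channel_rec(rep(1, 10))), "too short")
})

test_that("epoch extraction yields exact half-open windows and skips truncated events", {
  x <- matrix(rnorm(2 * 1200), 2, 1200)  # 120 s at 10 Hz
  rec <- make_recording(x, fs = 10, onsets = c(1, 40, 80),
                        labels = c("RHT", "LHT", "FT"))
  expect_message(eps <- extract_epochs(rec), "skipping event 1")
  expect_length(eps, 2)
  expect_equal(ncol(eps[[1]]$hbo), 300)  # (28 - (-2)) * 10
  expect_identical(as.character(vapply(eps, function(e) as.character(e$label),
                                       character(1))),
                   c("LHT", "FT"))
  # sample values line up with the source recording
  i0 <- (40 - 2) * 10 + 1
  expect_identical(eps[[1]]$hbo[1, ], x[1, i0:(i0 + 299)])

  rec0 <- make_recording(x, fs = 10)
  expect_warning(e0 <- extract_epochs(rec0), "no events")
  expect_length(e0, 0)
  expect_error(extract_epochs(rec, window = c(1, 28)), "straddle")
})

test_that("baseline correction subtracts the reference mean and is idempotent", {
  x <- matrix(3.2, 2, 1200)
  rec <- make_recording(x, fs = 10, onsets = 40, labels = "RHT")
  ep <- extract_epochs(rec)[[1]]
  bc <- baseline_correct(ep)
  expect_equal(max(abs(bc$hbo)), 0)

  # ramp oracle: epoch equal to time t; reference samples are
  # t = -1.0, -0.9, ..., -0.1, so their mean is -0.55
  tt <- (0:1199) / 10
  rec_t <- make_recording(rbind(tt, tt), fs = 10, onsets = 40, labels = "RHT")
  ep_t <- extract_epochs(rec_t)[[1]]
  bc_t <- baseline_correct(ep_t)
  ref_mean <- mean(40 + seq(-1, -0.1, by = 0.1))
  expect_equal(unname(bc_t$hbo[1, 1]), (40 - 2) - ref_mean, tolerance = 1e-9)
  # mean over the reference interval is zero afterwards
  idx <- nirscgan:::epoch_window_idx(bc_t, -1, 0)
  expect_lt(abs(mean(bc_t$hbo[1, idx])), 1e-9)
  expect_equal(baseline_correct(bc_t)$hbo, bc_t$hbo, tolerance = 1e-12)
  expect_error(baseline_correct(ep, ref_interval = c(-0.01, -0.005)),
               "no samples")
})

test_that("window-mean features have the declared count, ordering and values", {
  x <- matrix(0, 20, 1200)
  x[1, ] <- 2.0  # channel 1 constant
  rec <- make_recording(x, hbr = matrix(0, 20, 1200), fs = 10,
                        onsets = c(40, 80), labels = c("RHT", "FT"))
  eps <- extract_epochs(rec)
  fm <- window_mean_features(eps)
  expect_s3_class(fm, "tbl_df")
  expect_equal(ncol(fm) - 2, 120)  # 20 channels x 2 chromophores x 3 windows
  expect_equal(nrow(fm), 2)
  expect_equal(fm$CH01_hbo_w0_5[1], 2.0)
  expect_equal(fm$CH01_hbr_w0_5[1], 0)
  expect_true(all(as.matrix(fm[2:1, -(1:2)])[, -(1:3)] == 0))
  # channel-major, chromophore, window ordering
  expect_identical(names(fm)[3:9],
                   c("CH01_hbo_w0_5", "CH01_hbo_w5_10", "CH01_hbo_w10_15",
                     "CH01_hbr_w0_5", "CH01_hbr_w5_10", "CH01_hbr_w10_15",
                     "CH02_hbo_w0_5"))

  # property: feature count = channels x 2 x |windows| for other shapes
  for (nc in c(4, 8)) {
    recn <- make_recording(matrix(rnorm(nc * 1200), nc, 1200), fs = 10,
                           onsets = 40, labels = "LHT")
    for (nw in 1:3) {
      wins <- lapply(seq_len(nw), function(i) c(5 * (i - 1), 5 * i))
      fmn <- window_mean_features(extract_epochs(recn), wins)
      expect_equal(ncol(fmn) - 2, nc * 2 * nw)
    }
  }
})

test_that("standardization uses population sd, fits only on training rows, and round-trips", {
  d <- tibble::tibble(epoch = 1:3, label = task_label(c(0, 1, 2)),
                      f1 = c(1, 2, 3), f2 = c(10, 10, 40))
  st <- standardize(d)
  expect_equal(st$values$f1, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(mean(st$values$f2), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(st$values$f2^2)), 1, tolerance = 1e-9)

  # idempotence: refitting already-standardized data changes nothing
  st2 <- standardize(st$values)
  expect_equal(as.matrix(st2$values[, 3:4]), as.matrix(st$values[, 3:4]),
               tolerance = 1e-9)

  # applying train params to a row equal to the train mean gives zeros
  test_row <- tibble::tibble(epoch = 9L, label = task_label("RHT"),
                             f1 = mean(d$f1), f2 = mean(d$f2))
  ap <- standardize(test_row, st$params)
  expect_equal(unlist(ap$values[, 3:4]), c(f1 = 0, f2 = 0))

  # round trip
  back <- destandardize(st$values, st$params)
  expect_equal(as.matrix(back[, 3:4]), as.matrix(d[, 3:4]), tolerance = 1e-9)

  dd <- tibble::tibble(f1 = c(1, 1, 1), f2 = c(1, 2, 3))
  expect_warning(stc <- standardize(dd), "constant")
  expect_true(all(is.finite(as.matrix(stc$values))))
})

test_that("linear-kernel kernel PCA matches the classical PCA oracle", {
  withr::with_seed(42, {
    for (i in 1:100) {
      X <- matrix(rnorm(60), 10, 6)
      kp <- kernel_pca_reduce(X, kernel = "linear", n_comp = 4)
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
      S <- as.matrix(kp$scores)
      for (j in 1:4) {
        # equal up to sign
        err <- min(max(abs(S[, j] - pc$x[, j])), max(abs(S[, j] + pc$x[, j])))
        expect_lt(err, 1e-6)
      }
    }
  })
})

test_that("kernel PCA enforces the rank bound and separates RBF blobs", {
  X5 <- matrix(rnorm(30), 5, 6)
  kp <- kernel_pca_reduce(X5, kernel = "linear")
  expect_lte(ncol(kp$scores), 4)
  expect_error(kernel_pca_reduce(X5, n_comp = 5), "at most")
  expect_error(kernel_pca_reduce(X5[1, , drop = FALSE]), "at least 2 rows")

  withr::with_seed(3, {
    A <- matrix(rnorm(40, mean = 0, sd = 0.3), 20, 2)
    B <- matrix(rnorm(40, mean = 5, sd = 0.3), 20, 2)
  })
  kp2 <- kernel_pca_reduce(rbind(A, B), kernel = "rbf", gamma = 0.5, n_comp = 2)
  s1 <- kp2$scores$kpc1
  # brute-force threshold search: some cut separates the blobs perfectly
  cuts <- sort(s1)
  best <- max(vapply(cuts, function(cc)
    max(mean((s1 <= cc) == c(rep(TRUE, 20), rep(FALSE, 20))),
        mean((s1 > cc) == c(rep(TRUE, 20), rep(FALSE, 20)))), numeric(1)))
  expect_equal(best, 1)

  # projecting training rows through the fitted model reproduces the scores
  pr <- kernel_pca_reduce(rbind(A, B), model = kp2$model)
  expect_equal(as.matrix(pr$scores), as.matrix(kp2$scores), tolerance = 1e-8)
})

test_that("channel selection maximizes the class F statistic with a deterministic tie-break", {
  fs <- 10
  make_eps <- function(signal_channel, n_per_class = 6, nc = 10, noise = 0.05) {
    shapes <- list(RHT = 1, LHT = -1, FT = 0.001)
    unlist(lapply(names(shapes), function(l) {
      lapply(seq_len(n_per_class), function(i) {
        hbo <- matrix(rnorm(nc * 300, sd = noise), nc, 300)
        hbo[signal_channel, 21:170] <- hbo[signal_channel, 21:170] + shapes[[l]]
        structure(list(hbo = hbo, hbr = hbo * 0, t0_offset = -2,
                       label = task_label(l), sampling_rate = fs),
                  class = "nirs_epoch")
      })
    }), recursive = FALSE)
  }
  eps <- withr::with_seed(8, make_eps(7))
  expect_equal(select_channel(eps), 7)
  # brute-force oracle over all channels
  scores <- vapply(1:10, function(ch) {
    labs <- task_label(vapply(eps, function(e) as.character(e$label),
                              character(1)))
    sum(vapply(list(c(0, 5), c(5, 10), c(10, 15)), function(w) {
      idx <- nirscgan:::epoch_window_idx(eps[[1]], w[1], w[2])
      y <- vapply(eps, function(e) mean(e$hbo[ch, idx]), numeric(1))
      nirscgan:::f_statistic(y, labs)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(which.max(scores), 7L)

  # permutation invariance of the selection
  expect_equal(select_channel(rev(eps)), 7)

  # exactly tied channels (identical columns) -> lowest index
  tied <- lapply(eps, function(e) { e$hbo <- e$hbo[rep(7, 10), ]; e })
  expect_equal(select_channel(tied), 1)

  one_class <- Filter(function(e) e$label == "RHT", eps)
  expect_error(select_channel(one_class), "2 classes")
})
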