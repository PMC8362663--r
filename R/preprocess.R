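# Signal preprocessing: zero-phase Butterworth band-pass, trial epoching,
# baseline correction, window-mean features, standardization, kernel PCA,
# and F-statistic channel selection.

# Steady-state initial conditions for an IIR filter (step-input matching),
# so a constant input produces its steady-state output from sample one.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  m <- n - 1
  A <- matrix(0, m, m)
  A[1, ] <- -a[2:n]
  if (m > 1) A[cbind(2:m, 1:(m - 1))] <- 1
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(m) - t(A), B)
}

# Zero-phase (forward-backward) IIR filtering with odd-reflection padding
# and steady-state initial conditions; mirrors the standard filtfilt scheme.
zerophase_filter <- function(x, b, a) {
  padlen <- 3 * (max(length(a), length(b)) - 1)
  n <- length(x)
  if (n <= padlen) {
    stop_invalid("signal too short for zero-phase filtering: length ", n,
                 " <= required padding ", padlen)
  }
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- .lfilter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- .lfilter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase Butterworth band-pass filter for a recording
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass of the
#' given order to every channel of both chromophores. The default
#' 0.01-0.1 Hz passband keeps the slow task-evoked hemodynamic response
#' while rejecting the DC offset, drift, Mayer waves (~0.1 Hz),
#' respiration (0.2-0.5 Hz) and cardiac pulsation (1-1.5 Hz). The
#' forward-backward pass squares the magnitude response and cancels phase
#' lag, so epoch timing is preserved.
#'
#' @param recording a `nirs_recording`.
#' @param low,high band edges in Hz; `0 < low < high < sampling_rate / 2`.
#' @param order Butterworth design order (the effective attenuation is that
#'   of a squared response of this order).
#' @return a filtered `nirs_recording` of identical shape.
#' @export
bandpass <- function(recording, low = 0.01, high = 0.1, order = 3) {
  stopifnot(inherits(recording, "nirs_recording"))
  nyq <- recording$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop_invalid("band [", low, ", ", high,
                 "] Hz must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- recording
  for (f in c("hbo", "hbr")) {
    out[[f]] <- t(apply(recording[[f]], 1, zerophase_filter, b = bf$b, a = bf$a))
    dimnames(out[[f]]) <- dimnames(recording[[f]])
  }
  out
}

#' Cut a recording into trial-locked epochs
#'
#' One epoch per event whose full window lies inside the recording; events
#' with insufficient margin are skipped with a message. Windows are
#' half-open `[start, end)` in seconds relative to the event onset, so an
#' epoch holds exactly `(end - start) * sampling_rate` samples.
#'
#' @param recording a `nirs_recording` (typically after [bandpass()]).
#' @param window numeric length-2, seconds relative to onset; the default
#'   `c(-2, 28)` spans 2 s of pre-onset baseline and 28 s of task window.
#' @return list of `nirs_epoch` objects (possibly empty, with a warning).
#' @export
extract_epochs <- function(recording, window = c(-2, 28)) {
  stopifnot(inherits(recording, "nirs_recording"))
  if (!(window[1] < 0 && window[2] > 0)) {
    stop_invalid("window must straddle the onset (start < 0 < end)")
  }
  fs <- recording$sampling_rate
  ns <- ncol(recording$hbo)
  n_want <- as.integer(round((window[2] - window[1]) * fs))
  ev <- recording$events
  if (nrow(ev) == 0) {
    warning("recording has no events; returning an empty epoch list")
    return(list())
  }
  epochs <- list()
  for (i in seq_len(nrow(ev))) {
    i0 <- as.integer(floor((ev$onset[i] + window[1]) * fs + 1e-9)) + 1L
    i1 <- i0 + n_want - 1L
    if (i0 < 1 || i1 > ns) {
      message("skipping event ", i, " (", as.character(ev$label[i]),
              " at ", ev$onset[i], " s): window outside recording")
      next
    }
    epochs[[length(epochs) + 1]] <- structure(list(
      hbo = recording$hbo[, i0:i1, drop = FALSE],
      hbr = recording$hbr[, i0:i1, drop = FALSE],
      t0_offset = window[1],
      label = ev$label[i],
      sampling_rate = fs,
      onset = ev$onset[i]
    ), class = "nirs_epoch")
  }
  epochs
}

# Sample indices of an epoch whose times fall in [a, b), half-open.
epoch_window_idx <- function(epoch, a, b) {
  t <- epoch$t0_offset + (seq_len(ncol(epoch$hbo)) - 1) / epoch$sampling_rate
  which(t >= a - 1e-9 & t < b - 1e-9)
}

#' Baseline-correct an epoch
#'
#' Subtracts, per channel and chromophore, the mean over the pre-onset
#' reference interval (default -1-0 s). After correction the mean of the
#' reference interval is zero to numerical precision.
#'
#' @param epoch a `nirs_epoch`.
#' @param ref_interval length-2 seconds relative to onset, inside the epoch.
#' @return the corrected `nirs_epoch`.
#' @export
baseline_correct <- function(epoch, ref_interval = c(-1, 0)) {
  stopifnot(inherits(epoch, "nirs_epoch"))
  idx <- epoch_window_idx(epoch, ref_interval[1], ref_interval[2])
  if (length(idx) == 0) {
    stop_invalid("reference interval [", ref_interval[1], ", ",
                 ref_interval[2], ") contains no samples")
  }
  out <- epoch
  out$hbo <- epoch$hbo - rowMeans(epoch$hbo[, idx, drop = FALSE])
  out$hbr <- epoch$hbr - rowMeans(epoch$hbr[, idx, drop = FALSE])
  out
}

#' Window-mean feature matrix from epochs
#'
#' For every epoch, channel, chromophore and time window, the arithmetic
#' mean of the samples in `[start, end)` becomes one feature. Feature order
#' is channel-major, then chromophore (HbO before HbR), then window, giving
#' `channels x 2 x |windows|` features -- 120 for 20 channels with the
#' default three windows (0-5, 5-10, 10-15 s).
#'
#' @param epochs list of (baseline-corrected) `nirs_epoch` objects.
#' @param windows list of length-2 numeric windows in seconds.
#' @return tibble with `epoch` (row index), `label`, and one numeric column
#'   per feature.
#' @export
window_mean_features <- function(epochs,
                                 windows = list(c(0, 5), c(5, 10), c(10, 15))) {
  if (length(epochs) == 0) stop_invalid("no epochs supplied")
  e1 <- epochs[[1]]
  idx_sets <- lapply(windows, function(w) {
    idx <- epoch_window_idx(e1, w[1], w[2])
    if (length(idx) == 0) {
      stop_invalid("window [", w[1], ", ", w[2], ") contains no samples")
    }
    idx
  })
  chans <- rownames(e1$hbo) %||% sprintf("CH%02d", seq_len(nrow(e1$hbo)))
  wtag <- vapply(windows, function(w)
    paste0("w", gsub("-", "m", format(w[1])), "_", gsub("-", "m", format(w[2]))),
    character(1))
  feature_names <- as.vector(t(outer(
    chans, as.vector(t(outer(c("hbo", "hbr"), wtag, paste, sep = "_"))),
    paste, sep = "_")))
  rows <- purrr::map(epochs, function(ep) {
    vals <- lapply(seq_along(chans), function(ch) {
      unlist(lapply(c("hbo", "hbr"), function(chrom) {
        vapply(idx_sets, function(idx)
          mean(ep[[chrom]][ch, idx]), numeric(1))
      }))
    })
    unlist(vals)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- feature_names
  dplyr::bind_cols(
    tibble::tibble(epoch = seq_along(epochs),
                   label = task_label(vapply(epochs, function(e)
                     as.character(e$label), character(1)))),
    tibble::as_tibble(mat)
  )
}

# Numeric feature columns of a feature tibble (drops epoch/label metadata).
feature_cols <- function(x) {
  keep <- vapply(x, is.numeric, logical(1))
  keep[names(x) %in% c("epoch", "label")] <- FALSE
  names(x)[keep]
}

#' Standardize features (fit or apply)
#'
#' With `params = NULL`, fits per-feature mean and population (divide-by-n)
#' standard deviation on the given rows and standardizes them; otherwise
#' applies the previously fitted parameters unchanged, so test rows never
#' leak into the fit. Constant columns have their sd floored at 1e-8 with a
#' warning.
#'
#' @param data feature tibble from [window_mean_features()] (metadata
#'   columns `epoch`/`label` are passed through).
#' @param params a `standardization_params` from a previous fit, or NULL.
#' @return list with `values` (standardized tibble) and `params`.
#' @export
standardize <- function(data, params = NULL) {
  cols <- feature_cols(data)
  X <- as.matrix(data[cols])
  if (is.null(params)) {
    mu <- colMeans(X)
    sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))
    if (any(sdev < 1e-8)) {
      warning("constant feature column(s) [code SD_FLOOR]: ",
              paste(cols[sdev < 1e-8], collapse = ", "))
      sdev <- pmax(sdev, 1e-8)
    }
    params <- structure(list(mean = mu, sd = sdev, features = cols),
                        class = "standardization_params")
  } else {
    stopifnot(inherits(params, "standardization_params"))
    if (!identical(params$features, cols)) {
      stop_invalid("feature columns do not match the fitted parameters")
    }
  }
  Z <- sweep(sweep(X, 2, params$mean), 2, params$sd, "/")
  out <- data
  out[cols] <- tibble::as_tibble(Z)
  list(values = out, params = params)
}

#' Invert a standardization
#' @param data standardized feature tibble.
#' @param params the `standardization_params` used to standardize.
#' @return tibble on the original scale.
#' @export
destandardize <- function(data, params) {
  cols <- params$features
  X <- sweep(sweep(as.matrix(data[cols]), 2, params$sd, "*"), 2, params$mean, "+")
  out <- data
  out[cols] <- tibble::as_tibble(X)
  out
}

kernel_matrix <- function(A, B, kernel, gamma) {
  if (kernel == "linear") return(A %*% t(B))
  # rbf: exp(-gamma * ||a - b||^2)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

#' Kernel PCA reduction (fit or apply)
#'
#' Centered-kernel eigendecomposition: with `model = NULL` fits on the
#' given rows and returns their scores on the leading components (ordered
#' by descending eigenvalue); otherwise projects new rows with the stored
#' training basis. The sign of each component is fixed so its
#' largest-magnitude training loading is positive; with a linear kernel the
#' scores coincide with classical PCA scores up to that convention.
#'
#' @param data feature tibble (metadata columns passed through) or matrix.
#' @param model a fitted `kpca_model`, or NULL to fit.
#' @param kernel `"rbf"` or `"linear"`.
#' @param gamma RBF width; default `1 / n_features`.
#' @param n_comp number of components; default `min(20, rows - 1)`. An
#'   explicit request above `rows - 1` is an error.
#' @return list with `scores` (tibble with metadata + `kpc1..k`) and `model`.
#' @export
kernel_pca_reduce <- function(data, model = NULL,
                              kernel = c("rbf", "linear"),
                              gamma = NULL, n_comp = NULL) {
  is_df <- is.data.frame(data)
  cols <- if (is_df) feature_cols(data) else colnames(data)
  X <- if (is_df) as.matrix(data[cols]) else as.matrix(data)
  if (is.null(model)) {
    kernel <- match.arg(kernel)
    n <- nrow(X)
    if (n < 2) stop_invalid("need at least 2 rows to fit kernel PCA")
    if (!is.null(n_comp) && n_comp > n - 1) {
      stop_invalid("requested ", n_comp, " components but at most ",
                   n - 1, " are available from ", n, " rows")
    }
    k_req <- n_comp %||% min(20L, n - 1L)
    gamma <- gamma %||% (1 / ncol(X))
    K <- kernel_matrix(X, X, kernel, gamma)
    H <- diag(n) - matrix(1 / n, n, n)
    Kc <- H %*% K %*% H
    eg <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
    keep <- which(eg$values > 1e-10)
    keep <- keep[seq_len(min(length(keep), k_req))]
    lambda <- eg$values[keep]
    V <- eg$vectors[, keep, drop = FALSE]
    # deterministic sign: largest-|entry| coordinate of each eigenvector > 0
    for (j in seq_along(keep)) {
      i_max <- which.max(abs(V[, j]))
      if (V[i_max, j] < 0) V[, j] <- -V[, j]
    }
    scores <- V %*% diag(sqrt(lambda), nrow = length(lambda))
    model <- structure(list(kernel = kernel, gamma = gamma,
                            X_train = X, K_train = K,
                            alpha = V, lambda = lambda,
                            features = cols),
                       class = "kpca_model")
  } else {
    stopifnot(inherits(model, "kpca_model"))
    Xtr <- model$X_train
    n <- nrow(Xtr)
    Kt <- kernel_matrix(X, Xtr, model$kernel, model$gamma)
    one_n <- matrix(1 / n, nrow(X), n)
    Ktc <- Kt - one_n %*% model$K_train - Kt %*% matrix(1 / n, n, n) +
      one_n %*% model$K_train %*% matrix(1 / n, n, n)
    scores <- Ktc %*% sweep(model$alpha, 2, sqrt(model$lambda), "/")
  }
  colnames(scores) <- paste0("kpc", seq_len(ncol(scores)))
  out <- if (is_df) {
    dplyr::bind_cols(data[setdiff(names(data), cols)], tibble::as_tibble(scores))
  } else {
    tibble::as_tibble(scores)
  }
  list(scores = out, model = model)
}

# One-way F statistic of y across groups g (classic between/within ratio).
f_statistic <- function(y, g) {
  n <- length(y); k <- nlevels(g)
  gm <- tapply(y, g, mean); gn <- tapply(y, g, length)
  ssb <- sum(gn * (gm - mean(y))^2)
  ssw <- sum((y - gm[as.integer(g)])^2)
  if (ssw < 1e-300) return(if (ssb < 1e-300) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Select the most class-informative channel
#'
#' Scores each channel by the one-way F statistic of its window-mean
#' \eqn{\Delta}HbO features (default windows 0-5, 5-10, 10-15 s) across the
#' task classes, summed over windows, and returns the arg-max channel.
#' Ties break to the lowest channel index. This is the model-free stand-in
#' for picking the channel that a baseline classifier finds most important.
#'
#' @param epochs list of baseline-corrected `nirs_epoch` objects with at
#'   least two classes present.
#' @param windows windows passed to the scoring, as in
#'   [window_mean_features()].
#' @return integer channel index (1-based).
#' @export
select_channel <- function(epochs, windows = list(c(0, 5), c(5, 10), c(10, 15))) {
  if (length(epochs) == 0) stop_invalid("no epochs supplied")
  labs <- droplevels(task_label(vapply(epochs, function(e)
    as.character(e$label), character(1))))
  if (nlevels(labs) < 2) stop_invalid("need at least 2 classes to rank channels")
  nc <- nrow(epochs[[1]]$hbo)
  idx_sets <- lapply(windows, function(w)
    epoch_window_idx(epochs[[1]], w[1], w[2]))
  scores <- vapply(seq_len(nc), function(ch) {
    sum(vapply(idx_sets, function(idx) {
      y <- vapply(epochs, function(ep) mean(ep$hbo[ch, idx]), numeric(1))
      f_statistic(y, labs)
    }, numeric(1)))
  }, numeric(1))
  which.max(scores)  # which.max takes the first (lowest) index on ties
}

#' @export
print.nirs_epoch <- function(x, ...) {
  cat("<nirs_epoch> ", as.character(x$label), ", ", nrow(x$hbo),
      " channels x ", ncol(x$hbo), " samples, window [",
      x$t0_offset, ", ", x$t0_offset + ncol(x$hbo) / x$sampling_rate,
      ") s\n", sep = "")
  invisible(x)
}
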