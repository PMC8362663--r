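# Gramian Angular Summation Field encoding: 1-D hemodynamic series ->
# 28x28 grayscale image in [0, 1].

#' Piecewise aggregate approximation
#'
#' Downsamples a series to `m` points by averaging over `m` contiguous
#' (near-)equal segments; when `m` divides the length, segments are exact
#' and the output holds exact segment means.
#'
#' @param series numeric vector.
#' @param m target length, `1 <= m <= length(series)`.
#' @return numeric vector of length `m`.
#' @export
#' @examples
#' paa_downsample(c(1, 2, 3, 4), 2)  # 1.5 3.5
paa_downsample <- function(series, m) {
  n <- length(series)
  if (m < 1 || m > n) stop_invalid("m must satisfy 1 <= m <= length(series)")
  bounds <- floor(seq_len(m) * n / m + 1e-9)
  starts <- c(1, head(bounds, -1) + 1)
  vapply(seq_len(m), function(i) mean(series[starts[i]:bounds[i]]), numeric(1))
}

#' Rescale a series to the unit interval of the polar encoding
#'
#' Affine map sending the minimum to -1 and the maximum to +1 (the polar
#' encoding precondition of the GASF). A constant series maps to all
#' zeros by convention, with a message.
#'
#' @param series non-empty numeric vector.
#' @return numeric vector in `[-1, 1]`.
#' @export
rescale_unit <- function(series) {
  if (length(series) == 0) stop_invalid("series must be non-empty")
  rng <- range(series)
  if (diff(rng) < 1e-300) {
    message("constant series rescaled to all zeros [code DEGENERATE_SERIES]")
    return(rep(0, length(series)))
  }
  2 * (series - rng[1]) / diff(rng) - 1
}

#' Gramian Angular Summation Field of a rescaled series
#'
#' With angles \eqn{\phi_i = \arccos(\tilde x_i)}, the GASF is
#' \eqn{G_{ij} = \cos(\phi_i + \phi_j) = \tilde x_i \tilde x_j -
#' \sqrt{1 - \tilde x_i^2}\sqrt{1 - \tilde x_j^2}}. The matrix is
#' symmetric, its entries lie in `[-1, 1]` and the diagonal satisfies
#' \eqn{G_{ii} = 2 \tilde x_i^2 - 1}.
#'
#' @param series numeric vector with values in `[-1, 1]` (tolerance 1e-12).
#' @return symmetric n x n matrix.
#' @export
#' @examples
#' gasf(c(-1, 0, 1))
gasf <- function(series) {
  if (any(abs(series) > 1 + 1e-12)) {
    stop_invalid("series values must lie in [-1, 1] (max |value| = ",
                 format(max(abs(series))), ")")
  }
  x <- pmin(pmax(series, -1), 1)
  s <- sqrt(1 - x^2)
  outer(x, x) - outer(s, s)
}

# Bilinear resampling of a matrix to side-by-side (used only when a GASF is
# not already 28x28).
bilinear_resize <- function(M, side) {
  n <- nrow(M); m <- ncol(M)
  if (n == side && m == side) return(M)
  map <- function(k, src) if (src == 1) rep(1, k) else (seq_len(k) - 1) * (src - 1) / (k - 1) + 1
  ri <- map(side, n); ci <- map(side, m)
  r0 <- pmin(floor(ri), n - 1); c0 <- pmin(floor(ci), m - 1)
  fr <- ri - r0; fc <- ci - c0
  A <- M[r0, c0, drop = FALSE]; B <- M[r0 + 1, c0, drop = FALSE]
  C <- M[r0, c0 + 1, drop = FALSE]; D <- M[r0 + 1, c0 + 1, drop = FALSE]
  wA <- outer(1 - fr, 1 - fc); wB <- outer(fr, 1 - fc)
  wC <- outer(1 - fr, fc); wD <- outer(fr, fc)
  A * wA + B * wB + C * wC + D * wD
}

#' Convert a GASF matrix into a labeled grayscale image
#'
#' Maps entries from `[-1, 1]` to `[0, 1]` via `(v + 1) / 2`; matrices that
#' are not 28x28 are first bilinearly resampled, then clamped.
#'
#' @param matrix square matrix with entries in `[-1, 1]`.
#' @param label a task label.
#' @param provenance `"real"` or `"generated"`.
#' @return object of class `gasf_image` (28x28 `pixels` in `[0, 1]`,
#'   `label`, `provenance`).
#' @export
to_image <- function(matrix, label, provenance = "real") {
  if (nrow(matrix) != ncol(matrix)) stop_invalid("matrix must be square")
  M <- bilinear_resize(matrix, 28L)
  px <- pmin(pmax((M + 1) / 2, 0), 1)
  structure(list(pixels = unname(px), label = task_label(label),
                 provenance = match.arg(provenance, c("real", "generated"))),
            class = "gasf_image")
}

#' Encode one epoch as a GASF image
#'
#' Takes the post-onset 0-28 s portion of the selected channel and
#' chromophore (the pre-onset baseline is reference only), PAA-downsamples
#' it to 28 points, rescales to `[-1, 1]`, builds the GASF and maps it to a
#' 28x28 grayscale image in `[0, 1]` carrying the epoch's label.
#'
#' @param epoch a baseline-corrected `nirs_epoch`.
#' @param channel 1-based channel index.
#' @param chromophore `"hbo"` (default) or `"hbr"`.
#' @return a `gasf_image`.
#' @export
encode_epoch <- function(epoch, channel, chromophore = c("hbo", "hbr")) {
  stopifnot(inherits(epoch, "nirs_epoch"))
  chromophore <- match.arg(chromophore)
  if (channel < 1 || channel > nrow(epoch$hbo)) {
    stop_invalid("channel ", channel, " out of range 1..", nrow(epoch$hbo))
  }
  idx <- epoch_window_idx(epoch, 0, epoch$t0_offset + ncol(epoch$hbo) / epoch$sampling_rate)
  series <- epoch[[chromophore]][channel, idx]
  to_image(gasf(rescale_unit(paa_downsample(series, 28L))), epoch$label)
}

#' Bundle GASF images into a dataset
#'
#' @param images list of `gasf_image` objects.
#' @param split `"train"` or `"test"`.
#' @return object of class `gasf_dataset`.
#' @export
gasf_dataset <- function(images, split = c("train", "test")) {
  split <- match.arg(split)
  stopifnot(all(vapply(images, inherits, logical(1), "gasf_image")))
  structure(list(images = images, split = split), class = "gasf_dataset")
}

#' Labels of a GASF dataset
#' @param ds a `gasf_dataset`.
#' @return factor of task labels.
#' @export
dataset_labels <- function(ds) {
  task_label(vapply(ds$images, function(im) as.character(im$label), character(1)))
}

dataset_provenance <- function(ds) {
  vapply(ds$images, function(im) im$provenance, character(1))
}

#' Number of images in a GASF dataset
#' @param x a `gasf_dataset`.
#' @export
length.gasf_dataset <- function(x) length(x$images)

# Stack a dataset's pixels into a [28, 28, 1, N] array on a given range:
# "unit" keeps [0,1]; "tanh" maps to [-1,1] for GAN internals.
dataset_array <- function(ds, range = c("unit", "tanh")) {
  range <- match.arg(range)
  n <- length(ds$images)
  X <- array(0, c(28, 28, 1, max(n, 1)))
  for (i in seq_len(n)) X[, , 1, i] <- ds$images[[i]]$pixels
  if (range == "tanh") X <- 2 * X - 1
  X
}

#' Stratified train/test split of a GASF dataset
#'
#' @param ds a `gasf_dataset`.
#' @param n_test total test-set size, drawn equally per class.
#' @param seed integer seed.
#' @return list with `train` and `test` datasets.
#' @export
split_dataset <- function(ds, n_test = 30, seed = 1L) {
  labs <- dataset_labels(ds)
  per_class <- n_test %/% nlevels(labs)
  with_seed(seed, {
    test_idx <- unlist(lapply(levels(labs), function(l) {
      pool <- which(labs == l)
      sample(pool, min(per_class, length(pool)))
    }))
  })
  list(train = gasf_dataset(ds$images[-test_idx], "train"),
       test = gasf_dataset(ds$images[test_idx], "test"))
}

#' @export
print.gasf_image <- function(x, ...) {
  cat("<gasf_image> 28x28, label ", as.character(x$label),
      ", provenance ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
print.gasf_dataset <- function(x, ...) {
  cat("<gasf_dataset> ", length(x$images), " images (", x$split, " split)\n",
      sep = "")
  if (length(x$images)) {
    print(table(label = as.character(dataset_labels(x)),
                provenance = dataset_provenance(x)))
  }
  invisible(x)
}

#' Tidy a GASF dataset into one row per image
#' @param x a `gasf_dataset`.
#' @param ... unused.
#' @return tibble with `image`, `label`, `provenance`, `split`.
#' @export
tidy.gasf_dataset <- function(x, ...) {
  tibble::tibble(
    image = seq_along(x$images),
    label = dataset_labels(x),
    provenance = dataset_provenance(x),
    split = x$split
  )
}
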