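# Evaluation: confusion matrices, accuracy, per-class precision,
# one-vs-rest AUROC, MS-SSIM diversity diagnostics, and the
# augmentation-fraction sweep.

#' Confusion matrix for the three task classes
#'
#' Rows are actual classes, columns predicted, in the canonical order
#' RHT, LHT, FT.
#'
#' @param actual,predicted equal-length label vectors.
#' @return 3x3 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(actual, predicted) {
  a <- task_label(actual); p <- task_label(predicted)
  if (length(a) != length(p)) {
    stop_invalid("actual and predicted lengths differ (", length(a),
                 " vs ", length(p), ")")
  }
  if (length(a) < 1) stop_invalid("need at least one pair")
  cm <- unclass(table(actual = a, predicted = p))
  structure(matrix(as.integer(cm), 3, 3,
                   dimnames = list(actual = TASK_LEVELS,
                                   predicted = TASK_LEVELS)),
            class = "confusion_matrix")
}

#' Build a confusion matrix from known counts
#' @param counts 3x3 numeric matrix, rows actual / columns predicted, class
#'   order RHT, LHT, FT.
#' @return a `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop_invalid("counts must be a 3x3 non-negative integer matrix")
  }
  structure(matrix(as.integer(counts), 3, 3,
                   dimnames = list(actual = TASK_LEVELS,
                                   predicted = TASK_LEVELS)),
            class = "confusion_matrix")
}

#' Classification accuracy in percent
#'
#' The multi-class reduction of the true/false positive/negative accuracy
#' ratio: 100 x trace / total.
#'
#' @param cm a `confusion_matrix`.
#' @return percent in `[0, 100]`.
#' @export
#' @examples
#' cm <- as_confusion_matrix(rbind(c(8, 1, 1), c(2, 7, 1), c(0, 1, 9)))
#' accuracy(cm)  # 80
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop_invalid("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Per-class precision
#'
#' Column-wise: `counts[c, c] / sum(counts[, c])` (the
#' predicted-positive denominator). A class never predicted yields `NaN`
#' with a warning.
#'
#' @param cm a `confusion_matrix`.
#' @return named numeric vector (RHT, LHT, FT) of fractions in `[0, 1]`.
#' @export
precision_per_class <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (sum(cm) == 0) stop_invalid("empty confusion matrix")
  denom <- colSums(cm)
  if (any(denom == 0)) {
    warning("class(es) never predicted; precision undefined [code PREC_NA]: ",
            paste(TASK_LEVELS[denom == 0], collapse = ", "))
  }
  out <- diag(unclass(cm)) / denom
  names(out) <- TASK_LEVELS
  out
}

# One-vs-rest AUROC of scores for a binary indicator, ties counted half
# (the rank / Mann-Whitney statistic).
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest AUROC per class and macro average
#'
#' For each class, the AUROC of that class's probability column for
#' class-vs-rest, computed as the rank statistic with ties counted one
#' half; the macro value is the unweighted mean.
#'
#' @param actual label vector.
#' @param probabilities matrix or data frame with one probability column
#'   per class in the order RHT, LHT, FT (the `.prob_*` columns of
#'   [predict.cnn_classifier()] also work).
#' @return named list with `per_class` (named vector) and `macro`.
#' @export
auroc_ovr <- function(actual, probabilities) {
  a <- task_label(actual)
  P <- as.matrix(as.data.frame(probabilities)[, 1:3])
  if (nrow(P) != length(a)) stop_invalid("probability rows must match labels")
  if (nlevels(droplevels(a)) < 2) {
    stop_invalid("need at least two classes present to compute AUROC")
  }
  per <- vapply(seq_along(TASK_LEVELS), function(k) {
    pos <- a == TASK_LEVELS[k]
    if (!any(pos) || all(pos)) return(NA_real_)
    auc_rank(P[, k], pos)
  }, numeric(1))
  names(per) <- TASK_LEVELS
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

# ---- MS-SSIM ----------------------------------------------------------------

ssim_window <- function(size = 11, sigma = 1.5) {
  g <- exp(-((seq_len(size) - (size + 1) / 2)^2) / (2 * sigma^2))
  g / sum(g)
}

# Valid-region separable Gaussian filtering of a matrix.
gauss_filter <- function(M, w) {
  k <- length(w)
  n <- nrow(M) - k + 1; m <- ncol(M) - k + 1
  A <- matrix(0, n, ncol(M))
  for (i in seq_len(k)) A <- A + w[i] * M[i:(i + n - 1), , drop = FALSE]
  B <- matrix(0, n, m)
  for (j in seq_len(k)) B <- B + w[j] * A[, j:(j + m - 1), drop = FALSE]
  B
}

ssim_maps <- function(a, b, w, C1, C2) {
  mu_a <- gauss_filter(a, w); mu_b <- gauss_filter(b, w)
  s_aa <- gauss_filter(a * a, w) - mu_a^2
  s_bb <- gauss_filter(b * b, w) - mu_b^2
  s_ab <- gauss_filter(a * b, w) - mu_a * mu_b
  l <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  cs <- (2 * s_ab + C2) / (s_aa + s_bb + C2)
  list(l = mean(l), cs = mean(cs))
}

downsample2 <- function(M) {
  H2 <- nrow(M) %/% 2; W2 <- ncol(M) %/% 2
  ri <- seq_len(2 * H2); ci <- seq_len(2 * W2)
  (M[ri[c(TRUE, FALSE)], ci[c(TRUE, FALSE)], drop = FALSE] +
   M[ri[c(FALSE, TRUE)], ci[c(TRUE, FALSE)], drop = FALSE] +
   M[ri[c(TRUE, FALSE)], ci[c(FALSE, TRUE)], drop = FALSE] +
   M[ri[c(FALSE, TRUE)], ci[c(FALSE, TRUE)], drop = FALSE]) / 4
}

#' Multi-scale structural similarity of two images
#'
#' Standard MS-SSIM with the five-scale weight vector (0.0448, 0.2856,
#' 0.3001, 0.2363, 0.1333), an 11x11 Gaussian window (sigma 1.5) and
#' dyadic downsampling; scales whose side would fall below the window size
#' are truncated and the remaining weights renormalized, so 28x28 images
#' use two scales. Contrast-structure terms are floored at zero before the
#' weighted geometric combination. Symmetric in its arguments; identical
#' images score 1.
#'
#' @param a,b `gasf_image`s or equal-shape numeric matrices in `[0, 1]`.
#' @return similarity in `[0, 1]`.
#' @export
ms_ssim <- function(a, b) {
  if (inherits(a, "gasf_image")) a <- a$pixels
  if (inherits(b, "gasf_image")) b <- b$pixels
  if (!all(dim(a) == dim(b))) stop_invalid("images must have equal shape")
  w <- ssim_window()
  weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  C1 <- 0.01^2; C2 <- 0.03^2  # dynamic range L = 1
  scales <- list()
  while (min(dim(a)) >= 11 && length(scales) < 5) {
    scales[[length(scales) + 1]] <- ssim_maps(a, b, w, C1, C2)
    a <- downsample2(a); b <- downsample2(b)
  }
  M <- length(scales)
  if (M == 0) stop_invalid("images smaller than the 11x11 SSIM window")
  wt <- weights[seq_len(M)] / sum(weights[seq_len(M)])
  val <- 1
  for (j in seq_len(M)) {
    cs <- max(scales[[j]]$cs, 0)
    term <- if (j == M) max(scales[[j]]$l, 0) * cs else cs
    val <- val * term^wt[j]
  }
  min(max(val, 0), 1)
}

#' Within-class diversity of generated images
#'
#' Mean pairwise MS-SSIM per class; values near 1 indicate near-identical
#' images, the signature of GAN mode collapse. Classes with more than 200
#' pairs are subsampled with the given seed.
#'
#' @param generated a `gasf_dataset`.
#' @param max_pairs pair budget per class.
#' @param seed subsampling seed.
#' @return tibble with `label`, `n_images`, `n_pairs`, `mean_ms_ssim`.
#' @export
diversity_report <- function(generated, max_pairs = 200, seed = 1L) {
  stopifnot(inherits(generated, "gasf_dataset"))
  labs <- dataset_labels(generated)
  purrr::map_dfr(TASK_LEVELS, function(l) {
    idx <- which(labs == l)
    if (length(idx) < 2) {
      if (length(idx) > 0) {
        warning("class ", l, " has fewer than 2 images; skipped [code DIV_SKIP]")
      }
      return(tibble::tibble(label = l, n_images = length(idx),
                            n_pairs = 0L, mean_ms_ssim = NA_real_))
    }
    pairs <- t(utils::combn(idx, 2))
    if (nrow(pairs) > max_pairs) {
      pairs <- with_seed(seed, pairs[sample(nrow(pairs), max_pairs), ,
                                     drop = FALSE])
    }
    vals <- vapply(seq_len(nrow(pairs)), function(i)
      ms_ssim(generated$images[[pairs[i, 1]]],
              generated$images[[pairs[i, 2]]]), numeric(1))
    tibble::tibble(label = l, n_images = length(idx),
                   n_pairs = nrow(pairs), mean_ms_ssim = mean(vals))
  })
}

#' Evaluate a classifier on a real-only test set
#'
#' @param model a `cnn_classifier`.
#' @param test a `gasf_dataset` of real images.
#' @param seed seed recorded in the report.
#' @return object of class `eval_report`: accuracy (percent), per-class
#'   precision, per-class and macro AUROC, the confusion matrix, and
#'   dataset bookkeeping certifying zero generated test images.
#' @export
evaluate_classifier <- function(model, test, seed = NA_integer_) {
  stopifnot(inherits(model, "cnn_classifier"), inherits(test, "gasf_dataset"))
  if (any(dataset_provenance(test) == "generated")) {
    stop_invalid("test set contains generated images [code TEST_PURITY]")
  }
  actual <- dataset_labels(test)
  pred <- predict(model, test)
  cm <- confusion_matrix(actual, pred$.pred)
  au <- auroc_ovr(actual, pred[, 1:3])
  structure(list(
    accuracy = accuracy(cm),
    precision = suppressWarnings(precision_per_class(cm)),
    auroc = au$per_class, macro_auroc = au$macro,
    confusion = cm, n_test = length(test),
    n_generated_in_test = 0L, seed = seed,
    config = model$config
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> accuracy ", sprintf("%.2f%%", x$accuracy),
      ", macro AUROC ", sprintf("%.3f", x$macro_auroc),
      " on ", x$n_test, " real test images\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Tidy a confusion matrix into long form
#' @param x a `confusion_matrix`.
#' @param ... unused.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    actual = task_label(rep(TASK_LEVELS, 3)),
    predicted = task_label(rep(TASK_LEVELS, each = 3)),
    n = as.integer(unclass(x))
  )
}

#' Tidy an evaluation report
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(class = task_label(TASK_LEVELS),
                 precision = unname(x$precision),
                 auroc = unname(x$auroc))
}

#' One-row summary of an evaluation report
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(accuracy_pct = x$accuracy, macro_auroc = x$macro_auroc,
                 n_test = x$n_test,
                 n_generated_in_test = x$n_generated_in_test)
}

# Regularization relaxation schedule: strict at fraction 0, linearly
# relaxed to (l2_final, dropout_final) at the top of the fraction grid.
relax_schedule <- function(fraction, f_max = 1.1, l2_0 = 0.5, l2_1 = 0.01,
                           dropout_0 = 0.4, dropout_1 = 0.2) {
  t <- if (f_max > 0) min(fraction / f_max, 1) else 0
  list(l2 = l2_0 + t * (l2_1 - l2_0),
       dropout = dropout_0 + t * (dropout_1 - dropout_0))
}

#' Augmentation-fraction sweep
#'
#' Trains the conditional GAN once on the real training images, then for
#' every fraction f in the grid synthesizes `round(f * n_train)`
#' class-balanced images, trains the CNN classifier on real + generated
#' with that step's relaxed regularization (l2 from 0.5 down to 0.01 and
#' dropout from 0.4 to 0.2, linearly over the grid), and evaluates on the
#' real-only test set. A small stratified slice of the real training images
#' is held out for validation-based early stopping at every step. A failed
#' step records a failure row and the sweep continues.
#'
#' @param real_train,real_test `gasf_dataset`s of real images.
#' @param cgan_cfg a [cgan_config()].
#' @param cnn_cfg a [cnn_config()] template (l2/dropout/seed overridden per
#'   step by the schedule).
#' @param fractions increasing fraction grid; the default
#'   `seq(0, 1.1, 0.1)` starts with a real-only baseline row.
#' @param seed master seed fanned out to every stage.
#' @param val_frac share of real training images held out for early
#'   stopping.
#' @return object of class `sweep_report` with one row per fraction and the
#'   trained `cgan_model` attached.
#' @export
augmentation_sweep <- function(real_train, real_test,
                               cgan_cfg = cgan_config(),
                               cnn_cfg = cnn_config(),
                               fractions = seq(0, 1.1, by = 0.1),
                               seed = 1L, val_frac = 0.2) {
  stopifnot(inherits(real_train, "gasf_dataset"),
            inherits(real_test, "gasf_dataset"))
  if (any(dataset_provenance(real_train) == "generated") ||
      any(dataset_provenance(real_test) == "generated")) {
    stop_invalid("sweep inputs must be real images only [code TEST_PURITY]")
  }
  if (any(diff(fractions) <= 0)) {
    stop_invalid("fractions must be strictly increasing")
  }
  n_train <- length(real_train)
  gan <- train_cgan(real_train, cgan_cfg, seed = derive_seed(seed, "cgan"))
  # held-out real validation slice for early stopping
  labs <- dataset_labels(real_train)
  per_class <- max(1L, floor(n_train * val_frac / 3))
  val_idx <- with_seed(derive_seed(seed, "val"), {
    unlist(lapply(TASK_LEVELS, function(l)
      sample(which(labs == l), min(per_class, sum(labs == l)))))
  })
  fit_train <- gasf_dataset(real_train$images[-val_idx], "train")
  fit_val <- gasf_dataset(real_train$images[val_idx], "train")
  f_max <- max(fractions)
  rows <- purrr::map(seq_along(fractions), function(i) {
    f <- fractions[i]
    reg <- relax_schedule(f, f_max)
    step_seed <- derive_seed(seed, paste0("step", i))
    tryCatch({
      gen <- synthesize(gan, n_train, f, seed = step_seed)
      train_i <- gasf_dataset(c(fit_train$images, gen$images), "train")
      cfg <- cnn_cfg
      cfg$l2 <- reg$l2; cfg$dropout <- reg$dropout; cfg$seed <- step_seed
      fit <- train_classifier(train_i, fit_val, cfg)
      rep <- evaluate_classifier(fit, real_test, seed = step_seed)
      tibble::tibble(
        fraction = f, n_generated = length(gen),
        accuracy_pct = rep$accuracy, macro_auroc = rep$macro_auroc,
        precision_RHT = rep$precision[["RHT"]],
        precision_LHT = rep$precision[["LHT"]],
        precision_FT = rep$precision[["FT"]],
        l2 = reg$l2, dropout = reg$dropout, seed = step_seed,
        status = "ok", message = NA_character_,
        confusion = list(rep$confusion))
    }, error = function(e) {
      tibble::tibble(
        fraction = f, n_generated = NA_integer_,
        accuracy_pct = NA_real_, macro_auroc = NA_real_,
        precision_RHT = NA_real_, precision_LHT = NA_real_,
        precision_FT = NA_real_,
        l2 = reg$l2, dropout = reg$dropout, seed = step_seed,
        status = "failed", message = conditionMessage(e),
        confusion = list(NULL))
    })
  })
  structure(list(results = dplyr::bind_rows(rows), cgan = gan,
                 n_train = n_train, n_test = length(real_test),
                 seed = seed),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("<sweep_report> ", nrow(x$results), " fractions, ", x$n_train,
      " real train / ", x$n_test, " real test images\n", sep = "")
  print(as.data.frame(x$results[, c("fraction", "n_generated",
                                    "accuracy_pct", "macro_auroc",
                                    "status")]), row.names = FALSE)
  invisible(x)
}

#' Tidy an augmentation sweep into one row per fraction
#' @param x a `sweep_report`.
#' @param ... unused.
#' @export
tidy.sweep_report <- function(x, ...) {
  x$results[, setdiff(names(x$results), "confusion")]
}

#' One-row summary of an augmentation sweep
#' @param x a `sweep_report`.
#' @param ... unused.
#' @export
glance.sweep_report <- function(x, ...) {
  ok <- x$results[x$results$status == "ok", ]
  best <- ok[which.max(ok$accuracy_pct), ]
  tibble::tibble(
    n_fractions = nrow(x$results),
    baseline_accuracy_pct = ok$accuracy_pct[ok$fraction == min(ok$fraction)][1],
    best_accuracy_pct = best$accuracy_pct,
    best_fraction = best$fraction,
    best_macro_auroc = best$macro_auroc
  )
}

#' Accuracy and AUROC across augmentation fractions
#' @param object a `sweep_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sweep_report <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(d[, c("fraction", "accuracy_pct", "macro_auroc")],
                           -"fraction", names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "generated fraction of real training size", y = NULL,
                  title = "Augmentation sweep") +
    ggplot2::theme_minimal()
}

#' Raster view of a GASF image
#' @param object a `gasf_image`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gasf_image <- function(object, ...) {
  d <- tidyr::expand_grid(col = 1:28, row = 1:28)  # row varies fastest,
  # matching R's column-major pixel vectorization
  d$value <- as.vector(object$pixels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("GASF (", as.character(object$label), ", ",
                                 object$provenance, ")"),
                  x = NULL, y = NULL, fill = "pixel") +
    ggplot2::theme_minimal()
}
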