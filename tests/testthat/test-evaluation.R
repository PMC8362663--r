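test_that("confusion matrices tally actual x predicted counts", {
  cm <- confusion_matrix(c("RHT", "LHT", "FT"), c("RHT", "LHT", "FT"))
  expect_equal(diag(unclass(cm)), c(RHT = 1L, LHT = 1L, FT = 1L))
  expect_equal(sum(cm), 3)

  cm2 <- confusion_matrix(c("RHT", "LHT", "FT"), rep("FT", 3))
  expect_true(all(unclass(cm2)[, 1:2] == 0))
  expect_equal(unname(unclass(cm2)[, 3]), c(1L, 1L, 1L))

  withr::with_seed(10, {
    a <- task_label(sample(0:2, 30, replace = TRUE))
    p <- task_label(sample(0:2, 30, replace = TRUE))
  })
  cm3 <- confusion_matrix(a, p)
  for (i in 1:3) for (j in 1:3) {
    # brute-force tally oracle
    expect_equal(unclass(cm3)[i, j],
                 sum(as.integer(a) == i & as.integer(p) == j))
  }
  expect_error(confusion_matrix(a, p[1:5]), "lengths differ")
  expect_error(confusion_matrix(c("RHT"), c("JUMP")), "unknown task label")
})

test_that("multi-class accuracy is trace over total, consistent with the one-vs-rest reduction", {
  expect_equal(accuracy(as_confusion_matrix(diag(10, 3))), 100)
  withr::with_seed(11, {
    for (i in 1:20) {
      # balanced matrices: each actual class has the same row total
      rows <- t(stats::rmultinom(3, size = 12, prob = rep(1 / 3, 3)))
      cm <- as_confusion_matrix(rows)
      acc <- accuracy(cm)
      # brute-force per-class (TP+TN)/(TP+FP+TN+FN) oracle, averaged
      ovr <- mean(vapply(1:3, function(c) {
        tp <- rows[c, c]; fn <- sum(rows[c, -c])
        fp <- sum(rows[-c, c]); tn <- sum(rows[-c, -c])
        (tp + tn) / (tp + fp + tn + fn)
      }, numeric(1)))
      # with balanced classes, 100 * (3 * ovr - 1) / 2 equals trace/total
      expect_equal(acc, 100 * (3 * ovr - 1) / 2, tolerance = 1e-9)
    }
  })
  expect_error(accuracy(as_confusion_matrix(matrix(0, 3, 3))), "empty")
})

test_that("per-class precision divides the diagonal by the predicted-column total", {
  cm <- as_confusion_matrix(rbind(c(9, 1, 0), c(0, 10, 0), c(0, 0, 10)))
  pr <- precision_per_class(cm)
  expect_equal(pr[["RHT"]], 1)
  expect_equal(pr[["FT"]], 1)
  expect_equal(pr[["LHT"]], 10 / 11)
  anti <- as_confusion_matrix(rbind(c(0, 0, 5), c(0, 5, 0), c(5, 0, 0)))
  expect_equal(unname(precision_per_class(anti)), c(0, 1, 0))
  never <- as_confusion_matrix(rbind(c(0, 5, 0), c(0, 5, 0), c(0, 5, 0)))
  expect_warning(pn <- precision_per_class(never), "PREC_NA")
  expect_true(is.nan(pn[["RHT"]]))
})

test_that("one-vs-rest AUROC equals the exhaustive pairwise statistic", {
  # perfectly ordered scores
  a <- task_label(c(0, 0, 1, 1, 2, 2))
  P <- rbind(c(.9, .05, .05), c(.8, .1, .1), c(.1, .8, .1),
             c(.2, .7, .1), c(.1, .1, .8), c(.05, .05, .9))
  au <- auroc_ovr(a, P)
  expect_equal(unname(au$per_class), c(1, 1, 1))
  expect_equal(au$macro, 1)

  # identical scores: every comparison is a tie
  Pu <- matrix(1 / 3, 6, 3)
  expect_equal(unname(auroc_ovr(a, Pu)$per_class), c(0.5, 0.5, 0.5))

  # random instances up to n = 12 against the brute-force pair count
  brute <- function(scores, pos) {
    pairs <- expand.grid(i = which(pos), j = which(!pos))
    mean(ifelse(scores[pairs$i] > scores[pairs$j], 1,
                ifelse(scores[pairs$i] == scores[pairs$j], 0.5, 0)))
  }
  withr::with_seed(12, {
    for (trial in 1:30) {
      n <- sample(4:12, 1)
      labs <- task_label(c(0, 1, 2, sample(0:2, n - 3, replace = TRUE)))
      Pr <- matrix(stats::runif(n * 3), n)
      Pr <- round(Pr / rowSums(Pr), 2)  # induces ties
      au <- auroc_ovr(labs, Pr)
      for (k in 1:3) {
        expect_equal(au$per_class[[k]], brute(Pr[, k], labs == c("RHT", "LHT", "FT")[k]))
      }
    }
  })
  expect_error(auroc_ovr(task_label(c(0, 0)), matrix(1 / 3, 2, 3)),
               "two classes")
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    labs <- task_label(sample(0:2, 40, replace = TRUE))
    P <- matrix(stats::runif(120), 40)
    P <- P / rowSums(P)
  })
  au <- auroc_ovr(labs, P)
  for (k in 1:3) {
    ref <- pROC::auc(pROC::roc(labs == c("RHT", "LHT", "FT")[k], P[, k],
                               quiet = TRUE, direction = "<"))
    expect_equal(au$per_class[[k]], as.numeric(ref), tolerance = 1e-12)
  }
})

# Independent MS-SSIM oracle: direct nested-loop implementation of the same
# published construction (11x11 Gaussian window, truncated scales).
ms_ssim_oracle <- function(a, b) {
  gwin <- outer(
    exp(-((1:11 - 6)^2) / (2 * 1.5^2)) / sum(exp(-((1:11 - 6)^2) / (2 * 1.5^2))),
    exp(-((1:11 - 6)^2) / (2 * 1.5^2)) / sum(exp(-((1:11 - 6)^2) / (2 * 1.5^2))))
  filt <- function(M) {
    n <- nrow(M) - 10; m <- ncol(M) - 10
    out <- matrix(0, n, m)
    for (i in 1:n) for (j in 1:m)
      out[i, j] <- sum(M[i:(i + 10), j:(j + 10)] * gwin)
    out
  }
  C1 <- 1e-4; C2 <- 9e-4
  stats_at <- function(a, b) {
    ma <- filt(a); mb <- filt(b)
    va <- filt(a * a) - ma^2; vb <- filt(b * b) - mb^2
    cab <- filt(a * b) - ma * mb
    list(l = mean((2 * ma * mb + C1) / (ma^2 + mb^2 + C1)),
         cs = mean((2 * cab + C2) / (va + vb + C2)))
  }
  half <- function(M) {
    n <- nrow(M) %/% 2
    out <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      out[i, j] <- mean(M[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    out
  }
  s1 <- stats_at(a, b)
  s2 <- stats_at(half(a), half(b))
  w <- c(0.0448, 0.2856) / sum(c(0.0448, 0.2856))
  max(s1$cs, 0)^w[1] * (max(s2$l, 0) * max(s2$cs, 0))^w[2]
}

test_that("MS-SSIM is 1 for identical images, symmetric, and matches the oracle", {
  withr::with_seed(14, {
    a <- to_image(gasf(rescale_unit(cumsum(rnorm(28)))), "RHT")
    b <- to_image(gasf(rescale_unit(cumsum(rnorm(28)))), "LHT")
  })
  expect_equal(ms_ssim(a, a), 1, tolerance = 1e-9)
  expect_equal(ms_ssim(a, b), ms_ssim(b, a))
  expect_gte(ms_ssim(a, b), 0)
  expect_lte(ms_ssim(a, b), 1)
  expect_equal(ms_ssim(a, b), ms_ssim_oracle(a$pixels, b$pixels),
               tolerance = 1e-3)
  # a noisy copy is more similar than an independent image
  n <- withr::with_seed(15, pmin(pmax(a$pixels + matrix(rnorm(784, sd = 0.02),
                                                        28), 0), 1))
  expect_gt(ms_ssim(a$pixels, n), ms_ssim(a, b))
  expect_error(ms_ssim(a$pixels, matrix(0, 14, 14)), "equal shape")
})

test_that("diversity reports aggregate pairwise MS-SSIM per class", {
  px <- matrix(runif(784), 28)
  lone <- structure(list(pixels = matrix(runif(784), 28),
                         label = task_label("LHT"), provenance = "generated"),
                    class = "gasf_image")
  same <- gasf_dataset(c(lapply(1:3, function(i)
    structure(list(pixels = px, label = task_label("RHT"),
                   provenance = "generated"), class = "gasf_image")),
    list(lone)), "train")
  # identical images score 1; the single-image class is skipped with warning
  expect_warning(dv <- diversity_report(same), "DIV_SKIP")
  expect_equal(dv$mean_ms_ssim[dv$label == "RHT"], 1)
  expect_true(is.na(dv$mean_ms_ssim[dv$label == "LHT"]))

  ds5 <- toy_images(5, seed = 16)
  dv5 <- diversity_report(ds5)
  rht <- which(dataset_labels(ds5) == "RHT")
  pairs <- utils::combn(rht, 2)
  manual <- mean(vapply(seq_len(ncol(pairs)), function(k)
    ms_ssim(ds5$images[[pairs[1, k]]], ds5$images[[pairs[2, k]]]),
    numeric(1)))
  expect_equal(dv5$mean_ms_ssim[dv5$label == "RHT"], manual)
  expect_equal(dv5$n_pairs[1], 10)

  two <- gasf_dataset(c(ds5$images[rht[1:2]], list(lone)), "train")
  expect_warning(dv2 <- diversity_report(two), "DIV_SKIP")
  expect_equal(dv2$mean_ms_ssim[dv2$label == "RHT"],
               ms_ssim(two$images[[1]], two$images[[2]]))
})

test_that("a miniature augmentation sweep has the declared structure and purity", {
  ds <- toy_images(8, seed = 17)
  parts <- split_dataset(ds, n_test = 6, seed = 18)
  parts$train$split <- "train"
  rep <- suppressWarnings(augmentation_sweep(
    parts$train, parts$test,
    cgan_cfg = cgan_config(latent_dim = 16, gen_filters = c(8, 6),
                           disc_filters = c(6, 8), steps = 15, seed = 1),
    cnn_cfg = cnn_config(filters = c(4, 6, 8, 10), dense = c(16, 12),
                         max_epochs = 2, batch_size = 8, seed = 1),
    fractions = c(0, 0.5), seed = 19, val_frac = 0.34))
  td <- tidy(rep)
  expect_equal(nrow(td), 2)
  expect_equal(td$fraction, c(0, 0.5))
  expect_equal(td$n_generated[1], 0L)
  expect_equal(td$n_generated[2], round(0.5 * length(parts$train)))
  expect_true(all(td$status == "ok"))
  # regularization relaxes monotonically along the grid
  expect_true(all(diff(td$l2) < 0))
  # purity certified per step
  expect_true(all(vapply(rep$results$confusion, function(cm)
    sum(cm) == length(parts$test), logical(1))))
  g <- glance(rep)
  expect_equal(g$n_fractions, 2L)
  expect_error(augmentation_sweep(parts$train, parts$test,
                                  fractions = c(0.5, 0.1)),
               "increasing")
})

test_that("evaluation reports certify real-only test data", {
  ds <- toy_images(4, seed = 20)
  fit <- train_classifier(ds, ds,
                          cnn_config(filters = c(4, 6, 8, 10),
                                     dense = c(16, 12), max_epochs = 2,
                                     batch_size = 8, seed = 1, l2 = 0.01))
  bad <- ds
  bad$images[[1]]$provenance <- "generated"
  expect_error(evaluate_classifier(fit, bad), "TEST_PURITY")
  rep <- evaluate_classifier(fit, ds, seed = 1)
  expect_s3_class(glance(rep), "tbl_df")
  expect_equal(rep$n_generated_in_test, 0L)
  expect_equal(sum(rep$confusion), 12)
  expect_equal(nrow(tidy(rep)), 3)
})
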