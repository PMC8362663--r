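# Conditional GAN: class-conditioned generator (dense 7x7x128 grid + three
# 4x4 transposed-convolution layers, batch-normalized, tanh output) and a
# small convolutional discriminator with a label-conditioning channel.
# Trained adversarially with alternating discriminator/generator updates.

#' Configuration for the conditional GAN
#'
#' @param latent_dim dimension of the standard-normal latent prior.
#' @param gen_filters filter counts of the first two up-sampling layers
#'   (7->14 and 14->28); the third (stride-1 refinement) layer maps to one
#'   output channel.
#' @param disc_filters filter counts of the two strided discriminator
#'   convolutions.
#' @param lr learning rate of the adaptive-moment optimizer for both
#'   networks.
#' @param beta1 first-moment decay (0.5, the stable convention for
#'   image GANs).
#' @param batch_size minibatch size for GAN training.
#' @param steps number of alternating training steps.
#' @param ms_ssim_ceiling mode-collapse warning threshold on the mean
#'   pairwise MS-SSIM within a generated class.
#' @param seed integer seed governing initialization and batch sampling.
#' @return object of class `cgan_config`.
#' @export
cgan_config <- function(latent_dim = 100, gen_filters = c(32, 16),
                        disc_filters = c(16, 32), lr = 2e-4, beta1 = 0.5,
                        batch_size = 32, steps = 400,
                        ms_ssim_ceiling = 0.98, seed = 1L) {
  structure(list(latent_dim = as.integer(latent_dim),
                 gen_filters = as.integer(gen_filters),
                 disc_filters = as.integer(disc_filters),
                 lr = lr, beta1 = beta1,
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps),
                 ms_ssim_ceiling = ms_ssim_ceiling,
                 seed = as.integer(seed)),
            class = "cgan_config")
}

cgan_init_params <- function(cfg) {
  L <- cfg$latent_dim; gf <- cfg$gen_filters; df <- cfg$disc_filters
  w <- function(...) array(rnorm(prod(c(...)), sd = 0.02), c(...))
  bn0 <- bn_init(128); bn1 <- bn_init(gf[1]); bn2 <- bn_init(gf[2])
  g <- list(
    fc_W = w(L, 7 * 7 * 128), fc_b = rep(0, 7 * 7 * 128),
    bn0_gamma = bn0$gamma, bn0_beta = bn0$beta,
    t1_W = w(16 * gf[1], 131), t1_b = rep(0, gf[1]),
    bn1_gamma = bn1$gamma, bn1_beta = bn1$beta,
    t2_W = w(16 * gf[2], gf[1]), t2_b = rep(0, gf[2]),
    bn2_gamma = bn2$gamma, bn2_beta = bn2$beta,
    t3_W = w(16 * 1, gf[2]), t3_b = rep(0, 1)
  )
  d <- list(
    c1_W = w(16 * 4, df[1]), c1_b = rep(0, df[1]),
    c2_W = w(16 * df[1], df[2]), c2_b = rep(0, df[2]),
    fc_W = w(7 * 7 * df[2], 1), fc_b = rep(0, 1)
  )
  list(g = g, d = d,
       g_state = list(bn0 = bn0$state, bn1 = bn1$state, bn2 = bn2$state),
       geom = list(
         gt1 = conv_geom(14, 14, gf[1], 4, 2, 1),
         gt2 = conv_geom(28, 28, gf[2], 4, 2, 1),
         gt3 = conv_geom(28, 28, 1, 4, 1, c(1, 2, 1, 2)),
         d1 = conv_geom(28, 28, 4, 4, 2, 1),
         d2 = conv_geom(14, 14, df[1], 4, 2, 1)
       ))
}

concat_c <- function(A, B) {
  d <- dim(A)
  out <- array(0, c(d[1], d[2], d[3] + dim(B)[3], d[4]))
  out[, , seq_len(d[3]), ] <- A
  out[, , d[3] + seq_len(dim(B)[3]), ] <- B
  out
}

# Constant one-hot label planes of a given spatial side: [side, side, 3, N].
label_planes <- function(y1h, side) {
  N <- nrow(y1h)
  out <- array(0, c(side, side, 3, N))
  for (k in 1:3) out[, , k, ] <- rep(y1h[, k], each = side * side)
  out
}

g_forward <- function(z, y1h, p, state, geom, training = FALSE) {
  N <- nrow(z)
  h0 <- z %*% p$fc_W; h0 <- h0 + rep(p$fc_b, each = nrow(h0))
  H0 <- array(t(h0), c(7, 7, 128, N))
  b0 <- bn_fwd(H0, p$bn0_gamma, p$bn0_beta, state$bn0, training)
  A0 <- relu(b0$Y)
  X1 <- concat_c(A0, label_planes(y1h, 7L))
  t1 <- tconv_fwd(X1, p$t1_W, p$t1_b, geom$gt1)
  b1 <- bn_fwd(t1$Y, p$bn1_gamma, p$bn1_beta, state$bn1, training)
  A1 <- relu(b1$Y)
  t2 <- tconv_fwd(A1, p$t2_W, p$t2_b, geom$gt2)
  b2 <- bn_fwd(t2$Y, p$bn2_gamma, p$bn2_beta, state$bn2, training)
  A2 <- relu(b2$Y)
  t3 <- tconv_fwd(A2, p$t3_W, p$t3_b, geom$gt3)
  out <- tanh(t3$Y)
  list(out = out,
       state = list(bn0 = b0$state, bn1 = b1$state, bn2 = b2$state),
       cache = list(z = z, y1h = y1h, b0 = b0, b1 = b1, b2 = b2,
                    t1 = t1, t2 = t2, t3 = t3, out = out))
}

g_backward <- function(dout, cache, p, geom) {
  N <- nrow(cache$z)
  dpre3 <- dout * (1 - cache$out^2)
  bw3 <- tconv_bwd(dpre3, p$t3_W, geom$gt3, cache$t3$cache)
  dA2 <- relu_bwd(bw3$dX, cache$b2$Y)
  bb2 <- bn_bwd(dA2, p$bn2_gamma, cache$b2$cache)
  bw2 <- tconv_bwd(bb2$dX, p$t2_W, geom$gt2, cache$t2$cache)
  dA1 <- relu_bwd(bw2$dX, cache$b1$Y)
  bb1 <- bn_bwd(dA1, p$bn1_gamma, cache$b1$cache)
  bw1 <- tconv_bwd(bb1$dX, p$t1_W, geom$gt1, cache$t1$cache)
  dX1 <- bw1$dX
  dA0 <- dX1[, , 1:128, , drop = FALSE]  # label planes are constants
  dA0r <- relu_bwd(dA0, cache$b0$Y)
  bb0 <- bn_bwd(dA0r, p$bn0_gamma, cache$b0$cache)
  dh0 <- t(matrix(bb0$dX, 7 * 7 * 128, N))
  list(
    fc_W = crossprod(cache$z, dh0), fc_b = colSums(dh0),
    bn0_gamma = bb0$dgamma, bn0_beta = bb0$dbeta,
    t1_W = bw1$dW, t1_b = bw1$db,
    bn1_gamma = bb1$dgamma, bn1_beta = bb1$dbeta,
    t2_W = bw2$dW, t2_b = bw2$db,
    bn2_gamma = bb2$dgamma, bn2_beta = bb2$dbeta,
    t3_W = bw3$dW, t3_b = bw3$db
  )
}

d_forward <- function(X, y1h, p, geom) {
  N <- dim(X)[4]
  X2 <- concat_c(X, label_planes(y1h, 28L))
  c1 <- conv_fwd(X2, p$c1_W, p$c1_b, geom$d1)
  A1 <- lrelu(c1$Y)
  c2 <- conv_fwd(A1, p$c2_W, p$c2_b, geom$d2)
  A2 <- lrelu(c2$Y)
  flat <- t(matrix(A2, length(A2) / N, N))
  logit <- as.vector(flat %*% p$fc_W + p$fc_b)
  list(logit = logit,
       cache = list(y1h = y1h, c1 = c1, c2 = c2, A2dim = dim(A2),
                    flat = flat, N = N))
}

d_backward <- function(dlogit, cache, p, geom) {
  N <- cache$N
  dflat <- matrix(dlogit, N, 1) %*% t(p$fc_W)
  dA2 <- array(t(dflat), cache$A2dim)
  dpre2 <- lrelu_bwd(dA2, cache$c2$Y)
  bw2 <- conv_bwd(dpre2, p$c2_W, geom$d2, cache$c2$cache)
  dpre1 <- lrelu_bwd(bw2$dX, cache$c1$Y)
  bw1 <- conv_bwd(dpre1, p$c1_W, geom$d1, cache$c1$cache)
  dX2 <- bw1$dX
  list(grads = list(
    c1_W = bw1$dW, c1_b = bw1$db,
    c2_W = bw2$dW, c2_b = bw2$db,
    fc_W = crossprod(cache$flat, matrix(dlogit, N, 1)),
    fc_b = sum(dlogit)
  ), dX = dX2[, , 1, , drop = FALSE])
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Train the conditional GAN
#'
#' Alternating adversarial updates: each step trains the discriminator on a
#' real batch (target 1) and a freshly generated batch (target 0), then
#' updates the generator to raise the discriminator's output on its
#' samples. Both networks use the adaptive-moment optimizer. Training is a
#' pure function of the dataset, configuration and seed. The per-step
#' history records the discriminator's two loss halves (whose sum is the
#' negated empirical value function), the generator loss, and the
#' discriminator's accuracy on its balanced real/fake batch.
#'
#' @param train a `gasf_dataset` containing all three classes.
#' @param config a [cgan_config()].
#' @param seed optional override of `config$seed`.
#' @return object of class `cgan_model` with `generator`, `discriminator`,
#'   `history` (tibble), and the latent-prior spec.
#' @export
train_cgan <- function(train, config = cgan_config(), seed = NULL) {
  stopifnot(inherits(train, "gasf_dataset"))
  seed <- seed %||% config$seed
  labs <- dataset_labels(train)
  if (length(train) == 0 || nlevels(droplevels(labs)) < 3) {
    stop_invalid("training set must contain all three classes")
  }
  X <- dataset_array(train, "tanh")
  n <- length(train)
  with_seed(seed, {
    mdl <- cgan_init_params(config)
    g <- mdl$g; d <- mdl$d; gs <- mdl$g_state; geom <- mdl$geom
    opt_g <- opt_init(g, "adam", lr = config$lr, beta1 = config$beta1)
    opt_d <- opt_init(d, "adam", lr = config$lr, beta1 = config$beta1)
    B <- min(config$batch_size, n)
    hist <- vector("list", config$steps)
    for (s in seq_len(config$steps)) {
      ri <- sample(n, B, replace = n < B)
      Xr <- X[, , , ri, drop = FALSE]
      yr <- one_hot(labs[ri])
      # --- discriminator step
      fr <- d_forward(Xr, yr, d, geom)
      loss_real <- mean(softplus(-fr$logit))
      yf_lab <- task_label(sample(0:2, B, replace = TRUE))
      yf <- one_hot(yf_lab)
      z <- matrix(rnorm(B * config$latent_dim), B)
      gen <- g_forward(z, yf, g, gs, geom, training = TRUE)
      gs <- gen$state
      ff <- d_forward(gen$out, yf, d, geom)
      loss_fake <- mean(softplus(ff$logit))
      # matching-aware conditioning: real images with wrong labels -> fake
      ym <- yr[, c(2, 3, 1), drop = FALSE]
      fm <- d_forward(Xr, ym, d, geom)
      loss_mismatch <- mean(softplus(fm$logit))
      if (!is.finite(loss_real + loss_fake)) {
        h <- dplyr::bind_rows(hist[seq_len(s - 1)])
        cond <- simpleError("GAN training diverged: non-finite discriminator loss")
        cond$history <- h
        stop(cond)
      }
      br <- d_backward((sigmoid(fr$logit) - 1) / B, fr$cache, d, geom)
      bf <- d_backward(sigmoid(ff$logit) / B, ff$cache, d, geom)
      bm <- d_backward(sigmoid(fm$logit) / (2 * B), fm$cache, d, geom)
      gr_d <- purrr::map2(purrr::map2(br$grads, bf$grads, `+`), bm$grads, `+`)
      st <- opt_step(opt_d, d, gr_d); opt_d <- st$opt; d <- st$params
      # --- generator step (non-saturating objective)
      z2 <- matrix(rnorm(B * config$latent_dim), B)
      y2_lab <- task_label(sample(0:2, B, replace = TRUE))
      y2 <- one_hot(y2_lab)
      gen2 <- g_forward(z2, y2, g, gs, geom, training = TRUE)
      gs <- gen2$state
      fg <- d_forward(gen2$out, y2, d, geom)
      g_loss <- mean(softplus(-fg$logit))
      if (!is.finite(g_loss)) {
        h <- dplyr::bind_rows(hist[seq_len(s - 1)])
        cond <- simpleError("GAN training diverged: non-finite generator loss")
        cond$history <- h
        stop(cond)
      }
      bg <- d_backward((sigmoid(fg$logit) - 1) / B, fg$cache, d, geom)
      gr_g <- g_backward(bg$dX, gen2$cache, g, geom)
      st <- opt_step(opt_g, g, gr_g); opt_g <- st$opt; g <- st$params
      hist[[s]] <- tibble::tibble(
        step = s, d_loss_real = loss_real, d_loss_fake = loss_fake,
        d_loss = loss_real + loss_fake,
        d_loss_mismatch = loss_mismatch, g_loss = g_loss,
        d_accuracy = (sum(fr$logit > 0) + sum(ff$logit < 0)) / (2 * B),
        value_fn = -(loss_real + loss_fake)
      )
    }
    model <- structure(list(
      generator = g, discriminator = d, g_state = gs, geom = geom,
      config = config, latent_dim = config$latent_dim, n_classes = 3L,
      history = dplyr::bind_rows(hist)
    ), class = "cgan_model")
  })
  div <- tryCatch(
    diversity_report(synthesize(model, 30, 1, seed = derive_seed(seed, "msssim"))),
    warning = function(w) NULL, error = function(e) NULL)
  if (!is.null(div) && any(div$mean_ms_ssim > config$ms_ssim_ceiling, na.rm = TRUE)) {
    warning("possible mode collapse [code MODE_COLLAPSE]: mean within-class ",
            "MS-SSIM above ", config$ms_ssim_ceiling)
  }
  model
}

#' Run the generator once (inference mode)
#'
#' Deterministic given `(z, y)` and the model: batch-normalization uses the
#' stored running statistics. Output values lie strictly in (-1, 1).
#'
#' @param model a `cgan_model`.
#' @param z numeric latent vector of length `model$latent_dim`.
#' @param y a task label.
#' @return 28 x 28 numeric matrix in (-1, 1).
#' @export
generator_forward <- function(model, z, y) {
  stopifnot(inherits(model, "cgan_model"))
  if (length(z) != model$latent_dim) {
    stop_invalid("z has length ", length(z), ", expected ", model$latent_dim)
  }
  out <- g_forward(matrix(z, 1), one_hot(task_label(y)), model$generator,
                   model$g_state, model$geom, training = FALSE)$out
  matrix(out[, , 1, 1], 28, 28)
}

#' Run the discriminator once
#'
#' @param model a `cgan_model`.
#' @param image 28 x 28 matrix (pixels in `[0, 1]`) or a `gasf_image`.
#' @param y a task label.
#' @return real-vs-fake probability, strictly inside (0, 1).
#' @export
discriminator_forward <- function(model, image, y) {
  stopifnot(inherits(model, "cgan_model"))
  if (inherits(image, "gasf_image")) image <- image$pixels
  if (!all(dim(image) == c(28, 28))) {
    stop_invalid("image must be 28 x 28 (got ",
                 paste(dim(image), collapse = " x "), ")")
  }
  X <- array(2 * image - 1, c(28, 28, 1, 1))
  p <- sigmoid(d_forward(X, one_hot(task_label(y)), model$discriminator,
                         model$geom)$logit)
  min(max(p, 1e-12), 1 - 1e-12)
}

#' Synthesize a class-balanced set of augmentation images
#'
#' Generates `round(fraction * n_train_real)` images split equally across
#' the three classes (remainder assigned round-robin by class code
#' RHT, LHT, FT), tagged with provenance `"generated"` and pixel values
#' mapped to `[0, 1]`.
#'
#' @param model a trained `cgan_model`.
#' @param n_train_real size of the real training set the fraction refers to.
#' @param fraction augmentation fraction (>= 0); 1.1 means "110% generated".
#' @param seed integer seed for the latent draws.
#' @return a `gasf_dataset` (train split) of generated images.
#' @export
synthesize <- function(model, n_train_real, fraction, seed = 1L) {
  stopifnot(inherits(model, "cgan_model"))
  if (fraction < 0) stop_invalid("fraction must be >= 0")
  n <- as.integer(round(fraction * n_train_real))
  base <- n %/% 3L; rem <- n %% 3L
  counts <- base + as.integer(0:2 < rem)
  labels <- task_label(rep(0:2, counts))
  if (n == 0) return(gasf_dataset(list(), "train"))
  with_seed(seed, {
    z <- matrix(rnorm(n * model$latent_dim), n)
  })
  images <- vector("list", n)
  done <- 0L
  while (done < n) {
    take <- seq(done + 1L, min(done + 64L, n))
    out <- g_forward(z[take, , drop = FALSE], one_hot(labels[take]),
                     model$generator, model$g_state, model$geom,
                     training = FALSE)$out
    for (j in seq_along(take)) {
      px <- pmin(pmax((out[, , 1, j] + 1) / 2, 0), 1)
      images[[take[j]]] <- structure(
        list(pixels = px, label = labels[take[j]], provenance = "generated"),
        class = "gasf_image")
    }
    done <- done + length(take)
  }
  gasf_dataset(images, "train")
}

#' Tidy the training history of a conditional GAN
#' @param x a `cgan_model`.
#' @param ... unused.
#' @return the per-step history tibble.
#' @export
tidy.cgan_model <- function(x, ...) x$history

#' @export
print.cgan_model <- function(x, ...) {
  cat("<cgan_model> latent dim ", x$latent_dim, ", ",
      nrow(x$history), " training steps; final d_loss ",
      round(tail(x$history$d_loss, 1), 3), ", g_loss ",
      round(tail(x$history$g_loss, 1), 3), "\n", sep = "")
  invisible(x)
}

#' Loss curves of a trained conditional GAN
#' @param object a `cgan_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cgan_model <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history[c("step", "d_loss", "g_loss", "d_accuracy")],
    -"step", names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$step, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "training step", y = NULL,
                  title = "Conditional GAN training history") +
    ggplot2::theme_minimal()
}

#' Train a small discriminator on a known 1-D two-sample problem
#'
#' Fits a one-hidden-layer network with a logistic output to distinguish
#' samples of a "real" density from samples of a "generator" density. At
#' the optimum the discriminator equals `p_r(x) / (p_r(x) + p_g(x))`, which
#' is what this helper is used to verify empirically on densities known in
#' closed form.
#'
#' @param x_real,x_fake numeric samples from the two densities.
#' @param hidden hidden-layer width.
#' @param steps full-batch training steps.
#' @param lr learning rate.
#' @param seed integer seed.
#' @return function mapping numeric x to the estimated probability.
#' @export
toy_discriminator <- function(x_real, x_fake, hidden = 16, steps = 2000,
                              lr = 0.05, seed = 1L) {
  x <- matrix(c(x_real, x_fake), ncol = 1)
  t_lab <- c(rep(1, length(x_real)), rep(0, length(x_fake)))
  n <- nrow(x)
  with_seed(seed, {
    p <- list(W1 = matrix(rnorm(hidden, sd = 1), 1), b1 = rep(0, hidden),
              W2 = matrix(rnorm(hidden, sd = 1 / sqrt(hidden)), hidden, 1),
              b2 = 0)
    opt <- opt_init(p, "adam", lr = lr)
    for (s in seq_len(steps)) {
      H <- tanh(sweep(x %*% p$W1, 2, p$b1, "+"))
      logit <- as.vector(H %*% p$W2 + p$b2)
      pr <- sigmoid(logit)
      dlogit <- (pr - t_lab) / n
      dW2 <- crossprod(H, matrix(dlogit)); db2 <- sum(dlogit)
      dH <- matrix(dlogit) %*% t(p$W2) * (1 - H^2)
      g <- list(W1 = crossprod(x, dH), b1 = colSums(dH), W2 = dW2, b2 = db2)
      st <- opt_step(opt, p, g); opt <- st$opt; p <- st$params
    }
  })
  function(xx) {
    H <- tanh(sweep(matrix(xx, ncol = 1) %*% p$W1, 2, p$b1, "+"))
    sigmoid(as.vector(H %*% p$W2 + p$b2))
  }
}
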