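# CNN task classifier: 18 counted layers -- input, four
# convolution/batch-norm/max-pool blocks, two fully connected layers each
# followed by dropout, and a 3-way softmax output. Trained with categorical
# cross-entropy plus an l2 kernel penalty, plateau learning-rate decay and
# early stopping.

#' Configuration for the CNN task classifier
#'
#' @param filters convolution filter counts of the four blocks; with 2x2
#'   pooling the 28x28 input shrinks 28 -> 14 -> 7 -> 3 -> 1.
#' @param kernel odd convolution kernel size (same-padding).
#' @param dense widths of the two fully connected layers.
#' @param dropout dropout rate on the fully connected layers, in [0, 1).
#' @param l2 l2 kernel-penalty strength (applied to every convolution and
#'   hidden dense kernel; the output layer is exempt). 0.5 is the strict
#'   small-sample default, relaxed as augmentation grows (see
#'   [augmentation_sweep()]).
#' @param batch_size minibatch size (4 by default: small batches act as a
#'   regularizer at these sample sizes).
#' @param optimizer `"rmsprop"` (default) or `"adam"`.
#' @param lr initial learning rate.
#' @param plateau_factor,plateau_patience multiply `lr` by the factor when
#'   the validation loss has not improved for this many epochs.
#' @param early_patience stop after this many epochs without validation
#'   improvement; the best weights are restored.
#' @param max_epochs epoch cap.
#' @param seed integer seed (initialization, shuffling, dropout).
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(filters = c(16, 32, 64, 128), kernel = 3,
                       dense = c(128, 64), dropout = 0.3, l2 = 0.5,
                       batch_size = 4, optimizer = c("rmsprop", "adam"),
                       lr = 1e-3, plateau_factor = 0.5, plateau_patience = 4,
                       early_patience = 8, max_epochs = 30, seed = 1L) {
  if (dropout < 0 || dropout >= 1) stop_invalid("dropout must lie in [0, 1)")
  if (l2 < 0) stop_invalid("l2 must be >= 0")
  if (batch_size < 1) stop_invalid("batch_size must be >= 1")
  if (kernel %% 2 != 1) stop_invalid("kernel must be odd")
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 dense = as.integer(dense), dropout = dropout, l2 = l2,
                 batch_size = as.integer(batch_size),
                 optimizer = match.arg(optimizer), lr = lr,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_patience = as.integer(early_patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "cnn_config")
}

cnn_init <- function(cfg) {
  f <- cfg$filters; k <- cfg$kernel; d <- cfg$dense
  he <- function(fan_in, ...) array(rnorm(prod(c(...)), sd = sqrt(2 / fan_in)), c(...))
  cin <- c(1, f[1], f[2], f[3])
  sides <- c(28, 14, 7, 3)
  params <- list(); states <- list(); geom <- list()
  for (i in 1:4) {
    params[[paste0("c", i, "_W")]] <- he(k * k * cin[i], k * k * cin[i], f[i])
    params[[paste0("c", i, "_b")]] <- rep(0, f[i])
    bn <- bn_init(f[i])
    params[[paste0("bn", i, "_gamma")]] <- bn$gamma
    params[[paste0("bn", i, "_beta")]] <- bn$beta
    states[[paste0("bn", i)]] <- bn$state
    geom[[i]] <- conv_geom(sides[i], sides[i], cin[i], k, 1, (k - 1) / 2)
  }
  params$fcA_W <- he(f[4], f[4], d[1]); params$fcA_b <- rep(0, d[1])
  params$fcB_W <- he(d[1], d[1], d[2]); params$fcB_b <- rep(0, d[2])
  params$out_W <- he(d[2], d[2], 3); params$out_b <- rep(0, 3)
  list(params = params, states = states, geom = geom)
}

# Kernels subject to the l2 penalty (output layer exempt).
L2_KERNELS <- c("c1_W", "c2_W", "c3_W", "c4_W", "fcA_W", "fcB_W")

cnn_forward <- function(X, params, states, geom, training = FALSE,
                        dropout = 0) {
  cache <- list(blocks = vector("list", 4))
  A <- X
  for (i in 1:4) {
    cv <- conv_fwd(A, params[[paste0("c", i, "_W")]],
                   params[[paste0("c", i, "_b")]], geom[[i]])
    bn <- bn_fwd(cv$Y, params[[paste0("bn", i, "_gamma")]],
                 params[[paste0("bn", i, "_beta")]],
                 states[[paste0("bn", i)]], training)
    states[[paste0("bn", i)]] <- bn$state
    R <- relu(bn$Y)
    mp <- maxpool_fwd(R)
    cache$blocks[[i]] <- list(cv = cv, bn = bn, R_in = bn$Y, mp = mp)
    A <- mp$Y
  }
  N <- dim(A)[4]
  flat <- t(matrix(A, length(A) / N, N))
  hA_pre <- flat %*% params$fcA_W
  hA_pre <- hA_pre + rep(params$fcA_b, each = nrow(hA_pre))
  hA <- relu(hA_pre)
  if (training && dropout > 0) {
    mA <- matrix(runif(length(hA)) >= dropout, nrow(hA)) / (1 - dropout)
    hA <- hA * mA
  } else mA <- NULL
  hB_pre <- hA %*% params$fcB_W
  hB_pre <- hB_pre + rep(params$fcB_b, each = nrow(hB_pre))
  hB <- relu(hB_pre)
  if (training && dropout > 0) {
    mB <- matrix(runif(length(hB)) >= dropout, nrow(hB)) / (1 - dropout)
    hB <- hB * mB
  } else mB <- NULL
  logits <- hB %*% params$out_W
  logits <- logits + rep(params$out_b, each = nrow(logits))
  probs <- softmax_rows(logits)
  cache <- c(cache, list(flat = flat, hA_pre = hA_pre, hA = hA, mA = mA,
                         hB_pre = hB_pre, hB = hB, mB = mB,
                         Adim = dim(A), N = N))
  list(probs = probs, logits = logits, cache = cache, states = states)
}

cnn_backward <- function(dlogits, cache, params, geom) {
  g <- list()
  g$out_W <- crossprod(cache$hB, dlogits); g$out_b <- colSums(dlogits)
  dhB <- tcrossprod(dlogits, params$out_W)
  if (!is.null(cache$mB)) dhB <- dhB * cache$mB
  dhB <- relu_bwd(dhB, cache$hB_pre)
  g$fcB_W <- crossprod(cache$hA, dhB); g$fcB_b <- colSums(dhB)
  dhA <- tcrossprod(dhB, params$fcB_W)
  if (!is.null(cache$mA)) dhA <- dhA * cache$mA
  dhA <- relu_bwd(dhA, cache$hA_pre)
  g$fcA_W <- crossprod(cache$flat, dhA); g$fcA_b <- colSums(dhA)
  dflat <- tcrossprod(dhA, params$fcA_W)
  dA <- array(t(dflat), cache$Adim)
  for (i in 4:1) {
    blk <- cache$blocks[[i]]
    dR <- maxpool_bwd(dA, blk$mp$cache)
    dbn <- relu_bwd(dR, blk$R_in)
    bb <- bn_bwd(dbn, params[[paste0("bn", i, "_gamma")]], blk$bn$cache)
    g[[paste0("bn", i, "_gamma")]] <- bb$dgamma
    g[[paste0("bn", i, "_beta")]] <- bb$dbeta
    cb <- conv_bwd(bb$dX, params[[paste0("c", i, "_W")]], geom[[i]],
                   blk$cv$cache)
    g[[paste0("c", i, "_W")]] <- cb$dW
    g[[paste0("c", i, "_b")]] <- cb$db
    dA <- cb$dX
  }
  g
}

cnn_eval <- function(params, states, geom, X, Y1h, l2) {
  out <- cnn_forward(X, params, states, geom, training = FALSE)
  p <- pmax(out$probs, 1e-12)
  ce <- -mean(log(p[cbind(seq_len(nrow(Y1h)), max.col(Y1h))]))
  pen <- l2 * sum(vapply(L2_KERNELS, function(nm)
    sum(params[[nm]]^2), numeric(1)))
  acc <- mean(max.col(out$probs, ties.method = "first") == max.col(Y1h))
  list(loss = ce + pen, ce = ce, acc = acc)
}

#' Train the CNN task classifier
#'
#' Categorical cross-entropy with an l2 kernel penalty, minibatch training
#' (RMSprop by default), learning-rate reduction on validation-loss
#' plateau, early stopping, and restoration of the best validation
#' weights. The validation set must contain only real images: augmentation
#' never contaminates evaluation data.
#'
#' @param train,val `gasf_dataset`s; `train` may mix real and generated
#'   images, `val` must be all real.
#' @param config a [cnn_config()].
#' @return object of class `cnn_classifier` with fitted weights, the
#'   configuration, and a per-epoch `history` tibble.
#' @export
train_classifier <- function(train, val, config = cnn_config()) {
  stopifnot(inherits(train, "gasf_dataset"), inherits(val, "gasf_dataset"))
  if (length(train) == 0 || length(val) == 0) {
    stop_invalid("train and val must be non-empty")
  }
  if (any(dataset_provenance(val) == "generated")) {
    stop_invalid("validation/evaluation data must be real only; found ",
                 "generated images in val [code TEST_PURITY]")
  }
  X <- dataset_array(train, "unit")
  Y <- one_hot(dataset_labels(train))
  Xv <- dataset_array(val, "unit")
  Yv <- one_hot(dataset_labels(val))
  n <- length(train)
  with_seed(config$seed, {
    net <- cnn_init(config)
    params <- net$params; states <- net$states; geom <- net$geom
    opt <- opt_init(params, ifelse(config$optimizer == "adam", "adam", "rmsprop"),
                    lr = config$lr)
    lr <- config$lr
    best <- list(loss = Inf, params = params, states = states, epoch = 0L)
    wait_plateau <- 0L; wait_stop <- 0L
    hist <- list()
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_n <- 0L; ep_correct <- 0L
      for (b0 in seq(1, n, by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1, n)]
        Xb <- X[, , , bi, drop = FALSE]
        Yb <- Y[bi, , drop = FALSE]
        fw <- cnn_forward(Xb, params, states, geom, training = TRUE,
                          dropout = config$dropout)
        states <- fw$states
        p <- pmax(fw$probs, 1e-12)
        ce <- -mean(log(p[cbind(seq_along(bi), max.col(Yb))]))
        dlogits <- (fw$probs - Yb) / length(bi)
        grads <- cnn_backward(dlogits, fw$cache, params, geom)
        if (config$l2 > 0) {
          for (nm in L2_KERNELS) grads[[nm]] <- grads[[nm]] + 2 * config$l2 * params[[nm]]
        }
        opt$lr <- lr
        st <- opt_step(opt, params, grads); opt <- st$opt; params <- st$params
        ep_loss <- ep_loss + ce * length(bi); ep_n <- ep_n + length(bi)
        ep_correct <- ep_correct +
          sum(max.col(fw$probs, ties.method = "first") == max.col(Yb))
      }
      ev <- cnn_eval(params, states, geom, Xv, Yv, config$l2)
      hist[[ep]] <- tibble::tibble(
        epoch = ep, train_loss = ep_loss / ep_n, train_acc = ep_correct / ep_n,
        val_loss = ev$loss, val_ce = ev$ce, val_acc = ev$acc, lr = lr)
      if (ev$loss < best$loss - 1e-5) {
        best <- list(loss = ev$loss, params = params, states = states,
                     epoch = ep)
        wait_plateau <- 0L; wait_stop <- 0L
      } else {
        wait_plateau <- wait_plateau + 1L
        wait_stop <- wait_stop + 1L
        if (wait_plateau >= config$plateau_patience) {
          lr <- lr * config$plateau_factor
          wait_plateau <- 0L
        }
        if (wait_stop >= config$early_patience) break
      }
    }
    structure(list(params = best$params, states = best$states, geom = geom,
                   config = config, best_epoch = best$epoch,
                   history = dplyr::bind_rows(hist)),
              class = "cnn_classifier")
  })
}

#' Predict task probabilities for GASF images
#'
#' Inference is deterministic: dropout is off and batch normalization uses
#' running statistics. Each probability row sums to one; the hard label is
#' the arg-max, with ties broken toward the lowest class code.
#'
#' @param object a `cnn_classifier`.
#' @param images a `gasf_dataset` or a `[28, 28, 1, N]` array in `[0, 1]`.
#' @param ... unused.
#' @return tibble with columns `.prob_RHT`, `.prob_LHT`, `.prob_FT` and
#'   `.pred` (factor).
#' @export
predict.cnn_classifier <- function(object, images, ...) {
  X <- if (inherits(images, "gasf_dataset")) dataset_array(images, "unit")
       else images
  if (length(dim(X)) != 4 || !all(dim(X)[1:3] == c(28, 28, 1))) {
    stop_invalid("images must be 28 x 28 x 1 (got ",
                 paste(dim(X), collapse = " x "), ")")
  }
  n <- dim(X)[4]
  probs <- matrix(0, n, 3)
  for (b0 in seq(1, n, by = 64)) {
    bi <- b0:min(b0 + 63, n)
    probs[bi, ] <- cnn_forward(X[, , , bi, drop = FALSE], object$params,
                               object$states, object$geom,
                               training = FALSE)$probs
  }
  tibble::tibble(
    .prob_RHT = probs[, 1], .prob_LHT = probs[, 2], .prob_FT = probs[, 3],
    .pred = task_label(max.col(probs, ties.method = "first") - 1L)
  )
}

#' @export
print.cnn_classifier <- function(x, ...) {
  h <- x$history
  cat("<cnn_classifier> trained ", nrow(h), " epochs (best at ",
      x$best_epoch, "); best val accuracy ",
      round(max(h$val_acc), 3), "\n", sep = "")
  invisible(x)
}

#' Tidy per-epoch training history of the classifier
#' @param x a `cnn_classifier`.
#' @param ... unused.
#' @export
tidy.cnn_classifier <- function(x, ...) x$history

#' One-row summary of a trained classifier
#' @param x a `cnn_classifier`.
#' @param ... unused.
#' @export
glance.cnn_classifier <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), best_epoch = x$best_epoch,
                 best_val_loss = min(h$val_loss),
                 best_val_acc = h$val_acc[which.min(h$val_loss)],
                 final_lr = tail(h$lr, 1),
                 l2 = x$config$l2, dropout = x$config$dropout)
}

#' Hyperparameter search space for the classifier
#'
#' @param dropout,optimizer,kernel,dense1,dense2 candidate sets.
#' @param budget number of random trials.
#' @param seed search seed.
#' @return object of class `search_space`.
#' @export
search_space <- function(dropout = c(0.2, 0.3, 0.5),
                         optimizer = c("rmsprop", "adam"),
                         kernel = c(3, 5),
                         dense1 = c(64, 128), dense2 = c(32, 64),
                         budget = 5, seed = 1L) {
  sets <- list(dropout = dropout, optimizer = optimizer, kernel = kernel,
               dense1 = dense1, dense2 = dense2)
  if (any(lengths(sets) == 0)) stop_invalid("candidate sets must be non-empty")
  if (budget < 1) stop_invalid("budget must be >= 1")
  structure(c(sets, list(budget = as.integer(budget), seed = as.integer(seed))),
            class = "search_space")
}

#' Random hyperparameter search
#'
#' Samples `budget` configurations uniformly from the space (with the
#' space's seed), trains each on `train`, scores validation accuracy, and
#' returns the best configuration (ties favor the earlier trial).
#'
#' @param space a [search_space()].
#' @param train,val `gasf_dataset`s.
#' @param base_config [cnn_config()] supplying every field the space does
#'   not sample.
#' @return list with `best_config`, `best_accuracy`, and a `trials` tibble.
#' @export
random_search <- function(space, train, val, base_config = cnn_config()) {
  stopifnot(inherits(space, "search_space"))
  pick <- function(v) v[sample.int(length(v), 1)]
  draws <- with_seed(space$seed, {
    purrr::map(seq_len(space$budget), function(i) list(
      dropout = pick(space$dropout),
      optimizer = pick(space$optimizer),
      kernel = pick(space$kernel),
      dense1 = pick(space$dense1),
      dense2 = pick(space$dense2)
    ))
  })
  trials <- purrr::imap(draws, function(d, i) {
    cfg <- cnn_config(filters = base_config$filters, kernel = d$kernel,
                      dense = c(d$dense1, d$dense2), dropout = d$dropout,
                      l2 = base_config$l2, batch_size = base_config$batch_size,
                      optimizer = d$optimizer, lr = base_config$lr,
                      plateau_factor = base_config$plateau_factor,
                      plateau_patience = base_config$plateau_patience,
                      early_patience = base_config$early_patience,
                      max_epochs = base_config$max_epochs,
                      seed = derive_seed(base_config$seed, paste0("trial", i)))
    fit <- train_classifier(train, val, cfg)
    tibble::tibble(trial = i, dropout = d$dropout, optimizer = d$optimizer,
                   kernel = d$kernel, dense1 = d$dense1, dense2 = d$dense2,
                   val_accuracy = max(fit$history$val_acc[
                     which(fit$history$val_loss == min(fit$history$val_loss))]),
                   config = list(cfg))
  })
  trials <- dplyr::bind_rows(trials)
  best_i <- which.max(trials$val_accuracy)
  list(best_config = trials$config[[best_i]],
       best_accuracy = trials$val_accuracy[best_i],
       trials = trials)
}
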