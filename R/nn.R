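# Minimal neural-network primitives used by the conditional GAN and the CNN
# classifier. Images are [H, W, C, N] arrays; dense activations are N x D
# matrices. Convolutions run as one BLAS matmul per layer via im2col with
# precomputed index maps; transposed convolutions reuse the same geometry
# with the roles of input and output swapped (scatter-add instead of gather).
# All layers have exact analytic gradients, verified against finite
# differences in the test suite.

# ---- geometry ---------------------------------------------------------------

# Index map for a convolution from [H, W, C] to [Ho, Wo]. pad is
# c(top, bottom, left, right). idx[p, q] is the linear index into the padded
# [Hp, Wp, C] volume feeding output position p (row-major over Ho then Wo)
# through kernel tap q (kh, then kw, then channel).
conv_geom <- function(H, W, C, k, stride, pad) {
  if (length(pad) == 1) pad <- rep(pad, 4)
  Hp <- H + pad[1] + pad[2]; Wp <- W + pad[3] + pad[4]
  Ho <- (Hp - k) %/% stride + 1L; Wo <- (Wp - k) %/% stride + 1L
  oh <- rep(seq_len(Ho), times = Wo); ow <- rep(seq_len(Wo), each = Ho)
  kh <- rep(seq_len(k), times = k * C)
  kw <- rep(rep(seq_len(k), each = k), times = C)
  kc <- rep(seq_len(C), each = k * k)
  ih <- outer((oh - 1) * stride, kh, "+")           # (HoWo) x (kkC)
  iw <- outer((ow - 1) * stride, kw, "+")
  idx <- ih + Hp * (iw - 1) + Hp * Wp
  idx <- sweep(idx, 2, Hp * Wp * (kc - 1) - Hp * Wp, "+")
  storage.mode(idx) <- "integer"
  list(H = H, W = W, C = C, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, idx = idx)
}

pad_array <- function(X, g) {
  if (all(g$pad == 0)) return(X)
  d <- dim(X)
  Xp <- array(0, c(g$Hp, g$Wp, d[3], d[4]))
  Xp[g$pad[1] + seq_len(d[1]), g$pad[3] + seq_len(d[2]), , ] <- X
  Xp
}

unpad_array <- function(Xp, g, C, N) {
  if (all(g$pad == 0)) return(Xp)
  Xp[g$pad[1] + seq_len(g$H), g$pad[3] + seq_len(g$W), , , drop = FALSE]
}

# Gather: padded input -> (HoWo * N) x (kkC) patch matrix.
im2col <- function(X, g) {
  N <- dim(X)[4]
  Xp <- pad_array(X, g)
  Xm <- matrix(Xp, ncol = N)
  .im2col_cpp(Xm, g$idx, N)
}

# Scatter-add: (HoWo * N) x (kkC) patch-gradient matrix -> [H, W, C, N].
col2im <- function(cols, g, N) {
  acc <- .col2im_cpp(cols, g$idx, g$Hp * g$Wp * g$C, N)
  dim(acc) <- c(g$Hp, g$Wp, g$C, N)
  unpad_array(acc, g, g$C, N)
}

# ---- layers -----------------------------------------------------------------

# Convolution. W: (kkC x F), b: length F.
conv_fwd <- function(X, W, b, g) {
  N <- dim(X)[4]
  cols <- im2col(X, g)
  Y <- cols %*% W
  Y <- Y + rep(b, each = nrow(Y))
  Y <- .mat_to_img(Y, g$Ho, g$Wo, ncol(W), N)
  list(Y = Y, cache = list(cols = cols, N = N))
}

conv_bwd <- function(dY, W, g, cache) {
  N <- cache$N
  dYm <- .img_to_mat(dY)
  dW <- crossprod(cache$cols, dYm)
  db <- colSums(dYm)
  dcols <- tcrossprod(dYm, W)
  dX <- col2im(dcols, g, N)
  list(dX = dX, dW = dW, db = db)
}

# Transposed convolution from [h, w, Cin] to [H, W, Cout]; g is the geometry
# of the *reverse* convolution ([H, W, Cout] -> [h, w]). W: (kkCout x Cin).
tconv_fwd <- function(X, W, b, g) {
  d <- dim(X); N <- d[4]
  Xm <- .img_to_mat(X)                       # (hwN) x Cin
  cols <- tcrossprod(Xm, W)                  # (hwN) x (kkCout)
  Y <- col2im(cols, g, N)
  # per-channel bias, exploiting [H, W, C, N] column-major layout
  Y <- Y + rep(b, each = g$H * g$W)
  list(Y = Y, cache = list(Xm = Xm, N = N, din = d))
}

tconv_bwd <- function(dY, W, g, cache) {
  N <- cache$N
  cols <- im2col(dY, g)                      # (hwN) x (kkCout)
  dXm <- cols %*% W                          # (hwN) x Cin
  dW <- crossprod(cols, cache$Xm)
  db <- colSums(.img_to_mat(dY))
  d <- cache$din
  dX <- .mat_to_img(dXm, d[1], d[2], d[3], N)
  list(dX = dX, dW = dW, db = db)
}

# Batch normalization over the channel axis (dim 3 of a 4-d array, or the
# columns of a matrix). Functional: returns the updated running state.
bn_fwd <- function(X, gamma, beta, state, training, momentum = 0.9, eps = 1e-5) {
  conv_mode <- length(dim(X)) == 4
  if (conv_mode) {
    d <- dim(X)
    Xm <- .img_to_mat(X)
  } else Xm <- X
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean; v <- state$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- .col_affine(Xm, ivar, -mu * ivar)
  Ym <- .col_affine(xhat, gamma, beta)
  Y <- if (conv_mode) .mat_to_img(Ym, d[1], d[2], d[3], d[4]) else Ym
  list(Y = Y, state = state,
       cache = list(xhat = xhat, ivar = ivar, conv_mode = conv_mode,
                    d = if (conv_mode) d else dim(X)))
}

bn_bwd <- function(dY, gamma, cache) {
  dYm <- if (cache$conv_mode) .img_to_mat(dY) else dY
  m <- nrow(dYm)
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- .col_affine(dYm, gamma, numeric(length(gamma)))
  dXm <- .bn_bwd_core(dxhat, xhat, colSums(dxhat) / m,
                      colSums(dxhat * xhat) / m, cache$ivar)
  dX <- if (cache$conv_mode) {
    d <- cache$d
    .mat_to_img(dXm, d[1], d[2], d[3], d[4])
  } else dXm
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       state = list(mean = rep(0, C), var = rep(1, C)))
}

# 2x2 max pooling with stride 2 (floor semantics on odd sides).
maxpool_fwd <- function(X) {
  d <- dim(X)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  ri <- seq_len(2 * H2); ci <- seq_len(2 * W2)
  s00 <- X[ri[c(TRUE, FALSE)], ci[c(TRUE, FALSE)], , , drop = FALSE]
  s10 <- X[ri[c(FALSE, TRUE)], ci[c(TRUE, FALSE)], , , drop = FALSE]
  s01 <- X[ri[c(TRUE, FALSE)], ci[c(FALSE, TRUE)], , , drop = FALSE]
  s11 <- X[ri[c(FALSE, TRUE)], ci[c(FALSE, TRUE)], , , drop = FALSE]
  c00 <- s00 >= s10 & s00 >= s01 & s00 >= s11
  c10 <- !c00 & s10 >= s01 & s10 >= s11
  c01 <- !c00 & !c10 & s01 >= s11
  c11 <- !(c00 | c10 | c01)
  Y <- s00 * c00 + s10 * c10 + s01 * c01 + s11 * c11
  list(Y = Y, cache = list(c00 = c00, c10 = c10, c01 = c01, c11 = c11,
                           d = d, H2 = H2, W2 = W2))
}

maxpool_bwd <- function(dY, cache) {
  d <- cache$d
  dX <- array(0, d)
  ro <- seq_len(2 * cache$H2); co <- seq_len(2 * cache$W2)
  dX[ro[c(TRUE, FALSE)], co[c(TRUE, FALSE)], , ] <- dY * cache$c00
  dX[ro[c(FALSE, TRUE)], co[c(TRUE, FALSE)], , ] <- dY * cache$c10
  dX[ro[c(TRUE, FALSE)], co[c(FALSE, TRUE)], , ] <- dY * cache$c01
  dX[ro[c(FALSE, TRUE)], co[c(FALSE, TRUE)], , ] <- dY * cache$c11
  dX
}

relu <- function(X) pmax(X, 0)
relu_bwd <- function(dY, X) dY * (X > 0)
lrelu <- function(X, a = 0.2) ifelse(X > 0, X, a * X)
lrelu_bwd <- function(dY, X, a = 0.2) dY * ifelse(X > 0, 1, a)

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

one_hot <- function(labels, k = 3L) {
  code <- task_code(labels)
  Y <- matrix(0, length(code), k)
  Y[cbind(seq_along(code), code + 1L)] <- 1
  Y
}

# ---- optimizers -------------------------------------------------------------

opt_init <- function(params, method = c("adam", "rmsprop"), lr = 1e-3,
                     beta1 = 0.9, beta2 = 0.999, rho = 0.9, eps = 1e-8) {
  method <- match.arg(method)
  zeros <- lapply(params, function(p) p * 0)  # keeps each param's shape/type
  list(method = method, lr = lr, beta1 = beta1, beta2 = beta2, rho = rho,
       eps = eps, t = 0L, m = zeros, v = zeros)
}

opt_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (opt$method == "adam") {
      opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
      opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
      mhat <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
      vhat <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
      params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    } else {
      opt$v[[nm]] <- opt$rho * opt$v[[nm]] + (1 - opt$rho) * g^2
      params[[nm]] <- params[[nm]] - opt$lr * g / (sqrt(opt$v[[nm]]) + opt$eps)
    }
  }
  list(opt = opt, params = params)
}
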