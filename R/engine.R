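#' @useDynLib odseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- minimal CNN engine -----------------------------------------------------
#
# Feature maps are dense arrays of dim (H, W, C, N) (row, column, channel,
# batch). Layers are environments holding their weights, accumulated
# gradients (g_<name>) and, while training, the forward cache needed by the
# hand-derived backward pass. Convolutions are one GEMM over an im2col patch
# matrix; everything runs in double precision on the CPU.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  list2env(list(...), envir = e)
  e$type <- type
  class(e) <- c(paste0("od_", type), "od_layer")
  e
}

#' @keywords internal
he_init <- function(n, fan_in) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

conv_layer <- function(cin, cout, k = 1, stride = 1, pad = 0, bias = TRUE) {
  wm <- matrix(he_init(k * k * cin * cout, k * k * cin), k * k * cin, cout)
  ly <- new_layer("conv", cin = cin, cout = cout, k = k, stride = stride,
                  pad = pad, bias = bias, wm = wm,
                  params = if (bias) c("wm", "b") else "wm")
  if (bias) ly$b <- numeric(cout)
  zero_grads(list(ly))
  ly
}

conv_fwd <- function(ly, x, training = FALSE) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  stopifnot(C == ly$cin)
  cols <- im2col_cpp(x, H, W, C, N, ly$k, ly$k, ly$stride, ly$stride, ly$pad, ly$pad)
  Ho <- (H + 2 * ly$pad - ly$k) %/% ly$stride + 1L
  Wo <- (W + 2 * ly$pad - ly$k) %/% ly$stride + 1L
  y2 <- crossprod(cols, ly$wm)
  if (ly$bias) y2 <- y2 + rep(ly$b, each = nrow(y2))
  y <- aperm(array(y2, c(Ho, Wo, N, ly$cout)), c(1L, 2L, 4L, 3L))
  if (training) ly$cache <- list(cols = cols, d = c(H, W, C, N, Ho, Wo))
  y
}

conv_bwd <- function(ly, dy) {
  cc <- ly$cache
  H <- cc$d[1L]; W <- cc$d[2L]; C <- cc$d[3L]; N <- cc$d[4L]
  Ho <- cc$d[5L]; Wo <- cc$d[6L]
  dy2 <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), Ho * Wo * N, ly$cout)
  ly$g_wm <- ly$g_wm + cc$cols %*% dy2
  if (ly$bias) ly$g_b <- ly$g_b + colSums(dy2)
  dcols <- tcrossprod(ly$wm, dy2)
  ly$cache <- NULL
  col2im_cpp(dcols, H, W, C, N, ly$k, ly$k, ly$stride, ly$stride, ly$pad, ly$pad)
}

# Transposed 3x3/stride-2 convolution (output exactly doubles H and W); the
# forward pass is the adjoint of a stride-2 conv, realised with col2im.
convT_layer <- function(cin, cout, bias = TRUE) {
  k <- 3L
  wm <- matrix(he_init(k * k * cout * cin, k * k * cin), k * k * cout, cin)
  ly <- new_layer("convT", cin = cin, cout = cout, k = k, wm = wm, bias = bias,
                  params = if (bias) c("wm", "b") else "wm")
  if (bias) ly$b <- numeric(cout)
  zero_grads(list(ly))
  ly
}

convT_fwd <- function(ly, x, training = FALSE) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  stopifnot(C == ly$cin)
  xm <- matrix(aperm(x, c(3L, 1L, 2L, 4L)), C, H * W * N)
  cols <- ly$wm %*% xm
  y <- col2im_cpp(cols, 2L * H, 2L * W, ly$cout, N, ly$k, ly$k, 2L, 2L, 1L, 1L)
  if (ly$bias) y <- y + rep(ly$b, each = 4L * H * W)
  if (training) ly$cache <- list(xm = xm, d = c(H, W, C, N))
  y
}

convT_bwd <- function(ly, dy) {
  cc <- ly$cache
  H <- cc$d[1L]; W <- cc$d[2L]; C <- cc$d[3L]; N <- cc$d[4L]
  cols_dy <- im2col_cpp(dy, 2L * H, 2L * W, ly$cout, N, ly$k, ly$k, 2L, 2L, 1L, 1L)
  ly$g_wm <- ly$g_wm + tcrossprod(cols_dy, cc$xm)
  if (ly$bias) ly$g_b <- ly$g_b + rowSums(colSums(dy, dims = 2L))
  dxm <- crossprod(ly$wm, cols_dy)
  ly$cache <- NULL
  aperm(array(dxm, c(C, H, W, N)), c(2L, 3L, 1L, 4L))
}

bn_layer <- function(C, momentum = 0.1, eps = 1e-5) {
  ly <- new_layer("bn", C = C, momentum = momentum, eps = eps,
                  gamma = rep(1, C), beta = numeric(C),
                  run_mean = numeric(C), run_var = rep(1, C),
                  params = c("gamma", "beta"))
  zero_grads(list(ly))
  ly
}

bn_fwd <- function(ly, x, training = FALSE) {
  d <- dim(x)
  HW <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
  if (training) {
    m <- HW * N
    mu <- rowMeans(colMeans(x, dims = 2L))
    ex2 <- rowMeans(colMeans(x * x, dims = 2L))
    v <- pmax(ex2 - mu * mu, 0)
    ivar <- 1 / sqrt(v + ly$eps)
    xhat <- (x - rep(mu, each = HW)) * rep(ivar, each = HW)
    ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
    ly$run_var <- (1 - ly$momentum) * ly$run_var +
      ly$momentum * v * m / max(m - 1, 1)
    ly$cache <- list(xhat = xhat, ivar = ivar, HW = HW)
    xhat * rep(ly$gamma, each = HW) + rep(ly$beta, each = HW)
  } else {
    sc <- ly$gamma / sqrt(ly$run_var + ly$eps)
    sh <- ly$beta - ly$run_mean * sc
    x * rep(sc, each = HW) + rep(sh, each = HW)
  }
}

bn_bwd <- function(ly, dy) {
  cc <- ly$cache
  HW <- cc$HW
  xhat <- cc$xhat
  dxhat <- dy * rep(ly$gamma, each = HW)
  m1 <- rowMeans(colMeans(dxhat, dims = 2L))
  m2 <- rowMeans(colMeans(dxhat * xhat, dims = 2L))
  ly$g_gamma <- ly$g_gamma + rowSums(colSums(dy * xhat, dims = 2L))
  ly$g_beta <- ly$g_beta + rowSums(colSums(dy, dims = 2L))
  dx <- rep(cc$ivar, each = HW) *
    (dxhat - rep(m1, each = HW) - xhat * rep(m2, each = HW))
  ly$cache <- NULL
  dx
}

pool_layer <- function(k, stride = k, pad = 0L) {
  new_layer("pool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), params = character(0))
}

pool_fwd <- function(ly, x, training = FALSE) {
  d <- dim(x)
  r <- maxpool_fwd_cpp(x, d[1L], d[2L], d[3L], d[4L], ly$k, ly$stride, ly$pad)
  if (training) ly$cache <- list(idx = r$idx, len = length(x), d = d)
  r$y
}

pool_bwd <- function(ly, dy) {
  cc <- ly$cache
  dx <- maxpool_bwd_cpp(dy, cc$idx, cc$len)
  dim(dx) <- cc$d
  ly$cache <- NULL
  dx
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax without apply(): max.col is C-level.
softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

zero_grads <- function(layers) {
  for (ly in layers) for (p in ly$params) ly[[paste0("g_", p)]] <- 0
  invisible(NULL)
}

n_params_layer <- function(ly) {
  s <- 0L
  for (p in ly$params) s <- s + length(ly[[p]])
  s
}

# Adam with decoupled-from-nothing L2 weight decay added to the gradient
# (classic Adam + weight_decay, matching the optimisation protocol).
adam_step <- function(layers, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (ly in layers) {
    for (p in ly$params) {
      g <- ly[[paste0("g_", p)]]
      w <- ly[[p]]
      if (weight_decay > 0) g <- g + weight_decay * w
      mn <- paste0("m_", p); vn <- paste0("v_", p)
      m <- if (is.null(ly[[mn]])) 0 else ly[[mn]]
      v <- if (is.null(ly[[vn]])) 0 else ly[[vn]]
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      ly[[mn]] <- m
      ly[[vn]] <- v
      ly[[p]] <- w - lr * (m / b1t) / (sqrt(v / b2t) + eps)
    }
  }
  invisible(NULL)
}
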