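# Brute-force reference oracles, written as straight-line/looped code with no
# shared machinery with the package internals they check.

rand_map <- function(H, W, C, seed, lo = -1, hi = 1) {
  set.seed(seed)
  array(stats::runif(H * W * C, lo, hi), c(H, W, C))
}

# 1x1 convolution by explicit per-pixel loops; wm is (Cin, Cout).
conv1x1_loop <- function(X, wm, b) {
  d <- dim(X)
  cout <- length(b)
  Y <- array(0, c(d[1], d[2], cout))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (o in seq_len(cout))
    Y[i, j, o] <- sum(X[i, j, ] * wm[, o]) + b[o]
  Y
}

# Bilinear upsampling with half-pixel centres and border clamping, per pixel.
bilinear_loop <- function(X, Ho, Wo) {
  d <- dim(X)
  Y <- array(0, c(Ho, Wo, d[3]))
  for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    sy <- min(max((i - 0.5) * d[1] / Ho - 0.5, 0), d[1] - 1)
    sx <- min(max((j - 0.5) * d[2] / Wo - 0.5, 0), d[2] - 1)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- min(y0 + 1, d[1] - 1); x1 <- min(x0 + 1, d[2] - 1)
    wy <- sy - y0; wx <- sx - x0
    for (ch in seq_len(d[3]))
      Y[i, j, ch] <- X[y0 + 1, x0 + 1, ch] * (1 - wy) * (1 - wx) +
                     X[y1 + 1, x0 + 1, ch] * wy * (1 - wx) +
                     X[y0 + 1, x1 + 1, ch] * (1 - wy) * wx +
                     X[y1 + 1, x1 + 1, ch] * wy * wx
  }
  Y
}

# DsSE by brute force: for every output pixel, the softmax-weighted sum over
# all H*W value vectors, with explicit nested loops over pixel pairs.
oracle_dsse <- function(mod, F, N) {
  H <- dim(F)[1]; W <- dim(F)[2]; C <- dim(F)[3]
  Nup <- bilinear_loop(conv1x1_loop(N, mod$map$wm, mod$map$b), H, W)
  Q <- conv1x1_loop(Nup, mod$q$wm, mod$q$b)
  K <- conv1x1_loop(F, mod$k$wm, mod$k$b)
  V <- conv1x1_loop(F, mod$v$wm, mod$v$b)
  HW <- H * W
  Qf <- matrix(Q, HW, dim(Q)[3])
  Kf <- matrix(K, HW, dim(K)[3])
  Vf <- matrix(V, HW, C)
  Tf <- matrix(0, HW, C)
  for (p in seq_len(HW)) {
    s <- numeric(HW)
    for (q in seq_len(HW)) s[q] <- sum(Qf[p, ] * Kf[q, ])
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (ch in seq_len(C)) Tf[p, ch] <- sum(w * Vf[, ch])
  }
  F + array(Tf, c(H, W, C))
}

# AM gate by explicit element-wise loops.
oracle_am <- function(mod, X) {
  A <- conv1x1_loop(X, mod$c1$wm, mod$c1$b)
  A[A < 0] <- 0
  P <- 1 / (1 + exp(-conv1x1_loop(A, mod$c2$wm, mod$c2$b)))
  Y <- array(0, dim(X))
  d <- dim(X)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (ch in seq_len(d[3]))
    Y[i, j, ch] <- P[i, j, ch] * X[i, j, ch]
  list(Y = Y, P = P)
}

maxpool_loop <- function(X, k) {
  d <- dim(X)
  Y <- array(0, c(d[1] %/% k, d[2] %/% k, d[3]))
  for (i in seq_len(dim(Y)[1])) for (j in seq_len(dim(Y)[2]))
    for (ch in seq_len(d[3]))
      Y[i, j, ch] <- max(X[((i - 1) * k + 1):(i * k), ((j - 1) * k + 1):(j * k), ch])
  Y
}

# Straight-line transcription of the fusion rule
# Y_F = X5 + Y5 + (1 - P5) * (Y3' + Y4'), without the module abstraction.
oracle_msff <- function(mod, X3, X4, X5) {
  a3 <- oracle_am(mod$am3, maxpool_loop(X3, 4))
  a4 <- oracle_am(mod$am4, maxpool_loop(X4, 2))
  a5 <- oracle_am(mod$am5, X5)
  Y3p <- conv1x1_loop(a3$Y, mod$p3$wm, mod$p3$b)
  Y4p <- conv1x1_loop(a4$Y, mod$p4$wm, mod$p4$b)
  X5 + a5$Y + (1 - a5$P) * (Y3p + Y4p)
}

# Per-pixel transcription of the cross-entropy sum.
oracle_bce <- function(X, Y) {
  s <- 0
  for (i in seq_along(X)) {
    x <- min(max(X[i], 1e-7), 1 - 1e-7)
    s <- s - ((1 - Y[i]) * log(1 - x) + Y[i] * log(x))
  }
  s / length(X)
}

oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1L
    else if (pred[i, j] == 1) fp <- fp + 1L
    else if (truth[i, j] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# Zero all weights of a 1x1 conv layer inside a module (helper for identity
# and gating tests).
zero_conv <- function(ly) {
  ly$wm[] <- 0
  if (ly$bias) ly$b[] <- 0
  invisible(ly)
}

make_desk_dataset <- function(n = 12, seed = 11, mix = c(easy = 1)) {
  dir <- file.path(tempdir(), sprintf("ds_n%d_s%d_%s", n, seed,
                                      paste(names(mix), collapse = "")))
  if (!dir.exists(dir)) generate_dataset(n, mix, seed, dir)
  dir
}
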