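# ---- attention modules ------------------------------------------------------
#
# DsSE reconstructs a skip connection: the next-deeper encoder map N
# (2C channels, half resolution) is channel-mapped, bilinearly upsampled and
# used as the query against key/value projections of the current map F.
# The row-normalised similarity matrix E weights all H*W value vectors and
# the spatial response is added back residually (M = F + T).
#
# AM is a squeeze-style gate (1x1 conv -> ReLU -> 1x1 conv -> sigmoid) whose
# confidence map P multiplies the input. MsFF pools stage-3/4 maps down to
# stage-5 resolution, gates each with its own AM, projects the shallow gated
# maps to the deep width and fuses them as
#   Y_F = X5 + Y5 + (1 - P5) * (Y3' + Y4').

compressed_width <- function(C, r) {
  cr <- C %/% r
  if (cr < 1L) {
    message("attention compression ratio r = ", r, " exceeds channel width ",
            C, "; compressed width clamped to 1")
    cr <- 1L
  }
  as.integer(cr)
}

#' Construct a dual-scale semantic-enhancement (DsSE) skip module
#'
#' The module holds four 1x1 convolutions: a channel-mapping conv that brings
#' the deeper map \code{N} (2C channels) to \code{C} channels before bilinear
#' upsampling, and the query/key/value projections of a non-local attention
#' block compressed by ratio \code{r} (effective width \code{max(floor(C/r), 1)}).
#'
#' @param C Channel width of the skip feature map to reconstruct.
#' @param r Compression ratio of the query/key projections (default 16).
#' @return An opaque module object accepted by [dsse_forward()].
#' @export
dsse_module <- function(C, r = 16L) {
  stopifnot(C >= 1L, r >= 1L)
  cr <- compressed_width(C, r)
  mod <- new_layer("dsse", C = as.integer(C), r = as.integer(r), cr = cr,
                   map = conv_layer(2L * C, C, k = 1L),
                   q = conv_layer(C, cr, k = 1L),
                   k = conv_layer(C, cr, k = 1L),
                   v = conv_layer(C, C, k = 1L),
                   params = character(0))
  mod$layers <- list(mod$map, mod$q, mod$k, mod$v)
  mod
}

dsse_fwd <- function(mod, F, N, training = FALSE, keep_internals = FALSE) {
  dF <- dim(F); dN <- dim(N)
  if (dN[3L] != 2L * dF[3L] || dN[1L] * 2L != dF[1L] || dN[2L] * 2L != dF[2L])
    stop("DsSE skip is mis-wired: N must have 2x the channels and half the ",
         "spatial extent of F")
  H <- dF[1L]; W <- dF[2L]; C <- dF[3L]; Nb <- dF[4L]
  Nm <- conv_fwd(mod$map, N, training)
  Nup <- bilinear_resize_cpp(Nm, dN[1L], dN[2L], C, Nb, H, W)
  Q <- conv_fwd(mod$q, Nup, training)
  K <- conv_fwd(mod$k, F, training)
  V <- conv_fwd(mod$v, F, training)
  HW <- H * W
  M <- F
  cache <- vector("list", Nb)
  internals <- if (keep_internals) vector("list", Nb) else NULL
  for (n in seq_len(Nb)) {
    Qm <- matrix(Q[, , , n], HW, mod$cr)          # rows = query positions
    Km <- matrix(K[, , , n], HW, mod$cr)
    E <- softmax_rows(Qm %*% t(Km))               # (HW, HW), rows sum to 1
    Vm <- t(matrix(V[, , , n], HW, C))            # (C, HW)
    Tn <- Vm %*% t(E)                             # spatial response
    M[, , , n] <- M[, , , n] + array(t(Tn), c(H, W, C))
    if (training) cache[[n]] <- list(Qm = Qm, Km = Km, E = E, Vm = Vm)
    if (keep_internals)
      internals[[n]] <- list(query = Qm, key = t(Km), value = Vm, similarity = E)
  }
  if (training) mod$cache <- list(percase = cache, H = H, W = W, C = C, Nb = Nb,
                                  Hn = dN[1L], Wn = dN[2L])
  if (keep_internals) attr(M, "internals") <- internals
  M
}

dsse_bwd <- function(mod, dM) {
  cc <- mod$cache
  H <- cc$H; W <- cc$W; C <- cc$C; Nb <- cc$Nb
  HW <- H * W
  dQ <- array(0, c(H, W, mod$cr, Nb))
  dK <- array(0, c(H, W, mod$cr, Nb))
  dV <- array(0, c(H, W, C, Nb))
  for (n in seq_len(Nb)) {
    pc <- cc$percase[[n]]
    dTn <- t(matrix(dM[, , , n], HW, C))          # (C, HW)
    dVm <- dTn %*% pc$E                           # T = V E^t
    dE <- crossprod(dTn, pc$Vm)                   # (HW, HW)
    dS <- pc$E * (dE - rowSums(dE * pc$E))        # softmax backward, row-wise
    dQ[, , , n] <- array(dS %*% pc$Km, c(H, W, mod$cr))
    dK[, , , n] <- array(crossprod(dS, pc$Qm), c(H, W, mod$cr))
    dV[, , , n] <- array(t(dVm), c(H, W, C))
  }
  dF <- dM + conv_bwd(mod$k, dK) + conv_bwd(mod$v, dV)
  dNup <- conv_bwd(mod$q, dQ)
  dNm <- bilinear_resize_bwd_cpp(dNup, cc$Hn, cc$Wn, C, Nb, H, W)
  dN <- conv_bwd(mod$map, dNm)
  mod$cache <- NULL
  list(dF = dF, dN = dN)
}

#' Apply a DsSE module to a skip-connection pair
#'
#' Reconstructs the skip feature map \code{F} using its next-deeper neighbour
#' \code{N}: the similarity matrix between upsampled-\code{N} queries and
#' \code{F} keys softmax-weights all value vectors of \code{F}, and the
#' resulting spatial response is added to \code{F}.
#'
#' @param mod Module from [dsse_module()].
#' @param F Current feature map, array of dim \code{(H, W, C)}.
#' @param N Next-deeper feature map, array of dim \code{(H/2, W/2, 2C)}.
#' @param keep_internals If \code{TRUE}, attach the per-image query/key/value
#'   matrices and the row-stochastic similarity matrix as an attribute.
#' @return Array of dim \code{(H, W, C)} (same shape as \code{F}).
#' @export
dsse_forward <- function(mod, F, N, keep_internals = FALSE) {
  F4 <- add_batch(F); N4 <- add_batch(N)
  M <- dsse_fwd(mod, F4, N4, training = FALSE, keep_internals = keep_internals)
  out <- drop_batch(M)
  if (keep_internals) attr(out, "internals") <- attr(M, "internals")[[1L]]
  out
}

#' Construct an attention-module (AM) gate
#'
#' Two 1x1 convolutions (compress to \code{max(floor(C/r), 1)} channels, ReLU,
#' expand back to \code{C}) followed by a sigmoid yield a confidence map
#' \code{P} in (0,1); the gated output is \code{Y = P * X}.
#'
#' @inheritParams dsse_module
#' @return An opaque module object accepted by [am_forward()].
#' @export
am_module <- function(C, r = 16L) {
  stopifnot(C >= 1L, r >= 1L)
  cr <- compressed_width(C, r)
  mod <- new_layer("am", C = as.integer(C), r = as.integer(r), cr = cr,
                   c1 = conv_layer(C, cr, k = 1L),
                   c2 = conv_layer(cr, C, k = 1L),
                   params = character(0))
  mod$layers <- list(mod$c1, mod$c2)
  mod
}

am_fwd <- function(mod, X, training = FALSE) {
  A1 <- conv_fwd(mod$c1, X, training)
  R <- relu(A1)
  P <- sigmoid(conv_fwd(mod$c2, R, training))
  if (training) mod$cache <- list(X = X, P = P, mask = A1 > 0)
  list(Y = P * X, P = P)
}

am_bwd <- function(mod, dY, dP_extra = 0) {
  cc <- mod$cache
  dP <- dY * cc$X + dP_extra
  dA2 <- dP * cc$P * (1 - cc$P)
  dR <- conv_bwd(mod$c2, dA2)
  dX <- conv_bwd(mod$c1, dR * cc$mask) + dY * cc$P
  mod$cache <- NULL
  dX
}

#' Apply an AM gate
#'
#' @param mod Module from [am_module()].
#' @param X Feature map, array of dim \code{(H, W, C)}.
#' @return List with gated map \code{Y} and confidence map \code{P}, both of
#'   \code{X}'s shape; every entry of \code{P} is strictly inside (0, 1).
#' @export
am_forward <- function(mod, X) {
  r <- am_fwd(mod, add_batch(X), training = FALSE)
  list(Y = drop_batch(r$Y), P = drop_batch(r$P))
}

#' Construct a multiscale feature-fusion (MsFF) module
#'
#' Holds three AM gates at the native widths of encoder stages 3-5, max-pool
#' downsamplers (factor 4 for stage 3, factor 2 for stage 4) and two 1x1
#' projections that bring the gated shallow maps to the stage-5 width.
#'
#' @param C3,C4,C5 Channel widths of the stage-3/4/5 encoder outputs.
#' @param r Compression ratio shared by the three AM gates (default 16).
#' @return An opaque module object accepted by [msff_forward()].
#' @export
msff_module <- function(C3, C4, C5, r = 16L) {
  mod <- new_layer("msff", C3 = as.integer(C3), C4 = as.integer(C4),
                   C5 = as.integer(C5), r = as.integer(r),
                   pool3 = pool_layer(4L), pool4 = pool_layer(2L),
                   am3 = am_module(C3, r), am4 = am_module(C4, r),
                   am5 = am_module(C5, r),
                   p3 = conv_layer(C3, C5, k = 1L),
                   p4 = conv_layer(C4, C5, k = 1L),
                   params = character(0))
  mod$layers <- c(mod$am3$layers, mod$am4$layers, mod$am5$layers,
                  list(mod$p3, mod$p4))
  mod
}

msff_fwd <- function(mod, X3, X4, X5, training = FALSE) {
  d3 <- dim(X3); d4 <- dim(X4); d5 <- dim(X5)
  if (d3[1L] != 4L * d5[1L] || d4[1L] != 2L * d5[1L] ||
      d3[2L] != 4L * d5[2L] || d4[2L] != 2L * d5[2L])
    stop("MsFF stage wiring is wrong: X3 and X4 must be 4x and 2x the ",
         "spatial size of X5")
  D3 <- pool_fwd(mod$pool3, X3, training)
  D4 <- pool_fwd(mod$pool4, X4, training)
  a3 <- am_fwd(mod$am3, D3, training)
  a4 <- am_fwd(mod$am4, D4, training)
  a5 <- am_fwd(mod$am5, X5, training)
  Y3p <- conv_fwd(mod$p3, a3$Y, training)
  Y4p <- conv_fwd(mod$p4, a4$Y, training)
  G <- 1 - a5$P
  S34 <- Y3p + Y4p
  if (training) mod$cache <- list(G = G, S34 = S34)
  X5 + a5$Y + G * S34
}

msff_bwd <- function(mod, dYF) {
  cc <- mod$cache
  dS34 <- dYF * cc$G
  dP5 <- -dYF * cc$S34
  dD3 <- am_bwd(mod$am3, conv_bwd(mod$p3, dS34))
  dD4 <- am_bwd(mod$am4, conv_bwd(mod$p4, dS34))
  dX5 <- dYF + am_bwd(mod$am5, dYF, dP5)
  dX3 <- pool_bwd(mod$pool3, dD3)
  dX4 <- pool_bwd(mod$pool4, dD4)
  mod$cache <- NULL
  list(dX3 = dX3, dX4 = dX4, dX5 = dX5)
}

#' Fuse the three deepest encoder stages with an MsFF module
#'
#' Stage-3/4 maps are max-pooled to stage-5 resolution, each stage passes its
#' own AM gate, the shallow gated maps are projected to the stage-5 width and
#' the fusion \code{Y_F = X5 + Y5 + (1 - P5) * (Y3' + Y4')} supplements the
#' detail the deepest map lost.
#'
#' @param mod Module from [msff_module()].
#' @param X3,X4,X5 Encoder stage outputs, arrays of dim \code{(H, W, C)} with
#'   spatial sizes in ratio 4:2:1.
#' @return Array with \code{X5}'s shape.
#' @export
msff_forward <- function(mod, X3, X4, X5) {
  drop_batch(msff_fwd(mod, add_batch(X3), add_batch(X4), add_batch(X5)))
}

add_batch <- function(x) {
  stopifnot(length(dim(x)) == 3L, all(is.finite(x)))
  array(x, c(dim(x), 1L))
}

drop_batch <- function(x) array(x, dim(x)[1:3])
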