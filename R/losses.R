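# ---- joint segmentation loss ------------------------------------------------

#' Dice loss
#'
#' \code{1 - 2(sum(X*Y) + eps) / (sum(X) + sum(Y) + eps)}. The smoothing term
#' \code{eps} (default 1) keeps the loss and its gradient finite on empty
#' masks; pass \code{eps = 0} for the analytic limit.
#'
#' @param X Predicted probabilities in [0, 1].
#' @param Y Binary ground truth of the same shape.
#' @param eps Smoothing constant added to numerator and denominator.
#' @return Scalar in [0, 1).
#' @export
dice_loss <- function(X, Y, eps = 1) {
  check_pair(X, Y)
  1 - (2 * sum(X * Y) + eps) / (sum(X) + sum(Y) + eps)
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of \code{-[(1-Y) log(1-X) + Y log X]}; probabilities are
#' clipped to \code{[1e-7, 1 - 1e-7]} before the logarithms. Set
#' \code{reduction = "sum"} for the unscaled pixel sum.
#'
#' @inheritParams dice_loss
#' @param reduction \code{"mean"} (default, resolution-independent) or
#'   \code{"sum"}.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(X, Y, reduction = c("mean", "sum")) {
  check_pair(X, Y)
  reduction <- match.arg(reduction)
  Xc <- pmin(pmax(X, 1e-7), 1 - 1e-7)
  s <- -sum((1 - Y) * log(1 - Xc) + Y * log(Xc))
  if (reduction == "mean") s / length(X) else s
}

#' Joint Dice + BCE loss
#'
#' The training objective: exact sum of [dice_loss()] and [bce_loss()],
#' optimising overlap at the image level and classification at the pixel
#' level simultaneously -- the standard remedy when the foreground (the optic
#' disc) covers only a few percent of the image.
#'
#' @inheritParams bce_loss
#' @param eps Dice smoothing constant.
#' @return Scalar loss.
#' @export
total_loss <- function(X, Y, eps = 1, reduction = "mean") {
  dice_loss(X, Y, eps) + bce_loss(X, Y, reduction)
}

# Gradient of the joint loss wrt the probability map (used by the trainer,
# chained with the sigmoid derivative onto the logits).
total_loss_grad <- function(X, Y, eps = 1) {
  num <- 2 * sum(X * Y) + eps
  den <- sum(X) + sum(Y) + eps
  d_dice <- (num - 2 * Y * den) / (den * den)
  Xc <- pmin(pmax(X, 1e-7), 1 - 1e-7)
  d_bce <- (Xc - Y) / (Xc * (1 - Xc)) / length(X)
  d_bce[X < 1e-7 | X > 1 - 1e-7] <- 0
  d_dice + d_bce
}

check_pair <- function(X, Y) {
  if (!identical(dim2(X), dim2(Y)))
    stop("prediction and ground truth have mismatching shapes")
  invisible(NULL)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)
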