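# ---- network assembly -------------------------------------------------------

#' Architecture configuration
#'
#' @param variant One of \code{"baseline"} (ResNet34 U-shape),
#'   \code{"baseline_dsse"}, \code{"baseline_msff"}, \code{"afenet"} (both
#'   attention modules).
#' @param input_size Integer vector \code{(H, W)}; both must be divisible by 32.
#' @param r Compression ratio of all attention branches (default 16).
#' @param decoder_reduction Internal channel-reduction factor of every decoder
#'   block (default 4).
#' @param pretrained_encoder If \code{TRUE}, encoder weights must be supplied
#'   via \code{encoder_weights} (a checkpoint path); no weights ship with the
#'   package, so the default is random (He) initialisation.
#' @param width_multiplier Real in (0, 1]: uniform channel scaling for
#'   reduced-scale experiments. The printed parameter counts of the published
#'   variants hold only at the default 1.
#' @param encoder_weights Optional path used when \code{pretrained_encoder}.
#' @return A \code{network_config} list.
#' @export
network_config <- function(variant = c("afenet", "baseline", "baseline_dsse",
                                       "baseline_msff"),
                           input_size = c(256L, 256L), r = 16L,
                           decoder_reduction = 4L, pretrained_encoder = FALSE,
                           width_multiplier = 1, encoder_weights = NULL) {
  variant <- match.arg(variant)
  stopifnot(length(input_size) == 2L, all(input_size %% 32L == 0L),
            r >= 1L, decoder_reduction >= 1L,
            width_multiplier > 0, width_multiplier <= 1)
  base <- c(64L, 64L, 128L, 256L, 512L)
  stage_channels <- pmax(1L, as.integer(round(base * width_multiplier)))
  structure(list(variant = variant, input_size = as.integer(input_size),
                 stage_channels = stage_channels, r = as.integer(r),
                 decoder_reduction = as.integer(decoder_reduction),
                 pretrained_encoder = isTRUE(pretrained_encoder),
                 width_multiplier = width_multiplier,
                 encoder_weights = encoder_weights),
            class = "network_config")
}

use_dsse <- function(cfg) cfg$variant %in% c("baseline_dsse", "afenet")
use_msff <- function(cfg) cfg$variant %in% c("baseline_msff", "afenet")

# Basic residual block of the ResNet34 trunk (two 3x3 convs, optional 1x1
# downsample projection). Trunk convs carry no bias (BN absorbs it).
res_block <- function(cin, cout, stride = 1L) {
  blk <- new_layer("resblock", stride = stride,
                   conv1 = conv_layer(cin, cout, k = 3L, stride = stride,
                                      pad = 1L, bias = FALSE),
                   bn1 = bn_layer(cout),
                   conv2 = conv_layer(cout, cout, k = 3L, pad = 1L, bias = FALSE),
                   bn2 = bn_layer(cout),
                   params = character(0))
  blk$layers <- list(blk$conv1, blk$bn1, blk$conv2, blk$bn2)
  if (stride != 1L || cin != cout) {
    blk$convd <- conv_layer(cin, cout, k = 1L, stride = stride, bias = FALSE)
    blk$bnd <- bn_layer(cout)
    blk$layers <- c(blk$layers, list(blk$convd, blk$bnd))
  }
  blk
}

res_block_fwd <- function(blk, x, training = FALSE) {
  out <- bn_fwd(blk$bn1, conv_fwd(blk$conv1, x, training), training)
  m1 <- out > 0
  out <- bn_fwd(blk$bn2, conv_fwd(blk$conv2, out * m1, training), training)
  idn <- if (is.null(blk$convd)) x else
    bn_fwd(blk$bnd, conv_fwd(blk$convd, x, training), training)
  y <- out + idn
  m2 <- y > 0
  if (training) blk$cache <- list(m1 = m1, m2 = m2)
  y * m2
}

res_block_bwd <- function(blk, dy) {
  cc <- blk$cache
  dpre <- dy * cc$m2
  dmain <- conv_bwd(blk$conv2, bn_bwd(blk$bn2, dpre)) * cc$m1
  dx <- conv_bwd(blk$conv1, bn_bwd(blk$bn1, dmain))
  dx <- dx + if (is.null(blk$convd)) dpre else
    conv_bwd(blk$convd, bn_bwd(blk$bnd, dpre))
  blk$cache <- NULL
  dx
}

res_stage <- function(cin, cout, n_blocks, stride) {
  blocks <- vector("list", n_blocks)
  blocks[[1L]] <- res_block(cin, cout, stride)
  for (i in seq_len(n_blocks - 1L) + 1L) blocks[[i]] <- res_block(cout, cout)
  blocks
}

stage_fwd <- function(blocks, x, training = FALSE) {
  for (blk in blocks) x <- res_block_fwd(blk, x, training)
  x
}

stage_bwd <- function(blocks, dy) {
  for (blk in rev(blocks)) dy <- res_block_bwd(blk, dy)
  dy
}

# Decoder block: 1x1 reduce -> 3x3 transposed conv (x2 upsample) -> 1x1 to the
# target skip width, BN + ReLU after each conv.
dec_block <- function(cin, cout, reduction) {
  cmid <- max(1L, cin %/% reduction)
  blk <- new_layer("decblock",
                   c1 = conv_layer(cin, cmid, k = 1L), bn1 = bn_layer(cmid),
                   ct = convT_layer(cmid, cmid), bn2 = bn_layer(cmid),
                   c2 = conv_layer(cmid, cout, k = 1L), bn3 = bn_layer(cout),
                   params = character(0))
  blk$layers <- list(blk$c1, blk$bn1, blk$ct, blk$bn2, blk$c2, blk$bn3)
  blk
}

dec_block_fwd <- function(blk, x, training = FALSE) {
  a <- bn_fwd(blk$bn1, conv_fwd(blk$c1, x, training), training)
  m1 <- a > 0
  b <- bn_fwd(blk$bn2, convT_fwd(blk$ct, a * m1, training), training)
  m2 <- b > 0
  cc <- bn_fwd(blk$bn3, conv_fwd(blk$c2, b * m2, training), training)
  m3 <- cc > 0
  if (training) blk$cache <- list(m1 = m1, m2 = m2, m3 = m3)
  cc * m3
}

dec_block_bwd <- function(blk, dy) {
  cc <- blk$cache
  d <- conv_bwd(blk$c2, bn_bwd(blk$bn3, dy * cc$m3))
  d <- convT_bwd(blk$ct, bn_bwd(blk$bn2, d * cc$m2))
  d <- conv_bwd(blk$c1, bn_bwd(blk$bn1, d * cc$m1))
  blk$cache <- NULL
  d
}

#' Build a segmentation model
#'
#' Assembles the configured variant: a ResNet34 encoder (stem conv + four
#' residual stages; classifier head removed), optional DsSE reconstruction of
#' the stage-2/3/4 skip connections, optional MsFF fusion of stages 3-5
#' replacing the raw deepest map, four decoder blocks fused with the skips by
#' element-wise addition, and a head (3x3 transposed conv + two 1x1 convs)
#' that restores full resolution and emits a single-channel logit map.
#'
#' @param cfg A [network_config()].
#' @return An \code{od_model} object.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  sc <- cfg$stage_channels
  m <- new_layer("model", cfg = cfg,
                 stem_conv = conv_layer(3L, sc[1L], k = 7L, stride = 2L,
                                        pad = 3L, bias = FALSE),
                 stem_bn = bn_layer(sc[1L]),
                 stem_pool = pool_layer(3L, 2L, 1L),
                 params = character(0))
  m$stage2 <- res_stage(sc[1L], sc[2L], 3L, 1L)
  m$stage3 <- res_stage(sc[2L], sc[3L], 4L, 2L)
  m$stage4 <- res_stage(sc[3L], sc[4L], 6L, 2L)
  m$stage5 <- res_stage(sc[4L], sc[5L], 3L, 2L)
  if (use_dsse(cfg)) {
    m$dsse2 <- dsse_module(sc[2L], cfg$r)
    m$dsse3 <- dsse_module(sc[3L], cfg$r)
    m$dsse4 <- dsse_module(sc[4L], cfg$r)
  }
  if (use_msff(cfg))
    m$msff <- msff_module(sc[3L], sc[4L], sc[5L], cfg$r)
  dr <- cfg$decoder_reduction
  m$dec1 <- dec_block(sc[5L], sc[4L], dr)
  m$dec2 <- dec_block(sc[4L], sc[3L], dr)
  m$dec3 <- dec_block(sc[3L], sc[2L], dr)
  m$dec4 <- dec_block(sc[2L], sc[1L], dr)
  ch <- max(1L, sc[1L] %/% 2L)
  m$head_ct <- convT_layer(sc[1L], ch)
  m$head_bn1 <- bn_layer(ch)
  m$head_c1 <- conv_layer(ch, ch, k = 1L)
  m$head_bn2 <- bn_layer(ch)
  m$head_c2 <- conv_layer(ch, 1L, k = 1L)
  # prior-bias init: start near the foreground prior (~5%) so the early
  # optimisation does not waste steps driving the small target to background
  m$head_c2$b <- -3
  if (cfg$pretrained_encoder) {
    if (is.null(cfg$encoder_weights))
      stop("pretrained_encoder = TRUE requires `encoder_weights`; no ",
           "pretrained weights are bundled with the package")
    load_weights(m, cfg$encoder_weights)
  }
  m
}

model_layers <- function(m) {
  ls <- list(m$stem_conv, m$stem_bn)
  for (st in list(m$stage2, m$stage3, m$stage4, m$stage5))
    for (blk in st) ls <- c(ls, blk$layers)
  for (mod in list(m$dsse2, m$dsse3, m$dsse4, m$msff))
    if (!is.null(mod)) ls <- c(ls, mod$layers)
  for (blk in list(m$dec1, m$dec2, m$dec3, m$dec4)) ls <- c(ls, blk$layers)
  c(ls, list(m$head_ct, m$head_c1, m$head_c2, m$head_bn1, m$head_bn2))
}

#' Count trainable parameters
#'
#' Sums every trainable scalar: convolution weights and biases plus batch
#' normalisation scale/shift terms. Running BN statistics are not counted.
#'
#' @param model An \code{od_model}.
#' @return Integer scalar.
#' @export
count_parameters <- function(model) {
  sum(vapply(model_layers(model), n_params_layer, integer(1)))
}

model_forward <- function(m, x, training = FALSE) {
  cfg <- m$cfg
  s1 <- relu(bn_fwd(m$stem_bn, conv_fwd(m$stem_conv, x, training), training))
  if (training) m$stem_mask <- s1 > 0
  p1 <- pool_fwd(m$stem_pool, s1, training)
  s2 <- stage_fwd(m$stage2, p1, training)
  s3 <- stage_fwd(m$stage3, s2, training)
  s4 <- stage_fwd(m$stage4, s3, training)
  s5 <- stage_fwd(m$stage5, s4, training)
  skip2 <- if (use_dsse(cfg)) dsse_fwd(m$dsse2, s2, s3, training) else s2
  skip3 <- if (use_dsse(cfg)) dsse_fwd(m$dsse3, s3, s4, training) else s3
  skip4 <- if (use_dsse(cfg)) dsse_fwd(m$dsse4, s4, s5, training) else s4
  top <- if (use_msff(cfg)) msff_fwd(m$msff, s3, s4, s5, training) else s5
  f1 <- dec_block_fwd(m$dec1, top, training) + skip4
  f2 <- dec_block_fwd(m$dec2, f1, training) + skip3
  f3 <- dec_block_fwd(m$dec3, f2, training) + skip2
  f4 <- dec_block_fwd(m$dec4, f3, training) + s1
  h <- bn_fwd(m$head_bn1, convT_fwd(m$head_ct, f4, training), training)
  hm1 <- h > 0
  h2 <- bn_fwd(m$head_bn2, conv_fwd(m$head_c1, h * hm1, training), training)
  hm2 <- h2 > 0
  logits <- conv_fwd(m$head_c2, h2 * hm2, training)
  if (training) m$head_masks <- list(hm1, hm2)
  logits
}

model_backward <- function(m, dlogits) {
  cfg <- m$cfg
  d <- conv_bwd(m$head_c2, dlogits)
  d <- conv_bwd(m$head_c1, bn_bwd(m$head_bn2, d * m$head_masks[[2L]]))
  df4 <- convT_bwd(m$head_ct, bn_bwd(m$head_bn1, d * m$head_masks[[1L]]))
  ds1 <- df4
  df3 <- dec_block_bwd(m$dec4, df4)
  dskip2 <- df3
  df2 <- dec_block_bwd(m$dec3, df3)
  dskip3 <- df2
  df1 <- dec_block_bwd(m$dec2, df2)
  dskip4 <- df1
  dtop <- dec_block_bwd(m$dec1, df1)
  if (use_msff(cfg)) {
    g <- msff_bwd(m$msff, dtop)
    dX3m <- g$dX3; dX4m <- g$dX4; ds5 <- g$dX5
  } else {
    dX3m <- 0; dX4m <- 0; ds5 <- dtop
  }
  if (use_dsse(cfg)) {
    g4 <- dsse_bwd(m$dsse4, dskip4)
    g3 <- dsse_bwd(m$dsse3, dskip3)
    g2 <- dsse_bwd(m$dsse2, dskip2)
    ds5 <- ds5 + g4$dN
    ds4 <- g4$dF + g3$dN + dX4m + stage_bwd(m$stage5, ds5)
    ds3 <- g3$dF + g2$dN + dX3m + stage_bwd(m$stage4, ds4)
    ds2 <- g2$dF + stage_bwd(m$stage3, ds3)
  } else {
    ds4 <- dskip4 + dX4m + stage_bwd(m$stage5, ds5)
    ds3 <- dskip3 + dX3m + stage_bwd(m$stage4, ds4)
    ds2 <- dskip2 + stage_bwd(m$stage3, ds3)
  }
  dp1 <- stage_bwd(m$stage2, ds2)
  ds1 <- ds1 + pool_bwd(m$stem_pool, dp1)
  conv_bwd(m$stem_conv, bn_bwd(m$stem_bn, ds1 * m$stem_mask))
  m$stem_mask <- NULL
  m$head_masks <- NULL
  invisible(NULL)
}

#' Segment an image
#'
#' Runs the model in evaluation mode (batch-norm uses running statistics) and
#' thresholds the sigmoid probability map at 0.5, ties mapped to foreground.
#'
#' @param model An \code{od_model}.
#' @param image Array of dim \code{(H, W, 3)} with values in [0, 1]; H and W
#'   must be divisible by 32.
#' @return List with \code{probability} and \code{binary}, both \code{(H, W)}
#'   matrices.
#' @export
predict_mask <- function(model, image) {
  d <- dim(image)
  stopifnot(length(d) == 3L, d[3L] == 3L)
  if (any(d[1:2] %% 32L != 0L))
    stop("image height and width must be divisible by 32; resize first")
  logits <- model_forward(model, add_batch(image), training = FALSE)
  prob <- sigmoid(logits[, , 1L, 1L])
  list(probability = prob, binary = (prob >= 0.5) * 1L)
}

# ---- checkpoints ------------------------------------------------------------

layer_state <- function(ly) {
  s <- lapply(ly$params, function(p) ly[[p]])
  names(s) <- ly$params
  if (ly$type == "bn") {
    s$run_mean <- ly$run_mean
    s$run_var <- ly$run_var
  }
  s
}

#' Save model weights and the configuration that built them
#' @param model An \code{od_model}.
#' @param path Destination file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = model$cfg,
               state = lapply(model_layers(model), layer_state)), path)
  invisible(path)
}

load_weights <- function(model, path) {
  ck <- readRDS(path)
  layers <- model_layers(model)
  if (length(ck$state) != length(layers))
    stop("checkpoint does not match the model architecture")
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    st <- ck$state[[i]]
    for (p in ly$params) {
      if (length(ly[[p]]) != length(st[[p]]))
        stop("checkpoint does not match the model architecture")
      ly[[p]] <- st[[p]]
    }
    if (ly$type == "bn") {
      ly$run_mean <- st$run_mean
      ly$run_var <- st$run_var
    }
  }
  invisible(model)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path Checkpoint file.
#' @return An \code{od_model} with the stored configuration and weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg)
  ly <- model_layers(model)
  for (i in seq_along(ly)) {
    st <- ck$state[[i]]
    for (p in ly[[i]]$params) ly[[i]][[p]] <- st[[p]]
    if (ly[[i]]$type == "bn") {
      ly[[i]]$run_mean <- st$run_mean
      ly[[i]]$run_var <- st$run_var
    }
  }
  model
}
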