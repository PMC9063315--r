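# ---- synthetic fundus-like data ---------------------------------------------
#
# The generator emulates the data regime the network targets: 640x480
# neonatal fundus photographs with a bright, roughly elliptical optic disc on
# a reddish-orange background, a blurred disc boundary, uneven illumination,
# dark vessel-like curves emanating from the disc, sensor noise, and a
# low-contrast "blurred disc" difficulty tier. Images are resized to 256x256
# (bilinear) and normalised to [0, 1]; masks are resized nearest-neighbour so
# the ground truth stays binary. It is an emulation of that regime, not a
# reproduction of any clinical dataset.

NATIVE_H <- 480L
NATIVE_W <- 640L
OUT_SIZE <- 256L

#' Sample scene parameters for one synthetic fundus image
#'
#' Geometry and appearance are drawn reproducibly from \code{seed}. The disc
#' ellipse (semi-axes 25-60 px at native 640x480 scale) always lies fully
#' inside the canvas with a margin of at least 5 px, which keeps the mask
#' foreground fraction within 0.3-6\% of pixels -- the small-target regime
#' that motivates the joint Dice+BCE loss.
#'
#' @param seed Integer seed for this scene.
#' @param difficulty \code{"easy"} (obvious disc, contrast 0.7-1.0, boundary
#'   blur 1-3 px) or \code{"blurred"} (low contrast 0.15-0.3, blur 3-6 px).
#' @return A \code{scene_params} list.
#' @export
scene_params <- function(seed, difficulty = c("easy", "blurred")) {
  difficulty <- match.arg(difficulty)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old))
  set.seed(seed)
  a <- stats::runif(1, 25, 60)
  b <- stats::runif(1, 25, 60)
  m <- ceiling(max(a, b)) + 6L
  p <- list(
    canvas = c(NATIVE_H, NATIVE_W),
    disc_center = c(stats::runif(1, m, NATIVE_H - m),
                    stats::runif(1, m, NATIVE_W - m)),
    disc_axes = c(a, b),
    disc_angle = stats::runif(1, 0, 180),
    disc_contrast = if (difficulty == "easy") stats::runif(1, 0.7, 1.0)
                    else stats::runif(1, 0.15, 0.3),
    boundary_blur_sigma = if (difficulty == "easy") stats::runif(1, 1, 3)
                          else stats::runif(1, 3, 6),
    n_vessels = sample(4:7, 1),
    illumination = list(angle = stats::runif(1, 0, 2 * pi),
                        strength = stats::runif(1, 0.05, 0.25),
                        vignette = stats::runif(1, 0.1, 0.3)),
    noise_sigma = 0.02,
    difficulty = difficulty,
    seed = as.integer(seed))
  class(p) <- "scene_params"
  p
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Separable Gaussian blur by shift-and-add with replicated edges.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  blur_dim <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    acc <- 0
    for (o in -rad:rad) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      shifted <- if (along_rows) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
      acc <- acc + k[o + rad + 1L] * shifted
    }
    acc
  }
  blur_dim(blur_dim(mat, TRUE), FALSE)
}

ellipse_indicator <- function(p) {
  rr <- matrix(seq_len(NATIVE_H), NATIVE_H, NATIVE_W)
  cc <- matrix(seq_len(NATIVE_W), NATIVE_H, NATIVE_W, byrow = TRUE)
  th <- p$disc_angle * pi / 180
  dx <- cc - p$disc_center[2L]
  dy <- rr - p$disc_center[1L]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  ((u / p$disc_axes[1L])^2 + (v / p$disc_axes[2L])^2 <= 1) * 1
}

draw_vessels <- function(p) {
  ves <- matrix(0, NATIVE_H, NATIVE_W)
  n_steps <- 260L
  for (v in seq_len(p$n_vessels)) {
    th <- stats::runif(1, 0, 2 * pi)
    pos <- p$disc_center
    w <- stats::runif(1, 1.2, 2.8)
    wiggle <- stats::rnorm(n_steps, sd = 0.06)
    for (s in seq_len(n_steps)) {
      th <- th + wiggle[s]
      pos <- pos + 2 * c(sin(th), cos(th))
      r0 <- max(1L, floor(pos[1L] - w)); r1 <- min(NATIVE_H, ceiling(pos[1L] + w))
      c0 <- max(1L, floor(pos[2L] - w)); c1 <- min(NATIVE_W, ceiling(pos[2L] + w))
      if (r0 > r1 || c0 > c1) break
      ves[r0:r1, c0:c1] <- 1
    }
  }
  gaussian_blur(ves, 1.2)
}

#' Render one synthetic sample (image + binary disc mask)
#'
#' Fully deterministic given \code{params$seed}. The binary mask is exactly
#' the ellipse interior; boundary blur, illumination, vessels and noise
#' affect the image only.
#'
#' @param params A [scene_params()] object.
#' @return A \code{seg_sample} list: \code{image} (256, 256, 3) in [0, 1],
#'   \code{mask} (256, 256) binary, and \code{params}.
#' @export
generate_sample <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  if (params$disc_contrast <= 0 || params$disc_contrast > 1)
    stop("disc_contrast must be in (0, 1]")
  m <- max(params$disc_axes) + 5
  ctr <- params$disc_center
  if (ctr[1L] - m < 0 || ctr[1L] + m > NATIVE_H ||
      ctr[2L] - m < 0 || ctr[2L] + m > NATIVE_W)
    stop("disc ellipse leaves the canvas margin")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old))
  set.seed(params$seed + 1L)

  hard <- ellipse_indicator(params)
  soft <- gaussian_blur(hard, params$boundary_blur_sigma)
  ves <- draw_vessels(params)

  rr <- matrix(seq_len(NATIVE_H), NATIVE_H, NATIVE_W)
  cc <- matrix(seq_len(NATIVE_W), NATIVE_H, NATIVE_W, byrow = TRUE)
  il <- params$illumination
  lin <- (cos(il$angle) * (cc - NATIVE_W / 2) +
          sin(il$angle) * (rr - NATIVE_H / 2)) / NATIVE_W
  rad2 <- ((rr - NATIVE_H / 2)^2 + (cc - NATIVE_W / 2)^2) /
    ((NATIVE_H / 2)^2 + (NATIVE_W / 2)^2)
  light <- 1 + il$strength * lin - il$vignette * rad2

  base <- c(0.80, 0.42, 0.22)     # reddish-orange fundus background
  lift <- c(0.18, 0.38, 0.28)     # disc brightening, strongest in green
  vdim <- c(0.20, 0.45, 0.35)     # vessels darken green/blue most
  img <- array(0, c(NATIVE_H, NATIVE_W, 3L))
  for (ch in 1:3) {
    plane <- base[ch] * light + params$disc_contrast * lift[ch] * soft
    plane <- plane * (1 - vdim[ch] * ves)
    img[, , ch] <- plane + stats::rnorm(NATIVE_H * NATIVE_W, sd = params$noise_sigma)
  }
  img <- pmin(pmax(img, 0), 1)

  img256 <- bilinear_resize_cpp(array(img, c(dim(img), 1L)),
                                NATIVE_H, NATIVE_W, 3L, 1L, OUT_SIZE, OUT_SIZE)
  mask256 <- nearest_resize_cpp(array(hard, c(NATIVE_H, NATIVE_W, 1L, 1L)),
                                NATIVE_H, NATIVE_W, 1L, 1L, OUT_SIZE, OUT_SIZE)
  out <- list(image = array(img256, c(OUT_SIZE, OUT_SIZE, 3L)),
              mask = matrix(mask256, OUT_SIZE, OUT_SIZE),
              params = params)
  class(out) <- "seg_sample"
  out
}

# Floor the fractional sizes, then hand leftover samples to the groups with
# the largest fractional remainders (ties broken in the given order).
apportion <- function(n, fracs) {
  sizes <- floor(fracs * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    ord <- order(fracs * n - sizes, decreasing = TRUE)
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
  }
  as.integer(sizes)
}

#' Generate a dataset directory of synthetic image/mask pairs
#'
#' Writes \code{images/<split>/} and \code{masks/<split>/} PNG trees (8-bit;
#' mask foreground = 255) plus \code{manifest.csv}. Per-sample seeds are
#' derived from the master seed, so the dataset is bit-reproducible from
#' \code{(n, mix, seed)}.
#'
#' @param n Number of samples.
#' @param mix Named fractions over difficulties, e.g.
#'   \code{c(easy = 0.5, blurred = 0.5)}; must sum to 1.
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @param split_fracs Named train/val/test fractions (floor-then-distribute
#'   rounding).
#' @return The manifest as a \code{data.frame}, invisibly.
#' @export
generate_dataset <- function(n, mix = c(easy = 0.5, blurred = 0.5), seed,
                             out_dir,
                             split_fracs = c(train = 0.6, val = 0.2, test = 0.2)) {
  stopifnot(n >= 1L, abs(sum(mix) - 1) < 1e-8, abs(sum(split_fracs) - 1) < 1e-8)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old))
  set.seed(seed)
  diffs <- rep(names(mix), apportion(n, mix))
  diffs <- sample(diffs)
  seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  splits <- rep(names(split_fracs), apportion(n, split_fracs))

  for (sp in names(split_fracs)) {
    dir.create(file.path(out_dir, "images", sp), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks", sp), recursive = TRUE, showWarnings = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- scene_params(seeds[i], diffs[i])
    s <- generate_sample(p)
    fn <- sprintf("img_%04d.png", i)
    png::writePNG(s$image, file.path(out_dir, "images", splits[i], fn))
    png::writePNG(s$mask, file.path(out_dir, "masks", splits[i], fn))
    rows[[i]] <- data.frame(filename = fn, split = splits[i],
                            difficulty = diffs[i], seed = seeds[i],
                            center_row = p$disc_center[1L],
                            center_col = p$disc_center[2L],
                            axis_a = p$disc_axes[1L], axis_b = p$disc_axes[2L],
                            angle = p$disc_angle, contrast = p$disc_contrast,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  num <- vapply(manifest, is.numeric, logical(1))
  out <- manifest
  out[num] <- lapply(manifest[num], function(x) sprintf("%.8g", x))
  utils::write.csv(out, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

# ---- geometric augmentation -------------------------------------------------

# Inverse-mapping affine warp about the image centre. `A` maps output
# (col, row) homogeneous coords to source coords. Image uses bilinear
# sampling with edge clamping; masks use nearest with background fill.
warp_affine <- function(img, A, nearest = FALSE) {
  d <- dim(img)
  H <- d[1L]; W <- d[2L]
  xy <- cbind(rep(seq_len(W), each = H), rep(seq_len(H), W), 1)
  src <- xy %*% t(A)
  sx <- src[, 1L]; sy <- src[, 2L]
  if (nearest) {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= W & iy >= 1 & iy <= H
    ix <- pmin(pmax(ix, 1), W); iy <- pmin(pmax(iy, 1), H)
    out <- img[cbind(iy, ix)] * ok
    return(matrix(out, H, W))
  }
  sx <- pmin(pmax(sx, 1), W)
  sy <- pmin(pmax(sy, 1), H)
  x0 <- floor(sx); x1 <- pmin(x0 + 1, W)
  y0 <- floor(sy); y1 <- pmin(y0 + 1, H)
  wx <- sx - x0; wy <- sy - y0
  planes <- if (length(d) == 3L) d[3L] else 1L
  out <- array(0, dim(img))
  for (ch in seq_len(planes)) {
    pl <- if (length(d) == 3L) img[, , ch] else img
    v <- pl[cbind(y0, x0)] * (1 - wy) * (1 - wx) +
         pl[cbind(y1, x0)] * wy * (1 - wx) +
         pl[cbind(y0, x1)] * (1 - wy) * wx +
         pl[cbind(y1, x1)] * wy * wx
    if (length(d) == 3L) out[, , ch] <- matrix(v, H, W) else out <- matrix(v, H, W)
  }
  out
}

affine_matrix <- function(H, W, angle_deg = 0, scale = 1, shear_deg = 0,
                          tx = 0, ty = 0) {
  th <- angle_deg * pi / 180
  sh <- tan(shear_deg * pi / 180)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  S <- matrix(c(scale, 0, scale * sh, scale), 2L, 2L)
  M <- R %*% S
  ctr <- c((W + 1) / 2, (H + 1) / 2)
  off <- ctr + c(tx, ty) - M %*% ctr
  Mf <- rbind(cbind(M, off), c(0, 0, 1))
  solve(Mf)[1:2, ]                      # inverse map for output -> source
}

#' Online geometric augmentation of a sample
#'
#' With probability 0.5 each (independently): horizontal flip, rotation
#' uniform in [-10, 10] degrees, and a small affine perturbation (scale
#' 0.9-1.1, translation up to 5\% per axis, shear up to 5 degrees). Rotation
#' and affine are composed into a single warp applied with identical
#' geometry to the image (bilinear) and the mask (nearest), so the mask
#' stays binary.
#'
#' @param sample A \code{seg_sample}.
#' @param seed Integer seed for the transform draws.
#' @param p_flip,p_rot,p_affine Per-transform probabilities (set to 0/1 to
#'   disable/force a transform).
#' @return The augmented \code{seg_sample}.
#' @export
augment <- function(sample, seed, p_flip = 0.5, p_rot = 0.5, p_affine = 0.5) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old))
  set.seed(seed)
  img <- sample$image
  msk <- sample$mask
  H <- dim(msk)[1L]; W <- dim(msk)[2L]
  if (stats::runif(1) < p_flip) {
    img <- img[, W:1, , drop = FALSE]
    msk <- msk[, W:1, drop = FALSE]
  }
  angle <- if (stats::runif(1) < p_rot) stats::runif(1, -10, 10) else 0
  if (stats::runif(1) < p_affine) {
    scale <- stats::runif(1, 0.9, 1.1)
    shear <- stats::runif(1, -5, 5)
    tx <- stats::runif(1, -0.05, 0.05) * W
    ty <- stats::runif(1, -0.05, 0.05) * H
  } else {
    scale <- 1; shear <- 0; tx <- 0; ty <- 0
  }
  if (angle != 0 || scale != 1 || shear != 0 || tx != 0 || ty != 0) {
    A <- affine_matrix(H, W, angle, scale, shear, tx, ty)
    img <- warp_affine(img, A)
    msk <- warp_affine(msk, A, nearest = TRUE)
  }
  out <- list(image = img, mask = msk, params = sample$params)
  class(out) <- "seg_sample"
  out
}
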