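# ---- training / evaluation pipeline -----------------------------------------

#' Optimisation configuration
#'
#' Defaults follow the published protocol: Adam, initial learning rate 5e-4,
#' weight decay 1e-4, batch size 16, 100 epochs, constant learning rate, and
#' model selection by best validation Dice.
#'
#' @param lr Learning rate.
#' @param weight_decay L2 penalty added to the gradient inside Adam.
#' @param batch_size Mini-batch size.
#' @param epochs Number of epochs (fixed budget, no early stopping).
#' @param seed Seed controlling weight init, data order and augmentation.
#' @param augment_prob Per-transform augmentation probability.
#' @return A \code{train_config} list.
#' @export
train_config <- function(lr = 5e-4, weight_decay = 1e-4, batch_size = 16L,
                         epochs = 100L, seed = 1L, augment_prob = 0.5) {
  structure(list(optimizer = "adam", lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 model_selection = "best_val_dsc", device = "cpu",
                 augment_prob = augment_prob),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' A named reduced configuration for CPU-scale runs, kept distinct from the
#' full protocol so the two cannot be confused: width multiplier 0.25,
#' 128x128 inputs, 20 epochs, batch size 8, learning rate 2e-3 (a larger
#' step suits the few update steps and narrow model of a desk run).
#'
#' @param seed Seed passed through to [train_config()].
#' @param epochs,input_size,width_multiplier,batch_size,lr Profile overrides.
#' @param variant Architecture variant for the companion [network_config()].
#' @return List with elements \code{net} ([network_config()]) and
#'   \code{train} ([train_config()]).
#' @export
desk_profile <- function(seed = 1L, epochs = 20L, input_size = c(128L, 128L),
                         width_multiplier = 0.25, batch_size = 8L, lr = 2e-3,
                         variant = "afenet") {
  list(net = network_config(variant = variant, input_size = input_size,
                            width_multiplier = width_multiplier),
       train = train_config(lr = lr, batch_size = batch_size, epochs = epochs,
                            seed = seed))
}

load_png_sample <- function(img_path, mask_path, input_size) {
  img <- png::readPNG(img_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img <- img[, , 1:3, drop = FALSE]
  msk <- png::readPNG(mask_path)
  if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
  d <- dim(msk)
  if (!all(d == input_size)) {
    img <- array(bilinear_resize_cpp(array(img, c(dim(img), 1L)),
                                     d[1L], d[2L], 3L, 1L,
                                     input_size[1L], input_size[2L]),
                 c(input_size, 3L))
    msk <- matrix(nearest_resize_cpp(array(msk, c(d, 1L, 1L)),
                                     d[1L], d[2L], 1L, 1L,
                                     input_size[1L], input_size[2L]),
                  input_size[1L], input_size[2L])
  }
  out <- list(image = img, mask = (msk > 0.5) * 1, params = NULL)
  class(out) <- "seg_sample"
  out
}

load_split <- function(data_root, split, input_size) {
  img_dir <- file.path(data_root, "images", split)
  msk_dir <- file.path(data_root, "masks", split)
  files <- sort(list.files(img_dir, pattern = "\\.png$"))
  if (length(files) == 0L) stop("empty split: ", split)
  if (!all(file.exists(file.path(msk_dir, files))))
    stop("mask/image filename mismatch in split: ", split)
  samples <- lapply(files, function(f)
    load_png_sample(file.path(img_dir, f), file.path(msk_dir, f), input_size))
  names(samples) <- files
  samples
}

batch_tensors <- function(samples, idx, aug_seeds = NULL, p = 0.5) {
  n <- length(idx)
  d <- dim(samples[[1L]]$image)
  X <- array(0, c(d[1L], d[2L], 3L, n))
  Y <- array(0, c(d[1L], d[2L], 1L, n))
  for (j in seq_len(n)) {
    s <- samples[[idx[j]]]
    if (!is.null(aug_seeds))
      s <- augment(s, aug_seeds[j], p_flip = p, p_rot = p, p_affine = p)
    X[, , , j] <- s$image
    Y[, , 1L, j] <- s$mask
  }
  list(X = X, Y = Y)
}

val_dice <- function(model, samples) {
  scores <- vapply(samples, function(s) {
    pr <- predict_mask(model, s$image)
    dsc(confusion(pr$binary, s$mask))
  }, numeric(1))
  mean(scores)
}

#' Train a segmentation model
#'
#' Runs Adam on the joint Dice+BCE loss with online augmentation of the
#' training split only. Validation Dice (threshold 0.5, un-augmented images)
#' is computed after every epoch and the best-scoring weights are kept.
#' Fully seeded: weight initialisation, shuffling and augmentation all derive
#' from \code{train_cfg$seed}.
#'
#' @param data_root Dataset directory laid out as written by
#'   [generate_dataset()].
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @param run_dir Output directory for the best checkpoint and run record.
#' @param verbose Print per-epoch progress.
#' @return A run record: config snapshots, per-epoch history (train loss,
#'   validation Dice), best epoch and checkpoint path.
#' @export
train <- function(data_root, net_cfg, train_cfg, run_dir = tempfile("run"),
                  verbose = FALSE) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(train_cfg$seed)
  model <- build_model(net_cfg)
  layers <- model_layers(model)
  tr <- load_split(data_root, "train", net_cfg$input_size)
  va <- load_split(data_root, "val", net_cfg$input_size)

  n <- length(tr)
  best <- list(dsc = -Inf, epoch = 0L)
  ckpt <- file.path(run_dir, "best_model.rds")
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_dsc = numeric(0))
  step <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    for (b0 in seq(1L, n, by = train_cfg$batch_size)) {
      idx <- ord[b0:min(b0 + train_cfg$batch_size - 1L, n)]
      aug_seeds <- (train_cfg$seed + 131071L * epoch + 8191L * idx) %% 2000000000L
      bt <- batch_tensors(tr, idx, aug_seeds, train_cfg$augment_prob)
      logits <- model_forward(model, bt$X, training = TRUE)
      prob <- sigmoid(logits)
      losses <- c(losses, total_loss(prob, bt$Y))
      dlogits <- total_loss_grad(prob, bt$Y) * prob * (1 - prob)
      zero_grads(layers)
      model_backward(model, dlogits)
      step <- step + 1L
      adam_step(layers, step, train_cfg$lr,
                weight_decay = train_cfg$weight_decay)
    }
    vd <- val_dice(model, va)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(losses), val_dsc = vd))
    if (vd > best$dsc) {
      best <- list(dsc = vd, epoch = epoch)
      save_checkpoint(model, ckpt)
    }
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f  val Dsc %.4f%s",
                      epoch, mean(losses), vd,
                      if (best$epoch == epoch) "  *" else ""))
  }
  record <- list(net_cfg = net_cfg, train_cfg = train_cfg, history = hist,
                 best_epoch = best$epoch, best_val_dsc = best$dsc,
                 checkpoint = ckpt)
  jsonlite::write_json(
    list(net_cfg = net_cfg[setdiff(names(net_cfg), "encoder_weights")],
         train_cfg = unclass(train_cfg), history = hist,
         best_epoch = best$epoch, best_val_dsc = best$dsc,
         checkpoint = ckpt),
    file.path(run_dir, "run_record.json"), auto_unbox = TRUE, digits = NA)
  record
}

#' Evaluate a checkpoint on a dataset split
#'
#' Deterministic per-image Dice/sensitivity with confusion counts; optionally
#' written as CSV (plus summary row) via [write_metrics_csv()].
#'
#' @param checkpoint Path to a checkpoint or an \code{od_model}.
#' @param data_root Dataset directory.
#' @param split One of \code{"train"}, \code{"val"}, \code{"test"}.
#' @param csv Optional output CSV path.
#' @return A [metrics_report()] data frame.
#' @export
evaluate <- function(checkpoint, data_root, split = "test", csv = NULL) {
  model <- if (inherits(checkpoint, "od_layer")) checkpoint
           else load_checkpoint(checkpoint)
  samples <- load_split(data_root, split, model$cfg$input_size)
  preds <- lapply(samples, function(s) predict_mask(model, s$image)$binary)
  truths <- lapply(samples, `[[`, "mask")
  rep <- metrics_report(preds, truths, ids = names(samples))
  if (!is.null(csv)) write_metrics_csv(rep, csv)
  rep
}

#' Ablation harness over architecture variants
#'
#' Trains every requested variant on the same dataset with the same seed and
#' optimisation scheme, evaluates each on the test split, and reports a
#' comparison table (variant, Dsc, Sen, parameters in millions) plus paired
#' t-tests of the full model against every other variant on per-image Dice.
#'
#' @param data_root Dataset directory.
#' @param variants Subset of
#'   \code{c("baseline", "baseline_dsse", "baseline_msff", "afenet")}.
#' @param train_cfg A [train_config()] shared by all variants.
#' @param input_size,width_multiplier Architecture scale shared by variants.
#' @param run_dir Output directory.
#' @return List with \code{table} and \code{ttests} data frames.
#' @export
ablate <- function(data_root, variants = c("baseline", "afenet"), train_cfg,
                   input_size = c(128L, 128L), width_multiplier = 0.25,
                   run_dir = tempfile("ablate")) {
  stopifnot(all(variants %in% c("baseline", "baseline_dsse", "baseline_msff",
                                "afenet")))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  rows <- list()
  for (v in variants) {
    cfg <- network_config(variant = v, input_size = input_size,
                          width_multiplier = width_multiplier)
    rec <- train(data_root, cfg, train_cfg,
                 run_dir = file.path(run_dir, v))
    rep <- evaluate(rec$checkpoint, data_root, "test",
                    csv = file.path(run_dir, v, "test_metrics.csv"))
    model <- load_checkpoint(rec$checkpoint)
    reports[[v]] <- rep
    rows[[v]] <- data.frame(variant = v,
                            Dsc = attr(rep, "mean_dsc"),
                            Sen = attr(rep, "mean_sen"),
                            Parameters_M = round(count_parameters(model) / 1e6, 2),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tt <- NULL
  if ("afenet" %in% variants && length(variants) > 1L &&
      nrow(reports[["afenet"]]) >= 3L) {
    others <- setdiff(variants, "afenet")
    tt <- do.call(rbind, lapply(others, function(v) {
      r <- paired_t_test(reports[["afenet"]]$Dsc, reports[[v]]$Dsc)
      data.frame(comparison = paste0("afenet-", v), t = r$t, p = r$p,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(tt, file.path(run_dir, "ttests.csv"), row.names = FALSE)
  }
  utils::write.csv(tab, file.path(run_dir, "ablation.csv"), row.names = FALSE)
  list(table = tab, ttests = tt, reports = reports)
}

#' Colour overlay of a prediction against the ground truth
#'
#' Correctly segmented pixels (prediction and truth agree on foreground) are
#' drawn red, missed foreground (false negatives) yellow, and spurious
#' foreground (false positives) blue, alpha-blended (0.5) over the image.
#'
#' @param pred_mask,truth_mask Binary matrices.
#' @param image RGB array \code{(H, W, 3)} of the same spatial size.
#' @param alpha Blend weight of the overlay colours.
#' @return RGB array \code{(H, W, 3)}.
#' @export
overlay <- function(pred_mask, truth_mask, image, alpha = 0.5) {
  if (!all(pred_mask %in% c(0, 1)) || !all(truth_mask %in% c(0, 1)))
    stop("overlay() expects binary masks")
  stopifnot(identical(dim(pred_mask), dim(truth_mask)),
            identical(dim(image)[1:2], dim(pred_mask)))
  tp <- pred_mask == 1 & truth_mask == 1
  fn <- pred_mask == 0 & truth_mask == 1
  fp <- pred_mask == 1 & truth_mask == 0
  cols <- list(c(1, 0, 0), c(1, 1, 0), c(0, 0, 1))   # red, yellow, blue
  out <- image
  for (ch in 1:3) {
    pl <- image[, , ch]
    ov <- cols[[1L]][ch] * tp + cols[[2L]][ch] * fn + cols[[3L]][ch] * fp
    any_ov <- tp | fn | fp
    out[, , ch] <- ifelse(any_ov, (1 - alpha) * pl + alpha * ov, pl)
  }
  out
}
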