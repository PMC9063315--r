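# Tiny-scale configurations keep these structural tests fast; the published
# full-width parameter counts are covered by the acceptance suite.

tiny_cfg <- function(variant = "afenet", input = 64L)
  network_config(variant, input_size = c(input, input), width_multiplier = 0.125)

test_that("the variant factory controls module presence and baseline equivalence", {
  set.seed(1)
  suppressMessages({
    base <- build_model(tiny_cfg("baseline"))
    full <- build_model(tiny_cfg("afenet"))
    dss <- build_model(tiny_cfg("baseline_dsse"))
    msf <- build_model(tiny_cfg("baseline_msff"))
  })
  expect_null(base$dsse2); expect_null(base$msff)
  expect_null(dss$msff); expect_null(msf$dsse2)
  module_params <- function(mods) sum(vapply(unlist(lapply(mods, `[[`, "layers"),
                                                    recursive = FALSE),
                                             odseg:::n_params_layer, integer(1)))
  expect_identical(count_parameters(full) - module_params(
    list(full$dsse2, full$dsse3, full$dsse4, full$msff)),
    count_parameters(base))
})

test_that("DsSE parameter cost follows closed-form 1x1-conv arithmetic", {
  set.seed(2)
  base <- build_model(network_config("baseline"))
  dss <- build_model(network_config("baseline_dsse"))
  closed_form <- function(C, r = 16) {
    cr <- C %/% r
    (2 * C * C + C) + 2 * (C * cr + cr) + (C * C + C)  # map + Q + K + V
  }
  expect_equal(count_parameters(dss) - count_parameters(base),
               sum(vapply(c(64L, 128L, 256L), closed_form, numeric(1))))
})

test_that("forward pass yields full-resolution probabilities for several input sizes", {
  for (sz in c(64L, 96L)) {
    set.seed(sz)
    suppressMessages(m <- build_model(tiny_cfg("afenet", sz)))
    pr <- predict_mask(m, array(runif(sz * sz * 3), c(sz, sz, 3)))
    expect_identical(dim(pr$probability), c(sz, sz))
    expect_true(all(pr$probability >= 0 & pr$probability <= 1))
    expect_true(all(pr$binary %in% c(0, 1)))
  }
  set.seed(99)
  m <- build_model(network_config("afenet"))      # full-width, 256x256
  pr <- predict_mask(m, array(runif(256 * 256 * 3), c(256, 256, 3)))
  expect_identical(dim(pr$probability), c(256L, 256L))
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
})

test_that("prediction is deterministic, rejects bad sizes, ties go to foreground", {
  set.seed(3)
  suppressMessages(m <- build_model(tiny_cfg()))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_identical(predict_mask(m, img), predict_mask(m, img))
  expect_error(predict_mask(m, array(0.5, c(65, 65, 3))), "divisible by 32")
  m$head_c2$wm[] <- 0
  m$head_c2$b[] <- 0
  pr <- predict_mask(m, img)
  expect_true(all(pr$probability == 0.5))
  expect_true(all(pr$binary == 1))                # >= threshold rule
})

test_that("one backward pass reaches every trainable tensor", {
  set.seed(4)
  suppressMessages(m <- build_model(tiny_cfg()))
  layers <- odseg:::model_layers(m)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  Y <- array(rbinom(64 * 64 * 2, 1, 0.1), c(64, 64, 1, 2))
  logits <- odseg:::model_forward(m, x, training = TRUE)
  p <- odseg:::sigmoid(logits)
  odseg:::zero_grads(layers)
  odseg:::model_backward(m, odseg:::total_loss_grad(p, Y) * p * (1 - p))
  for (ly in layers) for (pn in ly$params)
    expect_gt(max(abs(ly[[paste0("g_", pn)]])), 0)
})

test_that("analytic gradients match finite differences through all modules", {
  set.seed(5)
  suppressMessages(m <- build_model(tiny_cfg()))
  layers <- odseg:::model_layers(m)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  Y <- array(rbinom(64 * 64, 1, 0.1), c(64, 64, 1, 1))
  loss_at <- function() {
    logits <- odseg:::model_forward(m, x, training = TRUE)
    for (ly in layers) ly$cache <- NULL
    total_loss(odseg:::sigmoid(logits), Y)
  }
  logits <- odseg:::model_forward(m, x, training = TRUE)
  p <- odseg:::sigmoid(logits)
  odseg:::zero_grads(layers)
  odseg:::model_backward(m, odseg:::total_loss_grad(p, Y) * p * (1 - p))
  set.seed(6)
  # h must be small: the loss is piecewise smooth (ReLU, max-pool argmax) and
  # larger steps flip kinks, which corrupts the finite-difference reference
  h <- 1e-6
  for (rep in 1:12) {
    li <- sample(length(layers), 1)
    if (length(layers[[li]]$params) == 0) next
    ly <- layers[[li]]
    pn <- sample(ly$params, 1)
    wi <- sample(length(ly[[pn]]), 1)
    g_an <- ly[[paste0("g_", pn)]][wi]
    orig <- ly[[pn]][wi]
    ly[[pn]][wi] <- orig + h; Lp <- loss_at()
    ly[[pn]][wi] <- orig - h; Lm <- loss_at()
    ly[[pn]][wi] <- orig
    g_fd <- (Lp - Lm) / (2 * h)
    rel <- abs(g_an - g_fd) / max(1e-4, abs(g_an), abs(g_fd))
    expect_lt(rel, 0.02,
              label = sprintf("relative gradient error of %s[%d] in layer %d (%s)",
                              pn, wi, li, ly$type))
  }
})

test_that("checkpoints round-trip weights, running stats and predictions", {
  set.seed(7)
  suppressMessages(m <- build_model(tiny_cfg()))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- suppressMessages(load_checkpoint(ck))
  expect_identical(predict_mask(m, img), predict_mask(m2, img))
  expect_error(suppressMessages(load_weights <- odseg:::load_weights(
    build_model(tiny_cfg("baseline")), ck)), "architecture")
})

test_that("pretrained encoder requires a weights file", {
  cfg <- network_config("baseline", pretrained_encoder = TRUE)
  expect_error(build_model(cfg), "encoder_weights")
})
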