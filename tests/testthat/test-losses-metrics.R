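test_that("Dice loss identities hold in the analytic eps -> 0 limit", {
  set.seed(1)
  Y <- matrix(rbinom(64, 1, 0.3), 8, 8)
  expect_equal(dice_loss(Y, Y, eps = 0), 0)
  A <- matrix(0, 4, 4); A[1:2, 1] <- 1
  B <- matrix(0, 4, 4); B[3:4, 4] <- 1
  expect_equal(dice_loss(A, B, eps = 0), 1)
  X <- matrix(0, 4, 4); X[1, 1:4] <- 1            # 4 foreground pixels
  Z <- matrix(0, 4, 4); Z[1, 1:2] <- 1; Z[2, 1:2] <- 1  # overlap 2 of 4
  expect_equal(dice_loss(X, Z, eps = 0), 0.5)
  expect_true(dice_loss(matrix(runif(16), 4), matrix(rbinom(16, 1, .5), 4)) < 1)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("BCE matches its analytic values and a per-pixel loop oracle", {
  Y <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_equal(bce_loss(matrix(0.5, 4, 4), Y), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(Y, Y), 1e-6)
  set.seed(8)
  X <- matrix(runif(16), 4, 4)
  expect_equal(bce_loss(X, Y), oracle_bce(X, Y), tolerance = 1e-8)
  expect_equal(bce_loss(X, Y, reduction = "sum"), 16 * bce_loss(X, Y))
})

test_that("the joint loss is the exact sum of its components", {
  set.seed(9)
  X <- matrix(runif(64), 8, 8)
  Y <- matrix(rbinom(64, 1, 0.2), 8, 8)
  expect_identical(total_loss(X, Y), dice_loss(X, Y) + bce_loss(X, Y))
  expect_lt(total_loss(Y, Y, eps = 0), 1e-6)
  Yh <- matrix(rep(c(0, 1), each = 32), 8, 8)
  expect_equal(total_loss(matrix(0.5, 8, 8), Yh),
               dice_loss(matrix(0.5, 8, 8), Yh) + log(2), tolerance = 1e-12)
})

test_that("the loss gradient matches finite differences", {
  set.seed(10)
  X <- matrix(runif(16, 0.05, 0.95), 4, 4)
  Y <- matrix(rbinom(16, 1, 0.3), 4, 4)
  g <- odseg:::total_loss_grad(X, Y)
  h <- 1e-6
  for (i in c(1, 7, 13)) {
    Xp <- X; Xp[i] <- X[i] + h
    Xm <- X; Xm[i] <- X[i] - h
    expect_equal(g[i], (total_loss(Xp, Y) - total_loss(Xm, Y)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("confusion counting matches the double-loop oracle and sums to n", {
  expect_identical(confusion(matrix(1, 4, 4), matrix(1, 4, 4)),
                   list(TP = 16L, FP = 0L, FN = 0L, TN = 0L))
  set.seed(11)
  truth <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_identical(confusion(1 - truth, truth)$TP, 0L)
  expect_identical(confusion(1 - truth, truth)$TN, 0L)
  pred <- matrix(rbinom(64, 1, 0.4), 8, 8)
  cts <- confusion(pred, truth)
  expect_identical(cts, oracle_confusion(pred, truth))
  expect_identical(cts$TP + cts$FP + cts$FN + cts$TN, 64L)
  expect_error(confusion(matrix(0.5, 2, 2), matrix(1, 2, 2)), "binary")
})

test_that("Dice and sensitivity formulas and edge conventions", {
  expect_equal(dsc(list(TP = 50, FP = 10, FN = 10, TN = 30)), 100 / 120)
  expect_equal(dsc(list(TP = 5, FP = 0, FN = 0, TN = 5)), 1)
  expect_equal(dsc(list(TP = 0, FP = 3, FN = 2, TN = 5)), 0)
  expect_message(v <- dsc(list(TP = 0, FP = 0, FN = 0, TN = 9)), "empty")
  expect_equal(v, 1)
  expect_equal(sen(list(TP = 8, FP = 0, FN = 2, TN = 0)), 0.8)
  expect_equal(sen(list(TP = 4, FP = 1, FN = 0, TN = 2)), 1)
  expect_equal(sen(list(TP = 0, FP = 1, FN = 6, TN = 2)), 0)
  expect_message(s <- sen(list(TP = 0, FP = 2, FN = 0, TN = 5)), "undefined")
  expect_true(is.na(s))
})

test_that("1 - dice_loss on binary masks equals Dice from confusion counts", {
  for (seed in 1:20) {
    set.seed(seed)
    a <- matrix(rbinom(100, 1, runif(1, 0.1, 0.9)), 10, 10)
    b <- matrix(rbinom(100, 1, runif(1, 0.1, 0.9)), 10, 10)
    if (sum(a) + sum(b) == 0) next
    expect_equal(1 - dice_loss(a, b, eps = 0), dsc(confusion(a, b)),
                 tolerance = 1e-9)
    expect_equal(dsc(confusion(a, b)), dsc(confusion(b, a)))
  }
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  b <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_false(isTRUE(all.equal(sen(confusion(a, b)), sen(confusion(b, a)))))
})

test_that("paired t-test detects a constant shift and honours conventions", {
  set.seed(12)
  b <- runif(5, 0.8, 0.9)
  a <- b + 0.1 + rnorm(5, sd = 1e-3)
  r <- paired_t_test(a, b)
  expect_lt(r$p, 0.05)
  # cross-check against the textbook formula on the same differences
  d <- a - b
  tt <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(r$t, tt, tolerance = 1e-12)
  expect_equal(r$p, 2 * stats::pt(-abs(tt), df = 4), tolerance = 1e-12)
  expect_message(r2 <- paired_t_test(b, b), "convention")
  expect_identical(r2$p, 1)
  expect_error(paired_t_test(1:4 / 10, 1:5 / 10), "equal length")
})

test_that("metrics report aggregates per-image rows and writes stable CSV", {
  set.seed(13)
  truths <- replicate(3, matrix(rbinom(64, 1, 0.3), 8, 8), simplify = FALSE)
  preds <- replicate(3, matrix(rbinom(64, 1, 0.3), 8, 8), simplify = FALSE)
  rep <- metrics_report(preds, truths)
  expect_equal(nrow(rep), 3L)
  expect_equal(attr(rep, "mean_dsc"), mean(rep$Dsc))
  expect_equal(attr(rep, "mean_sen"), mean(rep$Sen, na.rm = TRUE))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_metrics_csv(rep, f1)
  write_metrics_csv(rep, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(utils::read.csv(f1)), 4L)   # 3 images + summary row
})
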