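# ---- evaluation metrics -----------------------------------------------------

#' Pixel confusion counts
#'
#' @param pred,truth Same-shape 0/1 arrays.
#' @return List with integer \code{TP}, \code{FP}, \code{FN}, \code{TN}
#'   summing to the pixel count.
#' @export
confusion <- function(pred, truth) {
  check_pair(pred, truth)
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("confusion() expects binary masks")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  list(TP = tp, FP = fp, FN = fn, TN = length(pred) - tp - fp - fn)
}

#' Dice similarity coefficient from confusion counts
#'
#' \code{2 TP / (2 TP + FP + FN)}. When both masks are empty the union is
#' empty and the score is 1 by convention (reported with a message).
#'
#' @param counts List from [confusion()].
#' @return Scalar in [0, 1].
#' @export
dsc <- function(counts) {
  den <- 2 * counts$TP + counts$FP + counts$FN
  if (den == 0) {
    message("both masks empty; Dice defined as 1 by convention")
    return(1)
  }
  2 * counts$TP / den
}

#' Sensitivity (recall) from confusion counts
#'
#' \code{TP / (TP + FN)}; undefined (NA, with a message) when the ground
#' truth is empty -- such images are excluded from aggregation.
#'
#' @inheritParams dsc
#' @return Scalar in [0, 1], or NA for an empty ground truth.
#' @export
sen <- function(counts) {
  den <- counts$TP + counts$FN
  if (den == 0) {
    message("empty ground truth; sensitivity undefined (NA)")
    return(NA_real_)
  }
  counts$TP / den
}

#' Two-sided paired t-test on per-image scores
#'
#' Compares two models evaluated on the same images. Zero-variance
#' differences are handled by convention: all-zero differences give p = 1,
#' a constant non-zero shift gives p = 0 (both reported with a message).
#'
#' @param scores_a,scores_b Equal-length numeric vectors (length >= 3).
#' @return List with statistic \code{t} and p-value \code{p}.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must have equal length")
  stopifnot(length(scores_a) >= 3L)
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      message("identical scores; paired t-test p = 1 by convention")
      return(list(t = 0, p = 1))
    }
    message("constant non-zero difference; paired t-test p = 0 by convention")
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Per-image metrics table for a set of predictions
#'
#' @param preds,truths Lists of same-shape binary masks.
#' @param ids Optional image identifiers.
#' @return A \code{data.frame} (image_id, Dsc, Sen, TP, FP, FN, TN) with
#'   attributes \code{mean_dsc} and \code{mean_sen} (NA sensitivities
#'   excluded from the mean).
#' @export
metrics_report <- function(preds, truths, ids = NULL) {
  stopifnot(length(preds) == length(truths))
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    cts <- confusion(preds[[i]], truths[[i]])
    data.frame(image_id = ids[[i]], Dsc = dsc(cts), Sen = sen(cts),
               TP = cts$TP, FP = cts$FP, FN = cts$FN, TN = cts$TN,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "mean_dsc") <- mean(rep$Dsc)
  attr(rep, "mean_sen") <- mean(rep$Sen, na.rm = TRUE)
  rep
}

#' Write a metrics report as CSV with a trailing summary row
#' @param report Output of [metrics_report()].
#' @param path Destination CSV file.
#' @export
write_metrics_csv <- function(report, path) {
  out <- report
  out$Dsc <- sprintf("%.6f", out$Dsc)
  out$Sen <- ifelse(is.na(report$Sen), "NA", sprintf("%.6f", report$Sen))
  summary_row <- data.frame(image_id = "mean",
                            Dsc = sprintf("%.6f", attr(report, "mean_dsc")),
                            Sen = sprintf("%.6f", attr(report, "mean_sen")),
                            TP = sum(report$TP), FP = sum(report$FP),
                            FN = sum(report$FN), TN = sum(report$TN),
                            stringsAsFactors = FALSE)
  utils::write.csv(rbind(out, summary_row), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
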