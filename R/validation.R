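#' Count confusion matrix
#'
#' Cross-tabulates manually validated (true) against predicted per-frame bird
#' counts over aligned frame sequences.
#'
#' @param true_counts,predicted_counts equal-length integer vectors of
#'   per-frame counts.
#' @param c_max largest count indexed by the matrix; defaults to the largest
#'   observed value and never below the flock size of 6.
#' @return a \code{count_confusion}: square matrix with rows = true count
#'   0..\code{c_max}, columns = predicted count, entries summing to the
#'   number of frames.
#' @export
count_confusion <- function(true_counts, predicted_counts, c_max = NULL) {
  if (length(true_counts) != length(predicted_counts))
    stop("true and predicted count sequences differ in length")
  if (any(true_counts < 0) || any(predicted_counts < 0))
    stop("counts must be non-negative")
  c_max <- c_max %||% max(6L, true_counts, predicted_counts)
  lev <- 0:c_max
  m <- table(factor(true_counts, levels = lev),
             factor(predicted_counts, levels = lev))
  m <- unclass(as.matrix(m))
  dimnames(m) <- list(true = lev, predicted = lev)
  structure(m, class = c("count_confusion", "matrix"))
}

#' @export
print.count_confusion <- function(x, ...) {
  cat(sprintf("<count_confusion> %d frames, accuracy %.1f%%, over-count %.2f%%\n",
              sum(x), count_accuracy(x), overcount_rate(x)))
  print(unclass(x))
  invisible(x)
}

#' Exact-count accuracy
#'
#' Percentage of frames whose predicted count equals the validated count
#' (trace over total).  Report to one decimal place.
#'
#' @param m a \code{\link{count_confusion}}.
#' @return accuracy in percent (unrounded).
#' @export
count_accuracy <- function(m) {
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(unclass(m))) / total
}

#' Over-count-by-one rate
#'
#' Percentage of frames where the detector predicted exactly one bird more
#' than were present -- the signature of doorway double detections.  Report to
#' two decimal places.
#'
#' @param m a \code{\link{count_confusion}}.
#' @return rate in percent (unrounded).
#' @export
overcount_rate <- function(m) {
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  mm <- unclass(m)
  n <- nrow(mm)
  100 * sum(mm[cbind(1:(n - 1), 2:n)]) / total
}

#' Finite-population sample size for annotation planning
#'
#' How many frames must be annotated to estimate a proportion within a margin
#' of error at a given confidence, out of a finite population of \code{N}
#' frames:
#' \deqn{n = \frac{p(1-p) Z^2 N}{\epsilon^2 (N-1) + Z^2 p(1-p)}}
#' rounded \emph{up} -- a sample size must cover the requested margin.  The
#' default quantile for 99\% confidence is the two-decimal value 2.58; the
#' three-decimal 2.576 is equally valid and gives a slightly smaller n (the
#' two conventions differ by a handful of frames at planning scale).  With
#' no prior information, \code{p = 0.5} is the conservative (maximizing)
#' choice.
#'
#' @param N population size in frames.
#' @param p expected proportion (default 0.5).
#' @param margin desired margin of error \eqn{\epsilon} (e.g. 0.04 for 4\%).
#' @param z normal quantile for the confidence level (default 2.58 for 99\%).
#' @return required sample size in frames (integer).
#' @examples
#' sample_size(N = 35e6, p = 0.5, margin = 0.04, z = 2.58)  # 1041
#' @export
sample_size <- function(N, p = 0.5, margin, z = 2.58) {
  if (N < 1) stop("N must be >= 1")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (margin <= 0) stop("margin of error must be > 0")
  if (z <= 0) stop("z must be > 0")
  n <- p * (1 - p) * z^2 * N / (margin^2 * (N - 1) + z^2 * p * (1 - p))
  as.integer(ceiling(n))
}

#' Single-class average precision of a detector
#'
#' Matches predicted boxes to ground-truth boxes greedily in descending
#' confidence order (within each image, a prediction matches the unmatched
#' ground-truth box of highest IoU when that IoU reaches the threshold) and
#' integrates the resulting precision-recall curve with all-point
#' interpolation (the precision envelope).  With a single object category the
#' mean average precision equals this AP.
#'
#' @param predictions data frame of predicted boxes: \code{image},
#'   \code{score}, \code{x_min,y_min,x_max,y_max}.  Ties in score are broken
#'   by row order.
#' @param truth data frame of ground-truth boxes: \code{image},
#'   \code{x_min,y_min,x_max,y_max}.
#' @param iou_threshold minimum IoU for a match, in (0, 1]; 0.5 by default.
#' @return an \code{ap_result} list: \code{ap}, \code{m_ap} (= ap, one
#'   class), \code{n_predictions}, \code{n_truth}, \code{iou_threshold},
#'   and the raw \code{precision}/\code{recall} vectors.  AP is invariant to
#'   any monotone rescaling of the confidence scores.
#' @export
average_precision <- function(predictions, truth, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must lie in (0, 1]")
  n_truth <- nrow(truth)
  if (n_truth == 0) {
    warning("no ground-truth boxes: AP undefined", call. = FALSE)
    return(structure(list(ap = NA_real_, m_ap = NA_real_,
                          n_predictions = nrow(predictions), n_truth = 0,
                          iou_threshold = iou_threshold,
                          precision = numeric(0), recall = numeric(0)),
                     class = "ap_result"))
  }
  ord <- order(-predictions$score)
  preds <- predictions[ord, , drop = FALSE]
  matched <- rep(FALSE, n_truth)
  tp <- logical(nrow(preds))
  for (i in seq_len(nrow(preds))) {
    cand <- which(truth$image == preds$image[i] & !matched)
    if (!length(cand)) next
    ious <- as.vector(box_iou(preds[i, , drop = FALSE],
                              truth[cand, , drop = FALSE]))
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      tp[i] <- TRUE
      matched[cand[j]] <- TRUE
    }
  }
  tpc <- cumsum(tp)
  recall <- tpc / n_truth
  precision <- tpc / seq_along(tpc)
  # all-point interpolation: right-to-left precision envelope
  mrec <- c(0, recall)
  mpre <- c(1, precision)
  if (length(mpre) > 1)
    for (i in (length(mpre) - 1):1) mpre[i] <- max(mpre[i], mpre[i + 1])
  ap <- sum(diff(mrec) * mpre[-1])
  structure(list(ap = ap, m_ap = ap, n_predictions = nrow(preds),
                 n_truth = n_truth, iou_threshold = iou_threshold,
                 precision = precision, recall = recall),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result> AP = %.4f (mAP = %.4f) over %d prediction(s), %d ground-truth box(es), IoU >= %.2f\n",
              x$ap, x$m_ap, x$n_predictions, x$n_truth, x$iou_threshold))
  invisible(x)
}
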