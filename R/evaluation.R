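# Segmentation scoring: pixel-level metrics on binary maps and
# object-level detection metrics on instance maps.

#' Pixel-level confusion matrix of two binary masks
#'
#' @param pred,truth Binary matrices (0/1 or logical) of equal size.
#' @return 2 x 2 integer matrix `n[i, j]`: pixels of true class `i`
#'   predicted as class `j`, classes ordered (background, granule).
#' @export
confusion_matrix <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) abort("masks differ in shape")
  p <- as.integer(unclass(pred) > 0)
  t <- as.integer(unclass(truth) > 0)
  n <- matrix(0L, 2, 2, dimnames = list(true = c("background", "granule"),
                                        pred = c("background", "granule")))
  n[1, 1] <- sum(t == 0L & p == 0L)
  n[1, 2] <- sum(t == 0L & p == 1L)
  n[2, 1] <- sum(t == 1L & p == 0L)
  n[2, 2] <- sum(t == 1L & p == 1L)
  n
}

#' Pixel accuracy, mean accuracy and mean IU
#'
#' With \eqn{n_{ij}} the count of pixels of true class i predicted as class
#' j and \eqn{t_i = \sum_j n_{ij}}: pixel accuracy is
#' \eqn{\sum_i n_{ii} / \sum_i t_i}; mean accuracy the mean over classes of
#' \eqn{n_{ii}/t_i}; mean IU the mean over classes of
#' \eqn{n_{ii} / (t_i + \sum_j n_{ji} - n_{ii})}. Classes absent from the
#' truth (\eqn{t_i = 0}) are excluded from the means, with the divisor
#' reduced accordingly. A high pixel accuracy can mask total detection
#' failure when granules occupy a small image fraction — mean IU does not.
#'
#' @param pred,truth Binary masks of equal shape.
#' @return One-row tibble: `pixel_accuracy`, `mean_accuracy`, `mean_iu`.
#' @export
pixel_metrics <- function(pred, truth) {
  n <- confusion_matrix(pred, truth)
  t_i <- rowSums(n)
  p_j <- colSums(n)
  diag_n <- diag(n)
  present <- t_i > 0
  acc_i <- diag_n[present] / t_i[present]
  iu_i <- diag_n[present] /
    (t_i[present] + p_j[present] - diag_n[present])
  tibble(
    pixel_accuracy = sum(diag_n) / sum(t_i),
    mean_accuracy = mean(acc_i),
    mean_iu = mean(iu_i)
  )
}

#' Match predicted and ground-truth granule instances
#'
#' Computes pairwise IoU between all overlapping (prediction, truth)
#' instance pairs, then assigns greedily in descending IoU (one-to-one).
#' Pairs with IoU at or above the threshold are true positives; unmatched
#' predictions are false positives, unmatched truths false negatives.
#' Object-level true negatives are not reported: there is no countable set
#' of "true negative objects". When there are no predictions, precision is
#' undefined and reported as 0 with `precision_defined = FALSE` so scores
#' aggregate stably across scenes.
#'
#' @param pred,truth Instance maps of equal shape.
#' @param iou_threshold Matching threshold in (0, 1).
#' @return An object of class `detection_result`; `glance()` gives the
#'   one-row tp/fp/fn/precision/recall summary, `tidy()` the matched-pair
#'   table.
#' @export
match_instances <- function(pred, truth, iou_threshold = 0.5) {
  if (!all(dim(pred) == dim(truth))) abort("instance maps differ in shape")
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    abort("`iou_threshold` must lie in (0, 1)")
  }
  p <- unclass(pred); t <- unclass(truth)
  np <- max(p, 0L); nt <- max(t, 0L)
  pa <- if (np > 0) tabulate(p[p > 0L], nbins = np) else integer(0)
  ta <- if (nt > 0) tabulate(t[t > 0L], nbins = nt) else integer(0)
  sel <- p > 0L & t > 0L
  pairs <- if (any(sel)) {
    ov <- as.data.frame(table(truth_id = t[sel], pred_id = p[sel]),
                        stringsAsFactors = FALSE)
    ov <- ov[ov$Freq > 0, ]
    ov$truth_id <- as.integer(ov$truth_id)
    ov$pred_id <- as.integer(ov$pred_id)
    ov$iou <- ov$Freq / (ta[ov$truth_id] + pa[ov$pred_id] - ov$Freq)
    ov[order(-ov$iou, ov$truth_id, ov$pred_id), ]
  } else {
    data.frame(truth_id = integer(0), pred_id = integer(0),
               Freq = integer(0), iou = numeric(0))
  }
  used_t <- logical(nt); used_p <- logical(np)
  matched <- list()
  for (r in seq_len(nrow(pairs))) {
    ti <- pairs$truth_id[r]; pi <- pairs$pred_id[r]
    if (used_t[ti] || used_p[pi]) next
    if (pairs$iou[r] < iou_threshold) next
    used_t[ti] <- TRUE; used_p[pi] <- TRUE
    matched[[length(matched) + 1]] <- tibble(
      truth_id = ti, pred_id = pi, iou = pairs$iou[r])
  }
  tp <- length(matched)
  fp <- np - tp
  fn <- nt - tp
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    precision_defined = tp + fp > 0,
    pairs = if (tp > 0) bind_rows(matched) else
      tibble(truth_id = integer(0), pred_id = integer(0), iou = numeric(0)),
    iou_threshold = iou_threshold
  ), class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result> tp %d, fp %d, fn %d; precision %.3f%s, recall %.3f (IoU >= %.2f)\n",
    x$tp, x$fp, x$fn, x$precision,
    if (x$precision_defined) "" else " (undefined: no predictions)",
    x$recall, x$iou_threshold))
  invisible(x)
}

#' Tidy object-detection results
#'
#' @param x A `detection_result`.
#' @param ... Unused.
#' @return `tidy()` returns the matched (truth, prediction) pairs with
#'   their IoU; `glance()` the one-row count/precision/recall summary.
#' @export
tidy.detection_result <- function(x, ...) x$pairs

#' @rdname tidy.detection_result
#' @export
glance.detection_result <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, precision = x$precision,
         recall = x$recall, precision_defined = x$precision_defined,
         iou_threshold = x$iou_threshold)
}
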