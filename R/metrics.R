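#' Multi-class confusion matrix of two masks
#'
#' Entry `[i, j]` counts pixels whose true class is `i - 1` and predicted
#' class is `j - 1`.
#'
#' @param true,pred Class masks of identical shape, values in
#'   `{0, ..., num_classes - 1}`.
#' @param num_classes Number of classes including background.
#' @return `num_classes x num_classes` matrix of class `confusion`.
#' @export
confusion <- function(true, pred, num_classes = 3) {
  if (!all(dim(true) == dim(pred)))
    stop("true and pred masks have different shapes", call. = FALSE)
  validate_class_mask(true, num_classes, "true")
  validate_class_mask(pred, num_classes, "pred")
  k1 <- num_classes
  cm <- matrix(tabulate(as.vector(true) * k1 + as.vector(pred) + 1L,
                        nbins = k1 * k1),
               k1, k1, byrow = TRUE)
  dimnames(cm) <- list(true = 0:(k1 - 1), pred = 0:(k1 - 1))
  structure(cm, class = c("confusion", "matrix"))
}

per_class_iou <- function(cm) {
  diag(cm) / (rowSums(cm) + colSums(cm) - diag(cm))
}

#' Jaccard index (intersection over union) of two binary masks
#'
#' `|A n B| / (|A| + |B| - |A n B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b Binary masks (logical or 0/1) of identical shape.
#' @return Fraction in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("masks have different shapes", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  inter <- sum(a & b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) 1 else inter / uni
}

#' Dice score of two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#' Related to the Jaccard index by `D = 2 J / (1 + J)`.
#'
#' @inheritParams jaccard
#' @return Fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("masks have different shapes", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) 1 else 2 * sum(a & b) / denom
}

#' Mean intersection over union from a confusion matrix
#'
#' Per-class IoU is `p_ii / (sum_j p_ij + sum_j p_ji - p_ii)`; the mean is
#' taken over classes.  By default classes absent from both truth and
#' prediction (an undefined 0/0 IoU) are excluded from the mean;
#' `strict_k_plus_1 = TRUE` divides by the full class count
#' unconditionally, treating absent classes as IoU 0.
#'
#' @param cm A [confusion()] matrix.
#' @param strict_k_plus_1 Divide by the number of classes even when some
#'   are absent.
#' @return Fraction in \[0, 1\].
#' @export
miou <- function(cm, strict_k_plus_1 = FALSE) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  iou <- per_class_iou(cm)
  if (strict_k_plus_1) {
    iou[is.nan(iou)] <- 0
    mean(iou)
  } else {
    mean(iou[!is.nan(iou)])
  }
}

#' Frequency-weighted intersection over union
#'
#' Per-class IoUs weighted by each class's true pixel frequency; classes
#' with zero frequency contribute nothing.
#'
#' @param cm A [confusion()] matrix.
#' @return Fraction in \[0, 1\].
#' @export
fwiou <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  freq <- rowSums(cm) / total
  iou <- per_class_iou(cm)
  sum(ifelse(freq > 0, freq * iou, 0))
}

#' Evaluate predicted masks against ground truth
#'
#' Sums confusion matrices over one or more image pairs (micro-average)
#' and reports per-class IoU, Dice and pixel frequency together with mIoU
#' and FWIoU.  Multi-class Dice is the unweighted mean over foreground
#' classes.
#'
#' @param true,pred A mask or list of masks.
#' @param num_classes Number of classes including background.
#' @param macro Also report the per-image macro-averaged mIoU.
#' @return List with `confusion`, `per_class` (data frame), `miou`,
#'   `fwiou`, `dice`, and optionally `macro_miou`.
#' @export
eval_masks <- function(true, pred, num_classes = 3, macro = FALSE) {
  if (is.matrix(true)) true <- list(true)
  if (is.matrix(pred)) pred <- list(pred)
  stopifnot(length(true) == length(pred))
  cms <- Map(function(t, p) confusion(t, p, num_classes), true, pred)
  cm <- Reduce(`+`, lapply(cms, unclass))
  iou <- per_class_iou(cm)
  freq <- rowSums(cm) / sum(cm)
  dice_c <- 2 * iou / (1 + iou)
  per_class <- data.frame(class = 0:(num_classes - 1), iou = iou,
                          dice = dice_c, frequency = freq)
  fg <- 2:num_classes
  out <- list(confusion = cm, per_class = per_class,
              miou = mean(iou[!is.nan(iou)]),
              fwiou = sum(ifelse(freq > 0, freq * iou, 0)),
              dice = mean(dice_c[fg][!is.nan(dice_c[fg])]))
  if (macro)
    out$macro_miou <- mean(vapply(cms, miou, numeric(1)))
  out
}
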