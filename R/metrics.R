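#' Pixel confusion matrix
#'
#' Accumulates a `c x c` count matrix with rows indexed by ground truth and
#' columns by prediction. Every pixel is counted; matrices from several
#' images add elementwise.
#'
#' @param truth,pred integer vectors/matrices of class labels in `[0, c)`.
#' @param n_class number of classes `c`.
#' @return integer matrix of class `confusion_matrix` with class names on
#'   both dimensions when `n_class == 5`.
#' @examples
#' confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), n_class = 2)
#' @export
confusion_matrix <- function(truth, pred, n_class = 5L) {
  g <- as.integer(truth); p <- as.integer(pred)
  if (length(g) != length(p)) {
    stop("truth and pred must have the same length", call. = FALSE)
  }
  if (any(g < 0L | g >= n_class) || any(p < 0L | p >= n_class)) {
    stop("labels out of range [0, ", n_class, ")", call. = FALSE)
  }
  cm <- matrix(tabulate(g * n_class + p + 1L, nbins = n_class * n_class),
               nrow = n_class, byrow = TRUE)
  nm <- if (n_class == 5L) class_names() else as.character(seq_len(n_class) - 1L)
  dimnames(cm) <- list(truth = nm, pred = nm)
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Segmentation metrics from a confusion matrix
#'
#' Per-class intersection over union
#' `IoU_i = P_ii / (sum_j P_ij + sum_j P_ji - P_ii)` and per-class pixel
#' accuracy `P_ii / sum_j P_ij`, both in percent. `miou` and `mpa` are the
#' unweighted means over all classes, background included. Classes absent
#' from both ground truth and prediction are excluded from the means and
#' listed in `absent`.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `iou` (named vector, %), `pixel_accuracy` (named
#'   vector, %), `miou`, `mpa`, and `absent` (character vector).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(cm)
  row_s <- rowSums(cm); col_s <- colSums(cm); diag_s <- diag(cm)
  union <- row_s + col_s - diag_s
  absent <- union == 0
  iou <- ifelse(absent, NA_real_, 100 * diag_s / union)
  pa <- ifelse(row_s == 0, NA_real_, 100 * diag_s / row_s)
  list(
    iou = iou,
    pixel_accuracy = pa,
    miou = mean(iou[!absent]),
    mpa = mean(pa[!is.na(pa)]),
    absent = rownames(cm)[absent]
  )
}

## one-hot encode an integer target raster against C classes -> N,C,H,W array
one_hot_nchw <- function(targets, n_class) {
  d <- dim(targets)
  if (is.null(d)) d <- c(1L, 1L, length(targets))
  if (length(d) == 2L) d <- c(1L, d)
  t4 <- array(as.integer(targets), dim = d) # N,H,W
  out <- array(0, dim = c(d[1], n_class, d[2], d[3]))
  for (k in seq_len(n_class)) out[, k, , ] <- (t4 == (k - 1L)) * 1
  out
}

## normalize probability input to an N,C,H,W array
as_prob_nchw <- function(probabilities) {
  d <- dim(probabilities)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("probabilities must be a C x H x W or N x C x H x W array",
         call. = FALSE)
  }
  if (length(d) == 3L) dim(probabilities) <- c(1L, d)
  probabilities
}

#' Focal loss for semantic segmentation
#'
#' Mean over pixels of `-alpha_t * (1 - p_t)^gamma * log(p_t)`, where `p_t`
#' is the probability assigned to the true class. `gamma = 0` with unit alpha
#' recovers plain cross-entropy. Down-weights easy pixels so the scarce
#' broken-cane class is not drowned out by background.
#'
#' @param probabilities array `N x C x H x W` (or `C x H x W`) of class
#'   probabilities; each pixel's C values must sum to 1.
#' @param targets integer array `N x H x W` (or `H x W`) of true labels in
#'   `[0, C)`.
#' @param alpha scalar or length-C class weight `alpha_t`; default 0.25.
#' @param gamma focusing exponent, `>= 0`; default 2.
#' @return scalar loss (non-negative).
#' @examples
#' p <- array(c(0.5, 0.5), dim = c(1, 2, 1, 1))
#' focal_loss(p, array(0L, dim = c(1, 1, 1)), alpha = 1) # 0.25 * log(2)
#' @export
focal_loss <- function(probabilities, targets, alpha = 0.25, gamma = 2) {
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  p <- as_prob_nchw(probabilities)
  nc <- dim(p)[2]
  oh <- one_hot_nchw(targets, nc)
  if (!identical(dim(oh), dim(p))) {
    stop("probabilities and targets have incompatible shapes", call. = FALSE)
  }
  pt <- apply(p * oh, c(1, 3, 4), sum)
  if (any(pt <= 0)) pt <- pmax(pt, 1e-7) # clamp log(0); prediction gave the
                                         # true class zero probability
  at <- if (length(alpha) == 1L) rep(alpha, nc) else alpha
  stopifnot(length(at) == nc)
  tcls <- as.integer(targets) + 1L
  mean(-at[tcls] * (1 - pt)^gamma * log(pt))
}

#' Multi-class soft Dice loss
#'
#' Default mode is the standard soft Dice over classes:
#' `1 - sum_j 2 W_j sum_i g_ji p_ji / sum_i (g_ji^2 + p_ji^2)`, with class
#' weights `W_j` normalized to sum to one. `weights = "uniform"` (default)
#' uses `1/c`; `weights = "inverse_index"` uses weights proportional to `1/j`
#' over class index `j`; a numeric vector gives explicit weights.
#' `literal_log = TRUE` switches to a variant with `log(p)` in place of `p`
#' inside both the numerator and the squared denominator, kept for
#' auditability only.
#'
#' @inheritParams focal_loss
#' @param weights `"uniform"`, `"inverse_index"`, or numeric length-C vector.
#' @param literal_log use the log-probability variant; default `FALSE`.
#' @param smooth smoothing epsilon guarding empty classes; default 1e-6.
#' @return scalar loss in `[0, 1]` for the default mode.
#' @export
dice_loss <- function(probabilities, targets, weights = "uniform",
                      literal_log = FALSE, smooth = 1e-6) {
  p <- as_prob_nchw(probabilities)
  nc <- dim(p)[2]
  oh <- one_hot_nchw(targets, nc)
  stopifnot(identical(dim(oh), dim(p)))
  w <- dice_weights(weights, nc)
  pw <- if (literal_log) log(pmax(p, 1e-7)) else p
  num <- den <- numeric(nc)
  for (j in seq_len(nc)) {
    g <- oh[, j, , ]; q <- pw[, j, , ]
    num[j] <- sum(g * q)
    den[j] <- sum(g^2 + q^2)
  }
  1 - sum(w * (2 * num + smooth) / (den + smooth))
}

dice_weights <- function(weights, nc) {
  if (is.character(weights)) {
    w <- switch(match.arg(weights, c("uniform", "inverse_index")),
                uniform = rep(1, nc),
                inverse_index = 1 / seq_len(nc))
  } else {
    stopifnot(is.numeric(weights), length(weights) == nc, all(weights >= 0))
    w <- weights
  }
  w / sum(w)
}

#' Combined focal + Dice loss
#'
#' `w_focal * L_F + w_dice * L_D`; the combination stabilizes training under
#' class imbalance (focal handles hard pixels, Dice handles region overlap).
#'
#' @inheritParams dice_loss
#' @param w_focal,w_dice non-negative weights; defaults 1 and 1.
#' @param alpha,gamma passed to [focal_loss()].
#' @return scalar loss.
#' @export
combined_loss <- function(probabilities, targets, w_focal = 1, w_dice = 1,
                          alpha = 0.25, gamma = 2, weights = "uniform") {
  if (w_focal < 0 || w_dice < 0) stop("loss weights must be >= 0", call. = FALSE)
  lf <- if (w_focal > 0) focal_loss(probabilities, targets, alpha, gamma) else 0
  ld <- if (w_dice > 0) dice_loss(probabilities, targets, weights) else 0
  w_focal * lf + w_dice * ld
}

#' Serialize a metrics report
#'
#' Writes the evaluation metrics of a model as JSON, or as a single CSV row
#' (per-class IoUs, mIoU, mPA, parameters, FLOPs, inference time) in the
#' style of a model-comparison table.
#'
#' @param metrics list as returned by [metrics_from_confusion()], optionally
#'   augmented with `params`, `flops`, `inference_time_ms`, `model`.
#' @param json,csv output paths (`NULL` to skip).
#' @return invisible `metrics`.
#' @export
write_metrics_report <- function(metrics, json = NULL, csv = NULL) {
  if (!is.null(json)) {
    jsonlite::write_json(metrics, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  if (!is.null(csv)) {
    row <- data.frame(model = metrics$model %||% "model",
                      t(round(metrics$iou, 2)),
                      miou = round(metrics$miou, 2),
                      mpa = round(metrics$mpa, 2),
                      params = metrics$params %||% NA,
                      flops = metrics$flops %||% NA,
                      inference_time_ms = metrics$inference_time_ms %||% NA)
    utils::write.csv(row, csv, row.names = FALSE)
  }
  invisible(metrics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
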