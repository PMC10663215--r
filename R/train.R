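## Training machinery: differentiable focal + Dice loss on logits, the Adam
## optimizer, and the train/evaluate orchestration.

## one-hot constant array for an H,W,N integer target, as H,W,C,N
target_one_hot <- function(targets, n_class) {
  d <- dim(targets)
  if (length(d) == 2L) {
    dim(targets) <- c(d, 1L)
    d <- dim(targets)
  }
  oh <- array(0, dim = c(d[1], d[2], n_class, d[3]))
  for (k in seq_len(n_class)) oh[, , k, ] <- (targets == (k - 1L)) * 1
  oh
}

## differentiable combined focal + Dice loss on raw logits
ag_combined_loss <- function(logits, targets, w_focal = 1, w_dice = 1,
                             alpha = 0.25, gamma = 2, weights = "uniform",
                             smooth = 1e-6) {
  if (w_focal < 0 || w_dice < 0) stop("loss weights must be >= 0", call. = FALSE)
  d <- ag_dim(logits)
  nc <- d[3]
  oh <- target_one_hot(targets, nc)
  p <- ag_softmax_c(logits)
  total <- NULL
  if (w_focal > 0) {
    pt <- ag_clamp_min(ag_sum_c(ag_mul(p, oh)), 1e-7)
    at <- if (length(alpha) == 1L) rep(alpha, nc) else alpha
    at_map <- array(at[as.integer(targets) + 1L], dim = c(d[1], d[2], 1L, d[4]))
    one_minus <- ag_ew(pt, function(v) 1 - v, function(xv, v) -1)
    lf <- ag_scale(
      ag_mean_all(ag_mul(at_map,
                         ag_mul(ag_pow_const(one_minus, gamma), ag_log(pt)))),
      -1)
    total <- ag_scale(lf, w_focal)
  }
  if (w_dice > 0) {
    w <- dice_weights(weights, nc)
    wconst <- array(w, dim = c(1L, 1L, nc, 1L))
    gsq <- bc_reduce(oh, dim(oh), c(1L, 1L, nc, 1L)) # g^2 == g
    num <- ag_sum_nhw(ag_mul(p, oh))
    den <- ag_add(ag_sum_nhw(ag_pow_const(p, 2)), gsq)
    frac <- ag_div(ag_shift(ag_scale(num, 2), smooth), ag_shift(den, smooth))
    ld <- ag_shift(ag_scale(ag_sum_all(ag_mul(frac, wconst)), -1), 1)
    ld <- ag_scale(ld, w_dice)
    total <- if (is.null(total)) ld else ag_add_scalar(total, ld)
  }
  if (is.null(total)) stop("at least one loss weight must be positive",
                           call. = FALSE)
  total
}

## scalar + scalar node addition (both length-1 values)
ag_add_scalar <- function(a, b) {
  ag_node(ag_value(a) + ag_value(b), list(a, b), function(g) list(g, g))
}

## ---- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st$t <- 0L
  st
}

adam_step <- function(params, state, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    p$value <- p$value - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
    p$grad <- NULL
  }
  invisible(state)
}

## ---- data plumbing ---------------------------------------------------------

## nearest-neighbour resize of an integer label matrix
resize_mask_nearest <- function(mask, out_h, out_w) {
  h <- nrow(mask); w <- ncol(mask)
  ri <- pmin(pmax(floor((seq_len(out_h) - 0.5) * h / out_h) + 1L, 1L), h)
  ci <- pmin(pmax(floor((seq_len(out_w) - 0.5) * w / out_w) + 1L, 1L), w)
  mask[ri, ci, drop = FALSE]
}

## bilinear resize of an H x W x 3 image via the tensor kernel
resize_image_bilinear <- function(img, out_h, out_w) {
  x <- img
  dim(x) <- c(dim(img), 1L)
  y <- cpp_bilinear_forward(x, dim(x), as.integer(out_h), as.integer(out_w))
  array(y, dim = dim(y)[1:3])
}

## stack scenes (image + mask) into an S,S,3,N batch and S,S,N target array
make_batch <- function(scenes, input_size) {
  n <- length(scenes)
  x <- array(0, dim = c(input_size, input_size, 3L, n))
  y <- array(0L, dim = c(input_size, input_size, n))
  for (i in seq_len(n)) {
    img <- scenes[[i]]$image
    msk <- scenes[[i]]$mask
    if (nrow(msk) != input_size || ncol(msk) != input_size) {
      img <- resize_image_bilinear(img, input_size, input_size)
      msk <- resize_mask_nearest(msk, input_size, input_size)
    }
    x[, , , i] <- img
    y[, , i] <- msk
  }
  list(x = x, y = y)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam, initial learning rate 1e-4
#' (constant by default, cosine decay available), batch size 6, 100 epochs,
#' combined focal + Dice loss with unit weights. The batch size auto-reduces
#' with a warning when the dataset is smaller than one batch.
#'
#' @param learning_rate positive; default 1e-4.
#' @param batch_size integer >= 1; default 6.
#' @param epochs integer >= 1; default 100.
#' @param input_size one of 256, 512, 768.
#' @param w_focal,w_dice loss weights.
#' @param alpha,gamma focal-loss parameters.
#' @param lr_schedule `"constant"` (default) or `"cosine"`.
#' @param seed RNG seed for shuffling.
#' @param max_iterations optional hard cap on optimizer steps.
#' @param eval_every evaluate training mIoU every this many iterations
#'   (`NULL` to skip).
#' @param target_miou stop early once training mIoU (percent) reaches this
#'   value (requires `eval_every`).
#' @param checkpoint path to write best-validation-mIoU weights (`NULL` to
#'   skip).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 6L,
                         epochs = 100L, input_size = 512L,
                         w_focal = 1, w_dice = 1, alpha = 0.25, gamma = 2,
                         lr_schedule = c("constant", "cosine"),
                         seed = 1L, max_iterations = NULL,
                         eval_every = NULL, target_miou = NULL,
                         checkpoint = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (!input_size %in% c(256L, 512L, 768L)) {
    stop("input_size must be one of 256, 512, 768", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 input_size = as.integer(input_size),
                 w_focal = w_focal, w_dice = w_dice,
                 alpha = alpha, gamma = gamma,
                 lr_schedule = match.arg(lr_schedule),
                 seed = as.integer(seed),
                 max_iterations = max_iterations,
                 eval_every = eval_every,
                 target_miou = target_miou,
                 checkpoint = checkpoint),
            class = "train_config")
}

#' Train the segmentation network
#'
#' Standard loop: per-epoch reshuffle, bilinear image / nearest mask resize
#' to the training resolution, combined focal + Dice loss, Adam step. When a
#' validation set is given, the best-validation-mIoU weights are
#' checkpointed. Fully deterministic under `config$seed`.
#'
#' @param model a [build_model()] network (modified in place and returned).
#' @param dataset list of scenes, each a list with `image` (`H x W x 3`,
#'   values in \[0,1\]) and `mask` (`H x W` integer class indices).
#' @param config a [train_config()].
#' @param validation optional validation scene list.
#' @param verbose print per-epoch progress.
#' @return list with `model` and `log` (data.frame: epoch, iterations,
#'   train_loss, train_miou, val_miou, val_mpa, seconds).
#' @export
train_model <- function(model, dataset, config = train_config(),
                        validation = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(dataset) == 0) stop("dataset is empty", call. = FALSE)
  bs <- config$batch_size
  if (bs > length(dataset)) {
    warning("batch size ", bs, " exceeds dataset size ", length(dataset),
            "; reducing", call. = FALSE)
    bs <- length(dataset)
  }
  set.seed(config$seed)
  opt <- adam_state(model$ctx$params)
  log_rows <- list()
  it <- 0L
  best_val <- -Inf
  stop_now <- FALSE
  for (epoch in seq_len(config$epochs)) {
    t0 <- Sys.time()
    ord <- sample(length(dataset))
    losses <- c()
    train_miou <- NA_real_
    for (b0 in seq(1, length(ord), by = bs)) {
      idx <- ord[b0:min(b0 + bs - 1, length(ord))]
      batch <- make_batch(dataset[idx], config$input_size)
      lr <- if (config$lr_schedule == "cosine") {
        config$learning_rate * 0.5 *
          (1 + cos(pi * (epoch - 1) / config$epochs))
      } else config$learning_rate
      out <- model$forward(ag_node(batch$x), training = TRUE)
      loss <- ag_combined_loss(out, batch$y,
                               w_focal = config$w_focal,
                               w_dice = config$w_dice,
                               alpha = config$alpha, gamma = config$gamma)
      ag_backward(loss)
      adam_step(model$ctx$params, opt, lr = lr)
      losses <- c(losses, ag_value(loss))
      it <- it + 1L
      if (!is.null(config$eval_every) && it %% config$eval_every == 0L) {
        train_miou <- evaluate_model(model, dataset,
                                     input_size = config$input_size)$miou
        if (verbose) {
          message(sprintf("iter %d: loss %.4f, train mIoU %.2f",
                          it, ag_value(loss), train_miou))
        }
        if (!is.null(config$target_miou) &&
            is.finite(train_miou) && train_miou >= config$target_miou) {
          stop_now <- TRUE
          break
        }
      }
      if (!is.null(config$max_iterations) && it >= config$max_iterations) {
        stop_now <- TRUE
        break
      }
    }
    val_miou <- val_mpa <- NA_real_
    if (!is.null(validation)) {
      vm <- evaluate_model(model, validation, input_size = config$input_size)
      val_miou <- vm$miou
      val_mpa <- vm$mpa
      if (!is.null(config$checkpoint) && val_miou > best_val) {
        best_val <- val_miou
        save_checkpoint(model, config$checkpoint)
      }
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, iterations = it, train_loss = mean(losses),
      train_miou = train_miou, val_miou = val_miou, val_mpa = val_mpa,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f (%.1fs)", epoch, mean(losses),
                      log_rows[[epoch]]$seconds))
    }
    if (stop_now) break
  }
  list(model = model, log = do.call(rbind, log_rows))
}

#' Evaluate a model on a labelled dataset
#'
#' Accumulates one pixel confusion matrix over the whole dataset (images
#' resized bilinearly, masks with nearest neighbour) and derives the IoU/mPA
#' metrics, plus the model's parameter count.
#'
#' @param model a `cane_model`.
#' @param dataset list of scenes with `image` and `mask`.
#' @param input_size evaluation resolution; defaults to the model config.
#' @param flops also compute FLOPs at `input_size` (slower); default FALSE.
#' @return [metrics_from_confusion()] output, augmented with `params`,
#'   `confusion`, mean `inference_time_ms` and optionally `flops`.
#' @export
evaluate_model <- function(model, dataset, input_size = model$config$input_size,
                           flops = FALSE) {
  nc <- model$config$num_classes
  cm <- matrix(0L, nc, nc)
  times <- numeric(0)
  for (i in seq_along(dataset)) {
    sc <- dataset[[i]]
    if (!identical(dim(sc$mask), dim(sc$image)[1:2])) {
      stop("image/mask size mismatch in sample ",
           sc$id %||% i, call. = FALSE)
    }
    batch <- make_batch(dataset[i], input_size)
    t0 <- Sys.time()
    out <- with_no_grad(model$forward(ag_node(batch$x), training = FALSE))
    lab <- hwcn_argmax(ag_value(out))
    times <- c(times, as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000)
    cm <- cm + unclass(confusion_matrix(batch$y, lab, n_class = nc))
  }
  dimnames(cm) <- list(truth = if (nc == 5) class_names() else NULL,
                       pred = if (nc == 5) class_names() else NULL)
  m <- metrics_from_confusion(cm)
  m$confusion <- cm
  m$params <- count_parameters(model)
  m$inference_time_ms <- mean(times)
  if (flops) m$flops <- count_flops(model, input_size)
  m
}

#' Segment images and estimate breakage/impurity ratios
#'
#' The end-to-end protocol: forward pass, argmax labels, per-class pixel
#' counting, mass estimation via the surface-density model, and ratio
#' estimation. Predictions are made at `input_size` and the label map is
#' resized (nearest neighbour) back to the native image size before counting.
#' A per-image failure (e.g. an all-background prediction, for which the
#' ratios are undefined) is recorded in the `error` column and the batch
#' continues.
#'
#' @param images list of `H x W x 3` arrays (or a single array).
#' @param model a `cane_model`.
#' @param density a `surface_density_model`; default the reference densities.
#' @param input_size network input resolution.
#' @param oracle_masks optional list of ground-truth masks substituted for
#'   the network output (oracle mode, used for protocol validation).
#' @return data.frame with one row per image: pixel counts, estimated masses
#'   (g), `breakage`, `impurity`, and `error` (NA when successful).
#' @export
infer_and_estimate <- function(images, model, density = default_surface_density(),
                               input_size = model$config$input_size,
                               oracle_masks = NULL) {
  if (is.array(images)) images <- list(images)
  cols <- c("image", paste0("pixels_", class_names()),
            paste0("mass_", material_classes()), "breakage", "impurity")
  rows <- lapply(seq_along(images), function(i) {
    vals <- rep(NA_real_, length(cols))
    err <- NA_character_
    tryCatch({
      if (!is.null(oracle_masks)) {
        lab <- oracle_masks[[i]]
      } else {
        img <- images[[i]]
        h <- dim(img)[1]; w <- dim(img)[2]
        rs <- resize_image_bilinear(img, input_size, input_size)
        pred <- predict_segmentation(model, rs)
        lab <- resize_mask_nearest(
          matrix(pred$labels[1, , ], input_size, input_size), h, w)
        storage.mode(lab) <- "integer"
      }
      px <- count_class_pixels(lab)
      ms <- estimate_mass(px[material_classes()], density)
      rt <- estimate_ratios(ms)
      vals <- c(i, unname(px), unname(unclass(ms)), rt$breakage, rt$impurity)
    }, error = function(e) err <<- conditionMessage(e))
    vals[1] <- i
    df <- as.data.frame(as.list(stats::setNames(vals, cols)))
    df$error <- err
    df
  })
  do.call(rbind, rows)
}
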