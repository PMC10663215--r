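#' Backbone stage table
#'
#' The truncated MobileNetv2 backbone: a 3x3 stride-2 stem to 32 channels
#' followed by seven inverted-residual stages described by expansion factor
#' `t`, output channels `c`, repeat count `n`, first-block stride `s` and
#' dilation `r`. Only the first block of a stage uses stride `s`; repeats use
#' stride 1. The default (improved) table keeps the deep stages at stride 1
#' with dilations 2 and 5, giving output stride 16; `improved = FALSE`
#' restores the original strides (the 160-channel stage downsamples) with all
#' dilations 1.
#'
#' @param improved use the dilated stride-16 variant (default `TRUE`).
#' @return data.frame with columns `t, c, n, s, r`.
#' @export
backbone_config <- function(improved = TRUE) {
  if (improved) {
    data.frame(
      t = c(1, 6, 6, 6, 6, 6, 6),
      c = c(16, 24, 32, 64, 96, 160, 320),
      n = c(1, 2, 3, 4, 3, 3, 1),
      s = c(1, 2, 2, 2, 1, 1, 1),
      r = c(1, 1, 1, 1, 1, 2, 5)
    )
  } else {
    data.frame(
      t = c(1, 6, 6, 6, 6, 6, 6),
      c = c(16, 24, 32, 64, 96, 160, 320),
      n = c(1, 2, 3, 4, 3, 3, 1),
      s = c(1, 2, 2, 2, 1, 2, 1),
      r = c(1, 1, 1, 1, 1, 1, 1)
    )
  }
}

#' Segmentation model configuration
#'
#' Collects every architectural switch of the network: the number of classes,
#' training resolution, ASPP dilations and width, decoder low-level width,
#' and the four enhancement flags (dilated backbone, strip pooling in the
#' ASPP, coordinate attention before the decoder and after the ASPP).
#'
#' @param num_classes integer >= 2; default 5 (background + 4 materials).
#' @param input_size default training resolution; spatial dims must be
#'   divisible by 16 at forward time.
#' @param aspp_dilations strictly increasing positive dilation triple.
#' @param aspp_channels ASPP output width; default 256.
#' @param low_level_channels decoder low-level projection width; default 48.
#' @param use_improved_backbone,use_strip_pooling,ca_before_decoder,ca_after_aspp
#'   enhancement flags.
#' @param output_stride 16 (default) or 8.
#' @return a `model_config` list.
#' @export
model_config <- function(num_classes = 5L, input_size = 512L,
                         aspp_dilations = c(4L, 8L, 12L),
                         aspp_channels = 256L, low_level_channels = 48L,
                         use_improved_backbone = TRUE,
                         use_strip_pooling = TRUE,
                         ca_before_decoder = TRUE,
                         ca_after_aspp = TRUE,
                         output_stride = 16L) {
  if (num_classes < 2) stop("num_classes must be >= 2", call. = FALSE)
  if (length(aspp_dilations) != 3L || any(aspp_dilations < 1) ||
      any(diff(aspp_dilations) <= 0)) {
    stop("aspp_dilations must be three strictly increasing positive integers",
         call. = FALSE)
  }
  if (!output_stride %in% c(8L, 16L)) {
    stop("output_stride must be 8 or 16", call. = FALSE)
  }
  structure(list(
    num_classes = as.integer(num_classes),
    input_size = as.integer(input_size),
    aspp_dilations = as.integer(aspp_dilations),
    aspp_channels = as.integer(aspp_channels),
    low_level_channels = as.integer(low_level_channels),
    use_improved_backbone = isTRUE(use_improved_backbone),
    use_strip_pooling = isTRUE(use_strip_pooling),
    ca_before_decoder = isTRUE(ca_before_decoder),
    ca_after_aspp = isTRUE(ca_after_aspp),
    output_stride = as.integer(output_stride)
  ), class = "model_config")
}

#' Ablation variants
#'
#' Seven configurations spanning the ablation ladder: `base` (plain
#' MobileNetv2 backbone, plain ASPP with dilations 6/12/18, no attention),
#' `M` (dilated backbone), `MDS` (adds the strip-pooled ASPP with dilations
#' 4/8/12), `MC1`/`MC2`/`MC` (coordinate attention before the decoder / after
#' the ASPP / both, on `M`), and `MDSC` (everything on).
#'
#' @param name one of `"base"`, `"M"`, `"MDS"`, `"MC1"`, `"MC2"`, `"MC"`,
#'   `"MDSC"`.
#' @param ... overrides passed on to [model_config()].
#' @return a `model_config`.
#' @examples
#' make_variant("MDSC")
#' @export
make_variant <- function(name, ...) {
  valid <- c("base", "M", "MDS", "MC1", "MC2", "MC", "MDSC")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    stop("unknown variant '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  flags <- switch(name,
    base = list(FALSE, FALSE, FALSE, FALSE),
    M    = list(TRUE,  FALSE, FALSE, FALSE),
    MDS  = list(TRUE,  TRUE,  FALSE, FALSE),
    MC1  = list(TRUE,  FALSE, TRUE,  FALSE),
    MC2  = list(TRUE,  FALSE, FALSE, TRUE),
    MC   = list(TRUE,  FALSE, TRUE,  TRUE),
    MDSC = list(TRUE,  TRUE,  TRUE,  TRUE)
  )
  dil <- if (flags[[2]]) c(4L, 8L, 12L) else c(6L, 12L, 18L)
  model_config(
    aspp_dilations = dil,
    use_improved_backbone = flags[[1]],
    use_strip_pooling = flags[[2]],
    ca_before_decoder = flags[[3]],
    ca_after_aspp = flags[[4]],
    ...
  )
}

## apply the output-stride-8 transform: the 64-channel stage stops striding
## and later dilations double
apply_output_stride <- function(stages, output_stride) {
  if (output_stride == 8L) {
    i64 <- which(stages$c == 64)
    stages$s[i64] <- 1
    stages$r[i64:nrow(stages)] <- pmax(stages$r[i64:nrow(stages)] * 2,
                                       c(2, rep(1, nrow(stages) - i64)))
  }
  stages
}

#' Build the segmentation network
#'
#' Constructs the encoder-decoder network described by a [model_config()]:
#' truncated MobileNetv2 backbone (low-level features after the 24-channel
#' stage, high-level after the 320-channel stage), ASPP head (optionally with
#' the strip-pooling branch and coordinate attention after its fusion), and a
#' DeepLabv3+-style decoder (low-level 1x1 projection, optionally preceded by
#' coordinate attention; high-level features upsampled, concatenated,
#' refined by a depthwise-separable 3x3, classified, and upsampled to input
#' resolution). Weights use Kaiming initialization behind a single seed.
#'
#' @param config a [model_config()] or variant name accepted by
#'   [make_variant()].
#' @param seed integer RNG seed for weight initialization.
#' @return an object of class `cane_model` with elements `config`, `ctx`
#'   (parameters and batch-norm state) and `forward`.
#' @export
build_model <- function(config = make_variant("MDSC"), seed = 42L) {
  if (is.character(config)) config <- make_variant(config)
  stopifnot(inherits(config, "model_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  ctx <- new_model_ctx()
  stages <- apply_output_stride(backbone_config(config$use_improved_backbone),
                                config$output_stride)

  stem <- conv_unit(ctx, "stem", 3L, 32L, k = 3L, stride = 2L, act = "relu6")
  blocks <- list()
  cin <- 32L
  low_level_stage <- which(stages$c == 24)
  for (i in seq_len(nrow(stages))) {
    for (j in seq_len(stages$n[i])) {
      s <- if (j == 1L) stages$s[i] else 1L
      r <- stages$r[i]
      if (s == 2L) r <- 1L # striding block cannot dilate
      blocks[[length(blocks) + 1L]] <- list(
        fn = inverted_residual(ctx, sprintf("backbone.s%d.b%d", i, j),
                               cin, stages$c[i], t = stages$t[i],
                               stride = s, dilation = r),
        stage = i)
      cin <- stages$c[i]
    }
  }
  high_channels <- stages$c[nrow(stages)]

  aspp <- aspp_head(ctx, "aspp", high_channels, config$aspp_channels,
                    config$aspp_dilations, strip = config$use_strip_pooling)
  ca_aspp <- if (config$ca_after_aspp) {
    coordinate_attention_layer(ctx, "ca_aspp", config$aspp_channels)
  } else NULL
  ca_low <- if (config$ca_before_decoder) {
    coordinate_attention_layer(ctx, "ca_low", 24L)
  } else NULL
  low_proj <- conv_unit(ctx, "decoder.low_proj", 24L,
                        config$low_level_channels, k = 1L)
  fuse_dw <- conv_unit(ctx, "decoder.fuse.dwise",
                       config$aspp_channels + config$low_level_channels,
                       config$aspp_channels + config$low_level_channels,
                       k = 3L,
                       groups = config$aspp_channels + config$low_level_channels,
                       act = "relu")
  fuse_pw <- conv_unit(ctx, "decoder.fuse.pwise",
                       config$aspp_channels + config$low_level_channels,
                       config$aspp_channels, k = 1L)
  classifier <- conv_unit(ctx, "decoder.classifier", config$aspp_channels,
                          config$num_classes, k = 1L, act = "linear",
                          bn = FALSE, bias = TRUE)

  ## full forward pass; returns list(scores = ag_node, labels = array)
  forward <- function(x, training = FALSE) {
    d <- ag_dim(x)
    if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
      stop("input spatial size ", d[1], "x", d[2], " is not divisible by 16; ",
           "resize the input (e.g. to ", 16L * round(d[1] / 16), "x",
           16L * round(d[2] / 16), ")", call. = FALSE)
    }
    h <- stem(x, training)
    low <- NULL
    last_in_stage <- cumsum(stages$n)
    for (k in seq_along(blocks)) {
      h <- blocks[[k]]$fn(h, training)
      if (k == last_in_stage[low_level_stage]) low <- h
    }
    h <- aspp(h, training)
    if (!is.null(ca_aspp)) h <- ca_aspp(h, training)
    if (!is.null(ca_low)) low <- ca_low(low, training)
    low <- low_proj(low, training)
    ld <- ag_dim(low)
    h <- ag_bilinear(h, ld[1], ld[2])
    h <- ag_concat_c(list(low, h))
    h <- fuse_pw(fuse_dw(h, training), training)
    h <- classifier(h, training)
    ag_bilinear(h, d[1], d[2])
  }

  structure(list(config = config, ctx = ctx, forward = forward,
                 seed = as.integer(seed)),
            class = "cane_model")
}

#' @export
print.cane_model <- function(x, ...) {
  cfg <- x$config
  on_off <- function(b) if (b) "on" else "off"
  cat("<cane_model> ", cfg$num_classes, " classes, output stride ",
      cfg$output_stride, "\n", sep = "")
  cat("  dilated backbone ", on_off(cfg$use_improved_backbone),
      ", strip pooling ", on_off(cfg$use_strip_pooling),
      ", CA decoder/ASPP ", on_off(cfg$ca_before_decoder), "/",
      on_off(cfg$ca_after_aspp), "\n", sep = "")
  cat("  parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' Run the network on an image batch
#'
#' @param model a [build_model()] network.
#' @param images a single `H x W x 3` array in \[0, 1\], or a list of such
#'   images of equal size; H and W must be divisible by 16.
#' @param training propagate batch statistics (TRUE) or running statistics
#'   (FALSE, default).
#' @return list with `scores` (`N x num_classes x H x W` array) and `labels`
#'   (`N x H x W` integer array of argmax class indices).
#' @export
predict_segmentation <- function(model, images, training = FALSE) {
  x <- as_image_batch(images)
  out <- with_no_grad(model$forward(ag_node(x), training = training))
  scores <- ag_value(out)
  list(scores = aperm(scores, c(4, 3, 1, 2)),
       labels = aperm(hwcn_argmax(scores), c(3, 1, 2)))
}

## accept H x W x 3 (single image), a list of such, or the internal
## H x W x 3 x N batch; returns the internal batch layout
as_image_batch <- function(images) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    x <- array(0, dim = c(d[1], d[2], 3L, length(images)))
    for (i in seq_along(images)) x[, , , i] <- images[[i]]
    return(x)
  }
  d <- dim(images)
  if (length(d) == 3L && d[3] == 3L) dim(images) <- c(d, 1L)
  stopifnot(length(dim(images)) == 4L, dim(images)[3] == 3L)
  images
}

## argmax over the channel axis of an H,W,C,N array -> H,W,N (0-based)
hwcn_argmax <- function(scores) {
  d <- dim(scores)
  best <- scores[, , 1, , drop = FALSE]
  lab <- array(0L, dim = d[c(1, 2, 4)])
  for (k in seq_len(d[3])[-1]) {
    sk <- scores[, , k, , drop = FALSE]
    upd <- sk > best
    best[upd] <- sk[upd]
    dim(upd) <- d[c(1, 2, 4)]
    lab[upd] <- k - 1L
  }
  lab
}

## run an expression with graph construction disabled (inference)
with_no_grad <- function(expr) {
  old <- .ag_counter$grad_on
  .ag_counter$grad_on <- FALSE
  on.exit(.ag_counter$grad_on <- old)
  expr
}

#' Count trainable parameters
#'
#' Sum of element counts over all trainable tensors (convolution weights and
#' biases, batch-norm scales and shifts).
#'
#' @param model a `cane_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$ctx$params, function(p) length(p$value), numeric(1)))
}

#' Count FLOPs of a forward pass
#'
#' Runs one batch-1 forward pass at the given square input size with the FLOP
#' counter enabled. Convention: 2 FLOPs per multiply-accumulate, counting
#' convolutions, linear maps and normalization.
#'
#' @param model a `cane_model`.
#' @param input_size square input side; default the config's `input_size`.
#' @return numeric FLOP count.
#' @export
count_flops <- function(model, input_size = model$config$input_size) {
  x <- array(0, dim = c(input_size, input_size, 3L, 1L))
  model$ctx$count_flops <- TRUE
  model$ctx$flops <- 0
  on.exit(model$ctx$count_flops <- FALSE)
  with_no_grad(model$forward(ag_node(x), training = FALSE))
  model$ctx$flops
}

#' Save and load model checkpoints
#'
#' `save_checkpoint` writes the weights, batch-norm running statistics and
#' configuration to a single serialized file, plus the configuration as a
#' JSON sidecar (`<path>.json`). `load_checkpoint` rebuilds the model and
#' restores the state.
#'
#' @param model a `cane_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `cane_model`.
#' @export
save_checkpoint <- function(model, path) {
  state <- list(
    config = unclass(model$config),
    seed = model$seed,
    params = lapply(model$ctx$params, function(p) p$value),
    bn = lapply(model$ctx$bn, function(s) {
      list(running_mean = s$running_mean, running_var = s$running_var)
    })
  )
  saveRDS(state, path)
  jsonlite::write_json(state$config, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  config <- do.call(model_config, state$config)
  model <- build_model(config, seed = state$seed)
  stopifnot(identical(sort(names(model$ctx$params)), sort(names(state$params))))
  for (nm in names(state$params)) {
    model$ctx$params[[nm]]$value <- state$params[[nm]]
  }
  for (nm in names(state$bn)) {
    model$ctx$bn[[nm]]$running_mean <- state$bn[[nm]]$running_mean
    model$ctx$bn[[nm]]$running_var <- state$bn[[nm]]$running_var
  }
  model
}

#' Read and write a model configuration as YAML
#'
#' @param config a [model_config()].
#' @param path YAML file path.
#' @return `write_model_config` returns `path` invisibly; `read_model_config`
#'   returns a `model_config`.
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  do.call(model_config, yaml::read_yaml(path))
}
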