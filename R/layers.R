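## Layer constructors. Each constructor registers its parameters (ag_param
## nodes) and batch-norm running statistics in the model context `ctx` under
## a dotted name, and returns a closure `function(x, training)` that applies
## the layer to an ag_node. FLOPs are accumulated into ctx$flops when
## ctx$count_flops is TRUE (2 FLOPs per multiply-accumulate; convolutions,
## linear maps and normalization are counted).

new_model_ctx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- list()
  ctx$bn <- list()
  ctx$count_flops <- FALSE
  ctx$flops <- 0
  ctx
}

ctx_add_param <- function(ctx, name, value) {
  node <- ag_param(value)
  ctx$params[[name]] <- node
  node
}

kaiming_weights <- function(cout, cin_g, kh, kw) {
  fan_in <- cin_g * kh * kw
  array(stats::rnorm(cout * cin_g * kh * kw, sd = sqrt(2 / fan_in)),
        dim = c(cout, cin_g, kh, kw))
}

## convolution + optional batch norm + activation
conv_unit <- function(ctx, name, cin, cout, k = 1L, stride = 1L,
                      dilation = 1L, groups = 1L,
                      act = c("relu", "relu6", "sigmoid", "linear"),
                      bn = TRUE, bias = !bn, zero_init = FALSE) {
  act <- match.arg(act)
  kh <- if (length(k) == 2L) k[1] else k
  kw <- if (length(k) == 2L) k[2] else k
  cin_g <- cin %/% groups
  wv <- if (zero_init) array(0, dim = c(cout, cin_g, kh, kw))
        else kaiming_weights(cout, cin_g, kh, kw)
  w <- ctx_add_param(ctx, paste0(name, ".weight"), wv)
  b <- if (bias) ctx_add_param(ctx, paste0(name, ".bias"), numeric(cout))
       else NULL
  gamma <- beta <- bn_state <- NULL
  if (bn) {
    gamma <- ctx_add_param(ctx, paste0(name, ".bn.gamma"), rep(1, cout))
    beta <- ctx_add_param(ctx, paste0(name, ".bn.beta"), numeric(cout))
    bn_state <- new.env(parent = emptyenv())
    bn_state$running_mean <- numeric(cout)
    bn_state$running_var <- rep(1, cout)
    ctx$bn[[name]] <- bn_state
  }
  pad_h <- dilation * (kh - 1L) %/% 2L
  pad_w <- dilation * (kw - 1L) %/% 2L
  function(x, training = FALSE) {
    y <- ag_conv2d(x, w, b, stride = c(stride, stride),
                   pad = c(pad_h, pad_w),
                   dilation = c(dilation, dilation), groups = groups)
    if (ctx$count_flops) {
      od <- ag_dim(y)
      macs <- prod(od) * cin_g * kh * kw
      ctx$flops <- ctx$flops + 2 * macs +
        (if (!is.null(b)) prod(od) else 0)
    }
    if (!is.null(gamma)) {
      fused <- if (act %in% c("relu", "relu6")) act else "linear"
      y <- ag_batchnorm(y, gamma, beta, bn_state, training = training,
                        act = fused)
      if (ctx$count_flops) ctx$flops <- ctx$flops + 2 * prod(ag_dim(y))
      return(if (act == "sigmoid") ag_sigmoid(y) else y)
    }
    switch(act,
           relu = ag_relu(y),
           relu6 = ag_relu6(y),
           sigmoid = ag_sigmoid(y),
           linear = y)
  }
}

## inverted residual block: expand (1x1, relu6) -> depthwise 3x3 -> project
## (1x1, linear); shortcut when stride 1 and matching channel count
inverted_residual <- function(ctx, name, cin, cout, t, stride = 1L,
                              dilation = 1L) {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2", call. = FALSE)
  if (t < 1) stop("expansion factor t must be >= 1", call. = FALSE)
  if (stride == 2L && dilation > 1L) {
    stop("stride 2 with dilation > 1 is undefined in an inverted residual block",
         call. = FALSE)
  }
  hidden <- cin * t
  expand <- if (t > 1) {
    conv_unit(ctx, paste0(name, ".expand"), cin, hidden, k = 1L, act = "relu6")
  } else NULL
  dwise <- conv_unit(ctx, paste0(name, ".dwise"), hidden, hidden, k = 3L,
                     stride = stride, dilation = dilation, groups = hidden,
                     act = "relu6")
  project <- conv_unit(ctx, paste0(name, ".project"), hidden, cout, k = 1L,
                       act = "linear")
  use_shortcut <- stride == 1L && cin == cout
  function(x, training = FALSE) {
    h <- if (is.null(expand)) x else expand(x, training)
    h <- dwise(h, training)
    h <- project(h, training)
    if (use_shortcut) ag_add(x, h) else h
  }
}

## strip pooling: directional mean pooling, 1-D expansions (kernel 3),
## broadcast-sum fusion, 1x1 convolution + sigmoid gate on the input
strip_pool_layer <- function(ctx, name, channels) {
  conv_h <- conv_unit(ctx, paste0(name, ".conv_h"), channels, channels,
                      k = c(3L, 1L), act = "linear", bn = FALSE, bias = FALSE)
  conv_v <- conv_unit(ctx, paste0(name, ".conv_v"), channels, channels,
                      k = c(1L, 3L), act = "linear", bn = FALSE, bias = FALSE)
  fuse <- conv_unit(ctx, paste0(name, ".fuse"), channels, channels,
                    k = 1L, act = "linear", bn = FALSE, bias = TRUE)
  function(x, training = FALSE) {
    yh <- conv_h(ag_mean_axis(x, "W"), training)   # H,1,C,N
    yv <- conv_v(ag_mean_axis(x, "H"), training)   # 1,W,C,N
    y <- ag_add(yh, yv)                            # broadcast to H,W,C,N
    gate <- ag_sigmoid(fuse(y, training))
    ag_mul(x, gate)
  }
}

## coordinate attention: factorized directional pooling -> shared bottleneck
## -> per-direction sigmoid gates a_h (C,H,1) and a_w (C,1,W)
coordinate_attention_layer <- function(ctx, name, channels, reduction = 32L) {
  mid <- max(8L, channels %/% reduction)
  shared <- conv_unit(ctx, paste0(name, ".shared"), channels, mid, k = 1L,
                      act = "relu")
  conv_ah <- conv_unit(ctx, paste0(name, ".attn_h"), mid, channels, k = 1L,
                       act = "sigmoid", bn = FALSE, bias = TRUE)
  conv_aw <- conv_unit(ctx, paste0(name, ".attn_w"), mid, channels, k = 1L,
                       act = "sigmoid", bn = FALSE, bias = TRUE)
  function(x, training = FALSE) {
    d <- ag_dim(x)
    xh <- ag_mean_axis(x, "W")                     # H,1,C,N
    xw <- ag_transpose_hw(ag_mean_axis(x, "H"))    # W,1,C,N
    y <- shared(ag_concat_h(list(xh, xw)), training)
    ah <- conv_ah(ag_slice_h(y, seq_len(d[1])), training)
    aw <- ag_transpose_hw(conv_aw(ag_slice_h(y, d[1] + seq_len(d[2])), training))
    ag_mul(ag_mul(x, ah), aw)
  }
}

## ASPP head; with `strip = TRUE` the dilated branches are joined by a
## strip-pooling branch (6 branches instead of 5)
aspp_head <- function(ctx, name, cin, out_channels, dilations,
                      strip = FALSE) {
  stopifnot(length(dilations) == 3L, all(diff(dilations) > 0),
            all(dilations >= 1))
  b_1x1 <- conv_unit(ctx, paste0(name, ".b0"), cin, out_channels, k = 1L)
  b_atrous <- lapply(seq_along(dilations), function(i) {
    d <- dilations[i]
    dw <- conv_unit(ctx, sprintf("%s.b%d.dwise", name, i), cin, cin, k = 3L,
                    dilation = d, groups = cin, act = "relu")
    pw <- conv_unit(ctx, sprintf("%s.b%d.pwise", name, i), cin, out_channels,
                    k = 1L)
    function(x, training) pw(dw(x, training), training)
  })
  b_pool <- conv_unit(ctx, paste0(name, ".pool"), cin, out_channels, k = 1L)
  b_strip <- if (strip) {
    sp <- strip_pool_layer(ctx, paste0(name, ".strip"), cin)
    pw <- conv_unit(ctx, paste0(name, ".strip.pwise"), cin, out_channels,
                    k = 1L)
    function(x, training) pw(sp(x, training), training)
  } else NULL
  n_branch <- 5L + as.integer(strip)
  project <- conv_unit(ctx, paste0(name, ".project"),
                       n_branch * out_channels, out_channels, k = 1L)
  warned <- FALSE
  function(x, training = FALSE) {
    d <- ag_dim(x)
    if (!warned && min(d[1], d[2]) < max(dilations) * 2 + 1) {
      warned <<- TRUE
      warning("ASPP input (", d[1], "x", d[2],
              ") is smaller than the largest effective dilation field",
              call. = FALSE)
    }
    branches <- c(
      list(b_1x1(x, training)),
      lapply(b_atrous, function(f) f(x, training)),
      list(ag_bilinear(b_pool(ag_mean_axis(x, "HW"), training), d[1], d[2])),
      if (strip) list(b_strip(x, training))
    )
    project(ag_concat_c(branches), training)
  }
}

## concatenate along the H axis (coordinate attention embedding)
ag_concat_h <- function(xs) {
  dims <- lapply(xs, ag_dim)
  hs <- vapply(dims, function(d) d[1], numeric(1))
  d1 <- dims[[1]]
  to <- c(sum(hs), d1[2], d1[3], d1[4])
  v <- array(0, dim = to)
  off <- 0L
  for (k in seq_along(xs)) {
    v[off + seq_len(hs[k]), , , ] <- ag_value(xs[[k]])
    off <- off + hs[k]
  }
  ag_node(v, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (k in seq_along(xs)) {
      gk <- g[off + seq_len(hs[k]), , , , drop = FALSE]
      dim(gk) <- dims[[k]]
      out[[k]] <- gk
      off <- off + hs[k]
    }
    out
  })
}
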