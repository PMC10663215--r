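## Reverse-mode automatic differentiation over H,W,C,N arrays (each channel
## image a contiguous block, the layout the C++ kernels stream over).
##
## Nodes are environments carrying a value, an accumulated gradient, parent
## nodes and a grad_fn that maps the output gradient to a list of parent
## gradients. Parameters are long-lived nodes; every forward pass builds a
## fresh graph of intermediate nodes, so old graphs are garbage-collected
## once the optimizer step is done. Heavy kernels (convolution, batch norm,
## bilinear resize) live in C++; everything elementwise stays in R.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$id <- 0L
.ag_counter$grad_on <- TRUE

ag_next_id <- function() {
  .ag_counter$id <- .ag_counter$id + 1L
  .ag_counter$id
}

ag_node <- function(value, parents = list(), grad_fn = NULL,
                    is_param = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  if (.ag_counter$grad_on || is_param) {
    e$parents <- parents
    e$grad_fn <- grad_fn
  } else {
    # inference mode: drop the graph so activations free as the pass proceeds
    e$parents <- list()
    e$grad_fn <- NULL
  }
  e$is_param <- is_param
  e$id <- ag_next_id()
  class(e) <- "ag_node"
  e
}

ag_param <- function(value) ag_node(value, is_param = TRUE)

ag_is_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (ag_is_node(x)) x$value else x

ag_dim <- function(x) {
  d <- dim(ag_value(x))
  if (is.null(d)) length(ag_value(x)) else d
}

## Accumulate `g` into node's grad slot
ag_accumulate <- function(node, g) {
  if (is.null(g)) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

## Backpropagate from a scalar (or seeded) root through the graph
ag_backward <- function(root, seed = NULL) {
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$expanded) {
      order[[length(order) + 1L]] <- node
      next
    }
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    stack[[length(stack) + 1L]] <- list(node = node, expanded = TRUE)
    for (p in node$parents) {
      if (ag_is_node(p) && is.null(seen[[as.character(p$id)]])) {
        stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
      }
    }
  }
  if (is.null(seed)) {
    stopifnot(length(root$value) == 1L)
    seed <- 1
  }
  root$grad <- seed
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$grad_fn) || is.null(node$grad)) next
    grads <- node$grad_fn(node$grad)
    for (k in seq_along(node$parents)) {
      p <- node$parents[[k]]
      if (ag_is_node(p)) ag_accumulate(p, grads[[k]])
    }
    if (!node$is_param) node$grad <- NULL # free memory as we go
  }
  invisible(root)
}

## ---- broadcasting helpers (dims are length-4 c(H,W,C,N)) -------------------
## bc_expand / bc_reduce are purely positional: axis 4 varies slowest.

## expand an array from `from` dims to `to` dims, broadcasting size-1 axes
bc_expand <- function(x, from, to) {
  if (identical(from, to)) return(x)
  stopifnot(length(from) == 4L, length(to) == 4L,
            all(from == to | from == 1L))
  # expand axis 4 (W): whole-vector recycling
  if (from[4] == 1L && to[4] > 1L) {
    x <- array(rep(as.vector(x), to[4]), dim = c(from[1:3], to[4]))
    from[4] <- to[4]
  }
  # expand axis 3 (H): repeat each W-slab H times
  if (from[3] == 1L && to[3] > 1L) {
    m <- matrix(x, from[1] * from[2], from[4])
    x <- array(m[, rep(seq_len(from[4]), each = to[3]), drop = FALSE],
               dim = c(from[1], from[2], to[3], from[4]))
    from[3] <- to[3]
  }
  # expand axis 2 (C): repeat each N-block C times within each (h,w)
  if (from[2] == 1L && to[2] > 1L) {
    m <- matrix(x, from[1], from[3] * from[4])
    idx <- rep(seq_len(from[1]), times = to[2])
    x <- array(m[idx, , drop = FALSE],
               dim = c(from[1], to[2], from[3], from[4]))
    from[2] <- to[2]
  }
  # expand axis 1 (N)
  if (from[1] == 1L && to[1] > 1L) {
    m <- matrix(as.vector(x), 1L, prod(from[2:4]))
    x <- array(m[rep(1L, to[1]), , drop = FALSE],
               dim = c(to[1], from[2:4]))
  }
  x
}

## reduce (sum) a full-size gradient back to broadcast-source dims
bc_reduce <- function(g, full, to) {
  if (identical(full, to)) return(g)
  # reduce W
  if (to[4] == 1L && full[4] > 1L) {
    g <- array(rowSums(matrix(g, prod(full[1:3]), full[4])),
               dim = c(full[1:3], 1L))
    full[4] <- 1L
  }
  # reduce H
  if (to[3] == 1L && full[3] > 1L) {
    a <- array(g, dim = c(full[1] * full[2], full[3], full[4]))
    g <- array(colSums(aperm(a, c(2, 1, 3))),
               dim = c(full[1], full[2], 1L, full[4]))
    full[3] <- 1L
  }
  # reduce C
  if (to[2] == 1L && full[2] > 1L) {
    a <- array(g, dim = c(full[1], full[2], full[3] * full[4]))
    g <- array(colSums(aperm(a, c(2, 1, 3))),
               dim = c(full[1], 1L, full[3], full[4]))
    full[2] <- 1L
  }
  # reduce N
  if (to[1] == 1L && full[1] > 1L) {
    g <- array(colSums(matrix(g, full[1], prod(full[2:4]))),
               dim = c(1L, full[2:4]))
  }
  g
}

bc_target_dim <- function(da, db) {
  stopifnot(length(da) == 4L, length(db) == 4L, all(da == db | da == 1L | db == 1L))
  pmax(da, db)
}

## ---- primitive ops ---------------------------------------------------------

ag_add <- function(a, b) {
  da <- ag_dim(a); db <- ag_dim(b)
  to <- bc_target_dim(da, db)
  v <- bc_expand(ag_value(a), da, to) + bc_expand(ag_value(b), db, to)
  ag_node(v, list(a, b), function(g) {
    list(bc_reduce(g, to, da), bc_reduce(g, to, db))
  })
}

ag_sub <- function(a, b) {
  da <- ag_dim(a); db <- ag_dim(b)
  to <- bc_target_dim(da, db)
  v <- bc_expand(ag_value(a), da, to) - bc_expand(ag_value(b), db, to)
  ag_node(v, list(a, b), function(g) {
    list(bc_reduce(g, to, da), -bc_reduce(g, to, db))
  })
}

ag_mul <- function(a, b) {
  da <- ag_dim(a); db <- ag_dim(b)
  to <- bc_target_dim(da, db)
  av <- bc_expand(ag_value(a), da, to)
  bv <- bc_expand(ag_value(b), db, to)
  ag_node(av * bv, list(a, b), function(g) {
    list(bc_reduce(g * bv, to, da), bc_reduce(g * av, to, db))
  })
}

ag_div <- function(a, b) {
  da <- ag_dim(a); db <- ag_dim(b)
  to <- bc_target_dim(da, db)
  av <- bc_expand(ag_value(a), da, to)
  bv <- bc_expand(ag_value(b), db, to)
  v <- av / bv
  ag_node(v, list(a, b), function(g) {
    list(bc_reduce(g / bv, to, da), bc_reduce(-g * av / bv^2, to, db))
  })
}

## generic elementwise op with a constant-parameter derivative
ag_ew <- function(x, f, fprime) {
  xv <- ag_value(x)
  v <- f(xv)
  ag_node(v, list(x), function(g) list(g * fprime(xv, v)))
}

ag_relu <- function(x) {
  xv <- ag_value(x)
  ag_node(cpp_clamp_forward(xv, 0, Inf), list(x),
          function(g) list(cpp_clamp_backward(xv, g, 0, Inf)))
}

ag_relu6 <- function(x) {
  xv <- ag_value(x)
  ag_node(cpp_clamp_forward(xv, 0, 6), list(x),
          function(g) list(cpp_clamp_backward(xv, g, 0, 6)))
}

ag_sigmoid <- function(x) ag_ew(x, function(v) 1 / (1 + exp(-v)),
                                function(xv, v) v * (1 - v))

ag_log <- function(x) ag_ew(x, log, function(xv, v) 1 / xv)

ag_scale <- function(x, k) ag_ew(x, function(v) v * k, function(xv, v) k)

ag_shift <- function(x, k) ag_ew(x, function(v) v + k, function(xv, v) 1)

ag_pow_const <- function(x, p) {
  ag_ew(x, function(v) v^p, function(xv, v) p * xv^(p - 1))
}

ag_clamp_min <- function(x, lo) {
  ag_ew(x, function(v) pmax(v, lo), function(xv, v) (xv >= lo) * 1)
}

## mean over one or both spatial axes, keeping dims
ag_mean_axis <- function(x, axis = c("W", "H", "HW")) {
  axis <- match.arg(axis)
  d <- ag_dim(x)
  to <- switch(axis,
               W = c(d[1], 1L, d[3], d[4]),
               H = c(1L, d[2], d[3], d[4]),
               HW = c(1L, 1L, d[3], d[4]))
  cnt <- prod(d) / prod(to)
  v <- bc_reduce(ag_value(x), d, to) / cnt
  ag_node(v, list(x), function(g) list(bc_expand(g / cnt, to, d)))
}

## sum over N, H, W keeping C (dice per-class sums) -> dim (1, 1, C, 1)
ag_sum_nhw <- function(x) {
  d <- ag_dim(x)
  to <- c(1L, 1L, d[3], 1L)
  v <- bc_reduce(ag_value(x), d, to)
  ag_node(v, list(x), function(g) list(bc_expand(g, to, d)))
}

## sum over the channel axis, keepdim -> (H, W, 1, N)
ag_sum_c <- function(x) {
  d <- ag_dim(x)
  to <- c(d[1], d[2], 1L, d[4])
  v <- bc_reduce(ag_value(x), d, to)
  ag_node(v, list(x), function(g) list(bc_expand(g, to, d)))
}

ag_sum_all <- function(x) {
  d <- ag_dim(x)
  ag_node(sum(ag_value(x)), list(x),
          function(g) list(array(g, dim = d)))
}

ag_mean_all <- function(x) {
  d <- ag_dim(x)
  n <- prod(d)
  ag_node(mean(ag_value(x)), list(x),
          function(g) list(array(g / n, dim = d)))
}

## concatenate along the channel axis
ag_concat_c <- function(xs) {
  dims <- lapply(xs, ag_dim)
  d1 <- dims[[1]]
  cs <- vapply(dims, function(d) d[3], numeric(1))
  to <- c(d1[1], d1[2], sum(cs), d1[4])
  v <- array(0, dim = to)
  off <- 0L
  for (k in seq_along(xs)) {
    v[, , off + seq_len(cs[k]), ] <- ag_value(xs[[k]])
    off <- off + cs[k]
  }
  ag_node(v, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (k in seq_along(xs)) {
      gk <- g[, , off + seq_len(cs[k]), , drop = FALSE]
      dim(gk) <- dims[[k]]
      out[[k]] <- gk
      off <- off + cs[k]
    }
    out
  })
}

## transpose H <-> W (used by coordinate attention)
ag_transpose_hw <- function(x) {
  d <- ag_dim(x)
  v <- aperm(ag_value(x), c(2, 1, 3, 4))
  ag_node(v, list(x), function(g) list(aperm(g, c(2, 1, 3, 4))))
}

## slice along H axis: rows `idx` (used to split after concat)
ag_slice_h <- function(x, idx) {
  d <- ag_dim(x)
  v <- ag_value(x)[idx, , , , drop = FALSE]
  ag_node(v, list(x), function(g) {
    out <- array(0, dim = d)
    out[idx, , , ] <- g
    list(out)
  })
}

ag_conv2d <- function(x, w, b = NULL, stride = c(1L, 1L), pad = c(0L, 0L),
                      dilation = c(1L, 1L), groups = 1L) {
  xv <- ag_value(x); wv <- ag_value(w)
  bv <- if (is.null(b)) numeric(0) else as.numeric(ag_value(b))
  xd <- dim(xv); wd <- dim(wv)
  depthwise <- groups > 1L && groups == xd[3] && wd[1] == xd[3] &&
    wd[2] == 1L && is.null(b)
  if (depthwise) {
    v <- cpp_dwconv_forward(xv, xd, wv, wd,
                            stride[1], stride[2], pad[1], pad[2],
                            dilation[1], dilation[2])
    return(ag_node(v, list(x, w), function(g) {
      bk <- cpp_dwconv_backward(xv, xd, wv, wd, g,
                                stride[1], stride[2], pad[1], pad[2],
                                dilation[1], dilation[2])
      list(bk$dx, bk$dw)
    }))
  }
  v <- cpp_conv2d_forward(xv, xd, wv, wd, bv,
                          stride[1], stride[2], pad[1], pad[2],
                          dilation[1], dilation[2], groups)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(v, parents, function(g) {
    bk <- cpp_conv2d_backward(xv, xd, wv, wd, g,
                              stride[1], stride[2], pad[1], pad[2],
                              dilation[1], dilation[2], groups, !is.null(b))
    if (is.null(b)) list(bk$dx, bk$dw) else list(bk$dx, bk$dw, bk$db)
  })
}

## batch norm with optionally fused clamp activation (act: "linear",
## "relu", "relu6"); `state` is an env with running_mean / running_var,
## updated in training mode with the given momentum
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5, act = "linear") {
  xv <- ag_value(x)
  xd <- dim(xv)
  act_code <- match(act, c("linear", "relu", "relu6")) - 1L
  fw <- cpp_bn_forward(xv, xd, as.numeric(ag_value(gamma)),
                       as.numeric(ag_value(beta)), eps, training,
                       state$running_mean, state$running_var, act_code)
  if (training) {
    m <- prod(xd[c(1, 2, 4)])
    unbias <- if (m > 1) m / (m - 1) else 1
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * fw$mean
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * fw$var * unbias
  }
  mu <- fw$mean; va <- fw$var
  yv <- fw$y
  ag_node(yv, list(x, gamma, beta), function(g) {
    bk <- cpp_bn_backward(xv, xd, as.numeric(ag_value(gamma)), mu, va, g, eps,
                          act_code, yv)
    list(bk$dx, bk$dgamma, bk$dbeta)
  })
}

ag_bilinear <- function(x, out_h, out_w) {
  xv <- ag_value(x)
  xd <- dim(xv)
  if (xd[1] == out_h && xd[2] == out_w) return(if (ag_is_node(x)) x else ag_node(x))
  v <- cpp_bilinear_forward(xv, xd, as.integer(out_h), as.integer(out_w))
  ag_node(v, list(x), function(g) {
    list(cpp_bilinear_backward(g, dim(v), xd[1], xd[2]))
  })
}

## softmax along the channel axis
ag_softmax_c <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  cdim <- c(d[1], d[2], 1L, d[4])
  mx <- xv[, , 1, , drop = FALSE]
  for (k in seq_len(d[3])[-1]) mx <- pmax(mx, xv[, , k, , drop = FALSE])
  ex <- exp(xv - bc_expand(mx, cdim, d))
  s <- bc_reduce(ex, d, cdim)
  p <- ex / bc_expand(s, cdim, d)
  ag_node(p, list(x), function(g) {
    gp <- bc_reduce(g * p, d, cdim)
    list(p * (g - bc_expand(gp, cdim, d)))
  })
}
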