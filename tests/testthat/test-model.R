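test_that("backbone table matches the reference hyperparameters", {
  bb <- backbone_config()
  expect_equal(bb$t, c(1, 6, 6, 6, 6, 6, 6))
  expect_equal(bb$c, c(16, 24, 32, 64, 96, 160, 320))
  expect_equal(bb$n, c(1, 2, 3, 4, 3, 3, 1))
  expect_equal(bb$s, c(1, 2, 2, 2, 1, 1, 1))
  expect_equal(bb$r, c(1, 1, 1, 1, 1, 2, 5))
  # original backbone keeps the 160-channel downsampling, no dilation
  bb0 <- backbone_config(improved = FALSE)
  expect_equal(bb0$s[6], 2)
  expect_true(all(bb0$r == 1))
})

test_that("make_variant yields seven pairwise distinct flag combinations", {
  names <- c("base", "M", "MDS", "MC1", "MC2", "MC", "MDSC")
  cfgs <- lapply(names, make_variant)
  keys <- vapply(cfgs, function(cf) {
    paste(cf$use_improved_backbone, cf$use_strip_pooling,
          cf$ca_before_decoder, cf$ca_after_aspp,
          paste(cf$aspp_dilations, collapse = "-"))
  }, character(1))
  expect_equal(length(unique(keys)), 7L)
  base <- cfgs[[1]]
  expect_false(base$use_improved_backbone || base$use_strip_pooling ||
               base$ca_before_decoder || base$ca_after_aspp)
  mdsc <- cfgs[[7]]
  expect_true(mdsc$use_improved_backbone && mdsc$use_strip_pooling &&
              mdsc$ca_before_decoder && mdsc$ca_after_aspp)
  expect_equal(mdsc$aspp_dilations, c(4L, 8L, 12L))
  expect_error(make_variant("XY"), "valid names")
  expect_error(model_config(aspp_dilations = c(8, 4, 12)), "increasing")
  expect_error(model_config(num_classes = 1), "num_classes")
})

test_that("inverted residual blocks obey the shape and shortcut contract", {
  ctx <- caneratio:::new_model_ctx()
  set.seed(1)
  blk <- caneratio:::inverted_residual(ctx, "b", 16L, 16L, t = 6, stride = 1L)
  x <- caneratio:::ag_node(array(rnorm(16 * 64 * 64), dim = c(64, 64, 16, 1)))
  y <- blk(x, training = FALSE)
  expect_equal(caneratio:::ag_dim(y), c(64L, 64L, 16L, 1L))
  # expansion layer width is t * c_in
  expect_equal(dim(ctx$params[["b.expand.weight"]]$value)[1], 96L)
  # shortcut active: zeroing the projection makes the block an identity
  ctx$params[["b.project.weight"]]$value[] <- 0
  ctx$params[["b.project.bn.gamma"]]$value[] <- 0
  y0 <- blk(x, training = FALSE)
  expect_equal(caneratio:::ag_value(y0), caneratio:::ag_value(x))

  blk2 <- caneratio:::inverted_residual(ctx, "b2", 24L, 32L, t = 6, stride = 2L)
  x2 <- caneratio:::ag_node(array(rnorm(24 * 64 * 64), dim = c(64, 64, 24, 1)))
  expect_equal(caneratio:::ag_dim(blk2(x2)), c(32L, 32L, 32L, 1L))
  expect_error(
    caneratio:::inverted_residual(ctx, "b3", 16L, 16L, t = 6, stride = 2L,
                                  dilation = 2L),
    "undefined")
})

test_that("strip pooling and coordinate attention have zero-gate closed forms", {
  set.seed(2)
  ctx <- caneratio:::new_model_ctx()
  sp <- caneratio:::strip_pool_layer(ctx, "sp", 6L)
  x <- array(rnorm(6 * 10 * 12), dim = c(10, 12, 6, 1))
  y <- sp(caneratio:::ag_node(x))
  expect_equal(caneratio:::ag_dim(y), dim(x))
  # zero the fusion convolution: sigmoid(0) = 0.5 => Z = 0.5 * X exactly
  ctx$params[["sp.fuse.weight"]]$value[] <- 0
  ctx$params[["sp.fuse.bias"]]$value[] <- 0
  y0 <- sp(caneratio:::ag_node(x))
  expect_equal(caneratio:::ag_value(y0), 0.5 * x, tolerance = 1e-12)

  # constant input: both pooled vectors equal the constant (mean pooling)
  xc <- array(3.7, dim = c(4, 5, 2, 1))
  expect_equal(caneratio:::ag_value(caneratio:::ag_mean_axis(
    caneratio:::ag_node(xc), "W"))[, 1, , ],
    matrix(3.7, 4, 2), ignore_attr = TRUE)

  ca <- caneratio:::coordinate_attention_layer(ctx, "ca", 32L)
  x2 <- array(rnorm(32 * 8 * 9), dim = c(8, 9, 32, 1))
  y2 <- ca(caneratio:::ag_node(x2))
  expect_equal(caneratio:::ag_dim(y2), dim(x2))
  # attention maps are sigmoid outputs: output bounded by |x|
  expect_true(all(abs(caneratio:::ag_value(y2)) <= abs(x2) + 1e-12))
  # zero the two per-direction convolutions: a_h = a_w = 0.5 => 0.25 * x
  ctx$params[["ca.attn_h.weight"]]$value[] <- 0
  ctx$params[["ca.attn_h.bias"]]$value[] <- 0
  ctx$params[["ca.attn_w.weight"]]$value[] <- 0
  ctx$params[["ca.attn_w.bias"]]$value[] <- 0
  y0 <- ca(caneratio:::ag_node(x2))
  expect_equal(caneratio:::ag_value(y0), 0.25 * x2, tolerance = 1e-12)
})

test_that("the ASPP head concatenates 5 or 6 branches and keeps spatial size", {
  set.seed(3)
  ctx <- caneratio:::new_model_ctx()
  head6 <- caneratio:::aspp_head(ctx, "a6", 32L, 16L, c(4L, 8L, 12L),
                                 strip = TRUE)
  x <- caneratio:::ag_node(array(rnorm(32 * 32 * 32), dim = c(32, 32, 32, 1)))
  expect_equal(caneratio:::ag_dim(head6(x)), c(32L, 32L, 16L, 1L))
  expect_equal(dim(ctx$params[["a6.project.weight"]]$value)[2], 6L * 16L)

  ctx2 <- caneratio:::new_model_ctx()
  head5 <- caneratio:::aspp_head(ctx2, "a5", 32L, 16L, c(6L, 12L, 18L),
                                 strip = FALSE)
  expect_equal(dim(ctx2$params[["a5.project.weight"]]$value)[2], 5L * 16L)
  # small input triggers the receptive-field warning, not an error
  xs <- caneratio:::ag_node(array(rnorm(32 * 8 * 8), dim = c(8, 8, 32, 1)))
  expect_warning(head6(xs), "dilation field")
})

test_that("backbone output strides follow the stage table", {
  m <- build_model(make_variant("MDSC", input_size = 512), seed = 1)
  out <- suppressWarnings(predict_segmentation(
    m, array(runif(256 * 256 * 3), dim = c(256, 256, 3))))
  expect_equal(dim(out$scores), c(1L, 5L, 256L, 256L))
  expect_equal(dim(out$labels), c(1L, 256L, 256L))
  expect_true(all(out$labels %in% 0:4))

  # improved (stride-16) and original (stride-32) backbones genuinely differ
  # in their deepest feature resolution: verified via the stage tables
  imp <- caneratio:::apply_output_stride(backbone_config(TRUE), 16L)
  ori <- caneratio:::apply_output_stride(backbone_config(FALSE), 16L)
  expect_equal(2 * prod(imp$s), 16)  # stem stride 2 times stage strides
  expect_equal(2 * prod(ori$s), 32)
})

test_that("forward rejects inputs not divisible by 16 with resize advice", {
  m <- build_model(make_variant("MDSC"), seed = 1)
  bad <- array(runif(100 * 100 * 3), dim = c(100, 100, 3))
  expect_error(predict_segmentation(m, bad), "divisible by 16")
  expect_error(predict_segmentation(m, bad), "resize")
})

test_that("shape contract holds for every variant across input sizes", {
  sizes <- c(256L, 512L, 768L)
  for (name in c("base", "M", "MDS", "MC1", "MC2", "MC", "MDSC")) {
    m <- build_model(make_variant(name), seed = 7)
    for (s in sizes) {
      img <- array(runif(s * s * 3), dim = c(s, s, 3))
      out <- suppressWarnings(predict_segmentation(m, img))
      expect_equal(dim(out$scores), c(1L, 5L, s, s),
                   info = paste(name, s))
      expect_true(all(is.finite(out$scores)))
    }
  }
})

test_that("deterministic forward: same weights and input give identical output", {
  m <- build_model(make_variant("MDSC"), seed = 3)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  o1 <- suppressWarnings(predict_segmentation(m, img))
  o2 <- suppressWarnings(predict_segmentation(m, img))
  expect_identical(o1$scores, o2$scores)
  # rebuilding from the same seed reproduces the weights
  m2 <- build_model(make_variant("MDSC"), seed = 3)
  expect_equal(m$ctx$params[["stem.weight"]]$value,
               m2$ctx$params[["stem.weight"]]$value)
})

test_that("shifting a constant background leaves the prediction constant", {
  m <- build_model(make_variant("MDSC"), seed = 5)
  img <- array(0.05, dim = c(64, 64, 3))
  p1 <- suppressWarnings(predict_segmentation(m, img))$labels
  # translation of a constant image is the same image; prediction unchanged
  img2 <- img
  img2[] <- img[c(11:64, 1:10), , ] # cyclic shift of constant = identity
  p2 <- suppressWarnings(predict_segmentation(m, img2))$labels
  expect_identical(p1, p2)
  # and the prediction is near-constant away from the border (the dilated
  # receptive field lets padding effects reach a few interior pixels)
  inner <- p1[1, 17:48, 17:48]
  expect_gte(max(table(inner)) / length(inner), 0.95)
})

test_that("parameter counts order across the ablation ladder", {
  pM <- count_parameters(build_model(make_variant("M"), seed = 1))
  pMDS <- count_parameters(build_model(make_variant("MDS"), seed = 1))
  pMDSC <- count_parameters(build_model(make_variant("MDSC"), seed = 1))
  expect_gt(pMDS, pM)        # strip pooling adds parameters
  expect_gt(pMDSC, pMDS)     # coordinate attention adds more
  # soft deployability band for the full variant, logged not asserted
  message(sprintf("MDSC parameters: %.2fM (soft band 3.0-5.0M)", pMDSC / 1e6))
})

test_that("parameter and FLOP counting follow the stated conventions", {
  # single bias-free 3x3 convolution, 3 -> 32 channels: 864 parameters
  ctx <- caneratio:::new_model_ctx()
  cu <- caneratio:::conv_unit(ctx, "c", 3L, 32L, k = 3L, act = "linear",
                              bn = FALSE, bias = FALSE)
  expect_equal(sum(lengths(lapply(ctx$params, function(p) p$value))), 864L)

  # 1x1 convolution 32 -> 64 on a 64x64 map: 2 * 64 * 64 * 32 * 64 FLOPs
  ctx2 <- caneratio:::new_model_ctx()
  cu2 <- caneratio:::conv_unit(ctx2, "c", 32L, 64L, k = 1L, act = "linear",
                               bn = FALSE, bias = FALSE)
  ctx2$count_flops <- TRUE
  x <- caneratio:::ag_node(array(0, dim = c(64, 64, 32, 1)))
  cu2(x)
  expect_equal(ctx2$flops, 2 * 64 * 64 * 32 * 64)

  # FLOPs are monotone in resolution for the full model
  m <- build_model(make_variant("MDSC"), seed = 1)
  f256 <- suppressWarnings(count_flops(m, 256))
  f512 <- suppressWarnings(count_flops(m, 512))
  expect_gt(f512, f256)
})

test_that("every trainable parameter receives gradient signal", {
  m <- build_model(make_variant("MDSC", input_size = 256), seed = 11)
  set.seed(12)
  nonzero <- setNames(logical(length(m$ctx$params)), names(m$ctx$params))
  for (rep in 1:2) {
    x <- array(runif(64 * 64 * 3 * 2), dim = c(64, 64, 3, 2))
    y <- array(sample(0:4, 64 * 64 * 2, TRUE), dim = c(64, 64, 2))
    out <- suppressWarnings(m$forward(caneratio:::ag_node(x), training = TRUE))
    loss <- caneratio:::ag_combined_loss(out, y)
    caneratio:::ag_backward(loss)
    for (nm in names(m$ctx$params)) {
      g <- m$ctx$params[[nm]]$grad
      if (!is.null(g) && any(g != 0)) nonzero[nm] <- TRUE
      m$ctx$params[[nm]]$grad <- NULL
    }
    if (all(nonzero)) break
  }
  expect_true(all(nonzero),
              info = paste("zero-gradient params:",
                           paste(names(nonzero)[!nonzero], collapse = ", ")))
})

test_that("checkpoints round-trip weights, bn state, and config", {
  m <- build_model(make_variant("MDS", input_size = 256), seed = 2)
  # perturb state so the round trip is non-trivial
  m$ctx$params[["stem.weight"]]$value <- m$ctx$params[["stem.weight"]]$value + 0.1
  m$ctx$bn[["stem"]]$running_mean <- runif(32)
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_checkpoint(path)
  expect_equal(m2$config, m$config)
  expect_equal(m2$ctx$params[["stem.weight"]]$value,
               m$ctx$params[["stem.weight"]]$value)
  expect_equal(m2$ctx$bn[["stem"]]$running_mean,
               m$ctx$bn[["stem"]]$running_mean)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  expect_equal(suppressWarnings(predict_segmentation(m, img))$scores,
               suppressWarnings(predict_segmentation(m2, img))$scores)
})

test_that("model config round-trips through YAML", {
  cfg <- make_variant("MC1", input_size = 256)
  path <- tempfile(fileext = ".yaml")
  write_model_config(cfg, path)
  expect_equal(read_model_config(path), cfg)
})
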