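test_that("the palette is the fixed five-color VOC-style map", {
  pal <- scene_palette()
  expect_equal(unname(pal["background", ]), c(0L, 0L, 0L))
  expect_equal(unname(pal["cane", ]), c(128L, 0L, 0L))
  expect_equal(unname(pal["broken_cane", ]), c(0L, 0L, 128L))
  expect_equal(unname(pal["top", ]), c(0L, 128L, 0L))
  expect_equal(unname(pal["leaf", ]), c(128L, 128L, 0L))
  # bijective class <-> color mapping
  codes <- pal[, 1] * 65536 + pal[, 2] * 256 + pal[, 3]
  expect_equal(length(unique(codes)), 5L)
})

test_that("generate_scene is seeded, palette-valid, and self-consistent", {
  sc <- generate_scene(size = 128, seed = 42)
  expect_s3_class(sc, "synthetic_scene")
  expect_equal(dim(sc$image), c(128, 128, 3))
  expect_equal(dim(sc$mask), c(128, 128))
  expect_true(all(sc$mask %in% 0:4))
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  # pixel counts equal counts recomputed from the mask
  expect_equal(sc$pixel_counts,
               count_class_pixels(sc$mask)[material_classes()])
  # bit-identical regeneration under the same seed
  sc2 <- generate_scene(size = 128, seed = 42)
  expect_identical(sc$image, sc2$image)
  expect_identical(sc$mask, sc2$mask)
  expect_identical(sc$true_masses, sc2$true_masses)
  # different seed differs
  expect_false(identical(sc$mask, generate_scene(size = 128, seed = 43)$mask))
  expect_error(generate_scene(size = 32), ">= 64")
})

test_that("sigma = 0 densities give exactly mass = mu * pixels", {
  d0 <- default_surface_density()
  d0$sigma[] <- 0
  sc <- generate_scene(size = 128, density = d0, seed = 5)
  expect_equal(unname(sc$true_masses),
               unname(d0$mu * sc$pixel_counts))
  # end-to-end closure: count -> estimate -> ratios reproduces generator truth
  est <- estimate_mass(count_class_pixels(sc$mask), d0)
  expect_equal(unname(unclass(est)), unname(sc$true_masses))
  expect_equal(estimate_ratios(est)$breakage,
               estimate_ratios(sc$true_masses)$breakage)
})

test_that("make_mass_dataset has the structure fit_surface_density assumes", {
  ds <- make_mass_dataset(300, seed = 31)
  expect_length(ds, 300)
  expect_identical(ds, make_mass_dataset(300, seed = 31))
  fit <- fit_surface_density(ds)
  gen <- generator_density_model()
  for (cl in material_classes()) {
    se <- gen$sigma[[cl]] / sqrt(300)
    expect_lt(abs(fit$mu[[cl]] - gen$mu[[cl]]), 3 * se)
  }
  # sigma = 0 dataset closes the ratio-evaluation loop with zero error
  d0 <- default_surface_density(); d0$sigma[] <- 0
  ds0 <- make_mass_dataset(20, density = d0, seed = 2)
  pairs <- data.frame(
    measured = sapply(ds0, function(s) estimate_ratios(s$masses)$breakage),
    estimated = sapply(ds0, function(s) {
      estimate_ratios(estimate_mass(s$pixels, d0))$breakage
    }))
  expect_equal(suppressWarnings(evaluate_ratio_tables(pairs))$mean_relative_error, 0)
  expect_error(make_mass_dataset(3, pixel_ranges = list(cane = c(5, 1))),
               "min <= max")
})

test_that("density parameter recovery is unbiased over seeded replicates", {
  gen <- generator_density_model()
  mu_hat <- vapply(1:100, function(r) {
    ds <- make_mass_dataset(300, seed = 1000 + r)
    fit_surface_density(ds, classes = "broken_cane")$mu[["broken_cane"]]
  }, numeric(1))
  se_mean <- gen$sigma[["broken_cane"]] / sqrt(300) / sqrt(100)
  expect_lt(abs(mean(mu_hat) - gen$mu[["broken_cane"]]), 3 * se_mean)
})

test_that("geometric augmentations act jointly and photometric ones leave masks", {
  sc <- generate_scene(size = 96, seed = 9)
  # rotation by 0 degrees is the identity on both image and mask
  r0 <- augment(sc$image, sc$mask,
                augmentation_spec("rotation", list(angle = 0), seed = 1))
  expect_equal(r0$image, sc$image, tolerance = 1e-12)
  expect_identical(r0$mask, sc$mask)

  # median filter on a constant image changes nothing
  const <- array(0.4, dim = c(32, 32, 3))
  cm <- matrix(0L, 32, 32)
  mf <- augment(const, cm, augmentation_spec("median_filter", seed = 2))
  expect_equal(mf$image, const, tolerance = 1e-6)
  expect_identical(mf$mask, cm)

  # cutout of a k x k interior patch turns exactly k^2 pixels to background
  full <- matrix(1L, 64, 64)
  img <- array(0.5, dim = c(64, 64, 3))
  co <- augment(img, full,
                augmentation_spec("cutout", list(frac = 0.25), seed = 3))
  expect_equal(sum(co$mask == 0L), 16L^2)
  expect_equal(sum(co$image == 0), 3L * 16L^2)

  # fog brightens toward the atmospheric value and keeps the mask
  fo <- augment(sc$image, sc$mask,
                augmentation_spec("fog", list(transmission = 0.7), seed = 4))
  expect_identical(fo$mask, sc$mask)
  expect_equal(fo$image, 0.7 * sc$image + 0.3 * 0.9, tolerance = 1e-12)

  expect_error(augmentation_spec("zoom"), "unknown augmentation")
  expect_error(augment(sc$image, matrix(0L, 5, 5),
                       augmentation_spec("fog")), "same spatial size")
})

test_that("augmented pairs stay palette-valid and size-consistent", {
  sc <- generate_scene(size = 96, seed = 77)
  ops <- c("rotation", "affine", "fog", "gaussian_noise", "median_filter",
           "cutout")
  set.seed(123)
  for (i in 1:30) {
    op <- sample(ops, 1)
    a <- augment(sc$image, sc$mask, augmentation_spec(op, seed = i))
    expect_equal(dim(a$image), dim(sc$image), info = op)
    expect_equal(dim(a$mask), dim(sc$mask), info = op)
    expect_true(all(a$mask %in% 0:4), info = op)
    expect_true(all(a$image >= -1e-9 & a$image <= 1 + 1e-9), info = op)
    # same spec twice gives the same result
    b <- augment(sc$image, sc$mask, augmentation_spec(op, seed = i))
    expect_identical(a, b)
  }
})

test_that("split_dataset reproduces the 6:2:2 bookkeeping", {
  m <- split_dataset(910, seed = 7)
  expect_equal(unname(m$counts), c(546L, 182L, 182L))
  expect_equal(unname(m$augmented_counts), c(5460L, 1820L, 1820L))
  expect_equal(sum(m$augmented_counts), 9100L)

  m10 <- split_dataset(10, seed = 1)
  expect_equal(unname(m10$counts), c(6L, 2L, 2L))

  # partition: union = all ids, pairwise disjoint
  ids <- unlist(m$splits)
  expect_equal(sort(unname(ids)), sprintf("img_%05d", 1:910))
  expect_length(intersect(m$splits$train, m$splits$val), 0)
  expect_length(intersect(m$splits$train, m$splits$test), 0)
  expect_length(intersect(m$splits$val, m$splits$test), 0)

  # largest-remainder handles non-divisible sizes and stays a partition
  m11 <- split_dataset(11, seed = 2)
  expect_equal(sum(m11$counts), 11L)
  expect_error(split_dataset(5), "at least 10")
})

test_that("VOC trees round-trip masks bit-exactly", {
  scenes <- lapply(1:4, function(i) generate_scene(size = 96, seed = 200 + i))
  names(scenes) <- sprintf("img_%05d", 1:4)
  manifest <- split_dataset(names(scenes), ratios = c(2, 1, 1),
                            aug_factor = 1, seed = 3)
  root <- file.path(tempdir(), "voc_test")
  unlink(root, recursive = TRUE)
  write_voc(scenes, root, manifest)
  expect_true(file.exists(file.path(root, "JPEGImages", "img_00001.jpg")))
  expect_true(file.exists(file.path(root, "SegmentationClass", "img_00001.png")))

  back <- read_voc(root)
  expect_setequal(names(back$scenes), names(scenes))
  for (id in names(scenes)) {
    expect_identical(back$scenes[[id]]$mask, scenes[[id]]$mask)
    expect_equal(back$scenes[[id]]$pixel_counts,
                 scenes[[id]]$pixel_counts)
  }
  expect_setequal(names(back$splits), names(manifest$splits))
  for (nm in names(manifest$splits)) {
    expect_equal(sort(back$splits[[nm]]), sort(manifest$splits[[nm]]))
  }

  # palette PNG stores exactly the palette colors
  png_rgb <- png::readPNG(file.path(root, "SegmentationClass", "img_00001.png"))
  cols <- unique(matrix(round(png_rgb * 255), ncol = 3,
                        dimnames = NULL)[, 1, drop = TRUE])
  expect_true(all(round(png_rgb * 255) %in% c(0, 128)))

  # a corrupted mask color is reported with the file name
  bad <- png_rgb; bad[1, 1, ] <- c(10, 20, 30) / 255
  png::writePNG(bad, file.path(root, "SegmentationClass", "img_00001.png"))
  expect_error(read_voc(root), "img_00001.png")
  expect_error(read_voc(tempfile()), "missing directory|not a VOC tree")
})
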