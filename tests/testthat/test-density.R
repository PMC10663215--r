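test_that("mass_pixel_sample enforces its invariants", {
  s <- mass_pixel_sample("a", c(cane = 100, leaf = 10), c(cane = 0.2, leaf = 0.001))
  expect_s3_class(s, "mass_pixel_sample")
  expect_identical(unname(s$pixels[["broken_cane"]]), 0L)
  expect_error(mass_pixel_sample("b", c(cane = -1), c(cane = 0)), "non-negative")
  expect_error(mass_pixel_sample("c", c(cane = 0), c(cane = 1)), "zero pixels")
  expect_error(mass_pixel_sample("d", c(stalk = 5), c(stalk = 1)), "names")
})

test_that("count_class_pixels counts palette classes and rejects unknown colors", {
  m <- matrix(0L, 10, 10)
  expect_equal(unname(count_class_pixels(m)["background"]), 100L)
  m[1:10, 1:10] <- 1L
  cc <- count_class_pixels(m)
  expect_equal(unname(cc["cane"]), 100L)
  expect_equal(sum(cc), 100L)

  m2 <- matrix(0L, 10, 10)
  m2[1:3, 1:10] <- 1L   # 30 cane
  m2[4:5, 1:10] <- 2L   # 20 broken
  cc2 <- count_class_pixels(m2)
  expect_equal(unname(cc2[c("cane", "broken_cane", "top", "leaf")]),
               c(30L, 20L, 0L, 0L))
  expect_equal(sum(cc2), 100L)

  # RGB raster path with an off-palette color names the pixel value
  rgb <- class_to_rgb(m2)
  expect_identical(rgb_to_class(rgb), m2)
  rgb[1, 1, ] <- c(7, 7, 7) / 255
  expect_error(count_class_pixels(rgb), "\\(7,7,7\\)")
  expect_error(count_class_pixels(matrix(9L, 2, 2)), "offending value 9")
})

test_that("fit_surface_density recovers Gaussian parameters and flags degeneracy", {
  # constant densities: exact mean, zero spread, perfect fit by convention
  px <- rep(1000L, 10)
  samples <- lapply(1:10, function(i) {
    mass_pixel_sample(paste0("s", i), c(cane = px[i]), c(cane = px[i] * 1.52e-3))
  })
  fit <- fit_surface_density(samples, classes = "cane")
  expect_equal(unname(fit$mu["cane"]), 1.52e-3)
  expect_equal(unname(fit$sigma["cane"]), 0)
  expect_equal(unname(fit$r2["cane"]), 1)

  expect_error(fit_surface_density(samples[1], classes = "cane"),
               "fewer than 2")

  # sampling oracle: n = 300 draws from Normal(m, s) recovers m within 3 se
  set.seed(77)
  m0 <- 7.4e-4; s0 <- 1.5e-4
  samples2 <- lapply(1:300, function(i) {
    p <- round(runif(1, 5e4, 5e5))
    mass_pixel_sample(paste0("t", i), c(broken_cane = p),
                      c(broken_cane = p * max(rnorm(1, m0, s0), 1e-6)))
  })
  fit2 <- fit_surface_density(samples2, classes = "broken_cane")
  expect_lt(abs(fit2$mu[["broken_cane"]] - m0), 3 * s0 / sqrt(300))
  expect_gt(fit2$r2[["broken_cane"]], 0.95)
  expect_equal(fit2$n_samples[["broken_cane"]], 300L)

  # histogram least-squares mode agrees with moments on clean data
  fit3 <- fit_surface_density(samples2, classes = "broken_cane",
                              method = "histogram", bins = 15)
  expect_lt(abs(fit3$mu[["broken_cane"]] - fit2$mu[["broken_cane"]]), 5e-5)
})

test_that("estimate_mass is mu * pixels with the reference densities", {
  expect_equal(unname(estimate_mass(c(cane = 0, leaf = 0))), rep(0, 4))
  est <- estimate_mass(c(cane = 1e5))
  expect_equal(unname(est["cane"]), 152)
  expect_equal(unname(estimate_mass(c(leaf = 1e6))["leaf"]), 30)
  # background from count_class_pixels is tolerated, other names are not
  expect_equal(unname(estimate_mass(c(background = 50, cane = 1e5))["cane"]), 152)
  expect_error(estimate_mass(c(cane = -5)), ">= 0")
  # value is zero iff the pixel count is zero
  est2 <- estimate_mass(c(cane = 10, top = 0))
  expect_true(est2[["cane"]] > 0 && est2[["top"]] == 0)
})

test_that("estimate_ratios implements the breakage/impurity definitions", {
  expect_equal(estimate_ratios(c(cane = 100, broken_cane = 0))$breakage, 0)
  expect_equal(estimate_ratios(c(cane = 100, broken_cane = 100))$breakage, 0.5)
  expect_equal(estimate_ratios(c(cane = 100))$impurity, 0)

  # pixel form with the reference densities
  est <- estimate_mass(c(cane = 1e5, broken_cane = 1e5))
  r <- estimate_ratios(est)
  expect_equal(r$breakage, 7.4e-4 / (1.52e-3 + 7.4e-4), tolerance = 1e-12)
  expect_equal(round(r$breakage, 4), 0.3274)

  expect_error(estimate_ratios(c(cane = 0, broken_cane = 0)), "undefined")

  # scale equivariance: k x pixels -> k x masses, unchanged ratios
  px <- c(cane = 12345, broken_cane = 2345, top = 999, leaf = 54321)
  m1 <- estimate_mass(px); m10 <- estimate_mass(px * 10)
  expect_equal(unname(unclass(m10)), unname(unclass(m1)) * 10)
  r1 <- estimate_ratios(m1); r10 <- estimate_ratios(m10)
  expect_equal(r1$breakage, r10$breakage)
  expect_equal(r1$impurity, r10$impurity)
  # unit invariance (g vs kg)
  rk <- estimate_ratios(unclass(m1) / 1000)
  expect_equal(rk$breakage, r1$breakage)
  expect_equal(rk$impurity, r1$impurity)
})

test_that("relative_error and evaluate_ratio_tables agree elementwise", {
  expect_equal(relative_error(5, 5), 0)
  expect_equal(round(relative_error(0.328, 0.319), 4), 0.0274)
  expect_equal(round(relative_error(0.328, 0.319), 3), 0.027)
  expect_equal(relative_error(0.1, 0.15), 0.5)
  expect_error(relative_error(0, 1), "> 0")

  pairs <- data.frame(measured = c(0.2, 0.3, 0.4, 0.25),
                      estimated = c(0.22, 0.27, 0.40, 0.30))
  rep <- evaluate_ratio_tables(pairs)
  expect_equal(rep$mean_relative_error,
               mean(relative_error(pairs$measured, pairs$estimated)))
  expect_equal(rep$per_sample$relative_error,
               relative_error(pairs$measured, pairs$estimated))
  expect_error(evaluate_ratio_tables(data.frame()), "at least one")

  ident <- data.frame(measured = c(0.2, 0.4), estimated = c(0.2, 0.4))
  expect_equal(evaluate_ratio_tables(ident)$mean_relative_error, 0)
})

test_that("regress_estimated_vs_measured returns OLS + exact ANOVA identity", {
  perfect <- data.frame(measured = 1:5, estimated = 1:5)
  r <- suppressWarnings(regress_estimated_vs_measured(perfect))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$r2, 1)
  expect_equal(r$anova$ss_residual, 0, tolerance = 1e-20)

  lin <- data.frame(measured = 0:3, estimated = c(0, 2, 4, 6))
  r2 <- suppressWarnings(regress_estimated_vs_measured(lin))
  expect_equal(r2$slope, 2)
  expect_equal(r2$r2, 1)

  set.seed(5)
  noisy <- data.frame(measured = runif(30), estimated = runif(30))
  r3 <- regress_estimated_vs_measured(noisy)
  expect_equal(r3$anova$ss_total,
               r3$anova$ss_regression + r3$anova$ss_residual)
  expect_equal(r3$anova$df_regression, 1)
  expect_equal(r3$anova$df_residual, 28)
  expect_equal(r3$anova$F,
               (r3$anova$ss_regression / 1) / (r3$anova$ss_residual / 28))
  expect_equal(r3$anova$significance,
               pf(r3$anova$F, 1, 28, lower.tail = FALSE))
  expect_error(regress_estimated_vs_measured(
    data.frame(measured = rep(1, 5), estimated = 1:5)), "degenerate")
})

test_that("confidence-interval selection retains the expected fraction", {
  expect_error(select_confidence_interval(fixture_samples(5), level = 1.2),
               "between 0 and 1")
  samples <- fixture_samples(400, seed = 99)
  dens <- generator_density_model()
  # near-certain band keeps everything
  all_kept <- select_confidence_interval(samples, level = 1 - 1e-12,
                                         density = dens)
  expect_equal(all_kept$n_retained, 400)
  # per-class marginal retention ~95% at level 0.95
  sel <- select_confidence_interval(samples, level = 0.95, density = dens)
  per_class_keep <- sapply(material_classes(), function(cl) {
    d <- sapply(samples, function(s) s$masses[[cl]] / s$pixels[[cl]])
    mean(abs(d - dens$mu[[cl]]) <= qnorm(0.975) * dens$sigma[[cl]])
  })
  expect_true(all(abs(per_class_keep - 0.95) < 3 * sqrt(0.95 * 0.05 / 400)))
  # joint marginal filtering keeps roughly 0.95^4 of samples
  expect_gt(sel$n_retained / 400, 0.95^4 - 0.06)
  expect_lt(sel$n_retained / 400, 0.95^4 + 0.06)
})

test_that("mass CSV round-trips and feeds the fitting pipeline", {
  samples <- fixture_samples(8)
  path <- tempfile(fileext = ".csv")
  write_mass_csv(samples, path)
  back <- read_mass_csv(path)
  expect_equal(length(back), 8)
  s0 <- samples[[3]]
  b0 <- back[[s0$sample_id]]
  expect_equal(b0$pixels, s0$pixels)
  expect_equal(b0$masses, s0$masses, tolerance = 1e-8)

  rep <- evaluate_ratio_tables(data.frame(measured = c(0.2, 0.3),
                                          estimated = c(0.25, 0.28),
                                          sample_id = c("a", "b")))
  out_csv <- tempfile(fileext = ".csv")
  out_json <- tempfile(fileext = ".json")
  write_evaluation_report(rep, csv = out_csv, json = out_json)
  got <- utils::read.csv(out_csv)
  expect_equal(nrow(got), 3) # two samples + summary row
  expect_equal(got$relative_error[3], rep$mean_relative_error)
  js <- jsonlite::read_json(out_json)
  expect_equal(js$mean_relative_error, rep$mean_relative_error)
})
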