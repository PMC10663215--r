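#' Per-sample pixel counts and measured masses
#'
#' A `mass_pixel_sample` records, for one image, the number of pixels and the
#' measured mass (grams) of each material class. Surface density is mass
#' divided by pixels (g/pixel), the quantity that bridges segmentation output
#' and mass.
#'
#' @param sample_id character scalar.
#' @param pixels named non-negative integer vector over (a subset of)
#'   [material_classes()].
#' @param masses named non-negative numeric vector (grams), same classes.
#' @return an object of class `mass_pixel_sample`.
#' @examples
#' mass_pixel_sample("s1", c(cane = 120000, leaf = 50000),
#'                   c(cane = 180.4, leaf = 1.6))
#' @export
mass_pixel_sample <- function(sample_id, pixels, masses) {
  cls <- material_classes()
  p <- stats::setNames(rep(0, 4), cls)
  m <- stats::setNames(rep(0, 4), cls)
  if (length(pixels) > 0) {
    check_class_names(names(pixels))
    p[names(pixels)] <- pixels
  }
  if (length(masses) > 0) {
    check_class_names(names(masses))
    m[names(masses)] <- masses
  }
  if (any(p < 0) || any(p != round(p))) {
    stop("pixel counts must be non-negative integers", call. = FALSE)
  }
  if (any(m < 0)) stop("masses must be non-negative", call. = FALSE)
  if (any(m > 0 & p == 0)) {
    stop("class with mass > 0 but zero pixels in sample '", sample_id,
         "': ", paste(cls[m > 0 & p == 0], collapse = ", "), call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 pixels = stats::setNames(as.integer(round(p)), cls),
                 masses = m),
            class = "mass_pixel_sample")
}

check_class_names <- function(nm) {
  if (is.null(nm) || !all(nm %in% material_classes())) {
    stop("names must be among: ", paste(material_classes(), collapse = ", "),
         call. = FALSE)
  }
  invisible(nm)
}

#' @export
print.mass_pixel_sample <- function(x, ...) {
  cat("<mass_pixel_sample>", x$sample_id, "\n")
  print(rbind(pixels = x$pixels, mass_g = x$masses))
  invisible(x)
}

#' Reference surface densities (g/pixel)
#'
#' The fitted mean surface densities shipped as defaults: 1.52e-3 (cane),
#' 7.4e-4 (broken cane), 8.8e-4 (top) and 3e-5 (leaf) grams per pixel. Cane is
#' roughly twice as dense per pixel as broken cane or top, and more than fifty
#' times denser than leaf, so cane mass errors dominate the ratio error
#' budget. Any fitted [fit_surface_density()] model can override these.
#'
#' @return a `surface_density_model` with the default means and `sigma = NA`.
#' @examples
#' default_surface_density()
#' @export
default_surface_density <- function() {
  new_surface_density_model(
    mu = c(cane = 1.52e-3, broken_cane = 7.4e-4, top = 8.8e-4, leaf = 3e-5),
    sigma = stats::setNames(rep(NA_real_, 4), material_classes()),
    r2 = stats::setNames(rep(NA_real_, 4), material_classes()),
    n_samples = stats::setNames(rep(0L, 4), material_classes())
  )
}

new_surface_density_model <- function(mu, sigma, r2, n_samples) {
  cls <- material_classes()
  stopifnot(identical(names(mu), cls))
  if (any(mu <= 0, na.rm = TRUE)) stop("mu must be > 0", call. = FALSE)
  if (any(sigma < 0, na.rm = TRUE)) stop("sigma must be >= 0", call. = FALSE)
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) stop("r2 must lie in [0,1]", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, r2 = r2, n_samples = n_samples),
            class = "surface_density_model")
}

#' @export
print.surface_density_model <- function(x, ...) {
  cat("<surface_density_model> (g/pixel)\n")
  print(rbind(mu = signif(x$mu, 4), sigma = signif(x$sigma, 4),
              r2 = round(x$r2, 4), n = x$n_samples))
  invisible(x)
}

#' Fit a Gaussian surface-density model per class
#'
#' For every material class, the per-sample surface densities `mass / pixels`
#' are collected over samples with a positive pixel count and a Gaussian is
#' fitted. The default method is moment matching (sample mean and standard
#' deviation); method `"histogram"` instead least-squares fits the Gaussian
#' PDF to the normalized frequency histogram. In both cases the reported
#' `r2` measures agreement between the normalized histogram heights and the
#' fitted PDF evaluated at the bin centers.
#'
#' @param samples list of [mass_pixel_sample()] objects.
#' @param classes classes to fit; default all four material classes.
#' @param method `"moments"` (default) or `"histogram"`.
#' @param bins number of histogram bins; default Sturges' rule.
#' @return a `surface_density_model`.
#' @export
fit_surface_density <- function(samples, classes = material_classes(),
                                method = c("moments", "histogram"),
                                bins = NULL) {
  method <- match.arg(method)
  cls <- material_classes()
  mu <- sg <- r2 <- stats::setNames(rep(NA_real_, 4), cls)
  ns <- stats::setNames(rep(0L, 4), cls)
  for (cl in classes) {
    px <- vapply(samples, function(s) s$pixels[[cl]], numeric(1))
    ms <- vapply(samples, function(s) s$masses[[cl]], numeric(1))
    drop <- px == 0
    if (any(drop & ms > 0)) {
      warning(sum(drop), " sample(s) with zero '", cl,
              "' pixels excluded from the fit", call. = FALSE)
    }
    dens <- ms[!drop] / px[!drop]
    if (length(dens) < 2) {
      stop("fewer than 2 usable samples for class '", cl, "'", call. = FALSE)
    }
    nb <- if (is.null(bins)) grDevices::nclass.Sturges(dens) else bins
    h <- graphics_free_hist(dens, nb)
    if (method == "moments") {
      fit_mu <- mean(dens)
      fit_sd <- stats::sd(dens)
    } else {
      start <- c(mean(dens), max(stats::sd(dens), 1e-12))
      obj <- function(th) {
        sum((h$density - stats::dnorm(h$mids, th[1], max(th[2], 1e-15)))^2)
      }
      opt <- stats::optim(start, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      fit_mu <- opt$par[1]
      fit_sd <- abs(opt$par[2])
    }
    mu[cl] <- fit_mu
    sg[cl] <- fit_sd
    r2[cl] <- histogram_r2(h, fit_mu, fit_sd)
    ns[cl] <- length(dens)
  }
  new_surface_density_model(mu, sg, r2, ns)
}

## equal-width histogram without graphics: densities at bin centers
graphics_free_hist <- function(x, bins) {
  bins <- max(2L, as.integer(bins))
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-1, 1) * max(abs(rng[1]) * 1e-8, 1e-12)
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  cnt <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), bins),
                  nbins = bins)
  wid <- diff(br)
  list(mids = (br[-1] + br[-length(br)]) / 2,
       density = cnt / (length(x) * wid),
       counts = cnt)
}

## R^2 of the Gaussian PDF against normalized histogram heights at bin centers
histogram_r2 <- function(h, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0) {
    # degenerate (constant) data: the fit is exact by convention
    return(1)
  }
  yhat <- stats::dnorm(h$mids, mu, sigma)
  ss_res <- sum((h$density - yhat)^2)
  ss_tot <- sum((h$density - mean(h$density))^2)
  if (ss_tot == 0) return(as.numeric(ss_res == 0))
  max(0, min(1, 1 - ss_res / ss_tot))
}

#' Estimate per-class mass from pixel counts
#'
#' Mass is surface density times pixel count: `M'_k = mu_k * P_k` for each
#' material class, in grams. With the default densities, 100000 cane pixels
#' weigh an estimated 152 g.
#'
#' @param pixels named non-negative vector of pixel counts per class (classes
#'   from [material_classes()]; missing classes count as 0). The full
#'   five-class vector from [count_class_pixels()] is accepted (background is
#'   ignored).
#' @param density a `surface_density_model`; default [default_surface_density()].
#' @return named numeric vector of estimated masses (g), one per material
#'   class, of class `mass_estimate`.
#' @examples
#' estimate_mass(c(cane = 1e5, leaf = 1e6))
#' @export
estimate_mass <- function(pixels, density = default_surface_density()) {
  cls <- material_classes()
  p <- stats::setNames(rep(0, 4), cls)
  keep <- intersect(names(pixels), cls)
  if (length(keep) < length(pixels) &&
      !all(setdiff(names(pixels), cls) %in% "background")) {
    check_class_names(setdiff(names(pixels), "background"))
  }
  p[keep] <- pixels[keep]
  if (any(p < 0)) stop("pixel counts must be >= 0", call. = FALSE)
  est <- density$mu[cls] * p
  structure(stats::setNames(as.numeric(est), cls), class = "mass_estimate")
}

#' Breakage and impurity ratios from per-class masses
#'
#' Breakage is the mass fraction of broken cane in all cane,
#' `M_B / (M_C + M_B)`; impurity is the mass fraction of top plus leaf in the
#' total, `(M_T + M_L) / (M_C + M_B + M_T + M_L)`. The same formulas apply to
#' measured masses and to estimates from [estimate_mass()]. Ratios are
#' fractions in \[0, 1\].
#'
#' @param masses named numeric vector of per-class masses (g); classes from
#'   [material_classes()], missing classes count as 0.
#' @return list with elements `breakage` and `impurity`, class `ratio_pair`.
#' @examples
#' estimate_ratios(estimate_mass(c(cane = 1e5, broken_cane = 1e5)))
#' @export
estimate_ratios <- function(masses) {
  cls <- material_classes()
  m <- stats::setNames(rep(0, 4), cls)
  check_class_names(names(masses))
  m[names(masses)] <- masses
  if (any(m < 0)) stop("masses must be >= 0", call. = FALSE)
  denom_b <- m[["cane"]] + m[["broken_cane"]]
  denom_i <- sum(m)
  if (denom_i == 0) {
    stop("undefined ratios: total mass is zero (no material present)",
         call. = FALSE)
  }
  breakage <- if (m[["broken_cane"]] == 0) 0 else {
    if (denom_b == 0) {
      stop("undefined breakage ratio: cane and broken-cane mass both zero",
           call. = FALSE)
    }
    m[["broken_cane"]] / denom_b
  }
  impurity <- if (m[["top"]] + m[["leaf"]] == 0) 0 else
    (m[["top"]] + m[["leaf"]]) / denom_i
  structure(list(breakage = as.numeric(breakage),
                 impurity = as.numeric(impurity)),
            class = "ratio_pair")
}

#' @export
print.ratio_pair <- function(x, ...) {
  cat(sprintf("<ratio_pair> breakage %.4f  impurity %.4f\n",
              x$breakage, x$impurity))
  invisible(x)
}

#' Relative error between a measured and an estimated value
#'
#' `|measured - estimated| / measured`, as a fraction. The measured value must
#' be positive.
#'
#' @param measured positive numeric vector.
#' @param estimated non-negative numeric vector, recycled against `measured`.
#' @return numeric vector of relative errors.
#' @examples
#' relative_error(0.328, 0.319) # 0.0274...
#' @export
relative_error <- function(measured, estimated) {
  if (any(measured <= 0)) stop("measured values must be > 0", call. = FALSE)
  if (any(estimated < 0)) stop("estimated values must be >= 0", call. = FALSE)
  abs(measured - estimated) / measured
}

#' Evaluate measured-vs-estimated ratio tables
#'
#' Given pairs of measured and estimated ratios (one row per sample), computes
#' the per-sample relative errors, their arithmetic mean, and the ordinary
#' least-squares regression of estimated on measured with its ANOVA
#' decomposition. This is the end-to-end evaluation protocol for breakage and
#' impurity ratio estimation.
#'
#' @param pairs data.frame with columns `measured` and `estimated`
#'   (fractions); an optional `sample_id` column is carried through.
#' @return an `evaluation_report`: list with `per_sample` (data.frame),
#'   `mean_relative_error`, and `regression` (the [regress_estimated_vs_measured()]
#'   output, `NULL` when fewer than 3 pairs).
#' @export
evaluate_ratio_tables <- function(pairs) {
  if (!is.data.frame(pairs) || nrow(pairs) < 1) {
    stop("need a data.frame with at least one (measured, estimated) pair",
         call. = FALSE)
  }
  stopifnot(all(c("measured", "estimated") %in% names(pairs)))
  err <- relative_error(pairs$measured, pairs$estimated)
  per <- data.frame(
    sample_id = if ("sample_id" %in% names(pairs)) pairs$sample_id
                else seq_len(nrow(pairs)),
    measured = pairs$measured,
    estimated = pairs$estimated,
    relative_error = err
  )
  reg <- if (nrow(pairs) >= 3 && stats::var(pairs$measured) > 0) {
    regress_estimated_vs_measured(pairs)
  } else NULL
  structure(list(per_sample = per,
                 mean_relative_error = mean(err),
                 regression = reg),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", nrow(x$per_sample), "samples\n")
  cat(sprintf("  mean relative error: %.4f (%.1f%%)\n",
              x$mean_relative_error, 100 * x$mean_relative_error))
  if (!is.null(x$regression)) {
    r <- x$regression
    cat(sprintf("  OLS estimated ~ measured: slope %.4f, intercept %.5f, R^2 %.4f\n",
                r$slope, r$intercept, r$r2))
    cat(sprintf("  ANOVA: F(1,%d) = %.2f, p = %.3g\n",
                r$anova$df_residual, r$anova$F, r$anova$significance))
  }
  invisible(x)
}

#' Ordinary least squares of estimated on measured, with ANOVA
#'
#' Decomposes the total sum of squares into regression and residual parts with
#' degrees of freedom (1, n - 2); `F = MS_reg / MS_res` and the significance
#' is the upper tail of the F distribution.
#'
#' @param pairs data.frame with `measured` and `estimated` columns (>= 3 rows).
#' @return list with `slope`, `intercept`, `r2`, and `anova` (list: `ss_regression`,
#'   `ss_residual`, `ss_total`, `df_regression`, `df_residual`, `F`,
#'   `significance`).
#' @export
regress_estimated_vs_measured <- function(pairs) {
  stopifnot(all(c("measured", "estimated") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(pairs$measured) == 0) {
    stop("degenerate regressor: measured values have zero variance",
         call. = FALSE)
  }
  fit <- stats::lm(estimated ~ measured, data = pairs)
  an <- stats::anova(fit)
  ss_reg <- an["measured", "Sum Sq"]
  ss_res <- an["Residuals", "Sum Sq"]
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = summary(fit)$r.squared,
    anova = list(
      ss_regression = ss_reg,
      ss_residual = ss_res,
      ss_total = ss_reg + ss_res,
      df_regression = an["measured", "Df"],
      df_residual = an["Residuals", "Df"],
      F = an["measured", "F value"],
      significance = an["measured", "Pr(>F)"]
    )
  )
}

#' Keep samples whose surface densities fall inside a confidence band
#'
#' A sample is retained when, for every material class present in it
#' (pixels > 0), its surface density lies within `mu +/- z(level) * sigma` of
#' the fitted per-class Gaussian. Filtering is marginal per class: one
#' out-of-band class drops the sample.
#'
#' @param samples list of [mass_pixel_sample()] objects.
#' @param level confidence level in (0, 1); default 0.95 (z = 1.96).
#' @param density optional `surface_density_model`; fitted from `samples`
#'   when omitted.
#' @return list with `retained` (the surviving samples), `kept` (logical
#'   vector), and `n_retained`.
#' @export
select_confidence_interval <- function(samples, level = 0.95, density = NULL) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  if (is.null(density)) density <- fit_surface_density(samples)
  z <- stats::qnorm(1 - (1 - level) / 2)
  kept <- vapply(samples, function(s) {
    ok <- TRUE
    for (cl in material_classes()) {
      if (s$pixels[[cl]] > 0) {
        d <- s$masses[[cl]] / s$pixels[[cl]]
        mu <- density$mu[[cl]]; sg <- density$sigma[[cl]]
        if (is.finite(sg) && sg > 0 && abs(d - mu) > z * sg) ok <- FALSE
      }
    }
    ok
  }, logical(1))
  list(retained = samples[kept], kept = kept, n_retained = sum(kept))
}

#' Read and write per-sample mass tables
#'
#' CSV layout: columns `sample_id, class, pixels, mass_g`, one row per sample
#' and class, `class` among [material_classes()], UTF-8 with header.
#'
#' @param path CSV file path.
#' @param samples list of [mass_pixel_sample()] objects.
#' @return `read_mass_csv` returns a list of `mass_pixel_sample`;
#'   `write_mass_csv` returns `path` invisibly.
#' @export
read_mass_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "pixels", "mass_g")
  if (!all(need %in% names(df))) {
    stop("mass CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  check_class_names(unique(df$class))
  lapply(split(df, df$sample_id), function(d) {
    mass_pixel_sample(d$sample_id[1],
                      stats::setNames(d$pixels, d$class),
                      stats::setNames(d$mass_g, d$class))
  })
}

#' @rdname read_mass_csv
#' @export
write_mass_csv <- function(samples, path) {
  rows <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, class = material_classes(),
               pixels = unname(s$pixels), mass_g = unname(s$masses))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an evaluation report to CSV and JSON
#'
#' The CSV holds the per-sample rows followed by a summary row carrying the
#' mean relative error; the JSON mirrors the full report structure.
#'
#' @param report an `evaluation_report`.
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return invisible `report`.
#' @export
write_evaluation_report <- function(report, csv = NULL, json = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(csv)) {
    per <- report$per_sample
    summary_row <- data.frame(sample_id = "mean", measured = NA,
                              estimated = NA,
                              relative_error = report$mean_relative_error)
    utils::write.csv(rbind(per, summary_row), csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(unclass(report), json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(report)
}
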