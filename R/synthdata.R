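#' Synthetic raw-sugarcane scene generation
#'
#' Renders scenes that emulate conveyor-belt images of harvested raw
#' sugarcane on a dark background: long slightly-curved cane ribbons, short
#' jagged broken-cane fragments, tapered tops and thin curved leaf strips.
#' Objects are painted in that order, later objects occluding earlier ones;
#' the mask records the topmost object per pixel. Per-class true masses are
#' pixel counts times a surface-density draw from `Normal(mu, sigma)`
#' truncated at zero, so a `sigma = 0` model yields exactly
#' `mass = mu * pixels`.
#'
#' @param n_objects named vector of object counts per material class;
#'   default 3 cane, 3 broken cane, 3 tops, 4 leaves.
#' @param size square image side in pixels (>= 64); default 512.
#' @param density a `surface_density_model` supplying `mu` and `sigma`
#'   (g/pixel); default [generator_density_model()].
#' @param seed integer seed; the same seed reproduces the scene bit-exactly.
#' @return a `synthetic_scene`: list with `image` (`size x size x 3` in
#'   \[0,1\]), `mask` (integer matrix, palette indices 0..4), `pixel_counts`
#'   (recomputed from the mask), `true_masses` (g), `density_draws`
#'   (g/pixel) and `seed`.
#' @export
generate_scene <- function(n_objects = c(cane = 3, broken_cane = 3,
                                         top = 3, leaf = 4),
                           size = 512L, density = generator_density_model(),
                           seed = 1L) {
  if (size < 64) stop("size must be >= 64", call. = FALSE)
  if (any(n_objects < 0)) stop("object counts must be >= 0", call. = FALSE)
  check_class_names(names(n_objects))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  s <- as.integer(size)
  mask <- matrix(0L, s, s)
  # per-object id layer so image shading can follow occlusion order
  shade <- matrix(0, s, s)
  counts <- stats::setNames(rep(0L, 4), material_classes())

  paint <- function(cls_idx, centers_r, centers_c, radii) {
    jitter_level <- stats::rnorm(1, 0, 0.05)
    for (k in seq_along(centers_r)) {
      r <- radii[k]
      rr <- round(centers_r[k]); cc <- round(centers_c[k])
      r0 <- max(1, rr - ceiling(r)); r1 <- min(s, rr + ceiling(r))
      c0 <- max(1, cc - ceiling(r)); c1 <- min(s, cc + ceiling(r))
      if (r0 > r1 || c0 > c1) next
      ir <- r0:r1
      ic <- c0:c1
      dr <- outer((ir - centers_r[k])^2, (ic - centers_c[k])^2, "+")
      inside <- dr <= r^2
      mask[ir, ic][inside] <<- cls_idx
      shade[ir, ic][inside] <<- jitter_level
    }
  }

  ## a slightly curved quadratic path across the image
  bezier_path <- function(len_frac, n_pts) {
    p0 <- stats::runif(2, 0.05, 0.95) * s
    ang <- stats::runif(1, 0, 2 * pi)
    len <- len_frac * s
    p2 <- p0 + len * c(cos(ang), sin(ang))
    mid <- (p0 + p2) / 2 + stats::rnorm(2, 0, 0.08 * len)
    t <- seq(0, 1, length.out = n_pts)
    list(r = (1 - t)^2 * p0[1] + 2 * t * (1 - t) * mid[1] + t^2 * p2[1],
         c = (1 - t)^2 * p0[2] + 2 * t * (1 - t) * mid[2] + t^2 * p2[2])
  }

  draw_class <- function(cls) {
    idx <- match(cls, class_names()) - 1L
    n <- n_objects[[cls]] %||% 0
    if (is.na(n) || n == 0) return(invisible(NULL))
    for (obj in seq_len(n)) {
      ok <- FALSE
      for (try in 1:8) {
        if (cls == "cane") {
          w <- stats::runif(1, 0.055, 0.085) * s / 2
          pth <- bezier_path(stats::runif(1, 0.6, 1.1), max(12, round(s / 8)))
          rad <- rep(w, length(pth$r))
        } else if (cls == "broken_cane") {
          w <- stats::runif(1, 0.045, 0.07) * s / 2
          pth <- bezier_path(stats::runif(1, 0.08, 0.2), 10)
          rad <- w * stats::runif(length(pth$r), 0.65, 1.1) # jagged edge
        } else if (cls == "top") {
          w0 <- stats::runif(1, 0.05, 0.075) * s / 2
          pth <- bezier_path(stats::runif(1, 0.25, 0.45), max(10, round(s / 16)))
          rad <- seq(w0, 0.1 * w0, length.out = length(pth$r)) # taper
        } else { # leaf
          w <- max(2, stats::runif(1, 0.025, 0.045) * s / 2)
          pth <- bezier_path(stats::runif(1, 0.5, 0.9), max(14, round(s / 8)))
          rad <- rep(w, length(pth$r))
        }
        keep <- pth$r > -s * 0.2 & pth$r < s * 1.2 &
          pth$c > -s * 0.2 & pth$c < s * 1.2
        if (sum(keep) >= 3) {
          paint(idx, pth$r[keep], pth$c[keep], rad[keep])
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place a '", cls, "' object in a ", s, "x", s,
                    " scene", call. = FALSE)
    }
  }

  for (cls in material_classes()) draw_class(cls)

  counts_all <- count_class_pixels(mask)
  counts <- counts_all[material_classes()]

  ## image: per-class base colors + per-object shading + pixel noise
  base_cols <- rbind(
    background  = c(0.04, 0.04, 0.05),
    cane        = c(0.62, 0.46, 0.29),
    broken_cane = c(0.85, 0.79, 0.55),
    top         = c(0.33, 0.60, 0.27),
    leaf        = c(0.63, 0.72, 0.32)
  )
  img <- array(0, dim = c(s, s, 3))
  for (k in 1:3) {
    img[, , k] <- matrix(base_cols[mask + 1L, k], s, s) +
      shade * (mask > 0) +
      matrix(stats::rnorm(s * s, 0, 0.025), s, s)
  }
  img <- pmin(pmax(img, 0), 1)

  draws <- stats::setNames(rep(NA_real_, 4), material_classes())
  masses <- stats::setNames(rep(0, 4), material_classes())
  for (cls in material_classes()) {
    if (counts[[cls]] > 0) {
      draws[cls] <- rtrunc_normal(1, density$mu[[cls]],
                                  ifelse(is.finite(density$sigma[[cls]]),
                                         density$sigma[[cls]], 0))
      masses[cls] <- counts[[cls]] * draws[cls]
    }
  }

  structure(list(image = img, mask = mask, pixel_counts = counts,
                 true_masses = masses, density_draws = draws,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

## normal draw truncated to (0, Inf); sigma 0 returns the mean
rtrunc_normal <- function(n, mu, sigma) {
  if (sigma == 0) return(rep(mu, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mu, sigma)
      if (v > 0) break
    }
    out[i] <- v
  }
  out
}

#' Default generator surface densities
#'
#' Means equal the reference densities; standard deviations reflect the
#' qualitative spread of the material classes (cane concentrated at about 8%
#' relative spread; broken cane, top and leaf scattered at roughly 20%).
#'
#' @return a `surface_density_model` with positive sigmas.
#' @export
generator_density_model <- function() {
  new_surface_density_model(
    mu = c(cane = 1.52e-3, broken_cane = 7.4e-4, top = 8.8e-4, leaf = 3e-5),
    sigma = c(cane = 1.2e-4, broken_cane = 1.5e-4, top = 1.8e-4, leaf = 7e-6),
    r2 = stats::setNames(rep(NA_real_, 4), material_classes()),
    n_samples = stats::setNames(rep(0L, 4), material_classes())
  )
}

#' Synthetic mass/pixel dataset
#'
#' Emulates a weighed mass dataset: per sample, pixel counts are drawn
#' uniformly from per-class ranges and masses are counts times a truncated
#' normal surface-density draw, matching the statistical structure assumed
#' by [fit_surface_density()].
#'
#' @param n_samples number of samples (>= 1).
#' @param density a `surface_density_model` (means and sigmas used).
#' @param pixel_ranges named list of `c(min, max)` pixel-count ranges per
#'   class.
#' @param seed integer seed.
#' @return list of [mass_pixel_sample()] objects.
#' @export
make_mass_dataset <- function(n_samples, density = generator_density_model(),
                              pixel_ranges = list(
                                cane = c(1e5, 6e5),
                                broken_cane = c(2e4, 3e5),
                                top = c(3e4, 2.5e5),
                                leaf = c(1e5, 2e6)),
                              seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  check_class_names(names(pixel_ranges))
  for (rg in pixel_ranges) {
    if (length(rg) != 2 || rg[1] < 0 || rg[2] < rg[1]) {
      stop("pixel ranges must be c(min, max) with 0 <= min <= max",
           call. = FALSE)
    }
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  lapply(seq_len(n_samples), function(i) {
    px <- vapply(material_classes(), function(cls) {
      rg <- pixel_ranges[[cls]]
      if (is.null(rg)) 0 else round(stats::runif(1, rg[1], rg[2]))
    }, numeric(1))
    ms <- vapply(material_classes(), function(cls) {
      if (px[[cls]] == 0) return(0)
      sg <- density$sigma[[cls]]
      px[[cls]] * rtrunc_normal(1, density$mu[[cls]],
                                if (is.finite(sg)) sg else 0)
    }, numeric(1))
    mass_pixel_sample(sprintf("synthetic_%04d", i), px, ms)
  })
}

#' Image/mask augmentation
#'
#' The six augmentation operators: `rotation` and `affine` are applied
#' jointly to image (bilinear) and mask (nearest neighbour) with exposed
#' borders filled with background; `fog` (blend toward a bright atmospheric
#' value by a transmission factor), `gaussian_noise` and `median_filter`
#' alter the image only; `cutout` zeroes a rectangular image patch and sets
#' the same patch to background in the mask.
#'
#' @param op one of `"rotation"`, `"affine"`, `"fog"`, `"gaussian_noise"`,
#'   `"median_filter"`, `"cutout"`.
#' @param params named list of operator parameters (see Details); missing
#'   parameters are drawn randomly under `seed`.
#' @param seed integer seed.
#' @details Parameters: rotation `angle` (degrees); affine `scale`, `shear`,
#'   `translate` (fraction of size); fog `transmission` in \[0.6, 0.95\] and
#'   `atmosphere` (bright value, default 0.9); gaussian_noise `sd` (default
#'   0.02); median_filter `radius` (default 1, i.e. a 3x3 window); cutout
#'   `frac` (patch side as a fraction of image side, default 0.1-0.3).
#' @return an `augmentation_spec` list.
#' @export
augmentation_spec <- function(op, params = list(), seed = 1L) {
  ops <- c("rotation", "affine", "fog", "gaussian_noise", "median_filter",
           "cutout")
  if (!op %in% ops) {
    stop("unknown augmentation '", op, "'; valid: ",
         paste(ops, collapse = ", "), call. = FALSE)
  }
  structure(list(op = op, params = params, seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' @rdname augmentation_spec
#' @param image `H x W x 3` array in \[0,1\].
#' @param mask integer class-index matrix of the same spatial size.
#' @param spec an [augmentation_spec()].
#' @export
augment <- function(image, mask, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  if (!identical(dim(image)[1:2], dim(mask))) {
    stop("image and mask must have the same spatial size", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  p <- spec$params
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- switch(spec$op,
    rotation = {
      ang <- p$angle %||% stats::runif(1, -180, 180)
      th <- ang * pi / 180
      m <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
      warp_pair(image, mask, m, center = TRUE)
    },
    affine = {
      sc <- p$scale %||% stats::runif(1, 0.9, 1.1)
      sh <- p$shear %||% stats::runif(1, -0.1, 0.1)
      tr <- p$translate %||% stats::runif(2, -0.1, 0.1)
      m <- rbind(c(sc, sh), c(0, sc))
      warp_pair(image, mask, m, center = TRUE, shift = tr * c(h, w))
    },
    fog = {
      tt <- p$transmission %||% stats::runif(1, 0.6, 0.95)
      a <- p$atmosphere %||% 0.9
      list(image = tt * image + (1 - tt) * a, mask = mask)
    },
    gaussian_noise = {
      sd <- p$sd %||% 0.02
      list(image = pmin(pmax(image + array(stats::rnorm(length(image), 0, sd),
                                           dim = dim(image)), 0), 1),
           mask = mask)
    },
    median_filter = {
      r <- p$radius %||% 1L
      eb <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
      fl <- EBImage::medianFilter(eb, size = r)
      list(image = aperm(EBImage::imageData(fl), c(2, 1, 3)), mask = mask)
    },
    cutout = {
      frac <- p$frac %||% stats::runif(1, 0.1, 0.3)
      kh <- max(1L, round(frac * h)); kw <- max(1L, round(frac * w))
      r0 <- sample.int(h - kh + 1L, 1L); c0 <- sample.int(w - kw + 1L, 1L)
      img2 <- image; msk2 <- mask
      img2[r0:(r0 + kh - 1L), c0:(c0 + kw - 1L), ] <- 0
      msk2[r0:(r0 + kh - 1L), c0:(c0 + kw - 1L)] <- 0L
      list(image = img2, mask = msk2)
    }
  )
  out
}

## inverse-mapped joint warp: image bilinear, mask nearest, background fill
warp_pair <- function(image, mask, m, center = TRUE, shift = c(0, 0)) {
  h <- dim(image)[1]; w <- dim(image)[2]
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  minv <- solve(m)
  gr <- rep(seq_len(h), times = w) - (if (center) cr else 0) - shift[1]
  gc <- rep(seq_len(w), each = h) - (if (center) cc else 0) - shift[2]
  sr <- minv[1, 1] * gr + minv[1, 2] * gc + (if (center) cr else 0)
  sc <- minv[2, 1] * gr + minv[2, 2] * gc + (if (center) cc else 0)
  inside <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  # nearest for the mask
  nr <- pmin(pmax(round(sr), 1L), h); nc <- pmin(pmax(round(sc), 1L), w)
  msk <- matrix(0L, h, w)
  msk[inside] <- mask[cbind(nr[inside], nc[inside])]
  # bilinear for the image
  fr <- pmin(pmax(floor(sr), 1L), h); fc <- pmin(pmax(floor(sc), 1L), w)
  cr2 <- pmin(fr + 1L, h); cc2 <- pmin(fc + 1L, w)
  ar <- sr - fr; ac <- sc - fc
  img <- array(0, dim = dim(image))
  for (k in 1:3) {
    ch <- image[, , k]
    v <- (1 - ar) * ((1 - ac) * ch[cbind(fr, fc)] + ac * ch[cbind(fr, cc2)]) +
      ar * ((1 - ac) * ch[cbind(cr2, fc)] + ac * ch[cbind(cr2, cc2)])
    pl <- matrix(0, h, w)
    pl[inside] <- v[inside]
    img[, , k] <- pl
  }
  list(image = img, mask = msk)
}

#' Split a dataset into train/validation/test
#'
#' Random disjoint split with sizes proportional to `ratios` by
#' largest-remainder rounding. The augmentation factor gives the
#' post-augmentation image count per split (the original counts toward the
#' factor: factor 10 means the original plus 9 augmented copies).
#'
#' @param ids integer count or character vector of sample ids.
#' @param ratios split proportions; default `c(6, 2, 2)`.
#' @param aug_factor augmentation multiplier; default 10.
#' @param seed integer seed for the random assignment.
#' @return a `dataset_manifest`: list with `splits` (named list of id
#'   vectors), `counts`, `augmented_counts`, `ratios`, `aug_factor`.
#' @examples
#' m <- split_dataset(910, seed = 7)
#' m$counts            # 546 182 182
#' m$augmented_counts  # 5460 1820 1820
#' @export
split_dataset <- function(ids, ratios = c(6, 2, 2), aug_factor = 10L,
                          seed = 1L) {
  if (length(ids) == 1L && is.numeric(ids)) {
    ids <- sprintf("img_%05d", seq_len(ids))
  }
  n <- length(ids)
  if (n < sum(ratios)) {
    stop("need at least ", sum(ratios), " ids for ratios ",
         paste(ratios, collapse = ":"), call. = FALSE)
  }
  exact <- n * ratios / sum(ratios)
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    give <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[give] <- sizes[give] + 1L
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  perm <- sample(ids)
  splits <- list(
    train = sort(perm[seq_len(sizes[1])]),
    val = sort(perm[sizes[1] + seq_len(sizes[2])]),
    test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  )
  structure(list(splits = splits,
                 counts = stats::setNames(sizes, names(splits)),
                 augmented_counts = stats::setNames(sizes * aug_factor,
                                                    names(splits)),
                 ratios = ratios, aug_factor = aug_factor),
            class = "dataset_manifest")
}

#' Write and read a PASCAL-VOC-style dataset tree
#'
#' Layout: `JPEGImages/<id>.jpg` (RGB JPEG), `SegmentationClass/<id>.png`
#' (lossless PNG colored with the scene palette, so masks round-trip
#' bit-exactly) and `ImageSets/Segmentation/{train,val,test}.txt` with one id
#' per line.
#'
#' @param scenes named list of scenes (lists with `image` and `mask`); names
#'   are the sample ids.
#' @param root dataset root directory (created if needed).
#' @param manifest optional [split_dataset()] manifest; defaults to a single
#'   `train` split containing every id.
#' @return `write_voc` returns `root` invisibly. `read_voc` returns a list
#'   with `scenes` (images, masks, per-scene pixel counts) and `splits`.
#' @export
write_voc <- function(scenes, root, manifest = NULL) {
  ids <- names(scenes)
  if (is.null(ids)) ids <- sprintf("img_%05d", seq_along(scenes))
  dir.create(file.path(root, "JPEGImages"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(root, "SegmentationClass"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(root, "ImageSets", "Segmentation"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_along(scenes)) {
    eb <- EBImage::Image(aperm(scenes[[i]]$image, c(2, 1, 3)),
                         colormode = "Color")
    EBImage::writeImage(eb, file.path(root, "JPEGImages",
                                      paste0(ids[i], ".jpg")), quality = 95)
    png::writePNG(class_to_rgb(scenes[[i]]$mask),
                  file.path(root, "SegmentationClass", paste0(ids[i], ".png")))
  }
  splits <- if (is.null(manifest)) list(train = ids) else manifest$splits
  for (nm in names(splits)) {
    writeLines(splits[[nm]],
               file.path(root, "ImageSets", "Segmentation",
                         paste0(nm, ".txt")))
  }
  invisible(root)
}

#' @rdname write_voc
#' @export
read_voc <- function(root) {
  set_dir <- file.path(root, "ImageSets", "Segmentation")
  if (!dir.exists(set_dir)) {
    stop("not a VOC tree: missing directory ", set_dir, call. = FALSE)
  }
  split_files <- list.files(set_dir, pattern = "\\.txt$", full.names = TRUE)
  splits <- lapply(split_files, readLines)
  names(splits) <- tools::file_path_sans_ext(basename(split_files))
  ids <- unique(unlist(splits))
  scenes <- lapply(ids, function(id) {
    ipath <- file.path(root, "JPEGImages", paste0(id, ".jpg"))
    mpath <- file.path(root, "SegmentationClass", paste0(id, ".png"))
    if (!file.exists(ipath)) stop("missing image file ", ipath, call. = FALSE)
    if (!file.exists(mpath)) stop("missing mask file ", mpath, call. = FALSE)
    img <- aperm(EBImage::imageData(EBImage::readImage(ipath)), c(2, 1, 3))
    msk <- tryCatch(rgb_to_class(png::readPNG(mpath)),
                    error = function(e) {
                      stop("in mask file ", mpath, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    list(id = id, image = img, mask = msk,
         pixel_counts = count_class_pixels(msk)[material_classes()])
  })
  names(scenes) <- ids
  list(scenes = scenes, splits = splits)
}
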