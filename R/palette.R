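#' Material classes and segmentation palette
#'
#' Five segmentation classes are used throughout the package: background plus
#' the four material classes of harvested raw sugarcane. Class indices are
#' fixed: 0 background, 1 cane, 2 broken cane, 3 top, 4 leaf. Masks are stored
#' as integer matrices of class indices; on disk they are palette-colored PNGs
#' using the RGB triples returned by [scene_palette()].
#'
#' @return `class_names()` returns the five class names in index order.
#'   `material_classes()` returns the four material classes (no background).
#'   `scene_palette()` returns a 5x3 integer matrix of 8-bit RGB values with
#'   class names as rownames.
#' @examples
#' scene_palette()
#' @export
class_names <- function() {
  c("background", "cane", "broken_cane", "top", "leaf")
}

#' @rdname class_names
#' @export
material_classes <- function() {
  c("cane", "broken_cane", "top", "leaf")
}

#' @rdname class_names
#' @export
scene_palette <- function() {
  pal <- rbind(
    background  = c(0L, 0L, 0L),
    cane        = c(128L, 0L, 0L),
    broken_cane = c(0L, 0L, 128L),
    top         = c(0L, 128L, 0L),
    leaf        = c(128L, 128L, 0L)
  )
  colnames(pal) <- c("r", "g", "b")
  pal
}

#' Count pixels of each segmentation class in a mask
#'
#' Accepts either an integer class-index matrix (values 0..4) or an RGB array
#' (`H x W x 3`, 8-bit integers or values in \[0, 1\]) colored with the scene
#' palette. Any value or color outside the palette is an error naming the
#' offending pixel value.
#'
#' @param mask integer matrix of class indices, or an RGB array.
#' @param palette palette matrix as returned by [scene_palette()].
#' @return named integer vector of per-class pixel counts (all five classes,
#'   background included); counts sum to the raster area.
#' @examples
#' m <- matrix(0L, 10, 10); m[3:6, 2:9] <- 1L
#' count_class_pixels(m)
#' @export
count_class_pixels <- function(mask, palette = scene_palette()) {
  cls <- rownames(palette)
  n_class <- nrow(palette)
  if (is.array(mask) && length(dim(mask)) == 3L) {
    idx <- rgb_to_class(mask, palette)
  } else {
    idx <- as.integer(mask)
    bad <- which(is.na(idx) | idx < 0L | idx >= n_class)
    if (length(bad) > 0L) {
      stop("mask contains value(s) outside the palette index range [0, ",
           n_class - 1L, "]: first offending value ", mask[bad[1L]],
           call. = FALSE)
    }
  }
  counts <- tabulate(idx + 1L, nbins = n_class)
  names(counts) <- cls
  counts
}

## RGB array (H x W x 3) -> integer class indices; errors on unknown colors
rgb_to_class <- function(img, palette = scene_palette()) {
  v <- img
  if (max(v) <= 1 + 1e-9 && !is.integer(v)) v <- round(v * 255)
  v <- round(v)
  code <- v[, , 1] * 65536 + v[, , 2] * 256 + v[, , 3]
  pal_code <- palette[, 1] * 65536 + palette[, 2] * 256 + palette[, 3]
  idx <- match(as.vector(code), pal_code)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    hw <- arrayInd(bad, dim(code))
    stop(sprintf(
      "mask contains a color not in the palette: (%d,%d,%d) at row %d, col %d",
      v[hw[1], hw[2], 1], v[hw[1], hw[2], 2], v[hw[1], hw[2], 3],
      hw[1], hw[2]), call. = FALSE)
  }
  matrix(idx - 1L, nrow = nrow(code))
}

## integer class-index matrix -> RGB array in [0,1]
class_to_rgb <- function(mask, palette = scene_palette()) {
  stopifnot(all(mask >= 0L), all(mask < nrow(palette)))
  h <- nrow(mask); w <- ncol(mask)
  out <- array(0, dim = c(h, w, 3))
  for (k in 1:3) out[, , k] <- matrix(palette[mask + 1L, k] / 255, h, w)
  out
}
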