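# Preprocessing chain: resize -> grayscale -> unsharp mask -> Sobel edge
# enhancement, plus training-time augmentation. Images are plain numeric
# matrices (height x width) or arrays (height x width x channels) with
# values in [0, 1].

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Load an image file
#'
#' Reads PNG directly and JPEG/TIFF through EBImage, returning a
#' `height x width` matrix or `height x width x 3` array in `[0, 1]`.
#' Alpha channels are dropped.
#'
#' @param path image file path
#' @return numeric matrix or array
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))
    img <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  }
  d <- dim(img)
  if (length(d) == 3L) {
    if (d[3] == 2L) img <- img[, , 1L]            # gray + alpha
    if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
    if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1L]
  }
  clip01(img)
}

#' Resize an image to a standard square size
#'
#' Bilinear resampling to `side x side`; values stay in `[0, 1]`.
#'
#' @param img numeric matrix or `H x W x C` array
#' @param side target side length (default 224)
#' @return resized image
#' @export
resize_to_standard <- function(img, side = 224L) {
  d <- dim(img)
  if (is.null(d) || any(d[1:2] < 2L)) {
    stop("input image must have at least 2 pixels per axis")
  }
  if (d[1] == side && d[2] == side) return(img)
  out <- EBImage::imageData(EBImage::resize(img, w = side, h = side,
                                            filter = "bilinear"))
  clip01(out)
}

#' Convert an image to grayscale
#'
#' RGB inputs are reduced with the standard luminance weights
#' (0.299, 0.587, 0.114); grayscale inputs pass through unchanged.
#'
#' @param img matrix (grayscale) or `H x W x 3` array (RGB)
#' @return numeric matrix
#' @export
to_grayscale <- function(img) {
  d <- dim(img)
  if (length(d) == 2L) return(img)
  if (length(d) == 3L && d[3] == 1L) return(img[, , 1L])
  if (length(d) == 3L && d[3] == 3L) {
    return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  }
  stop("image must have 1 or 3 channels, got ",
       if (length(d) == 3L) d[3] else length(d))
}

#' Unsharp masking
#'
#' Sharpens by adding back the difference between the image and a blurred
#' copy: `clip(img + amount * (img - blur(img)), 0, 1)`. The named radius is
#' realised as a Gaussian blur with `sigma = radius / 3`, truncated at three
#' standard deviations, with reflecting boundaries.
#'
#' @param img grayscale matrix
#' @param radius blur radius in pixels (> 0); default 100
#' @param amount sharpening strength; 0 is the identity
#' @return sharpened matrix in `[0, 1]`
#' @export
unsharp_mask <- function(img, radius = 100, amount = 1.0) {
  stopifnot(is.matrix(img))
  if (radius <= 0) stop("radius must be > 0")
  blur <- cpp_gaussian_blur(img, radius / 3)
  clip01(img + amount * (img - blur))
}

sobel_kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L)

pad_replicate1 <- function(m) {
  m[c(1L, seq_len(nrow(m)), nrow(m)), c(1L, seq_len(ncol(m)), ncol(m))]
}

#' Sobel gradient magnitude
#'
#' `sqrt(Gx^2 + Gy^2)` with the standard 3 x 3 Sobel kernels; borders are
#' handled by replicate padding so the output has the input's size.
#'
#' @param img grayscale matrix
#' @return gradient-magnitude matrix
#' @export
sobel_magnitude <- function(img) {
  stopifnot(is.matrix(img))
  p <- pad_replicate1(img)
  gx <- conv2d_valid(p, sobel_kx)
  gy <- conv2d_valid(p, t(sobel_kx))
  sqrt(gx^2 + gy^2)
}

#' Sobel edge enhancement
#'
#' Adds a weighted Sobel gradient magnitude onto the image to accentuate
#' edges: `clip(img + weight * sobel_magnitude(img), 0, 1)`.
#'
#' @param img grayscale matrix
#' @param weight edge weight; default 0.5
#' @return enhanced matrix in `[0, 1]`
#' @export
sobel_enhance <- function(img, weight = 0.5) {
  clip01(img + weight * sobel_magnitude(img))
}

#' Full deterministic preprocessing chain
#'
#' Resize to `side x side`, grayscale conversion, unsharp masking, Sobel
#' edge enhancement. Augmentation is not part of this chain; it is applied
#' separately, and only during training.
#'
#' @param img image matrix/array or a file path
#' @param side target side length
#' @param unsharp_radius,unsharp_amount unsharp-mask parameters
#' @param sobel_weight Sobel enhancement weight
#' @return preprocessed `side x side` matrix in `[0, 1]`
#' @export
preprocess_image <- function(img, side = 224L, unsharp_radius = 100,
                             unsharp_amount = 1.0, sobel_weight = 0.5) {
  if (is.character(img)) img <- load_image(img)
  img <- resize_to_standard(img, side)
  img <- to_grayscale(img)
  img <- unsharp_mask(img, unsharp_radius, unsharp_amount)
  sobel_enhance(img, sobel_weight)
}

#' Rotate an image about its centre
#'
#' Bilinear interpolation, zero fill outside the source; output keeps the
#' input size. Positive angles rotate counter-clockwise in matrix (row,
#' column) coordinates.
#'
#' @param img grayscale matrix
#' @param angle rotation angle in degrees
#' @return rotated matrix
#' @export
rotate_image <- function(img, angle) {
  if (angle == 0) return(img)
  cpp_rotate_bilinear(img, angle)
}

shift_image <- function(img, dr, dc) {
  if (dr == 0 && dc == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  src_r <- seq_len(h) - dr
  src_c <- seq_len(w) - dc
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Draw random augmentation parameters
#'
#' Each transform fires independently with probability `p`; parameters are
#' uniform within the stated bounds: rotation within ±`max_rotate` degrees,
#' horizontal flip, translation within ±`max_translate` of the image size,
#' brightness and contrast adjustments within ±`max_intensity`.
#'
#' @param p per-transform application probability
#' @param max_rotate rotation bound in degrees
#' @param max_translate translation bound as a fraction of the side
#' @param max_intensity brightness/contrast bound as a fraction
#' @return list of transform parameters for [apply_augmentation()]
#' @export
draw_augmentation <- function(p = 0.5, max_rotate = 15, max_translate = 0.1,
                              max_intensity = 0.1) {
  list(
    angle = if (stats::runif(1) < p) stats::runif(1, -max_rotate, max_rotate) else 0,
    flip = stats::runif(1) < p,
    translate = if (stats::runif(1) < p) {
      stats::runif(2, -max_translate, max_translate)
    } else c(0, 0),
    brightness = if (stats::runif(1) < p) {
      stats::runif(1, -max_intensity, max_intensity)
    } else 0,
    contrast = if (stats::runif(1) < p) {
      1 + stats::runif(1, -max_intensity, max_intensity)
    } else 1
  )
}

#' Apply augmentation parameters to an image
#'
#' Deterministic given the parameter list; the output has the input's shape
#' and stays in `[0, 1]`. Identity parameters (angle 0, no flip, zero
#' translation, brightness 0, contrast 1) reproduce the input exactly.
#'
#' @param img grayscale matrix
#' @param par parameter list from [draw_augmentation()]
#' @return augmented matrix
#' @export
apply_augmentation <- function(img, par) {
  out <- rotate_image(img, par$angle)
  if (par$flip) out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  dr <- round(par$translate[1] * nrow(out))
  dc <- round(par$translate[2] * ncol(out))
  out <- shift_image(out, dr, dc)
  if (par$contrast != 1) {
    m <- mean(out)
    out <- (out - m) * par$contrast + m
  }
  if (par$brightness != 0) out <- out + par$brightness
  clip01(out)
}

#' Randomly augment an image (training only)
#'
#' Draws parameters from the current RNG and applies them; see
#' [draw_augmentation()] for the transform set and bounds.
#'
#' @param img grayscale matrix
#' @param ... passed to [draw_augmentation()]
#' @return augmented matrix
#' @export
augment <- function(img, ...) {
  apply_augmentation(img, draw_augmentation(...))
}
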