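# Seeded four-class phantom generator. Each phantom is an elliptical
# "brain" on a dark background with low-frequency internal texture,
# additive Gaussian noise, and a class-dependent lesion:
#   elongated - a curved high-intensity strip with a jagged boundary
#               (anisotropic, the geometry strip pooling is built for)
#   compact   - a round blob near the brain boundary
#   central   - a small bright blob near the centroid
#   none      - no lesion
# Class folders mirror the familiar four-class MRI layout so the phantom
# loader and a real-data loader share one code path.

phantom_class_levels <- c("elongated", "compact", "central", "none")

#' Mapping from phantom lesion classes to class-folder names
#'
#' @return named character vector: phantom class -> folder name
#' @export
phantom_class_map <- function() {
  c(elongated = "glioma", compact = "meningioma",
    central = "pituitary", none = "notumor")
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic integer mixing for per-image sub-seeds (kept below 2^31).
mix_seed <- function(...) {
  h <- 0
  for (v in c(...)) h <- (h * 1000003 + as.numeric(v)) %% 2147483647
  as.integer(h)
}

#' Phantom specification
#'
#' @param class_label one of `"elongated"`, `"compact"`, `"central"`, `"none"`
#' @param image_side image side length in pixels (>= 32)
#' @param lesion_intensity lesion gray level in `[0, 1]`; must exceed the
#'   brain texture (which stays below about 0.55) for the lesion to be bright
#' @param noise_sigma standard deviation of the additive Gaussian noise
#' @param seed integer seed; the same spec always renders the bit-identical
#'   image
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(class_label, image_side = 224L,
                         lesion_intensity = 0.9, noise_sigma = 0.05,
                         seed = 1L) {
  if (length(class_label) != 1L || !class_label %in% phantom_class_levels) {
    stop("unknown phantom class '", paste(class_label, collapse = ","),
         "'; must be one of ", paste(phantom_class_levels, collapse = ", "),
         call. = FALSE)
  }
  if (image_side < 32L) stop("image_side must be at least 32")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  stopifnot(lesion_intensity >= 0, lesion_intensity <= 1)
  structure(list(class_label = class_label,
                 image_side = as.integer(image_side),
                 lesion_intensity = lesion_intensity,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

runif1 <- function(lo, hi) stats::runif(1L, lo, hi)

# Rasterise the union of discs centred on a sampled curve. px/py are the
# pixel-centre coordinate vectors of the full grid.
paint_curve <- function(px, py, cx, cy, radius, side) {
  mask <- logical(side * side)
  for (t in seq_along(cx)) {
    d2 <- (px - cx[t])^2 + (py - cy[t])^2
    mask <- mask | (d2 <= radius[t]^2)
  }
  matrix(mask, side, side)
}

lesion_mask_for <- function(class_label, side, cx, cy, a, b) {
  grid_c <- rep(seq_len(side), each = side)   # column (x) of each pixel
  grid_r <- rep(seq_len(side), times = side)  # row (y) of each pixel
  px <- as.numeric(grid_c)
  py <- as.numeric(grid_r)
  if (class_label == "none") {
    return(matrix(FALSE, side, side))
  }
  if (class_label == "elongated") {
    # curved strip: quadratic Bezier, near-axis orientation, jagged
    # half-width; length about half the image side
    horiz <- stats::runif(1L) < 0.5
    theta <- runif1(-5, 5) * pi / 180 + if (horiz) 0 else pi / 2
    dirx <- cos(theta); diry <- sin(theta)
    perp_x <- -diry; perp_y <- dirx
    len <- side * runif1(0.45, 0.55)
    c0x <- cx + runif1(-0.06, 0.06) * side
    c0y <- cy + runif1(-0.06, 0.06) * side
    sag <- side * runif1(0.015, 0.035) * sample(c(-1, 1), 1L)
    p0 <- c(c0x - dirx * len / 2, c0y - diry * len / 2)
    p2 <- c(c0x + dirx * len / 2, c0y + diry * len / 2)
    p1 <- c(c0x + perp_x * sag, c0y + perp_y * sag)
    tt <- seq(0, 1, length.out = 81L)
    bx <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
    by <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
    w0 <- side * 0.02
    wt <- w0 * (1 + 0.5 * stats::runif(length(tt), -1, 1))
    return(paint_curve(px, py, bx, by, wt, side))
  }
  if (class_label == "compact") {
    # round blob near the brain boundary
    ang <- runif1(0, 2 * pi)
    f <- runif1(0.55, 0.65)
    lx <- cx + f * a * cos(ang)
    ly <- cy + f * b * sin(ang)
    r <- side * 0.09 * runif1(0.85, 1.15)
    return(matrix((px - lx)^2 + (py - ly)^2 <= r^2, side, side))
  }
  # central: small bright blob near the centroid
  lx <- cx + runif1(-0.05, 0.05) * side
  ly <- cy + runif1(-0.05, 0.05) * side
  r <- side * 0.045 * runif1(0.85, 1.15)
  matrix((px - lx)^2 + (py - ly)^2 <= r^2, side, side)
}

#' Generate a single phantom image
#'
#' Renders the phantom described by a [phantom_spec()]. The returned matrix
#' is `image_side x image_side` with values in `[0, 1]`; the ground-truth
#' lesion mask used during compositing is attached as attribute
#' `"lesion_mask"` (a logical matrix) so rendered lesions can be checked
#' against what the generator intended.
#'
#' @param spec a [phantom_spec()]
#' @return numeric matrix with attribute `lesion_mask`
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  side <- spec$image_side
  with_local_seed(spec$seed, {
    cx <- side * (0.5 + runif1(-0.02, 0.02))
    cy <- side * (0.5 + runif1(-0.02, 0.02))
    a <- side * 0.38 * runif1(0.95, 1.05)
    b <- side * 0.45 * runif1(0.95, 1.05)
    grid_c <- rep(seq_len(side), each = side)
    grid_r <- rep(seq_len(side), times = side)
    brain <- matrix(((grid_c - cx) / a)^2 + ((grid_r - cy) / b)^2 <= 1,
                    side, side)

    # low-frequency internal texture: a few random cosine waves
    tex <- matrix(0.35, side, side)
    for (k in 1:4) {
      fx <- sample(1:4, 1L); fy <- sample(1:4, 1L)
      phase <- runif1(0, 2 * pi)
      wave <- 0.04 * cos(2 * pi * (fx * grid_c + fy * grid_r) / side + phase)
      tex <- tex + matrix(wave, side, side)
    }
    tex <- pmin(tex, 0.55)

    lesion <- lesion_mask_for(spec$class_label, side, cx, cy, a, b) & brain

    img <- matrix(0.02, side, side)
    img[brain] <- tex[brain]
    img[lesion] <- spec$lesion_intensity
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(side * side, 0, spec$noise_sigma),
                          side, side)
    }
    img <- pmin(pmax(img, 0), 1)
    attr(img, "lesion_mask") <- lesion
    img
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `4 * n_per_class` 8-bit grayscale PNGs into four class-named
#' sub-folders of `out_dir` (`glioma`, `meningioma`, `pituitary`,
#' `notumor`), plus a tab-delimited `manifest.tsv`. Per-image sub-seeds are
#' derived deterministically from `seed`, so the same call reproduces
#' byte-identical files and manifests.
#'
#' @param n_per_class images per class (>= 1)
#' @param out_dir output directory (created if needed)
#' @param seed integer root seed
#' @param image_side side length of the generated images
#' @param noise_sigma,lesion_intensity passed to [phantom_spec()]
#' @return the dataset manifest, a data frame with columns `global_id`,
#'   `source_id`, `path`, `class_label`, and `split` (initially `NA`;
#'   assign with [split_dataset()])
#' @export
generate_phantom_dataset <- function(n_per_class, out_dir, seed = 1L,
                                     image_side = 224L, noise_sigma = 0.05,
                                     lesion_intensity = 0.9) {
  stopifnot(n_per_class >= 1L)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2L) != 0L) {
    stop("cannot write to output directory: ", out_dir)
  }
  cmap <- phantom_class_map()
  rows <- list()
  for (ci in seq_along(phantom_class_levels)) {
    cls <- phantom_class_levels[ci]
    folder <- cmap[[cls]]
    dir.create(file.path(out_dir, folder), showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      img_seed <- mix_seed(seed, ci, i)
      spec <- phantom_spec(cls, image_side = image_side,
                           noise_sigma = noise_sigma,
                           lesion_intensity = lesion_intensity,
                           seed = img_seed)
      img <- generate_phantom(spec)
      gid <- sprintf("syn-%s-%05d", folder, i)
      path <- file.path(out_dir, folder, paste0(gid, ".png"))
      png::writePNG(img, path)
      rows[[length(rows) + 1L]] <- data.frame(
        global_id = gid,
        source_id = sprintf("phantom/%s/%05d", cls, i),
        path = path,
        class_label = folder,
        split = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}

#' Write a dataset manifest as tab-delimited text
#' @param manifest manifest data frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest written by [write_manifest()]
#' @param path manifest file
#' @return manifest data frame
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", na.strings = "NA",
                    stringsAsFactors = FALSE)
}
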