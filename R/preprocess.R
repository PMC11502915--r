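#' Pre-processing configuration
#'
#' Two named profiles are provided. The `"deployed"` profile reproduces the
#' deployed geometry: inputs must be high-resolution (height over 1440
#' pixels), images are standardized to 800 x 1024. The `"test"` profile
#' uses a 64 x 80 target with the resolution check suppressed so the whole
#' pipeline runs on small phantoms.
#'
#' @param profile `"deployed"` or `"test"`, or omit and set fields directly.
#' @param min_input_height_px Minimum allowed input height (0 disables).
#' @param target_height_px,target_width_px Output geometry.
#' @param black_threshold Intensity at or below which a row/column counts
#'   as black padding. Default 0: any strictly positive pixel ends padding.
#' @return A validated list of class `PreprocessConfig`.
#' @export
#' @examples
#' preprocessConfig("test")
preprocessConfig <- function(profile = c("deployed", "test"),
                             min_input_height_px = NULL,
                             target_height_px = NULL,
                             target_width_px = NULL,
                             black_threshold = 0) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    deployed = list(min_h = 1440L, th = 800L, tw = 1024L),
    test  = list(min_h = 0L,    th = 64L,  tw = 80L))
  cfg <- list(profile = profile,
              min_input_height_px = min_input_height_px %||% defaults$min_h,
              target_height_px = target_height_px %||% defaults$th,
              target_width_px = target_width_px %||% defaults$tw,
              black_threshold = black_threshold)
  if (cfg$target_height_px <= 0 || cfg$target_width_px <= 0)
    stop("target dimensions must be positive", call. = FALSE)
  if (cfg$min_input_height_px > 0 &&
      cfg$min_input_height_px < cfg$target_height_px)
    stop("min_input_height_px must be at least target_height_px", call. = FALSE)
  if (cfg$black_threshold < 0 || cfg$black_threshold > 1)
    stop("black_threshold must lie in [0, 1]", call. = FALSE)
  structure(cfg, class = "PreprocessConfig")
}

#' Crop away black padding at the image edges
#'
#' Returns the minimal bounding window containing every row and column
#' whose maximum intensity exceeds `black_threshold`; content pixels are
#' preserved bit-exactly. An all-black image is returned unchanged with a
#' warning.
#'
#' @param image Numeric matrix with intensities in \[0, 1\].
#' @param black_threshold Padding intensity cutoff (default 0).
#' @return The cropped matrix.
#' @export
#' @examples
#' img <- matrix(0, 20, 20); img[6:15, 6:15] <- 0.5
#' dim(cropBlackPadding(img))  # 10 x 10
cropBlackPadding <- function(image, black_threshold = 0) {
  stopIfNot2dImage(image)
  rows <- which(apply(image, 1, max) > black_threshold)
  cols <- which(apply(image, 2, max) > black_threshold)
  if (length(rows) == 0L || length(cols) == 0L) {
    warning("image is entirely black at the given threshold; returning unchanged")
    return(image)
  }
  image[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
}

#' Standardize a radiograph to the target geometry
#'
#' Scales the (already black-cropped) image by `target_height / height` on
#' both axes, preserving aspect ratio; downscaling uses anti-aliased
#' bilinear interpolation, upscaling plain bilinear. If the scaled width
#' falls short of the target the image is zero-padded symmetrically (extra
#' pixel on the right); if it overshoots it is center-cropped (extra pixel
#' dropped on the right).
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param cfg A [preprocessConfig()].
#' @return Matrix of exactly `target_height_px x target_width_px`.
#' @export
standardizeImage <- function(image, cfg = preprocessConfig("deployed")) {
  stopIfNot2dImage(image)
  stopifnot(inherits(cfg, "PreprocessConfig"))
  h <- nrow(image); w <- ncol(image)
  if (cfg$min_input_height_px > 0 && h < cfg$min_input_height_px)
    stop("input resolution too low: height ", h, " is below the required ",
         cfg$min_input_height_px, " px", call. = FALSE)
  th <- cfg$target_height_px; tw <- cfg$target_width_px
  scale <- th / h
  new_w <- max(1L, round(w * scale))
  antialias <- scale < 1
  resized <- resampleImage(image, th, new_w, antialias = antialias)
  resized <- clamp(resized, 0, 1)
  if (new_w == tw) return(resized)
  if (new_w < tw) {
    pad <- tw - new_w
    left <- pad %/% 2
    out <- matrix(0, th, tw)
    out[, (left + 1):(left + new_w)] <- resized
    out
  } else {
    extra <- new_w - tw
    left <- extra %/% 2
    resized[, (left + 1):(left + tw), drop = FALSE]
  }
}

#' Standardize every image of a case or case set
#'
#' Applies [cropBlackPadding()] then [standardizeImage()] to each
#' radiograph. Truth boxes are mapped through the same crop, scale and
#' pad/crop geometry so downstream ground-truth maps stay aligned.
#'
#' @param x A [CxrCase-class] or [CxrCaseSet-class].
#' @param cfg A [preprocessConfig()].
#' @return Object of the same class with standardized images.
#' @export
preprocessCases <- function(x, cfg = preprocessConfig("test")) {
  if (is(x, "CxrCaseSet")) {
    x@cases <- lapply(x@cases, preprocessCases, cfg = cfg)
    return(x)
  }
  stopifnot(is(x, "CxrCase"))
  th <- cfg$target_height_px; tw <- cfg$target_width_px
  for (ii in seq_along(x@images)) {
    img <- x@images[[ii]]
    rows <- which(apply(img, 1, max) > cfg$black_threshold)
    cols <- which(apply(img, 2, max) > cfg$black_threshold)
    if (length(rows) == 0L) { r0 <- 0L; c0 <- 0L } else {
      r0 <- min(rows) - 1L; c0 <- min(cols) - 1L
      img <- img[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
    }
    h <- nrow(img); w <- ncol(img)
    scale <- th / h
    new_w <- max(1L, round(w * scale))
    std <- standardizeImage(img, cfg)
    # horizontal offset applied after scaling: +pad/2 or -crop/2
    off_c <- if (new_w < tw) (tw - new_w) %/% 2 else -((new_w - tw) %/% 2)
    sel <- x@truths$image_index == ii
    if (any(sel)) {
      tr <- x@truths[sel, ]
      tr$row0 <- clamp((tr$row0 - r0) * scale, 0, th)
      tr$row1 <- clamp((tr$row1 - r0) * scale, 0, th)
      tr$col0 <- clamp((tr$col0 - c0) * scale + off_c, 0, tw)
      tr$col1 <- clamp((tr$col1 - c0) * scale + off_c, 0, tw)
      x@truths[sel, ] <- tr
    }
    x@images[[ii]] <- std
  }
  keep <- (x@truths$row1 - x@truths$row0) > 0 & (x@truths$col1 - x@truths$col0) > 0
  x@truths <- x@truths[keep, , drop = FALSE]
  validObject(x)
  x
}
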