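# Internal numerical utilities shared across modules.

# Deterministic fan-out of one user seed into independent stream seeds.
# Linear congruential mix keeps every derived seed a valid 32-bit integer.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + k * 7919) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
stopIfNot2dImage <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L)
    stop("image must be a non-empty numeric matrix", call. = FALSE)
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

# 1-D resampling weight matrix (n_out x n_in) with a triangle (bilinear)
# kernel. When downscaling with antialias = TRUE the kernel support is
# widened by the inverse scale, the standard anti-aliased resize; upscaling
# always uses the plain bilinear kernel. Rows are normalized so a constant
# signal is reproduced exactly.
resampleMatrix <- function(n_in, n_out, antialias = TRUE) {
  if (n_in == n_out) return(diag(n_out))
  scale <- n_out / n_in
  support <- if (antialias && scale < 1) 1 / scale else 1
  # output pixel centers in input coordinates
  x <- (seq_len(n_out) - 0.5) / scale - 0.5
  j <- seq_len(n_in) - 1
  d <- abs(outer(x, j, "-")) / support
  w <- pmax(1 - d, 0)
  w / rowSums(w)
}

# Separable resize of a matrix (rows = image height) to out_h x out_w.
resampleImage <- function(image, out_h, out_w, antialias = TRUE) {
  A <- resampleMatrix(nrow(image), out_h, antialias)
  B <- resampleMatrix(ncol(image), out_w, antialias)
  A %*% image %*% t(B)
}

# Separable Gaussian blur used by the phantom background generator.
gaussBlur <- function(image, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), seq(-half, half), "+")
    idx <- clamp(idx, 1L, n)  # replicate edges
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k)) out <- out + k[t] * m[idx[, t], , drop = FALSE]
    out
  }
  t(blur1(t(blur1(image))))
}

# Bilinear sampling of `image` at fractional (row, col) positions
# (0-based pixel-center coordinates); zero outside the support.
bilinearSample <- function(image, rows, cols) {
  h <- nrow(image); w <- ncol(image)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  get <- function(r, c) {
    ok <- r >= 0 & r <= h - 1 & c >= 0 & c <= w - 1
    v <- numeric(length(r))
    v[ok] <- image[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  (1 - fr) * (1 - fc) * get(r0, c0) +
    (1 - fr) * fc * get(r0, c0 + 1) +
    fr * (1 - fc) * get(r0 + 1, c0) +
    fr * fc * get(r0 + 1, c0 + 1)
}

# Rotate an image by `degrees` about its center (bilinear, zero fill).
rotateImage <- function(image, degrees, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (degrees == 0) return(image)
  h <- nrow(image); w <- ncol(image)
  th <- degrees * pi / 180
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  g <- expand.grid(r = seq_len(h) - 1, c = seq_len(w) - 1)
  # inverse mapping: rotate output coords by -theta
  dr <- g$r - cr; dc <- g$c - cc
  sr <- cos(th) * dr - sin(th) * dc + cr
  sc <- sin(th) * dr + cos(th) * dc + cc
  if (interp == "nearest") { sr <- round(sr); sc <- round(sc) }
  matrix(bilinearSample(image, sr, sc), h, w)
}

# Rasterize 0-based half-open boxes [row0,row1) x [col0,col1) into a
# binary h x w mask. `boxes` is a data.frame/matrix with columns
# row0, col0, row1, col1.
rasterizeBoxes <- function(boxes, h, w) {
  mask <- matrix(0, h, w)
  if (is.null(boxes) || NROW(boxes) == 0) return(mask)
  boxes <- as.data.frame(boxes)
  for (i in seq_len(nrow(boxes))) {
    r0 <- max(0L, floor(boxes$row0[i])); r1 <- min(h, ceiling(boxes$row1[i]))
    c0 <- max(0L, floor(boxes$col0[i])); c1 <- min(w, ceiling(boxes$col1[i]))
    if (r1 > r0 && c1 > c0) mask[(r0 + 1):r1, (c0 + 1):c1] <- 1
  }
  mask
}

# Scale a box between coordinate frames (e.g. image grid -> map grid).
scaleBox <- function(box, from_h, from_w, to_h, to_w) {
  sr <- to_h / from_h; sc <- to_w / from_w
  c(row0 = box[[1]] * sr, col0 = box[[2]] * sc,
    row1 = box[[3]] * sr, col1 = box[[4]] * sc)
}
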