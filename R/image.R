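#' Read a fundus image from PNG or JPEG
#'
#' @param path file path ending in `.png`, `.jpg` or `.jpeg`.
#' @return Numeric array `H x W x 3` with intensities in `[0, 1]`. An alpha
#'   channel, if present, is dropped. Grayscale files are refused: the
#'   pipeline is defined on RGB fundus photographs.
#' @export
read_fundus <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                jpg = ,
                jpeg = jpeg::readJPEG(path),
                stop("unsupported image format '.", ext, "' (PNG/JPEG only)",
                     call. = FALSE))
  if (length(dim(img)) == 2)
    stop("grayscale image: an RGB fundus photograph is required", call. = FALSE)
  if (dim(img)[3] >= 4) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB array as PNG
#'
#' @param image numeric array `H x W x 3`; values are clipped to `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fundus_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}

#' Bilinear image resize
#'
#' Plain bilinear interpolation at output pixel centres, implemented
#' directly since no raster package is assumed. Aspect ratio is not
#' preserved; both output sides are set independently.
#'
#' @param image numeric array `H x W x C`.
#' @param height,width output size in pixels.
#' @return Numeric array `height x width x C`.
#' @export
resize_bilinear <- function(image, height, width) {
  d <- dim(image)
  if (length(d) != 3) stop("image must be an H x W x C array", call. = FALSE)
  ih <- d[1]; iw <- d[2]; nc <- d[3]
  ys <- pmin(pmax((seq_len(height) - 0.5) * ih / height + 0.5, 1), ih)
  xs <- pmin(pmax((seq_len(width) - 0.5) * iw / width + 0.5, 1), iw)
  y0 <- pmax(pmin(floor(ys), ih - 1L), 1L)
  x0 <- pmax(pmin(floor(xs), iw - 1L), 1L)
  y1 <- pmin(y0 + 1L, ih); x1 <- pmin(x0 + 1L, iw)
  wy <- matrix(ys - y0, height, width)
  wx <- matrix(xs - x0, height, width, byrow = TRUE)
  out <- array(0, c(height, width, nc))
  for (ch in seq_len(nc)) {
    m <- image[, , ch]
    out[, , ch] <- (1 - wy) * (1 - wx) * m[y0, x0] +
      (1 - wy) * wx * m[y0, x1] +
      wy * (1 - wx) * m[y1, x0] +
      wy * wx * m[y1, x1]
  }
  out
}

#' Preprocess a fundus image for the detector
#'
#' Resizes the image so that both sides equal `size` (the shorter side is
#' brought up to at least `size` while the longer side may not exceed it,
#' which jointly forces a square resize; aspect ratio is not preserved), then
#' standardizes each RGB channel to zero mean and unit variance over the
#' image. A channel with (near-)zero variance is mean-subtracted only, so a
#' constant image maps to all zeros.
#'
#' @param image numeric array `H x W x 3`.
#' @param size output side length in pixels, default 224.
#' @param normalize apply per-channel standardization (default `TRUE`).
#' @return Numeric array `size x size x 3`.
#' @export
preprocess <- function(image, size = 224, normalize = TRUE) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stop("preprocess() needs a non-empty H x W x 3 RGB array", call. = FALSE)
  if (d[1] < 1 || d[2] < 1) stop("empty image", call. = FALSE)
  out <- if (d[1] == size && d[2] == size) image else
    resize_bilinear(image, size, size)
  if (normalize) {
    for (ch in 1:3) {
      m <- out[, , ch]
      mu <- mean(m)
      s <- stats::sd(m)
      out[, , ch] <- if (is.finite(s) && s > 1e-8) (m - mu) / s else m - mu
    }
  }
  out
}
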