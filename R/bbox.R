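#' Axis-aligned bounding box
#'
#' Boxes live in continuous pixel coordinates with the origin at the image's
#' top-left corner, x increasing rightwards and y downwards. A box is stored
#' as the numeric vector `(x_min, y_min, x_max, y_max)`: `(x_min, y_min)` is
#' the top-left corner and `(x_max, y_max)` the bottom-right corner. Width is
#' `x_max - x_min` and height `y_max - y_min`; there is no +1 pixel-count
#' convention (the printed disc radii of the packaged reference table are
#' reproduced only under this convention).
#'
#' @param x_min,y_min,x_max,y_max corner coordinates in pixels; `x_min <=
#'   x_max` and `y_min <= y_max` is required. Degenerate (zero-area) boxes
#'   are allowed.
#' @return A length-4 named numeric vector of class `"bbox"`.
#' @examples
#' b <- bbox(186, 209, 259, 292)
#' box_center(b)
#' box_radius(b)              # semi-major convention, 41.5
#' box_radius(b, "euclidean") # centre-to-corner distance, ~55.3
#' @seealso [box_radius()], [compute_cdr()]
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min)[[1]], y_min = as.numeric(y_min)[[1]],
         x_max = as.numeric(x_max)[[1]], y_max = as.numeric(y_max)[[1]])
  if (any(!is.finite(b)))
    stop("bounding box coordinates must be finite numbers", call. = FALSE)
  if (b[["x_min"]] > b[["x_max"]] || b[["y_min"]] > b[["y_max"]])
    stop("invalid bounding box: need x_min <= x_max and y_min <= y_max",
         call. = FALSE)
  class(b) <- "bbox"
  b
}

#' Coerce a length-4 numeric vector to a bounding box
#'
#' @param x a `bbox`, or an unclassed numeric vector `(x_min, y_min, x_max,
#'   y_max)`.
#' @return A `bbox`.
#' @export
as_bbox <- function(x) {
  if (inherits(x, "bbox")) return(x)
  if (!is.numeric(x) || length(x) != 4)
    stop("a bounding box needs exactly 4 numeric coordinates", call. = FALSE)
  bbox(x[[1]], x[[2]], x[[3]], x[[4]])
}

#' Convert a COCO-style `[x, y, width, height]` vector to a bounding box
#'
#' @param x numeric vector `(x, y, width, height)` with the top-left corner
#'   first, as used in COCO annotation JSON.
#' @return A `bbox` in corner format.
#' @export
bbox_from_coco <- function(x) {
  if (!is.numeric(x) || length(x) != 4)
    stop("COCO bbox needs exactly 4 numbers: x, y, width, height", call. = FALSE)
  if (x[[3]] < 0 || x[[4]] < 0)
    stop("COCO bbox width and height must be non-negative", call. = FALSE)
  bbox(x[[1]], x[[2]], x[[1]] + x[[3]], x[[2]] + x[[4]])
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox> [%g, %g, %g, %g]  (w = %g, h = %g)\n",
              x[[1]], x[[2]], x[[3]], x[[4]], box_width(x), box_height(x)))
  invisible(x)
}

#' Box width and height
#' @param box a `bbox` or length-4 numeric vector.
#' @return Width (`x_max - x_min`) or height (`y_max - y_min`) in pixels.
#' @export
box_width <- function(box) {
  b <- as_bbox(box)
  unname(b[[3]] - b[[1]])
}

#' @rdname box_width
#' @export
box_height <- function(box) {
  b <- as_bbox(box)
  unname(b[[4]] - b[[2]])
}

#' Centre of a bounding box
#'
#' The arithmetic midpoint of the two corners:
#' `Center_x = (x_min + x_max) / 2`, `Center_y = (y_min + y_max) / 2`.
#'
#' @param box a `bbox` or length-4 numeric vector.
#' @return Named numeric vector `c(x = ..., y = ...)` in pixels.
#' @export
box_center <- function(box) {
  b <- as_bbox(box)
  c(x = (b[[1]] + b[[3]]) / 2, y = (b[[2]] + b[[4]]) / 2)
}

#' Radius of a bounding box under a named convention
#'
#' Treats a detection box around a roughly elliptical structure (optic disc
#' or cup) as carrying a scalar "radius". Three conventions are implemented,
#' with `hw = width / 2` and `hh = height / 2`:
#'
#' * `"semi_major"` — `max(hw, hh)`, the semi-major axis of the inscribed
#'   ellipse. This is the default: it is the convention that exactly
#'   reproduces the disc radii of the packaged reference table
#'   (see [load_table2_fixture()]).
#' * `"euclidean"` — `sqrt(hw^2 + hh^2)`, the distance from the box centre
#'   to a corner.
#' * `"vertical"` — `hh`, half the box height, matching the clinical habit
#'   of reading the *vertical* cup-to-disc ratio.
#'
#' For any box `euclidean >= semi_major >= vertical`, with the last two
#' equal exactly when the box is at least as tall as it is wide. Which
#' convention is used matters for a single radius but cancels in the CDR
#' whenever disc and cup boxes share their aspect ratio.
#'
#' @param box a `bbox` or length-4 numeric vector.
#' @param convention one of `"semi_major"`, `"euclidean"`, `"vertical"`.
#' @return Radius in pixels (0 for a degenerate box).
#' @export
box_radius <- function(box, convention = c("semi_major", "euclidean", "vertical")) {
  convention <- match.arg(convention)
  b <- as_bbox(box)
  hw <- box_width(b) / 2
  hh <- box_height(b) / 2
  switch(convention,
         euclidean  = sqrt(hw^2 + hh^2),
         semi_major = max(hw, hh),
         vertical   = hh)
}

#' @rdname box_radius
#' @format NULL
#' @export
radius_conventions <- c("semi_major", "euclidean", "vertical")
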