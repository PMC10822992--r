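#' Read and write bounding-box annotations
#'
#' The package's annotation dialect is a CSV with header
#' `image,structure,x_min,y_min,x_max,y_max`, one row per structure per
#' image, with `structure` either `"OD"` (optic disc) or `"OC"` (optic cup)
#' and corner coordinates in pixels.
#'
#' @param path CSV file path.
#' @return A data frame with the dialect's six columns.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image", "structure", "x_min", "y_min", "x_max", "y_max")
  missing <- setdiff(required, names(ann))
  if (length(missing))
    stop("annotation CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(ann$structure), c("OD", "OC"))
  if (length(bad))
    stop("unknown structure labels: ", paste(bad, collapse = ", "),
         " (expected OD or OC)", call. = FALSE)
  for (col in c("x_min", "y_min", "x_max", "y_max"))
    ann[[col]] <- as.numeric(ann[[col]])
  if (any(ann$x_min > ann$x_max | ann$y_min > ann$y_max))
    stop("annotation contains an invalid box (min > max)", call. = FALSE)
  ann[, required]
}

#' @rdname read_annotations
#' @param annotations data frame in the dialect above.
#' @export
write_annotations <- function(annotations, path) {
  required <- c("image", "structure", "x_min", "y_min", "x_max", "y_max")
  stopifnot(all(required %in% names(annotations)))
  utils::write.csv(annotations[, required], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read COCO-style annotations into the CSV dialect
#'
#' Accepts the common COCO layout: `images` (with `id` and `file_name`),
#' `annotations` (with `image_id`, `category_id` and `bbox` as
#' `[x, y, width, height]`), and `categories` whose names must map onto
#' `OD`/`OC` (case-insensitively; `optic disc`/`optic cup` also accepted).
#' Boxes are converted to corner format on load.
#'
#' @param path JSON file path.
#' @return A data frame in the [read_annotations()] dialect.
#' @export
read_coco_annotations <- function(path) {
  coco <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  for (field in c("images", "annotations", "categories"))
    if (is.null(coco[[field]]))
      stop("COCO file lacks '", field, "'", call. = FALSE)
  cat_name <- toupper(trimws(coco$categories$name))
  cat_name[cat_name %in% c("OPTIC DISC", "DISC")] <- "OD"
  cat_name[cat_name %in% c("OPTIC CUP", "CUP")] <- "OC"
  bad <- setdiff(unique(cat_name), c("OD", "OC"))
  if (length(bad))
    stop("COCO categories not recognisable as OD/OC: ",
         paste(bad, collapse = ", "), call. = FALSE)
  cat_map <- stats::setNames(cat_name, coco$categories$id)
  img_map <- stats::setNames(coco$images$file_name, coco$images$id)
  boxes <- coco$annotations$bbox
  if (is.list(boxes)) boxes <- do.call(rbind, boxes)
  corner <- t(apply(boxes, 1, function(b) as.numeric(bbox_from_coco(b))))
  data.frame(
    image = unname(img_map[as.character(coco$annotations$image_id)]),
    structure = unname(cat_map[as.character(coco$annotations$category_id)]),
    x_min = corner[, 1], y_min = corner[, 2],
    x_max = corner[, 3], y_max = corner[, 4],
    stringsAsFactors = FALSE)
}

# One box from an annotation data frame, as a bbox.
annotation_box <- function(annotations, image, structure) {
  row <- annotations[annotations$image == image &
                       annotations$structure == structure, , drop = FALSE]
  if (nrow(row) != 1)
    stop("expected exactly one ", structure, " annotation for image '",
         image, "', found ", nrow(row), call. = FALSE)
  bbox(row$x_min, row$y_min, row$x_max, row$y_max)
}
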