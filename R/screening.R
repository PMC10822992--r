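#' End-to-end glaucoma screening over a set of fundus images
#'
#' For each image: load (if a path), predict the optic-disc and optic-cup
#' boxes with the two detectors, compute the cup-to-disc ratio under the
#' active radius convention, apply the diagnosis rule, and record the rim
#' width (`od_radius - oc_radius`, an auxiliary output echoing the clinical
#' neuroretinal-rim sign; it is derived entirely from the CDR radii, no
#' separate rim detector exists). The diagnosis always comes from
#' [diagnose()] via [compute_cdr()] -- there is no second threshold rule in
#' the pipeline.
#'
#' Per-sample failures (unreadable file, degenerate disc detection) are
#' isolated: the record is kept with `status = "failed"` and the run
#' continues. Structural errors -- detectors whose configurations disagree
#' -- abort immediately.
#'
#' When ground truth is supplied an evaluation report is attached:
#' diagnostic confusion metrics and ROC/PR on the predicted ratio as risk
#' score, plus mean IoU per structure. With `use_ground_truth = TRUE` the
#' ground-truth boxes are substituted for the detectors (oracle mode: no
#' models needed), which isolates the geometry + rule stages.
#'
#' @param images character vector of PNG/JPEG paths, a list of `H x W x 3`
#'   arrays, or a list of `fundus_sample` objects.
#' @param od_model,oc_model `"vit_detector"` models (not needed in oracle
#'   mode).
#' @param annotations optional data frame in the [read_annotations()]
#'   dialect (or path to one) carrying ground-truth boxes; matched to
#'   images by file name for paths, by position otherwise. For
#'   `fundus_sample` input the embedded truth is used directly.
#' @param convention radius convention, see [box_radius()].
#' @param threshold,inclusive diagnosis rule parameters, see [diagnose()].
#' @param use_ground_truth substitute ground-truth boxes for the detectors.
#' @return A list of class `"screening_result"`: `records` (one data frame
#'   row per image: predicted boxes, radii, `ratio`, `display_ratio`,
#'   `diagnosis`, `rim_width`, `status`) and `report` (an
#'   [evaluation_report()] or `NULL` when no truth was available).
#' @export
run_screening <- function(images, od_model = NULL, oc_model = NULL,
                          annotations = NULL,
                          convention = c("semi_major", "euclidean", "vertical"),
                          threshold = 0.6, inclusive = TRUE,
                          use_ground_truth = FALSE) {
  convention <- match.arg(convention)
  if (length(images) == 0)
    return(structure(list(records = empty_screening_records(), report = NULL),
                     class = "screening_result"))
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (!use_ground_truth) {
    if (is.null(od_model) || is.null(oc_model))
      stop("both an OD and an OC model are required unless ",
           "use_ground_truth = TRUE", call. = FALSE)
    if (!inherits(od_model, "vit_detector") ||
        !inherits(oc_model, "vit_detector"))
      stop("models must be 'vit_detector' objects", call. = FALSE)
    if (!identical(unclass(od_model$config), unclass(oc_model$config)))
      stop("incompatible models: OD and OC detector configs differ",
           call. = FALSE)
  }

  if (is.character(images)) {
    items <- lapply(images, function(p) list(path = p, id = basename(p)))
  } else if (is.list(images)) {
    items <- lapply(seq_along(images), function(i) {
      x <- images[[i]]
      if (inherits(x, "fundus_sample"))
        list(sample = x, id = x$sample_id)
      else
        list(array = x, id = sprintf("image_%04d", i))
    })
  } else stop("images must be paths or a list of arrays/samples", call. = FALSE)
  if (length(items) == 0)
    return(structure(list(records = empty_screening_records(),
                          report = NULL), class = "screening_result"))

  gt_box <- function(item, structure_name) {
    if (!is.null(item$sample))
      return(if (structure_name == "OD") item$sample$od_box else item$sample$oc_box)
    if (is.null(annotations)) return(NULL)
    annotation_box(annotations, item$id, structure_name)
  }

  rows <- vector("list", length(items))
  gt <- list(od = vector("list", length(items)),
             oc = vector("list", length(items)),
             label = rep(NA_integer_, length(items)))
  for (i in seq_along(items)) {
    item <- items[[i]]
    rows[[i]] <- tryCatch({
      img <- if (!is.null(item$path)) read_fundus(item$path)
             else if (!is.null(item$array)) item$array
             else item$sample$image
      od_gt <- tryCatch(gt_box(item, "OD"), error = function(e) NULL)
      oc_gt <- tryCatch(gt_box(item, "OC"), error = function(e) NULL)
      gt$od[i] <- list(od_gt)
      gt$oc[i] <- list(oc_gt)
      if (!is.null(item$sample)) gt$label[i] <- item$sample$label
      else if (!is.null(od_gt) && !is.null(oc_gt))
        gt$label[i] <- as.integer(
          diagnose(box_radius(oc_gt, convention) / box_radius(od_gt, convention),
                   threshold, inclusive) == "glaucoma")
      if (use_ground_truth) {
        if (is.null(od_gt) || is.null(oc_gt))
          stop("oracle mode needs ground-truth boxes for every image")
        od_box <- od_gt; oc_box <- oc_gt
      } else {
        od_box <- predict_box(img, od_model)
        oc_box <- predict_box(img, oc_model)
      }
      cdr <- compute_cdr(oc_box, od_box, convention = convention,
                         threshold = threshold, inclusive = inclusive)
      data.frame(sample_id = item$id,
                 od_x_min = od_box[[1]], od_y_min = od_box[[2]],
                 od_x_max = od_box[[3]], od_y_max = od_box[[4]],
                 oc_x_min = oc_box[[1]], oc_y_min = oc_box[[2]],
                 oc_x_max = oc_box[[3]], oc_y_max = oc_box[[4]],
                 od_radius = cdr$od_radius, oc_radius = cdr$oc_radius,
                 ratio = cdr$ratio, display_ratio = cdr$display_ratio,
                 diagnosis = cdr$diagnosis,
                 rim_width = cdr$od_radius - cdr$oc_radius,
                 status = "ok", message = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(sample_id = item$id,
                 od_x_min = NA_real_, od_y_min = NA_real_,
                 od_x_max = NA_real_, od_y_max = NA_real_,
                 oc_x_min = NA_real_, oc_y_min = NA_real_,
                 oc_x_max = NA_real_, oc_y_max = NA_real_,
                 od_radius = NA_real_, oc_radius = NA_real_,
                 ratio = NA_real_, display_ratio = NA_real_,
                 diagnosis = NA_character_, rim_width = NA_real_,
                 status = "failed", message = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  }
  records <- do.call(rbind, rows)

  report <- NULL
  ok <- records$status == "ok" & !is.na(gt$label)
  if (any(ok)) {
    have_boxes <- ok & !vapply(gt$od, is.null, TRUE) &
      !vapply(gt$oc, is.null, TRUE)
    pred_boxes <- gt_boxes <- NULL
    iou_rows <- which(have_boxes)
    if (length(iou_rows)) {
      pred_boxes <- c(
        lapply(iou_rows, function(i)
          as.numeric(records[i, c("od_x_min", "od_y_min", "od_x_max", "od_y_max")])),
        lapply(iou_rows, function(i)
          as.numeric(records[i, c("oc_x_min", "oc_y_min", "oc_x_max", "oc_y_max")])))
      gt_boxes <- c(gt$od[iou_rows], gt$oc[iou_rows])
    }
    report <- evaluation_report(
      actual = gt$label[ok],
      predicted = as.integer(records$diagnosis[ok] == "glaucoma"),
      scores = records$ratio[ok],
      pred_boxes = pred_boxes, gt_boxes = gt_boxes)
  }
  structure(list(records = records, report = report),
            class = "screening_result")
}

empty_screening_records <- function() {
  data.frame(sample_id = character(0),
             od_x_min = numeric(0), od_y_min = numeric(0),
             od_x_max = numeric(0), od_y_max = numeric(0),
             oc_x_min = numeric(0), oc_y_min = numeric(0),
             oc_x_max = numeric(0), oc_y_max = numeric(0),
             od_radius = numeric(0), oc_radius = numeric(0),
             ratio = numeric(0), display_ratio = numeric(0),
             diagnosis = character(0), rim_width = numeric(0),
             status = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.screening_result <- function(x, ...) {
  n <- nrow(x$records)
  ok <- sum(x$records$status == "ok")
  cat(sprintf("<screening_result> %d images (%d ok, %d failed)\n",
              n, ok, n - ok))
  if (ok)
    cat(sprintf("  glaucoma flagged: %d/%d\n",
                sum(x$records$diagnosis == "glaucoma", na.rm = TRUE), ok))
  if (!is.null(x$report)) {
    cat("-- evaluation --\n")
    print(x$report)
  }
  invisible(x)
}

#' Write screening records as CSV
#'
#' @param result a `"screening_result"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screening_csv <- function(result, path) {
  stopifnot(inherits(result, "screening_result"))
  utils::write.csv(result$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
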