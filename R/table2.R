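#' Packaged reference table of disc/cup boxes, radii, ratios and labels
#'
#' Nine fundus test images with ground-truth and predicted bounding boxes for
#' the optic disc (OD) and optic cup (OC), the published radii, cup-to-disc
#' ratios and binary classifications, shipped verbatim as a plain-text
#' fixture. The table is used as an exact oracle for the geometry code: every
#' ground-truth OD radius equals `box_radius(box, "semi_major")` of its
#' printed box.
#'
#' The printed table is internally corrupted in two known ways, and the
#' loader flags rather than repairs this:
#'
#' * the OC box column of rows 1-8 duplicates the OD column shifted up by
#'   one row (`oc_box_suspect`);
#' * the printed ratios of images 3-9 cannot be recovered from the printed
#'   radii (`gt_ratio_consistent`, `pred_ratio_consistent`), and most
#'   predicted radii carry decimals irreproducible from the printed integer
#'   predicted boxes (`gt_radius_consistent`, `pred_radius_consistent`).
#'
#' All flags are recomputed from the data at load time, never stored.
#' `consistent` summarises a record as fully self-consistent on the
#' ground-truth side (radii reproducible from boxes and ratio reproducible
#' from radii): images 1 and 2 only.
#'
#' @return A data frame with one row per image (9 rows): box corner columns
#'   `gt_od_*`, `pred_od_*`, `gt_oc_*`, `pred_oc_*`; printed radii
#'   `gt_od_radius`, `pred_od_radius`, `gt_oc_radius`, `pred_oc_radius`;
#'   printed ratios `gt_ratio`, `pred_ratio`; printed classes `actual_class`,
#'   `predicted_class`; and the logical consistency flags described above.
#' @examples
#' t2 <- load_table2_fixture()
#' t2[t2$consistent, c("image", "gt_ratio", "actual_class")]
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2.csv", package = "fundusvit",
                      mustWork = TRUE)
  t2 <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(t2) == 9)

  semi <- function(prefix) {
    vapply(seq_len(nrow(t2)), function(i) {
      box_radius(as.numeric(t2[i, paste0(prefix, c("_x_min", "_y_min",
                                                   "_x_max", "_y_max"))]),
                 "semi_major")
    }, numeric(1))
  }

  t2$gt_od_radius_consistent   <- semi("gt_od")   == t2$gt_od_radius
  t2$pred_od_radius_consistent <- semi("pred_od") == t2$pred_od_radius
  t2$gt_oc_radius_consistent   <- semi("gt_oc")   == t2$gt_oc_radius
  t2$pred_oc_radius_consistent <- semi("pred_oc") == t2$pred_oc_radius
  t2$gt_radius_consistent   <- t2$gt_od_radius_consistent & t2$gt_oc_radius_consistent
  t2$pred_radius_consistent <- t2$pred_od_radius_consistent & t2$pred_oc_radius_consistent

  t2$gt_ratio_consistent <-
    round(t2$gt_oc_radius / t2$gt_od_radius, 1) == t2$gt_ratio
  t2$pred_ratio_consistent <-
    round(t2$pred_oc_radius / t2$pred_od_radius, 1) == t2$pred_ratio

  # OC boxes of rows 1-8 equal OD boxes of rows 2-9: a printing artefact.
  oc <- as.matrix(t2[, paste0("gt_oc", c("_x_min", "_y_min", "_x_max", "_y_max"))])
  od <- as.matrix(t2[, paste0("gt_od", c("_x_min", "_y_min", "_x_max", "_y_max"))])
  t2$oc_box_suspect <- c(rowSums(oc[-nrow(t2), ] != od[-1, ]) == 0, FALSE)

  t2$consistent <- t2$gt_radius_consistent & t2$gt_ratio_consistent
  t2
}

#' Self-check of the geometry code against the packaged reference table
#'
#' Recomputes, from the printed boxes and ratios of [load_table2_fixture()],
#' every quantity that the table states and that is self-consistent, and
#' compares with the printed values:
#'
#' * all 9 ground-truth OD radii and OC radii under the `semi_major`
#'   convention (exact match required);
#' * the predicted radii for the records whose printed predicted radius is
#'   reproducible from the printed predicted box;
#' * both classification columns, by applying the inclusive 0.6 rule to the
#'   printed ratios;
#' * the printed ratios themselves, for the records flagged consistent.
#'
#' @param verbose print a per-check summary.
#' @return Invisibly, a list with `radius_checks` and `class_checks` data
#'   frames and a single logical `pass`.
#' @examples
#' chk <- table2_check(verbose = FALSE)
#' chk$pass
#' @export
table2_check <- function(verbose = TRUE) {
  t2 <- load_table2_fixture()
  coords <- c("_x_min", "_y_min", "_x_max", "_y_max")
  semi <- function(prefix, i)
    box_radius(as.numeric(t2[i, paste0(prefix, coords)]), "semi_major")

  radius_checks <- do.call(rbind, lapply(seq_len(nrow(t2)), function(i) {
    data.frame(
      image = t2$image[i],
      gt_od_recomputed = semi("gt_od", i),
      gt_od_printed = t2$gt_od_radius[i],
      gt_oc_recomputed = semi("gt_oc", i),
      gt_oc_printed = t2$gt_oc_radius[i],
      pred_od_recomputed = semi("pred_od", i),
      pred_od_printed = t2$pred_od_radius[i])
  }))
  radius_checks$gt_od_match <-
    radius_checks$gt_od_recomputed == radius_checks$gt_od_printed
  radius_checks$gt_oc_match <-
    radius_checks$gt_oc_recomputed == radius_checks$gt_oc_printed
  radius_checks$pred_od_match <-
    radius_checks$pred_od_recomputed == radius_checks$pred_od_printed

  class_checks <- data.frame(
    image = t2$image,
    actual_printed = t2$actual_class,
    actual_recomputed = as.integer(diagnose(t2$gt_ratio) == "glaucoma"),
    predicted_printed = t2$predicted_class,
    predicted_recomputed = as.integer(diagnose(t2$pred_ratio) == "glaucoma"))
  class_checks$actual_match <-
    class_checks$actual_printed == class_checks$actual_recomputed
  class_checks$predicted_match <-
    class_checks$predicted_printed == class_checks$predicted_recomputed

  ratio_checks <- data.frame(
    image = t2$image,
    consistent = t2$consistent,
    ratio_printed = t2$gt_ratio,
    ratio_recomputed = round(t2$gt_oc_radius / t2$gt_od_radius, 1))
  ratio_checks$match <- !ratio_checks$consistent |
    ratio_checks$ratio_printed == ratio_checks$ratio_recomputed

  pass <- all(radius_checks$gt_od_match) &&
    all(radius_checks$gt_oc_match) &&
    all(radius_checks$pred_od_match[t2$pred_od_radius_consistent]) &&
    all(class_checks$actual_match) &&
    all(class_checks$predicted_match) &&
    all(ratio_checks$match)

  if (verbose) {
    cat(sprintf("GT OD radii (semi_major): %d/9 exact\n",
                sum(radius_checks$gt_od_match)))
    cat(sprintf("GT OC radii (semi_major): %d/9 exact\n",
                sum(radius_checks$gt_oc_match)))
    cat(sprintf("Predicted OD radii, self-consistent rows: %d/%d exact\n",
                sum(radius_checks$pred_od_match & t2$pred_od_radius_consistent),
                sum(t2$pred_od_radius_consistent)))
    cat(sprintf("Actual class from printed GT ratios (>= 0.6): %d/9\n",
                sum(class_checks$actual_match)))
    cat(sprintf("Predicted class from printed predicted ratios: %d/9\n",
                sum(class_checks$predicted_match)))
    incons <- t2$image[!t2$consistent]
    if (length(incons))
      cat("Rows flagged inconsistent (printed ratios not reproducible):",
          paste(incons, collapse = ", "), "\n")
    cat(if (pass) "PASS\n" else "FAIL\n")
  }
  invisible(list(radius_checks = radius_checks,
                 class_checks = class_checks,
                 ratio_checks = ratio_checks,
                 pass = pass))
}
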