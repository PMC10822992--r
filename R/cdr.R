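#' Binary glaucoma call from a cup-to-disc ratio
#'
#' Applies the screening rule: a cup-to-disc ratio (CDR) at or above the
#' decision threshold is flagged as glaucoma. The default threshold is 0.6,
#' the value commonly quoted as "suspicious for glaucoma". The comparison is
#' inclusive (`>=`) by default, which is the reading consistent with the
#' packaged reference table, where ratio-0.6 cases carry the glaucoma label;
#' `inclusive = FALSE` gives the strict `>` variant.
#'
#' The rule is always applied to the unrounded ratio; one-decimal rounding is
#' display-only (see [compute_cdr()]).
#'
#' @param ratio non-negative CDR value(s).
#' @param threshold decision threshold, default 0.6.
#' @param inclusive logical; call glaucoma when `ratio >= threshold`
#'   (default) rather than `ratio > threshold`.
#' @return Character vector, `"glaucoma"` or `"non_glaucoma"`.
#' @examples
#' diagnose(c(0.5, 0.6, 0.8))
#' diagnose(0.6, inclusive = FALSE)
#' @export
diagnose <- function(ratio, threshold = 0.6, inclusive = TRUE) {
  if (!is.numeric(ratio)) stop("ratio must be numeric", call. = FALSE)
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop("CDR ratio must be finite and non-negative", call. = FALSE)
  positive <- if (inclusive) ratio >= threshold else ratio > threshold
  ifelse(positive, "glaucoma", "non_glaucoma")
}

#' Cup-to-disc ratio and diagnosis from detection boxes
#'
#' Computes the disc and cup radii under a common convention, their ratio
#' (the CDR), and the binary glaucoma call. The ratio is kept unrounded for
#' the decision rule; `display_ratio` is the one-decimal rounding used for
#' reporting.
#'
#' @param oc_box optic-cup bounding box (`bbox` or length-4 numeric).
#' @param od_box optic-disc bounding box.
#' @param convention radius convention, see [box_radius()].
#' @param threshold CDR decision threshold, default 0.6.
#' @param inclusive inclusive (`>=`, default) or strict (`>`) rule.
#' @return An object of class `"cdr_result"`: a list with `od_radius`,
#'   `oc_radius`, `ratio`, `display_ratio`, `diagnosis`, `convention`,
#'   `threshold`.
#' @examples
#' r <- compute_cdr(oc_box = c(195, 214, 251, 280),
#'                  od_box = c(186, 209, 259, 292))
#' r$ratio          # 33 / 41.5
#' r$display_ratio  # 0.8
#' r$diagnosis
#' @export
compute_cdr <- function(oc_box, od_box,
                        convention = c("semi_major", "euclidean", "vertical"),
                        threshold = 0.6, inclusive = TRUE) {
  convention <- match.arg(convention)
  od_r <- box_radius(od_box, convention)
  oc_r <- box_radius(oc_box, convention)
  if (od_r <= 0)
    stop("optic-disc box has zero radius under the '", convention,
         "' convention: invalid disc detection", call. = FALSE)
  ratio <- oc_r / od_r
  structure(
    list(od_radius = od_r,
         oc_radius = oc_r,
         ratio = ratio,
         display_ratio = round(ratio, 1),
         diagnosis = diagnose(ratio, threshold = threshold, inclusive = inclusive),
         convention = convention,
         threshold = threshold),
    class = "cdr_result")
}

#' @export
print.cdr_result <- function(x, ...) {
  cat("Cup-to-disc ratio (", x$convention, " radii)\n", sep = "")
  cat(sprintf("  OD radius: %.3f px   OC radius: %.3f px\n",
              x$od_radius, x$oc_radius))
  cat(sprintf("  CDR: %.4f (display %.1f), threshold %.2f -> %s\n",
              x$ratio, x$display_ratio, x$threshold, x$diagnosis))
  invisible(x)
}
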