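#' Binary expression mask with physical pixel size
#'
#' A per-gene binary mask derived upstream from RNA in situ hybridization
#' images by a pixel classifier. Pixels default to 0.14 x 0.14 um.
#'
#' @param grid Logical (or 0/1) matrix.
#' @param pixel_size_um Physical pixel edge in micrometres (> 0).
#' @param gene Gene label.
#' @return An object of class \code{mask_image}.
#' @export
mask_image <- function(grid, pixel_size_um = 0.14, gene = NA_character_) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix", call. = FALSE)
  if (is.numeric(grid)) {
    if (!all(grid %in% c(0, 1))) {
      stop("`grid` must be binary (logical or 0/1)", call. = FALSE)
    }
    grid <- grid == 1
  }
  if (!is.logical(grid)) stop("`grid` must be binary", call. = FALSE)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be positive", call. = FALSE)
  }
  structure(list(grid = grid, pixel_size_um = pixel_size_um, gene = gene),
            class = "mask_image")
}

#' @export
print.mask_image <- function(x, ...) {
  cat(sprintf("mask_image%s: %dx%d px (%.2f um/px), %d positive\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              nrow(x$grid), ncol(x$grid), x$pixel_size_um, sum(x$grid)))
  invisible(x)
}

#' Pixel co-occurrence probability of two expression masks
#'
#' Tallies the pixels in which the target gene coexists with the reference
#' gene at the same pixel and divides by the total number of pixels in
#' which the reference gene is expressed, regardless of the target. The
#' statistic is a conditional probability and is asymmetric in its
#' arguments. Same-pixel only: no spatial tolerance is applied.
#'
#' @param target,reference \code{\link{mask_image}}s with identical shape
#'   and pixel size; the reference must have at least one positive pixel.
#' @return List (class \code{cooc_result}) with \code{dual_positive},
#'   \code{reference_total} and \code{probability}.
#' @export
cooccurrence <- function(target, reference) {
  stopifnot(inherits(target, "mask_image"), inherits(reference, "mask_image"))
  if (!identical(dim(target$grid), dim(reference$grid))) {
    stop("mask shapes differ", call. = FALSE)
  }
  if (abs(target$pixel_size_um - reference$pixel_size_um) > 1e-12) {
    stop("mask pixel sizes differ", call. = FALSE)
  }
  ref_total <- sum(reference$grid)
  if (ref_total == 0L) stop("reference mask has no positive pixels", call. = FALSE)
  dual <- sum(target$grid & reference$grid)
  structure(list(dual_positive = dual, reference_total = ref_total,
                 probability = probability_from_counts(dual, ref_total)),
            class = "cooc_result")
}

#' @export
print.cooc_result <- function(x, ...) {
  cat(sprintf("co-occurrence: %d / %d = %.4f\n",
              x$dual_positive, x$reference_total, x$probability))
  invisible(x)
}

#' Co-occurrence probability from pixel counts
#'
#' @param dual Dual-positive pixel count.
#' @param total Reference-positive pixel count (> 0, >= dual).
#' @return \code{dual / total}.
#' @examples
#' probability_from_counts(2.63e7, 3.51e7)  # ~0.75
#' @export
probability_from_counts <- function(dual, total) {
  assert_scalar_number(dual, "dual"); assert_scalar_number(total, "total")
  if (total <= 0) stop("`total` must be positive", call. = FALSE)
  if (dual < 0 || dual > total) {
    stop("`dual` must lie in [0, total]", call. = FALSE)
  }
  dual / total
}
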