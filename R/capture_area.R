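#' Visium capture area container
#'
#' Bundles one capture area's spot table, counts, image and scale factors.
#' Spot coordinates follow Space Ranger: \code{pxl_row}/\code{pxl_col} are
#' 0-based full-resolution image pixels.
#'
#' @param section_id Single non-empty label.
#' @param spots data.frame with columns \code{barcode}, \code{in_tissue},
#'   \code{array_row}, \code{array_col}, \code{pxl_row}, \code{pxl_col}.
#' @param counts genes x spots matrix (coerced to \code{dgCMatrix}) with
#'   unique gene rownames; column count must equal the spot count.
#' @param image Non-empty numeric matrix.
#' @param scale List with positive \code{spot_diameter_fullres},
#'   \code{tissue_hires_scalef} and \code{tissue_lowres_scalef}.
#' @return An object of class \code{capture_area}.
#' @export
capture_area <- function(section_id, spots, counts, image, scale) {
  if (!is.character(section_id) || length(section_id) != 1L || !nzchar(section_id)) {
    stop("`section_id` must be a single non-empty string", call. = FALSE)
  }
  spots <- validate_spots(spots)
  counts <- as_dgc(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("`counts` must have unique gene identifiers as rownames", call. = FALSE)
  }
  if (ncol(counts) != nrow(spots)) {
    stop(sprintf("counts has %d columns but there are %d spots",
                 ncol(counts), nrow(spots)), call. = FALSE)
  }
  if (any(counts@x < 0)) stop("`counts` must be nonnegative", call. = FALSE)
  if (!is.matrix(image) || length(image) == 0L) {
    stop("`image` must be a non-empty matrix", call. = FALSE)
  }
  scale <- validate_scalefactors(scale)
  structure(list(section_id = section_id, spots = spots, counts = counts,
                 image = image, scale = scale),
            class = "capture_area")
}

validate_spots <- function(spots) {
  need <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row", "pxl_col")
  if (!is.data.frame(spots) || !all(need %in% names(spots))) {
    stop("`spots` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(spots$barcode))) stop("empty barcode", call. = FALSE)
  if (any(spots$array_row < 0) || any(spots$array_col < 0)) {
    stop("array_row/array_col must be >= 0", call. = FALSE)
  }
  spots$in_tissue <- as.logical(spots$in_tissue)
  spots[, c(need, setdiff(names(spots), need))]
}

validate_scalefactors <- function(scale) {
  need <- c("spot_diameter_fullres", "tissue_hires_scalef", "tissue_lowres_scalef")
  if (!is.list(scale) || !all(need %in% names(scale))) {
    stop("`scale` must be a list with ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (nm in need) {
    if (!is.numeric(scale[[nm]]) || scale[[nm]] <= 0) {
      stop("scale factor `", nm, "` must be positive", call. = FALSE)
    }
  }
  scale[need]
}

#' @export
print.capture_area <- function(x, ...) {
  cat(sprintf("capture_area '%s': %d spots, %d genes, image %dx%d px\n",
              x$section_id, nrow(x$spots), nrow(x$counts),
              nrow(x$image), ncol(x$image)))
  invisible(x)
}

#' @export
print.stitched_section <- function(x, ...) {
  cat(sprintf(
    "stitched_section: %d spots from %d sections, %d genes, image %dx%d px\n",
    nrow(x$spots), length(x$transforms_used), nrow(x$counts),
    nrow(x$image), ncol(x$image)))
  invisible(x)
}
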