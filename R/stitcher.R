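#' Transform a capture area's spots into the reconstructed frame
#'
#' Applies an affine transform to the full-resolution pixel coordinates of
#' every spot. Barcodes are suffixed with \code{-<section_id>} so that the
#' same spatial barcode on different capture areas of one chip stays unique
#' after merging; array coordinates are carried through unchanged, and a
#' \code{section_id} provenance column is added.
#'
#' @param area A \code{\link{capture_area}}.
#' @param t An \code{\link{affine2d}} into the reconstructed frame.
#' @param suffix_sep Separator between barcode and section id.
#' @return data.frame of transformed spot records.
#' @export
transform_spots <- function(area, t, suffix_sep = "-") {
  stopifnot(inherits(area, "capture_area"), is_affine2d(t))
  spots <- area$spots
  if (nrow(spots) == 0L) stop("capture area has no spots", call. = FALSE)
  pts <- apply_affine(t, cbind(spots$pxl_col, spots$pxl_row))
  out <- spots
  out$barcode <- paste0(spots$barcode, suffix_sep, area$section_id)
  out$pxl_col <- pts[, 1]
  out$pxl_row <- pts[, 2]
  out$section_id <- area$section_id
  out
}

#' Merge multiple capture areas into one stitched section
#'
#' The core stitching step for anatomically continuous sections placed on
#' different capture areas of one slide. Spot positions are mapped into one
#' reconstructed frame by the per-section affine transforms; the section
#' images are composited with the centre section taking priority in
#' overlaps; the libraries are merged into a single counts matrix by outer
#' join on gene identifiers (zero fill), keeping every spot — spots are
#' never dropped or masked in image-overlap regions. The whole frame is
#' translated so the composite's minimum corner is (0, 0); the translation
#' is stored as \code{frame_offset} so raw transform outputs stay
#' recoverable.
#'
#' @param areas List of \code{\link{capture_area}} objects with distinct ids.
#' @param transforms Named list of \code{\link{affine2d}}, one per section,
#'   mapping section pixels to the reconstructed frame.
#' @param centre_id Section whose image wins in overlapping regions.
#' @param priority Optional full priority order (centre first); defaults to
#'   the centre followed by the remaining sections in input order.
#' @param suffix_sep Barcode suffix separator.
#' @param scale_tol Sections are assumed to come from one chip; merging
#'   errors if spot-diameter scale factors disagree by more than this
#'   relative tolerance (default 1%).
#' @return An object of class \code{stitched_section} with elements
#'   \code{spots}, \code{counts}, \code{image}, \code{frame_offset},
#'   \code{transforms_used} and \code{scale}.
#' @export
merge_sections <- function(areas, transforms, centre_id, priority = NULL,
                           suffix_sep = "-", scale_tol = 0.01) {
  if (length(areas) == 0L) stop("no capture areas supplied", call. = FALSE)
  ids <- vapply(areas, function(a) a$section_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate section ids", call. = FALSE)
  names(areas) <- ids
  missing_t <- setdiff(ids, names(transforms))
  if (length(missing_t)) {
    stop("missing transform for section(s): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  }
  if (!centre_id %in% ids) {
    stop("`centre_id` is not among the section ids", call. = FALSE)
  }
  if (is.null(priority)) priority <- c(centre_id, setdiff(ids, centre_id))
  if (priority[1] != centre_id) {
    stop("`priority` must list the centre section first", call. = FALSE)
  }

  diam <- vapply(areas, function(a) a$scale$spot_diameter_fullres, numeric(1))
  if (diff(range(diam)) > scale_tol * min(diam)) {
    stop("sections have incompatible scale factors (differ by more than ",
         scale_tol * 100, "%); stitching across chips is not supported",
         call. = FALSE)
  }

  comp <- composite_images(lapply(areas, function(a) a$image),
                           transforms[ids], priority)

  spot_list <- lapply(ids, function(id) {
    transform_spots(areas[[id]], transforms[[id]], suffix_sep)
  })
  spots <- do.call(rbind, spot_list)
  spots$pxl_col <- spots$pxl_col - comp$frame_offset[["x"]]
  spots$pxl_row <- spots$pxl_row - comp$frame_offset[["y"]]
  spots$section_id <- factor(spots$section_id, levels = ids)
  rownames(spots) <- NULL
  if (anyDuplicated(spots$barcode)) {
    stop("barcodes are not unique after suffixing", call. = FALSE)
  }

  genes <- unique(unlist(lapply(areas, function(a) rownames(a$counts))))
  blocks <- lapply(ids, function(id) {
    cts <- areas[[id]]$counts
    colnames(cts) <- paste0(areas[[id]]$spots$barcode, suffix_sep, id)
    pad_genes(cts, genes)
  })
  counts <- do.call(cbind, blocks)

  structure(list(spots = spots, counts = counts, image = comp$image,
                 frame_offset = comp$frame_offset,
                 transforms_used = transforms[ids],
                 scale = areas[[1]]$scale),
            class = "stitched_section")
}

# Outer-join helper: re-index a sparse gene x spot block onto a gene union,
# filling absent genes with zeros.
pad_genes <- function(counts, genes) {
  if (identical(rownames(counts), genes)) return(counts)
  out <- Matrix::Matrix(0, nrow = length(genes), ncol = ncol(counts),
                        sparse = TRUE,
                        dimnames = list(genes, colnames(counts)))
  present <- intersect(genes, rownames(counts))
  out[present, ] <- counts[present, , drop = FALSE]
  as_dgc(out)
}
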