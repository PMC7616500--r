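# Image handling. Images are plain numeric matrices; the pixel at matrix
# position [r, c] has coordinates (x = c - 1, y = r - 1), i.e. 0-based
# column/row pixel centres, matching the Space Ranger full-resolution frame.

#' Sample an image at continuous coordinates with bilinear interpolation
#'
#' Coordinates outside the image domain return \code{fill}. Used for
#' inverse-mapping resampling when compositing sections.
#'
#' @param img Numeric matrix.
#' @param x,y Numeric vectors of 0-based (column, row) coordinates.
#' @param fill Background value for out-of-domain samples.
#' @return Numeric vector of sampled intensities.
#' @export
bilinear_sample <- function(img, x, y, fill = 0) {
  stopifnot(is.matrix(img), length(x) == length(y))
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(fill, length(x))
  eps <- 1e-9
  inside <- x >= -eps & x <= nc - 1 + eps & y >= -eps & y <= nr - 1 + eps
  if (!any(inside)) return(out)
  xi <- pmin(pmax(x[inside], 0), nc - 1)
  yi <- pmin(pmax(y[inside], 0), nr - 1)
  x0 <- pmin(floor(xi), nc - 2); x0[nc == 1] <- 0
  y0 <- pmin(floor(yi), nr - 2); y0[nr == 1] <- 0
  fx <- xi - x0; fy <- yi - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  v <- img[i00] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, pmin(x0 + 2, nc))] * fx * (1 - fy) +
    img[cbind(pmin(y0 + 2, nr), x0 + 1)] * (1 - fx) * fy +
    img[cbind(pmin(y0 + 2, nr), pmin(x0 + 2, nc))] * fx * fy
  out[inside] <- v
  out
}

#' Write / read an image as ASCII PGM (P2)
#'
#' Plain-text grayscale image format used for materialised fixtures and
#' composite images. Values are rounded to integers in \code{[0, maxval]}.
#'
#' @param img Numeric matrix.
#' @param path File path.
#' @param maxval Maximum gray value.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  stopifnot(is.matrix(img))
  vals <- round(pmin(pmax(img, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  write.table(vals, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 3L || trimws(lines[1]) != "P2") {
    stop("not an ASCII PGM (P2) file: ", path, call. = FALSE)
  }
  dims <- scan(text = lines[2], quiet = TRUE)
  vals <- scan(text = paste(lines[-(1:3)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != dims[1] * dims[2]) {
    stop("PGM pixel count does not match header dimensions: ", path,
         call. = FALSE)
  }
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

# Exact text round-trip for float-valued images (stitched container).
write_image_txt <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(img), ncol(img)), con)
  writeLines(vapply(seq_len(nrow(img)), function(r) {
    paste(format_double(img[r, ]), collapse = " ")
  }, character(1)), con)
  invisible(path)
}

read_image_txt <- function(path) {
  lines <- readLines(path)
  dims <- scan(text = lines[1], quiet = TRUE)
  vals <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
}

#' Composite transformed section images under a priority rule
#'
#' Renders every section image into one reconstructed frame. The canvas is
#' the bounding box of all transformed image corners, translated so its
#' minimum corner is (0, 0); the translation is returned as
#' \code{frame_offset}. Where sections overlap, each output pixel keeps the
#' value of the highest-priority section covering it — with the centre
#' section first in \code{priority}, this is the centre-priority rule used
#' when stitching consecutive sections. Resampling is inverse-mapping with
#' bilinear interpolation and background fill.
#'
#' @param images Named list of numeric matrices (one per section).
#' @param transforms Named list of \code{\link{affine2d}} mapping each
#'   section's pixels into the reconstructed frame.
#' @param priority Character vector listing every section id exactly once,
#'   highest priority first.
#' @param fill Background value.
#' @return A list with \code{image} (numeric matrix) and \code{frame_offset}
#'   (named vector \code{c(x, y)}: the reconstructed-frame coordinate of the
#'   canvas origin before translation).
#' @export
composite_images <- function(images, transforms, priority, fill = 0) {
  if (length(images) == 0L) stop("empty image list", call. = FALSE)
  ids <- names(images)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids)) {
    stop("`images` must be a uniquely named list", call. = FALSE)
  }
  if (!setequal(priority, ids) || length(priority) != length(ids)) {
    stop("`priority` must list every section id exactly once", call. = FALSE)
  }
  missing_t <- setdiff(ids, names(transforms))
  if (length(missing_t)) {
    stop("missing transform for section(s): ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }

  corners <- do.call(rbind, lapply(ids, function(id) {
    img <- images[[id]]
    pts <- cbind(c(0, ncol(img) - 1, 0, ncol(img) - 1),
                 c(0, 0, nrow(img) - 1, nrow(img) - 1))
    apply_affine(transforms[[id]], pts)
  }))
  xmin <- floor(min(corners[, 1])); xmax <- ceiling(max(corners[, 1]))
  ymin <- floor(min(corners[, 2])); ymax <- ceiling(max(corners[, 2]))
  nc_out <- xmax - xmin + 1L
  nr_out <- ymax - ymin + 1L

  gx <- rep(seq(xmin, xmax), each = nr_out)
  gy <- rep(seq(ymin, ymax), times = nc_out)
  canvas <- matrix(fill, nrow = nr_out, ncol = nc_out)

  # paint lowest priority first so the highest-priority section wins
  for (id in rev(priority)) {
    inv <- affine_invert(transforms[[id]])
    local <- apply_affine(inv, cbind(gx, gy))
    img <- images[[id]]
    eps <- 1e-9
    covered <- local[, 1] >= -eps & local[, 1] <= ncol(img) - 1 + eps &
      local[, 2] >= -eps & local[, 2] <= nrow(img) - 1 + eps
    if (any(covered)) {
      vals <- bilinear_sample(img, local[covered, 1], local[covered, 2], fill)
      canvas[covered] <- vals
    }
  }
  list(image = canvas, frame_offset = c(x = xmin, y = ymin))
}

#' Otsu threshold convenience converter
#'
#' Turns a grayscale image into a binary mask by maximising between-class
#' variance over a 256-bin histogram. This is plumbing for quick mask
#' creation only — production masks come from an external pixel classifier.
#'
#' @param img Numeric matrix.
#' @return Logical matrix of the same shape.
#' @export
otsu_mask <- function(img) {
  stopifnot(is.matrix(img))
  v <- as.vector(img)
  rng <- range(v)
  if (rng[1] == rng[2]) return(matrix(FALSE, nrow(img), ncol(img)))
  bins <- 256L
  h <- tabulate(pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L, bins),
                nbins = bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(bins))
  mu_t <- mu[bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  thr <- rng[1] + k / bins * (rng[2] - rng[1])
  img > thr
}
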