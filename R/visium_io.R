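#' Read a Space Ranger tissue positions file
#'
#' Accepts both dialects: the headerless \code{tissue_positions_list.csv}
#' and the headered \code{tissue_positions.csv}. Six columns are required:
#' barcode, in_tissue, array_row, array_col, pxl_row_in_fullres,
#' pxl_col_in_fullres. Malformed rows are rejected with the line number.
#'
#' @param path CSV path.
#' @return data.frame of spot records (columns \code{barcode},
#'   \code{in_tissue}, \code{array_row}, \code{array_col}, \code{pxl_row},
#'   \code{pxl_col}); zero rows for an empty file.
#' @export
read_tissue_positions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(barcode = character(), in_tissue = logical(),
                      array_row = integer(), array_col = integer(),
                      pxl_row = numeric(), pxl_col = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  offset <- 0L
  if (grepl("^barcode", lines[1])) {
    lines <- lines[-1]
    offset <- 1L
    if (length(lines) == 0L) return(empty)
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 6L)) {
    bad <- which(nfield != 6L)[1]
    stop(sprintf("line %d of %s has %d fields (expected 6)",
                 bad + offset, path, nfield[bad]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 2:6, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 5)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stop(sprintf("line %d of %s: non-numeric field", bad + offset, path),
         call. = FALSE)
  }
  if (!all(num[, 1] %in% c(0, 1))) {
    stop("in_tissue column must be 0 or 1: ", path, call. = FALSE)
  }
  validate_spots(data.frame(
    barcode = m[, 1], in_tissue = num[, 1] == 1,
    array_row = as.integer(num[, 2]), array_col = as.integer(num[, 3]),
    pxl_row = num[, 4], pxl_col = num[, 5], stringsAsFactors = FALSE))
}

#' @rdname read_tissue_positions
#' @param spots Spot record data.frame.
#' @param header Write the headered dialect?
#' @export
write_tissue_positions <- function(spots, path, header = FALSE) {
  spots <- validate_spots(spots)
  df <- data.frame(barcode = spots$barcode,
                   in_tissue = as.integer(spots$in_tissue),
                   array_row = spots$array_row, array_col = spots$array_col,
                   pxl_row_in_fullres = format_double(spots$pxl_row),
                   pxl_col_in_fullres = format_double(spots$pxl_col))
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read / write a feature-barcode matrix as an MTX triplet
#'
#' \code{matrix.mtx} plus \code{features.tsv} and \code{barcodes.tsv}
#' (gzipped variants accepted when reading). Dimensions are checked against
#' the feature and barcode lists.
#'
#' @param dir Directory holding the triplet.
#' @return List with \code{genes}, \code{barcodes}, and sparse
#'   \code{counts} (genes x barcodes \code{dgCMatrix}).
#' @export
read_counts_mtx <- function(dir) {
  find1 <- function(stems) {
    for (s in stems) {
      p <- file.path(dir, s)
      if (file.exists(p)) return(p)
      if (file.exists(paste0(p, ".gz"))) return(paste0(p, ".gz"))
    }
    stop("missing ", stems[1], " under ", dir, call. = FALSE)
  }
  m <- Matrix::readMM(find1("matrix.mtx"))
  feats <- utils::read.delim(find1(c("features.tsv", "genes.tsv")),
                             header = FALSE, stringsAsFactors = FALSE)
  bcs <- utils::read.delim(find1("barcodes.tsv"), header = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m)) {
    stop(sprintf("features.tsv has %d rows but matrix has %d rows",
                 nrow(feats), nrow(m)), call. = FALSE)
  }
  if (nrow(bcs) != ncol(m)) {
    stop(sprintf("barcodes.tsv has %d rows but matrix has %d columns",
                 nrow(bcs), ncol(m)), call. = FALSE)
  }
  m <- as_dgc(m)
  dimnames(m) <- list(feats[[1]], bcs[[1]])
  list(genes = feats[[1]], barcodes = bcs[[1]], counts = m)
}

#' @rdname read_counts_mtx
#' @param counts Genes x barcodes matrix with dimnames.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a capture area from a Space Ranger-layout directory
#'
#' Counterpart of \code{\link{write_spaceranger_dir}}.
#'
#' @param dir Directory with \code{spatial/} and the MTX triplet.
#' @param section_id Label for the loaded area.
#' @return A \code{\link{capture_area}}.
#' @export
read_capture_area <- function(dir, section_id) {
  spots <- read_tissue_positions(
    file.path(dir, "spatial", "tissue_positions_list.csv"))
  scale <- jsonlite::read_json(
    file.path(dir, "spatial", "scalefactors_json.json"), simplifyVector = TRUE)
  mtx <- read_counts_mtx(dir)
  img <- read_pgm(file.path(dir, "tissue_image.pgm"))
  capture_area(section_id, spots, mtx$counts, img, as.list(scale))
}

#' Read per-section affine transforms
#'
#' Two dialects are accepted. The canonical dialect is JSON:
#' \preformatted{{"resolution": "fullres",
#'   "transforms": {"C42B1": [a, b, c, d, e, f], ...}}}
#' with coefficients in SVG/TrakEM2 \code{matrix(a,b,c,d,e,f)} order. The
#' \code{resolution} field is mandatory and must be \code{"fullres"}:
#' registration tools do not record which image resolution their matrices
#' act on, so the file must declare it rather than the reader guessing.
#' Alternatively a TrakEM2 XML subset is parsed: \code{t2_patch} nodes with
#' a \code{transform="matrix(...)"} attribute, section ids taken from the
#' \code{title} attribute. Singular matrices are rejected.
#'
#' @param path File path (.json or TrakEM2-style .xml).
#' @return Named list of \code{\link{affine2d}} keyed by section id.
#' @export
read_affine_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- trimws(paste(readLines(path, n = 5L), collapse = " "))
  if (startsWith(first, "{")) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$resolution)) {
      stop("affine file must declare `resolution` (e.g. \"fullres\")",
           call. = FALSE)
    }
    if (!identical(obj$resolution, "fullres")) {
      stop("only `resolution: \"fullres\"` affine files are supported; got ",
           obj$resolution, call. = FALSE)
    }
    tr <- obj$transforms
    if (is.null(tr) || length(tr) == 0L) {
      stop("affine file has no `transforms` entries", call. = FALSE)
    }
    return(lapply(tr, function(v) {
      if (length(v) != 6L) stop("each transform needs 6 coefficients", call. = FALSE)
      do.call(affine2d, as.list(as.numeric(v)))
    }))
  }
  if (startsWith(first, "<")) {
    doc <- xml2::read_xml(path)
    patches <- xml2::xml_find_all(doc, "//t2_patch[@transform]")
    if (length(patches) == 0L) {
      stop("no t2_patch nodes with a transform attribute in ", path,
           call. = FALSE)
    }
    out <- lapply(patches, function(p) {
      parse_trakem_matrix(xml2::xml_attr(p, "transform"))
    })
    names(out) <- vapply(patches, function(p) xml2::xml_attr(p, "title"),
                         character(1))
    if (anyNA(names(out)) || any(names(out) == "")) {
      stop("t2_patch nodes must carry a title attribute (section id)",
           call. = FALSE)
    }
    return(out)
  }
  stop("unknown affine file dialect: ", path, call. = FALSE)
}

# "matrix(a,b,c,d,e,f)" -> affine2d, per the SVG/TrakEM2 convention.
parse_trakem_matrix <- function(s) {
  m <- regmatches(s, regexec("matrix\\(([^)]*)\\)", s))[[1]]
  if (length(m) != 2L) stop("not a matrix(a,b,c,d,e,f) string: ", s, call. = FALSE)
  v <- as.numeric(strsplit(m[2], "[,\\s]+", perl = TRUE)[[1]])
  v <- v[!is.na(v)]
  if (length(v) != 6L) stop("expected 6 coefficients in: ", s, call. = FALSE)
  do.call(affine2d, as.list(v))
}

#' @rdname read_affine_file
#' @param transforms Named list of \code{\link{affine2d}}.
#' @export
write_affine_file <- function(transforms, path) {
  stopifnot(length(transforms) > 0, !is.null(names(transforms)))
  jsonlite::write_json(
    list(resolution = "fullres",
         transforms = lapply(transforms, function(t) {
           c(t$a, t$b, t$c, t$d, t$e, t$f)
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read the stitched-section container
#'
#' Plain-text directory layout: the merged counts as an MTX triplet, the
#' spot table (reconstructed-frame coordinates plus per-spot section
#' provenance) as CSV with full float precision, the composite image as a
#' text matrix, and frame offset / transforms / scale factors as JSON.
#' \code{read_stitched(write_stitched(x))} is the identity on counts,
#' coordinates, provenance and image.
#'
#' @param stitched A \code{stitched_section} from \code{\link{merge_sections}}.
#' @param dir Container directory.
#' @return \code{dir} (write) or a \code{stitched_section} (read).
#' @export
write_stitched <- function(stitched, dir) {
  stopifnot(inherits(stitched, "stitched_section"))
  if (nrow(stitched$counts) == 0L) {
    stop("stitched section has an empty gene set", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts_mtx(stitched$counts, dir)
  sp <- stitched$spots
  df <- data.frame(barcode = sp$barcode, section_id = as.character(sp$section_id),
                   in_tissue = as.integer(sp$in_tissue),
                   array_row = sp$array_row, array_col = sp$array_col,
                   pxl_row = format_double(sp$pxl_row),
                   pxl_col = format_double(sp$pxl_col))
  utils::write.csv(df, file.path(dir, "spots.csv"), row.names = FALSE,
                   quote = FALSE)
  write_image_txt(stitched$image, file.path(dir, "image.txt"))
  meta <- list(
    frame_offset = as.numeric(stitched$frame_offset),
    section_ids = names(stitched$transforms_used),
    transforms_used = lapply(stitched$transforms_used, function(t) {
      c(t$a, t$b, t$c, t$d, t$e, t$f)
    }),
    scale = stitched$scale)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_stitched
#' @export
read_stitched <- function(dir) {
  for (f in c("matrix.mtx", "spots.csv", "image.txt", "meta.json")) {
    if (!file.exists(file.path(dir, f))) {
      stop("corrupted stitched container: missing ", f, call. = FALSE)
    }
  }
  mtx <- read_counts_mtx(dir)
  sp <- utils::read.csv(file.path(dir, "spots.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  sp$in_tissue <- sp$in_tissue == 1
  sp$pxl_row <- as.numeric(sp$pxl_row)
  sp$pxl_col <- as.numeric(sp$pxl_col)
  sp$section_id <- factor(sp$section_id, levels = meta$section_ids)
  sp <- sp[, c("barcode", "in_tissue", "array_row", "array_col",
               "pxl_row", "pxl_col", "section_id")]
  structure(list(
    spots = sp, counts = mtx$counts,
    image = read_image_txt(file.path(dir, "image.txt")),
    frame_offset = c(x = meta$frame_offset[1], y = meta$frame_offset[2]),
    transforms_used = lapply(meta$transforms_used, function(v) {
      do.call(affine2d, as.list(as.numeric(v)))
    }),
    scale = as.list(meta$scale)), class = "stitched_section")
}
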