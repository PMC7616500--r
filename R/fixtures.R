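#' Fixture specification for synthetic Visium-like data
#'
#' The generators below produce deterministic, seeded synthetic data with
#' the geometric and statistical structure the rest of the toolkit needs:
#' a reduced hexagonal Visium lattice (array_col parity equals array_row
#' parity, as on the real 78x128 array, but 8x16 by default), negative
#' binomial counts, and a smooth per-section image pattern. They make no
#' attempt to simulate limb biology.
#'
#' @param seed Integer RNG seed; identical specs give bit-identical output.
#' @param grid_rows,grid_cols Array dimensions (both >= 2).
#' @param n_genes Number of genes (>= 1).
#' @param image_shape Image size in pixels, \code{c(rows, cols)}.
#' @param noise_sd Nonnegative sd of additive image noise.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1L, grid_rows = 8L, grid_cols = 16L,
                         n_genes = 50L, image_shape = c(96L, 128L),
                         noise_sd = 2) {
  if (grid_rows < 2L || grid_cols < 2L) {
    stop("grid_rows and grid_cols must both be >= 2", call. = FALSE)
  }
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (length(image_shape) != 2L || any(image_shape < 4L)) {
    stop("image_shape must be c(rows, cols), both >= 4", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(seed = as.integer(seed), grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols), n_genes = as.integer(n_genes),
                 image_shape = as.integer(image_shape), noise_sd = noise_sd),
            class = "fixture_spec")
}

# Reduced Visium lattice: keep (row, col) positions with matching parity.
visium_lattice <- function(grid_rows, grid_cols) {
  g <- expand.grid(array_col = seq_len(grid_cols) - 1L,
                   array_row = seq_len(grid_rows) - 1L)
  g <- g[g$array_col %% 2L == g$array_row %% 2L, c("array_row", "array_col")]
  rownames(g) <- NULL
  g
}

# Pixel geometry of the synthetic lattice: one array-column step is half a
# spot pitch. With a 100 um pitch and ~8.33 um/px this gives a 6 px column
# step and (hexagonal) ~10.4 px row step, rounded to 10 for readability.
FIXTURE_COL_STEP_PX <- 6
FIXTURE_ROW_STEP_PX <- 10
FIXTURE_MARGIN_PX <- 12

# Smooth deterministic scene evaluated analytically at any global (x, y);
# per-section phase makes each section's pattern distinguishable.
fixture_scene <- function(x, y, phase = 0) {
  128 + 60 * sin(x / 23 + phase) * cos(y / 17) + 40 * sin((x + y) / 31 - phase)
}

#' Generate one synthetic capture area
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param section_id Section label (also salts the RNG stream and image
#'   pattern so different sections are distinguishable).
#' @return A \code{\link{capture_area}}.
#' @examples
#' ca <- make_capture_area(fixture_spec(seed = 1, grid_rows = 4, grid_cols = 6))
#' nrow(ca$spots)  # 12 parity-matching lattice positions
#' @export
make_capture_area <- function(spec, section_id = "S1") {
  stopifnot(inherits(spec, "fixture_spec"))
  lat <- visium_lattice(spec$grid_rows, spec$grid_cols)
  n_spots <- nrow(lat)
  spots <- data.frame(
    barcode = sprintf("BC%05d-1", seq_len(n_spots)),
    in_tissue = TRUE,
    array_row = lat$array_row,
    array_col = lat$array_col,
    pxl_row = FIXTURE_MARGIN_PX + lat$array_row * FIXTURE_ROW_STEP_PX,
    pxl_col = FIXTURE_MARGIN_PX + lat$array_col * FIXTURE_COL_STEP_PX,
    stringsAsFactors = FALSE
  )
  sec_seed <- (spec$seed + str_hash(section_id)) %% .Machine$integer.max
  counts <- with_seed(sec_seed, {
    mu <- exp(stats::rnorm(spec$n_genes, log(2), 1))
    m <- matrix(stats::rnbinom(spec$n_genes * n_spots, size = 2,
                               mu = rep(mu, times = n_spots)),
                nrow = spec$n_genes, ncol = n_spots)
    dimnames(m) <- list(sprintf("GENE%04d", seq_len(spec$n_genes)),
                        spots$barcode)
    m
  })
  image <- fixture_section_image(spec, section_id, affine_identity())
  scale <- list(spot_diameter_fullres = 7.8,
                tissue_hires_scalef = 0.5, tissue_lowres_scalef = 0.15)
  capture_area(section_id, spots, counts, image, scale)
}

# Section image: the analytic scene sampled through `t` (local -> global),
# so merging sections with their true transforms reassembles one scene.
fixture_section_image <- function(spec, section_id, t) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  phase <- (str_hash(section_id) %% 7) / 7 * 2 * pi
  gx <- rep(seq_len(nc) - 1, each = nr)
  gy <- rep(seq_len(nr) - 1, times = nc)
  glob <- apply_affine(t, cbind(gx, gy))
  img <- matrix(fixture_scene(glob[, 1], glob[, 2], phase = 0), nr, nc)
  # faint per-section stamp in a corner so sections are tell-apart-able
  stamp <- 20 * sin(gx / 3 + phase) * exp(-((gx - 6)^2 + (gy - 6)^2) / 50)
  img <- img + matrix(stamp, nr, nc)
  if (spec$noise_sd > 0) {
    sec_seed <- (spec$seed + str_hash(section_id) + 7919L) %% .Machine$integer.max
    img <- img + with_seed(sec_seed, matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc))
  }
  pmin(pmax(img, 0), 255)
}

#' Generate consecutive overlapping sections with known true transforms
#'
#' Emulates consecutive thin sections of one tissue placed on different
#' capture areas: each section's image and spot coordinates are consistent
#' with the supplied ground-truth affine transforms into a shared global
#' frame, with a known overlap between consecutive sections. Each returned
#' capture area carries its true global spot coordinates in the
#' \code{"true_global_spots"} attribute for round-trip testing.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param n_sections Number of sections (>= 2).
#' @param true_transforms Optional list of invertible \code{\link{affine2d}}
#'   (local pixels to global frame), one per section; defaults to
#'   translations by 60% of the image width so consecutive sections overlap
#'   by 40%.
#' @return List with \code{areas} (capture areas named S1..Sn) and
#'   \code{transforms} (the ground-truth affines, same names).
#' @export
make_overlapping_sections <- function(spec, n_sections = 3L,
                                      true_transforms = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (n_sections < 2L) stop("n_sections must be >= 2", call. = FALSE)
  ids <- paste0("S", seq_len(n_sections))
  if (is.null(true_transforms)) {
    shift <- round(0.6 * (spec$image_shape[2] - 1))
    true_transforms <- lapply(seq_len(n_sections) - 1L, function(i) {
      affine_translation(i * shift, 0)
    })
  }
  if (length(true_transforms) != n_sections) {
    stop("need one transform per section", call. = FALSE)
  }
  ok <- vapply(true_transforms, is_affine2d, logical(1))
  if (!all(ok)) stop("true_transforms must be affine2d objects", call. = FALSE)
  names(true_transforms) <- ids

  areas <- lapply(ids, function(id) {
    ca <- make_capture_area(spec, id)
    ca$image <- fixture_section_image(spec, id, true_transforms[[id]])
    attr(ca, "true_global_spots") <-
      apply_affine(true_transforms[[id]], cbind(ca$spots$pxl_col, ca$spots$pxl_row))
    ca
  })
  names(areas) <- ids
  list(areas = areas, transforms = true_transforms)
}

#' Generate a per-cell doublet-score table with planted doublet clusters
#'
#' Scores are drawn from a normal around \code{base_score}, except in the
#' planted clusters where they centre on \code{doublet_score}; everything
#' is clipped to [0, 1]. Truth labels are retained for power evaluation.
#'
#' @param n_clusters Number of fine clusters.
#' @param cells_per_cluster Cells per cluster.
#' @param planted_doublet_clusters Character vector of planted cluster
#'   labels (subset of \code{C1..Cn}); may be empty.
#' @param base_score,doublet_score Means with \code{0 <= base < doublet <= 1}.
#' @param noise_sd Score noise sd.
#' @param seed RNG seed.
#' @return data.frame with \code{cell_id}, \code{lane_id},
#'   \code{raw_score}, \code{fine_cluster}, \code{is_doublet_truth}.
#' @export
make_doublet_scores <- function(n_clusters = 20L, cells_per_cluster = 20L,
                                planted_doublet_clusters = character(),
                                base_score = 0.05, doublet_score = 0.6,
                                noise_sd = 0.02, seed = 1L) {
  if (!(base_score >= 0 && base_score < doublet_score && doublet_score <= 1)) {
    stop("need 0 <= base_score < doublet_score <= 1", call. = FALSE)
  }
  labels <- paste0("C", seq_len(n_clusters))
  if (!all(planted_doublet_clusters %in% labels)) {
    stop("planted labels are not a subset of the cluster labels", call. = FALSE)
  }
  n <- n_clusters * cells_per_cluster
  cl <- rep(labels, each = cells_per_cluster)
  is_doublet <- cl %in% planted_doublet_clusters
  mu <- ifelse(is_doublet, doublet_score, base_score)
  raw <- with_seed(seed, pmin(pmax(stats::rnorm(n, mu, noise_sd), 0), 1))
  data.frame(cell_id = sprintf("cell%05d", seq_len(n)), lane_id = "L1",
             raw_score = raw, fine_cluster = cl,
             is_doublet_truth = is_doublet, stringsAsFactors = FALSE)
}

#' Generate a reference/target mask pair with known joint occupancy
#'
#' The reference mask has exactly \code{n_ref} positive pixels; the target
#' mask is positive on exactly \code{n_dual} of them plus
#' \code{n_target_only} pixels outside the reference, so the co-occurrence
#' probability of the pair is \code{n_dual / n_ref} by construction.
#'
#' @param shape \code{c(rows, cols)} in pixels.
#' @param n_ref Reference-positive pixel count.
#' @param n_dual Dual-positive pixel count (<= n_ref).
#' @param seed RNG seed.
#' @param n_target_only Extra target-only positives.
#' @param pixel_size_um Physical pixel edge (default 0.14 um).
#' @return List of two \code{\link{mask_image}}s: \code{reference}, \code{target}.
#' @export
make_mask_pair <- function(shape = c(64L, 64L), n_ref, n_dual, seed = 1L,
                           n_target_only = 0L, pixel_size_um = 0.14) {
  npx <- prod(shape)
  if (!(n_dual <= n_ref && n_ref <= npx)) {
    stop("need n_dual <= n_ref <= total pixels", call. = FALSE)
  }
  if (n_ref + n_target_only > npx) {
    stop("requested positives exceed image capacity", call. = FALSE)
  }
  idx <- with_seed(seed, {
    ref <- sample.int(npx, n_ref)
    dual <- if (n_dual > 0) ref[seq_len(n_dual)] else integer()
    extra <- if (n_target_only > 0) {
      sample(setdiff(seq_len(npx), ref), n_target_only)
    } else integer()
    list(ref = ref, target = c(dual, extra))
  })
  ref_grid <- matrix(FALSE, shape[1], shape[2]); ref_grid[idx$ref] <- TRUE
  tgt_grid <- matrix(FALSE, shape[1], shape[2]); tgt_grid[idx$target] <- TRUE
  list(reference = mask_image(ref_grid, pixel_size_um, gene = "REF"),
       target = mask_image(tgt_grid, pixel_size_um, gene = "TGT"))
}

#' Materialise a capture area to disk in Space Ranger layout
#'
#' Writes \code{spatial/tissue_positions_list.csv},
#' \code{spatial/scalefactors_json.json}, the MTX triplet
#' (\code{matrix.mtx}, \code{barcodes.tsv}, \code{features.tsv}) and the
#' section image as ASCII PGM, so readers are tested against files.
#'
#' @param area A \code{\link{capture_area}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_spaceranger_dir <- function(area, dir) {
  stopifnot(inherits(area, "capture_area"))
  dir.create(file.path(dir, "spatial"), recursive = TRUE, showWarnings = FALSE)
  write_tissue_positions(area$spots, file.path(dir, "spatial", "tissue_positions_list.csv"))
  jsonlite::write_json(area$scale,
                       file.path(dir, "spatial", "scalefactors_json.json"),
                       auto_unbox = TRUE, digits = NA)
  write_counts_mtx(area$counts, dir)
  write_pgm(area$image, file.path(dir, "tissue_image.pgm"))
  invisible(dir)
}
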