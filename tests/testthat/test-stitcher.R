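test_that("apply_affine follows the SVG/TrakEM convention", {
  expect_equal(apply_affine(affine_identity(), cbind(10, 20)),
               cbind(x = 10, y = 20))
  expect_equal(apply_affine(affine_translation(100, 50), cbind(10, 20)),
               cbind(x = 110, y = 70))
  expect_equal(apply_affine(affine2d(0, 1, -1, 0, 0, 0), cbind(1, 0)),
               cbind(x = 0, y = 1))
})

test_that("inverse and composition round-trip random transforms", {
  set.seed(42)
  for (i in 1:25) {
    t <- random_affine()
    pts <- matrix(runif(20, -100, 100), ncol = 2)
    expect_lt(max(abs(apply_affine(affine_invert(t), apply_affine(t, pts)) - pts)),
              1e-9)
    comp <- affine_compose(t, affine_invert(t))
    expect_lt(max(abs(unlist(comp) - unlist(affine_identity()))), 1e-9)
  }
})

test_that("landmark estimation recovers generating transforms exactly", {
  set.seed(7)
  for (i in 1:20) {
    t <- random_affine()
    src <- matrix(runif(8, 0, 100), ncol = 2)
    est <- estimate_affine_from_landmarks(src, apply_affine(t, src))
    expect_lt(max(abs(unlist(est) - unlist(t))), 1e-9)
  }
  src <- cbind(c(0, 10, 0), c(0, 0, 10))
  est <- estimate_affine_from_landmarks(src, src)
  expect_lt(max(abs(unlist(est) - unlist(affine_identity()))), 1e-12)
  expect_error(
    estimate_affine_from_landmarks(cbind(1:3, (1:3) * 2), cbind(1:3, 1:3)),
    "collinear")
  expect_error(estimate_affine_from_landmarks(cbind(1:2, 1:2), cbind(1:2, 1:2)),
               "3 landmark")
})

test_that("transform_spots suffixes barcodes and preserves array coords", {
  ca <- make_capture_area(small_spec(), "S9")
  out <- transform_spots(ca, affine_identity())
  expect_equal(out$pxl_row, ca$spots$pxl_row)
  expect_equal(out$barcode, paste0(ca$spots$barcode, "-S9"))
  expect_equal(out$array_row, ca$spots$array_row)

  empty <- ca
  empty$spots <- ca$spots[0, ]
  empty$counts <- ca$counts[, 0, drop = FALSE]
  expect_error(transform_spots(empty, affine_identity()), "no spots")
})

test_that("composite_images applies the centre-priority overlap rule", {
  img <- matrix(runif(12 * 15), 12, 15)
  one <- composite_images(list(A = img), list(A = affine_identity()), "A")
  expect_equal(one$image, img)
  expect_equal(unname(one$frame_offset), c(0, 0))

  # two constant images, horizontal overlap: overlap keeps priority-A value
  a <- matrix(10, 20, 30)
  b <- matrix(200, 20, 30)
  tr <- list(A = affine_identity(), B = affine_translation(15, 0))
  comp <- composite_images(list(A = a, B = b), tr, priority = c("A", "B"))
  expect_equal(dim(comp$image), c(20, 45))
  expect_true(all(comp$image[, 16:30] == 10))   # overlap: A wins
  expect_true(all(comp$image[, 31:45] == 200))  # B-only region
  comp_b <- composite_images(list(A = a, B = b), tr, priority = c("B", "A"))
  expect_true(all(comp_b$image[, 16:30] == 200))

  # disjoint placements: both patterns present, fill elsewhere
  tr2 <- list(A = affine_identity(), B = affine_translation(40, 0))
  comp2 <- composite_images(list(A = a, B = b), tr2, priority = c("A", "B"),
                            fill = -1)
  expect_equal(sum(comp2$image == 10), 20 * 30)
  expect_equal(sum(comp2$image == 200), 20 * 30)
  expect_equal(dim(comp2$image), c(20, 70))  # canvas spans x = 0..69
  expect_equal(sum(comp2$image == -1), prod(dim(comp2$image)) - 2 * 20 * 30)

  expect_error(composite_images(list(), list(), character()), "empty")
  expect_error(composite_images(list(A = a), list(A = affine_identity()),
                                c("A", "A")), "exactly once")
})

test_that("permuting non-centre priority never changes centre-covered pixels", {
  fx <- make_overlapping_sections(small_spec(5L), 3)
  imgs <- lapply(fx$areas, function(a) a$image)
  p1 <- composite_images(imgs, fx$transforms, c("S2", "S1", "S3"))
  p2 <- composite_images(imgs, fx$transforms, c("S2", "S3", "S1"))
  # centre-covered pixels: inverse-map canvas into S2's frame
  inv <- affine_invert(fx$transforms$S2)
  nr <- nrow(p1$image); ncn <- ncol(p1$image)
  gx <- rep(seq_len(ncn) - 1 + p1$frame_offset[["x"]], each = nr)
  gy <- rep(seq_len(nr) - 1 + p1$frame_offset[["y"]], times = ncn)
  loc <- apply_affine(inv, cbind(gx, gy))
  img2 <- fx$areas$S2$image
  covered <- loc[, 1] >= 0 & loc[, 1] <= ncol(img2) - 1 &
    loc[, 2] >= 0 & loc[, 2] <= nrow(img2) - 1
  expect_identical(p1$image[covered], p2$image[covered])
})

test_that("merge_sections conserves spots and outer-joins genes", {
  fx <- make_overlapping_sections(small_spec(13L), 3)
  st <- merge_sections(fx$areas, fx$transforms, centre_id = "S2")
  n_spots <- sum(vapply(fx$areas, function(a) nrow(a$spots), integer(1)))
  expect_equal(nrow(st$spots), n_spots)         # 3 x 12 = 36, none dropped
  expect_equal(ncol(st$counts), n_spots)
  expect_false(anyDuplicated(st$spots$barcode) > 0)
  # identical gene lists -> merged gene count equals the shared list
  expect_equal(nrow(st$counts), nrow(fx$areas$S1$counts))
  expect_equal(levels(st$spots$section_id), c("S1", "S2", "S3"))

  # gene private to one section is zero-filled on other sections' spots
  fx2 <- fx
  extra <- Matrix::sparseMatrix(i = rep(1, 3), j = 1:3, x = c(4, 5, 6),
                                dims = c(1, ncol(fx2$areas$S1$counts)),
                                dimnames = list("GENE_EXTRA",
                                                colnames(fx2$areas$S1$counts)))
  fx2$areas$S1$counts <- rbind(fx2$areas$S1$counts, extra)
  st2 <- merge_sections(fx2$areas, fx2$transforms, centre_id = "S2")
  expect_equal(nrow(st2$counts), nrow(fx$areas$S1$counts) + 1L)
  other <- st2$spots$section_id != "S1"
  expect_true(all(st2$counts["GENE_EXTRA", other] == 0))
  expect_equal(sum(st2$counts["GENE_EXTRA", !other]), 15)
})

test_that("merge geometry: frame offset, round-trip and overlap-free pixels", {
  fx <- make_overlapping_sections(small_spec(17L), 3)
  st <- merge_sections(fx$areas, fx$transforms, centre_id = "S2")

  # re-express each spot in its source frame via the inverse transform
  for (id in names(fx$areas)) {
    sel <- st$spots$section_id == id
    glob <- cbind(st$spots$pxl_col[sel] + st$frame_offset[["x"]],
                  st$spots$pxl_row[sel] + st$frame_offset[["y"]])
    local <- apply_affine(affine_invert(fx$transforms[[id]]), glob)
    expect_lt(max(abs(local - cbind(fx$areas[[id]]$spots$pxl_col,
                                    fx$areas[[id]]$spots$pxl_row))), 1e-6)
  }

  # a spot outside all overlaps sees its source section's pixels
  s1 <- fx$areas$S1
  sel <- st$spots$section_id == "S1" & st$spots$pxl_col < fx$transforms$S2$e
  i <- which(sel)[1]
  r <- round(st$spots$pxl_row[i]) + 1
  c <- round(st$spots$pxl_col[i]) + 1
  src_r <- round(s1$spots$pxl_row[match(st$spots$barcode[i],
                                        paste0(s1$spots$barcode, "-S1"))]) + 1
  src_c <- round(s1$spots$pxl_col[match(st$spots$barcode[i],
                                        paste0(s1$spots$barcode, "-S1"))]) + 1
  expect_equal(st$image[r, c], s1$image[src_r, src_c])
})

test_that("merge_sections validates its inputs", {
  fx <- make_overlapping_sections(small_spec(), 2)
  expect_error(merge_sections(fx$areas, fx$transforms["S1"], "S1"),
               "missing transform")
  expect_error(merge_sections(fx$areas, fx$transforms, "S9"), "centre_id")
  dup <- list(fx$areas$S1, fx$areas$S1)
  expect_error(merge_sections(dup, fx$transforms, "S1"), "duplicate")
  other_chip <- fx$areas
  other_chip$S2$scale$spot_diameter_fullres <- 20
  expect_error(merge_sections(other_chip, fx$transforms, "S1"),
               "incompatible scale factors")
})

test_that("spot conservation holds across random fixture configurations", {
  for (seed in c(1L, 2L, 3L, 4L, 5L)) {
    fx <- make_overlapping_sections(small_spec(seed), 2 + seed %% 2)
    st <- merge_sections(fx$areas, fx$transforms, centre_id = "S1")
    expect_equal(nrow(st$spots),
                 sum(vapply(fx$areas, function(a) nrow(a$spots), integer(1))))
  }
})
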