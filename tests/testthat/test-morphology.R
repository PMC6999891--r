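test_that("area and centroid follow pixel count and pixel-center mean", {
  # 2x2 pixel square at the grid origin, 0.25 um/px
  m <- structure(list(labels = {
    lab <- matrix(0L, 8, 8); lab[1:2, 1:2] <- 1L; lab
  }, resolution = 0.25, origin = c(0, 0)), class = "mask_image")
  ac <- compute_area_centroid(m, 1)
  expect_equal(ac$area_um2, 4 * 0.25^2)
  expect_equal(ac$centroid, c(0.25, 0.25))

  disk <- rasterize_shapes(list(list(kind = "disk", center = c(15, 15),
                                     radius = 10)), 0.25)
  expect_equal(compute_area_centroid(disk, 1)$area_um2, pi * 100,
               tolerance = 0.01)
  expect_error(compute_area_centroid(disk, 9), "not present")
})

test_that("centroid is translation-equivariant", {
  set.seed(21)
  for (r in 1:5) {
    blob <- rand_blob(120)
    c0 <- compute_area_centroid(blob, 1)$centroid
    shift <- sample(1:5, 2)
    lab2 <- matrix(0L, nrow(blob$labels) + 10, ncol(blob$labels) + 10)
    idx <- which(blob$labels == 1L, arr.ind = TRUE)
    lab2[cbind(idx[, 1] + shift[1], idx[, 2] + shift[2])] <- 1L
    blob2 <- structure(list(labels = lab2, resolution = 0.25,
                            origin = c(0, 0)), class = "mask_image")
    c1 <- compute_area_centroid(blob2, 1)$centroid
    expect_equal(c1 - c0, rev(shift) * 0.25, tolerance = 1e-12)
  }
})

test_that("eccentricity: disk ~ 0, 2:1 ellipse ~ 0.866, rotation-invariant", {
  disk <- rasterize_shapes(list(list(kind = "disk", center = c(15, 15),
                                     radius = 10)), 0.25)
  expect_lte(compute_eccentricity(disk, 1), 0.05)

  ell <- rasterize_shapes(list(list(kind = "ellipse", center = c(10, 10),
                                    a = 7.5, b = 3.75)), 0.25)
  expect_equal(compute_eccentricity(ell, 1), sqrt(3) / 2, tolerance = 0.025)

  rot <- rasterize_shapes(list(list(kind = "ellipse", center = c(10, 10),
                                    a = 7.5, b = 3.75, angle = 30)), 0.25)
  expect_equal(compute_eccentricity(rot, 1),
               compute_eccentricity(ell, 1), tolerance = 0.02)

  # single pixel: defined as 0
  single <- structure(list(labels = matrix(c(0L, 1L, 0L, 0L), 2, 2),
                           resolution = 0.25, origin = c(0, 0)),
                      class = "mask_image")
  expect_equal(compute_eccentricity(single, 1), 0)
})

test_that("solidity: convex shapes ~ 1, cross ~ 2000/2800, monotone under erosion", {
  disk <- rasterize_shapes(list(list(kind = "disk", center = c(15, 15),
                                     radius = 10)), 0.25)
  expect_gte(compute_solidity(disk, 1), 0.98)

  # plus sign of two 60x20 px rectangles: hull is the 2800 px^2 octagon
  cross <- rasterize_shapes(list(list(kind = "cross", center = c(10, 10),
                                      length = 15, width = 5)), 0.25)
  expect_equal(compute_solidity(cross, 1), 2000 / 2800, tolerance = 0.02)

  # deleting interior pixels strictly decreases solidity
  lab <- disk$labels
  interior <- which(lab == 1L, arr.ind = TRUE)
  ctr <- colMeans(interior)
  near <- which((interior[, 1] - ctr[1])^2 +
                (interior[, 2] - ctr[2])^2 < 100)
  lab[interior[near, , drop = FALSE]] <- 0L
  eroded <- structure(list(labels = lab, resolution = 0.25,
                           origin = c(0, 0)), class = "mask_image")
  expect_lt(compute_solidity(eroded, 1), compute_solidity(disk, 1))
})

test_that("maximal Feret diameter matches analytics and the brute-force oracle", {
  disk <- rasterize_shapes(list(list(kind = "disk", center = c(15, 15),
                                     radius = 10)), 0.25)
  expect_equal(compute_feret_max(disk, 1), 20, tolerance = 0.3 / 20)

  # 100x1 px line
  lab <- matrix(0L, 5, 104)
  lab[3, 3:102] <- 1L
  line <- structure(list(labels = lab, resolution = 0.25, origin = c(0, 0)),
                    class = "mask_image")
  expect_equal(compute_feret_max(line, 1), 25, tolerance = 0.3 / 25)

  set.seed(22)
  for (r in 1:50) {
    blob <- rand_blob(sample(20:200, 1))
    p <- cd30nbhd:::.label_pixels(blob, 1)
    brute <- sqrt(max(outer(p$x, p$x, "-")^2 + outer(p$y, p$y, "-")^2))
    expect_equal(compute_feret_max(blob, 1), brute, tolerance = 1e-12)
  }
})

test_that("extract_features composes descriptors and feeds classification", {
  m <- rasterize_shapes(list(
    list(kind = "disk", center = c(20, 20), radius = 10),
    list(kind = "ellipse", center = c(60, 20), a = 12, b = 6),
    list(kind = "cross", center = c(100, 20), length = 16, width = 5)),
    resolution = 0.25)
  ds <- extract_features(m, "fixture", "LA")
  expect_equal(nrow(ds$cells), 3L)
  expect_true(all(is.na(ds$cells$pc)))
  expect_equal(ds$cells$area_um2[1], pi * 100, tolerance = 0.01)
  expect_equal(ds$cells$area_um2[2], pi * 72, tolerance = 0.01)
  expect_equal(ds$cells$eccentricity[2], sqrt(3) / 2, tolerance = 0.025)
  expect_lt(ds$cells$solidity[3], 0.9)

  classified <- classify_cells(filter_small_objects(ds, 109))
  expect_false(anyNA(classified$cells$pc))

  empty <- structure(list(labels = matrix(0L, 4, 4), resolution = 0.25,
                          origin = c(0, 0)), class = "mask_image")
  expect_equal(nrow(extract_features(empty)$cells), 0L)
})
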