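test_that("CSR sampler has Poisson counts, uniform locations, and is seeded", {
  win <- c(0, 1000, 0, 1000)
  set.seed(1)
  expect_equal(nrow(sample_csr(win, 0)), 0L)
  expect_error(sample_csr(win, -1), "non-negative")

  set.seed(2)
  counts <- replicate(200, nrow(sample_csr(win, 1e-3)))
  expect_equal(mean(counts), 1000, tolerance = 0.02)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.25)

  set.seed(3); a <- sample_csr(win, 5e-4)
  set.seed(3); b <- sample_csr(win, 5e-4)
  expect_identical(a, b)
  # uniformity: x coordinates pass a KS test against U(0, 1000)
  set.seed(4); p <- sample_csr(win, 2e-3)
  expect_gt(ks.test(p$x_um, "punif", 0, 1000)$p.value, 1e-4)
})

test_that("CSR nearest-neighbor mean matches the closed form 1/(2 sqrt(lambda))", {
  lambda <- 4e-4
  win <- c(0, 2500, 0, 2500)
  set.seed(5)
  # pool the NN distances of several independent realizations to push
  # sampling noise well below the tolerance
  d <- unlist(lapply(1:5, function(r) {
    p <- sample_csr(win, lambda)
    cells <- data.frame(cell_id = seq_len(nrow(p)), p,
                        area_um2 = 200, eccentricity = 0.2,
                        solidity = 0.95, feret_um = 17, pc = 0L)
    ds <- image_dataset(cells, "csr", "LA", window = win)
    nearest_neighbors(ds, cutoff = 300)$nn_distance_um
  }))
  expect_equal(mean(d), csr_nn_distribution(lambda)$mean,
               tolerance = 0.02)
})

test_that("Thomas clustering shortens NN distances; large sigma approaches CSR", {
  win <- c(0, 1000, 0, 1000)
  csr_mean <- csr_nn_distribution(1e-3)$mean
  set.seed(6)
  below <- replicate(20, {
    p <- sample_thomas(win, parent_intensity = 5e-5, offspring_mean = 20,
                       sigma = 10)
    d <- as.matrix(dist(p))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  })
  expect_true(all(below < csr_mean))

  expect_equal(nrow(sample_thomas(win, 5e-5, 0, 10)), 0L)

  # sigma of half the window washes clustering out: NN distances match the
  # Rayleigh law for the realized intensity
  set.seed(7)
  p <- sample_thomas(win, 2e-4, 10, sigma = 500)
  d <- as.matrix(dist(p))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  lam_hat <- nrow(p) / 1e6
  ks <- suppressWarnings(
    ks.test(nn, function(r) 1 - exp(-pi * lam_hat * r^2)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("cohorts are reproducible and class-consistent with the classifier", {
  spec <- dense_spec()
  a <- sample_preferential_cohort(spec, n_images = 2, diagnoses = "MCcHL",
                                  seed = 9)
  b <- sample_preferential_cohort(spec, n_images = 2, diagnoses = "MCcHL",
                                  seed = 9)
  expect_identical(a$datasets[[1]]$cells, b$datasets[[1]]$cells)
  expect_identical(a$manifest$image_id, c("MCcHL_01", "MCcHL_02"))

  # planted classes survive reclassification from morphology exactly
  ds <- a$datasets[[1]]
  reclass <- classify_cells(ds, threshold_config())
  expect_identical(reclass$cells$pc, ds$cells$pc)

  # single-class CSR spec: every cell classified PC 0
  solo <- synthetic_spec(window = c(0, 500, 0, 500),
                         intensity = c(2e-3, rep(0, 7)), clustering = NULL)
  ds0 <- sample_preferential_cohort(solo, n_images = 1, diagnoses = "LA",
                                    seed = 2)$datasets[[1]]
  expect_true(all(classify_cells(ds0)$cells$pc == 0L))
})

test_that("class marginals of null cohorts match spec intensities (chi-square)", {
  spec <- null_spec(1e-3)
  expected_p <- spec$intensity / sum(spec$intensity)
  set.seed(10)
  rejections <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    ds <- sample_preferential_cohort(spec, n_images = 1, diagnoses = "LA",
                                     seed = 1000 + r)$datasets[[1]]
    counts <- tabulate(ds$cells$pc + 1L, nbins = 8L)
    pv <- suppressWarnings(chisq.test(counts, p = expected_p)$p.value)
    if (pv < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)  # >= 95% non-rejections
})

test_that("morphology features fall in the target classifier cell with margin", {
  set.seed(11)
  pc <- sample(0:7, 500, replace = TRUE)
  m <- cd30nbhd:::sample_morphology(pc, threshold_config(), margin = 0.05)
  expect_identical(classify_cell(m$area_um2, m$eccentricity, m$solidity), pc)
  th <- threshold_config()
  large <- bitwAnd(pc, 1L) > 0
  expect_true(all(abs(m$area_um2 - th$area_large) >=
                    0.05 * th$area_large - 1e-9))
  expect_true(all(m$feret_um >=
                    equivalent_disk_diameter(m$area_um2) - 1e-9))
})

test_that("rasterized shapes have analytic areas and reject overlap", {
  m <- rasterize_shapes(list(list(kind = "disk", center = c(15, 15),
                                  radius = 10)), resolution = 0.25)
  npx <- sum(m$labels == 1L)
  expect_equal(npx, pi * 40^2, tolerance = 0.01)

  two <- rasterize_shapes(list(
    list(kind = "disk", center = c(15, 15), radius = 5),
    list(kind = "disk", center = c(45, 15), radius = 5)), 0.25)
  c1 <- compute_area_centroid(two, 1)$centroid
  c2 <- compute_area_centroid(two, 2)$centroid
  expect_equal(sqrt(sum((c1 - c2)^2)), 30, tolerance = 0.5 / 30)

  expect_error(rasterize_shapes(list(
    list(kind = "disk", center = c(15, 15), radius = 5),
    list(kind = "disk", center = c(18, 15), radius = 5)), 0.25),
    "overlap")
  expect_error(rasterize_shapes(list(list(kind = "blob", center = c(0, 0))),
                                0.25), "unknown shape")
})
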