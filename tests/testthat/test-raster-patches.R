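test_that("binarize applies the >= threshold rule and maps missing to non-forest", {
  cov <- cover_raster(matrix(c(50, 30, 10, 30), 2, 2, byrow = TRUE))
  land <- binarize(cov, 30)
  expect_identical(land$mask, matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
                                     byrow = TRUE))
  expect_true(all(!binarize(cover_raster(matrix(0, 3, 3)), 20)$mask))
  withna <- cover_raster(matrix(c(80, NA, NA, 80), 2, 2))
  expect_identical(sum(binarize(withna, 20)$mask), 2L)
  expect_error(binarize(cov, 0), "threshold")
  expect_error(binarize(cov, 120), "threshold")
  expect_error(cover_raster(matrix(c(-5, 10), 1, 2)), "0, 100")
})

test_that("higher thresholds give nested forest sets", {
  set.seed(41)
  for (i in 1:5) {
    cov <- cover_raster(matrix(sample(0:100, 400, TRUE), 20, 20))
    m40 <- binarize(cov, 40)$mask
    m20 <- binarize(cov, 20)$mask
    expect_true(all(m20[m40]))
  }
})

test_that("Moore labelling counts diagonal adjacency and matches a flood-fill oracle", {
  m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(label_patches(m)$sizes, 2)
  checker <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0)
  expect_equal(label_patches(checker)$sizes, flood_fill_sizes(checker))
  expect_equal(label_patches(checker)$sizes, 8)
  empty <- label_patches(matrix(FALSE, 5, 5))
  expect_equal(empty$n_patches, 0L)
  expect_equal(empty$total_forest, 0)
  expect_true(is.na(empty$rs_max))
  set.seed(7)
  for (i in 1:20) {
    mk <- matrix(runif(20 * 20) < runif(1, 0.2, 0.7), 20, 20)
    expect_equal(sort(label_patches(mk)$sizes), flood_fill_sizes(mk))
  }
})

test_that("census conserves forest area and respects cell_area", {
  set.seed(8)
  cov <- cover_raster(matrix(sample(0:100, 900, TRUE), 30, 30))
  cen <- label_patches(binarize(cov, 30))
  expect_equal(sum(cen$sizes), cen$total_forest)
  expect_equal(cen$total_forest, sum(cov$values >= 30))
  expect_equal(cen$s_max, max(cen$sizes))
  expect_true(cen$rs_max > 0 && cen$rs_max <= 1)
  cov_km <- cover_raster(cov$values, cell_area = 0.0534)
  cen_km <- label_patches(binarize(cov_km, 30))
  expect_equal(cen_km$total_forest, cen$total_forest * 0.0534)
})

test_that("census_sweep covers the default thresholds with monotone totals", {
  set.seed(9)
  cov <- cover_raster(matrix(sample(0:100, 2500, TRUE), 50, 50))
  sweep <- census_sweep(cov)
  expect_length(sweep, 5L)
  expect_equal(vapply(sweep, function(x) x$threshold, numeric(1)),
               c(20, 25, 30, 35, 40))
  totals <- vapply(sweep, function(x) x$total_forest, numeric(1))
  smax <- vapply(sweep, function(x) x$s_max, numeric(1))
  expect_true(all(diff(totals) <= 0))
  expect_true(all(diff(smax) <= 0))
  expect_error(census_sweep(cov, numeric(0)), "non-empty")
})

test_that("patches at a higher threshold nest inside patches at a lower one", {
  set.seed(10)
  cov <- cover_raster(matrix(sample(0:100, 625, TRUE), 25, 25))
  l20 <- fragcrit:::.ccl_label(binarize(cov, 20)$mask, FALSE)
  l40 <- fragcrit:::.ccl_label(binarize(cov, 40)$mask, FALSE)
  for (lab in setdiff(unique(as.vector(l40)), 0L)) {
    parents <- unique(l20[l40 == lab])
    expect_length(parents, 1L)
    expect_true(parents > 0L)
  }
})

test_that("ASCII grid and patch-size files round-trip", {
  dir <- withr::local_tempdir()
  vals <- matrix(sample(c(0:100, NA), 60, TRUE), 6, 10)
  cov <- cover_raster(vals, region_id = "AF1", year = 2005)
  p <- file.path(dir, "af1.asc")
  write_ascii_grid(cov, p)
  back <- read_ascii_grid(p, region_id = "AF1", year = 2005)
  expect_equal(back$values, unname(vals))
  cen <- label_patches(binarize(cov, 30))
  f <- write_patch_sizes(cen, dir)
  expect_equal(basename(f), "AF1_2005_30.csv")
  cen2 <- read_patch_sizes(f)
  expect_equal(sort(cen2$sizes), sort(cen$sizes))
  expect_equal(cen2$threshold, 30)
  expect_equal(cen2$year, 2005L)
})

test_that("largest-patch identity follows maximal overlap", {
  m1 <- matrix(FALSE, 8, 8); m1[1:4, 1:4] <- TRUE; m1[7:8, 7:8] <- TRUE
  m2 <- m1; m2[4, ] <- FALSE      # big patch loses a row, identity persists
  m3 <- matrix(FALSE, 8, 8); m3[6:8, 1:8] <- TRUE  # new patch elsewhere
  tr <- track_largest_patch(list(
    fragcrit:::as_binary_landscape(m1, year = 2000),
    fragcrit:::as_binary_landscape(m2, year = 2001),
    fragcrit:::as_binary_landscape(m3, year = 2002)))
  expect_equal(tr$s_max, c(16, 12, 24))
  expect_true(is.na(tr$overlap_prev[1]))
  expect_gt(tr$overlap_prev[2], 0.9)
  expect_true(tr$same_patch[2])
  expect_false(tr$same_patch[3])
})

test_that("largest-patch PNG export writes one frame per year", {
  skip_if_not_installed("png")
  dir <- withr::local_tempdir()
  lands <- lapply(1:3, function(i)
    percolation_lattice(16, 0.5, seed = i))
  paths <- write_largest_patch_pngs(lands, dir)
  expect_length(paths, 3L)
  expect_true(all(file.exists(paths)))
  img <- png::readPNG(paths[1])
  expect_equal(dim(img), c(16, 16))
})

test_that("single-band TIFF rasters are read back intact", {
  skip_if_not_installed("tiff")
  dir <- withr::local_tempdir()
  vals <- matrix(sample(0:100, 200, TRUE), 10, 20)
  p <- file.path(dir, "cov.tif")
  tiff::writeTIFF(vals / 100, p)
  back <- read_cover_tiff(p)
  expect_equal(round(back$values), vals)
})
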