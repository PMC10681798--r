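test_that("image_stack validates roles and dimensions", {
  px <- array(0L, c(2, 1, 4, 4))
  expect_error(image_stack(matrix(0L, 4, 4), list(foci = 1)), "4-D")
  expect_error(image_stack(px, list(foci = 3)), "out of range")
  expect_error(image_stack(px, list(foci = 1, mito = 1)), "distinct")
  expect_error(image_stack(px, list(blobs = 1)), "unknown channel role")
  expect_error(image_stack(px, list(foci = 1), pixel_size = -1), "> 0")
  s <- image_stack(px, list(foci = 1, mito = 2))
  expect_s3_class(s, "image_stack")
})

test_that("stack write/read round-trip is pixel-identical", {
  s <- random_stack(11)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, tf)
  r <- read_stack(tf, s$channel_roles, n_channels = 2)
  expect_identical(r$pixels, s$pixels)
  expect_true(is.na(r$pixel_size)) # no resolution metadata in our TIFFs
  r2 <- read_stack(tf, s$channel_roles, pixel_size_override = 0.063,
                   n_channels = 2)
  expect_equal(r2$pixel_size, 0.063)
})

test_that("2-D and single-channel TIFFs get degenerate axes", {
  m <- matrix(sample.int(256L, 64, replace = TRUE) - 1L, 8, 8)
  tf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(m / 255, tf, bits.per.sample = 8L, reduce = FALSE)
  s <- read_stack(tf, list(foci = 1))
  expect_equal(dim(s$pixels), c(1L, 1L, 8L, 8L))
  expect_identical(s$pixels[1, 1, , ], m)
})

test_that("read_stack errors on missing or page-mismatched files", {
  expect_error(read_stack("no-such-file.tif", list(foci = 1)),
               "does not exist")
  tf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0, 4, 4), matrix(0, 4, 4), matrix(0, 4, 4)),
                  tf, reduce = FALSE)
  expect_error(read_stack(tf, list(foci = 1, mito = 2)), "not divisible")
  bad <- withr::local_tempfile(fileext = ".tif")
  writeLines("this is not a tiff", bad)
  expect_error(read_stack(bad, list(foci = 1)), "unreadable")
})

test_that("max projection matches an elementwise loop oracle", {
  s <- random_stack(21, c = 1L, z = 4L, h = 8L, w = 8L,
                    roles = list(foci = 1))
  p <- max_project(s, "foci")
  want <- matrix(0L, 8, 8)
  for (y in 1:8) for (x in 1:8) want[y, x] <- max(s$pixels[1, , y, x])
  expect_identical(p$pixels, want)
})

test_that("projection handles z = 1, mean rounding, and bad arguments", {
  s <- random_stack(31, c = 1L, z = 1L, roles = list(foci = 1))
  expect_identical(max_project(s, "foci")$pixels, s$pixels[1, 1, , ])
  # mean of 3 and 8 is 5.5 -> rounds half up to 6
  px <- array(c(3L, 8L), c(1, 2, 1, 1))
  s2 <- image_stack(px, list(foci = 1))
  expect_equal(as.integer(max_project(s2, "foci", "mean")$pixels), 6L)
  expect_equal(as.integer(max_project(s2, "foci", "max")$pixels), 8L)
  expect_error(max_project(s, "mito"), "not present")
  expect_error(max_project(s, "foci", "median"), "arg")
})

test_that("max projection is invariant to z-slice permutation", {
  s <- random_stack(41, c = 1L, z = 5L, roles = list(foci = 1))
  perm <- s
  perm$pixels <- s$pixels[, c(3, 5, 1, 4, 2), , , drop = FALSE]
  expect_identical(max_project(s, "foci")$pixels,
                   max_project(perm, "foci")$pixels)
})

test_that("cell CSV round-trips field-for-field", {
  rec <- data.frame(
    cell_id = c("a", "a", "b"), source_image = "img.tif",
    experiment_id = c("e1", "e1", "e2"), prominence = c(5L, 83L, 83L),
    n_foci_raw = c(400L, 310L, 123L), n_foci_filtered = c(350L, 300L, 120L),
    mito_area_um2 = c(213.17, 213.17, 99.123456789012345),
    density_per_um2 = c(350 / 213.17, 300 / 213.17, 120 / 99.123456789012345),
    pixel_size_um = 0.1, stringsAsFactors = FALSE)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_cell_csv(rec, tf)
  back <- read_cell_csv(tf)
  expect_identical(back, rec)
  expect_error(write_cell_csv(rec[0, ], tf), "non-empty")
  expect_error(write_cell_csv(data.frame(x = 1), tf), "lack column")
  writeLines("cell,count\nx,1", tf)
  expect_error(read_cell_csv(tf), "malformed")
})

test_that("binary mask TIFF round-trips exactly and rejects non-binary", {
  checker <- binary_mask(outer(1:9, 1:7, function(a, b) (a + b) %% 2 == 0),
                         kind = "mito", pixel_size = 0.1)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_binary_mask(checker, tf)
  back <- read_binary_mask(tf, kind = "mito", pixel_size = 0.1)
  expect_identical(back$pixels, checker$pixels)
  allf <- binary_mask(matrix(FALSE, 4, 4))
  write_binary_mask(allf, tf)
  expect_equal(sum(read_binary_mask(tf)$pixels), 0L)
  tiff::writeTIFF(matrix(0.5, 4, 4), tf, bits.per.sample = 8L)
  expect_error(read_binary_mask(tf), "not a binary mask.*127")
})
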