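test_that("polygon_roi validates vertex count and simplicity", {
  expect_error(polygon_roi(rbind(c(0, 0), c(1, 1)), "a"), ">= 3")
  bowtie <- rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 4))
  expect_error(polygon_roi(bowtie, "bt"), "self-intersect")
  tri <- polygon_roi(rbind(c(0, 0), c(4, 0), c(0, 4)), "t")
  expect_s3_class(tri, "polygon_roi")
})

test_that("JSON ROI files round-trip vertex lists exactly", {
  set.seed(5)
  rois <- lapply(1:5, function(i) {
    k <- sample(3:8, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    r <- runif(k, 5, 20)
    polygon_roi(cbind(30 + r * cos(ang), 30 + r * sin(ang)),
                label = sprintf("cell%02d", i))
  })
  tf <- withr::local_tempfile(fileext = ".json")
  write_rois_json(rois, tf)
  back <- read_rois(tf)
  expect_length(back, 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$label, rois[[i]]$label)
    expect_equal(back[[i]]$vertices, rois[[i]]$vertices)
  }
})

test_that("single JSON object yields one ROI", {
  tf <- withr::local_tempfile(fileext = ".json")
  writeLines('{"label":"tri","vertices":[[0,0],[10,0],[0,10]]}', tf)
  rois <- read_rois(tf)
  expect_length(rois, 1)
  expect_equal(nrow(rois[[1]]$vertices), 3)
  expect_equal(rois[[1]]$label, "tri")
})

test_that("ImageJ .roi files read back what the encoder wrote", {
  roi <- polygon_roi(rbind(c(12, 5), c(40, 8), c(35, 30), c(10, 22)), "c1")
  tf <- withr::local_tempfile(fileext = ".roi")
  focicount:::write_imagej_roi(roi, tf)
  back <- read_rois(tf)
  expect_length(back, 1)
  expect_equal(unname(back[[1]]$vertices), unname(roi$vertices))
})

test_that("zips of .roi files load with labels from entry names", {
  dir <- withr::local_tempdir()
  paths <- character(4)
  for (i in 1:4) {
    roi <- polygon_roi(rbind(c(0, 0), c(10 + i, 0), c(0, 10 + i)),
                       sprintf("cell%d", i))
    paths[i] <- file.path(dir, sprintf("cell%d.roi", i))
    focicount:::write_imagej_roi(roi, paths[i])
  }
  zf <- file.path(dir, "rois.zip")
  zip::zip(zf, basename(paths), root = dir)
  rois <- read_rois(zf)
  expect_length(rois, 4)
  expect_equal(sort(vapply(rois, function(r) r$label, "")),
               paste0("cell", 1:4))
})

test_that("non-polygon ImageJ ROI types are rejected by name", {
  roi <- polygon_roi(rbind(c(0, 0), c(10, 0), c(0, 10)), "p")
  tf <- withr::local_tempfile(fileext = ".roi")
  focicount:::write_imagej_roi(roi, tf)
  raw <- readBin(tf, "raw", file.size(tf))
  raw[7] <- as.raw(10) # point ROI
  writeBin(raw, tf)
  expect_error(read_rois(tf), "point")
  raw[7] <- as.raw(3) # line ROI
  writeBin(raw, tf)
  expect_error(read_rois(tf), "line")
})

test_that("rasterization counts pixel centres inside the polygon", {
  rect <- polygon_roi(rbind(c(0, 0), c(10, 0), c(10, 6), c(0, 6)), "r")
  m <- rasterize_roi(rect, 20, 20)
  expect_equal(sum(m$pixels), 60L) # centres 0.5..9.5 x 0.5..5.5
  expect_true(all(m$pixels[1:6, 1:10]))
  # polygon covering the whole image
  all_roi <- polygon_roi(rbind(c(-1, -1), c(21, -1), c(21, 21), c(-1, 21)))
  expect_true(all(rasterize_roi(all_roi, 20, 20)$pixels))
  # determinism
  m2 <- rasterize_roi(rect, 20, 20)
  expect_identical(m$pixels, m2$pixels)
  # degenerate polygon
  line <- polygon_roi(rbind(c(0, 0), c(5, 5), c(10, 10)))
  expect_error(rasterize_roi(line, 20, 20), "degenerate")
})

test_that("pixel centres exactly on edges are foreground", {
  # diamond through pixel centres (0.5, 3.5) .. (3.5, 0.5) etc.
  d <- polygon_roi(rbind(c(0.5, 3.5), c(3.5, 0.5), c(6.5, 3.5), c(3.5, 6.5)))
  m <- rasterize_roi(d, 8, 8)
  expect_true(m$pixels[4, 1]) # centre (0.5, 3.5) is a vertex
  expect_true(m$pixels[1, 4])
  expect_true(m$pixels[2, 3]) # centre (2.5, 1.5) lies on the edge
})

test_that("rasterized area approaches the shoelace area at fine resolution", {
  set.seed(8)
  ang <- sort(runif(12, 0, 2 * pi))
  r <- runif(12, 8, 14)
  v <- cbind(16 + r * cos(ang), 16 + r * sin(ang))
  roi <- polygon_roi(v)
  true_a <- abs(focicount:::shoelace_area(v))
  # 10x supersampling: scale the polygon up, count pixels, scale back
  roi10 <- polygon_roi(v * 10)
  n10 <- sum(rasterize_roi(roi10, 320, 320)$pixels)
  expect_lt(abs(n10 / 100 - true_a) / true_a, 0.02)
})

test_that("mask area is pixel count times squared pixel size", {
  m <- binary_mask(matrix(rep(c(TRUE, FALSE), 50), 10, 10), "mito",
                   pixel_size = 0.1)
  expect_equal(mask_area(m), 50 * 0.01)
  one <- binary_mask(matrix(c(TRUE, rep(FALSE, 99)), 10, 10), "mito",
                     pixel_size = 0.063)
  expect_equal(mask_area(one), 0.003969)
  empty <- binary_mask(matrix(FALSE, 5, 5), "mito", pixel_size = 0.1)
  expect_equal(mask_area(empty), 0)
  expect_error(mask_area(binary_mask(matrix(TRUE, 2, 2), "mito")),
               "pixel size")
  # additivity over disjoint masks and pixel_size^2 scaling
  a <- matrix(FALSE, 10, 10); a[1:3, ] <- TRUE
  b <- matrix(FALSE, 10, 10); b[7:9, ] <- TRUE
  s <- mask_area(binary_mask(a, "mito", pixel_size = 0.2)) +
    mask_area(binary_mask(b, "mito", pixel_size = 0.2))
  expect_equal(mask_area(binary_mask(a | b, "mito", pixel_size = 0.2)), s)
  expect_equal(mask_area(binary_mask(a, "mito", pixel_size = 0.4)),
               4 * mask_area(binary_mask(a, "mito", pixel_size = 0.2)))
})
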