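test_that("worked 1-D example: prominence separates the two peaks", {
  img <- matrix(c(0L, 80L, 70L, 100L, 0L), nrow = 1)
  # drop from the 80-peak to the saddle (70) towards the 100-peak is 10:
  # prominence 9 keeps both, 10 rejects it (drop <= prominence), 15 too
  m9 <- find_maxima(img, 9)
  expect_equal(m9$x, c(3L, 1L))
  expect_equal(m9$value, c(100L, 80L))
  expect_equal(find_maxima(img, 10)$x, 3L)
  expect_equal(find_maxima(img, 15)$x, 3L)
})

test_that("flat and single-peak images behave as contracted", {
  expect_equal(nrow(find_maxima(matrix(0L, 10, 10), 10)), 0L)
  expect_equal(nrow(find_maxima(matrix(7L, 4, 6), 1)), 0L)
  img <- matrix(0L, 10, 10)
  img[6, 6] <- 100L
  m <- find_maxima(img, 50)
  expect_equal(m$x, 5L)
  expect_equal(m$y, 5L)
  expect_equal(m$value, 100L)
})

test_that("input validation rejects bad images and parameters", {
  img <- matrix(0L, 5, 5)
  expect_error(find_maxima(1:10, 5), "2-D")
  expect_error(find_maxima(img, 0), "> 0")
  expect_error(find_maxima(img, -3), "> 0")
  expect_error(find_maxima(matrix(c(0.5, 1, 2, 3), 2, 2), 1), "integer")
  expect_error(find_maxima(img, 5, connectivity = 6), "4 or 8")
})

test_that("plateau maxima report the rounded centroid, half-ties down", {
  img <- matrix(0L, 7, 9)
  img[3, 4:5] <- 50L # 2-pixel plateau, centroid x = 3.5 (0-based) -> 3
  m <- find_maxima(img, 10)
  expect_equal(nrow(m), 1L)
  expect_equal(m$x, 3L)
  expect_equal(m$y, 2L)
  img2 <- matrix(0L, 7, 9)
  img2[3:5, 4] <- 50L # vertical 3-pixel plateau, centroid exact
  m2 <- find_maxima(img2, 10)
  expect_equal(m2$x, 3L)
  expect_equal(m2$y, 3L)
})

test_that("equal maxima within tolerance merge to the first in row-major order", {
  img <- matrix(0L, 5, 9)
  img[3, 2] <- 90L
  img[3, 8] <- 90L
  img[3, 3:7] <- 85L # shallow saddle between two equal peaks
  m <- find_maxima(img, 20) # drop 5 <= 20: within tolerance, merged
  expect_equal(nrow(m), 1L)
  expect_equal(m$x, 1L) # row-major first plateau survives
  m2 <- find_maxima(img, 4) # drop 5 > 4: both survive
  expect_equal(nrow(m2), 2L)
})

test_that("detector agrees with the flood oracle on random small images", {
  n_trials <- 60
  for (trial in seq_len(n_trials)) {
    set.seed(trial)
    img <- matrix(sample.int(16L, 144, replace = TRUE) - 1L, 12, 12)
    for (p in c(1, 3, 5)) {
      for (conn in c(8, 4)) {
        got <- find_maxima(img, p, connectivity = conn)
        want <- oracle_find_maxima(img, p, connectivity = conn)
        expect_equal(got$x, want$x,
                     info = sprintf("trial %d, p %g, conn %d", trial, p, conn))
        expect_equal(got$y, want$y)
        expect_equal(got$value, want$value)
      }
    }
  }
})

test_that("count monotonicity, shift invariance and scale covariance hold", {
  set.seed(99)
  for (trial in 1:10) {
    img <- matrix(sample.int(200L, 400, replace = TRUE), 20, 20)
    counts <- vapply(c(1, 5, 20, 60, 150),
                     function(p) nrow(find_maxima(img, p)), numeric(1))
    expect_true(all(diff(counts) <= 0))
    # adding a constant changes nothing
    m1 <- find_maxima(img, 17)
    m2 <- find_maxima(img + 1000L, 17)
    expect_equal(m1$x, m2$x)
    expect_equal(m1$y, m2$y)
    expect_equal(m2$value, m1$value + 1000L)
    # integer scaling of image and prominence together changes nothing
    m3 <- find_maxima(img * 3L, 51)
    expect_equal(m1$x, m3$x)
    expect_equal(m1$y, m3$y)
  }
})

test_that("transpose equivariance: maxima transpose with the image", {
  set.seed(7)
  img <- matrix(sample.int(100L, 300, replace = TRUE), 15, 20)
  a <- find_maxima(img, 10)
  b <- find_maxima(t(img), 10)
  # same maxima as (x,y) sets with coordinates swapped
  key_a <- sort(paste(a$x, a$y, a$value))
  key_b <- sort(paste(b$y, b$x, b$value))
  expect_equal(key_a, key_b)
})

test_that("edge-maxima exclusion drops only border plateaus", {
  img <- matrix(0L, 9, 9)
  img[1, 5] <- 80L # on the border
  img[5, 5] <- 90L
  expect_equal(nrow(find_maxima(img, 10)), 2L)
  m <- find_maxima(img, 10, exclude_edge_maxima = TRUE)
  expect_equal(nrow(m), 1L)
  expect_equal(m$value, 90L)
})

test_that("make_sweep produces evenly spaced integer prominences", {
  expect_identical(make_sweep(5, 200, 6), c(5L, 44L, 83L, 122L, 161L, 200L))
  expect_identical(make_sweep(10, 20, 2), c(10L, 20L))
  expect_identical(make_sweep(1, 100, 4), c(1L, 34L, 67L, 100L))
  expect_error(make_sweep(0, 10, 3), "min_prominence")
  expect_error(make_sweep(10, 5, 3), "min_prominence")
  expect_error(make_sweep(5, 200, 1), ">= 2")
  expect_error(make_sweep(1, 3, 6), "collapse")
})

test_that("sweep_counts counts raw maxima and persists foci images", {
  expect_equal(sweep_counts(matrix(0L, 8, 8), c(10, 50))$counts, c(0L, 0L))
  # two peaks whose drops differ: the global maximum always survives (no
  # higher ground exists to flood to), the minor one falls out of the sweep
  img <- matrix(0L, 12, 12)
  img[6, 6] <- 200L
  img[3, 3] <- 100L
  sw <- sweep_counts(img, c(50, 150), cell_id = "c1")
  expect_equal(sw$counts, c(2L, 1L))
  expect_error(sweep_counts(img, c(50, 50)), "increasing")
  dir <- withr::local_tempdir()
  sweep_counts(img, c(50, 150), output_dir = dir)
  m <- read_binary_mask(file.path(dir, "foci_p50.tif"))
  expect_equal(sum(m$pixels), 2L)
  expect_true(m$pixels[6, 6])
  expect_equal(sum(read_binary_mask(file.path(dir, "foci_p150.tif"))$pixels), 1L)
})
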