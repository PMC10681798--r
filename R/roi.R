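#' Polygonal cell region of interest
#'
#' A simple (non-self-intersecting) polygon outlining one cell, with 0-based
#' pixel coordinates: `x` is the column, `y` the row, and the point `(0, 0)`
#' is the top-left corner of the top-left pixel.
#'
#' @param vertices numeric matrix or two-column structure of `(x, y)`
#'   vertices, at least three.
#' @param label cell identifier, unique within an image.
#' @return An object of class `polygon_roi`.
#' @export
polygon_roi <- function(vertices, label = "cell") {
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3)
    stop_f("a polygon ROI needs >= 3 (x, y) vertices")
  if (anyNA(v) || !is.numeric(v)) stop_f("ROI vertices must be numeric")
  if (polygon_self_intersects(v))
    stop_f("ROI '%s' is not a simple polygon (edges self-intersect)", label)
  colnames(v) <- c("x", "y")
  structure(list(vertices = v, label = as.character(label)),
            class = "polygon_roi")
}

#' @export
print.polygon_roi <- function(x, ...) {
  cat(sprintf("<polygon_roi> '%s', %d vertices, area %.1f px^2\n",
              x$label, nrow(x$vertices), abs(shoelace_area(x$vertices))))
  invisible(x)
}

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# proper-crossing test for all non-adjacent edge pairs; shared endpoints of
# consecutive edges are allowed
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

#' Read cell ROIs from ImageJ or JSON files
#'
#' Supports single ImageJ `.roi` files (polygon, freehand and traced
#' subtypes), `.zip` archives of `.roi` files, and a JSON schema
#' `{"label": str, "vertices": [[x, y], ...]}` (one object or an array of
#' objects). ImageJ stores polygon vertices as 0-based pixel coordinates,
#' which is also this package's convention, so values pass through
#' unchanged. Labels come from JSON keys or from file names.
#'
#' @param path `.roi`, `.zip` or `.json` file.
#' @return A list of [polygon_roi()] objects.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop_f("ROI file '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    roi = list(read_imagej_roi(path)),
    zip = {
      exdir <- tempfile("rois")
      dir.create(exdir)
      on.exit(unlink(exdir, recursive = TRUE))
      files <- unzip(path, exdir = exdir)
      files <- sort(files[tolower(tools::file_ext(files)) == "roi"])
      if (length(files) == 0) stop_f("'%s' contains no .roi entries", path)
      lapply(files, read_imagej_roi)
    },
    json = read_rois_json(path),
    stop_f("unsupported ROI format '.%s' (use .roi, .zip or .json)", ext)
  )
}

imagej_roi_types <- c("polygon", "rect", "oval", "line", "freeline",
                      "polyline", "noRoi", "freehand", "traced", "angle",
                      "point")

read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop_f("'%s' is not an ImageJ ROI file", path)
  be_i16 <- function(off, n = 1L) # 1-based byte offset
    readBin(raw[off:(off + 2L * n - 1L)], "integer", n = n, size = 2L,
            signed = TRUE, endian = "big")
  type <- as.integer(raw[7])
  tname <- if (type + 1L <= length(imagej_roi_types))
    imagej_roi_types[type + 1L] else sprintf("type %d", type)
  if (!tname %in% c("polygon", "freehand", "traced"))
    stop_f("'%s' holds a '%s' ROI; only polygon ROIs are supported",
           path, tname)
  top <- be_i16(9); left <- be_i16(11)
  n <- be_i16(17)
  if (n < 3) stop_f("'%s': polygon with %d vertices", path, n)
  xs <- be_i16(65, n)
  ys <- be_i16(65 + 2 * n, n)
  polygon_roi(cbind(left + xs, top + ys),
              label = tools::file_path_sans_ext(basename(path)))
}

read_rois_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(obj$label)) obj <- list(obj)
  rois <- lapply(obj, function(o) {
    v <- do.call(rbind, lapply(o$vertices, unlist))
    polygon_roi(v, label = o$label)
  })
  labs <- vapply(rois, function(r) r$label, character(1))
  if (anyDuplicated(labs)) stop_f("duplicate ROI labels in '%s'", path)
  rois
}

#' Write ROIs as a JSON file
#'
#' Inverse of the JSON branch of [read_rois()].
#'
#' @param rois list of [polygon_roi()] objects.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_rois_json <- function(rois, path) {
  if (inherits(rois, "polygon_roi")) rois <- list(rois)
  obj <- lapply(rois, function(r)
    list(label = r$label,
         vertices = lapply(seq_len(nrow(r$vertices)),
                           function(i) as.numeric(r$vertices[i, ]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# minimal ImageJ .roi encoder (polygon subtype); integer coordinates only.
# Used to build read_rois fixtures and to export ROIs for ImageJ inspection.
write_imagej_roi <- function(roi, path) {
  v <- round(roi$vertices)
  left <- min(v[, 1]); top <- min(v[, 2])
  right <- max(v[, 1]); bottom <- max(v[, 2])
  n <- nrow(v)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  writeBin(c(227L, 0L), con, size = 2L, endian = "big") # version, type=polygon
  writeBin(as.integer(c(top, left, bottom, right, n)), con, size = 2L,
           endian = "big")
  writeBin(raw(64 - 18), con)
  writeBin(as.integer(v[, 1] - left), con, size = 2L, endian = "big")
  writeBin(as.integer(v[, 2] - top), con, size = 2L, endian = "big")
  invisible(path)
}

#' Rasterize a polygon ROI to a binary cell mask
#'
#' A pixel `(x, y)` belongs to the mask iff its centre `(x + 0.5, y + 0.5)`
#' lies inside the polygon under the even-odd rule; centres exactly on a
#' polygon edge count as foreground. This single documented convention makes
#' rasterization deterministic and resolution-consistent (the mask area
#' converges to the polygon's shoelace area as the pixel size shrinks).
#'
#' @param roi a [polygon_roi()].
#' @param height,width mask dimensions in pixels.
#' @param pixel_size pixel size in um/px carried into the mask, for area
#'   measurement.
#' @return A [binary_mask()] of kind `"cell"`.
#' @export
rasterize_roi <- function(roi, height, width, pixel_size = NA_real_) {
  stopifnot(inherits(roi, "polygon_roi"))
  v <- roi$vertices
  if (abs(shoelace_area(v)) < 1e-12)
    stop_f("ROI '%s' is degenerate (zero area)", roi$label)
  cx <- rep(seq_len(width) - 0.5, each = height)   # centre x, column-major
  cy <- rep(seq_len(height) - 0.5, times = width)  # centre y
  n <- nrow(v)
  jj <- c(2:n, 1L)
  crossings <- integer(length(cx))
  on_edge <- logical(length(cx))
  eps <- 1e-9
  for (i in seq_len(n)) {
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[jj[i], 1]; y2 <- v[jj[i], 2]
    # even-odd ray casting, half-open in y to count shared vertices once
    hit <- ((y1 > cy) != (y2 > cy)) &
      (cx < (x2 - x1) * (cy - y1) / (y2 - y1) + x1)
    crossings <- crossings + hit
    # centre exactly on the closed segment
    crossp <- (x2 - x1) * (cy - y1) - (y2 - y1) * (cx - x1)
    seglen2 <- (x2 - x1)^2 + (y2 - y1)^2
    dotp <- (cx - x1) * (x2 - x1) + (cy - y1) * (y2 - y1)
    on_edge <- on_edge |
      (abs(crossp) <= eps * max(1, sqrt(seglen2)) &
         dotp >= -eps & dotp <= seglen2 + eps)
  }
  m <- matrix(crossings %% 2L == 1L | on_edge, nrow = height, ncol = width)
  binary_mask(m, kind = "cell", pixel_size = pixel_size)
}
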