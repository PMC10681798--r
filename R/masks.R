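#' Binary image mask
#'
#' 2-D boolean image used as inclusion (mitochondria), exclusion (nucleus)
#' or cell-extent mask.
#'
#' @param pixels logical matrix (y, x).
#' @param kind one of `"cell"`, `"mito"`, `"nucleus"`.
#' @param pixel_size um/px, needed for [mask_area()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, kind = c("cell", "mito", "nucleus"),
                        pixel_size = NA_real_) {
  kind <- match.arg(kind)
  m <- as.matrix(pixels)
  if (!is.logical(m)) {
    if (!all(m %in% c(0, 1))) stop_f("mask pixels must be logical or 0/1")
    m <- m == 1
  }
  structure(list(pixels = m, kind = kind, pixel_size = as.numeric(pixel_size)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> kind '%s', %d x %d px, %d foreground\n",
              x$kind, nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Segmentation parameters
#'
#' The segmentation recipe applied inside a cell ROI: smoothing, automatic
#' or fixed thresholding, small-object removal and morphological
#' post-processing. The threshold is always computed from intensities
#' inside the cell mask only, because expression levels (and hence
#' intensity scales) differ between individual cells.
#'
#' Defaults follow two standard recipes:
#' * [mito_params()]: median filter radius 1 px, Otsu threshold, drop
#'   objects smaller than 4 px, closing radius 1 px — suited to thin
#'   curvilinear mitochondrial networks.
#' * [nucleus_params()]: Gaussian blur sigma 2 px, Otsu threshold, fill
#'   holes, keep the largest component — suited to one dominant DNA-stain
#'   blob per cell.
#'
#' @param smooth_method `"median"`, `"gaussian"` or `"none"`.
#' @param smooth_radius median filter radius (px) or Gaussian sigma (px).
#' @param threshold_method `"otsu"`, `"li"`, `"triangle"` or `"fixed"`.
#' @param threshold_value threshold in au, used when
#'   `threshold_method = "fixed"` (foreground is `intensity >= value`).
#' @param min_object_px remove connected components smaller than this.
#' @param closing_radius morphological closing radius in px (0 = none).
#' @param fill_holes fill enclosed background holes.
#' @param keep_largest keep only the largest connected component.
#' @return A `seg_params` list.
#' @export
seg_params <- function(smooth_method = c("median", "gaussian", "none"),
                       smooth_radius = 1, threshold_method = c("otsu", "li",
                       "triangle", "fixed"), threshold_value = NA_real_,
                       min_object_px = 0L, closing_radius = 0L,
                       fill_holes = FALSE, keep_largest = FALSE) {
  smooth_method <- match.arg(smooth_method)
  threshold_method <- match.arg(threshold_method)
  if (smooth_radius < 0) stop_f("'smooth_radius' must be >= 0")
  if (min_object_px < 0) stop_f("'min_object_px' must be >= 0")
  if (threshold_method == "fixed" && !is.finite(threshold_value))
    stop_f("fixed thresholding needs a finite 'threshold_value'")
  structure(list(smooth_method = smooth_method,
                 smooth_radius = smooth_radius,
                 threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_object_px = as.integer(min_object_px),
                 closing_radius = as.integer(closing_radius),
                 fill_holes = isTRUE(fill_holes),
                 keep_largest = isTRUE(keep_largest)),
            class = "seg_params")
}

#' @rdname seg_params
#' @param ... overrides passed to [seg_params()].
#' @export
mito_params <- function(...) {
  args <- list(smooth_method = "median", smooth_radius = 1,
               threshold_method = "otsu", min_object_px = 4L,
               closing_radius = 1L)
  do.call(seg_params, utils::modifyList(args, list(...)))
}

#' @rdname seg_params
#' @export
nucleus_params <- function(...) {
  args <- list(smooth_method = "gaussian", smooth_radius = 2,
               threshold_method = "otsu", fill_holes = TRUE,
               keep_largest = TRUE)
  do.call(seg_params, utils::modifyList(args, list(...)))
}

smooth_pixels <- function(px, params) {
  if (params$smooth_method == "none" || params$smooth_radius == 0)
    return(px)
  if (params$smooth_method == "median") {
    # EBImage's constant-time median filter works on [0, 1] data; rescaling
    # by the 16-bit maximum keeps integer intensities exact
    sm <- EBImage::medianFilter(px / 65535, size = params$smooth_radius)
    round_half_up(sm * 65535)
  } else {
    round_half_up(EBImage::gblur(px * 1.0, sigma = params$smooth_radius))
  }
}

compute_threshold <- function(vals, params) {
  switch(params$threshold_method,
    fixed = params$threshold_value,
    otsu = {
      rng <- range(vals)
      lv <- min(rng[2] - rng[1] + 1, 4096)
      EBImage::otsu(matrix(vals, nrow = 1), range = rng, levels = lv)
    },
    li = threshold_li(vals),
    triangle = threshold_triangle(vals)
  )
}

# Li's iterative minimum cross-entropy threshold (no installed package
# exposes it on raw samples, so the 10-line fixpoint lives here)
threshold_li <- function(vals) {
  vals <- as.numeric(vals)
  t_old <- -Inf
  t_new <- mean(vals)
  eps <- 0.5
  while (abs(t_new - t_old) > eps) {
    t_old <- t_new
    lo <- vals[vals <= t_old]; hi <- vals[vals > t_old]
    if (!length(lo) || !length(hi)) break
    m0 <- mean(lo); m1 <- mean(hi)
    if (m0 <= 0) m0 <- .Machine$double.eps
    t_new <- (m1 - m0) / (log(m1) - log(m0))
  }
  t_new
}

# triangle threshold on a 256-bin histogram of the sample range
threshold_triangle <- function(vals) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rng[1])
  nb <- min(256L, diff(rng) + 1)
  brks <- seq(rng[1], rng[2], length.out = nb + 1)
  bin <- pmin(nb, pmax(1L, findInterval(vals, brks, rightmost.closed = TRUE)))
  h <- tabulate(bin, nbins = nb)
  pk <- which.max(h)
  # walk towards the longer tail
  right <- (nb - pk) >= (pk - 1)
  idx <- if (right) pk:nb else pk:1
  hh <- h[idx]
  x <- seq_along(hh) - 1
  # distance from the line joining the peak to the histogram end
  x2 <- length(hh) - 1
  y2 <- hh[length(hh)]
  d <- abs((y2 - hh[1]) * x - x2 * (hh - hh[1])) / sqrt((y2 - hh[1])^2 + x2^2)
  split <- idx[which.max(d)]
  mids <- (brks[-1] + brks[-length(brks)]) / 2
  mids[split]
}

# shared machinery: smooth -> threshold inside cell mask -> morphology
segment_channel <- function(image, cell_mask, params, kind) {
  stopifnot(inherits(image, "projected_image"),
            inherits(cell_mask, "binary_mask"))
  px <- image$pixels
  cm <- cell_mask$pixels
  if (!identical(dim(px), dim(cm)))
    stop_f("image (%s) and cell mask (%s) differ in shape",
           paste(dim(px), collapse = "x"), paste(dim(cm), collapse = "x"))
  if (!any(cm)) stop_f("empty cell mask")
  sm <- smooth_pixels(px, params)
  vals <- sm[cm]
  if (length(unique(vals)) == 1L && params$threshold_method != "fixed") {
    warn_f("all intensities inside the cell mask are equal; %s mask is empty",
           kind)
    return(binary_mask(matrix(FALSE, nrow(px), ncol(px)), kind = kind,
                       pixel_size = image$pixel_size))
  }
  thr <- compute_threshold(vals, params)
  fg <- if (params$threshold_method == "fixed") sm >= thr else sm > thr
  fg <- fg & cm
  if (params$min_object_px > 0 && any(fg)) {
    lab <- EBImage::bwlabel(fg)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_object_px)
    fg <- matrix(lab %in% keep, nrow(fg), ncol(fg))
  }
  if (params$closing_radius > 0 && any(fg)) {
    brush <- EBImage::makeBrush(2L * params$closing_radius + 1L, "disc")
    fg <- EBImage::closing(fg, brush) > 0
  }
  if (params$fill_holes && any(fg))
    fg <- EBImage::fillHull(fg) > 0
  if (params$keep_largest && any(fg)) {
    lab <- EBImage::bwlabel(fg)
    sizes <- tabulate(lab[lab > 0])
    fg <- lab == which.max(sizes)
  }
  fg <- fg & cm # masks are subsets of the cell mask, always
  if (!any(fg)) warn_f("%s segmentation produced an empty mask", kind)
  binary_mask(fg, kind = kind, pixel_size = image$pixel_size)
}

#' Segment the mitochondrial network inside a cell
#'
#' Builds the mitochondrial inclusion mask from the projected mitochondria
#' channel: smoothing, a threshold computed from intensities inside the
#' cell mask only, small-object removal and closing; the result is
#' intersected with the cell mask. Externally pre-segmented masks can be
#' passed to the pipeline directly instead (see [quantify_cell()]).
#'
#' @param image a `projected_image` of the mitochondria channel.
#' @param cell_mask the rasterized cell ROI.
#' @param params a [seg_params()] recipe; defaults to [mito_params()].
#' @return A [binary_mask()] of kind `"mito"`.
#' @export
segment_mitochondria <- function(image, cell_mask, params = mito_params()) {
  segment_channel(image, cell_mask, params, kind = "mito")
}

#' Segment the nucleus inside a cell
#'
#' As [segment_mitochondria()], with hole filling and retention of the
#' largest component (one dominant DNA-stain blob per cell). When `roi` is
#' supplied, the manual-segmentation path is taken and the function simply
#' rasterizes the polygon, clipped to the cell mask.
#'
#' @inheritParams segment_mitochondria
#' @param params a [seg_params()] recipe; defaults to [nucleus_params()].
#' @param roi optional [polygon_roi()] of a manually outlined nucleus.
#' @return A [binary_mask()] of kind `"nucleus"`.
#' @export
segment_nucleus <- function(image, cell_mask, params = nucleus_params(),
                            roi = NULL) {
  if (!is.null(roi)) {
    m <- rasterize_roi(roi, nrow(cell_mask$pixels), ncol(cell_mask$pixels),
                       pixel_size = cell_mask$pixel_size)
    return(binary_mask(m$pixels & cell_mask$pixels, kind = "nucleus",
                       pixel_size = cell_mask$pixel_size))
  }
  segment_channel(image, cell_mask, params, kind = "nucleus")
}

#' Measure the area of a binary mask
#'
#' Foreground pixel count times the squared pixel size, in um^2. This is
#' the "mitochondrial area" reported per cell when applied to the
#' inclusion mask.
#'
#' @param mask a [binary_mask()] with a positive `pixel_size`.
#' @return Area in square micrometres.
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is.na(mask$pixel_size) || mask$pixel_size <= 0)
    stop_f("mask has no valid pixel size; supply one to measure area")
  sum(mask$pixels) * mask$pixel_size^2
}
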