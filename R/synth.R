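#' Specification of a synthetic cell image
#'
#' Parameters of the ground-truth generator. A synthetic cell emulates the
#' package's target imagery: a curvilinear mitochondrial network rendered as
#' momentum random-walk curves dilated to a few pixels width, an elliptical
#' nucleus overlapping part of the network, and diffraction-limited
#' Gaussian foci planted on the network at known positions, over a constant
#' background with Gaussian camera noise (optional Poisson shot noise).
#' All structure is rendered before noise; pixels are quantised to 16-bit.
#'
#' Defaults model a confocal-like acquisition: 320 x 320 px at 0.1 um/px,
#' spot sigma 1.3 px, foci amplitudes 120-160 au over background 100 au with
#' noise sigma 5 au, so the standard prominence sweep 5..200 au brackets the
#' true-recovery regime around 83 au.
#'
#' @param width,height image size in px.
#' @param pixel_size um per pixel.
#' @param cell_vertices optional polygon for the cell outline; by default a
#'   random star-shaped blob filling most of the frame.
#' @param n_branches,branch_length,mito_width,curvature mitochondrial
#'   network: number of random-walk branches, steps per branch, dilation
#'   width (px) and angular diffusion per step (radians).
#' @param mito_intensity,nucleus_intensity rendered structure intensities
#'   (au) of the mitochondria and nucleus channels.
#' @param nucleus_axes ellipse semi-axes (px) of the nucleus.
#' @param n_foci number of true mitochondrial foci (outside the nucleus).
#' @param spot_sigma Gaussian spot sigma in px.
#' @param amplitude_range foci amplitude range (au) at the spot centre.
#' @param min_separation minimum centre-to-centre distance between any two
#'   planted foci (px).
#' @param fraction_spurious_outside_mito,fraction_in_nucleus fractions of
#'   `n_foci` planted as real image structure outside the mitochondrial
#'   mask, respectively on mitochondria inside the nucleus, to exercise the
#'   mask filters end-to-end.
#' @param background,noise_sd,poisson_noise foci-channel background offset
#'   (au), Gaussian noise sigma (au) and Poisson shot-noise flag.
#' @param structure_noise_sd noise sigma (au) of the mitochondria and
#'   nucleus channels.
#' @param seed default seed used by [generate_cell()].
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(width = 320, height = 320, pixel_size = 0.1,
                           cell_vertices = NULL,
                           n_branches = 24, branch_length = 340,
                           mito_width = 3, curvature = 0.15,
                           mito_intensity = 9000,
                           nucleus_axes = c(44, 32),
                           nucleus_intensity = 12000,
                           n_foci = 300, spot_sigma = 1.3,
                           amplitude_range = c(120, 160),
                           min_separation = 6,
                           fraction_spurious_outside_mito = 0,
                           fraction_in_nucleus = 0,
                           background = 100, noise_sd = 5,
                           poisson_noise = FALSE,
                           structure_noise_sd = 150, seed = 1) {
  if (any(amplitude_range <= 0)) stop_f("amplitudes must be > 0")
  if (min_separation < 1) stop_f("'min_separation' must be >= 1 px")
  if (pixel_size <= 0) stop_f("'pixel_size' must be > 0")
  if (n_foci < 0) stop_f("'n_foci' must be >= 0")
  structure(as.list(environment()), class = "synthetic_spec")
}

dilate_mask <- function(m, radius) {
  if (radius <= 0) return(m)
  EBImage::dilate(m, EBImage::makeBrush(2L * radius + 1L, "disc")) > 0
}

erode_mask <- function(m, radius) {
  if (radius <= 0) return(m)
  EBImage::erode(m, EBImage::makeBrush(2L * radius + 1L, "disc")) > 0
}

# random star-shaped cell outline filling most of the frame
random_cell_polygon <- function(w, h) {
  k <- 24
  ang <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  r0 <- 0.44 * min(w, h)
  rad <- r0 * runif(k, 0.82, 1.0)
  cx <- w / 2; cy <- h / 2
  x <- pmin(pmax(cx + rad * cos(ang), 2), w - 2)
  y <- pmin(pmax(cy + rad * sin(ang), 2), h - 2)
  polygon_roi(cbind(x, y), label = "cell")
}

# momentum random walks seeded partly at the nucleus centre so the network
# always overlaps the nucleus (needed for nucleus-subtraction testing)
render_skeleton <- function(spec, allowed, nuc_centre) {
  h <- nrow(allowed); w <- ncol(allowed)
  skel <- matrix(FALSE, h, w)
  starts_idx <- which(allowed)
  for (b in seq_len(spec$n_branches)) {
    if (b %% 3 == 1) {
      pos <- nuc_centre + runif(2, -3, 3)
    } else {
      s <- starts_idx[sample.int(length(starts_idx), 1)]
      pos <- c((s - 1) %% h + 1, (s - 1) %/% h + 1)[c(2, 1)] # (x, y)
    }
    theta <- runif(1, 0, 2 * pi)
    for (step in seq_len(spec$branch_length)) {
      theta <- theta + rnorm(1, 0, spec$curvature)
      nxt <- pos + c(cos(theta), sin(theta))
      xi <- round(nxt[1]); yi <- round(nxt[2])
      tries <- 0
      while ((xi < 1 || xi > w || yi < 1 || yi > h || !allowed[yi, xi]) &&
             tries < 8) {
        theta <- theta + pi / 2 + runif(1, -0.3, 0.3)
        nxt <- pos + c(cos(theta), sin(theta))
        xi <- round(nxt[1]); yi <- round(nxt[2])
        tries <- tries + 1
      }
      if (tries >= 8) break
      pos <- nxt
      skel[yi, xi] <- TRUE
    }
  }
  skel
}

ellipse_mask <- function(h, w, centre, axes, theta) {
  x <- matrix(rep(seq_len(w), each = h), h, w) - centre[1]
  y <- matrix(rep(seq_len(h), times = w), h, w) - centre[2]
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

# sequential adsorption: walk a random permutation of the eligible pixels
# and accept each one lying at least min_sep from everything accepted so
# far, until k spots are placed; errors when the permutation is exhausted
# (the region is jammed and cannot hold k spots at this separation)
place_spots <- function(eligible, k, min_sep, placed, what) {
  if (k == 0) return(placed)
  idx <- which(eligible)
  if (length(idx) == 0)
    stop_f("no eligible pixels to place %s foci", what)
  h <- nrow(eligible)
  perm <- idx[sample.int(length(idx))]
  xs <- (perm - 1) %/% h + 1
  ys <- (perm - 1) %% h + 1
  ax <- placed$x; ay <- placed$y
  kept_x <- integer(k); kept_y <- integer(k)
  added <- 0L
  for (i in seq_along(perm)) {
    px <- xs[i]; py <- ys[i]
    if (length(ax) && min((ax - px)^2 + (ay - py)^2) < min_sep^2) next
    added <- added + 1L
    kept_x[added] <- px; kept_y[added] <- py
    ax <- c(ax, px); ay <- c(ay, py)
    if (added == k) break
  }
  if (added < k)
    stop_f("infeasible placement: only %d of %d %s foci fit at separation %g px",
           added, k, what, min_sep)
  rbind(placed, data.frame(x = kept_x, y = kept_y, class = what))
}

render_spots <- function(h, w, spots, amplitudes, sigma) {
  img <- matrix(0, h, w)
  if (nrow(spots) == 0) return(img)
  r <- ceiling(4 * sigma)
  off <- seq(-r, r)
  kern_x <- outer(off, off, function(dy, dx) dx)
  kern_y <- outer(off, off, function(dy, dx) dy)
  for (i in seq_len(nrow(spots))) {
    cx <- spots$x[i]; cy <- spots$y[i]
    ys <- cy + off; xs <- cx + off
    sel_y <- ys >= 1 & ys <= h; sel_x <- xs >= 1 & xs <= w
    g <- amplitudes[i] *
      exp(-(kern_x[sel_y, sel_x]^2 + kern_y[sel_y, sel_x]^2) /
            (2 * sigma^2))
    img[ys[sel_y], xs[sel_x]] <- img[ys[sel_y], xs[sel_x]] + g
  }
  img
}

quantise16 <- function(x) {
  m <- pmax(0, pmin(65535, round_half_up(x)))
  storage.mode(m) <- "integer"
  m
}

#' Generate one synthetic cell with ground truth
#'
#' Renders the three channels described by a [synthetic_spec()] and returns
#' them with the exact ground truth: planted foci coordinates, amplitudes
#' and classes, the true cell/mitochondria/nucleus masks, per-class counts
#' and the true mitochondrial area. Fully deterministic for a given seed.
#'
#' True mitochondrial foci are planted on the network outside the nucleus;
#' optional spurious foci are planted as real image structure outside the
#' mitochondrial mask (margin 4 px) and on network inside the nucleus
#' (margin 2 px), so mask filtering can be verified end-to-end.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A `synthetic_cell`: list with `stack` ([image_stack()] with roles
#'   mito = 1, nucleus = 2, foci = 3), `cell_roi`, `masks` (true cell, mito,
#'   nucleus [binary_mask()]s), `foci` (data frame `x`, `y` 0-based,
#'   `amplitude`, `class`), `counts` (`total`, `in_mito`, `in_nucleus`,
#'   `spurious`), `mito_area_um2_true` and `pixel_size`.
#' @export
generate_cell <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    h <- spec$height; w <- spec$width
    roi <- if (is.null(spec$cell_vertices)) random_cell_polygon(w, h)
           else polygon_roi(spec$cell_vertices, "cell")
    cell <- rasterize_roi(roi, h, w, pixel_size = spec$pixel_size)
    cm <- cell$pixels

    # nucleus: ellipse near the cell centroid, kept inside the cell
    cyx <- which(cm, arr.ind = TRUE)
    centre <- c(mean(cyx[, 2]), mean(cyx[, 1])) + runif(2, -8, 8)
    nuc <- ellipse_mask(h, w, centre, spec$nucleus_axes,
                        runif(1, 0, pi)) & cm

    # mitochondrial network
    interior <- erode_mask(cm, spec$mito_width + 1L)
    skel <- render_skeleton(spec, interior, centre)
    mito <- dilate_mask(skel, (spec$mito_width - 1L) %/% 2L) & cm

    # foci placement
    n_spur <- round(spec$fraction_spurious_outside_mito * spec$n_foci)
    n_nuc <- round(spec$fraction_in_nucleus * spec$n_foci)
    nuc_safe <- dilate_mask(nuc, 2L)
    core <- erode_mask(mito, 1L)
    if (!any(core)) core <- mito
    elig_main <- core & !nuc_safe
    elig_nuc <- core & erode_mask(nuc, 2L)
    if (n_nuc > 0 && !any(elig_nuc)) elig_nuc <- erode_mask(nuc, 2L)
    elig_spur <- erode_mask(cm, 2L) & !dilate_mask(mito, 4L) & !nuc_safe

    placed <- data.frame(x = integer(), y = integer(), class = character())
    placed <- place_spots(elig_main, spec$n_foci, spec$min_separation,
                          placed, "mito")
    placed <- place_spots(elig_spur, n_spur, spec$min_separation, placed,
                          "spurious")
    placed <- place_spots(elig_nuc, n_nuc, spec$min_separation, placed,
                          "nucleus")
    amps <- runif(nrow(placed), spec$amplitude_range[1],
                  spec$amplitude_range[2])

    # rendering: structure first, then noise, then quantisation
    foci_ch <- spec$background +
      render_spots(h, w, placed, amps, spec$spot_sigma)
    mito_ch <- spec$background +
      EBImage::gblur((mito * 1.0) * spec$mito_intensity, sigma = 0.8)
    nuc_ch <- spec$background +
      EBImage::gblur((nuc * 1.0) * spec$nucleus_intensity, sigma = 1.5)
    if (spec$poisson_noise) {
      foci_ch <- rpois(length(foci_ch), pmax(foci_ch, 0))
      dim(foci_ch) <- c(h, w)
    }
    if (spec$noise_sd > 0)
      foci_ch <- foci_ch + rnorm(h * w, 0, spec$noise_sd)
    if (spec$structure_noise_sd > 0) {
      mito_ch <- mito_ch + rnorm(h * w, 0, spec$structure_noise_sd)
      nuc_ch <- nuc_ch + rnorm(h * w, 0, spec$structure_noise_sd)
    }

    px <- array(0L, c(3, 1, h, w))
    px[1, 1, , ] <- quantise16(mito_ch)
    px[2, 1, , ] <- quantise16(nuc_ch)
    px[3, 1, , ] <- quantise16(foci_ch)
    stack <- image_stack(px, list(mito = 1, nucleus = 2, foci = 3),
                         pixel_size = spec$pixel_size)

    mito_mask <- binary_mask(mito, "mito", spec$pixel_size)
    foci <- data.frame(x = placed$x - 1L, y = placed$y - 1L,
                       amplitude = amps, class = placed$class,
                       stringsAsFactors = FALSE)
    structure(list(
      stack = stack, cell_roi = roi,
      masks = list(cell = cell, mito = mito_mask,
                   nucleus = binary_mask(nuc, "nucleus", spec$pixel_size)),
      foci = foci,
      counts = list(total = nrow(foci), in_mito = spec$n_foci,
                    in_nucleus = n_nuc, spurious = n_spur),
      mito_area_um2_true = mask_area(mito_mask),
      pixel_size = spec$pixel_size, seed = seed),
      class = "synthetic_cell")
  })
}

#' @export
print.synthetic_cell <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cell> %d foci (%d mito / %d nucleus / %d spurious), mito area %.1f um^2\n",
    x$counts$total, x$counts$in_mito, x$counts$in_nucleus,
    x$counts$spurious, x$mito_area_um2_true))
  invisible(x)
}

#' Generate a synthetic dataset in the batch input layout
#'
#' Writes `n_cells` synthetic cells as multi-page TIFFs with sibling JSON
#' ROI files and per-cell truth JSONs, laid out as
#' `<experiment_id>/<cell>.tif` + `<cell>.rois.json` + `<cell>.truth.json`
#' so the directory can be fed straight to [run_batch()]. Per-cell true
#' foci counts are drawn from `count_distribution`; cells are assigned
#' round-robin to `n_experiments` experiment folders.
#'
#' The default count distribution is lognormal with median 299 and
#' log-scale sigma 0.49, matching the scale and skew of nucleoid counts in
#' cultured fibroblast populations (median about 300, interquartile range
#' about two thirds of the median).
#'
#' @param dir output directory (created if needed).
#' @param n_cells number of cells (>= 1).
#' @param spec base [synthetic_spec()]; the per-cell foci count is
#'   overridden by draws from `count_distribution`.
#' @param count_distribution either
#'   `list(type = "lognormal", median = 299, sdlog = 0.49)` or
#'   `list(type = "fixed", n = 300)`.
#' @param n_experiments number of experiment folders.
#' @param seed master seed; per-cell seeds are derived from it.
#' @return Invisibly, a data frame with `cell_id`, `experiment_id`, `path`
#'   and the true counts.
#' @export
generate_dataset <- function(dir, n_cells, spec = synthetic_spec(),
                             count_distribution = list(type = "lognormal",
                                                       median = 299,
                                                       sdlog = 0.49,
                                                       max = 500),
                             n_experiments = 1, seed = 1) {
  if (!is_count(n_cells) || n_cells < 1) stop_f("'n_cells' must be >= 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_f("cannot create output directory '%s'", dir)
  counts <- with_seed(seed, draw_counts(count_distribution, n_cells))
  manifest <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    expt <- sprintf("expt%02d", (i - 1L) %% n_experiments + 1L)
    edir <- file.path(dir, expt)
    dir.create(edir, showWarnings = FALSE)
    cid <- sprintf("cell%03d", i)
    sp <- spec
    sp$n_foci <- counts[i]
    cell_seed <- (seed + 7919 * i) %% 2147483647L
    cell <- generate_cell(sp, seed = cell_seed)
    tif <- file.path(edir, paste0(cid, ".tif"))
    write_stack(cell$stack, tif)
    roi <- cell$cell_roi
    roi$label <- cid
    write_rois_json(list(roi), file.path(edir, paste0(cid, ".rois.json")))
    truth <- list(cell_id = cid, experiment_id = expt,
                  n_true = cell$counts$in_mito,
                  n_total = cell$counts$total,
                  n_in_nucleus = cell$counts$in_nucleus,
                  n_spurious = cell$counts$spurious,
                  foci = lapply(seq_len(nrow(cell$foci)), function(k)
                    list(x = cell$foci$x[k], y = cell$foci$y[k],
                         amplitude = cell$foci$amplitude[k],
                         class = cell$foci$class[k])),
                  mito_area_um2_true = cell$mito_area_um2_true,
                  pixel_size_um = cell$pixel_size, seed = cell_seed)
    jsonlite::write_json(truth, file.path(edir, paste0(cid, ".truth.json")),
                         auto_unbox = TRUE, digits = NA)
    manifest[[i]] <- data.frame(cell_id = cid, experiment_id = expt,
                                path = tif, n_true = cell$counts$in_mito,
                                n_total = cell$counts$total,
                                stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, manifest))
}

# per-cell true foci counts under the configured distribution; the
# lognormal is truncated at `max` (default 500) because spot placement on
# the rendered network jams near 600 spots at the default 6 px separation
draw_counts <- function(count_distribution, n_cells) {
  switch(count_distribution$type,
    lognormal = {
      n <- pmax(1, round(rlnorm(n_cells,
                                meanlog = log(count_distribution$median),
                                sdlog = count_distribution$sdlog)))
      if (!is.null(count_distribution$max))
        n <- pmin(n, count_distribution$max)
      as.integer(n)
    },
    fixed = rep(as.integer(count_distribution$n), n_cells),
    stop_f("unknown count distribution type '%s'", count_distribution$type))
}

#' Read the truth files of a synthetic dataset
#'
#' @param dir dataset directory written by [generate_dataset()].
#' @return A list of truth records (one per cell, sorted by cell id).
#' @export
read_truth <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.truth\\.json$",
                           recursive = TRUE, full.names = TRUE))
  if (length(files) == 0) stop_f("no truth files under '%s'", dir)
  lapply(files, jsonlite::read_json, simplifyVector = FALSE)
}

#' Match detected foci to ground truth
#'
#' Greedy nearest-neighbour matching of detected maxima to true foci
#' within `max_dist` pixels, yielding detection recall and precision.
#'
#' @param detected data frame with 0-based `x`, `y` (e.g. from
#'   [find_maxima()] or [filter_foci()]).
#' @param truth data frame with 0-based `x`, `y` of true foci.
#' @param max_dist maximum matching distance in px.
#' @return List with `n_matched`, `recall`, `precision`.
#' @export
evaluate_detection <- function(detected, truth, max_dist = 2) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(n_matched = 0L,
                recall = if (nt == 0) 1 else 0,
                precision = if (nd == 0) 1 else 0))
  used <- rep(FALSE, nt)
  matched <- 0L
  for (i in seq_len(nd)) {
    d2 <- (truth$x - detected$x[i])^2 + (truth$y - detected$y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= max_dist^2) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_matched = matched, recall = matched / nt, precision = matched / nd)
}
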