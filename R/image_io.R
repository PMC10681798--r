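#' Multi-channel image stack
#'
#' Container for a multi-channel, optionally z-resolved intensity image with
#' pixel-size metadata and a channel-role map. Pixels are stored as an
#' integer array indexed `(channel, z, y, x)` in arbitrary units (au).
#'
#' @param pixels integer array with dimensions `(channel, z, y, x)`.
#' @param channel_roles named list or vector mapping roles (any of `foci`,
#'   `mito`, `nucleus`) to 1-based channel indices. Roles must be distinct
#'   and within range.
#' @param pixel_size isotropic x/y pixel size in micrometres per pixel, or
#'   `NA` when unknown (area measurements will then fail, nothing else).
#' @param z_step z spacing in micrometres, or `NA`.
#' @param source_path provenance string recording where the pixels came from.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, channel_roles, pixel_size = NA_real_,
                        z_step = NA_real_, source_path = NA_character_) {
  if (length(dim(pixels)) != 4L)
    stop_f("'pixels' must be a 4-D (channel, z, y, x) array")
  storage.mode(pixels) <- "integer"
  roles <- validate_roles(channel_roles, dim(pixels)[1])
  if (!is.na(pixel_size) && pixel_size <= 0)
    stop_f("'pixel_size' must be > 0 (got %g)", pixel_size)
  structure(list(pixels = pixels, channel_roles = roles,
                 pixel_size = as.numeric(pixel_size),
                 z_step = as.numeric(z_step),
                 source_path = source_path),
            class = "image_stack")
}

validate_roles <- function(channel_roles, n_channels) {
  roles <- as.list(channel_roles)
  if (length(roles) == 0) stop_f("at least one channel role is required")
  bad <- setdiff(names(roles), c("foci", "mito", "nucleus"))
  if (length(bad)) stop_f("unknown channel role(s): %s",
                          paste(bad, collapse = ", "))
  idx <- unlist(roles)
  if (any(idx < 1 | idx > n_channels | idx != floor(idx)))
    stop_f("channel role index out of range 1..%d", n_channels)
  if (anyDuplicated(idx)) stop_f("channel roles must map to distinct channels")
  lapply(roles, as.integer)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d channel(s), %d z-slice(s), %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat("  roles:", paste(sprintf("%s=%d", names(x$channel_roles),
                                unlist(x$channel_roles)), collapse = ", "), "\n")
  cat(sprintf("  pixel size: %s um/px\n",
              ifelse(is.na(x$pixel_size), "unknown", format(x$pixel_size))))
  invisible(x)
}

#' Read a TIFF image stack
#'
#' Reads a single- or multi-page TIFF into an [image_stack()] with normalised
#' `(channel, z, y, x)` axes. 2-D inputs become `z = 1`; a single page with a
#' samples dimension is treated as one z-slice of multiple channels.
#' Multi-page files are folded into channels and z-slices using
#' `n_channels` and `page_order`.
#'
#' The pixel size is resolved in this order: `pixel_size_override`, ImageJ
#' description metadata (`unit=micron` plus the TIFF x-resolution tag),
#' plain TIFF resolution tags in cm or inch, otherwise `NA`. A missing pixel
#' size is only an error once an area measurement is requested downstream.
#'
#' @param path TIFF file.
#' @param channel_roles named role map, see [image_stack()].
#' @param pixel_size_override pixel size in um/px overriding file metadata.
#' @param n_channels number of channels interleaved in the pages; defaults
#'   to the largest channel index in `channel_roles`.
#' @param page_order `"channel_first"` (channel varies fastest from page to
#'   page, the ImageJ hyperstack default) or `"z_first"`.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_roles, pixel_size_override = NULL,
                       n_channels = NULL,
                       page_order = c("channel_first", "z_first")) {
  page_order <- match.arg(page_order)
  if (!file.exists(path)) stop_f("cannot read TIFF: '%s' does not exist", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                    error = function(e) stop_f("unreadable TIFF '%s': %s",
                                               path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop_f("TIFF '%s' contains no images", path)

  ps <- resolve_pixel_size(pages[[1]], pixel_size_override)

  # single page carrying a samples dimension -> channels
  if (length(pages) == 1 && length(dim(pages[[1]])) == 3) {
    a <- pages[[1]]
    px <- aperm(array(a, c(dim(a)[1], dim(a)[2], dim(a)[3], 1)), c(3, 4, 1, 2))
    return(image_stack(px, channel_roles, pixel_size = ps, source_path = path))
  }
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p
  })
  hw <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), hw), logical(1))))
    stop_f("TIFF '%s': pages differ in size", path)

  if (is.null(n_channels)) n_channels <- max(unlist(channel_roles))
  n_channels <- as.integer(n_channels)
  np <- length(mats)
  if (np %% n_channels != 0)
    stop_f("TIFF '%s': %d page(s) not divisible by %d channel(s)",
           path, np, n_channels)
  nz <- np %/% n_channels
  px <- array(0L, c(n_channels, nz, hw[1], hw[2]))
  for (p in seq_len(np)) {
    if (page_order == "channel_first") {
      ci <- (p - 1L) %% n_channels + 1L
      zi <- (p - 1L) %/% n_channels + 1L
    } else {
      zi <- (p - 1L) %% nz + 1L
      ci <- (p - 1L) %/% nz + 1L
    }
    px[ci, zi, , ] <- mats[[p]]
  }
  image_stack(px, channel_roles, pixel_size = ps, source_path = path)
}

# pixel size (um/px) from override > ImageJ metadata > TIFF resolution tags
resolve_pixel_size <- function(page, override = NULL) {
  if (!is.null(override)) {
    if (!is.numeric(override) || override <= 0)
      stop_f("pixel size override must be a positive number")
    return(as.numeric(override))
  }
  at <- attributes(page)
  desc <- at$description
  xres <- at$x.resolution
  if (!is.null(desc) && grepl("unit=micron", desc, fixed = TRUE) &&
      !is.null(xres) && is.numeric(xres) && xres > 0)
    return(1 / xres) # resolution stored as pixels per micron
  unit <- at$resolution.unit
  if (!is.null(xres) && is.numeric(xres) && xres > 0 && !is.null(unit)) {
    if (identical(unit, "cm")) return(1e4 / xres)
    if (identical(unit, "inch")) return(25400 / xres)
  }
  NA_real_
}

#' Z-project one channel of a stack
#'
#' Collapses the z dimension of the channel with the given role by per-pixel
#' maximum (default) or mean intensity. The mean is rounded half up so the
#' result stays in the integer intensity domain required by exact maxima
#' detection.
#'
#' @param stack an [image_stack()].
#' @param role one of the roles present in `stack$channel_roles`.
#' @param method `"max"` or `"mean"`.
#' @return A `projected_image`: list with integer matrix `pixels` (y, x),
#'   `role`, `pixel_size` and `projection_method`.
#' @export
max_project <- function(stack, role, method = c("max", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "image_stack"))
  if (!role %in% names(stack$channel_roles))
    stop_f("role '%s' not present in stack (has: %s)", role,
           paste(names(stack$channel_roles), collapse = ", "))
  ci <- stack$channel_roles[[role]]
  ch <- stack$pixels[ci, , , , drop = FALSE]
  dim(ch) <- dim(stack$pixels)[2:4]
  px <- if (method == "max") apply(ch, c(2, 3), max)
        else round_half_up(apply(ch, c(2, 3), mean))
  storage.mode(px) <- "integer"
  structure(list(pixels = px, role = role, pixel_size = stack$pixel_size,
                 projection_method = method),
            class = "projected_image")
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Pages are written channel-first (channel varies fastest), the layout
#' [read_stack()] assumes by default. The TIFF carries no resolution
#' metadata; the pixel size travels in run configurations and truth files.
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "image_stack"), bits %in% c(8L, 16L))
  maxv <- 2^bits - 1
  d <- dim(stack$pixels)
  if (max(stack$pixels) > maxv || min(stack$pixels) < 0)
    stop_f("pixel values outside 0..%d; cannot write %d-bit TIFF", maxv, bits)
  pages <- vector("list", d[1] * d[2])
  p <- 1L
  for (zi in seq_len(d[2])) {
    for (ci in seq_len(d[1])) {
      m <- stack$pixels[ci, zi, , ]
      dim(m) <- d[3:4]
      pages[[p]] <- m / maxv
      p <- p + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none", reduce = FALSE)
  invisible(path)
}

cell_csv_header <- c("cell_id", "source_image", "experiment_id", "prominence",
                     "n_foci_raw", "n_foci_filtered", "mito_area_um2",
                     "density_per_um2", "pixel_size_um")

#' Write and read the per-cell results table
#'
#' One row per cell and prominence value with the fixed column set
#' `cell_id, source_image, experiment_id, prominence, n_foci_raw,
#' n_foci_filtered, mito_area_um2, density_per_um2, pixel_size_um`.
#' Numeric fields are written with 17 significant digits so
#' `read_cell_csv(write_cell_csv(x))` reproduces `x` exactly.
#'
#' @param records data frame of cell records (see [quantify_cell()]).
#' @param path CSV file.
#' @return `path` invisibly (write); the records data frame (read).
#' @export
write_cell_csv <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop_f("'records' must be a non-empty data frame")
  miss <- setdiff(cell_csv_header, names(records))
  if (length(miss)) stop_f("records lack column(s): %s",
                           paste(miss, collapse = ", "))
  r <- records[, cell_csv_header]
  lines <- paste(r$cell_id, r$source_image, r$experiment_id,
                 as.integer(r$prominence), as.integer(r$n_foci_raw),
                 as.integer(r$n_foci_filtered), num_chr(r$mito_area_um2),
                 num_chr(r$density_per_um2), num_chr(r$pixel_size_um),
                 sep = ",")
  writeLines(c(paste(cell_csv_header, collapse = ","), lines), path)
  invisible(path)
}

#' @rdname write_cell_csv
#' @export
read_cell_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, cell_csv_header))
    stop_f("malformed cell CSV header in '%s'", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(cell_id = "character",
                                source_image = "character",
                                experiment_id = "character",
                                prominence = "integer",
                                n_foci_raw = "integer",
                                n_foci_filtered = "integer",
                                mito_area_um2 = "numeric",
                                density_per_um2 = "numeric",
                                pixel_size_um = "numeric"))
  df
}

#' Write and read a binary mask TIFF
#'
#' Masks are stored as 8-bit single-channel TIFFs with foreground 255 and
#' background 0, the format segmentation outputs are archived in for
#' traceability. Reading rejects any pixel value other than 0 or 255.
#'
#' @param mask a [binary_mask()].
#' @param path TIFF file.
#' @param kind,pixel_size mask metadata to attach on read (the TIFF itself
#'   stores only pixels).
#' @return `path` invisibly (write); a [binary_mask()] (read).
#' @export
write_binary_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  tiff::writeTIFF(mask$pixels * 1.0, path, bits.per.sample = 8L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' @rdname write_binary_mask
#' @export
read_binary_mask <- function(path, kind = "cell", pixel_size = NA_real_) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  bad <- setdiff(unique(as.vector(m)), c(0L, 255L))
  if (length(bad))
    stop_f("'%s' is not a binary mask: found pixel value %s", path, bad[1])
  binary_mask(m == 255L, kind = kind, pixel_size = pixel_size)
}
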