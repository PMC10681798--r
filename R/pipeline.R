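#' Run configuration for per-cell quantification
#'
#' Collects every knob of the per-cell pipeline so that a run is fully
#' described by (input data, config, seed) and can be reproduced exactly.
#'
#' @param channel_roles named list mapping `foci`, `mito`, `nucleus` to
#'   1-based channel indices; only the roles a run uses need be present.
#' @param projection z-projection method, `"max"` (default) or `"mean"`.
#' @param prominences prominence value(s) in au; detection and counting run
#'   once per value. Defaults to the standard six-value sweep 5..200 au.
#' @param connectivity,exclude_edge_maxima see [find_maxima()].
#' @param mito_params,nucleus_params segmentation recipes, see
#'   [seg_params()].
#' @param use_mito_filter keep only foci inside the mitochondrial mask.
#' @param use_nucleus_subtraction drop foci inside the nuclear mask
#'   (removes nuclear-DNA false positives created by z-projection).
#' @param pixel_size_override pixel size in um/px taking precedence over
#'   image metadata.
#' @param output_dir directory for per-cell artifacts (masks, foci lists,
#'   overlay, manifest) and the batch CSV; `NULL` disables persistence.
#' @param overlay_prominence prominence whose foci are drawn on the overlay
#'   image; defaults to the middle sweep value.
#' @param seed integer seed recorded in manifests (the per-cell pipeline
#'   itself is deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(channel_roles = list(foci = 1, mito = 2, nucleus = 3),
                       projection = "max",
                       prominences = make_sweep(5, 200, 6),
                       connectivity = 8, exclude_edge_maxima = FALSE,
                       mito_params = focicount::mito_params(),
                       nucleus_params = focicount::nucleus_params(),
                       use_mito_filter = TRUE,
                       use_nucleus_subtraction = TRUE,
                       pixel_size_override = NULL, output_dir = NULL,
                       overlay_prominence = NULL, seed = NULL) {
  if (length(prominences) < 1 || any(prominences <= 0) ||
      (length(prominences) > 1 && any(diff(prominences) <= 0)))
    stop_f("'prominences' must be positive and strictly increasing")
  if (isTRUE(use_mito_filter) && is.null(channel_roles$mito))
    stop_f("mito filtering enabled but no 'mito' channel role given")
  if (isTRUE(use_nucleus_subtraction) && is.null(channel_roles$nucleus))
    stop_f("nucleus subtraction enabled but no 'nucleus' channel role given")
  if (is.null(channel_roles$foci))
    stop_f("a 'foci' channel role is required")
  structure(list(channel_roles = channel_roles, projection = projection,
                 prominences = as.integer(prominences),
                 connectivity = connectivity,
                 exclude_edge_maxima = isTRUE(exclude_edge_maxima),
                 mito_params = mito_params, nucleus_params = nucleus_params,
                 use_mito_filter = isTRUE(use_mito_filter),
                 use_nucleus_subtraction = isTRUE(use_nucleus_subtraction),
                 pixel_size_override = pixel_size_override,
                 output_dir = output_dir,
                 overlay_prominence = overlay_prominence, seed = seed),
            class = "run_config")
}

#' Filter detected maxima with inclusion and exclusion masks
#'
#' Keeps a maximum iff its coordinate pixel is foreground in the
#' mitochondrial mask (when given) and background in the nuclear mask (when
#' given). Filtering is by the single coordinate pixel, not a
#' neighbourhood, so the effect of mask erosion or dilation is predictable.
#' Input order is preserved and counts never increase.
#'
#' @param maxima data frame from [find_maxima()] (0-based `x`, `y`).
#' @param mito_mask,nucleus_mask optional [binary_mask()]s matching the
#'   image shape.
#' @return The filtered maxima data frame.
#' @export
filter_foci <- function(maxima, mito_mask = NULL, nucleus_mask = NULL) {
  stopifnot(is.data.frame(maxima))
  if (nrow(maxima) == 0 || (is.null(mito_mask) && is.null(nucleus_mask)))
    return(maxima)
  dims <- if (!is.null(mito_mask)) dim(mito_mask$pixels)
          else dim(nucleus_mask$pixels)
  if (!is.null(mito_mask) && !is.null(nucleus_mask) &&
      !identical(dim(mito_mask$pixels), dim(nucleus_mask$pixels)))
    stop_f("mito and nucleus masks differ in shape")
  if (any(maxima$x < 0 | maxima$x >= dims[2] |
          maxima$y < 0 | maxima$y >= dims[1]))
    stop_f("maxima coordinates fall outside the mask shape")
  idx <- cbind(maxima$y + 1L, maxima$x + 1L)
  keep <- rep(TRUE, nrow(maxima))
  if (!is.null(mito_mask)) keep <- keep & mito_mask$pixels[idx]
  if (!is.null(nucleus_mask)) keep <- keep & !nucleus_mask$pixels[idx]
  maxima[keep, , drop = FALSE]
}

#' Quantify foci in one cell
#'
#' The per-cell pipeline, in fixed order: z-project the channels, rasterize
#' the cell ROI, zero intensities outside the ROI (so neighbouring cells
#' cannot contribute maxima), segment the mitochondrial and nuclear masks
#' (or take supplied ones), detect maxima at each configured prominence,
#' filter with the masks, and measure counts, mitochondrial area (um^2) and
#' foci density (um^-2, filtered count / area). With an `output_dir` set in
#' the config, masks, per-prominence foci images, the foci list, an overlay
#' PNG and a run manifest are persisted per cell.
#'
#' @param stack an [image_stack()].
#' @param cell_roi a [polygon_roi()] outlining the cell.
#' @param config a [run_config()].
#' @param cell_id identifier; defaults to the ROI label.
#' @param experiment_id replicate identifier (e.g. sampling date).
#' @param mito_mask,nucleus_mask optional pre-segmented [binary_mask()]s
#'   from external tools, used verbatim instead of the built-in recipes.
#' @return A data frame of cell records, one row per prominence, with the
#'   columns of the results CSV (see [write_cell_csv()]).
#' @export
quantify_cell <- function(stack, cell_roi, config = run_config(),
                          cell_id = cell_roi$label,
                          experiment_id = NA_character_,
                          mito_mask = NULL, nucleus_mask = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(cell_roi, "polygon_roi"),
            inherits(config, "run_config"))
  ps <- if (!is.null(config$pixel_size_override))
    config$pixel_size_override else stack$pixel_size

  proj_foci <- max_project(stack, "foci", config$projection)
  dims <- dim(proj_foci$pixels)
  cell_mask <- rasterize_roi(cell_roi, dims[1], dims[2], pixel_size = ps)
  if (!any(cell_mask$pixels))
    stop_f("cell ROI '%s' rasterizes to an empty mask", cell_id)

  det <- proj_foci$pixels
  det[!cell_mask$pixels] <- 0L

  need_mito <- !is.null(config$channel_roles$mito) || !is.null(mito_mask)
  mm <- NULL
  if (need_mito) {
    mm <- if (!is.null(mito_mask)) {
      binary_mask(mito_mask$pixels & cell_mask$pixels, "mito", ps)
    } else {
      proj_mito <- max_project(stack, "mito", config$projection)
      proj_mito$pixel_size <- ps
      segment_mitochondria(proj_mito, cell_mask, config$mito_params)
    }
  } else if (config$use_mito_filter) {
    stop_f("mito filter enabled but no mito channel or mask available")
  }

  nm <- NULL
  if (config$use_nucleus_subtraction) {
    nm <- if (!is.null(nucleus_mask)) {
      binary_mask(nucleus_mask$pixels & cell_mask$pixels, "nucleus", ps)
    } else if (!is.null(config$channel_roles$nucleus)) {
      proj_nuc <- max_project(stack, "nucleus", config$projection)
      proj_nuc$pixel_size <- ps
      segment_nucleus(proj_nuc, cell_mask, config$nucleus_params)
    } else {
      stop_f("nucleus subtraction enabled but no nucleus channel or mask")
    }
  }

  area <- if (!is.null(mm)) mask_area(mm) else NA_real_

  records <- vector("list", length(config$prominences))
  all_foci <- vector("list", length(config$prominences))
  for (i in seq_along(config$prominences)) {
    p <- config$prominences[i]
    fm <- find_maxima(det, p, config$connectivity,
                      config$exclude_edge_maxima)
    ff <- filter_foci(fm, if (config$use_mito_filter) mm else NULL, nm)
    all_foci[[i]] <- ff
    # density pairs the filtered count with the inclusion-mask area, so it
    # is only reported when mito filtering is actually applied
    dens <- if (config$use_mito_filter && !is.na(area) && area > 0)
      nrow(ff) / area else NA_real_
    records[[i]] <- data.frame(
      cell_id = cell_id, source_image = basename2(stack$source_path),
      experiment_id = experiment_id, prominence = as.integer(p),
      n_foci_raw = nrow(fm), n_foci_filtered = nrow(ff),
      mito_area_um2 = area, density_per_um2 = dens,
      pixel_size_um = as.numeric(ps), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, records)

  if (!is.null(config$output_dir))
    persist_cell(config, cell_id, stack, cell_mask, mm, nm, det,
                 all_foci, out)
  out
}

basename2 <- function(p) if (is.na(p)) NA_character_ else basename(p)

persist_cell <- function(config, cell_id, stack, cell_mask, mm, nm, det,
                         all_foci, records) {
  dir <- file.path(config$output_dir, cell_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(mm)) write_binary_mask(mm, file.path(dir, "mito_mask.tif"))
  if (!is.null(nm)) write_binary_mask(nm, file.path(dir, "nucleus_mask.tif"))
  foci_rows <- list()
  for (i in seq_along(config$prominences)) {
    p <- config$prominences[i]
    ff <- all_foci[[i]]
    write_binary_mask(foci_mask(ff, dim(det)),
                      file.path(dir, sprintf("foci_p%d.tif", p)))
    if (nrow(ff))
      foci_rows[[length(foci_rows) + 1L]] <-
        data.frame(cell_id = cell_id, prominence = p, x = ff$x, y = ff$y,
                   value = ff$value)
  }
  foci_df <- if (length(foci_rows)) do.call(rbind, foci_rows) else
    data.frame(cell_id = character(), prominence = integer(),
               x = integer(), y = integer(), value = integer())
  write.csv(foci_df, file.path(dir, "foci.csv"), row.names = FALSE,
            quote = FALSE)
  ov_p <- config$overlay_prominence
  if (is.null(ov_p)) ov_p <- config$prominences[ceiling(length(
    config$prominences) / 2)]
  oi <- which(config$prominences == ov_p)[1]
  if (!is.na(oi))
    write_overlay(det, if (!is.null(mm)) mm$pixels else NULL,
                  all_foci[[oi]], file.path(dir, "overlay.png"))
  writeLines(cell_manifest(config, cell_id, stack, records),
             file.path(dir, "manifest.txt"))
}

# RGB overlay: mitochondria mask in red, foci-channel intensity in grey,
# detected foci as yellow 3x3 squares
write_overlay <- function(det, mito_px, foci, path) {
  h <- nrow(det); w <- ncol(det)
  g <- det / max(1L, max(det))
  img <- array(0, c(h, w, 3))
  img[, , 1] <- g; img[, , 2] <- g; img[, , 3] <- g
  if (!is.null(mito_px)) img[, , 1][mito_px] <- pmin(1, g[mito_px] + 0.35)
  if (nrow(foci)) {
    for (k in seq_len(nrow(foci))) {
      ys <- pmax(1, foci$y[k]):pmin(h, foci$y[k] + 2)
      xs <- pmax(1, foci$x[k]):pmin(w, foci$x[k] + 2)
      img[ys, xs, 1] <- 1; img[ys, xs, 2] <- 1; img[ys, xs, 3] <- 0
    }
  }
  png::writePNG(img, path)
}

cell_manifest <- function(config, cell_id, stack, records) {
  cfg <- config
  cfg$output_dir <- NULL
  cfg_lines <- strsplit(yaml::as.yaml(unclass(cfg)), "\n")[[1]]
  src <- stack$source_path
  chk <- if (!is.na(src) && file.exists(src)) unname(tools::md5sum(src))
         else "in-memory"
  c(sprintf("focicount %s", as.character(packageVersion("focicount"))),
    sprintf("cell_id: %s", cell_id),
    sprintf("source: %s", src),
    sprintf("source_md5: %s", chk),
    sprintf("config_md5: %s", md5_of(cfg_lines)),
    sprintf("n_records: %d", nrow(records)),
    "config:",
    paste0("  ", cfg_lines))
}

#' Batch quantification over a directory tree
#'
#' Processes every image under `input_dir` laid out as
#' `<experiment_id>/<image>.tif` with a sibling ROI file
#' `<image>.rois.json` or `<image>.rois.zip`. Every ROI in the file is one
#' cell. Files are enumerated in sorted order so results are independent of
#' filesystem order; per-cell failures are caught, logged and tabulated
#' while the batch continues. When the config has an `output_dir`, the
#' combined table is written to `results/cells.csv` below it along with the
#' per-cell artifact folders.
#'
#' @param input_dir root directory of the dataset.
#' @param config a [run_config()].
#' @return A list of class `foci_batch` with `records` (data frame over all
#'   cells and prominences) and `failures` (data frame of image/cell and
#'   error message).
#' @export
run_batch <- function(input_dir, config = run_config()) {
  if (!dir.exists(input_dir)) stop_f("input dir '%s' not found", input_dir)
  tifs <- sort(list.files(input_dir, pattern = "\\.tif{1,2}$",
                          recursive = TRUE, full.names = TRUE))
  if (length(tifs) == 0) stop_f("no TIFF images under '%s'", input_dir)
  records <- list(); failures <- list()
  for (tif in tifs) {
    expt <- experiment_id_of(tif, input_dir)
    roi_path <- sibling_roi_file(tif)
    res <- tryCatch({
      if (is.null(roi_path)) stop_f("no ROI file next to '%s'", tif)
      stack <- read_stack(tif, config$channel_roles,
                          pixel_size_override = config$pixel_size_override)
      rois <- read_rois(roi_path)
      img_id <- tools::file_path_sans_ext(basename(tif))
      do.call(rbind, lapply(rois, function(roi)
        quantify_cell(stack, roi, config,
                      cell_id = if (identical(roi$label, img_id)) img_id
                                else paste(img_id, roi$label, sep = "_"),
                      experiment_id = expt)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        image = tif, experiment_id = expt,
        error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  if (length(records) == 0) stop_f("no cell could be processed")
  records <- do.call(rbind, records)
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(image = character(), experiment_id = character(),
               error = character())
  if (!is.null(config$output_dir)) {
    resdir <- file.path(config$output_dir, "results")
    dir.create(resdir, recursive = TRUE, showWarnings = FALSE)
    write_cell_csv(records, file.path(resdir, "cells.csv"))
  }
  structure(list(records = records, failures = failures),
            class = "foci_batch")
}

#' @export
print.foci_batch <- function(x, ...) {
  cat(sprintf("<foci_batch> %d record(s) from %d cell(s), %d failure(s)\n",
              nrow(x$records), length(unique(x$records$cell_id)),
              nrow(x$failures)))
  invisible(x)
}

experiment_id_of <- function(tif, root) {
  rel <- sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", root),
                    "/?"), "", tif)
  parts <- strsplit(rel, "/", fixed = TRUE)[[1]]
  if (length(parts) > 1) parts[1] else NA_character_
}

sibling_roi_file <- function(tif) {
  base <- tools::file_path_sans_ext(tif)
  for (ext in c(".rois.json", ".rois.zip")) {
    p <- paste0(base, ext)
    if (file.exists(p)) return(p)
  }
  NULL
}
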