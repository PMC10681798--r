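#' Prominence-based local maxima detection
#'
#' Finds the local intensity maxima of a 2-D integer image that are
#' topographically prominent: a maximum survives only if the intensity drop
#' separating it from any higher ground exceeds the `prominence` parameter.
#' This is the foci-detection core of the package, equivalent in spirit to
#' ImageJ's FindMaxima, with the boundary behaviour pinned down exactly:
#'
#' * candidates are connected plateaus of equal value with no strictly
#'   higher neighbour (4- or 8-connectivity);
#' * a candidate at value `v` is rejected iff a connected path leads from it
#'   to a strictly higher pixel along which every pixel has intensity
#'   `>= v - prominence` (a drop of exactly `prominence` rejects);
#' * equal-valued surviving candidates connected within the same tolerance
#'   region are merged; the plateau whose top-left pixel comes first in
#'   row-major order is kept;
#' * each plateau reports the centroid of its pixels, rounded to the nearest
#'   pixel with half-ties towards the image origin;
#' * a flat image has no maxima.
#'
#' Detection runs on the raw projected intensities; no pre-smoothing is
#' applied. The integer intensity domain makes the rules exact (no floating
#' point ties).
#'
#' @param image integer matrix (y, x) of intensities in au.
#' @param prominence positive prominence threshold in au.
#' @param connectivity pixel neighbourhood, 8 (default) or 4.
#' @param exclude_edge_maxima drop maxima whose plateau touches the image
#'   border. Off by default: foci touching the cell boundary are real foci.
#' @return A data frame with one row per accepted maximum: 0-based `x`
#'   (column), `y` (row) and `value` (intensity au), sorted by decreasing
#'   value, then row-major position.
#' @examples
#' img <- matrix(0L, 10, 10)
#' img[6, 6] <- 100L
#' find_maxima(img, prominence = 50)
#' @export
find_maxima <- function(image, prominence, connectivity = 8,
                        exclude_edge_maxima = FALSE) {
  if (!is.matrix(image)) stop_f("'image' must be a 2-D matrix")
  if (!is.numeric(image) || anyNA(image) || any(image != floor(image)))
    stop_f("'image' must hold finite integer intensities")
  if (!is.numeric(prominence) || length(prominence) != 1 || prominence <= 0)
    stop_f("'prominence' must be a single value > 0")
  if (!connectivity %in% c(4, 8))
    stop_f("'connectivity' must be 4 or 8")
  storage.mode(image) <- "integer"
  cpp_find_maxima(image, as.numeric(prominence), as.integer(connectivity),
                  isTRUE(exclude_edge_maxima))
}

#' Build a prominence parameter sweep
#'
#' `n` evenly spaced prominence values from `min_prominence` to
#' `max_prominence` inclusive, rounded to the nearest integer au. Sweeping
#' detection over such a range (six values by default) exposes the sharp
#' drop between spurious and true foci and is how a working prominence is
#' chosen for a new imaging set-up.
#'
#' @param min_prominence,max_prominence positive range endpoints in au.
#' @param n number of values (>= 2).
#' @return Strictly increasing integer vector of length `n`.
#' @examples
#' make_sweep(5, 200)   # 5 44 83 122 161 200
#' @export
make_sweep <- function(min_prominence, max_prominence, n = 6) {
  if (!is.numeric(min_prominence) || !is.numeric(max_prominence) ||
      min_prominence <= 0 || max_prominence <= min_prominence)
    stop_f("need 0 < min_prominence < max_prominence")
  if (!is_count(n) || n < 2) stop_f("'n' must be an integer >= 2")
  vals <- as.integer(round_half_up(seq(min_prominence, max_prominence,
                                       length.out = n)))
  if (any(diff(vals) <= 0))
    stop_f("sweep values collapse after integer rounding; widen the range")
  vals
}

#' Foci counts across a prominence sweep
#'
#' Runs [find_maxima()] at each prominence and records the raw (pre-filter)
#' count. Counts are non-increasing in prominence. When `output_dir` is
#' given, a binary TIFF per prominence is written with one foreground pixel
#' per accepted maximum, for future inspection.
#'
#' @inheritParams find_maxima
#' @param prominences strictly increasing prominence values (au), e.g. from
#'   [make_sweep()].
#' @param cell_id label carried into the result.
#' @param output_dir optional directory for per-prominence foci masks.
#' @return A `sweep_result`: list with `prominences`, `counts`, `cell_id`.
#' @export
sweep_counts <- function(image, prominences, connectivity = 8,
                         exclude_edge_maxima = FALSE, cell_id = "cell",
                         output_dir = NULL) {
  if (length(prominences) < 1 || any(diff(prominences) <= 0))
    stop_f("'prominences' must be strictly increasing")
  counts <- integer(length(prominences))
  for (i in seq_along(prominences)) {
    fm <- find_maxima(image, prominences[i], connectivity,
                      exclude_edge_maxima)
    counts[i] <- nrow(fm)
    if (!is.null(output_dir)) {
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
      write_binary_mask(foci_mask(fm, dim(image)),
                        file.path(output_dir,
                                  sprintf("foci_p%d.tif", prominences[i])))
    }
  }
  structure(list(prominences = prominences, counts = counts,
                 cell_id = cell_id),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> cell '%s'\n", x$cell_id))
  print(setNames(x$counts, x$prominences))
  invisible(x)
}

# binary mask with one foreground pixel per maximum
foci_mask <- function(maxima, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  if (nrow(maxima)) m[cbind(maxima$y + 1L, maxima$x + 1L)] <- TRUE
  binary_mask(m, kind = "cell")
}
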