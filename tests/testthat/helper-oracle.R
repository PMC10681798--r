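# Brute-force prominence-maxima oracle, written independently of the
# package's C++ detector. Plateaus and tolerance regions are grown by
# repeated whole-matrix neighbour dilation (fixpoint flood), not by a
# pixel queue, so the two routes share no code.

# logical matrix: TRUE wherever any neighbour of a TRUE cell lies
neighbour_any <- function(m, connectivity = 8) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  up    <- pad[1:h, 2:(w + 1)]
  down  <- pad[3:(h + 2), 2:(w + 1)]
  left  <- pad[2:(h + 1), 1:w]
  right <- pad[2:(h + 1), 3:(w + 2)]
  out <- up | down | left | right
  if (connectivity == 8) {
    out <- out | pad[1:h, 1:w] | pad[1:h, 3:(w + 2)] |
      pad[3:(h + 2), 1:w] | pad[3:(h + 2), 3:(w + 2)]
  }
  out
}

# connected component of `allowed` containing the seed mask, by dilation
flood_component <- function(seed, allowed, connectivity = 8) {
  comp <- seed & allowed
  repeat {
    grown <- (comp | neighbour_any(comp, connectivity)) & allowed
    if (identical(grown, comp)) return(comp)
    comp <- grown
  }
}

# all equal-value plateaus of the image as a list of logical masks
oracle_plateaus <- function(img, connectivity = 8) {
  seen <- matrix(FALSE, nrow(img), ncol(img))
  out <- list()
  for (x in seq_len(ncol(img))) {
    for (y in seq_len(nrow(img))) {
      if (seen[y, x]) next
      seed <- matrix(FALSE, nrow(img), ncol(img))
      seed[y, x] <- TRUE
      comp <- flood_component(seed, img == img[y, x], connectivity)
      seen <- seen | comp
      out[[length(out) + 1]] <- comp
    }
  }
  out
}

# row-major rank of the first TRUE pixel of a mask (for merge tie-breaks)
rowmajor_first <- function(mask) {
  w <- which(t(mask)) # t() so row varies slowest, matching y*W + x order
  min(w)
}

oracle_find_maxima <- function(img, prominence, connectivity = 8) {
  h <- nrow(img); w <- ncol(img)
  plats <- oracle_plateaus(img, connectivity)
  cand <- list()
  for (pl in plats) {
    v <- img[pl][1]
    if (sum(pl) == h * w) next # flat image: no maxima
    ring <- neighbour_any(pl, connectivity) & !pl
    if (any(img[ring] > v)) next # strictly higher neighbour
    comp <- flood_component(pl, img >= v - prominence, connectivity)
    if (any(img[comp] > v)) next # within-tolerance path to higher ground
    cand[[length(cand) + 1]] <- list(mask = pl, value = v, comp = comp)
  }
  # merge equal-valued accepted candidates with intersecting tolerance
  # regions: keep the plateau whose top-left pixel comes first
  keep <- rep(TRUE, length(cand))
  if (length(cand) > 1) {
    for (i in seq_along(cand)) {
      for (j in seq_along(cand)) {
        if (i == j || !keep[i] || !keep[j]) next
        if (cand[[i]]$value == cand[[j]]$value &&
            any(cand[[i]]$comp & cand[[j]]$mask)) {
          drop <- if (rowmajor_first(cand[[i]]$mask) <=
                      rowmajor_first(cand[[j]]$mask)) j else i
          keep[drop] <- FALSE
        }
      }
    }
  }
  cand <- cand[keep]
  if (length(cand) == 0)
    return(data.frame(x = integer(), y = integer(), value = integer()))
  res <- do.call(rbind, lapply(cand, function(cc) {
    idx <- which(cc$mask, arr.ind = TRUE)
    mx <- mean(idx[, 2]) - 1 # 0-based
    my <- mean(idx[, 1]) - 1
    data.frame(x = ceiling(mx - 0.5), y = ceiling(my - 0.5),
               value = cc$value)
  }))
  res <- res[order(-res$value, res$y, res$x), , drop = FALSE]
  rownames(res) <- NULL
  res
}
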