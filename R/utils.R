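# internal helpers shared across modules

# round half away from zero for non-negative values; base round() is
# banker's rounding, which would make projections and sweeps seed-dependent
# on exact .5 values
round_half_up <- function(x) floor(x + 0.5)

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# format a numeric so that read-back with as.numeric() is bit-exact
num_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

stop_f <- function(...) stop(sprintf(...), call. = FALSE)

warn_f <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)

# md5 of a character vector via a temp file (tools::md5sum is file-based)
md5_of <- function(lines) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(lines, tf)
  unname(tools::md5sum(tf))
}
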