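# small, fast synthetic-cell spec shared by test files; the full-size
# defaults are exercised in the acceptance suite
small_spec <- function(...) {
  args <- utils::modifyList(
    list(width = 160, height = 160, n_branches = 10, branch_length = 160,
         n_foci = 60, nucleus_axes = c(26, 20)),
    list(...))
  do.call(synthetic_spec, args)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# a deterministic 4-channel-free random stack for io tests
random_stack <- function(seed, c = 2L, z = 3L, h = 12L, w = 10L,
                         roles = list(foci = 1, mito = 2)) {
  set.seed(seed)
  px <- array(sample.int(65536L, c * z * h * w, replace = TRUE) - 1L,
              c(c, z, h, w))
  image_stack(px, roles, pixel_size = 0.1)
}
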