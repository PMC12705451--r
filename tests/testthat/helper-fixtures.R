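# Shared small fixtures, built in code. Heavyweight artefacts (the full
# desk-scale study used by the acceptance checks) are memoised so that the
# several acceptance blocks that read them pay for one build.

.fixture_env <- new.env(parent = emptyenv())

# Small paired samples at 32 px (two stride-2 levels need multiples of 4).
tiny_pairs <- function(n = 6, size = 32, seed0 = 500) {
  key <- paste0("pairs_", n, "_", size, "_", seed0)
  if (is.null(.fixture_env[[key]])) {
    sp <- scene_params(size = size, n_nuclei = c(3, 6), radius_range = c(2, 3))
    .fixture_env[[key]] <- lapply(seq_len(n), function(i)
      render_pair(sample_scene(sp, seed = seed0 + i)))
  }
  .fixture_env[[key]]
}

# Identity-style stub transforms for cycle tests.
identity_vs <- function() as_transform(function(x) {
  array(x[, , rep(1L, 3L)], c(dim(x)[1], dim(x)[2], 3L))
}, "AF_TO_STAIN", id = "identity_vs")

identity_vaf <- function() as_transform(function(x) {
  array(rowMeans(matrix(x, ncol = dim(x)[3])), c(dim(x)[1], dim(x)[2], 1L))
}, "STAIN_TO_AF", id = "identity_vaf")

# Counting stubs: record how often each transform is invoked.
counting_transforms <- function() {
  counter <- new.env(parent = emptyenv())
  counter$vs <- 0L; counter$vaf <- 0L
  vs <- as_transform(function(x) {
    counter$vs <- counter$vs + 1L
    array(x[, , rep(1L, 3L)], c(dim(x)[1], dim(x)[2], 3L))
  }, "AF_TO_STAIN", id = "counting_vs")
  vaf <- as_transform(function(x) {
    counter$vaf <- counter$vaf + 1L
    array(rowMeans(matrix(x, ncol = dim(x)[3])), c(dim(x)[1], dim(x)[2], 1L))
  }, "STAIN_TO_AF", id = "counting_vaf")
  list(vs = vs, vaf = vaf, counter = counter)
}

# The desk-scale study shared by the acceptance checks (built once).
acceptance_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- run_desk_study(seed = 0, verbose = FALSE)
  .fixture_env$study
}
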