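# Shared synthetic cohort, generated once per test run.
fx <- make_fixture(seed = 7L)

# A tiny hand-built lesion set on a 5^3 grid for oracle comparisons:
# 8 patients, random but fixed blobs.
tiny_lesion_set <- function(seed = 11L, n = 8L, dims = c(5L, 5L, 5L)) {
  set.seed(seed)
  g <- voxel_grid(dims)
  lapply(seq_len(n), function(i) {
    arr <- array(0, dims)
    # random 2x2x2-ish box
    o <- sapply(dims, function(d) sample.int(d - 1, 1))
    arr[o[1]:(o[1] + 1), o[2]:(o[2] + 1), o[3]:(o[3] + 1)] <- 1
    volume(arr, g, "mask")
  })
}
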