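test_that("overlap, analysis mask and subtraction follow their definitions", {
  g <- voxel_grid(c(3, 3, 3))
  mk <- function(vox) {
    arr <- array(0, c(3, 3, 3)); arr[vox] <- 1
    volume(arr, g, "mask")
  }
  les <- c(lapply(1:6, function(i) mk(c(1, 14))),   # LG+ : voxels 1 and 14
           lapply(1:3, function(i) mk(c(2, 14))),   # LG- lesioned elsewhere
           lapply(1:3, function(i) mk(2)))
  labels <- rep(c(1, 0), c(6, 6))
  ov <- overlap_map(les)
  expect_equal(ov$values[[14]], 9)
  expect_equal(ov$values[[1]], 6)
  expect_equal(ov$values[[27]], 0)
  am <- analysis_mask(les)
  expect_equal(sum(am$values), 3)  # voxels 1, 2, 14
  expect_equal(sum(am$values), sum(ov$values > 0))

  sub <- subtraction_map(les, labels)
  expect_equal(sub$values[[1]], 100)       # 6/6 vs 0/6
  expect_equal(sub$values[[14]], 100 * (1 - 0.5))  # 6/6 vs 3/6 -> +50
  expect_equal(sub$values[[2]], -100)
  # antisymmetry under label flip
  sub2 <- subtraction_map(les, 1 - labels)
  expect_equal(sub2$values, -sub$values)
  expect_error(subtraction_map(les, rep(1, 12)), "non-empty")
})

test_that("Liebermeister p matches the augmented-table hypergeometric oracle", {
  expect_equal(liebermeister_p(6, 0, 0, 6), 1 / choose(14, 7), tolerance = 1e-12)
  expect_equal(liebermeister_p(3, 3, 3, 3), 0.5, tolerance = 1e-12)
  for (a in 0:5) for (b in 0:5) for (cc in 0:4) for (d in 0:4) {
    expect_equal(liebermeister_p(a, b, cc, d), oracle_lieb_p(a, b, cc, d),
                 tolerance = 1e-10,
                 label = sprintf("table %d %d %d %d", a, b, cc, d))
  }
})

test_that("Liebermeister p is monotone as association concentrates at fixed totals", {
  # move one lesioned patient from LG- to LG+ (totals fixed)
  for (k in 0:5) {
    p1 <- liebermeister_p(k, 6 - k, 6 - k, k)
    p2 <- liebermeister_p(k + 1, 5 - k, 5 - k, k + 1)
    expect_lte(p2, p1 + 1e-12)
  }
})

test_that("the negative direction mirrors the positive one", {
  expect_equal(liebermeister_p(6, 0, 0, 6, "negative"),
               liebermeister_p(0, 6, 6, 0, "positive"))
})

test_that("p to z conversion inverts the normal upper tail", {
  expect_equal(p_to_z(0.5), 0)
  expect_equal(round(p_to_z(0.025), 3), 1.960)
  expect_equal(round(p_to_z(0.05), 3), 1.645)
  expect_true(is.finite(p_to_z(0)) && is.finite(p_to_z(1)))
})

test_that("voxelwise map equals the brute-force oracle on a tiny grid", {
  les <- tiny_lesion_set()
  labels <- rep(c(1L, 0L), each = 4)
  sm <- voxelwise_liebermeister(les, labels)
  X <- sapply(les, function(v) as.vector(v$values))
  inmask <- as.vector(sm$mask$values) > 0
  for (v in which(inmask)) {
    lesv <- X[v, ]
    a <- sum(lesv == 1 & labels == 1); b <- sum(lesv == 1 & labels == 0)
    cc <- sum(lesv == 0 & labels == 1); d <- sum(lesv == 0 & labels == 0)
    z_oracle <- qnorm(1 - oracle_lieb_p(a, b, cc, d))
    expect_equal(sm$z$values[[v]], z_oracle, tolerance = 1e-9)
  }
  expect_true(all(is.na(sm$z$values[!inmask])))
  expect_error(voxelwise_liebermeister(les, rep(1L, 8)), "identical")
})

test_that("a voxel with equal lesion frequency in equal-size groups has z = 0", {
  g <- voxel_grid(c(2, 2, 2))
  mk <- function(on) volume(array(as.numeric(on), c(2, 2, 2)), g, "mask")
  les <- c(lapply(1:3, function(i) mk(c(1, rep(0, 7)))),
           lapply(1:3, function(i) mk(c(1, rep(0, 7)))),
           lapply(1:6, function(i) mk(c(0, 1, rep(0, 6)))))[c(1:3, 7:9, 4:6, 10:12)]
  # 3 of 6 LG+ and 3 of 6 LG- lesion voxel 1
  labels <- rep(c(1, 0), each = 6)
  sm <- voxelwise_liebermeister(les, labels)
  expect_equal(sm$z$values[[1]], 0, tolerance = 1e-9)
})

test_that("permutation FWE is exhaustive for the 6/6 case and matches the oracle", {
  les <- tiny_lesion_set(seed = 13L, n = 12L)
  labels <- rep(c(1L, 0L), each = 6)
  perm <- permutation_fwe(les, labels, n_perm = 4000L, seed = 2)
  expect_true(perm$exhaustive)
  expect_equal(perm$n_perm, choose(12, 6))
  expect_equal(perm$n_perm, 924)

  X <- sapply(les, function(v) as.vector(v$values))
  inmask <- as.vector(analysis_mask(les)$values) > 0
  zmax_oracle <- oracle_perm_max(X, labels, inmask)
  expect_equal(sort(perm$max_dist), sort(zmax_oracle), tolerance = 1e-9)
  # critical z: smallest max-stat value with exceedance <= alpha
  expect_lte(mean(perm$max_dist >= perm$critical_z), 0.05)
  smaller <- perm$max_dist[perm$max_dist < perm$critical_z]
  if (length(smaller))
    expect_gt(mean(perm$max_dist >= max(smaller)), 0.05)
})

test_that("corrected p collapses to the uncorrected permutation p on a single-voxel mask", {
  les <- tiny_lesion_set(seed = 19L, n = 10L)
  labels <- rep(c(1L, 0L), each = 5)
  am <- analysis_mask(les)
  vox <- which(as.vector(am$values) > 0)[1]
  arr <- array(0, dim(am$values)); arr[vox] <- 1
  mask1 <- volume(arr, am$grid, "mask")
  perm <- permutation_fwe(les, labels, mask = mask1, n_perm = 4000L)
  # direct uncorrected permutation p at that voxel
  X <- sapply(les, function(v) as.vector(v$values))
  combos <- utils::combn(10, 5)
  z_null <- apply(combos, 2, function(ii) {
    lab <- integer(10); lab[ii] <- 1L
    lesv <- X[vox, ]
    a <- sum(lesv & lab); b <- sum(lesv & !lab)
    cc <- sum(!lesv & lab); d <- sum(!lesv & !lab)
    qnorm(1 - oracle_lieb_p(a, b, cc, d))
  })
  z_obs <- perm$stat$z$values[[vox]]
  expect_equal(perm$p_fwe$values[[vox]], mean(z_null >= z_obs - 1e-12),
               tolerance = 1e-9)
})

test_that("permuting patients together with their labels leaves all maps unchanged", {
  les <- tiny_lesion_set(seed = 23L, n = 10L)
  labels <- c(1, 1, 1, 0, 0, 1, 0, 0, 1, 0)
  sm1 <- voxelwise_liebermeister(les, labels)
  set.seed(9); perm_idx <- sample(10)
  sm2 <- voxelwise_liebermeister(les[perm_idx], labels[perm_idx])
  expect_equal(sm1$z$values, sm2$z$values)
  expect_equal(subtraction_map(les, labels)$values,
               subtraction_map(les[perm_idx], labels[perm_idx])$values)
})

test_that("seed-mask extraction thresholds at the critical z and labels components", {
  les <- tiny_lesion_set(seed = 13L, n = 12L)
  labels <- rep(c(1L, 0L), each = 6)
  perm <- permutation_fwe(les, labels)
  sm <- suppressWarnings(extract_seed_mask(perm))
  expect_true(all(sm$mask$values[sm$mask$values > 0] == 1))
  # containment in the analysis mask
  am <- analysis_mask(les)
  expect_true(all(am$values[sm$mask$values > 0] == 1))
  # impossible critical z -> empty mask
  perm2 <- perm; perm2$critical_z <- Inf
  expect_warning(sm2 <- extract_seed_mask(perm2), "empty")
  expect_equal(sum(sm2$mask$values), 0)
})

test_that("two disjoint suprathreshold blobs yield two labeled components", {
  arr <- array(FALSE, c(6, 6, 6))
  arr[1:2, 1:2, 1] <- TRUE
  arr[5:6, 5:6, 6] <- TRUE
  lab <- label_components(arr)
  expect_equal(max(lab), 2L)
  expect_equal(sum(lab > 0), 8)
  # diagonal touch merges under 26-connectivity
  arr2 <- array(FALSE, c(4, 4, 4))
  arr2[1, 1, 1] <- TRUE; arr2[2, 2, 2] <- TRUE
  expect_equal(max(label_components(arr2)), 1L)
})

test_that("the full pipeline recovers the ground-truth critical region", {
  res <- lesion_symptom_pipeline(fx$lesions, fx$behavior, seed = 1)
  expect_true(res$perm$exhaustive)
  expect_gte(dice_coefficient(res$seed_mask$mask, fx$truth$critical_region),
             0.5)
})
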