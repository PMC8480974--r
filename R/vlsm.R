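as_lesion_matrix <- function(lesions) {
  stopifnot(length(lesions) >= 1)
  g <- lesions[[1]]$grid
  for (i in seq_along(lesions)) {
    if (lesions[[i]]$kind != "mask") stop("all lesion volumes must be masks")
    stop_if_grid_mismatch(g, lesions[[i]]$grid, "lesion masks")
  }
  vapply(lesions, function(v) as.vector(v$values), numeric(prod(g$dims)))
}

#' Lesion overlap map
#'
#' Per-voxel count of patients whose lesion covers the voxel.
#'
#' @param lesions list of mask `volume`s on one grid.
#' @return A `volume` of kind "count".
#' @export
overlap_map <- function(lesions) {
  X <- as_lesion_matrix(lesions)
  g <- lesions[[1]]$grid
  volume(array(rowSums(X), g$dims), g, "count")
}

#' Analysis mask: voxels lesioned in at least one patient
#'
#' @inheritParams overlap_map
#' @return A `volume` of kind "mask".
#' @export
analysis_mask <- function(lesions) {
  ov <- overlap_map(lesions)
  volume(array(as.numeric(ov$values >= 1), ov$grid$dims), ov$grid, "mask")
}

#' Lesion subtraction map
#'
#' Per voxel, the lesion frequency (percent) in the deficit-positive group
#' minus that in the deficit-negative group; range \[-100, 100\].
#'
#' @inheritParams overlap_map
#' @param labels 0/1 vector aligned with `lesions` (1 = LG+).
#' @return A `volume` of kind "percent".
#' @export
subtraction_map <- function(lesions, labels) {
  labels <- as.integer(labels)
  if (length(labels) != length(lesions))
    stop("labels must align one-to-one with the lesion list")
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop("both groups must be non-empty")
  X <- as_lesion_matrix(lesions)
  g <- lesions[[1]]$grid
  fp <- rowMeans(X[, labels == 1, drop = FALSE])
  fm <- rowMeans(X[, labels == 0, drop = FALSE])
  volume(array(100 * (fp - fm), g$dims), g, "percent")
}

#' Liebermeister quasi-exact p for a 2x2 table
#'
#' One-tailed quasi-exact test for binary lesion status against binary group
#' membership: the cumulative hypergeometric tail probability of the
#' augmented table (a+1, b; c, d+1), i.e. Fisher's one-tailed computation
#' after incrementing the concordant diagonal of the tested direction.
#'
#' @param a LG+ and lesioned; @param b LG- and lesioned;
#' @param c LG+ and intact; @param d LG- and intact (all counts >= 0).
#' @param direction "positive" tests lesion-more-frequent-in-LG+ (concordant
#'   cells a, d); "negative" tests the opposite diagonal.
#' @return One-tailed p-value. Vectorized over table cells.
#' @export
liebermeister_p <- function(a, b, c, d, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d))))
    stop("cell counts must be non-negative integers")
  if (direction == "negative") {
    tmp <- a; a <- b; b <- tmp
    tmp <- c; c <- d; d <- tmp
  }
  aa <- a + 1; dd <- d + 1
  # P(X >= aa) for X hypergeometric at the augmented margins
  stats::phyper(aa - 1, aa + b, c + dd, aa + c, lower.tail = FALSE)
}

#' Convert a one-tailed p to a z-score
#'
#' z = qnorm(1 - p): small p in the tested direction maps to large positive
#' z; p = 0.5 maps to 0. Values of p at 0 or 1 are clamped to
#' `[p_min, 1 - p_min]` to keep z finite.
#'
#' @param p p-value(s) in \[0, 1\].
#' @param p_min clamping bound.
#' @return z value(s).
#' @export
p_to_z <- function(p, p_min = 1e-15) {
  stats::qnorm(1 - pmin(1 - p_min, pmax(p_min, p)))
}

# z lookup table over all (lesioned total m, lesioned-in-LG+ a) cells that a
# voxel can produce for fixed group sizes; rows m = 0..n, cols a = 0..n1.
liebermeister_z_table <- function(n1, n2, direction = "positive") {
  zt <- matrix(NA_real_, n1 + n2 + 1, n1 + 1)
  for (m in 0:(n1 + n2)) {
    for (a in max(0, m - n2):min(m, n1)) {
      p <- liebermeister_p(a, m - a, n1 - a, n2 - (m - a), direction)
      zt[m + 1, a + 1] <- p_to_z(p)
    }
  }
  zt
}

#' Voxelwise Liebermeister statistic map
#'
#' For every voxel inside the analysis mask, builds the 2x2 lesion-by-group
#' contingency table and converts the one-tailed Liebermeister p to a
#' z-score (positive z = lesion more frequent in LG+ under the default
#' direction).
#'
#' @inheritParams subtraction_map
#' @param mask analysis mask `volume`; default: voxels lesioned in at least
#'   one patient.
#' @param direction tested tail, see [liebermeister_p()].
#' @return An object of class `stat_map`: `z` (zscore `volume`, NA outside
#'   the mask), `mask`, `direction`, `n_plus`, `n_minus`.
#' @export
voxelwise_liebermeister <- function(lesions, labels, mask = NULL,
                                    direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  labels <- as.integer(labels)
  if (length(labels) != length(lesions))
    stop("labels must align one-to-one with the lesion list")
  n1 <- sum(labels == 1); n2 <- sum(labels == 0)
  if (n1 == 0 || n2 == 0)
    stop("labels are all identical: association is undefined")
  if (is.null(mask)) mask <- analysis_mask(lesions)
  stop_if_grid_mismatch(lesions[[1]]$grid, mask$grid, "lesions and mask")
  X <- as_lesion_matrix(lesions)
  inmask <- as.vector(mask$values) > 0
  Xm <- X[inmask, , drop = FALSE]
  m <- rowSums(Xm)
  a <- as.vector(Xm %*% (labels == 1))
  zt <- liebermeister_z_table(n1, n2, direction)
  zvals <- zt[cbind(m + 1, a + 1)]
  g <- lesions[[1]]$grid
  zarr <- array(NA_real_, g$dims)
  zarr[inmask] <- zvals
  structure(list(z = volume(zarr, g, "zscore"), mask = mask,
                 direction = direction, n_plus = n1, n_minus = n2),
            class = "stat_map")
}

#' Max-statistic permutation FWE correction for a Liebermeister map
#'
#' Group labels are permuted over patients; for each relabeling the maximum
#' z over the analysis mask is recorded. When the number of distinct
#' relabelings C(n, k) is at most `n_perm` the enumeration is exhaustive
#' (true for the 12-patient 6/6 case: 924 < 4000); otherwise `n_perm`
#' distinct random relabelings are drawn without replacement, always
#' including the observed one. The critical z is the smallest observed value
#' of the max-statistic distribution whose exceedance proportion is <= alpha
#' (conservative under ties; corrected p-values are always >= 1/M).
#'
#' @inheritParams voxelwise_liebermeister
#' @param n_perm requested number of permutations (default 4000).
#' @param alpha family-wise error level (default 0.05).
#' @param seed RNG seed used when sampling relabelings.
#' @return An object of class `perm_result`: `n_perm` (relabelings used),
#'   `exhaustive`, `max_dist`, `critical_z`, `p_fwe` (`volume` of corrected
#'   p, NA outside the mask), `alpha`, `seed`, plus the observed `stat_map`.
#' @export
permutation_fwe <- function(lesions, labels, mask = NULL, n_perm = 4000L,
                            alpha = 0.05, seed = NULL,
                            direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  labels <- as.integer(labels)
  n <- length(labels)
  n1 <- sum(labels == 1)
  if (n1 < 2 || n - n1 < 2)
    stop("need at least 2 members per group for permutation testing")
  if (is.null(mask)) mask <- analysis_mask(lesions)
  stat <- voxelwise_liebermeister(lesions, labels, mask, direction)

  n_total <- choose(n, n1)
  exhaustive <- n_total <= n_perm
  if (exhaustive) {
    combos <- utils::combn(n, n1)
    S <- matrix(0L, n, ncol(combos))
    S[cbind(as.vector(combos),
            rep(seq_len(ncol(combos)), each = n1))] <- 1L
  } else {
    if (!is.null(seed)) set.seed(seed)
    keys <- new.env(hash = TRUE)
    obs_key <- paste(which(labels == 1), collapse = ",")
    assign(obs_key, TRUE, envir = keys)
    picks <- list(which(labels == 1))
    while (length(picks) < n_perm) {
      cand <- sort(sample.int(n, n1))
      key <- paste(cand, collapse = ",")
      if (!exists(key, envir = keys)) {
        assign(key, TRUE, envir = keys)
        picks[[length(picks) + 1L]] <- cand
      }
    }
    S <- matrix(0L, n, n_perm)
    for (j in seq_along(picks)) S[picks[[j]], j] <- 1L
  }
  M <- ncol(S)

  X <- as_lesion_matrix(lesions)
  inmask <- as.vector(mask$values) > 0
  Xm <- X[inmask, , drop = FALSE]
  m <- rowSums(Xm)
  A <- Xm %*% S
  zt <- liebermeister_z_table(n1, n - n1, direction)
  Z <- matrix(zt[cbind(rep(m + 1, M), as.vector(A) + 1)], nrow = nrow(Xm))
  max_dist <- apply(Z, 2, max)

  z_obs <- stat$z$values[inmask]
  p_fwe_vals <- vapply(z_obs, function(z) mean(max_dist >= z), numeric(1))
  g <- lesions[[1]]$grid
  parr <- array(NA_real_, g$dims)
  parr[inmask] <- p_fwe_vals

  vals <- sort(unique(max_dist))
  exceed <- vapply(vals, function(v) mean(max_dist >= v), numeric(1))
  ok <- which(exceed <= alpha)
  critical_z <- if (length(ok)) vals[min(ok)] else Inf

  structure(list(n_perm = M, exhaustive = exhaustive, max_dist = max_dist,
                 critical_z = critical_z,
                 p_fwe = volume(parr, g, "fraction"),
                 alpha = alpha, seed = seed, stat = stat),
            class = "perm_result")
}

#' Extract the significant-voxel seed mask
#'
#' Binary mask of voxels whose observed z reaches the permutation critical
#' z, with 26-connected components labeled and sized (the seed regions for
#' downstream tractography).
#'
#' @param stat a `stat_map` (defaults to the one inside `perm`).
#' @param perm a `perm_result` from the same run.
#' @return List: `mask` (mask `volume`), `components` (integer-labeled
#'   count `volume`), `sizes` (voxels per component).
#' @export
extract_seed_mask <- function(perm, stat = perm$stat) {
  zarr <- stat$z$values
  sig <- !is.na(zarr) & is.finite(perm$critical_z) & zarr >= perm$critical_z
  if (!any(sig))
    warning("no voxel reaches the critical z; seed mask is empty")
  g <- stat$z$grid
  lab <- label_components(sig)
  sizes <- if (any(sig)) as.integer(table(lab[lab > 0])) else integer(0)
  list(mask = volume(array(as.numeric(sig), g$dims), g, "mask"),
       components = volume(array(as.numeric(lab), g$dims), g, "count"),
       sizes = sizes)
}
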