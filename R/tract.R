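#' Streamline visit-count map from probabilistic tractography
#'
#' Wraps a count `volume` with its normalizing constants: the waytotal is
#' `samples_per_voxel * n_seed_voxels`, the total number of streamlines sent
#' out from the seed mask (5000 samples per voxel; seed masks here average a
#' few hundred voxels).
#'
#' @param counts a count `volume` of per-voxel streamline visits.
#' @param n_seed_voxels number of voxels in the seed mask.
#' @param samples_per_voxel streamlines launched per seed voxel (default
#'   5000).
#' @return An object of class `tract_count_map`.
#' @export
tract_count_map <- function(counts, n_seed_voxels, samples_per_voxel = 5000) {
  stopifnot(inherits(counts, "volume"), counts$kind == "count",
            n_seed_voxels >= 0, samples_per_voxel >= 0)
  waytotal <- samples_per_voxel * n_seed_voxels
  if (waytotal <= 0) stop("waytotal must be positive")
  structure(list(counts = counts, n_seed_voxels = n_seed_voxels,
                 samples_per_voxel = samples_per_voxel, waytotal = waytotal),
            class = "tract_count_map")
}

#' Scale a tract map by its waytotal
#'
#' Divides per-voxel streamline counts by the total number of streamlines
#' launched, yielding the fraction of streamlines visiting each voxel. This
#' removes differences between subjects due to differing seed sizes.
#'
#' @param map a [tract_count_map()].
#' @return A `volume` of kind "fraction".
#' @export
scale_tract <- function(map) {
  stopifnot(inherits(map, "tract_count_map"))
  volume(map$counts$values / map$waytotal, map$counts$grid, "fraction")
}

#' Threshold and binarize a scaled tract map
#'
#' Retains voxels receiving at least `tau` of the total streamlines. The
#' default tau = 1e-9 corresponds to the conventional cut of 1e-7 percent of
#' the scaled total (1e-7 % = 1e-9 as a fraction); with waytotals around
#' 4 million this keeps every voxel visited by at least one streamline. Set
#' `tau_is_percent = TRUE` to pass the cut on the percent scale instead.
#'
#' @param scaled a fraction `volume` from [scale_tract()].
#' @param tau threshold, as a fraction unless `tau_is_percent`.
#' @param tau_is_percent interpret `tau` as a percentage.
#' @return A mask `volume` (1 where scaled >= tau).
#' @export
threshold_and_binarize <- function(scaled, tau = 1e-9, tau_is_percent = FALSE) {
  stopifnot(inherits(scaled, "volume"), scaled$kind %in% c("fraction", "mask"))
  if (tau_is_percent) tau <- tau / 100
  keep <- scaled$values > 0 & scaled$values >= tau
  volume(array(as.numeric(keep), scaled$grid$dims), scaled$grid, "mask")
}

#' Group variability map from binarized tract masks
#'
#' Voxelwise mean of the per-subject binary maps: the fraction of subjects
#' (0.0 to 1.0) showing suprathreshold connectivity in each voxel. The
#' display mask keeps voxels exceeding `display_cut` (strictly, per the
#' conventional > 75% cut).
#'
#' @param masks list of mask `volume`s, one per subject, on one grid.
#' @param display_cut display threshold on the subject fraction.
#' @return List of class `group_variability`: `fraction` (fraction
#'   `volume`), `displayed` (mask `volume` of fraction > cut), `n_subjects`,
#'   `display_cut`.
#' @export
group_variability <- function(masks, display_cut = 0.75) {
  stopifnot(length(masks) >= 1)
  g <- masks[[1]]$grid
  for (mk in masks) {
    if (mk$kind != "mask") stop("all inputs must be mask volumes")
    stop_if_grid_mismatch(g, mk$grid, "tract masks")
  }
  X <- vapply(masks, function(v) as.vector(v$values), numeric(prod(g$dims)))
  frac <- rowMeans(X)
  structure(list(
    fraction = volume(array(frac, g$dims), g, "fraction"),
    displayed = volume(array(as.numeric(frac > display_cut), g$dims), g, "mask"),
    n_subjects = length(masks), display_cut = display_cut),
    class = "group_variability")
}
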