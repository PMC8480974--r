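#' Configuration of a synthetic lesion cohort
#'
#' The generator emulates the statistical structure the lesion-symptom
#' analysis assumes: 12 patients and 12 controls; spatially coherent lesion
#' blobs on a common grid whose overlap peaks around a posterior-temporal
#' locus; a critical region such that deficit patients' lesions cover most of
#' it while non-deficit lesions spare it; thresholds elevated roughly
#' tenfold in deficit patients (controls 15-60 ms vs patients 150-600 ms for
#' temporal order); and a selective place-of-articulation error increment in
#' pseudoword and phoneme discrimination.
#'
#' Thresholds are generated on a log scale (the deficit is multiplicative:
#' patient and control ranges differ by an order of magnitude) with a shared
#' latent factor so the two thresholds are positively correlated across
#' observers.
#'
#' @param dims grid dimensions (default 32^3, 1-mm voxels).
#' @param n_patients,n_controls cohort sizes (defaults 12 / 12).
#' @param n_deficit number of deficit patients (default 6, giving the 6/6
#'   split used downstream).
#' @param critical_center voxel coordinates (1-based) of the critical-region
#'   centre; default a posterior-temporal-like locus at ~(0.62, 0.38, 0.45)
#'   of the grid.
#' @param critical_radius radius (voxels) of the spherical critical region.
#' @param lesion_radius_range range of lesion blob radii (voxels) for
#'   non-deficit patients.
#' @param deficit_radius_range radius range for deficit patients' lesions;
#'   default `critical_radius + c(1, 4)`, so each deficit lesion covers the
#'   critical region with an individually varying margin and the territory
#'   shared by all deficit lesions approximates the region itself — the
#'   structure the mapping is meant to recover.
#' @param roughness amplitude of the smooth-noise deformation of the blob
#'   boundary (0 = perfect ellipsoid).
#' @param control_order_range_ms,control_mp_range_ms latent threshold ranges
#'   (ms) for non-deficit observers on the order and micropattern tasks.
#' @param deficit_multiplier multiplicative threshold elevation for deficit
#'   observers (default 10: 15-60 ms maps onto 150-600 ms).
#' @param threshold_corr weight of the shared latent factor inducing the
#'   positive correlation between the two thresholds.
#' @param baseline_error baseline per-feature error rate.
#' @param place_increment additive error-rate increment on
#'   place-of-articulation features (PW and P categories) for deficit
#'   observers.
#' @param measurement_cv lognormal sd of per-subject threshold measurement
#'   noise.
#' @param seed RNG seed; every generator output is deterministic given the
#'   seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(dims = c(32L, 32L, 32L),
                          n_patients = 12L, n_controls = 12L,
                          n_deficit = 6L,
                          critical_center = NULL,
                          critical_radius = 3,
                          lesion_radius_range = c(5, 9),
                          deficit_radius_range = NULL,
                          roughness = 0.3,
                          control_order_range_ms = c(15, 60),
                          control_mp_range_ms = c(5, 40),
                          deficit_multiplier = 10,
                          threshold_corr = 0.6,
                          baseline_error = 0.08,
                          place_increment = 0.35,
                          measurement_cv = 0.08,
                          seed = 1L) {
  dims <- as.integer(dims)
  if (is.null(critical_center))
    critical_center <- round(dims * c(0.62, 0.38, 0.45))
  stopifnot(n_deficit <= n_patients, n_patients >= 0L, n_controls >= 1L,
            critical_radius > 0, all(lesion_radius_range > 0),
            deficit_multiplier > 0, threshold_corr >= 0, threshold_corr <= 1,
            baseline_error >= 0, baseline_error <= 1,
            place_increment >= 0, place_increment <= 1)
  if (is.null(deficit_radius_range))
    deficit_radius_range <- critical_radius + c(1, 4)
  if (critical_radius > max(lesion_radius_range) ||
      critical_radius > max(deficit_radius_range))
    stop("critical region larger than the attainable lesion blob size")
  grid <- voxel_grid(dims, diag(4), "synthetic")
  cfg <- structure(list(
    dims = dims, grid = grid,
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_deficit = as.integer(n_deficit),
    critical_center = critical_center, critical_radius = critical_radius,
    critical_region = NULL,
    lesion_radius_range = lesion_radius_range,
    deficit_radius_range = deficit_radius_range, roughness = roughness,
    control_order_range_ms = control_order_range_ms,
    control_mp_range_ms = control_mp_range_ms,
    deficit_multiplier = deficit_multiplier,
    threshold_corr = threshold_corr,
    baseline_error = baseline_error, place_increment = place_increment,
    measurement_cv = measurement_cv,
    seed = as.integer(seed)), class = "cohort_config")
  cfg$critical_region <- sphere_mask(grid, critical_center, critical_radius)
  if (sum(cfg$critical_region$values) == 0)
    stop("critical region is empty on this grid")
  cfg
}

sphere_mask <- function(grid, center, radius) {
  d <- grid$dims
  dist2 <- outer(outer((seq_len(d[1]) - center[1])^2,
                       (seq_len(d[2]) - center[2])^2, `+`),
                 (seq_len(d[3]) - center[3])^2, `+`)
  volume(array(as.numeric(dist2 <= radius^2), d), grid, "mask")
}

# Separable Gaussian smoothing of a 3-D array (dense kernel matrix per axis;
# grids here are small).
smooth3d <- function(arr, sigma) {
  d <- dim(arr)
  for (ax in 1:3) {
    x <- seq_len(d[ax])
    K <- exp(-outer(x, x, `-`)^2 / (2 * sigma^2))
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dim_a <- dim(a)
    a <- K %*% matrix(a, nrow = d[ax])
    dim(a) <- dim_a
    arr <- aperm(a, order(perm))
  }
  arr
}

# One coherent lesion blob: ellipsoid level-set deformed by smooth noise,
# thresholded, largest 26-connected component kept.
lesion_blob <- function(grid, center, radius, roughness) {
  d <- grid$dims
  radii <- radius * stats::runif(3, 0.75, 1.25)
  dist2 <- outer(outer(((seq_len(d[1]) - center[1]) / radii[1])^2,
                       ((seq_len(d[2]) - center[2]) / radii[2])^2, `+`),
                 ((seq_len(d[3]) - center[3]) / radii[3])^2, `+`)
  f <- 1 - sqrt(dist2)
  if (roughness > 0) {
    noise <- smooth3d(array(stats::rnorm(prod(d)), d), sigma = radius / 2)
    noise <- noise / stats::sd(noise)
    f <- f + roughness * noise
  }
  m <- f > 0
  if (!any(m)) {
    m <- array(FALSE, d)
    m[center[1], center[2], center[3]] <- TRUE
  }
  keep_largest_component(m)
}

region_coverage <- function(mask_arr, region_arr) {
  sum(mask_arr & region_arr) / sum(region_arr)
}

#' Generate synthetic lesion masks plus ground truth
#'
#' Each patient receives one connected binary lesion blob. The first
#' `n_deficit` patients are deficit-positive: their lesions are centred on
#' the critical region and constructed to cover at least 50% of it (by
#' resampling, then union with the region as a last resort). Non-deficit
#' lesions are placed away from the region and cover at most 10% of it
#' (resampling, then carving the region out). Latent observer parameters
#' (log-scale threshold midpoints with a shared correlating factor, slope,
#' lapse) are drawn here for all subjects so that behaviour and lesions stem
#' from one ground truth.
#'
#' @param cfg a [cohort_config()].
#' @return A list with `lesions` (list of mask `volume`s, patients only) and
#'   `truth` (class `ground_truth`: critical region, per-subject observer
#'   table, per-patient deficit flag and lesion/region overlap counts).
#' @export
generate_lesions <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  grid <- cfg$grid
  d <- cfg$dims
  region <- cfg$critical_region$values > 0
  n_region <- sum(region)
  deficit <- c(rep(TRUE, cfg$n_deficit),
               rep(FALSE, cfg$n_patients - cfg$n_deficit))

  lesions <- vector("list", cfg$n_patients)
  overlap <- integer(cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    target_met <- FALSE
    for (try in seq_len(25L)) {
      if (deficit[i]) {
        center <- cfg$critical_center + round(stats::rnorm(3, 0, 1))
        radius <- stats::runif(1, cfg$deficit_radius_range[1],
                               cfg$deficit_radius_range[2])
      } else {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        radius <- stats::runif(1, cfg$lesion_radius_range[1],
                               cfg$lesion_radius_range[2])
        dist <- cfg$critical_radius + radius + 2
        center <- round(cfg$critical_center + dir * dist)
      }
      center <- pmin(pmax(center, 2), d - 1)
      m <- lesion_blob(grid, center, radius, cfg$roughness)
      cov <- region_coverage(m, region)
      if (deficit[i] && cov >= 0.5) { target_met <- TRUE; break }
      if (!deficit[i] && cov <= 0.1) { target_met <- TRUE; break }
    }
    if (!target_met) {
      if (deficit[i]) {
        m <- m | region
        m <- keep_component_containing(m, cfg$critical_center)
      } else {
        m[region] <- FALSE
        m <- keep_largest_component(m)
      }
    }
    lesions[[i]] <- volume(array(as.numeric(m), d), grid, "mask")
    overlap[i] <- sum(m & region)
  }

  n_total <- cfg$n_patients + cfg$n_controls
  subject_id <- c(sprintf("P%02d", seq_len(cfg$n_patients)),
                  sprintf("C%02d", seq_len(cfg$n_controls)))
  group <- rep(c("patient", "control"), c(cfg$n_patients, cfg$n_controls))
  deficit_all <- c(deficit, rep(FALSE, cfg$n_controls))

  # latent observers: shared factor induces positive threshold correlation
  w <- cfg$threshold_corr
  u <- stats::rnorm(n_total)
  e1 <- stats::rnorm(n_total); e2 <- stats::rnorm(n_total)
  q1 <- stats::pnorm(w * u + sqrt(1 - w^2) * e1)
  q2 <- stats::pnorm(w * u + sqrt(1 - w^2) * e2)
  lo <- log(cfg$control_order_range_ms); lm <- log(cfg$control_mp_range_ms)
  mid_order <- exp(lo[1] + q1 * diff(lo))
  mid_mp <- exp(lm[1] + q2 * diff(lm))
  mult <- ifelse(deficit_all, cfg$deficit_multiplier, 1)
  observers <- data.frame(
    subject_id = subject_id, group = group, deficit = deficit_all,
    midpoint_order_ms = mid_order * mult,
    midpoint_mp_ms = mid_mp * mult,
    slope = 8, guess_rate = 0.5, lapse_rate = 0.02,
    stringsAsFactors = FALSE)

  truth <- structure(list(
    critical_region = cfg$critical_region,
    observers = observers,
    deficit = deficit,
    region_overlap_voxels = overlap,
    n_region_voxels = n_region), class = "ground_truth")
  list(lesions = lesions, truth = truth)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate the behavioral table for a synthetic cohort
#'
#' Thresholds are the latent observer midpoints perturbed by lognormal
#' measurement noise and clamped to the presentable SOA range \[2, 1000\] ms.
#' Feature-level error rates are baseline plus Gaussian jitter; deficit
#' observers additionally receive the place-of-articulation increment on the
#' pseudoword and phoneme place features (and half of it on the combined
#' place+voicing feature). Category rates are the mean of their features plus
#' jitter; all rates are clipped to \[0, 1\].
#'
#' @param truth `ground_truth` from [generate_lesions()].
#' @param cfg the same [cohort_config()].
#' @param seed optional seed overriding `cfg$seed + 1` (used to draw
#'   replicate behavioral samples from one lesion ground truth).
#' @return A `behavior_table`.
#' @export
generate_behavior <- function(truth, cfg, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "cohort_config"))
  set.seed(if (is.null(seed)) cfg$seed + 1L else as.integer(seed))
  obs <- truth$observers
  n <- nrow(obs)
  noise <- function() exp(stats::rnorm(n, 0, cfg$measurement_cv))
  thr_order <- pmin(1000, pmax(2, obs$midpoint_order_ms * noise()))
  thr_mp <- pmin(1000, pmax(2, obs$midpoint_mp_ms * noise()))

  base <- cfg$baseline_error
  inc <- ifelse(obs$deficit, cfg$place_increment, 0)
  jit <- function(sd = 0.03) stats::rnorm(n, 0, sd)
  feat <- list(
    err_place_W = clip01(base + jit()),
    err_manner_W = clip01(base + jit()),
    err_place_PW = clip01(base + inc + jit()),
    err_manner_PW = clip01(base + jit()),
    err_place_P = clip01(base + inc + jit()),
    err_fricative_P = clip01(base + jit()),
    err_voice_P = clip01(base + jit()),
    err_place_voice_P = clip01(base + 0.5 * inc + jit()))
  cat_rate <- function(members) clip01(Reduce(`+`, feat[members]) / length(members) + jit(0.02))
  tab <- data.frame(
    subject_id = obs$subject_id, group = obs$group,
    order_threshold_ms = thr_order, micropattern_threshold_ms = thr_mp,
    err_W = cat_rate(c("err_place_W", "err_manner_W")),
    err_PW = cat_rate(c("err_place_PW", "err_manner_PW")),
    err_P = cat_rate(c("err_place_P", "err_fricative_P", "err_voice_P",
                       "err_place_voice_P")),
    stringsAsFactors = FALSE)
  for (nm in names(feat)) tab[[nm]] <- feat[[nm]]
  as_behavior_table(tab)
}

#' Build the standard small test cohort
#'
#' A deterministic 32 x 32 x 32 cohort of 12 patients (6 deficit) and 12
#' controls, regenerated from code wherever it is needed.
#'
#' @param seed RNG seed.
#' @param dims grid dimensions.
#' @param ... further arguments passed to [cohort_config()].
#' @return List with `lesions`, `behavior`, `truth`, `config`.
#' @export
make_fixture <- function(seed = 42L, dims = c(32L, 32L, 32L), ...) {
  cfg <- cohort_config(dims = dims, seed = seed, ...)
  gl <- generate_lesions(cfg)
  behavior <- generate_behavior(gl$truth, cfg)
  list(lesions = gl$lesions, behavior = behavior, truth = gl$truth,
       config = cfg)
}
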