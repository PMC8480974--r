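#' Common voxel grid for an analysis
#'
#' All volumes entering a single lesion-mapping analysis must live on one
#' raster: same dimensions and same voxel-to-world affine. World coordinates
#' (typically MNI millimetres) are obtained exclusively through the affine;
#' voxel indices are 0-based in world conversions, matching the NIfTI
#' convention.
#'
#' @param dims integer vector of length 3, voxel counts per axis (all >= 1).
#' @param affine 4x4 invertible matrix mapping 0-based voxel indices to
#'   world mm.
#' @param space_label free-text space tag (e.g. "MNI152"); metadata only,
#'   never interpreted.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, affine = diag(4), space_label = "unknown") {
  dims <- as.integer(dims)
  if (length(dims) != 3L || anyNA(dims) || any(dims < 1L))
    stop("`dims` must be three positive integers")
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) || anyNA(affine))
    stop("`affine` must be a numeric 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    stop("`affine` must be invertible")
  structure(list(dims = dims, affine = affine, space_label = space_label),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d [%s]\n",
              x$dims[1], x$dims[2], x$dims[3], x$space_label))
  invisible(x)
}

#' Test two grids for compatibility
#'
#' @param g1,g2 `voxel_grid` objects.
#' @param tol absolute tolerance (mm) on affine entries.
#' @return Logical scalar.
#' @export
grids_compatible <- function(g1, g2, tol = 1e-6) {
  all(g1$dims == g2$dims) && max(abs(g1$affine - g2$affine)) <= tol
}

stop_if_grid_mismatch <- function(g1, g2, what = "volumes") {
  if (!grids_compatible(g1, g2))
    stop(sprintf("grid mismatch between %s: dims/affine differ beyond tolerance; resampling is never performed implicitly", what))
  invisible(TRUE)
}

#' A scalar 3-D volume on a voxel grid
#'
#' Carries per-voxel values of a declared kind. Kinds enforce invariants:
#' `mask` volumes hold only 0/1, `count` volumes non-negative integers,
#' `fraction` volumes values in \[0, 1\]; `percent` and `zscore` maps may
#' contain `NA` outside their analysis mask.
#'
#' @param values numeric 3-D array with `dim(values) == grid$dims`.
#' @param grid a [voxel_grid()].
#' @param kind one of "mask", "count", "percent", "zscore", "fraction".
#' @return An object of class `volume`.
#' @export
volume <- function(values, grid,
                   kind = c("mask", "count", "percent", "zscore", "fraction")) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (!all(dim(values) == grid$dims))
    stop("`values` dimensions do not match the grid")
  v <- structure(list(values = values, grid = grid, kind = kind),
                 class = "volume")
  validate_volume(v)
  v
}

validate_volume <- function(vol) {
  x <- vol$values
  switch(vol$kind,
    mask = {
      if (anyNA(x) || !all(x %in% c(0, 1)))
        stop("mask volume must contain only 0/1 values")
    },
    count = {
      if (anyNA(x) || any(x < 0) || any(x != round(x)))
        stop("count volume must contain non-negative integers")
    },
    fraction = {
      xx <- x[!is.na(x)]
      if (any(xx < 0 | xx > 1))
        stop("fraction volume values must lie in [0, 1]")
    },
    percent = ,
    zscore = {
      if (any(is.infinite(x)))
        stop(sprintf("%s volume must be finite where defined", vol$kind))
    })
  invisible(vol)
}

#' @export
print.volume <- function(x, ...) {
  n <- sum(x$values != 0, na.rm = TRUE)
  cat(sprintf("<volume:%s> %d x %d x %d, %d non-zero voxels\n",
              x$kind, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], n))
  invisible(x)
}

nifti_datatype <- function(kind) {
  switch(kind, mask = "uint8", count = "int32", "float")
}

#' Read a binary lesion mask from a NIfTI-1 file
#'
#' Any strictly positive voxel value is mapped to 1 (lesion masks from
#' delineation tools are sometimes stored with arbitrary positive labels).
#' The grid is taken from the file's xform (sform preferred).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param space_label space tag to attach to the grid.
#' @return A `volume` of kind "mask".
#' @export
read_mask_volume <- function(path, space_label = "unknown") {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot read NIfTI file '%s': %s",
                                                   path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D image, got %d dimensions", length(d)))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  g <- voxel_grid(d, aff, space_label)
  vals <- array(as.numeric(img > 0), dim = d)
  volume(vals, g, "mask")
}

#' Read any scalar NIfTI volume
#'
#' @inheritParams read_mask_volume
#' @param kind value kind to assign (validated).
#' @return A `volume`.
#' @export
read_volume <- function(path, kind = "zscore", space_label = "unknown") {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot read NIfTI file '%s': %s",
                                                   path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D image, got %d dimensions", length(d)))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume(array(as.numeric(img), dim = d), voxel_grid(d, aff, space_label), kind)
}

#' Write a volume to a NIfTI-1 file
#'
#' Masks are written as unsigned 8-bit, counts as signed 32-bit integers and
#' real-valued maps as 32-bit float, matching common lesion-mapping tool
#' output. `NA` values in stat maps are written as 0.
#'
#' @param vol a `volume`.
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  validate_volume(vol)
  vals <- vol$values
  vals[is.na(vals)] <- 0
  img <- RNifti::asNifti(vals)
  xf <- structure(vol$grid$affine, code = 2L)
  RNifti::sform(img) <- xf
  RNifti::qform(img) <- xf
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = nifti_datatype(vol$kind))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write NIfTI file '%s'", path))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Behavioral table

#' Column schema of the behavioral table
#'
#' Two threshold columns (ms) and eleven error-rate columns: three stimulus
#' categories (words W, pseudowords PW, phonemes P) and eight contrastive
#' features within category (place/manner of articulation for W and PW;
#' place, fricative, voicing and combined place+voicing for P).
#'
#' @return Character vector of required column names, in canonical order.
#' @export
behavior_columns <- function() {
  c("subject_id", "group",
    "order_threshold_ms", "micropattern_threshold_ms",
    "err_W", "err_PW", "err_P",
    "err_place_W", "err_manner_W",
    "err_place_PW", "err_manner_PW",
    "err_place_P", "err_fricative_P", "err_voice_P", "err_place_voice_P")
}

behavior_rate_columns <- function() behavior_columns()[5:15]
behavior_threshold_columns <- function() behavior_columns()[3:4]

validate_behavior_table <- function(tab) {
  need <- behavior_columns()
  unknown <- setdiff(names(tab), need)
  if (length(unknown))
    stop(sprintf("unknown column(s) in behavior table: %s",
                 paste(unknown, collapse = ", ")))
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop(sprintf("missing column(s) in behavior table: %s",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(tab$subject_id))
    stop("subject_id values must be unique")
  if (!all(tab$group %in% c("patient", "control")))
    stop('group must be "patient" or "control"')
  for (cl in behavior_threshold_columns()) {
    v <- tab[[cl]]
    bad <- !is.na(v) & (v < 2 | v > 1000)
    if (any(bad))
      stop(sprintf("%s outside the presentable SOA range [2, 1000] ms", cl))
  }
  for (cl in behavior_rate_columns()) {
    v <- tab[[cl]]
    bad <- !is.na(v) & (v < 0 | v > 1)
    if (any(bad))
      stop(sprintf("%s outside [0, 1]", cl))
  }
  invisible(tab)
}

#' Read a behavioral table from delimited text
#'
#' Comma-separated, UTF-8, header row with the exact column set of
#' [behavior_columns()]. Empty cells become `NA` (explicit missing, never
#' zero); downstream tests shrink their N accordingly.
#'
#' @param path CSV file path.
#' @return A validated `data.frame` of class `behavior_table`.
#' @export
read_behavior_table <- function(path) {
  tab <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  tab <- tab[, , drop = FALSE]
  validate_behavior_table(tab)
  tab <- tab[, behavior_columns()]
  class(tab) <- c("behavior_table", "data.frame")
  tab
}

#' Construct a behavioral table from a data.frame
#'
#' @param df data.frame holding all columns of [behavior_columns()].
#' @return Validated `behavior_table`.
#' @export
as_behavior_table <- function(df) {
  validate_behavior_table(df)
  df <- df[, behavior_columns()]
  class(df) <- c("behavior_table", "data.frame")
  df
}

#' Write a behavioral table to CSV
#'
#' @param tab a `behavior_table`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_behavior_table <- function(tab, path) {
  validate_behavior_table(tab)
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
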