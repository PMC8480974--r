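# 3-D connected components under 26-connectivity, by iterative minimum-label
# propagation (vectorized array shifts; grids in this package are small).

shift3 <- function(a, off, fill = Inf) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    k <- off[ax]
    if (k >= 0) {
      if (k >= d[ax]) return(out)
      src[[ax]] <- seq_len(d[ax] - k)
      dst[[ax]] <- seq_len(d[ax] - k) + k
    } else {
      if (-k >= d[ax]) return(out)
      src[[ax]] <- seq_len(d[ax] + k) - k
      dst[[ax]] <- seq_len(d[ax] + k)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Label 26-connected components of a 3-D mask
#'
#' @param mask logical or 0/1 numeric 3-D array.
#' @return Integer array of the same shape: 0 background, components numbered
#'   1..k in decreasing size order.
#' @export
label_components <- function(mask) {
  mask <- array(mask > 0, dim = dim(mask))
  d <- dim(mask)
  L <- array(Inf, d)
  L[mask] <- which(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(offs))) {
      Ls <- shift3(L, offs[r, ])
      cand <- pmin(L, Ls)
      cand[!mask] <- Inf
      if (any(cand < L)) {
        L <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab <- array(0L, d)
  if (any(mask)) {
    roots <- L[mask]
    sizes <- table(roots)
    ord <- names(sizes)[order(-as.integer(sizes))]
    lab[mask] <- match(as.character(roots), ord)
  }
  lab
}

keep_largest_component <- function(mask) {
  lab <- label_components(mask)
  lab == 1L & any(lab > 0)
}

keep_component_containing <- function(mask, voxel) {
  lab <- label_components(mask)
  id <- lab[voxel[1], voxel[2], voxel[3]]
  if (id == 0L) return(lab == 1L & any(lab > 0))
  lab == id
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b mask `volume`s or 0/1 arrays on the same grid.
#' @return 2|A n B| / (|A| + |B|); 1 if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "volume")) {
    if (inherits(b, "volume")) stop_if_grid_mismatch(a$grid, b$grid, "masks")
    a <- a$values
  }
  if (inherits(b, "volume")) b <- b$values
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
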