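# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and base R shortcuts the package itself uses), so that
# agreement is a genuine cross-check.

# Mann-Whitney U of x vs y by direct pair counting.
oracle_u_stat <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exact one/two-sided Mann-Whitney p by enumerating all label assignments.
oracle_mw_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_null <- apply(idx, 2, function(ii) oracle_u_stat(pooled[ii], pooled[-ii]))
  u_obs <- oracle_u_stat(x, y)
  pg <- mean(u_null >= u_obs)
  pl <- mean(u_null <= u_obs)
  switch(alternative,
         greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# Exact signed-rank p by enumerating every sign pattern of the non-zero
# differences (mid-ranks on |d|).
oracle_wsr_p <- function(d, alternative) {
  d <- d[d != 0]
  m <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  w_null <- numeric(2^m)
  for (code in 0:(2^m - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    w_null[code + 1] <- sum(rk[bits == 1])
  }
  pg <- mean(w_null >= w_obs)
  pl <- mean(w_null <= w_obs)
  switch(alternative,
         greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# Liebermeister one-tailed p by explicit hypergeometric summation over the
# augmented table (a+1, b; c, d+1): sum the point probabilities of all
# tables at those margins with first cell >= a+1.
oracle_lieb_p <- function(a, b, c, d) {
  aa <- a + 1; dd <- d + 1
  r1 <- aa + b; c1 <- aa + c; N <- aa + b + c + dd
  xs <- max(0, c1 - (N - r1)):min(r1, c1)
  term <- function(x) exp(lchoose(r1, x) + lchoose(N - r1, c1 - x) - lchoose(N, c1))
  sum(vapply(xs[xs >= aa], term, numeric(1)))
}

# Tiny-scale permutation FWE by direct loops: returns max-z distribution and
# observed z map, using oracle_lieb_p throughout.
oracle_perm_max <- function(lesmat, labels, inmask) {
  n <- length(labels); n1 <- sum(labels == 1)
  combos <- utils::combn(n, n1)
  zmax <- numeric(ncol(combos))
  for (j in seq_len(ncol(combos))) {
    lab <- integer(n); lab[combos[, j]] <- 1L
    zbest <- -Inf
    for (v in which(inmask)) {
      les <- lesmat[v, ]
      a <- sum(les == 1 & lab == 1); b <- sum(les == 1 & lab == 0)
      c_ <- sum(les == 0 & lab == 1); d <- sum(les == 0 & lab == 0)
      z <- qnorm(1 - min(1 - 1e-15, max(1e-15, oracle_lieb_p(a, b, c_, d))))
      zbest <- max(zbest, z)
    }
    zmax[j] <- zbest
  }
  zmax
}

# Rank correlation computed from first principles (Pearson on ranks).
oracle_rank_corr <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
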