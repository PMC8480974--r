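#' Container for a non-parametric test result
#'
#' @param statistic_name one of "U", "W", "Z", "chi2", "rho", "p_fisher".
#' @param statistic_value observed statistic.
#' @param z_value standard-normal equivalent (NA where not defined).
#' @param p_value p-value.
#' @param sidedness "one" or "two".
#' @param effect_size_r effect size r = |Z|/sqrt(N), reported as magnitude.
#' @param n_effective sample size entering the effect-size denominator.
#' @param method short description.
#' @return An object of class `npar_test`.
#' @keywords internal
npar_test <- function(statistic_name, statistic_value, z_value, p_value,
                      sidedness, effect_size_r, n_effective, method = "") {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic_name = statistic_name,
                 statistic_value = statistic_value,
                 z_value = z_value, p_value = min(p_value, 1),
                 sidedness = sidedness,
                 effect_size_r = effect_size_r,
                 n_effective = n_effective, method = method),
            class = "npar_test")
}

#' @export
print.npar_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, Z = %.3f, p = %.4g (%s-sided), r = %.3f, N = %d\n",
              x$method, x$statistic_name, x$statistic_value,
              if (is.na(x$z_value)) NA else x$z_value, x$p_value,
              x$sidedness, x$effect_size_r, x$n_effective))
  invisible(x)
}

#' Normal approximation z for a Mann-Whitney U
#'
#' z = (U - n1 n2 / 2) / sqrt(n1 n2 (n1 + n2 + 1) / 12), untied variance,
#' no continuity correction. This is the mapping under which the published
#' (U, r) pairs for 12-vs-12 comparisons reproduce exactly (e.g. U = 114
#' gives z = 2.425 and r = 0.495 with N = 24).
#'
#' @param U observed U (0 <= U <= n1*n2; mid-rank U may be half-integer).
#' @param n1,n2 group sizes.
#' @return Signed z value.
#' @export
u_to_z <- function(U, n1, n2) {
  if (U < 0 || U > n1 * n2) stop("U out of range [0, n1*n2]")
  (U - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
}

#' Effect size r from a z value
#'
#' r = |z| / sqrt(N). N is the pooled sample size for between-group or
#' pooled analyses and the group size for within-group analyses.
#'
#' @param z z value (sign ignored).
#' @param n_effective denominator sample size (>= 1).
#' @return r in \[0, 1\] for any z arising from these tests.
#' @export
effect_size_r <- function(z, n_effective) {
  if (n_effective < 1) stop("n_effective must be >= 1")
  abs(z) / sqrt(n_effective)
}

#' Mann-Whitney U test with exact small-sample p-values
#'
#' U counts pairs (x_i, y_j) with x_i > y_j (plus half-ties), computed via
#' mid-ranks. The p-value is exact (full U null distribution) when
#' n1 + n2 <= `exact_limit` and there are no ties; otherwise the normal
#' approximation with tie-corrected variance and no continuity correction is
#' used. The z value (and hence r = |z|/sqrt(n1+n2)) is always reported from
#' the normal approximation.
#'
#' @param x,y numeric samples (NAs dropped).
#' @param alternative "two.sided", "greater" (x tends larger) or "less".
#' @param exact_limit switchover total sample size for the exact path.
#' @return An `npar_test` with `statistic_name = "U"`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         exact_limit = 20L) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))

  # tie-corrected normal approximation (reduces to untied formula otherwise)
  n <- n1 + n2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) (U - n1 * n2 / 2) / sqrt(sigma2) else 0

  if (!ties && n <= exact_limit) {
    p_greater <- 1 - stats::pwilcox(U - 1, n1, n2)
    p_less <- stats::pwilcox(U, n1, n2)
    p <- switch(alternative,
                greater = p_greater, less = p_less,
                two.sided = min(1, 2 * min(p_greater, p_less)))
    method <- "Mann-Whitney U (exact)"
  } else {
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    method <- "Mann-Whitney U (normal approximation)"
  }
  npar_test("U", U, z, p,
            if (alternative == "two.sided") "two" else "one",
            effect_size_r(z, n), n, method)
}

#' Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Zero differences are dropped; mid-ranks are assigned on |d|. The exact
#' p-value enumerates all 2^m sign patterns when the number of non-zero
#' pairs m <= `exact_limit` (valid under ties in |d|); otherwise the normal
#' approximation with tie correction is used. The effect size uses
#' r = |z| / sqrt(N) with N = the number of subjects in the tested set
#' (pairs before dropping zeros), the convention of within-group reports.
#'
#' @param x,y paired samples of equal length (pairs with any NA dropped).
#' @param alternative "two.sided", "greater" (x tends larger) or "less".
#' @param exact_limit switchover number of non-zero pairs.
#' @return An `npar_test` with `statistic_name = "W"` (sum of positive
#'   ranks).
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_limit = 15L) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("paired samples must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n_subjects <- length(x)
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) stop("all differences are zero: signed-rank test undefined")
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])

  mu <- m * (m + 1) / 4
  tie_tab <- table(abs(d))
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0

  if (m <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    null_w <- as.vector(signs %*% rk)
    p_greater <- mean(null_w >= W)
    p_less <- mean(null_w <= W)
    p <- switch(alternative,
                greater = p_greater, less = p_less,
                two.sided = min(1, 2 * min(p_greater, p_less)))
    method <- "Wilcoxon signed-rank (exact enumeration)"
  } else {
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  npar_test("W", W, z, p,
            if (alternative == "two.sided") "two" else "one",
            effect_size_r(z, n_subjects), n_subjects, method)
}

#' Friedman rank test for repeated measures
#'
#' Mid-ranks within each subject; chi-square statistic
#' 12/(n k (k+1)) * sum_j (R_j - n(k+1)/2)^2 divided by the tie-correction
#' factor 1 - sum(t^3 - t) / (n k (k^2 - 1)); df = k - 1. With all values
#' tied within every subject the statistic is defined as 0.
#'
#' @param data numeric matrix, subjects in rows, conditions in columns, no
#'   missing cells.
#' @return An `npar_test` with `statistic_name = "chi2"` and a `df` field.
#' @export
friedman <- function(data) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("Friedman test requires complete cells")
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  R <- t(apply(data, 1, rank))
  Rj <- colSums(R)
  stat <- 12 / (n * k * (k + 1)) * sum((Rj - n * (k + 1) / 2)^2)
  tie_sum <- sum(apply(data, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  C <- 1 - tie_sum / (n * k * (k^2 - 1))
  stat <- if (C > 0) stat / C else 0
  df <- k - 1
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  out <- npar_test("chi2", stat, NA_real_, p, "two",
                   NA_real_, n, "Friedman rank test")
  out$df <- df
  out
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of mid-ranks; exact permutation p for n <= 9 without
#' ties (via [stats::cor.test()]), t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3 (pairs with NA dropped).
#' @param alternative "two.sided", "greater" (increasing relation) or
#'   "less".
#' @param exact_limit maximum n for the exact permutation p.
#' @return An `npar_test` with `statistic_name = "rho"`.
#' @export
spearman_rho <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         exact_limit = 9L) {
  alternative <- match.arg(alternative)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ties <- any(duplicated(x)) || any(duplicated(y))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = alternative,
                    exact = (!ties && n <= exact_limit)))
  rho <- unname(ct$estimate)
  npar_test("rho", rho, NA_real_, ct$p.value,
            if (alternative == "two.sided") "two" else "one",
            abs(rho), n, "Spearman rank-order correlation")
}

#' Fisher's exact test for a 2x2 table
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative "two.sided", "greater" or "less" (association
#'   direction of the \[1,1\] cell).
#' @return An `npar_test` with `statistic_name = "p_fisher"`.
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table)))
    stop("`table` must be a 2x2 matrix of non-negative integer counts")
  ft <- stats::fisher.test(table, alternative = alternative)
  npar_test("p_fisher", ft$p.value, NA_real_, ft$p.value,
            if (alternative == "two.sided") "two" else "one",
            NA_real_, sum(table), "Fisher's exact test")
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level.
#' @param k number of comparisons (>= 1).
#' @return alpha / k (e.g. 0.05/3 = 0.0167, 0.05/6 = 0.00833).
#' @export
bonferroni_level <- function(alpha, k) {
  if (k < 1) stop("k must be >= 1")
  alpha / k
}
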