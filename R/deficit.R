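#' Subtests entering the deficit-classification rule
#'
#' Two non-speech subtests (temporal-order and micropattern thresholds) and
#' three speech subtests (word, pseudoword and phoneme discrimination error
#' rates). All are oriented worse-high, so a positive z means worse than
#' controls. Feature-level error rates are excluded from classification.
#'
#' @return Character vector of column names.
#' @export
classification_subtests <- function() {
  c("order_threshold_ms", "micropattern_threshold_ms",
    "err_W", "err_PW", "err_P")
}

#' Control-referenced z-scores for every patient and subtest
#'
#' z = (patient value - control mean) / control SD, per subtest, using the
#' non-missing control values. Thresholds and error rates are already
#' worse-high, so no reorientation is applied. Values > 0 indicate worse
#' performance than controls.
#'
#' @param tab a `behavior_table`.
#' @param subtests subtest columns (default [classification_subtests()]).
#' @return Numeric matrix, patients in rows (named by subject_id), subtests
#'   in columns; NA where the patient's value is missing.
#' @export
zscores_vs_controls <- function(tab, subtests = classification_subtests()) {
  validate_behavior_table(tab)
  ctrl <- tab[tab$group == "control", , drop = FALSE]
  pat <- tab[tab$group == "patient", , drop = FALSE]
  if (nrow(pat) == 0) stop("no patients in table")
  z <- matrix(NA_real_, nrow(pat), length(subtests),
              dimnames = list(pat$subject_id, subtests))
  for (s in subtests) {
    v <- ctrl[[s]]
    v <- v[!is.na(v)]
    if (length(v) < 2)
      stop(sprintf("subtest %s: need at least 2 non-missing control values", s))
    sdv <- stats::sd(v)
    if (sdv == 0)
      stop(sprintf("subtest %s: control SD is zero, z-scores undefined", s))
    z[, s] <- (pat[[s]] - mean(v)) / sdv
  }
  z
}

#' Split patients into deficit-positive and -negative groups
#'
#' A patient is deficit-positive (LG+) when performing outside `cutoff`
#' control SDs, in the worse direction, on at least `min_subtests` subtests;
#' remaining patients form LG-. The rule is one-sided by default (z strictly
#' greater than +cutoff counts as impaired; worse performance only);
#' `two_sided = TRUE` counts |z| > cutoff. Missing subtest z-scores count as
#' not impaired.
#'
#' @param z z-score matrix from [zscores_vs_controls()].
#' @param cutoff SD cutoff (default 2).
#' @param min_subtests minimum impaired subtests for LG+ (default 2).
#' @param two_sided use |z| > cutoff instead of z > cutoff.
#' @return A data.frame of class `deficit_profiles`: subject_id, per-subtest
#'   impaired flags, `n_impaired`, `group_label` ("LG_plus"/"LG_minus"),
#'   with the z matrix attached as attribute `z`.
#' @export
classify_deficit <- function(z, cutoff = 2, min_subtests = 2L,
                             two_sided = FALSE) {
  imp <- if (two_sided) abs(z) > cutoff else z > cutoff
  imp[is.na(imp)] <- FALSE
  n_imp <- rowSums(imp)
  out <- data.frame(subject_id = rownames(z),
                    n_impaired = as.integer(n_imp),
                    group_label = ifelse(n_imp >= min_subtests,
                                         "LG_plus", "LG_minus"),
                    stringsAsFactors = FALSE)
  for (s in colnames(z)) out[[paste0("impaired_", s)]] <- imp[, s]
  attr(out, "z") <- z
  class(out) <- c("deficit_profiles", "data.frame")
  out
}

#' Binomial labels (1 = LG+, 0 = LG-) aligned to the lesion-mask list
#'
#' @param profiles `deficit_profiles` from [classify_deficit()].
#' @param subject_ids subject order of the lesion-mask list; must be exactly
#'   the profiled patients.
#' @return Integer vector of 0/1, named by subject.
#' @export
labels_to_binomial <- function(profiles, subject_ids = profiles$subject_id) {
  if (!setequal(subject_ids, profiles$subject_id) ||
      length(subject_ids) != nrow(profiles))
    stop("subject_ids do not match the classified patients")
  idx <- match(subject_ids, profiles$subject_id)
  stats::setNames(as.integer(profiles$group_label[idx] == "LG_plus"),
                  subject_ids)
}
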