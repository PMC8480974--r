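#' Full lesion-symptom mapping pipeline
#'
#' Runs the analysis chain on a cohort: control-referenced z-scores, 2-SD
#' deficit classification into LG+/LG-, binomial labels, lesion overlap and
#' subtraction maps, the voxelwise Liebermeister map restricted to voxels
#' lesioned in at least one patient, max-statistic permutation FWE
#' correction, and seed-mask extraction.
#'
#' @param lesions list of patient lesion mask `volume`s (one per patient,
#'   ordered as the behavior table's patients).
#' @param behavior a `behavior_table` with these patients and the controls.
#' @param cutoff,min_subtests deficit rule parameters, see
#'   [classify_deficit()].
#' @param n_perm,alpha,seed,direction permutation parameters, see
#'   [permutation_fwe()].
#' @return List: `z` (patient x subtest matrix), `profiles`, `labels`,
#'   `overlap`, `subtraction` (NULL when a group is empty), `perm`
#'   (`perm_result` or NULL when labels are degenerate), `seed_mask`.
#' @export
lesion_symptom_pipeline <- function(lesions, behavior, cutoff = 2,
                                    min_subtests = 2L, n_perm = 4000L,
                                    alpha = 0.05, seed = NULL,
                                    direction = "positive") {
  z <- zscores_vs_controls(behavior)
  profiles <- classify_deficit(z, cutoff = cutoff, min_subtests = min_subtests)
  pat_ids <- behavior$subject_id[behavior$group == "patient"]
  if (length(pat_ids) != length(lesions))
    stop("one lesion mask per patient is required, in table order")
  labels <- labels_to_binomial(profiles, pat_ids)
  ov <- overlap_map(lesions)
  degenerate <- sum(labels == 1) < 2 || sum(labels == 0) < 2
  sub <- if (sum(labels == 1) > 0 && sum(labels == 0) > 0)
    subtraction_map(lesions, labels) else NULL
  perm <- NULL; seed_mask <- NULL
  if (!degenerate) {
    perm <- permutation_fwe(lesions, labels, n_perm = n_perm, alpha = alpha,
                            seed = seed, direction = direction)
    seed_mask <- extract_seed_mask(perm)
  }
  list(z = z, profiles = profiles, labels = labels, overlap = ov,
       subtraction = sub, perm = perm, seed_mask = seed_mask)
}
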