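#' Tidy per-drug FM scores
#' @param x A `fam_fm` object.
#' @param ... Unused.
#' @return Tibble with one row per scored drug.
#' @export
tidy.fam_fm <- function(x, ...) x$scores

#' @rdname tidy.fam_fm
#' @export
glance.fam_fm <- function(x, ...) {
  tibble(n_drugs = nrow(x$scores), n_unscoreable = length(x$unscoreable),
         n_perm = x$n_perm, seed = x$seed,
         mean_fm_z = mean(x$scores$fm_z), sd_fm_z = stats::sd(x$scores$fm_z))
}

#' Tidy per-drug AC scores
#' @param x A `fam_ac` object.
#' @param ... Unused.
#' @return Tibble with one row per scored drug.
#' @export
tidy.fam_ac <- function(x, ...) x$scores

#' @rdname tidy.fam_ac
#' @export
glance.fam_ac <- function(x, ...) {
  tibble(n_drugs = nrow(x$scores), n_excluded = nrow(x$excluded),
         min_overlap = x$min_overlap,
         mean_distance = mean(x$scores$cosine_distance))
}

#' Tidy under-sampled AUROC repetitions
#' @param x A `fam_auroc` object.
#' @param ... Unused.
#' @return Tibble with one row per repetition.
#' @export
tidy.fam_auroc <- function(x, ...) {
  tibble(rep = seq_along(x$reps), auroc = x$reps)
}

#' @rdname tidy.fam_auroc
#' @export
glance.fam_auroc <- function(x, ...) {
  tibble(mean_auroc = x$mean_auroc, sd_auroc = x$sd_auroc,
         n_reps = x$n_reps, n_pos = x$n_pos, undersampled = x$undersampled)
}

#' Tidy a permutation test
#' @param x A `fam_permutation` object.
#' @param ... Unused.
#' @return One-row tibble with the observed statistic and P-value.
#' @export
tidy.fam_permutation <- function(x, ...) {
  tibble(observed_stat = x$observed_stat, p_value = x$p_value,
         n_perm = x$n_perm, direction = x$direction)
}

#' Tidy the leave-one-out stability report
#' @param x A `fam_stability` object.
#' @param ... Unused.
#' @return Tibble with one row per excluded gene.
#' @export
tidy.fam_stability <- function(x, ...) x$report

#' @rdname tidy.fam_stability
#' @export
glance.fam_stability <- function(x, ...) {
  if (nrow(x$report) == 0) {
    return(tibble(top_k = x$top_k, min_tau = NA_real_, max_tau = NA_real_))
  }
  tibble(top_k = x$top_k, min_tau = min(x$report$tau),
         max_tau = max(x$report$tau))
}

#' Tidy the standard-method baseline
#' @param x A `fam_baseline` object.
#' @param ... Unused.
#' @return One-row tibble with recall, precision and F-score.
#' @export
tidy.fam_baseline <- function(x, ...) {
  tibble(recall = x$recall, precision = x$precision, f_score = x$f_score,
         n_predicted = length(x$predicted_set),
         empty_prediction = x$empty_prediction)
}
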