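#' Extract a named score vector from a drug score table
#'
#' @param table A `drug_score_table`.
#' @param metric Column to extract (default `"fam"`); unranked drugs
#'   (missing the metric) are dropped.
#' @return Named numeric vector of scores keyed by drug id.
#' @export
score_vector <- function(table, metric = "fam") {
  tab <- filter(table, !is.na(.data[[metric]]))
  setNames(tab[[metric]], tab$drug_id)
}

#' Area under the ROC curve for a drug scoring
#'
#' Computed as the Mann-Whitney U statistic of positive versus negative
#' scores divided by `n_pos * n_neg`; tied scores contribute 1/2, so the
#' value equals the trapezoidal AUROC with tie correction. 1 means every
#' positive outscores every negative; 0.5 is chance.
#'
#' @param scores Named numeric vector of scores (names are drug ids).
#' @param positives,negatives Disjoint character vectors of drug ids, all
#'   present in `scores`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, positives, negatives) {
  if (length(intersect(positives, negatives)) > 0) {
    abort("positives and negatives overlap")
  }
  if (length(positives) == 0 || length(negatives) == 0) {
    abort("positives and negatives must be nonempty")
  }
  missing <- setdiff(c(positives, negatives), names(scores))
  if (length(missing) > 0) {
    abort(paste0("unscored drugs: ", paste(head(missing, 5), collapse = ", ")))
  }
  x <- scores[positives]
  y <- scores[negatives]
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  u / (length(x) * length(y))
}

#' Class-imbalance corrected AUROC by random under-sampling
#'
#' Because effective drugs are a small fraction of all drugs, the AUROC for
#' discriminating them from everything else is estimated by repeated random
#' under-sampling: each repetition uses all positives against an equal-size
#' random sample of the remaining drugs, and the mean and standard
#' deviation over repetitions are reported. Deterministic given `seed`.
#'
#' @inheritParams auroc
#' @param all_drugs Universe to sample negatives from (default: all scored
#'   drugs); must leave at least `length(positives)` non-positives.
#' @param n_reps Number of under-sampling repetitions (default 1000).
#' @param seed Integer seed.
#' @return An object of class `fam_auroc`: list with `mean_auroc`,
#'   `sd_auroc`, `reps` (per-repetition values), `n_reps`, `n_pos`,
#'   `undersampled = TRUE`.
#' @export
undersampled_auroc <- function(scores, positives, all_drugs = names(scores),
                               n_reps = 1000, seed) {
  if (n_reps < 2) abort("n_reps must be >= 2")
  positives <- intersect(positives, names(scores))
  pool <- setdiff(intersect(all_drugs, names(scores)), positives)
  n_pos <- length(positives)
  if (n_pos == 0) abort("no positives are scored")
  if (length(pool) < n_pos) abort("insufficient negatives for under-sampling")
  reps <- withr::with_seed(seed, {
    purrr::map_dbl(seq_len(n_reps), function(i) {
      auroc(scores, positives, sample(pool, n_pos))
    })
  })
  structure(list(mean_auroc = mean(reps), sd_auroc = stats::sd(reps),
                 reps = reps, n_reps = n_reps, n_pos = n_pos,
                 undersampled = TRUE),
            class = "fam_auroc")
}

#' @export
print.fam_auroc <- function(x, ...) {
  cat(sprintf("Under-sampled AUROC: %.3f +/- %.3f (%d positives, %d repetitions)\n",
              x$mean_auroc, x$sd_auroc, x$n_pos, x$n_reps))
  invisible(x)
}

#' Median percentile rank of a drug set
#'
#' The average rank of a drug set within a phenotype's predictions,
#' summarized by the median (robust to outliers) of the set members'
#' percentile ranks. A value of 90 means the middle-ranked member outranks
#' 90% of all scored drugs.
#'
#' @param table A `drug_score_table`.
#' @param drug_set Character vector of drug ids.
#' @return Median percentile (real in `[0, 100]`).
#' @export
median_percentile <- function(table, drug_set) {
  drug_set <- unique(normalize_drug_ids(drug_set))
  members <- filter(table, .data$drug_id %in% drug_set,
                    !is.na(.data$percentile))
  if (nrow(members) == 0) abort("no member of drug_set is scored")
  median(members$percentile)
}

#' Permutation-null P-value for a rank statistic
#'
#' Builds a null distribution by randomly permuting the assignment of
#' scores to drugs `n_perm` times, recomputing the statistic each time, and
#' returns the add-one estimator
#' `p = (1 + #[null at least as extreme]) / (1 + n_perm)` in the declared
#' direction (never exactly zero; the floor at `1/(1 + n_perm)` reproduces
#' reported floors such as 1e-6 at one million permutations). The statistic
#' is any function of a named score vector, so compound claims — e.g. "these
#' drugs all rank above percentile X and in this order" — are expressible,
#' see [concordance_stat()].
#'
#' @param scores Named numeric vector of per-drug scores.
#' @param stat_fn Function taking a named score vector and returning a
#'   single number.
#' @param n_perm Number of permutations (>= 100; default 1e5).
#' @param seed Integer seed.
#' @param direction `"greater"` (observed large = extreme) or `"less"`.
#' @return An object of class `fam_permutation`: list with
#'   `observed_stat`, `null_stats`, `p_value`, `n_perm`, `direction`.
#' @export
permutation_pvalue <- function(scores, stat_fn, n_perm = 1e5, seed,
                               direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (n_perm < 100) abort("n_perm must be >= 100")
  observed <- stat_fn(scores)
  if (!is.finite(observed)) abort("stat_fn returned a non-finite observed value")
  nms <- names(scores)
  null_stats <- withr::with_seed(seed, {
    purrr::map_dbl(seq_len(n_perm), function(i) {
      out <- stat_fn(setNames(scores[sample.int(length(scores))], nms))
      if (is.na(out)) abort(sprintf("stat_fn failed on permutation %d", i))
      out
    })
  })
  extreme <- if (direction == "greater") sum(null_stats >= observed)
             else sum(null_stats <= observed)
  structure(list(observed_stat = observed, null_stats = null_stats,
                 p_value = (1 + extreme) / (1 + n_perm),
                 n_perm = n_perm, direction = direction),
            class = "fam_permutation")
}

#' @export
print.fam_permutation <- function(x, ...) {
  cat(sprintf("Permutation test: observed %.4g, p = %.3g (%d permutations, %s)\n",
              x$observed_stat, x$p_value, x$n_perm, x$direction))
  invisible(x)
}

#' Compound rank-concordance statistic for permutation testing
#'
#' Returns a statistic function (for [permutation_pvalue()]) encoding a
#' clinical-concordance hypothesis: the listed drugs all rank at or above a
#' percentile floor and, optionally, appear in the given order of predicted
#' efficacy. The statistic is 1 when the score assignment satisfies the
#' claim and 0 otherwise, so the permutation P-value is the chance
#' probability of the observed concordance.
#'
#' @param drug_ids Drugs in the claimed order (best first).
#' @param min_percentile Percentile floor each drug must reach (default 0).
#' @param require_order Whether the claimed order must hold (default TRUE).
#' @return A function mapping a named score vector to 0/1.
#' @export
concordance_stat <- function(drug_ids, min_percentile = 0,
                             require_order = TRUE) {
  drug_ids <- normalize_drug_ids(drug_ids)
  function(scores) {
    if (!all(drug_ids %in% names(scores))) return(0)
    n <- length(scores)
    pct <- 100 * (rank(scores) - 1) / (n - 1)
    s <- scores[drug_ids]
    ok <- all(pct[drug_ids] >= min_percentile)
    if (require_order) ok <- ok && !is.unsorted(rev(s), strictly = FALSE)
    as.numeric(ok)
  }
}

#' Benjamini-Hochberg correction
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]); adjusted values are monotone and capped at 1.
#'
#' @param p_values Numeric vector of P-values in (0, 1].
#' @return Adjusted P-values in input order.
#' @export
bh_correct <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) abort("p-values must be in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Baseline: predict drugs targeting genome-wide-significant genes
#'
#' The standard GWAS-to-drug method predicts a drug as efficacious when it
#' modulates the function of at least one protein whose gene passes a
#' genome-wide significance threshold. The predicted set is unranked;
#' performance against a reference set of known effective drugs is reported
#' as recall, precision and F-score (harmonic mean; 0 when either is 0,
#' with an explicit flag when no drug is predicted at all).
#'
#' @inheritParams raw_fm
#' @param significance_threshold Gene P-value threshold (default 5e-8).
#' @param reference_set Character vector of known effective drug ids.
#' @return An object of class `fam_baseline`: list with `recall`,
#'   `precision`, `f_score`, `predicted_set`, `n_significant_genes`,
#'   `empty_prediction` flag.
#' @export
standard_method_baseline <- function(assoc, drug_targets,
                                     significance_threshold = 5e-8,
                                     reference_set) {
  if (significance_threshold <= 0 || significance_threshold >= 1) {
    abort("significance_threshold must be in (0, 1)")
  }
  reference_set <- unique(normalize_drug_ids(reference_set))
  sig_genes <- assoc$gene_id[assoc$p_value <= significance_threshold]
  predicted <- drug_targets |>
    filter(.data$gene_id %in% sig_genes) |>
    pull(.data$drug_id) |>
    unique()
  tp <- length(intersect(predicted, reference_set))
  recall <- tp / length(reference_set)
  empty <- length(predicted) == 0
  precision <- if (empty) 0 else tp / length(predicted)
  structure(list(recall = recall, precision = precision,
                 f_score = f_score_value(precision, recall),
                 predicted_set = sort(predicted),
                 n_significant_genes = length(sig_genes),
                 empty_prediction = empty),
            class = "fam_baseline")
}

#' @export
print.fam_baseline <- function(x, ...) {
  cat(sprintf("Standard-method baseline: recall %.0f%%, precision %.0f%%, F-score %.0f%% (%d drugs predicted)\n",
              100 * x$recall, 100 * x$precision, 100 * x$f_score,
              length(x$predicted_set)))
  if (x$empty_prediction) cat("No candidate drugs identified at this threshold.\n")
  invisible(x)
}

#' Comparator: competitive gene-set t-test per drug
#'
#' The gene-set analysis comparator scores a drug by a one-sided Welch
#' two-sample t-test asking whether the genes whose products the drug
#' alters in function are, on average, more disease-associated than the
#' remaining genes (under this package's association-strength z convention,
#' where larger z means smaller gene P-value, the alternative is that the
#' target-gene mean z is greater). Drugs are ranked by ascending P-value.
#'
#' @inheritParams raw_fm
#' @param drug_id Optional single drug id; by default all drugs with >= 2
#'   scoreable targets are tested.
#' @return Tibble `drug_id`, `t_stat`, `p_value`, `n_targets`, sorted by
#'   ascending `p_value`; degenerate cases (zero variance in both groups)
#'   get `p_value = 1` and `degenerate = TRUE`.
#' @export
gene_set_ttest <- function(assoc, drug_targets, drug_id = NULL) {
  z <- setNames(assoc$z_stat, assoc$gene_id)
  drugs <- if (is.null(drug_id)) unique(drug_targets$drug_id) else drug_id
  targ <- split(drug_targets$gene_id, drug_targets$drug_id)
  out <- purrr::map(drugs, function(d) {
    genes <- intersect(targ[[d]], names(z))
    rest <- setdiff(names(z), genes)
    if (length(genes) < 2 || length(rest) < 2) {
      return(tibble(drug_id = d, t_stat = NA_real_, p_value = NA_real_,
                    n_targets = length(genes), degenerate = TRUE))
    }
    zi <- z[genes]
    zo <- z[rest]
    if (stats::sd(zi) == 0 && stats::sd(zo) == 0) {
      return(tibble(drug_id = d, t_stat = 0, p_value = 1,
                    n_targets = length(genes), degenerate = TRUE))
    }
    tt <- t.test(zi, zo, alternative = "greater", var.equal = FALSE)
    tibble(drug_id = d, t_stat = unname(tt$statistic),
           p_value = tt$p.value, n_targets = length(genes),
           degenerate = FALSE)
  }) |> purrr::list_rbind()
  arrange(out, .data$p_value, .data$drug_id)
}
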