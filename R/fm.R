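#' Raw function-modulation score for one drug
#'
#' The FM score combines, for every protein whose function a drug affects,
#' the degree of disease association of that protein (the gene z-statistic)
#' with the strength of the drug's effect on it (the affinity weight,
#' normalized by the maximum weight in the whole table so the score is
#' invariant to the affinity scale). The raw score is the mean over the
#' drug's scoreable targets of `weight_norm * z_stat`; targets absent from
#' the association table are skipped.
#'
#' @param drug_targets Drug-target tibble (`drug_id`, `gene_id`,
#'   `affinity_weight`), see [read_drug_targets()].
#' @param assoc Gene association tibble (`gene_id`, `z_stat`), see
#'   [read_gene_associations()].
#' @param drug_id Single drug identifier.
#' @return The raw FM score (a real), or `NA` with a warning when the drug
#'   has no target present in `assoc` (unscoreable).
#' @export
raw_fm <- function(drug_targets, assoc, drug_id) {
  tab <- raw_fm_scores(drug_targets, assoc, quiet = TRUE)
  row <- tab[tab$drug_id == drug_id, ]
  if (nrow(row) == 0) {
    warn(sprintf("drug '%s' is unscoreable (no target in the association table)",
                 drug_id))
    return(NA_real_)
  }
  row$raw_fm
}

# Raw FM for every drug: mean over scoreable targets of weight_norm * z.
# Affinity weights are normalized by the global maximum, so multiplying all
# weights by a constant changes nothing downstream.
raw_fm_scores <- function(drug_targets, assoc, quiet = FALSE) {
  w_max <- max(drug_targets$affinity_weight)
  if (w_max <= 0) abort("all affinity weights are zero")
  scored <- drug_targets |>
    mutate(weight_norm = .data$affinity_weight / w_max) |>
    inner_join(select(assoc, "gene_id", "z_stat"), by = "gene_id")
  n_total <- drug_targets |> count(.data$drug_id, name = "n_targets_total")
  out <- scored |>
    group_by(.data$drug_id) |>
    summarise(raw_fm = mean(.data$weight_norm * .data$z_stat),
              n_targets_scored = n(), .groups = "drop") |>
    left_join(n_total, by = "drug_id")
  dropped <- setdiff(unique(drug_targets$drug_id), out$drug_id)
  if (length(dropped) > 0 && !quiet) {
    inform(sprintf("%d drug(s) unscoreable (no target in association table): %s",
                   length(dropped),
                   paste(head(dropped, 5), collapse = ", ")))
  }
  attr(out, "unscoreable") <- dropped
  attr(out, "w_max") <- w_max
  out
}

# Size-matched permutation null for the raw FM score. For a drug with k
# scoreable targets, null scores are raw FM values recomputed over random
# k-gene sets drawn without replacement from all genes in `assoc`, reusing
# the drug's own normalized weights. Drugs sharing k share the sampled gene
# sets, which makes the null O(n_perm * sum over distinct k) instead of
# per-drug.
size_adjust_table <- function(raw_tab, assoc, drug_targets, n_perm, seed) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  z <- assoc$z_stat
  n_genes <- length(z)
  w_max <- attr(raw_tab, "w_max")
  weights <- drug_targets |>
    semi_join(assoc, by = "gene_id") |>
    mutate(weight_norm = .data$affinity_weight / w_max) |>
    arrange(.data$drug_id, .data$gene_id)
  w_by_drug <- split(weights$weight_norm, weights$drug_id)

  withr::with_seed(seed, {
    res <- raw_tab |>
      mutate(size_adjusted_fm = NA_real_)
    for (k in sort(unique(raw_tab$n_targets_scored))) {
      idx <- which(raw_tab$n_targets_scored == k)
      if (k >= n_genes) {
        # the null is a point mass: every size-n_genes draw is the whole
        # gene universe
        res$size_adjusted_fm[idx] <- 0
        next
      }
      Z <- vapply(seq_len(n_perm),
                  function(j) z[sample.int(n_genes, k)],
                  numeric(k))
      Z <- matrix(Z, nrow = k)
      for (i in idx) {
        w <- w_by_drug[[raw_tab$drug_id[i]]]
        null_scores <- as.numeric(crossprod(w, Z)) / k
        mu <- mean(null_scores)
        s <- stats::sd(null_scores)
        res$size_adjusted_fm[i] <-
          if (s == 0) 0 else (raw_tab$raw_fm[i] - mu) / s
      }
    }
    res
  })
}

#' Size-adjusted FM scores via a permutation null
#'
#' Adjusts raw FM scores for the number of proteins each drug affects:
#' drugs with few targets have noisier raw scores, so each drug's raw FM is
#' standardized against a null of raw FM values recomputed over `n_perm`
#' random target sets of the same size, drawn without replacement from all
#' genes in the association table and reusing the drug's own normalized
#' affinity weights. Deterministic given `seed`. When a drug's target set
#' spans the whole gene universe the null is degenerate and the adjusted
#' score is defined as 0.
#'
#' @inheritParams raw_fm
#' @param raw_scores Tibble from the internal raw-FM step with columns
#'   `drug_id`, `raw_fm`, `n_targets_scored`.
#' @param n_perm Number of permutation draws per target-set size (>= 100).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return `raw_scores` with a `size_adjusted_fm` column appended.
#' @export
size_adjust <- function(raw_scores, assoc, drug_targets, n_perm = 10000,
                        seed) {
  if (is.null(attr(raw_scores, "w_max"))) {
    attr(raw_scores, "w_max") <- max(drug_targets$affinity_weight)
  }
  size_adjust_table(raw_scores, assoc, drug_targets, n_perm, seed)
}

#' Function-modulation (FM) z-scores for all drugs
#'
#' Runs the full FM stage: raw per-drug scores, size-matched permutation
#' adjustment, then standardization across the scored drug cohort into
#' `fm_z` (mean 0, unit variance).
#'
#' @inheritParams size_adjust
#' @return An object of class `fam_fm`: list with `scores` (tibble
#'   `drug_id`, `raw_fm`, `size_adjusted_fm`, `fm_z`, `n_targets_scored`),
#'   `unscoreable` (dropped drug ids), `n_perm`, `seed`. Use [tidy()] for
#'   the per-drug tibble and [glance()] for a one-row summary.
#' @export
fm_scores <- function(drug_targets, assoc, n_perm = 10000, seed) {
  raw_tab <- raw_fm_scores(drug_targets, assoc)
  if (nrow(raw_tab) < 2) abort("insufficient drugs: fewer than 2 scoreable")
  adj <- size_adjust_table(raw_tab, assoc, drug_targets, n_perm, seed)
  adj$fm_z <- z_standardize(adj$size_adjusted_fm, "size-adjusted FM scores")
  structure(
    list(scores = select(adj, "drug_id", "raw_fm", "size_adjusted_fm",
                         "fm_z", "n_targets_scored", "n_targets_total"),
         unscoreable = attr(raw_tab, "unscoreable"),
         n_perm = n_perm, seed = seed),
    class = "fam_fm")
}

#' @export
print.fam_fm <- function(x, ...) {
  cat(sprintf("FM scores: %d drugs scored (%d unscoreable), %d permutations\n",
              nrow(x$scores), length(x$unscoreable), x$n_perm))
  print(head(arrange(x$scores, desc(.data$fm_z)), 5))
  invisible(x)
}
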