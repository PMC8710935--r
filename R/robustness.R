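#' Kendall rank correlation between two drug rankings
#'
#' Tie-corrected Kendall tau-b between two rankings of the same drug
#' universe, with a P-value from exact enumeration for small tie-free
#' inputs (n <= 8) and the normal approximation otherwise. tau = +1 means
#' the rankings are identical, -1 that one is the exact inverse of the
#' other, 0 that they are unrelated.
#'
#' @param rank_a,rank_b Named numeric vectors of ranks (or scores) over the
#'   same drug universe.
#' @return List with `tau`, `p_value`, `n`.
#' @export
kendall_tau <- function(rank_a, rank_b) {
  if (is.null(names(rank_a)) || is.null(names(rank_b))) {
    abort("rank vectors must be named by drug id")
  }
  if (!setequal(names(rank_a), names(rank_b))) {
    abort("rank universes differ")
  }
  b <- rank_b[names(rank_a)]
  n <- length(rank_a)
  ties <- anyDuplicated(rank_a) > 0 || anyDuplicated(b) > 0
  ct <- suppressWarnings(
    cor.test(rank_a, b, method = "kendall", exact = n <= 8 && !ties))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Kendall tau between two phenotypes' drug rankings
#'
#' Convenience contrast over the drugs ranked in both tables: rankings for
#' two related phenotypes should correlate, while two unrelated phenotypes
#' give tau near 0.
#'
#' @param table_a,table_b `drug_score_table`s.
#' @return List with `tau`, `p_value`, `n` (common ranked drugs).
#' @export
ranking_concordance <- function(table_a, table_b) {
  a <- filter(table_a, !is.na(.data$rank))
  b <- filter(table_b, !is.na(.data$rank))
  common <- intersect(a$drug_id, b$drug_id)
  if (length(common) < 3) abort("fewer than 3 common ranked drugs")
  kendall_tau(setNames(a$rank, a$drug_id)[common],
              setNames(b$rank, b$drug_id)[common])
}

#' Leave-one-protein-out stability of the FAM ranking
#'
#' Asks whether the drug predictions are driven by individual highly
#' disease-associated proteins: the `top_k` genes with the largest
#' z-statistics among genes that contribute to the ranking (targets of at
#' least one scored drug, or present in the disease signature) are excluded
#' one at a time; the whole FM/AC/FAM pipeline is re-run with the gene
#' removed from the association table, the disease signature and the
#' drug-target table; and the new ranking is compared with the original by
#' Kendall tau over the drugs ranked in both. Drugs whose target set
#' empties under an exclusion drop out of the comparison and are counted.
#'
#' @inheritParams fm_scores
#' @param disease Disease signature tibble.
#' @param signatures Genes x drugs signature matrix.
#' @param top_k Number of top-associated genes to exclude in turn
#'   (default 10). `top_k = 0` returns an empty report.
#' @param genes Optional explicit gene ids to exclude in turn, overriding
#'   the top-`top_k` selection.
#' @param min_overlap Passed to [ac_scores()].
#' @param n_perm,seed Passed to [fm_scores()] (the same seed is reused for
#'   every exclusion so tau reflects the exclusion, not permutation noise).
#' @return An object of class `fam_stability`: list with `report` (tibble
#'   `gene_id`, `z_stat`, `tau`, `p_value`, `n_common`, `n_dropped`),
#'   `baseline` (the full-data `drug_score_table`), `top_k`.
#' @export
leave_one_out <- function(drug_targets, assoc, disease, signatures,
                          top_k = 10, min_overlap = 10, n_perm = 2000,
                          seed, genes = NULL) {
  run <- function(dt, as_, dis) {
    fm <- fm_scores(dt, as_, n_perm = n_perm, seed = seed)
    ac <- suppressMessages(ac_scores(dis, signatures, min_overlap))
    fam_scores(fm, ac)
  }
  baseline <- run(drug_targets, assoc, disease)
  if (top_k == 0 && is.null(genes)) {
    return(structure(list(report = tibble(gene_id = character(),
                                          z_stat = numeric(),
                                          tau = numeric(),
                                          p_value = numeric(),
                                          n_common = integer(),
                                          n_dropped = integer()),
                          baseline = baseline, top_k = 0L),
                     class = "fam_stability"))
  }
  scored_drugs <- baseline$drug_id[!is.na(baseline$rank)]
  if (is.null(genes)) {
    contributing <- union(
      drug_targets$gene_id[drug_targets$drug_id %in% scored_drugs],
      disease$gene_id)
    candidates <- assoc |>
      filter(.data$gene_id %in% contributing) |>
      arrange(desc(.data$z_stat)) |>
      head(top_k)
  } else {
    candidates <- tibble(gene_id = genes) |>
      left_join(select(assoc, "gene_id", "z_stat"), by = "gene_id")
  }
  base_rank <- setNames(baseline$rank[!is.na(baseline$rank)], scored_drugs)
  report <- purrr::map(seq_len(nrow(candidates)), function(i) {
    g <- candidates$gene_id[i]
    # drugs whose only target is g vanish from dt and hence from the new
    # ranking; they are reported via n_dropped
    dt <- filter(drug_targets, .data$gene_id != g)
    tab <- suppressMessages(suppressWarnings(
      run(dt, filter(assoc, .data$gene_id != g),
          filter(disease, .data$gene_id != g))))
    new_rank <- setNames(tab$rank[!is.na(tab$rank)],
                         tab$drug_id[!is.na(tab$rank)])
    common <- intersect(names(base_rank), names(new_rank))
    kt <- kendall_tau(base_rank[common], new_rank[common])
    tibble(gene_id = g, z_stat = candidates$z_stat[i], tau = kt$tau,
           p_value = kt$p_value, n_common = length(common),
           n_dropped = length(base_rank) - length(common))
  }) |> purrr::list_rbind()
  structure(list(report = report, baseline = baseline, top_k = top_k),
            class = "fam_stability")
}

#' @export
print.fam_stability <- function(x, ...) {
  cat(sprintf("Leave-one-protein-out stability (top %d genes excluded in turn)\n",
              x$top_k))
  if (nrow(x$report) > 0) {
    cat(sprintf("Kendall tau range: %.3f to %.3f\n",
                min(x$report$tau), max(x$report$tau)))
  }
  invisible(x)
}
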