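#' Integrate FM and AC into the FAM score and rank drugs
#'
#' The FAM score for a drug is the arithmetic mean of its FM and AC
#' z-scores. Drugs scored by only one component (e.g. drugs without an
#' assayed transcriptomic signature have no AC score) carry that component
#' but no FAM score and are excluded from the ranking while remaining in
#' the table. Ranks run from 1 (best, highest FAM) with ties broken by drug
#' id; percentile ranks are `100 * (n - rank) / (n - 1)` over the `n` ranked
#' drugs, so the top drug has percentile 100 (ranked above 100% of the
#' others) and the bottom drug 0.
#'
#' @param fm A `fam_fm` object (or tibble with `drug_id`, `fm_z`).
#' @param ac A `fam_ac` object (or tibble with `drug_id`, `ac_z`), or
#'   `NULL` for an FM-only table (no FAM scores or ranks).
#' @param phenotype Phenotype label attached to the table.
#' @return A `drug_score_table` tibble: `drug_id`, `fm_z`, `ac_z`, `fam`,
#'   `rank`, `percentile`, sorted by rank.
#' @export
fam_scores <- function(fm, ac, phenotype = NA_character_) {
  fm_tab <- if (inherits(fm, "fam_fm")) fm$scores else as_tibble(fm)
  stopifnot(all(c("drug_id", "fm_z") %in% names(fm_tab)))
  if (is.null(ac)) {
    out <- fm_tab |>
      transmute(.data$drug_id, .data$fm_z, ac_z = NA_real_, fam = NA_real_,
                rank = NA_integer_, percentile = NA_real_) |>
      arrange(.data$drug_id)
    warn("no AC scores supplied: FM-only table, no FAM scores or ranks")
    return(new_score_table(out, phenotype))
  }
  ac_tab <- if (inherits(ac, "fam_ac")) ac$scores else as_tibble(ac)
  stopifnot(all(c("drug_id", "ac_z") %in% names(ac_tab)))
  merged <- full_join(select(fm_tab, "drug_id", "fm_z"),
                      select(ac_tab, "drug_id", "ac_z"), by = "drug_id") |>
    mutate(fam = (.data$fm_z + .data$ac_z) / 2)
  n_scored <- sum(!is.na(merged$fam))
  if (n_scored < 2) abort("fewer than 2 drugs scored by both FM and AC")
  ranked <- merged |>
    arrange(desc(.data$fam), .data$drug_id) |>
    mutate(rank = if_else(is.na(.data$fam), NA_integer_,
                          as.integer(cumsum(!is.na(.data$fam)))),
           percentile = 100 * (n_scored - .data$rank) / (n_scored - 1))
  new_score_table(ranked, phenotype)
}

new_score_table <- function(tab, phenotype = NA_character_) {
  out <- select(tab, all_of(score_table_cols))
  attr(out, "phenotype") <- phenotype
  class(out) <- c("drug_score_table", class(out))
  out
}

#' Demarcate the top candidate drugs by effective-drug enrichment
#'
#' Scans every cutoff k = 1..n over the ranked drug list and computes the
#' one-sided hypergeometric enrichment of a reference effective-drug set
#' among the top k; the demarcation is the cutoff minimizing the enrichment
#' P-value (smallest k on ties). P-values over the scan are
#' Benjamini-Hochberg corrected, and the result is flagged when no cutoff
#' reaches corrected P < 0.05 (no significant enrichment).
#'
#' @param table A `drug_score_table` (ranked drugs).
#' @param effective_set Character vector of drug ids (normalized with
#'   [normalize_drug_ids()] before matching).
#' @param alpha Significance level for the enrichment flag (default 0.05).
#' @return A list of class `fam_top_candidates`: `k` (demarcation rank),
#'   `drugs` (top-k drug ids in rank order), `p_value`,
#'   `p_adjusted`, `significant`, and `scan` (per-cutoff tibble).
#' @export
top_candidates <- function(table, effective_set, alpha = 0.05) {
  effective_set <- unique(normalize_drug_ids(effective_set))
  ranked <- table |> filter(!is.na(.data$rank)) |> arrange(.data$rank)
  n <- nrow(ranked)
  hits <- ranked$drug_id %in% effective_set
  m <- sum(hits)
  if (m == 0) abort("no member of effective_set is among the ranked drugs")
  scan <- tibble(k = seq_len(n),
                 n_effective = cumsum(hits)) |>
    mutate(p_value = phyper(.data$n_effective - 1, m, n - m, .data$k,
                            lower.tail = FALSE),
           p_adjusted = p.adjust(.data$p_value, method = "BH"))
  best <- which.min(scan$p_value)
  structure(
    list(k = best,
         drugs = ranked$drug_id[seq_len(best)],
         p_value = scan$p_value[best],
         p_adjusted = scan$p_adjusted[best],
         significant = scan$p_adjusted[best] < alpha,
         scan = scan),
    class = "fam_top_candidates")
}

#' @export
print.fam_top_candidates <- function(x, ...) {
  cat(sprintf("Top-candidate demarcation: k = %d (hypergeometric p = %.3g, BH-adjusted %.3g)\n",
              x$k, x$p_value, x$p_adjusted))
  if (!x$significant) cat("No significant enrichment of effective drugs.\n")
  invisible(x)
}

#' @export
print.drug_score_table <- function(x, ...) {
  ph <- attr(x, "phenotype")
  cat(sprintf("Drug score table%s: %d drugs, %d ranked by FAM\n",
              if (is.na(ph)) "" else paste0(" [", ph, "]"),
              nrow(x), sum(!is.na(x$rank))))
  NextMethod()
}
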