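#' Cosine distance between two signed signatures
#'
#' `1 - (u . v) / (|u| |v|)`, in `[0, 2]`: 0 for identical directions, 1 for
#' orthogonal vectors, 2 for exactly opposite vectors. This is the
#' dissimilarity used to compare a drug's induced abundance changes with the
#' disease's abundance changes: a distance near 2 means the drug shifts the
#' disease-associated proteins in the opposite direction to the disease.
#'
#' @param u,v Numeric vectors over the same genes, in the same order.
#' @return Cosine distance in `[0, 2]`.
#' @export
#' @examples
#' cosine_distance(c(1, 0), c(0, 1))   # orthogonal -> 1
#' cosine_distance(c(1, 2), c(-1, -2)) # opposite -> 2
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) abort("vectors differ in length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("degenerate vector: zero norm")
  1 - sum(u * v) / (nu * nv)
}

#' Abundance-correction (AC) z-scores for all drugs
#'
#' For each drug, the cosine distance between the disease signature and the
#' drug's transcriptomic signature is computed over the genes present (and
#' non-missing) in both; drugs overlapping the disease signature in fewer
#' than `min_overlap` genes are excluded and reported. Distances are
#' standardized across the scored cohort into `ac_z`, oriented so that a
#' larger distance (stronger anti-correlation with the disease, hence a
#' stronger predicted corrective effect) gives a higher `ac_z` — the same
#' higher-is-better orientation as `fm_z`.
#'
#' @param disease Disease signature tibble (`gene_id`, `effect`), see
#'   [read_disease_signature()].
#' @param signatures Genes x drugs numeric matrix, see
#'   [read_signature_matrix()].
#' @param min_overlap Minimum shared-gene count for a drug to be scored
#'   (default 10; cosine on fewer dimensions is noise-dominated).
#' @return An object of class `fam_ac`: list with `scores` (tibble
#'   `drug_id`, `cosine_distance`, `n_overlap`, `ac_z`), `excluded`
#'   (tibble of drugs failing `min_overlap` with reasons), `min_overlap`.
#' @export
ac_scores <- function(disease, signatures, min_overlap = 10) {
  genes <- intersect(disease$gene_id, rownames(signatures))
  eff <- setNames(disease$effect, disease$gene_id)[genes]
  per_drug <- purrr::map(colnames(signatures), function(d) {
    v <- signatures[genes, d]
    ok <- is.finite(v)
    u <- eff[ok]
    w <- v[ok]
    n <- sum(ok)
    if (n < min_overlap || sum(u^2) == 0 || sum(w^2) == 0) {
      return(tibble(drug_id = d, cosine_distance = NA_real_, n_overlap = n))
    }
    tibble(drug_id = d, cosine_distance = cosine_distance(u, w),
           n_overlap = n)
  }) |> purrr::list_rbind()
  excluded <- filter(per_drug, is.na(.data$cosine_distance))
  scored <- filter(per_drug, !is.na(.data$cosine_distance))
  if (nrow(scored) < 2) {
    abort(sprintf("fewer than 2 drugs pass min_overlap = %d", min_overlap))
  }
  if (nrow(excluded) > 0) {
    inform(sprintf("%d drug(s) excluded from AC scoring (overlap < %d): %s",
                   nrow(excluded), min_overlap,
                   paste(head(excluded$drug_id, 5), collapse = ", ")))
  }
  scored$ac_z <- z_standardize(scored$cosine_distance, "cosine distances")
  structure(list(scores = arrange(scored, .data$drug_id),
                 excluded = excluded, min_overlap = min_overlap),
            class = "fam_ac")
}

#' @export
print.fam_ac <- function(x, ...) {
  cat(sprintf("AC scores: %d drugs scored (%d below min_overlap = %d)\n",
              nrow(x$scores), nrow(x$excluded), x$min_overlap))
  print(head(arrange(x$scores, desc(.data$ac_z)), 5))
  invisible(x)
}
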