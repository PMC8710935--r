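#' Normalize gene identifiers
#'
#' Gene identifiers are harmonized across sources by exact string match after
#' uppercasing and trimming whitespace. Normalization is idempotent.
#'
#' @param x Character vector of gene symbols or stable IDs.
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_gene_ids(c(" scn1a", "Gabra1 "))
normalize_gene_ids <- function(x) {
  toupper(stringr::str_trim(as.character(x)))
}

#' Normalize drug identifiers
#'
#' Drug names are lowercased and stripped of punctuation and whitespace so
#' that e.g. `"Valproic Acid"` and `"valproic-acid"` collapse to the same
#' key. An optional synonym table (named character vector, `old = new`) is
#' applied before normalization, since drug-name vocabularies differ between
#' affinity databases and expression resources.
#'
#' @param x Character vector of drug names.
#' @param synonyms Optional named character vector mapping raw names to
#'   preferred names, applied before normalization.
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_drug_ids(c("Valproic Acid", "CARBAMAZEPINE"))
normalize_drug_ids <- function(x, synonyms = NULL) {
  x <- as.character(x)
  if (!is.null(synonyms)) {
    key <- stringr::str_to_lower(stringr::str_trim(x))
    names(synonyms) <- stringr::str_to_lower(stringr::str_trim(names(synonyms)))
    hit <- key %in% names(synonyms)
    x[hit] <- unname(synonyms[key[hit]])
  }
  stringr::str_remove_all(stringr::str_to_lower(x), "[^a-z0-9]")
}

#' Convert gene-level P-values to z-statistics
#'
#' Uses the one-sided convention z = qnorm(1 - p): larger z means stronger
#' disease association, and the median P-value 0.5 maps to z = 0. P-values
#' below 1e-300 are clamped so that the transform stays finite.
#'
#' @param p Numeric vector of P-values in (0, 1].
#' @param convention P-to-z convention; only `"one_sided"` is defined.
#' @return Numeric vector of z-statistics.
#' @export
#' @examples
#' p_to_z(c(0.5, 0.0231))
p_to_z <- function(p, convention = "one_sided") {
  convention <- match.arg(convention)
  if (any(!is.finite(p) | p > 1)) {
    abort("p-values must be finite and <= 1")
  }
  if (any(p <= 0)) {
    warn("p-values <= 0 clamped to 1e-300")
  }
  qnorm(pmax(p, 1e-300), lower.tail = FALSE)
}

find_column <- function(nms, patterns, what, path) {
  for (p in patterns) {
    hit <- grep(p, nms, ignore.case = TRUE, value = TRUE)
    if (length(hit) >= 1) return(hit[[1]])
  }
  abort(sprintf("no %s column found in '%s' (columns: %s)",
                what, path, paste(nms, collapse = ", ")))
}

read_delim_quiet <- function(path) {
  readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Read a GWAS gene-based association table
#'
#' Reads a tab- or comma-separated file with a header naming a gene column
#' and a P-value column. Duplicate gene rows are collapsed to the smallest
#' P-value (order-independent), and z-statistics are derived via [p_to_z()].
#'
#' @param path Path to a delimited file.
#' @param phenotype Free-text phenotype label attached to the table.
#' @param convention P-to-z convention, see [p_to_z()].
#' @param gene_col,p_col Optional explicit column names; by default columns
#'   matching "gene"/"symbol" and "p"/"pval" are detected.
#' @return A tibble with columns `gene_id`, `p_value`, `z_stat` and a
#'   `phenotype` attribute.
#' @export
read_gene_associations <- function(path, phenotype = NA_character_,
                                   convention = "one_sided",
                                   gene_col = NULL, p_col = NULL) {
  raw <- read_delim_quiet(path)
  gene_col <- gene_col %||%
    find_column(names(raw), c("^gene", "symbol", "^id$"), "gene", path)
  p_col <- p_col %||%
    find_column(names(raw), c("^p_?val", "^p$", "pvalue"), "p-value", path)
  p <- raw[[p_col]]
  bad <- which(!is.finite(p) | p <= 0 | p > 1)
  if (length(bad) > 0) {
    abort(sprintf("invalid p-value at row %d of '%s': %s",
                  bad[[1]], path, format(p[bad[[1]]])))
  }
  out <- tibble(gene_id = normalize_gene_ids(raw[[gene_col]]),
                p_value = as.numeric(p)) |>
    group_by(.data$gene_id) |>
    summarise(p_value = min(.data$p_value), .groups = "drop") |>
    arrange(.data$gene_id) |>
    mutate(z_stat = p_to_z(.data$p_value, convention))
  attr(out, "phenotype") <- phenotype
  out
}

#' Read a signed disease abundance-change signature
#'
#' Reads a table of per-gene signed association statistics (TWAS-style):
#' positive effects mean the gene product's abundance is increased in the
#' disease, negative means decreased.
#'
#' @inheritParams read_gene_associations
#' @param effect_col Optional explicit effect column name.
#' @return Tibble with columns `gene_id`, `effect`; `phenotype` attribute.
#' @export
read_disease_signature <- function(path, phenotype = NA_character_,
                                   gene_col = NULL, effect_col = NULL) {
  raw <- read_delim_quiet(path)
  if (nrow(raw) == 0) abort(sprintf("empty signature in '%s'", path))
  gene_col <- gene_col %||%
    find_column(names(raw), c("^gene", "symbol", "^id$"), "gene", path)
  effect_col <- effect_col %||%
    find_column(names(raw), c("effect", "^z", "stat", "beta"), "effect", path)
  eff <- raw[[effect_col]]
  if (!is.numeric(eff) || any(!is.finite(eff))) {
    abort(sprintf("non-numeric or non-finite effect values in '%s'", path))
  }
  out <- tibble(gene_id = normalize_gene_ids(raw[[gene_col]]),
                effect = as.numeric(eff)) |>
    group_by(.data$gene_id) |>
    summarise(effect = median(.data$effect), .groups = "drop") |>
    arrange(.data$gene_id)
  if (all(out$effect == 0)) abort(sprintf("all effects zero in '%s'", path))
  attr(out, "phenotype") <- phenotype
  out
}

affinity_transforms <- c("identity", "neglog10_nM")

apply_affinity_transform <- function(raw, transform) {
  transform <- match.arg(transform, affinity_transforms)
  switch(transform,
    identity = {
      if (any(raw < 0)) abort("negative affinity under identity transform")
      raw
    },
    neglog10_nM = {
      if (any(raw <= 0)) abort("non-positive affinity under neglog10_nM transform")
      -log10(raw * 1e-9)
    }
  )
}

#' Read a drug-target affinity table
#'
#' Reads a long-format table (drug, target gene, raw affinity). Raw
#' affinities are mapped to nonnegative potency-scale weights by the declared
#' transform: `"identity"` passes already-potency-scale values (e.g.
#' pAffinity) through; `"neglog10_nM"` converts a concentration in nanomolar
#' (Ki/Kd/IC50) to -log10(molar), so Ki = 100 nM becomes weight 7. Duplicate
#' (drug, target) rows collapse to the maximum weight (order-independent).
#'
#' @param path Path to a delimited file.
#' @param affinity_transform One of `"identity"`, `"neglog10_nM"`.
#' @param synonyms Optional drug synonym table, see [normalize_drug_ids()].
#' @param drug_col,gene_col,affinity_col Optional explicit column names.
#' @return Tibble with columns `drug_id`, `gene_id`, `affinity_weight`.
#' @export
read_drug_targets <- function(path, affinity_transform = "identity",
                              synonyms = NULL, drug_col = NULL,
                              gene_col = NULL, affinity_col = NULL) {
  raw <- read_delim_quiet(path)
  drug_col <- drug_col %||%
    find_column(names(raw), c("^drug", "compound"), "drug", path)
  gene_col <- gene_col %||%
    find_column(names(raw), c("^gene", "target", "symbol"), "target gene", path)
  affinity_col <- affinity_col %||%
    find_column(names(raw), c("affin", "weight", "^ki$", "pchembl"),
                "affinity", path)
  tibble(drug_id = normalize_drug_ids(raw[[drug_col]], synonyms),
         gene_id = normalize_gene_ids(raw[[gene_col]]),
         affinity_weight = apply_affinity_transform(
           as.numeric(raw[[affinity_col]]), affinity_transform)) |>
    group_by(.data$drug_id, .data$gene_id) |>
    summarise(affinity_weight = max(.data$affinity_weight), .groups = "drop") |>
    arrange(.data$drug_id, .data$gene_id)
}

#' Read a drug-induced transcriptomic signature matrix
#'
#' Accepts either a wide matrix file (first column genes, one column per
#' drug) or a long triplet file (gene, drug, value); both yield the same
#' genes x drugs numeric matrix. Cells absent from a long file stay `NA` and
#' are excluded from per-drug gene overlaps downstream. Drugs whose stored
#' signature is entirely zero are retained but reported.
#'
#' @param path Path to the signature file.
#' @param format `"auto"` (default), `"wide"` or `"long"`.
#' @param synonyms Optional drug synonym table.
#' @return Numeric matrix with gene rownames and drug colnames.
#' @export
read_signature_matrix <- function(path, format = c("auto", "wide", "long"),
                                  synonyms = NULL) {
  format <- match.arg(format)
  raw <- read_delim_quiet(path)
  if (format == "auto") {
    long_like <- ncol(raw) == 3 &&
      !is.numeric(raw[[2]]) && is.numeric(raw[[3]])
    format <- if (long_like) "long" else "wide"
  }
  if (format == "long") {
    dat <- tibble(gene_id = normalize_gene_ids(raw[[1]]),
                  drug_id = normalize_drug_ids(raw[[2]], synonyms),
                  value = as.numeric(raw[[3]]))
    if (anyDuplicated(dat[c("gene_id", "drug_id")]) > 0) {
      inform("duplicate (gene, drug) cells collapsed by median")
      dat <- dat |>
        group_by(.data$gene_id, .data$drug_id) |>
        summarise(value = median(.data$value), .groups = "drop")
    }
    wide <- tidyr::pivot_wider(dat, names_from = "drug_id",
                               values_from = "value")
    mat <- as.matrix(wide[-1])
    rownames(mat) <- wide$gene_id
  } else {
    genes <- normalize_gene_ids(raw[[1]])
    # duplicate detection must use the raw header: readr de-duplicates
    # repeated column names on read
    header <- strsplit(readr::read_lines(path, n_max = 1), "[\t,]")[[1]]
    drugs <- normalize_drug_ids(header[-1], synonyms)
    if (anyDuplicated(drugs) > 0) {
      abort(sprintf("duplicated drug column in '%s': %s", path,
                    paste(unique(drugs[duplicated(drugs)]), collapse = ", ")))
    }
    if (anyDuplicated(genes) > 0) {
      abort(sprintf("duplicated gene row in '%s'", path))
    }
    mat <- as.matrix(raw[-1])
    storage.mode(mat) <- "double"
    dimnames(mat) <- list(genes, drugs)
  }
  zero_cols <- colnames(mat)[colSums(abs(mat), na.rm = TRUE) == 0]
  if (length(zero_cols) > 0) {
    inform(paste0("all-zero signature columns retained: ",
                  paste(zero_cols, collapse = ", ")))
  }
  mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
}

#' Collapse replicate signature columns per drug
#'
#' When the signature matrix carries several columns per drug (cell lines,
#' doses), they are collapsed to one column per drug by the per-gene median,
#' which is robust to a single aberrant replicate.
#'
#' @param mat Numeric genes x columns matrix.
#' @param drug_of Named character vector mapping column names to drug ids
#'   (defaults to the column names themselves).
#' @return Numeric genes x drugs matrix with one column per drug.
#' @export
collapse_replicates <- function(mat, drug_of = NULL) {
  drug_of <- drug_of %||% setNames(colnames(mat), colnames(mat))
  drugs <- unname(drug_of[colnames(mat)])
  if (anyNA(drugs)) abort("drug_of must cover every column of mat")
  out <- vapply(unique(drugs), function(d) {
    cols <- mat[, drugs == d, drop = FALSE]
    apply(cols, 1, median, na.rm = TRUE)
  }, numeric(nrow(mat)))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- rownames(mat)
  out
}

#' Read drug-set annotations
#'
#' Reads a YAML mapping from set name (e.g. `ASM`, `more_effective`) to drug
#' name lists; names are normalized so they join against scored drugs. Sets
#' may overlap.
#'
#' @param path Path to a YAML file.
#' @param synonyms Optional drug synonym table.
#' @return Named list of character vectors of normalized drug ids.
#' @export
read_drug_sets <- function(path, synonyms = NULL) {
  sets <- yaml::read_yaml(path)
  lapply(sets, function(x) unique(normalize_drug_ids(unlist(x), synonyms)))
}

score_table_cols <- c("drug_id", "fm_z", "ac_z", "fam", "rank", "percentile")

#' Write / read a ranked drug score table
#'
#' The writer emits a TSV with a deterministic column order
#' (`drug_id, fm_z, ac_z, fam, rank, percentile`), rows sorted by rank with
#' FM-only (unranked) drugs last by drug id, and numeric values at 12
#' significant digits so the paired reader round-trips losslessly.
#'
#' @param table A drug score table as produced by [fam_scores()].
#' @param path Output path.
#' @return `write_score_table()` returns `path` invisibly;
#'   `read_score_table()` returns the tibble.
#' @export
write_score_table <- function(table, path) {
  stopifnot(all(score_table_cols %in% names(table)))
  out <- table |>
    select(all_of(score_table_cols)) |>
    arrange(is.na(.data$rank), .data$rank, .data$drug_id) |>
    mutate(across(where(is.numeric), \(x) signif(x, 12)))
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @param phenotype Phenotype label to attach on read.
#' @export
read_score_table <- function(path, phenotype = NA_character_) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           drug_id = readr::col_character(),
                           .default = readr::col_double())) |>
    mutate(rank = as.integer(.data$rank))
  attr(out, "phenotype") <- phenotype
  class(out) <- c("drug_score_table", class(out))
  out
}
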