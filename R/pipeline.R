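#' Run the full scoring and evaluation pipeline from a config
#'
#' Orchestrates the whole pipeline from a YAML config (or equivalent list):
#' read inputs, compute FM scores, AC scores (when a signature matrix is
#' configured; otherwise the pipeline degrades to an FM-only table with a
#' warning), integrate into the ranked FAM table, evaluate against the
#' configured drug set (under-sampled AUROC, median percentile, permutation
#' P-value) and, when requested, run the leave-one-protein-out stability
#' analysis. All outputs are written as TSV/JSON into `out_dir` together
#' with a manifest recording the config hash, seed and package version;
#' rerunning with an identical config reproduces identical score tables.
#'
#' Config keys: `phenotype`, `inputs` (paths relative to the config file:
#' `gene_associations`, `drug_targets`, optional `disease_signature`,
#' `drug_signatures`, `drug_sets`), `affinity_transform`, `min_overlap`,
#' `n_perm` (FM null size), `n_reps` (AUROC repetitions), `seed`,
#' optional `evaluation_set` (set name to evaluate), optional
#' `stability_top_k`.
#'
#' @param config Path to a YAML config file, or a named list (then
#'   `base_dir` resolves relative input paths).
#' @param out_dir Output directory (default `<config dir>/output`).
#' @param base_dir Directory against which relative input paths resolve.
#' @return Invisibly, a list with `score_table`, `fm`, `ac`, `evaluation`,
#'   `stability`, `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL, base_dir = NULL) {
  if (is.character(config)) {
    base_dir <- base_dir %||% dirname(config)
    config <- yaml::read_yaml(config)
  }
  base_dir <- base_dir %||% "."
  need <- function(key) {
    val <- config$inputs[[key]]
    if (is.null(val)) {
      abort(sprintf("config key 'inputs.%s' is missing", key))
    }
    path <- file.path(base_dir, val)
    if (!file.exists(path)) {
      abort(sprintf("input file for 'inputs.%s' not found: %s", key, path))
    }
    path
  }
  opt <- function(key) {
    if (is.null(config$inputs[[key]])) NULL else need(key)
  }
  seed <- config$seed %||% abort("config key 'seed' is missing")
  n_perm <- config$n_perm %||% 10000
  n_reps <- config$n_reps %||% 1000
  min_overlap <- config$min_overlap %||% 10
  phenotype <- config$phenotype %||% NA_character_

  assoc <- read_gene_associations(need("gene_associations"),
                                  phenotype = phenotype)
  drug_targets <- read_drug_targets(
    need("drug_targets"),
    affinity_transform = config$affinity_transform %||% "identity")
  fm <- fm_scores(drug_targets, assoc, n_perm = n_perm, seed = seed)

  sig_path <- opt("drug_signatures")
  dis_path <- opt("disease_signature")
  ac <- NULL
  if (!is.null(sig_path) && !is.null(dis_path)) {
    disease <- read_disease_signature(dis_path, phenotype = phenotype)
    signatures <- read_signature_matrix(sig_path)
    ac <- ac_scores(disease, signatures, min_overlap = min_overlap)
  } else {
    warn("no signature matrix / disease signature configured: FM-only mode")
  }
  table <- fam_scores(fm, ac, phenotype = phenotype)

  evaluation <- NULL
  sets_path <- opt("drug_sets")
  eval_set <- config$evaluation_set
  if (!is.null(sets_path) && !is.null(eval_set) && !is.null(ac)) {
    sets <- read_drug_sets(sets_path)
    if (is.null(sets[[eval_set]])) {
      abort(sprintf("config 'evaluation_set' names unknown set '%s'", eval_set))
    }
    positives <- intersect(sets[[eval_set]], table$drug_id[!is.na(table$fam)])
    scores <- score_vector(table)
    aur <- undersampled_auroc(scores, positives, n_reps = n_reps,
                              seed = seed + 1L)
    med <- median_percentile(table, positives)
    perm <- permutation_pvalue(
      scores, function(s) {
        n <- length(s)
        pct <- 100 * (rank(s) - 1) / (n - 1)
        median(pct[positives])
      }, n_perm = max(n_perm, 1000), seed = seed + 2L)
    evaluation <- list(set = eval_set, auroc = aur,
                       median_percentile = med, permutation = perm)
  }

  stability <- NULL
  top_k <- config$stability_top_k %||% 0
  if (top_k > 0 && !is.null(ac)) {
    stability <- leave_one_out(drug_targets, assoc, disease, signatures,
                               top_k = top_k, min_overlap = min_overlap,
                               n_perm = n_perm, seed = seed)
  }

  out_dir <- out_dir %||% file.path(base_dir, "output")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(scores = file.path(out_dir, "drug_scores.tsv"))
  write_score_table(table, paths$scores)
  readr::write_tsv(fm$scores, file.path(out_dir, "fm_scores.tsv"),
                   progress = FALSE)
  if (!is.null(ac)) {
    readr::write_tsv(ac$scores, file.path(out_dir, "ac_scores.tsv"),
                     progress = FALSE)
  }
  if (!is.null(evaluation)) {
    jsonlite::write_json(
      list(set = evaluation$set,
           auroc_mean = evaluation$auroc$mean_auroc,
           auroc_sd = evaluation$auroc$sd_auroc,
           n_reps = evaluation$auroc$n_reps,
           median_percentile = evaluation$median_percentile,
           permutation_p = evaluation$permutation$p_value),
      file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(stability)) {
    readr::write_tsv(stability$report,
                     file.path(out_dir, "stability.tsv"), progress = FALSE)
  }
  manifest <- list(phenotype = phenotype,
                   config_hash = rlang::hash(config),
                   seed = seed, n_perm = n_perm, n_reps = n_reps,
                   package_version =
                     as.character(utils::packageVersion("famscore")),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(score_table = table, fm = fm, ac = ac,
                 evaluation = evaluation, stability = stability,
                 paths = paths, out_dir = out_dir))
}
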