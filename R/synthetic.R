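#' Specification for the synthetic study generator
#'
#' Bundles and validates the parameters of the synthetic-cohort generator.
#' Defaults define the package's reference study conditions: a 2000-gene
#' universe with a small strongly associated tail, 300 licensed-drug-scale
#' compounds with sparse target sets spanning 1-100 proteins, and 20
#' planted effective drugs.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_drugs Number of drugs (default 300).
#' @param n_effective Number of planted effective drugs (default 20).
#' @param target_count_range Integer pair: per-drug target counts are drawn
#'   log-uniformly in this range (default `c(1, 100)`), giving the sparse
#'   heavy-tailed bipartite structure seen in affinity databases.
#' @param effect_strength Nonnegative real controlling how strongly
#'   effective drugs target top-associated genes and anti-correlate with
#'   the disease signature (default 3; 0 gives a pure null in which the
#'   planted drugs are statistically indistinguishable).
#' @param noise_sd Standard deviation of the noise added to effective
#'   drugs' signatures (default 1, the scale of a null signature).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated list of class `generator_spec`.
#' @export
generator_spec <- function(n_genes = 2000, n_drugs = 300, n_effective = 20,
                           target_count_range = c(1, 100),
                           effect_strength = 3, noise_sd = 1, seed = 1) {
  if (n_effective > n_drugs) abort("n_effective must be <= n_drugs")
  if (length(target_count_range) != 2 ||
      target_count_range[1] < 1 || target_count_range[2] > n_genes ||
      target_count_range[1] > target_count_range[2]) {
    abort("target_count_range must be an increasing pair within [1, n_genes]")
  }
  if (effect_strength < 0) abort("effect_strength must be >= 0")
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  structure(list(n_genes = n_genes, n_drugs = n_drugs,
                 n_effective = n_effective,
                 target_count_range = as.integer(target_count_range),
                 effect_strength = effect_strength, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic disease-drug cohort with planted effective drugs
#'
#' Emulates the statistical structure of the real inputs so that every
#' pipeline stage is testable without downloads:
#'
#' * gene-level P-values are a uniform null plus a planted low-P tail
#'   (2% of genes, Beta(0.1, 20)), reproducing the heavy-tailed regime in
#'   which only a handful of genes reach genome-wide significance;
#' * the signed disease signature has magnitudes proportional to
#'   association strength with random directions;
#' * each drug receives a log-uniform number of targets; targets of
#'   effective drugs fall on planted signal genes with probability
#'   `effect_strength / (effect_strength + 1)` and carry high affinity,
#'   other targets and affinities are background;
#' * effective drugs' transcriptomic signatures are
#'   `-strength * disease_effect + N(0, noise_sd)` with a per-drug strength
#'   multiplier in `[0.5, 1.5] * effect_strength` (the top half by
#'   multiplier forms the `more_effective` set), all other drugs pure
#'   noise.
#'
#' With `effect_strength = 0` every branch above reduces to the background
#' distribution, giving an exact null.
#'
#' @param spec A [generator_spec()].
#' @return A list of class `fam_cohort`: `assoc`, `disease`,
#'   `drug_targets`, `signatures`, `drug_sets` (list `ASM`,
#'   `more_effective`, `less_effective`), `truth` (planted effective drug
#'   ids), `spec`.
#' @export
generate_cohort <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  withr::with_seed(spec$seed, {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    drugs <- sprintf("drug%03d", seq_len(spec$n_drugs))
    n_signal <- max(10L, round(0.02 * spec$n_genes))
    signal_genes <- genes[seq_len(n_signal)]
    p <- c(rbeta(n_signal, 0.1, 20), runif(spec$n_genes - n_signal))
    p <- pmin(pmax(p, 1e-300), 1)
    assoc <- tibble(gene_id = genes, p_value = p, z_stat = p_to_z(p))

    direction <- sample(c(-1, 1), spec$n_genes, replace = TRUE)
    disease <- tibble(gene_id = genes,
                      effect = direction * abs(assoc$z_stat) +
                        rnorm(spec$n_genes, 0, 0.25))

    truth <- sort(sample(drugs, spec$n_effective))
    p_signal <- spec$effect_strength / (spec$effect_strength + 1)
    lo <- log(spec$target_count_range[1])
    hi <- log(spec$target_count_range[2])
    k <- pmin(pmax(round(exp(runif(spec$n_drugs, lo, hi))),
                   spec$target_count_range[1]),
              spec$target_count_range[2])
    # signal genes are drawn weighted by association strength, so planted
    # drugs preferentially hit the top-associated proteins
    sig_w <- pmax(assoc$z_stat[seq_len(n_signal)], 0.1)
    drug_targets <- purrr::map(seq_len(spec$n_drugs), function(i) {
      ki <- k[i]
      on_signal <- if (drugs[i] %in% truth) {
        runif(ki) < p_signal
      } else {
        rep(FALSE, ki)
      }
      n_sig <- min(sum(on_signal), n_signal)
      tg <- character(0)
      if (n_sig > 0) {
        tg <- sample(signal_genes, n_sig, prob = sig_w)
      }
      tg <- c(tg, sample(setdiff(genes, tg), ki - length(tg)))
      # only deliberately planted signal targets get the affinity boost, so
      # effect_strength = 0 reduces exactly to the background distribution
      aff <- runif(ki, 1, 9)
      planted <- seq_len(n_sig)
      aff[planted] <- runif(n_sig, 6, 9)
      tibble(drug_id = drugs[i], gene_id = tg, affinity_weight = aff)
    }) |> purrr::list_rbind() |>
      arrange(.data$drug_id, .data$gene_id)

    mult <- runif(spec$n_effective, 0.5, 1.5)
    signatures <- matrix(rnorm(spec$n_genes * spec$n_drugs),
                         nrow = spec$n_genes,
                         dimnames = list(genes, drugs))
    for (j in seq_len(spec$n_effective)) {
      signatures[, truth[j]] <-
        -mult[j] * spec$effect_strength * disease$effect +
        rnorm(spec$n_genes, 0, spec$noise_sd)
    }
    more <- truth[mult >= median(mult)]
    drug_sets <- list(ASM = truth, more_effective = more,
                      less_effective = setdiff(truth, more))
    structure(list(assoc = assoc, disease = disease,
                   drug_targets = drug_targets, signatures = signatures,
                   drug_sets = drug_sets, truth = truth, spec = spec),
              class = "fam_cohort")
  })
}

#' @export
print.fam_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d genes, %d drugs (%d planted effective), effect strength %.1f, seed %d\n",
    x$spec$n_genes, x$spec$n_drugs, x$spec$n_effective,
    x$spec$effect_strength, x$spec$seed))
  invisible(x)
}

#' Write a synthetic cohort as a fixture directory
#'
#' Writes the standard input files (`gene_associations.tsv`,
#' `disease_signature.tsv`, `drug_targets.tsv`, `drug_signatures.tsv` wide,
#' `drug_sets.yaml`, `truth.txt`) plus a ready-to-run `config.yaml` for
#' [run_pipeline()].
#'
#' @param cohort A `fam_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param phenotype Phenotype label written into the config.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, phenotype = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(cohort$assoc[c("gene_id", "p_value")],
                   p("gene_associations.tsv"), progress = FALSE)
  readr::write_tsv(cohort$disease, p("disease_signature.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$drug_targets, p("drug_targets.tsv"),
                   progress = FALSE)
  wide <- as_tibble(cohort$signatures, rownames = "gene_id") |>
    mutate(across(where(is.numeric), \(x) signif(x, 12)))
  readr::write_tsv(wide, p("drug_signatures.tsv"), progress = FALSE)
  yaml::write_yaml(cohort$drug_sets, p("drug_sets.yaml"))
  writeLines(cohort$truth, p("truth.txt"))
  cfg <- list(
    phenotype = phenotype,
    inputs = list(gene_associations = "gene_associations.tsv",
                  disease_signature = "disease_signature.tsv",
                  drug_targets = "drug_targets.tsv",
                  drug_signatures = "drug_signatures.tsv",
                  drug_sets = "drug_sets.yaml"),
    affinity_transform = "identity",
    min_overlap = 10,
    n_perm = 2000,
    n_reps = 1000,
    seed = cohort$spec$seed,
    evaluation_set = "ASM")
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(dir)
}
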