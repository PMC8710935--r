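test_that("generator specs are validated", {
  expect_error(generator_spec(n_drugs = 10, n_effective = 20),
               "n_effective")
  expect_error(generator_spec(target_count_range = c(0, 10)),
               "target_count_range")
  expect_error(generator_spec(n_genes = 50, target_count_range = c(1, 100)),
               "target_count_range")
  expect_error(generator_spec(effect_strength = -1), "effect_strength")
  expect_error(generator_spec(noise_sd = 0), "noise_sd")
})

test_that("generation is deterministic given the seed", {
  s <- generator_spec(n_genes = 200, n_drugs = 40, n_effective = 5, seed = 9)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$assoc, b$assoc)
  expect_identical(a$drug_targets, b$drug_targets)
  expect_identical(a$signatures, b$signatures)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(generator_spec(n_genes = 200, n_drugs = 40,
                                      n_effective = 5, seed = 10))
  expect_false(identical(a$assoc$p_value, c$assoc$p_value))
})

test_that("generated tables satisfy the declared invariants", {
  co <- generate_cohort(generator_spec(n_genes = 300, n_drugs = 50,
                                       n_effective = 6, seed = 2))
  expect_equal(anyDuplicated(co$assoc$gene_id), 0)
  expect_true(all(co$assoc$p_value > 0 & co$assoc$p_value <= 1))
  expect_equal(anyDuplicated(co$drug_targets[c("drug_id", "gene_id")]), 0)
  expect_true(all(co$drug_targets$affinity_weight >= 0))
  counts <- dplyr::count(co$drug_targets, drug_id)
  expect_equal(nrow(counts), 50)
  expect_true(all(counts$n >= 1 & counts$n <= 100))
  expect_true(all(is.finite(co$signatures)))
  expect_true(all(co$truth %in% colnames(co$signatures)))
  # planted low-p tail produces a handful of strong associations
  expect_gt(sum(co$assoc$p_value < 1e-4), 0)
  expect_lt(sum(co$assoc$p_value < 1e-4), 0.1 * 300)
})

test_that("effective drugs preferentially target top-associated genes", {
  co <- planted_cohort()
  n_signal <- max(10, round(0.02 * co$spec$n_genes))
  signal <- co$assoc$gene_id[seq_len(n_signal)]
  # pooled fraction of targets on signal genes; the signal-gene pool is
  # small, so large-target drugs saturate it and the pooled fraction sits
  # well below the per-target planting probability
  frac <- co$drug_targets |>
    dplyr::mutate(effective = drug_id %in% co$truth,
                  on_signal = gene_id %in% signal) |>
    dplyr::group_by(effective) |>
    dplyr::summarise(frac = mean(on_signal))
  expect_gt(frac$frac[frac$effective], 0.3)
  expect_lt(frac$frac[!frac$effective], 0.1)
  expect_gt(frac$frac[frac$effective], 5 * frac$frac[!frac$effective])
})

test_that("effective drugs anti-correlate with the disease signature", {
  co <- planted_cohort()
  cors <- cor(co$signatures, co$disease$effect)[, 1]
  expect_true(all(cors[co$truth] < -0.5))
  expect_lt(max(abs(cors[setdiff(colnames(co$signatures), co$truth)])), 0.3)
})

test_that("a zero-effect cohort carries no recoverable signal", {
  co <- generate_cohort(generator_spec(n_genes = 400, n_drugs = 120,
                                       n_effective = 15,
                                       effect_strength = 0, seed = 8))
  ac <- suppressMessages(ac_scores(co$disease, co$signatures))
  sv <- setNames(ac$scores$ac_z, ac$scores$drug_id)
  a <- undersampled_auroc(sv, co$truth, n_reps = 500, seed = 3)
  # chance-level discrimination, within the sampling noise of 15 positives
  expect_lt(abs(a$mean_auroc - 0.5), 0.2)
  # no affinity boost leaks into the null: weight distributions match
  w <- co$drug_targets |>
    dplyr::mutate(effective = drug_id %in% co$truth)
  expect_lt(abs(mean(w$affinity_weight[w$effective]) -
                  mean(w$affinity_weight[!w$effective])), 0.5)
})

test_that("truth recovery improves monotonically with effect strength", {
  # a noisier signature regime than the defaults, so recovery is not
  # already saturated at intermediate strengths
  recover <- function(strength, seed) {
    co <- generate_cohort(generator_spec(n_genes = 400, n_drugs = 80,
                                         n_effective = 10,
                                         effect_strength = strength,
                                         noise_sd = 3, seed = seed))
    ac <- suppressMessages(ac_scores(co$disease, co$signatures))
    fm <- suppressMessages(fm_scores(co$drug_targets, co$assoc,
                                     n_perm = 300, seed = seed + 500))
    sv <- score_vector(fam_scores(fm, ac))
    auroc(sv, intersect(co$truth, names(sv)),
          setdiff(names(sv), co$truth))
  }
  seeds <- 1:8
  a0 <- sapply(seeds, function(s) recover(0, s))
  a1 <- sapply(seeds, function(s) recover(0.3, s))
  a3 <- sapply(seeds, function(s) recover(3, s))
  expect_lt(suppressWarnings(
    wilcox.test(a0, a1, alternative = "less")$p.value), 0.05)
  expect_lt(suppressWarnings(
    wilcox.test(a1, a3, alternative = "less")$p.value), 0.05)
})

test_that("cohort fixtures round-trip through the readers", {
  co <- generate_cohort(generator_spec(n_genes = 120, n_drugs = 25,
                                       n_effective = 4, seed = 77))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  assoc <- read_gene_associations(file.path(dir, "gene_associations.tsv"))
  expect_equal(nrow(assoc), 120)
  expect_equal(sort(assoc$gene_id), sort(co$assoc$gene_id))
  dt <- read_drug_targets(file.path(dir, "drug_targets.tsv"))
  expect_equal(nrow(dt), nrow(co$drug_targets))
  mat <- suppressMessages(read_signature_matrix(
    file.path(dir, "drug_signatures.tsv")))
  expect_equal(dim(mat), dim(co$signatures))
  expect_equal(mat[sort(rownames(co$signatures)),
                   sort(colnames(co$signatures))],
               co$signatures[sort(rownames(co$signatures)),
                             sort(colnames(co$signatures))],
               tolerance = 1e-10)
  sets <- read_drug_sets(file.path(dir, "drug_sets.yaml"))
  expect_equal(sort(sets$ASM), sort(co$truth))
})
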