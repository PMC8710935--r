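# Small deterministic fixtures shared across test files. Built in code so
# the repository carries no binary data; sizes chosen so the whole suite
# runs in minutes.

tiny_assoc <- function() {
  tibble::tibble(
    gene_id = c("G1", "G2", "G3", "G4", "G5", "G6"),
    p_value = c(1e-6, 0.001, 0.02, 0.2, 0.5, 0.9)
  ) |>
    dplyr::mutate(z_stat = famscore::p_to_z(p_value))
}

tiny_targets <- function() {
  tibble::tibble(
    drug_id = c("d1", "d1", "d2", "d2", "d3", "d4"),
    gene_id = c("G1", "G2", "G3", "G5", "G4", "GX"),
    affinity_weight = c(8, 4, 6, 2, 5, 9)
  )
}

# Mid-size planted cohort reused by recovery-style tests (generated once
# per test run).
planted_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- famscore::generate_cohort(
        famscore::generator_spec(n_genes = 800, n_drugs = 150,
                                 n_effective = 15, effect_strength = 3,
                                 seed = 42))
    }
    cache
  }
})

write_tsv_fixture <- function(df, name = "fixture.tsv") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE)
  path
}
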