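test_that("auroc equals brute-force concordant-pair counting", {
  brute <- function(scores, pos, neg) {
    tot <- 0
    for (p in pos) for (n in neg) {
      tot <- tot + as.numeric(scores[[p]] > scores[[n]]) +
        0.5 * (scores[[p]] == scores[[n]])
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(2)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    scores <- setNames(sample(1:5, n, replace = TRUE) + runif(n, 0, 0.5),
                       paste0("d", 1:n))
    pos <- paste0("d", 1:3)
    neg <- paste0("d", 4:n)
    expect_equal(auroc(scores, pos, neg), brute(scores, pos, neg))
  }
  # perfect separation and the all-ties case
  s <- setNames(c(3, 2, 1, 0), c("p1", "p2", "n1", "n2"))
  expect_equal(auroc(s, c("p1", "p2"), c("n1", "n2")), 1)
  expect_equal(auroc(setNames(rep(1, 4), names(s)), c("p1", "p2"),
                     c("n1", "n2")), 0.5)
  expect_error(auroc(s, c("p1", "n1"), c("n1", "n2")), "overlap")
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- setNames(rnorm(40), paste0("d", 1:40))
  pos <- paste0("d", 1:12)
  neg <- paste0("d", 13:40)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(
    response = c(rep(1, 12), rep(0, 28)), predictor = scores,
    levels = c(0, 1), direction = "<", quiet = TRUE))))
  expect_equal(auroc(scores, pos, neg), ref, tolerance = 1e-12)
})

test_that("auroc complement identity holds for tie-free scores", {
  set.seed(5)
  scores <- setNames(rnorm(30), paste0("d", 1:30))
  pos <- paste0("d", 1:10); neg <- paste0("d", 11:30)
  expect_equal(auroc(scores, pos, neg) + auroc(-scores, pos, neg), 1)
})

test_that("under-sampled AUROC is deterministic and matches the full value", {
  co <- planted_cohort()
  fm <- suppressMessages(fm_scores(co$drug_targets, co$assoc,
                                   n_perm = 800, seed = 2))
  tab <- fam_scores(fm, suppressMessages(ac_scores(co$disease,
                                                   co$signatures)))
  sv <- score_vector(tab)
  pos <- intersect(co$truth, names(sv))
  a1 <- undersampled_auroc(sv, pos, n_reps = 1000, seed = 7)
  a2 <- undersampled_auroc(sv, pos, n_reps = 1000, seed = 7)
  expect_identical(a1$reps, a2$reps)
  full <- auroc(sv, pos, setdiff(names(sv), pos))
  expect_lt(abs(a1$mean_auroc - full), 0.02)
  # perfectly separated positives give mean 1, sd 0
  s <- setNames(c(10, 9, 1:8), c("p1", "p2", paste0("n", 1:8)))
  ap <- undersampled_auroc(s, c("p1", "p2"), n_reps = 50, seed = 1)
  expect_equal(ap$mean_auroc, 1)
  expect_equal(ap$sd_auroc, 0)
  expect_error(undersampled_auroc(s, paste0("n", 1:6), n_reps = 10, seed = 1),
               "insufficient negatives")
})

test_that("random scores give chance-level under-sampled AUROC", {
  set.seed(14)
  scores <- setNames(rnorm(200), paste0("d", 1:200))
  pos <- paste0("d", 1:25)
  a <- undersampled_auroc(scores, pos, n_reps = 1000, seed = 3)
  full <- auroc(scores, pos, setdiff(names(scores), pos))
  # the under-sampled mean estimates the full AUROC of this score draw
  expect_lt(abs(a$mean_auroc - full), 3 * a$sd_auroc / sqrt(1000) + 0.005)
})

test_that("median percentile summarizes a drug set's ranks", {
  ids <- sprintf("d%03d", 1:101)
  tab <- fam_scores(tibble::tibble(drug_id = ids, fm_z = seq(101, 1)),
                    tibble::tibble(drug_id = ids, ac_z = seq(101, 1)))
  # single drug at rank 7 of 101 -> percentile 94
  expect_equal(median_percentile(tab, ids[7]), 94)
  # even-cardinality set: mean of the two central percentiles
  expect_equal(median_percentile(tab,
                                 ids[c(which(tab$percentile == 27),
                                       which(tab$percentile == 73))]), 50)
  # the whole cohort centres on 50
  expect_equal(median_percentile(tab, ids), 50)
  expect_error(median_percentile(tab, "nope"), "no member")
})

test_that("permutation p-values match exhaustive enumeration on a toy", {
  scores <- setNames(c(4, 3, 2, 1), c("a", "b", "c", "d"))
  stat <- function(s) s[["a"]] - s[["d"]]
  obs <- stat(scores)
  # enumerate all 4! assignments of the scores to the drugs
  all_p <- expand.grid(rep(list(1:4), 4))
  all_p <- all_p[apply(all_p, 1, function(r) length(unique(r)) == 4), ]
  null_exact <- apply(all_p, 1, function(r) {
    s <- setNames(scores[r], names(scores))
    stat(s)
  })
  exact_p <- mean(null_exact >= obs)
  pt <- permutation_pvalue(scores, stat, n_perm = 4000, seed = 9)
  expect_lt(abs(pt$p_value - exact_p), 0.02)
  # observed at the null median gives p near 0.5: the value landing on
  # drug b is uniform over {4,3,2,1}, so P(null >= observed 3) = 1/2
  stat2 <- function(s) s[["b"]]
  pt2 <- permutation_pvalue(scores, stat2, n_perm = 1000, seed = 1)
  expect_lt(abs(pt2$p_value - 0.5), 0.05)
  # a constant statistic ties every permutation: p = 1
  pt3 <- permutation_pvalue(scores, function(s) 0, n_perm = 500, seed = 1)
  expect_equal(pt3$p_value, 1)
})

test_that("add-one estimator floors at 1/(1 + n_perm)", {
  # a statistic uniquely maximized by the observed assignment: the chance
  # a random permutation of 10 scores reproduces it is 1/10!, so with 999
  # sampled permutations the p-value sits at its floor
  scores <- setNames(seq(10, 1), paste0("d", 1:10))
  stat <- function(s) sum(s * seq(10, 1))
  pt <- permutation_pvalue(scores, stat, n_perm = 999, seed = 2)
  expect_equal(pt$p_value, 1 / 1000)
  expect_equal(pt$p_value, (1 + sum(pt$null_stats >= pt$observed_stat)) /
                 (1 + pt$n_perm))
})

test_that("concordance statistics encode order-and-percentile claims", {
  scores <- setNames(c(10, 9, 8, 1:7), c("top1", "top2", "top3",
                                         paste0("x", 1:7)))
  stat <- concordance_stat(c("top1", "top2", "top3"), min_percentile = 70)
  expect_equal(stat(scores), 1)
  # wrong claimed order fails
  stat_bad <- concordance_stat(c("top2", "top1"), min_percentile = 0)
  expect_equal(stat_bad(scores), 0)
  pt <- permutation_pvalue(scores, stat, n_perm = 2000, seed = 4)
  # chance of 3 named drugs taking the top 3 slots in a fixed order is
  # 7!/10! = 1/720
  expect_lt(abs(pt$p_value - 1 / 720), 0.005)
})

test_that("BH correction follows the step-up rule", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_correct(0.2), 0.2)
  expect_equal(bh_correct(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  out <- bh_correct(p)
  expect_true(all(diff(out[order(p)]) >= -1e-15))
  expect_true(all(out <= 1))
  expect_error(bh_correct(c(0, 0.5)), "in \\(0, 1\\]")
})

test_that("the standard significant-target baseline reports recall/precision/F", {
  # one genome-wide-significant gene targeted by 175 drugs, 56 of them in
  # the 160-drug reference set: recall 35%, precision 32%, F-score 33%
  assoc <- tibble::tibble(gene_id = c("SIG1", "OTH1"),
                          p_value = c(1e-9, 0.2)) |>
    dplyr::mutate(z_stat = p_to_z(p_value))
  pred_drugs <- sprintf("pd%03d", 1:175)
  ref <- c(pred_drugs[1:56], sprintf("ref%03d", 1:104))
  dt <- tibble::tibble(drug_id = pred_drugs, gene_id = "SIG1",
                       affinity_weight = 5)
  res <- standard_method_baseline(assoc, dt, 5e-8, ref)
  expect_equal(res$recall, 0.35)
  expect_equal(res$precision, 0.32)
  expect_equal(round(100 * res$f_score), 33)
  # empty prediction flags and zeroes out
  res0 <- standard_method_baseline(
    dplyr::mutate(assoc, p_value = c(0.5, 0.2)), dt, 5e-8, ref)
  expect_true(res0$empty_prediction)
  expect_equal(res0$recall, 0)
  expect_equal(res0$f_score, 0)
  # perfect prediction
  resp <- standard_method_baseline(assoc, dt, 5e-8, pred_drugs)
  expect_equal(resp$recall, 1)
  expect_equal(resp$precision, 1)
  expect_equal(resp$f_score, 1)
})

test_that("gene-set t-test matches a textbook Welch computation", {
  assoc <- tibble::tibble(
    gene_id = paste0("G", 1:6),
    p_value = rep(0.5, 6),
    z_stat = c(3.1, 2.7, 2.9, 0.2, -0.5, 0.1))
  dt <- tibble::tibble(drug_id = "d1", gene_id = c("G1", "G2", "G3"),
                       affinity_weight = 1)
  res <- gene_set_ttest(assoc, dt, "d1")
  ref <- t.test(c(3.1, 2.7, 2.9), c(0.2, -0.5, 0.1),
                alternative = "greater", var.equal = FALSE)
  expect_equal(res$t_stat, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  # identical target and non-target z gives p = 0.5
  assoc2 <- dplyr::mutate(assoc,
                          z_stat = c(1, 2, 3, 1, 2, 3))
  res2 <- gene_set_ttest(assoc2, dt, "d1")
  expect_equal(res2$p_value, 0.5, tolerance = 1e-9)
  # degenerate zero-variance case flagged with p = 1
  assoc3 <- dplyr::mutate(assoc, z_stat = 1)
  res3 <- gene_set_ttest(assoc3, dt, "d1")
  expect_equal(res3$p_value, 1)
  expect_true(res3$degenerate)
})
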