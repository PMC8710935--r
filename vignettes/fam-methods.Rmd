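---
title: "The FAM score: model, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The FAM score: model, assumptions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscore)
library(dplyr)
```

## The problem

For complex diseases such as the common epilepsies, genome-wide association
studies (GWAS) implicate many genes, almost all of them below genome-wide
significance, and transcriptome-wide association studies (TWAS) add signed
estimates of how gene-product abundance shifts in the disease. The question
this package addresses is how to turn those diffuse signals, together with
two drug-level resources — drug-target binding affinities and drug-induced
transcriptomic signatures — into a ranking of all licensed drugs by
predicted relative efficacy, rather than a short unranked list of drugs
hitting the one or two genome-wide-significant targets.

`famscore` computes a per-drug **FAM score** that averages two standardized
components:

* **FM (function modulation).** For drug $d$ with target set $T_d$ and
  per-gene association statistics $z_g = \Phi^{-1}(1 - p_g)$,
  $$\mathrm{FM}^{raw}_d = \frac{1}{|T_d|} \sum_{g \in T_d} \tilde w_{dg}\, z_g,$$
  where $\tilde w_{dg}$ is the drug-target affinity weight normalized by
  the largest weight in the table. The raw score is then standardized
  against a permutation null matched on target-set size: for a drug with
  $k$ scoreable targets, random $k$-gene sets are drawn without replacement
  from the association table (reusing the drug's own weights) and
  $\mathrm{FM}_d = (\mathrm{FM}^{raw}_d - \mu_k)/\sigma_k$. This controls
  for the very different numbers of proteins drugs are known to affect
  (1 to ~100 in affinity databases). Finally FM is z-scored across drugs.
* **AC (abundance correction).** With disease signature $u$ (signed
  abundance change per gene) and drug signature $v_d$, restricted to their
  shared genes,
  $$\mathrm{AC}^{raw}_d = 1 - \frac{u \cdot v_d}{\lVert u\rVert\,\lVert v_d\rVert} \in [0, 2],$$
  the cosine distance. A distance near 2 means the drug pushes
  disease-associated gene products in the direction opposite to the
  disease, i.e. a corrective signature; AC is the z-score of this distance
  across drugs, oriented so higher is better.

$$\mathrm{FAM}_d = \tfrac{1}{2}(\mathrm{FM}_d + \mathrm{AC}_d).$$

Drugs without an assayed transcriptomic signature get no AC and hence no
FAM score; they are retained in FM-only outputs but excluded from FAM
rankings. Ranks (1 = best) convert to percentiles by
$100\,(n - r)/(n - 1)$, so percentile 90 means "ranked above 90% of all
scored drugs".

## Conventions and parameters that matter

* **P-to-z convention.** $z = \Phi^{-1}(1 - p)$, one-sided: larger $z$ is
  stronger association, the median P-value maps to $z = 0$. P-values below
  1e-300 are clamped so the transform stays finite. The gene-set t-test
  comparator, which in its original form asks whether target genes have
  *lower* mean z under the opposite convention, is expressed internally
  with the direction flipped to match.
* **Affinity transform** (`identity` or `neglog10_nM`): affinity inputs
  arrive either already on a potency scale (e.g. pChEMBL) or as nanomolar
  concentrations; `neglog10_nM` maps Ki = 100 nM to weight 7. Weights are
  max-normalized, so all FM outputs are invariant to rescaling the whole
  affinity column.
* **`n_perm`** (default 10 000): size of the FM permutation null. The
  adjusted score's Monte Carlo error scales as $1/\sqrt{n_\mathrm{perm}}$;
  tests in this package use 200-2000 to keep the suite fast, which is
  plenty for rank stability at the cohort sizes used there.
* **`min_overlap`** (default 10 genes): minimum disease-drug gene overlap
  for an AC score; cosine similarity in fewer than ~10 dimensions is
  noise-dominated. Excluded drugs are reported, not silently dropped.
* **Identifier normalization.** Genes: uppercased symbols, exact string
  join. Drugs: lowercased, punctuation stripped, with an optional synonym
  table applied first — affinity and expression resources rarely agree on
  drug names, and no single reconciliation is canonical, so the hook is
  user-supplied.

## Validation machinery

Evaluation follows the design used for GWAS-driven drug-prediction
benchmarks:

* **Under-sampled AUROC.** Known effective drugs are a small fraction of
  all drugs, so the AUROC discriminating them from the rest is estimated
  by repeatedly (default 1000 times) sampling an equal-size negative set
  and averaging; the AUROC itself is the tie-corrected Mann-Whitney
  statistic. When comparing more- versus less-effective subsets the
  classes are balanced and under-sampling is unnecessary.
* **Median percentile.** The prioritization of a drug set is its members'
  median percentile rank — the median resists the skew of a few badly
  ranked members.
* **Permutation nulls.** Significance of any rank statistic comes from
  shuffling the score-to-drug assignment (default $10^5$, configurable to
  $10^6$) with the add-one estimator
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n)$, which never
  returns zero and floors at $1/(n+1)$. Compound clinical-concordance
  claims ("these drugs all above percentile X, in this order") are
  expressed as indicator statistics via `concordance_stat()`. Families of
  P-values are Benjamini-Hochberg corrected.
* **Comparators.** The *standard method* predicts drugs targeting any
  genome-wide-significant gene and is scored by recall/precision/F-score
  (it yields no ranking). The *gene-set method* scores each drug by a
  one-sided Welch t-test comparing its target genes' z to all other
  genes'.
* **Stability.** `leave_one_out()` removes the top-k most strongly
  associated contributing genes one at a time — from the association
  table, the disease signature and the target table together, since all
  three feed the score — and reports Kendall's tau-b between the
  recomputed and original rankings. Exclusions are judged over the drugs
  ranked in both; a drug whose only target was excluded drops out and is
  counted.

## What the synthetic generator emulates

`generate_cohort()` plants known structure so that recovery, calibration
and stability are all testable offline:

* gene P-values: 98% uniform, 2% from Beta(0.1, 20) — a heavy-tailed
  association profile where only a handful of genes pass genome-wide
  significance, matching the regime of common-epilepsy GWAS;
* disease signature: magnitudes proportional to association strength,
  random signs, small jitter;
* drug-target structure: per-drug target counts log-uniform in 1-100;
  planted effective drugs put each target on a signal gene with
  probability $s/(s+1)$ (weighted toward the strongest genes, with high
  affinity), where $s$ is `effect_strength`;
* drug signatures: effective drugs follow
  $-m_d\, s \cdot u + \mathcal N(0, \sigma)$ with a per-drug multiplier
  $m_d \in [0.5, 1.5]$ (the top half by $m_d$ forms a `more_effective`
  set), all other drugs pure noise;
* the planted drug set is a random subset of the universe, so two
  independently generated phenotypes share few effective drugs and their
  rankings are near-uncorrelated.

At `effect_strength = 0` every branch reduces exactly to the background
distribution — the planted labels become pure bookkeeping — which is what
the calibration tests rely on. The defaults (2000 genes, 300 drugs, 20
effective, strength 3, noise 1) are the package's reference conditions.

What the generator does **not** emulate: linkage disequilibrium between
genes, tissue-specific expression structure, correlated drug classes
sharing targets, or measurement error in affinity data. Passing recovery
tests on this generator therefore demonstrates that the machinery is
correct and well calibrated, not that real GWAS/TWAS/affinity inputs will
yield comparable accuracy.

## Numerical and design choices

* The exact composition of the FM ingredients (mean over targets;
  permutation-based size adjustment) is this package's choice among the
  variants consistent with the score's published description; both stated
  ingredients — per-target association strength and per-target drug
  effect — and the size adjustment are preserved, with the fewest free
  choices.
* Zero-variance standardization (all drugs tied) maps to all-zero
  z-scores with a warning rather than an error.
* A drug whose scoreable-target set spans the entire gene universe has a
  degenerate (point-mass) size-adjustment null; its adjusted score is
  defined as 0.
* Duplicate input rows collapse deterministically (min-P for genes,
  max-weight for targets, median for replicate signature columns), and
  collapsing is order-independent.
* FAM ties break lexicographically by drug id, making every output table
  deterministic.
* Cosine distances are standardized directly (not rank-transformed
  first); with hundreds of drugs the two are nearly monotone-equivalent,
  and direct standardization keeps AC on the same scale as FM.
* The top-candidate demarcation scans every cutoff k and minimizes the
  one-sided hypergeometric enrichment P-value (smallest k on ties), with
  BH correction over the scan; a fixed cutoff would hide the enrichment
  structure the scan makes explicit.
* The under-sampled AUROC of a *single* cohort of ~20 positives has
  sampling sd near 0.07 even under the null; calibration checks therefore
  average replicate cohorts rather than trusting one draw.
* Excluding a gene in `leave_one_out()` also shrinks the FM null universe
  by one gene and re-draws the sampled null, so tau for a
  nothing-contributing gene that is still in the association table is 1
  only up to Monte Carlo noise; the exact no-op property holds for genes
  outside all three inputs.
* Problem sizes in the test suite (cohorts of 300-800 genes, 60-150
  drugs, FM nulls of 200-2000 draws) were chosen as the smallest at which
  the planted-signal and calibration properties are stable across seeds.

## Known limitations

* FM ignores direction of drug action (agonist vs antagonist); a high FM
  score can belong to a disease-aggravating drug. AC is directional and
  partially compensates, which is one motivation for the average.
* Knowledge of drug targets is incomplete and unevenly so; sparsely
  annotated drugs have noisier (and likely underestimated) FM scores.
* Gene/drug identifier harmonization is string-based; supply a synonym
  table when joining resources with different vocabularies.
* The FAM average weights FM and AC equally; no attempt is made to learn
  weights, which would require labeled training data and risk
  circularity with the evaluation sets.
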