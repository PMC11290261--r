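---
title: "Predicting metabolite-gene-pathway sets: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting metabolite-gene-pathway sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Somatic mutations can rewire tumor metabolism; the canonical examples are
oncometabolites such as 2-hydroxyglutarate accumulating under IDH1/2
mutation. `mgpflux` screens a tumor cohort for such signals without
metabolomics on every sample: it predicts, from a genome-scale metabolic
model (GEM) and per-sample RNA-seq, which metabolites' turnover differs
between mutant and wild-type samples of each gene, and through which
biosynthetic pathway. One finding is a metabolite-gene-pathway set (MGP).

The method rests on three assumptions worth stating plainly:

1. **Pseudo-steady state.** Intracellular metabolism satisfies S·v = 0, so
   a metabolite's production and consumption balance; its *flux-sum*
   F_i = Σ_{j∈P_i} S_ij·v_j over producing reactions is a turnover proxy.
   We count only realized production (S_ij·v_j > 0 at the solution; a
   reversible reaction running backwards produces on its nominal substrate
   side) and never consumption.
2. **Expression is an imperfect but usable flux surrogate.** Per-sample
   fluxes are fitted by least absolute deviation (LAD) between reaction
   activity scores and flux magnitudes. LAD (rather than least squares)
   limits the influence of the many reactions where transcript abundance
   and flux disagree.
3. **Rank statistics suffice.** All group comparisons are two-sided
   Wilcoxon rank-sum tests; no distributional form is assumed for
   flux-sums, which are bounded, skewed, and often contain exact zeros.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 0.05 | probability | step-2 and step-3 significance gate; raw, no multiplicity correction by design; a Benjamini-Hochberg pass can be layered on the output tables |
| `z_threshold` | 3.5 | modified-Z units | step-4 outlier gate, the conventional robust-outlier cut |
| `scale_cap` | 1000 | flux units | the largest reaction score per sample is mapped to this value, the conventional GEM bound magnitude; makes the fit invariant to library-size rescaling |
| `min_alt_reads` | 7 | reads | variants with fewer alternative reads are unreliable calls |
| `min_group` | 3 | samples | a Wilcoxon test needs at least 3 vs 3 for any chance of p < 0.05 |
| `max_missing_frac` | 0.20 | fraction | metabolome peaks missing in more than 20 % of samples are dropped rather than imputed |
| `knn_k` | 10 | peaks | feature-wise KNN imputation neighborhood |
| `auc_threshold` | 0.7 | AUC | conventional "acceptable discrimination" cut for biomarker AUCs |
| `empirical_resamples` | 1e5 | draws | Monte-Carlo resolution of the empirical p-value (seed mandatory) |

## Numerical choices

**GPR scoring.** AND nodes take the minimum of operand scores (a complex is
limited by its scarcest subunit), OR nodes the sum (isozymes contribute
additively). Genes missing from the expression table score 0.

**The LAD linear program.** Each reaction is split into nonnegative
forward/backward components; the objective compares u_j = v_j⁺ + v_j⁻
(expression is directionless) with the rescaled score. Alternate optima are
resolved by a second lexicographic stage minimizing total flux Σ u_j subject
to the stage-1 optimum (slack 1e-9), which makes fluxes — not just the
objective — deterministic. Solutions are asserted, not assumed, to satisfy
steady state to 1e-6 in flux units and bounds to 1e-6. The LP is solved by
scipy's HiGHS backend through a bundled Python helper, batched over all
samples of a cohort per interpreter start; no LP solver exists in the
package's R dependency footprint, and HiGHS is deterministic.

**Quantile normalization.** Rank-mean convention (ties receive the mean of
the reference values at their rank positions), applied per cohort across
samples. Two rules follow: values that were exactly 0 before normalization
are reset to 0 (a metabolite with no production must not acquire one by
normalization), and the pathway decomposition is rescaled proportionally,
f*_{i,p} = (F*_i/F_i)·f_{i,p}, with all f*_{i,p} = 0 when F_i = 0 (the
ratio is undefined there, and the zero-restoration rule must hold).

**Wilcoxon mode.** Exact tail probabilities (full null distribution of the
rank sum) when min(n₁, n₂) ≤ 8 and the data are tie-free; otherwise the
normal approximation with tie correction and continuity correction. Exactness
is cheap precisely where small cohorts need it.

**Modified Z-score.** Z = (x − median) / (MAD/Φ⁻¹(3/4)); when MAD = 0 (at
least half the group identical) the mean absolute deviation from the median
takes over, Z = (x − median)/(√(π/2)·MeanAD); when both vanish the group is
constant, all Z are 0, and nothing is selected — no outlier exists by
construction.

**Step-4 statistic.** The score of a gene within a (metabolite, pathway)
group is the *mean of its mutant samples'* adjusted target flux-sums. The
alternative — averaging over all samples — dilutes the contrast between
genes, since wild-type samples dominate every gene's mean; it remains
available via `x_mean_samples = "all"`. Step-2 testing is per compartmented
metabolite (akg_c and akg_m tested separately); compartments are merged only
when counting unique MG pairs, which mirrors how pairs are reported.

**"Subset" gene filter.** A gene whose mutant-sample set is a strict subset
of another retained gene's mutant-sample set is statistically inseparable
from it (every test on the subset gene is confounded by the superset gene);
it is dropped, keeping the gene with the larger mutant set, ties broken
lexicographically. Identical sets are not strict subsets and both genes are
kept.

**Generalized logarithm.** glog(x) = log₂((x + √(x² + λ²))/2) with λ equal
to the smallest positive value of the sum-normalized matrix by default
(configurable). This pins the transform's linear-to-log transition at the
data's own detection floor, the behavior of the web tools commonly used for
this normalization chain.

**AUC direction.** Reported as max(a, 1 − a): a mutation can raise or lower
a metabolite, and "AUC > 0.7" is meant as two-sided discrimination.

**Empirical p-value.** Draw `n_pairs` AUCs without replacement from the
background pool (all annotated peaks × tested genes), count resamples with
at least the observed number above threshold, and smooth by +1/(N+1) so the
estimate is never exactly 0. The resampling scheme converges to the
hypergeometric tail on homogeneous pools, which is what the tests check.

## What the synthetic world emulates — and what it does not

`generate_toy_gem()` builds linear biosynthetic pathways (exchange →
transport → chain → hub), with hub metabolites shared between pathways so
the pathway decomposition of a flux-sum is non-trivial, plus transport and
exchange/demand reactions so the exclusion rules have something to exclude.
`simulate_cohort()` plants a multiplicative expression effect on one
pathway's genes in the mutant samples, emits a variant table that passes the
mutation filter cascade, and a metabolome with planted log-fold changes and
missing-at-random entries.

Three generator choices deserve justification, all fixed at design time:

* **A constitutive housekeeping pathway with high expression (5000 TPM).**
  The expression-to-flux rescaling divides by the sample's maximum reaction
  score. In genome-scale data that maximum comes from constitutive genes
  and is stable across mutation groups; in a toy model without such an
  anchor, a planted 5× effect would shift the maximum itself and thereby
  rescale every unperturbed pathway — an artifact no genome-scale run
  exhibits.
* **Scale: 12 pathways × 4 reactions, 4 hubs (~72 testable metabolites).**
  Quantile normalization is rank-based: with too few metabolites the
  normalized values live on a coarse grid, the Wilcoxon tests become
  heavily tied and conservative, and a planted effect on a top-ranked hub
  can be erased entirely. The real cohorts normalized over ~355 metabolites;
  the toy world needs enough metabolites for the same machinery to behave,
  and ~70 is the smallest scale at which the rank tests hold their nominal
  level while staying fast enough for 100 end-to-end runs in minutes.
* **2:1 condensation at the hub-producing step, and a log-normal
  per-pathway expression factor (sd 0.5).** Both keep hub turnover on the
  same scale as chain fluxes so that metabolite ranks interleave across
  samples, as they do in real flux-sum matrices, instead of freezing into a
  fixed order.

What a green end-to-end test establishes: on cohorts whose group structure
matches the workflow's assumptions (a coherent expression shift on one
pathway, stable library scale, enough metabolites for rank resolution), the
pipeline recovers the planted MGP and its false MG-pairing rate under the
null is consistent with the test level. What it does not establish: behavior
under expression effects that are not pathway-coherent, context-specific
model extraction (out of scope), batch effects, or the biological fidelity
of any particular GEM. Note also that a strong planted effect genuinely
changes the *relative* pathway mix of a hub metabolite (the proportional
rescaling preserves ratios), so pathway-level significance for an
unperturbed co-producing pathway is a real property of the workflow, not a
bug; the converse — a genome-level association with no single-pathway
support — is exactly what step 3 exists to remove.

## Degenerate inputs and tie-breaks

* Reactions without GPR never enter the LAD objective; a sample whose every
  score is 0 yields the zero flux vector (objective 0).
* A metabolite with no producing reaction at the solution has F_i = 0 and an
  empty pathway decomposition.
* Constant groups in any Wilcoxon test give p = 1; constant step-4 groups
  give all-zero Z.
* KNN imputation requires every peak to retain at least one observed value
  (`filter_peaks()` guarantees this at the default threshold); with fewer
  donors than k it uses all donors and warns; equidistant donors are ordered
  by peak id for determinism.
* Autoscaling drops constant peaks with a warning rather than dividing by 0.

## Known limitations

* The LAD fit allows simultaneous forward/backward flux on reversible
  target reactions (u_j matches the score without net flux). The stage-2
  total-flux minimization caps this at the minimum needed, and such futile
  pairs contribute no production to any flux-sum, but reported total flux
  is not a physiological quantity.
* Quantile normalization across metabolites assumes most metabolites are
  unaffected by any one mutation; a mutation with genuinely global
  metabolic impact would be partially normalized away.
* The empirical p-value treats the background AUC pool as exchangeable with
  the tested pairs; correlated peaks make it mildly anti-conservative.
* No multiple-testing correction is applied anywhere by default; treat MGP
  lists as ranked hypotheses, not discoveries.
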