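---
title: "Inferring cancer-associated ceRNA networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cancer-associated ceRNA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

MicroRNAs (miRNAs) repress RNA transcripts that carry their binding sites. When
two RNAs are targeted by the same miRNAs they compete for the same silencing
machinery, so a change in one transcript's abundance can indirectly derepress
the other — the competing endogenous RNA (ceRNA) hypothesis. `cernet` infers a
tumor-specific ceRNA interaction network from matched multi-omics matrices:
miRNA/mRNA/lncRNA expression, gene-level copy number (CNA), promoter
methylation (DNAm), and transcription-factor (TF) expression. The distinguishing
feature of the procedure is that miRNA-target relationships are learned while
CNA, DNAm and TF effects compete in the same regression, which removes a large
class of spurious miRNA-target correlations before any ceRNA pair is scored.

The pipeline has three stages:

1. **Putative network.** Sequence-level miRNA-target predictions (an input
   table aggregated from external databases) are restricted to differentially
   expressed (DE) miRNAs and DE RNAs.
2. **Regulator selection.** For each RNA $j$, its z-scored tumor expression is
   regressed on its candidate miRNAs plus (for mRNAs) its own CNA, own
   promoter methylation and candidate TFs, with the LASSO:
   $$\hat\beta(\lambda) = \arg\min_\beta \tfrac{1}{2n}\lVert y - \beta_0 - X\beta\rVert_2^2 + \lambda \lVert\beta\rVert_1 .$$
   The penalty is chosen by 10-fold cross validation with the one-standard-error
   rule; the fit is repeated 100 times with re-randomized folds and covariates
   selected in more than 75 runs are retained; 500 bootstrap refits build a
   95% percentile confidence interval, which must contain the median
   coefficient $\bar\alpha_{ij}$ and exclude zero; finally only miRNAs with
   $\bar\alpha_{ij} < 0$ (repression) become edges.
3. **ceRNA filtering.** All RNA pairs sharing at least one selected miRNA are
   candidates. A pair survives if (a) its Pearson correlation is at least 0.5
   with p < 0.05; (b) its shared-regulator count is hypergeometrically
   significant,
   $$p = 1 - \sum_{k=0}^{N_{ij}-1} \binom{N_j}{k}\binom{N-N_j}{N_i-k} \Big/ \binom{N}{N_i},$$
   BH-adjusted over the tested pairs at 0.05, where $N$ counts all DE miRNAs
   in the universe; and (c) its sensitivity correlation
   $SC = \mathrm{Corr}(i,j) - \mathrm{PC}(i,j \mid \{miRNA_{ij}\})$
   is positive, its partial-correlation p-value is below 0.05, and its
   empirical SC p-value — the fraction of 1000 random same-size miRNA subsets
   whose sampled SC strictly exceeds the observed SC — is below 0.05.

Downstream, the network is characterized by a log-log power-law fit of the
degree distribution, multilevel (Louvain) modularity clustering, hypergeometric
gene-set enrichment of modules, and degree-quantile hub calling. A
knockdown-based metric evaluates the network against perturbation data: the
ratio fold change (RFC) of a downstream ceRNA is its mean fold change after
knockdown of its partners divided by that after knockdown of non-partners, and
network accuracy is the percentage of evaluable downstream ceRNAs with
RFC < 1.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `cpm_threshold` | 1 CPM | a feature counts as unexpressed in a sample below this; dropped when unexpressed in more than `max(n_tumor, n_normal)` samples |
| `de_alpha` | 0.01 | adjusted-p threshold for DE labels |
| `log_offset` | 0.001 | offset in `log2(x + offset)`; an abundance of 0 maps to about -9.97 |
| promoter window | 200–1500 bp upstream of the TSS, inclusive | probes averaged into a gene's methylation level |
| `n_runs` / `freq_threshold` | 100 / 75 | stability-selection repeats and the strict selection-count threshold |
| `n_bootstrap` / `ci_level` | 500 / 0.95 | bootstrap refits and percentile-interval level |
| `n_folds`, `lambda_grid_size`, `lambda_min_ratio` | 10, 100, 1e-3 | CV folds; log-spaced grid from $\lambda_{max}$ down to $10^{-3}\lambda_{max}$ |
| `min_corr` / `corr_p` | 0.5 / 0.05 | Pearson stage (threshold applies to r itself, raw p) |
| `hyper_alpha` | 0.05 | BH-adjusted hypergeometric threshold |
| `sc_resamples`, `sc_alpha`, `pc_p_alpha` | 1000, 0.05, 0.05 | empirical SC null and the SC-stage thresholds |
| hub quantile | 0.90 | degree percentile defining hubs |
| `min_module_size` | 10 | smallest module tested for enrichment |

## Numerical choices

* **Lambda grid and ties.** $\lambda_{max} = \max_j |\langle x_j, y\rangle|/n$
  is computed on centered data — with an unpenalized intercept this is exactly
  the smallest penalty whose solution is all-zero, so the KKT boundary holds
  on the grid's first point. The grid is decreasing, and the one-SE rule picks
  the first (largest) lambda within one standard error of the minimal mean CV
  error, so ties break toward the simpler model.
* **Coordinate descent.** The solver uses covariance updates (precomputed
  $X^TX/n$, $X^Ty/n$ on centered data), warm starts along the path, and a
  glmnet-style active-set loop; convergence tolerance is 1e-7 on the maximal
  coefficient change. Coefficients below 1e-10 in magnitude are recorded as
  exact zeros so that "non-zero coefficient" selection counts are well
  defined at the KKT boundary.
* **What varies across the 100 runs.** Only the CV fold assignment; the
  full-data path is fixed given the data. The median coefficient is taken over
  all runs including zeros. In the bootstrap, the *entire* procedure
  (lambda grid, CV, one-SE pick) is refit on each resample; resamples with a
  constant response are redrawn and logged.
* **Partial correlation** is computed by residual regression (QR, with
  intercept). Rank-deficient conditioning sets are an error naming the
  collinear columns; a variable fully explained by the conditioning set has a
  numerically-zero residual and its partial correlation is defined as 0 rather
  than floating-point noise. The p-value uses
  $t = pc\sqrt{(n-2-|Z|)/(1-pc^2)}$ on $n-2-|Z|$ degrees of freedom.
* **Empirical SC p-value** uses strict ">" with no pseudo-count, so p = 0 is
  attainable; the resampling pool is all DE miRNAs with expression available,
  including the pair's own shared miRNAs. Per-pair and per-RNA random streams
  are keyed by a hash of the feature id and the global seed, so adding an RNA
  never perturbs another RNA's randomness and whole runs are byte-reproducible.
* **Hypergeometric kernel.** One implementation (log-space `lchoose`
  accumulation) serves the shared-regulator test, module enrichment and
  gene-list enrichment; tests pin them together and against exhaustive
  enumeration.
* **Hub quantile.** "High degree" is read as at or above the 90th percentile
  of the degree distribution, computed with the Weibull plotting position
  (quantile type 6). This convention makes the two declared tie cases come out
  right: in a star graph only the center is a hub, while in a regular graph
  every node sits at the threshold and all are hubs.
* **BH adjustment** is the step-up procedure
  $\tilde p_{(i)} = \min_{j \ge i} m\, p_{(j)}/j$, applied per testing stage
  over exactly the hypotheses reaching that stage; Bonferroni is available by
  argument. (The source procedure's "Bonferroni-Hochberg" is read as
  Benjamini–Hochberg, whose reference it cites.)

## Design decisions where the design was open

* **DE calling is an input.** Count-model DE tests (negative-binomial exact
  test, moderated linear models) belong to existing packages and are not
  re-implemented; `de_label_table()` consumes external results and
  `simple_de_test()` (Wilcoxon or Welch, BH-adjusted) is a documented
  surrogate for synthetic runs.
* **RPKM conversion** needs gene lengths and is treated as format plumbing:
  the pipeline accepts abundances and itself performs only
  `log2(x + 0.001)` + z-normalization over tumor samples.
* **Gene-level CNA** uses the overlap-length-weighted mean of segment means —
  a declared, testable rule replacing an external gene-centering tool.
* **Promoter window bounds** are inclusive on both ends and mirrored on the
  minus strand.
* **lncRNA designs** contain only miRNA covariates; mRNA designs additionally
  get own-CNA, own-DNAm and candidate-TF columns. Covariates are z-scored in
  the design so one penalty applies comparably to all kinds.
* **Sequence scanning.** The bundled seed-match scanner (6mer/7mer/8mer site
  types, U/T equivalent) exists to build synthetic fixtures; thermodynamic
  and conservation scoring are the business of external tools whose output
  the pipeline consumes as tables.

## What the synthetic generator emulates — and what it does not

`synth_generate()` produces post-preprocessing (z-scored, tumor-only)
matrices by default. miRNA, TF and CNA values are standard normal; promoter
methylation is a logistic transform of a standard normal. Each RNA is a linear
combination of its planted regulators plus N(0, 1) noise:

* planted miRNA effects are negative with $|\beta| \in [0.4, 0.8]$
  (the `recovery` scenario: 30 miRNAs, 100 mRNAs, 200 tumor samples);
* confounder prevalences mirror the multi-omics regulator percentages
  reported for real tumors (CNA on ~76% of targets, effects U(0.5, 1.5);
  DNAm on ~30%, effects U(-0.8, -0.2); one TF on ~54%, effects U(0.3, 0.9));
* the putative table carries 3 decoy edges per planted edge, emulating the
  large gap between database-predicted and expression-supported interactions;
* in the `cerna` scenario, groups of three RNAs share three strong miRNAs
  ($|\beta| \in [0.6, 0.8]$) and carry a within-group coupling term
  (coefficient 0.5 on a shared latent factor). The coupling emulates
  sequestration-driven co-expression: competition couples transcripts through
  miRNA *occupancy*, which miRNA *abundance* does not fully capture, so true
  ceRNA pairs retain co-expression beyond what conditioning on measured miRNA
  levels removes. Without such a term no linear-Gaussian world can pass the
  pipeline's own requirement that the partial correlation itself be
  significant — conditioning on the shared miRNAs would annihilate the entire
  dependence. Group members carry no CNA/DNAm/TF effects: a detectable ceRNA
  pair requires miRNA-mediated variance to dominate, which is precisely the
  regime the ceRNA hypothesis describes.
* `generate_perturbations()` derives knockdown fold changes from the planted
  model: partners of a knocked-down RNA receive
  $FC = \exp(-\tfrac12 \sum |\beta_{shared}|) < 1$, non-partners exactly 1,
  with optional multiplicative log-normal noise.

The generator does **not** model count dispersion (a Poisson raw-count mode
exists, but no empirical negative-binomial dispersions), batch effects,
miRNA-miRNA correlation structure, or nonlinear/saturating repression. A green
test therefore establishes that the estimator recovers the stated
linear-Gaussian world at the stated sizes — not that it would recover
interactions in data with heavy unmodeled structure.

## Known limitations

* The per-pair empirical SC null costs `sc_resamples` partial correlations;
  on networks with very many candidate pairs this dominates runtime.
* The hypergeometric test treats each RNA's regulator count as fixed and
  draws as independent, which ignores the dependence induced by the selection
  step itself (as does the original procedure).
* With `p = 0` attainable in the empirical null, the SC filter's boundary at
  1000 resamples is 0.05 exactly; rank-based smoothing was deliberately not
  applied to stay faithful to the strict-exceedance definition.
* The correlation-based baseline shares the Pearson stage thresholds but not
  the step-2 selection, so its pair set is not formally a superset of the
  full pipeline's on arbitrary data (it is on the bundled scenarios, where it
  is tested).
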