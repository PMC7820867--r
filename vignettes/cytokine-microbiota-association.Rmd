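---
title: "Modeling cytokine-microbiota association with Dirichlet-multinomial regression"
author: "cytotaxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cytokine-microbiota association with Dirichlet-multinomial regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytotaxa)
```

## The problem

Mucosal tissue carries both an immune state — measurable as a panel of
cytokine concentrations — and a bacterial community, measurable as counts of
16S amplicon clusters (OTUs). The question this package addresses is which
cytokines are associated with which parts of the community, in a paired
design where each patient contributes a tumor sample and a surrounding
healthy-mucosa sample.

Two features make this statistically awkward. First, microbiome counts are
*compositional* and *overdispersed*: only relative abundances are
informative, and sample-to-sample variation far exceeds multinomial noise.
Second, the cytokine panel is wide relative to the number of patients
(up to 26 cytokines for a few dozen samples), so a joint regression over
all cytokines is not directly estimable.

The package answers with a two-step analysis:

1. **Marginal screening** (`screen_cytokines()`): each cytokine alone
   predicts the community composition in a Dirichlet regression; a
   likelihood-ratio test against the intercept-only model ranks the
   cytokines, and the top few proceed to step 2.
2. **Bayesian variable selection** (`run_bvs()`): the selected cytokines
   jointly enter a Dirichlet-multinomial (DM) regression whose coefficients
   are sparsified by a hard-thresholding prior; an MCMC over the model space
   yields, for every cytokine-category pair, a posterior probability of
   inclusion (PPI) and a posterior mean effect conditional on inclusion.

The community response in both steps is deliberately low-dimensional: the
counts of the three dominant genera (in colorectal mucosa typically
*Bacteroides*, *Prevotella*, and *Escherichia/Shigella*) plus one residual
category pooling everything else (`build_composition_response()`), so J = 4
categories partition every sample's reads exactly.

## Models

### Dirichlet regression (step 1)

Sample $i$ has composition $p_i$ on the $(J-1)$-simplex and concentration
vector $\alpha_i$ with a log link on every component:
$$\alpha_{ij} = \exp(x_i^\top \beta_j), \qquad p_i \sim
\mathrm{Dirichlet}(\alpha_i).$$
We use the free log-concentration parametrization — no mean/precision
decomposition — so step-1 and step-2 coefficients live on the same scale.
Counts are mapped to interior compositions with a pseudocount of 0.5
(`counts_to_proportions()`); a Dirichlet density is undefined on the
boundary and raw tables contain zeros. The MLE (`fit_dirichlet_regression()`)
is found by BFGS with analytic gradients from a deterministic start
(intercepts at the log of mean proportions scaled to total concentration 10,
other coefficients 0), then polished with Newton steps. Convergence is
declared on the relative criterion
$\max_k |g_k| / (1 + |\ell|) < 10^{-6}$: the absolute gradient norm at a
numerical optimum scales with the magnitude of the log-likelihood through
floating-point cancellation, so an absolute cutoff would misreport perfectly
converged fits on strong-signal data as failures.

Each cytokine's evidence is $2(\ell_{\text{full}} - \ell_0)$ referred to
$\chi^2_J$ (one added coefficient per category). The p-values are used
**only to rank**; no multiplicity correction is applied, and none would be
appropriate for a screening rule. At the study scale ($n \approx 40$) the
$\chi^2$ reference is mildly anti-conservative (about 6–7% of null
p-values fall below 0.05), a standard $O(1/n)$ likelihood-ratio effect;
this shifts no ranks. The test-suite calibration checks therefore run at
$n = 100$, where the asymptotic regime applies.

### Dirichlet-multinomial regression with thresholded selection (step 2)

Counts $y_i$ with depth $N_i$ follow
$$y_i \sim \mathrm{DM}(\alpha_i, N_i), \qquad \alpha_{ij} =
\exp(x_i^\top \theta_j),$$
with the DM log-pmf computed entirely through `lgamma` (`dm_logpmf()`).
Sparsity comes from a thresholding map: raw coefficients $b_{kj}$ carry
independent $\mathcal N(0, \sigma_b^2)$ priors ($\sigma_b = 1$ by default)
and the effective coefficients are
$$\theta_{kj} = b_{kj}\,\mathbf 1[|b_{kj}| \ge t],$$
with intercepts never thresholded and a single global threshold
$t \sim \mathrm{Uniform}(0, t_{\max})$, $t_{\max} = 1$ (a fixed-$t$ option
exists and is used by the validation oracle). A pair $(k, j)$ is "included"
in a posterior draw when $\theta_{kj} \ne 0$; the PPI is the inclusion
fraction over retained draws, and the reported posterior mean is conditional
on inclusion — exactly 0 for pairs never included, which is why the rendered
coefficient table shows hard zeros.

The sampler (`run_bvs()`, inner loop in C++) is Metropolis-within-Gibbs:

* element-wise updates of $b_{kj}$ by a mixture kernel — Gaussian random
  walk (sd `proposal_sd` = 0.2) with probability $1-$`indep_prob`, and an
  independence draw from the prior with probability `indep_prob` = 0.2.
  The independence component exists because a small-step random walk
  crosses the inclusion boundary $|b| = t$ slowly; prior draws jump between
  the in and out modes, and their acceptance ratio reduces to the
  likelihood ratio.
* a Gaussian random-walk update of $t$ (rejected outside $(0, t_{\max})$),
  accepted on the full likelihood under the re-thresholded coefficients.

Each coefficient update costs $O(n)$: only column $j$ of the concentration
matrix changes, so the likelihood delta needs four `lgamma` evaluations per
sample. Defaults are 20000 iterations with 10000 burn-in; a default-sized
problem ($n = 40$, $K = 8$, $J = 4$) samples in roughly two seconds. The
reported covariate acceptance rate counts only likelihood-relevant proposals
(those changing some $\theta_{kj}$): prior-region moves of excluded
coefficients are near-automatic accepts and would mask poor tuning. Rates
outside $[0.1, 0.6]$ trigger a warning — on signal-free data at high depth
the rate legitimately falls toward 0, which is the sampler saying that no
inclusion move survives the likelihood.

Because the threshold is shared, the data calibrate it: with active effects
present, the posterior pushes $t$ up until noise coefficients are excluded,
which is what drives null PPIs far below their prior inclusion probability
(about 0.62 under the defaults).

### Interpreting identifiability

In the log-concentration parametrization, shifting one covariate's
coefficients by a constant across **all** categories changes only the total
concentration (dispersion), not the mean composition — a weakly identified
direction. The sparsity prior resolves it in practice (one inclusion beats
J inclusions), but users should read effects as *relative to the excluded
categories*, and expect occasional detection misses at boundary-power
effect sizes rather than sign flips: in our recovery checks every detected
effect carried the true sign.

## The synthetic study generator

No patient-level data ship with the package, so every downstream stage is
exercised on synthetic studies (`generate_paired_study()`) whose defaults
are the study conditions the tests assume:

| quantity | default | why |
|---|---|---|
| patients | 40 (80 samples) | paired tumor/healthy design of the sequenced cohort |
| cytokines $K$ | 8 | size of the second-analysis panel; up to 26 names from the packaged LOQ table |
| categories $J$ | 4 | three dominant genera + residual |
| active effects | 2 cells, $|\beta| = 1.5$, random sign | sparse truth at a magnitude comparable to reported posterior means (≈0.9–1.4) |
| overdispersion | total concentration 50 | no dispersion estimate is reported; 50 gives proportion noise clearly exceeding multinomial noise at these depths |
| depths | uniform $[10^4, 10^5]$ | typical per-sample 16S yields |
| cytokine marginals | log-normal, log-sd 1, patient effect sd 0.5 | immunoassay panels are right-skewed; the patient effect makes the paired design informative |
| cytokine medians | $\mathrm{LLOQ} \times e$ | places roughly a fifth of values below the LLOQ so the censoring rule (values under the LLOQ become 0 pg/ml, `apply_loq()`) is exercised |

The generator mirrors the inference model (log-link DM on the standardized,
censored cytokines) deliberately: parameter recovery is then well-posed, and
the acceptance checks measure the estimator rather than model mismatch. The
OTU table realizes each response category as taxa — two OTUs per named
genus, the residual spread over 20 background genera with slowly decaying
weights — so genus aggregation followed by response construction returns
the generated composition exactly.

What the generator does **not** emulate, and what passing tests therefore do
not establish about real data: taxonomic richness (tens of taxa, not
thousands, so at these depths every taxon is seen in every sample and
richness/Chao1 comparisons degenerate); patient-specific microbiota
signatures (samples of one patient are conditionally independent given the
cytokines, so the dendrogram pairing fraction is near zero by design, unlike
a real paired cohort where most pairs co-cluster); rare-taxon dynamics and
singleton structure; model mismatch between the data-generating process and
the DM regression; and any form of cross-covariate correlation in the
cytokine panel.

## Community metrics

Per-sample indices follow the field's formulas: Shannon $S = -\sum p_i
\ln p_i$ in natural log; Pielou evenness $E = S / \ln R$ with $R$ the
observed richness (the log base is configurable — with an unqualified
"log" both natural and common conventions exist — and natural log is the
recorded default, with $E$ returned as missing when $R \le 1$); Chao1 with
the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ when no
doubletons exist; Good's coverage $(1 - n/N) \times 100$ from singleton
reads.

Rarefaction (`rarefaction_curve()`) uses the exact hypergeometric
expectation $E[S_d] = \sum_i [1 - \binom{N-N_i}{d}/\binom{N}{d}]$ on a
step-spaced grid (default 50 reads, full depth appended so the curve ends at
observed richness) instead of random subsampling: the quantity being plotted
*is* an expectation, and the exact form is deterministic. A Monte-Carlo
subsampling oracle validates it in the test suite (N ≈ 2000 reads, 3000
replicates — scaled to keep the suite fast; agreement is required within 3
standard errors at every grid point). The saturation flag is the final
difference quotient — taxa gained per additional read over the last grid
interval — compared against $10^{-5}$.

The paired-design check (`pairing_cluster_check()`) clusters
$\sqrt{c_{ij}/N_i}$ rows by complete-linkage Euclidean distance and counts a
patient as paired when its two samples merge with each other before either
merges with anything else (a singleton-singleton merge in the dendrogram) —
a strict, deterministic reading of "paired in terms of composition".

The paired Wilcoxon signed-rank test computes its exact two-sided p-value
for up to 25 nonzero differences by dynamic programming over doubled
midranks, which handles tied differences exactly (the textbook exact
distribution conditions on the observed absolute values; standard
implementations refuse exactness under ties); beyond 25 it defers to the
tie-corrected normal approximation.

## Numerical choices and validation

* **DM pmf correctness** is checked against a direct gamma-product oracle
  and by exact normalization over enumerated count vectors.
* **The sampler is validated against brute force**: for $K = 1$, $J = 2$,
  $n = 15$ and a fixed threshold, the exact posterior over the four
  inclusion models is computed by Gauss-Legendre quadrature
  (`bvs_exact_ppi_k1j2()`) — excluded coefficients contribute their prior
  exclusion mass analytically, included ones are integrated over the
  truncated region, intercepts over a grid centred at their moment
  estimate. The quadrature is grid-converged to six decimals, and sampler
  PPIs agree within Monte-Carlo error. Shallow depths (12 reads) keep the
  integrand wide enough for fixed grids; the small-problem chains run
  60000 iterations so that Monte-Carlo error, not mixing, sets the
  comparison tolerance.
* **Screening calibration** is simulated from the Dirichlet layer directly
  (the model the screen fits); at depth $10^4$ and concentration 50 the
  extra multinomial layer is negligible for proportions, and calibration is
  a property of the test under its own model.
* **Degenerate inputs**: all-zero count vectors error; single-taxon
  evenness is missing-with-reason, not an error; constant cytokines are
  skipped by the screen with p = 1 and a warning; non-convergent fits are
  flagged, never silently accepted; ties in top-k genus totals break
  lexicographically.
* **Problem sizes in the suite** (the package's choices, stated here so the
  checks are interpretable): calibration at $n=100 \times 500$ replicates;
  screening power at 50 studies of 40 tumor samples; recovery at 10 studies
  with the default sampler config; oracle agreement over 5 chains.

## Reproducibility

Every stochastic function takes an explicit seed or config-carried seed;
identical seeds give bit-identical outputs (the MCMC consumes R's RNG
stream inside C++). `run_pipeline()` writes a JSON manifest with config,
seeds, input digests, package version and per-stage timings, and skips
stages whose input digests are unchanged. One caveat: because element-wise
updates consume randomness in a fixed cell order, permuting response
categories permutes results only in distribution, not bitwise.

## Known limitations

* The BVS prior commits to one concrete reading of thresholded selection
  (global threshold on the raw coefficient scale, uniform threshold prior);
  other readings (per-category thresholds, latent-scale thresholding) are
  plausible and would need new validation oracles.
* PPIs are conditional on the screened subset; uncertainty from step 1 is
  not propagated into step 2.
* The Dirichlet screen treats pseudocounted proportions as exact,
  discarding depth information; a DM-likelihood screen would use it, at
  higher cost per fit.
* Evenness and Shannon values depend on the log-base convention; comparisons
  across software must fix the base.
* At default iteration counts, runtime grows linearly in $K \cdot J$;
  above $K = 12$ the sampler warns that longer chains may be needed.
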