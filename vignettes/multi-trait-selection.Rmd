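---
title: "Multi-trait selection and stability in multi-environment provenance trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait selection and stability in multi-environment provenance trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsel)
```

## The problem

A provenance trial plants seed sources of known geographic origin
("provenances" — the genetic entries, playing the role genotypes play in
crop trials) in randomized complete blocks at one or more sites. Decades
later the breeder measures growth and quality traits on the surviving trees
and must (i) decompose the phenotypic variance into genetic
(between-provenance), genotype-by-environment, and residual parts, and
(ii) select a small fraction of provenances that are good *on all traits at
once* and, for deployment across a region, *stable across sites*. `metsel`
implements that chain: mixed-model variance decomposition, the
genotype–ideotype distance index (MGIDI) within sites, and the multi-trait
stability index (MTSI, built on WAASB/WAASBY) across sites.

## Mixed models

Within a site, for tree $l$ of provenance $j$ in block $k$:

$$Y_{jkl} = \mu + B_k + P_j + (P \times B)_{jk} + e_{jkl},$$

with block fixed and $P_j \sim N(0, V_p)$,
$(P\times B)_{jk} \sim N(0, V_{pb})$, $e \sim N(0, V_r)$. Across sites:

$$Y_{ijkl} = \mu + S_i + B_{k(i)} + P_j + (S \times P)_{ij} + e_{ijkl},$$

with site and block-within-site fixed and the provenance and interaction
terms random ($V_p$, $V_{ge}$, $V_r$). Both are fitted by REML through
`lme4` — the standard estimator and implementation for this model class;
variance components are constrained non-negative by construction, and an
estimate driven to the boundary is reported as 0, not dropped
(`fit_site_model()` keeps the $P\times B$ term either way).

Three reporting conventions matter:

* **Likelihood-ratio tests** for a random term refit the model without that
  term (same fixed effects, so the REML likelihoods are comparable) and
  refer $\max(0, 2\,\Delta\ell)$ to $\chi^2_1$. This is the conventional
  reported test; no 50:50 boundary-mixture correction is applied, so the
  p-values are mildly conservative.
* **Variance proportions** divide each component by the sum of the reported
  random components: $V_p + V_r$ within a site (the weakly identified
  $V_{pb}$ is excluded from the denominator — the conventional per-site
  summary, and the arithmetic under which the published percentages in this
  literature are closed-form functions of the printed components) and
  $V_p + V_{ge} + V_r$ across sites.
* **Fixed-effect mean squares** come from the sequential least-squares
  decomposition of the observations (block within a site; site and
  block-within-site across sites), tested against the REML residual
  variance with observation-level residual degrees of freedom. On balanced
  data this equals the cell-means decomposition up to the common scaling.

BLUPs are the conditional means of the random effects. "Predicted means"
(`predicted_means()`) are the fixed intercept averaged over the fixed-effect
levels plus the provenance BLUP; these shrunken means — not raw
means — feed the selection indices, matching the reference implementations
of these indices (raw means remain available by passing any genotype × trait
table directly). The interaction BLUP matrix $\Theta$ has one row per
provenance in the analysis set and one column per site; a provenance–site
pair absent from the data receives the BLUP of an unobserved effect,
exactly 0.

**Analysis set.** Across sites the default is the provenances present at
every site (the "common set"): interaction BLUPs for provenance–site pairs
never observed are pure shrinkage artifacts and would flatter the stability
of sparsely tested entries. `analysis_set = "all"` is available (with a
warning for single-site provenances) for the unbalanced reading.

## MGIDI

1. **Rescale** each trait over genotypes to 0–100, with 100 at the
   desirable extreme (direction per trait via `higher_better`). This
   absorbs units: the index is invariant to positive affine recoding of any
   raw trait.
2. **Factor analysis** of the trait correlation matrix: retain factors with
   eigenvalue $\ge 1$ (at least one), loadings are eigenvectors scaled by
   root eigenvalues, varimax-rotated (Kaiser-normalized, tolerance
   $10^{-5}$, up to 1000 sweeps via `stats::varimax`). Rotation is
   orthogonal, so communalities are preserved. Sign convention: each
   factor's dominant loading is made positive. Scores use the regression
   method, $Z R^{-1} L$.
3. **Ideotype**: the all-100 row, pushed through the *identical*
   standardization and scoring transform.
4. **Distance**: $\mathrm{MGIDI}_i = \big[\sum_{j=1}^f (y_{ij} - y_j)^2\big]^{1/2}$,
   lower is better; a genotype whose rescaled profile equals the ideotype
   scores exactly 0.

Degenerate inputs: a constant trait cannot be rescaled and raises an error
naming the trait; a numerically singular correlation matrix (e.g. duplicated
traits) is ridge-regularized with $10^{-8}$ on the diagonal and a warning. A
single trait is allowed as a degenerate one-factor case, in which the index
ranking reduces to the trait ranking.

## WAASB, WAASBY, MTSI

From the SVD $\Theta = U D V'$, the interaction principal component axis
scores are $\theta_{ik} = U_{ik} d_k$ over $p = \min(g-1, e-1)$ axes
(minimum 1; $\Theta$'s rows and columns are shrunken toward zero, so its
effective rank is at most that), the explained proportions are
$EP_k = d_k^2 / \sum d^2$, and

$$\mathrm{WAASB}_i = \frac{\sum_k |\theta_{ik}|\, EP_k}{\sum_k EP_k}.$$

All axes enter the weighted average — truncation is not part of the
statistic's definition. The SVD's sign ambiguity cancels under the absolute
value, and scaling $\Theta$ by $c>0$ scales WAASB by $c$. An all-zero
$\Theta$ gives WAASB 0 for everyone (axes then carry equal nominal weight so
the proportions still sum to one).

WAASBY rescales performance (best mean → 100) and stability (lowest
WAASB → 100) and blends them as $(r_Y w_Y + r_W w_S)/(w_Y + w_S)$. The
default is 50:50 — the neutral choice, since nothing in the analysis this
package reimplements states its weighting; both weights are exposed. If one
input is constant it maps to 100 for all genotypes (with a warning); both
constant is an error. The MTSI is then the ideotype-distance construction
applied verbatim to the genotype × trait WAASBY matrix (the mgidi factor
pipeline is reused, not re-derived).

## Selection

The selected-set size is `round(n × intensity / 100)` under
round-half-to-even, with a floor of 1. This rounding (R's default) is what
makes the canonical counts come out right: 15% of 55/49/48 gives 8/7/7 and
20% of 38 gives 8. Ties at the selection boundary are all included, with a
warning that the realized intensity exceeds the nominal one. Selection
differentials are $100(\bar x_{sel} - \bar x_{site})/\bar x_{site}$,
reported to one decimal; site means are over all measured trees, selected
means over the trees of the selected provenances.

## The synthetic scenario

The generator (`simulate_met()`) draws from exactly the across-site model
above. The default scenario emulates a three-site, 47-year Douglas fir
provenance trial network: 61 provenances, 55/49/48 per site with 38 common
to all, three blocks, 25 trees (5 × 5) per plot, traits DBH/TH/PH. Key
calibration choices, made once:

* Grand means and fixed site offsets reproduce the published per-site trait
  means (e.g. site-mean DBH 36.05/28.82/34.71 cm).
* $V_p$ and $V_r$ are the per-site REML components averaged over the three
  sites; $V_{ge}$ is the across-site estimate. The published across-site
  residuals are not mutually consistent with the per-site residuals or the
  printed overall SDs (they are an order of magnitude smaller for
  diameter), so the per-site scale was adopted: under it the simulated
  overall mean ± SD of every trait matches the published values. The
  published across-site component triplets are still used verbatim as
  simulation truth in the parameter-recovery study, where internal
  consistency is what is being tested.
* Block offsets are fixed and default to zero (block enters the models as a
  fixed effect); $V_{pb}$ defaults to 0 because the across-site model omits
  that term — both are per-scenario switches.
* All random terms are Gaussian (the REML-consistent default; nothing in
  the source analysis states distributions). Traits are generated
  independently by default; a cross-trait correlation matrix for the
  provenance effects is available for factor-analysis stress tests.
* Survival defaults to 1; `apply_mortality()` produces the unbalance of old
  field trials (no mortality figures are published for this network, so
  unbalance is exercised in tests rather than the default scenario). A plot
  emptied by thinning is redrawn a few times, then the provenance is
  dropped from that site with a message.
* One master seed; per-stage substreams (provenance, interaction,
  block-plot, residual draws) are derived from it deterministically, so
  datasets are bit-reproducible.

What the generator does **not** emulate: spatial within-plot
autocorrelation and microsite gradients, climate-driven site effects,
non-Gaussian or age-dependent effect distributions, and non-random
mortality. Passing tests therefore demonstrate that the estimation and
selection chain is correct *under the stated model*, not that the model
captures every feature of real 47-year field data.

## Validation design and problem sizes

* **Parameter recovery** (`recovery_study()`): trials simulated at ten
  times the field design's provenance count (550 within-site; 380 — ten
  times the common set — across sites; 3 blocks × 25 trees throughout),
  refit, and the components averaged over three replicate simulations
  before comparison at 15% relative error. Averaging replicates measures
  the estimator's bias at that size rather than one draw's Monte Carlo
  noise.
* **Linear-algebra oracles**: factor loadings/scores and WAASB are checked
  on small toy matrices against independent longhand routes (SVD of the
  standardized data instead of `eigen` on the correlation matrix; explicit
  SVD recomputation of the weighted absolute scores) to $10^{-8}$–$10^{-10}$.
* **The selection-count rule** is verified exhaustively for all
  $n \le 200$ at 5/10/15/20% against an independent restatement of
  round-half-even.
* The **full default pipeline** (11,400 trees, three traits, all model
  fits, both indices) runs in well under five minutes on one CPU; the test
  suite asserts that budget.

## Known limitations

* LRT p-values use plain $\chi^2_1$, conservative at the boundary.
* Denominator degrees of freedom for fixed-effect F tests are
  observation-level; no Satterthwaite/Kenward–Roger machinery.
* Heteroscedastic per-site residual variances and spatial models are out of
  scope, as are AMMI-style fixed-effect stability, GGE biplots, and
  economic-weight (Smith–Hazel) indices.
* With near-collinear traits the factor-score weights $R^{-1}L$ are
  stabilized by ridge regularization; rankings are then insensitive to the
  ridge at the $10^{-8}$ level but the individual scores inherit the
  conditioning of $R$.
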