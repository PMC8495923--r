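---
title: "Mixed-model GWAS for additive and epistatic effects: models, equivalences, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model GWAS for additive and epistatic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiblup)
```

## The models

All of `epiblup` is built around linear mixed models for a quantitative
trait measured once per genotyped individual (the random-effect design is
the identity throughout; replicated records are out of scope).

**Additive scans.** The standard association model in a structured
population (the "Q+K" model) is

$$y = X\beta + m_i a_i + g + e, \qquad
g \sim N(0, G\sigma_g^2),\; e \sim N(0, I\sigma_e^2),$$

where $X$ is the fixed design (intercept, subpopulation or environmental
covariates), $m_i$ is the coding vector of the tested marker and $G$ is a
genomic relationship matrix. Dropping the marker term gives the GBLUP
model, the *null model* of the scan. Under the P3D approximation the
variance components are estimated once, by REML, in the null model and
then frozen; each marker is tested by GLS. With

$$T = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}, \qquad V = I + \lambda G,
\quad \lambda = \sigma_g^2/\sigma_e^2,$$

the per-marker estimate, variance and statistic have the closed forms
implemented in `scan_additive_p3d()`:
$\hat a_i = m_i'Ty / m_i'Tm_i$, $\mathrm{Var}(\hat a_i) = \sigma_e^2 /
m_i'Tm_i$, $z_i = m_i'Ty / (\sigma_e \sqrt{m_i'Tm_i})$, referred to a
$t$ distribution on $n-k-1$ degrees of freedom (two-sided).

**GWAS by GBLUP.** Because GBLUP is equivalent to ridge-regression BLUP
with $G = MM'/c$, the fitted genetic values can be back-solved into
per-marker effects, $\hat a = \sigma_a^2/\sigma_e^2\, M'Ty$, with
Henderson-sense variance (the variance of the predictor, not the
prediction-error variance)
$\mathrm{Var}(\hat a)_{ii} = \sigma_a^4/\sigma_e^2\, m_i'Tm_i$, and a z
statistic formed from their ratio (`scan_additive_gblup()`). The central
additive result the package verifies numerically is that this back-solved
statistic **equals the P3D Q+K statistic for every marker, with arbitrary
fixed covariates** — the two scans are the same test computed two ways.
The same holds for window-based tests of a group of markers
(`test_window()` computes the fixed-effect GLS Wald statistic and the
back-solved random-route quadratic form and checks they agree). The exact
(non-P3D) scan, which re-runs REML per marker, is *not* equivalent; it is
provided as `scan_additive_exact()` for small problems, and the package's
tests demonstrate both the asymptotic agreement under the null and the
divergence at a strong signal.

A second identity the package checks: the full back-solved covariance can
be written either as
$\sigma_a^2 I - \sigma_e^2(\sigma_e^2/\sigma_a^2 I + M'SM)^{-1}$ with
$S = I - X(X'X)^{-1}X'$, or as $\sigma_a^4/\sigma_e^2\, M'TM$
(`marker_blup_variance_direct()` / `marker_blup_variance_projection()`).
We implement $S$ as the symmetric projector; one published rendering of
this formula omits the final transpose, which we read as a typesetting
slip. We verified numerically that the identity holds for arbitrary
full-rank $X$, not only an intercept.

**Epistasis scans.** For a pair $(i, j)$ the tested contrast is the
elementwise product $q = m_i \circ m_j$. Three models are compared:

* extended Q+K (`scan_epistasis_qk()`): fixed terms $m_i, m_j, q$ under
  the one-kernel covariance $\sigma_e^2(I + \lambda G)$;
* Q+2K (`scan_epistasis_q2k()`): the same fixed terms under the
  two-kernel covariance
  $\sigma_A^2 G + \sigma_{AA}^2 H + \sigma_e^2 I$, where
  $H = \tfrac12\!\left(G \circ G - (M\circ M)(M\circ M)'\right)$
  is the additive-by-additive kinship;
* REMMA (`scan_epistasis_remma()`): all pairs back-solved from one fitted
  extended-GBLUP null model, $w_{ij} = (q'Py)^2 / (q'Pq)$ with
  $P = T/\sigma_e^2$.

Wald statistics are referred to $\chi^2_1$ (upper tail). The epistatic
equivalence the package verifies is that the REMMA statistic equals, pair
for pair, the Wald statistic of an *auxiliary* model that includes only
$q$ as an extra fixed term under the two-kernel covariance
(`scan_epistasis_auxiliary()`). REMMA therefore differs from Q+2K exactly
by the absence of the two marker main effects among the fixed covariates
— the two are *not* equivalent in general, and the package constructs
instances where a strong marginal additive signal drives them apart
while a purely non-additive instance leaves them in close agreement.

$H = QQ'$ holds exactly, for any real marker coding, with $Q$ the
$n \times p(p-1)/2$ matrix of pairwise products (`build_pair_design()`);
this is the algebra that lets a single null fit score every pair. The
printed REMMA back-transform $\hat{aa} = Q'H^{-1}\hat g_{AA}$ requires an
invertible $H$; we implement the projection form, which is algebraically
identical when $H$ is invertible and well defined when it is not (marker
pruning routinely leaves $H$ rank-deficient), and cross-check the two
routes on small invertible instances.

## Marker coding for the epistatic kinship

Which coding of $M$ enters $H$ (and the product columns) is not a detail:
products of *centred* columns are nearly orthogonal to the marker main
effects in weak LD, while products of raw allele dosages retain a strong
marginal component. `build_epistatic_grm()` exposes both
(`coding = "raw"` or `"as_g"`) and records the choice in the kinship
set's `coding_note`. The default is `"raw"`, the convention of the
epistatic-GRM literature: on the package's simulated inbred panels it
yields a strong positive correlation between the off-diagonals of $G$
and $H$ (about 0.6 at $n = 200$, $p = 100$; the test suite computes
this), matching what is observed on real diversity panels, whereas
centred products give a correlation near zero. The additive $G$ defaults
to VanRaden scaling ($M$ centred by twice the allele frequency,
$c = 2\sum_j p_j(1-p_j)$); `scaling = "raw"` ($c = 1$) mirrors the
coding-free theory and is used in the algebraic-identity tests.

## REML machinery

The one-kernel fit (`reml_one_kernel()`) profiles the restricted
likelihood over $\log\lambda \in [-10, 10]$ after a one-off
eigendecomposition of $G$ projected on the orthogonal complement of $X$,
so the search (golden-section with parabolic refinement, tolerance
$10^{-8}$) costs $O(n)$ per candidate. A boundary solution is flagged
`converged = FALSE`. An independent generic-optimizer implementation on
the unprojected Cholesky likelihood serves as an internal cross-oracle in
the tests.

The two-kernel fit (`reml_two_kernel()`) profiles $\sigma_e^2$ out
analytically and maximises over the two log variance ratios by
Nelder–Mead from five deterministic starts whose additive:epistatic
ratios span 0.1–10 (relative tolerance $10^{-8}$, at most 2000
evaluations per start). A numerically zero kernel collapses the model to
the one-kernel fit with that component pinned at zero. All inversions go
through symmetric Cholesky factorisations; a ridge of $10^{-8}$ times the
mean diagonal guards the rank-deficient kernels that REML touches. The
explicit $n \times n$ matrices $T$ and $S$ are the only inverses ever
formed, because every scan statistic is linear in them.

## The phenotype simulator

`simulate_genotypes()` draws an inbred-style panel: allele frequencies
uniform on `maf_range` (default 0.05–0.5), $\{0, 2\}$ dosages thresholded
from a per-sample latent Gaussian with first-order autocorrelation
`ld_rho` (default 0.5) along a 10-kb-spaced map. This emulates a
diversity panel's local LD; it does not emulate subpopulation structure,
long-range LD, allele-frequency spectra after ascertainment, or
genotyping error, so conclusions drawn from it speak to the statistical
machinery rather than to any particular crop panel. One panel is
simulated per study and reused by every phenotype draw, as a real study
reuses its genotypes.

`simulate_phenotype()` draws
$y = g_A + g_{AA} + e$ with
$g_A \sim N(0, G\sigma_A^2)$, $g_{AA} \sim N(0, H\sigma_{AA}^2)$,
$e \sim N(0, I\sigma_e^2)$, and no per-locus QTL effects. Given a target
ratio $r = \sigma_A^2/\sigma_{AA}^2$ and broad-sense heritability $h^2 =
(\sigma_A^2+\sigma_{AA}^2)/(\sigma_A^2+\sigma_{AA}^2+\sigma_e^2)$, the
components are $\sigma_A^2 = h^2 r/(1+r)$, $\sigma_{AA}^2 = h^2/(1+r)$,
$\sigma_e^2 = 1-h^2$; both kernels are standardised to mean diagonal one
(`standardize_kernel()`) so that $h^2$ is on the per-record scale and the
phenotypic variance is one in expectation.

**Accept–reject calibration.** Because $G$ and $H$ are strongly
correlated, the realised (REML-estimated) components of a simulated
dataset can sit far from the generating values. `run_accept_reject()`
therefore redraws phenotypes until, for every cell of the
`ratio_grid` × `h2_grid` (default 7 × 9 = 63 cells, five accepted
replicates each, 315 datasets), the fitted components satisfy
$|\log_2 \hat r - \log_2 r| \le$ `ratio_tol` and
$|\hat h^2 - h^2| \le$ `h2_tol`. The reference half-widths are 0.5
$\log_2$ units and 0.05. These must be read jointly with the study size:
at the reduced sizes used in this package's own studies (for example
$n = 150$, $p = 80$) the ratio estimator's median absolute error exceeds
one $\log_2$ unit in the harder cells, so the bundled studies use
half-widths of 1.5 and 0.1 — about one median absolute error — with a
cap of 500 draws per cell; the design-count demonstration (63 cells × 5)
runs at $n = 60$ with generous bands, since it verifies retention
bookkeeping rather than calibration. Acceptance is monotone in the
half-widths and the accepted set is a pure function of the configuration,
including its seed.

## The model-comparison analysis

`run_simulation_study()` scans every accepted dataset with the three
epistasis models under the P3D approximation — the two-kernel components
from the acceptance fit are reused for Q+2K and REMMA; the one-kernel
components are refitted once per dataset for the extended Q+K — and then
summarises agreement between methods. `filtered_correlation()` computes,
per dataset, the Pearson correlation of $-\log_{10}(p)$ over the marker
pairs whose value exceeds a threshold $d$ in at least one of the two
methods (NAs removed listwise; fewer than `min_pairs = 10` retained pairs
give `NA` rather than a meaningless near-$\pm1$ value).
`trend_analysis()` then correlates these per-dataset values against
$\log_2(\hat\sigma_A^2/\hat\sigma_{AA}^2)$, stratified by the estimated
heritability classes $\hat h^2 \ge 0.7$, $0.4 \le \hat h^2 < 0.7$,
$\hat h^2 < 0.4$ (`classify_by_h2()`), with a two-sided p-value from the
$t$ transform and the significance key `*` $p<0.1$, `**` $p<0.05$,
`***` $p<0.01$. Pearson correlation is used throughout (configurable in
principle; the linear-trend presentation is the point of the analysis).

**What the trends show — and one honest caveat.** On the bundled
synthetic studies the extended Q+K scan converges to Q+2K as the
additive share of variance grows: their per-dataset similarity trends
strongly *upward* in $\log_2 \hat r$, as expected, because the second
kernel's weight $\sigma_{AA}^2$ vanishes from the covariance. For
REMMA-vs-Q+2K we consistently observe a *positive* trend as well, under
every genotype geometry we simulated (local LD, Balding–Nichols
subpopulation structure, raw or centred products, $p<n$ and $p \gg n$).
The mechanism is visible in the algebra: with the two scans sharing one
fitted covariance $V = I + (\sigma_A^2/\sigma_e^2) G +
(\sigma_{AA}^2/\sigma_e^2) H$, a growing additive weight makes $V^{-1}$
itself discount the marker-direction content of the product column, so
*not* fixing $m_i, m_j$ (REMMA) converges toward fixing them (Q+2K).
A decreasing similarity would require the two models to disagree about
the null covariance itself — which happens when the two scans are run in
separate software with independently estimated components, whose fitted
$\sigma_{AA}^2$ values diverge relatively as the true value approaches
zero. The package deliberately shares one fit across the two scans (that
is what makes the equivalence theorems exact and the comparison clean),
so it reports the positive trend and flags the discrepancy with the
reference direction rather than emulating between-software estimation
noise. The acceptance test for this study states the reference
directions and fails honestly on the REMMA half.

## Numerical conventions and edge cases

* Untestable markers or pairs (monomorphic, inside the column space of
  $X$, collinear triples) produce `NA` rows with a reason code; scans
  never abort mid-genome. Rank-deficient windows reduce the Wald degrees
  of freedom to the rank, with reason `rank_deficient`.
* Missing genotype tokens `NA`, `nan`, `-9` and the empty string;
  imputation by column mean (idempotent); monomorphic columns retained
  and flagged.
* LD pruning works on half-open windows `[start, start + window)`
  advanced by `step` over 1-based positions; within a window the
  most-correlated violating pair is resolved first, removing the member
  with the lower minor-allele frequency (an affine-invariant frequency
  proxy, so pruning is invariant to marker rescaling), ties removing the
  later column. PLINK's own tie-breaking is unspecified, so this rule is
  documented as this package's dialect.
* All p-values: two-sided $t_{n-k-1}$ for single-marker z statistics;
  upper-tail $\chi^2$ for Wald statistics (df = 1 for pairs, df = rank
  for windows; the window reference distribution is a convention choice
  — both routes' statistics are returned so an $F$-type recalibration is
  possible downstream).
* Every stochastic routine takes an explicit seed and is a pure function
  of it; study-level seeds derive from the single configuration seed and
  stay below $2^{31}$.

## Problem sizes used by the bundled checks

The test suite and the acceptance script run entirely on simulated data
at sizes chosen for a desk machine: equivalence sweeps over 50 instances
with $n$ up to 200 and up to 4 covariates; REML recovery at $n = 200$ to
$300$; the comparison study at $n = 150$, $p = 80$ (3160 pairs per
dataset, 24 datasets per seed, three seeds); the design-count study at
$n = 60$, $p = 30$ over the full 63-cell grid. The vignette's account of
expected behaviour states nothing that those runs do not themselves
compute.

## Known limitations

Single-record phenotypes only; no dominance or higher-order epistatic
kernels; no multiple-testing correction (thresholds enter only through
the comparison analysis); the simulator does not imitate any specific
crop panel's structure; variance-component standard errors are not
reported; and the exact per-marker REML scan is quadratic-per-marker and
meant for oracle use, not genome-wide application.
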