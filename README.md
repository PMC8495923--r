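# epiblup

Mixed-model GWAS for additive and epistatic effects in structured
populations, built around the equivalence between back-solving marker
effects from a fitted GBLUP model and the P3D-approximated Q+K
association scan.

## What it does, and for whom

For quantitative geneticists working with genomic prediction panels
(crop diversity panels, animal populations), `epiblup` provides:

* **Additive scans** under the Q+K linear mixed model
  `y = Xβ + m_i a_i + g + e`, `g ~ N(0, G σ²_g)`, with variance
  components estimated once by REML in the GBLUP null model (the P3D
  approximation). Two routes: the GLS test
  `z_i = m_i'Ty / (σ_e √(m_i'Tm_i))` with
  `T = V⁻¹ − V⁻¹X(X'V⁻¹X)⁻¹X'V⁻¹`, `V = I + λG` (`scan_additive_p3d()`),
  and the GBLUP back-solve `â = (σ²_a/σ²_e) M'Ty` with Henderson-sense
  variance `(σ⁴_a/σ²_e) m_i'Tm_i` (`scan_additive_gblup()`). The two z
  statistics are identical marker-for-marker, with arbitrary fixed
  covariates — the package verifies this to 1e−8 and below. Window-based
  joint tests (`test_window()`) and the exact per-marker REML scan
  (`scan_additive_exact()`) complete the set.
* **Exhaustive pairwise epistasis scans** for additive-by-additive
  effects under three models: extended Q+K (`scan_epistasis_qk()`),
  Q+2K with the epistatic kinship
  `H = ½(G∘G − (M∘M)(M∘M)')` (`scan_epistasis_q2k()`), and REMMA — all
  pairs scored from a single extended-GBLUP fit,
  `w_ij = (q'Py)²/(q'Pq)` with `q = m_i∘m_j`
  (`scan_epistasis_remma()`). REMMA is pairwise-identical to the
  auxiliary model that adds only `q` as a fixed term
  (`scan_epistasis_auxiliary()`), and is *not* equivalent to Q+2K.
* **REML machinery** for one- and two-kernel models
  (`reml_one_kernel()`, `reml_two_kernel()`), kinship construction
  (`build_additive_grm()`, `build_epistatic_grm()`,
  `build_pair_design()`), LD pruning (`ld_prune()`), genotype/phenotype
  I/O, a phenotype simulator with accept-reject calibration of realised
  variance components (`run_accept_reject()`), and the model-comparison
  analysis (`filtered_correlation()`, `trend_analysis()`,
  `run_simulation_study()`).

Scan results are tibbles; fitted variance components support
`tidy()`/`glance()`; `autoplot()` and `plot_trend()` give quick ggplot2
graphics. A thin command-line wrapper lives at
`inst/scripts/epiblup.R`.

## Worked example

```r
library(epiblup)

set.seed(1)
cfg <- simulation_config(n = 120, p = 30, seed = 7)
gm  <- simulate_genotypes(cfg)                      # 120 x 30 inbred panel
ks  <- build_epistatic_grm(build_additive_grm(gm))  # VanRaden G, raw-coded H
y   <- simulate_phenotype(standardize_kernel(ks$G), standardize_kernel(ks$H),
                          ratio = 2, h2 = 0.6, seed = 11)
ph  <- phenotype_table(y)

vc <- reml_one_kernel(ph, ks$G)
vc
#> <variance_components> one_kernel fit
#>   sigma_g2 = 0.243085  sigma_e2 = 0.494791  lambda = 0.491289
#>   h2 = 0.3294  restricted logLik = -148.2953

op <- projection_operator(ph, ks, vc)
head(scan_additive_p3d(ph, ks, op, vc), 3)
#> # A tibble: 3 x 8
#>   marker estimate variance statistic    df     p reason method
#>   <chr>     <dbl>    <dbl>     <dbl> <int> <dbl> <chr>  <chr>
#> 1 M1      -0.156     0.294   -0.289    118 0.773 <NA>   QK_P3D
#> 2 M2       0.0507    0.338    0.0871   118 0.931 <NA>   QK_P3D
#> 3 M3       0.546     0.383    0.884    118 0.379 <NA>   QK_P3D
```

The one-kernel null fit attributes about a third of the phenotypic
variance to the additive kernel (`h2`; `lambda` is the
genetic:residual variance ratio — the trait was simulated with
additive *and* epistatic variance, and the single-kernel fit captures
only part of it). Each scan row reports the marker's effect estimate
(trait units per allele-dosage unit), its variance, the z statistic and
the two-sided p-value on `n − k − 1` degrees of freedom.
`scan_additive_gblup(ph, ks, op, vc)` reproduces the `statistic` column
to machine precision — that identity is the point.

For epistasis:

```r
vc2 <- reml_two_kernel(ph, ks$G, ks$H)
op2 <- projection_operator(ph, ks, vc2, force = TRUE)
scan_epistasis_remma(ph, ks, NULL, op2, vc2)   # all 435 pairs from one fit
#> <scan_result> method = REMMA, 435 tests (18 NA)
#> # A tibble: 435 x 9
#>   marker1 marker2 estimate  variance statistic    df     p reason method
#>   <chr>   <chr>      <dbl>     <dbl>     <dbl> <int> <dbl> <chr>  <chr>
#> 1 M1      M2      -0.00366 0.000101      0.133     1 0.716 <NA>   REMMA
#> 2 M1      M3       0.00389 0.0000546     0.278     1 0.598 <NA>   REMMA
#> 3 M1      M4      -0.00290 0.0000203     0.415     1 0.519 <NA>   REMMA
#> # i 432 more rows
```

The 18 `NA` rows are pairs whose product column is constant or inside
the column space of the fixed design — skipped with a reason code, never
an error.

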