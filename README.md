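# mgmin

Gaussian-mixture normalization of Illumina Infinium HumanMethylation450
("450K") M-values, correcting the design bias between the array's two probe
chemistries.

## The problem

450K arrays measure CpG methylation with two probe designs: type I
(n ≈ 135,000) and type II (n ≈ 350,000). Both report a β-value
(the methylated fraction, in [0, 1]) or equivalently an M-value
(M = log2(β / (1 − β))), but type II probes have a compressed dynamic
range — their hypo- and hypermethylated peaks sit closer together than those
of type I probes measuring the same biology. Left uncorrected, this design
bias inflates technical variation and distorts downstream analyses such as
differential-methylation testing.

## The method

Per sample, the M-values of each probe type are modeled as a K-component
Gaussian mixture

&nbsp;&nbsp;&nbsp;&nbsp;p(M; θ) = Σₖ πₖ · N(M | μₖ, σₖ²),&nbsp;&nbsp;K = 3,

whose components correspond to hypomethylated (U), hemimethylated (H) and
hypermethylated (F) states. The parameters are fitted by EM from the
canonical starting point μ = (−4, 0, 4), σ = (1, 1, 1). When the fitted
type I hypermethylated flank μ_I^F − σ_I^F falls below the type II flank
μ_II^F − σ_II^F, the type I model is refitted with K = 4 (the two middle
components both labelled H), guaranteeing μ_I^F > μ_II^F.

Each type II probe is assigned to a state by maximum posterior probability
and split at its component mean into a left (L) and right (R) side. Then:

- **U_IIL** (hypomethylated, left of μ_II^U) and **F_IIR** (hypermethylated,
  right of μ_II^F) are quantile-mapped onto the matching type I component:
  q = Φ⁻¹(Φ(M | μ_II^S, σ_II^S) | μ_I^S, σ_I^S), which for Gaussians is the
  affine map μ_I^S + σ_I^S (M − μ_II^S)/σ_II^S.
- The middle set **G = U_IIR ∪ H_II ∪ F_IIL** receives a conformal
  (shift + dilation) transform M′ = minG′ + df · (M − minG) with dilation
  factor df = (maxG′ − minG′)/(maxG − minG), where the new bounds are chosen
  so the gaps Δ_UG and Δ_GF between G and the quantile-mapped flanks are
  exactly conserved — the normalized values stay continuous.

Type I values are never modified. β-matrices are converted to M on entry and
back on exit.

## Worked example

```r
library(mgmin)

sim <- simulate_array(simulation_spec(n_type1 = 4000, n_type2 = 10000,
                                      n_samples = 1, seed = 42))
res <- mgmin_normalize(sim$data, sim$annotation, scale = "m")
tidy(res)[, c("sample", "k_type1", "delta_ug", "delta_gf", "df")]
#> # A tibble: 1 × 5
#>   sample    k_type1 delta_ug delta_gf    df
#>   <chr>       <int>    <dbl>    <dbl> <dbl>
#> 1 sample_01       3 0.000354  0.00274  1.52
```

One sample was normalized with the default three type I components
(`k_type1 = 3`); the middle set was dilated by `df = 1.52`, stretching the
compressed type II range onto the type I scale while conserving the tiny
empirical gaps (`delta_ug`, `delta_gf`) to the quantile-mapped flanks. The
fitted type I mixture recovers the generating states:

```r
tidy(res$samples$sample_01$fit_type1)
#> # A tibble: 3 × 5
#>   component state weight    mean     sd
#>       <int> <chr>  <dbl>   <dbl>  <dbl>
#> 1         1 U      0.310 -4.02    1.07
#> 2         2 H      0.293  0.0389  1.07
#> 3         3 F      0.396  4.05    1.04
```

The design bias, measured as the two-sample Kolmogorov–Smirnov distance
between type I and type II M-value distributions, drops five-fold:

```r
is1 <- sim$annotation$type == "I"
distribution_distance(sim$data[[2]][is1], sim$data[[2]][!is1])   # raw
#> [1] 0.20055
distribution_distance(sim$data[[2]][is1], res$normalized[[2]][!is1])
#> [1] 0.03805
```

`autoplot(res)` draws the density curves (type I, raw type II, normalized
type II) per sample. Evaluation helpers cover replicate variation
(`probe_sd()`, `mean_abs_diff()`), deviation from a reference
(`deviation_summary()`), differential methylation (`detect_dmps()`,
`validate_dmps()`, `ppv()`) and detection-p sample QC
(`qc_filter_samples()`).

A command-line wrapper lives at `inst/cli/mgmin.R`:

```sh
Rscript inst/cli/mgmin.R normalize --input beta.tsv --annotation probes.tsv \
    --scale beta --output normalized.tsv --provenance fits.json
Rscript inst/cli/mgmin.R simulate --spec spec.json --output-prefix sim
Rscript inst/cli/mgmin.R evaluate --metric dmp --input m.tsv --labels a,a,b,b
```

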