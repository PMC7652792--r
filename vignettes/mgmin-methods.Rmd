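---
title: "Gaussian-mixture normalization of 450K M-values: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-mixture normalization of 450K M-values: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgmin)
```

## The model

Infinium 450K arrays mix two probe chemistries. Type II probes report a
compressed dynamic range: their hypo- and hypermethylated modes sit nearer
the center than the type I modes measuring the same underlying biology.
`mgmin` corrects this on the M-value scale, where probe-level variances are
far closer to homoscedastic than on the β scale, making a Gaussian mixture
an appropriate density model.

Per sample and per probe type, M-values are treated as a finite Gaussian
mixture

$$p(M;\theta) = \sum_{k=1}^{K} \pi_k\, \mathcal{N}(M \mid \mu_k, \sigma_k^2),
\qquad K = 3,$$

with components interpreted, in ascending mean order, as hypomethylated (U),
hemimethylated (H) and hypermethylated (F) states. No thresholds separate
the states; assignment is by maximum posterior $\pi_k \mathcal{N}(x \mid
\mu_k, \sigma_k^2)$, with ties broken to the lower-mean component (the
mixing proportions are part of the fitted model, so an unweighted density
criterion would discard information).

The correction maps the type II distribution onto type I in three pieces:

1. Type II probes in state U left of $\mu_{II}^U$ (the set $U_{IIL}$), and
   in state F right of $\mu_{II}^F$ ($F_{IIR}$), are quantile-mapped through
   their own component's CDF and the inverse CDF of the matching type I
   component. For Gaussians this composition is the affine map
   $\mu_I^S + \sigma_I^S (x - \mu_{II}^S)/\sigma_{II}^S$.
2. The remaining middle set $G = U_{IIR} \cup H_{II} \cup F_{IIL}$ is
   shifted and dilated: $x \mapsto minG' + df\,(x - minG)$ with
   $df = (maxG' - minG')/(maxG - minG)$. The new bounds are defined by
   conserving the empirical gaps $\Delta_{UG} = minG - \max U_{IIL}$ and
   $\Delta_{GF} = \min F_{IIR} - maxG$ to the transformed flanks, so the
   assembled output is continuous and the three pieces cannot drift apart.
3. Type I values pass through untouched; β input is converted to M on entry
   and back on exit.

### The four-component escalation

When the fitted type I hypermethylated flank $\mu_I^F - \sigma_I^F$ is
strictly smaller than the type II flank $\mu_{II}^F - \sigma_{II}^F$, the
type I mixture is refitted with $K = 4$; the lowest-mean component is U, the
highest F, and both middle components are labelled H. This guarantees
$\mu_I^F > \mu_{II}^F$, so mapping $F_{IIR}$ rightward cannot create a
spurious peak left of the type I hypermethylated mode in heterogeneous
samples. Equality does not trigger the rule. The refit starts from scratch
(initial means $(-4, 0, 3, 6)$, adding a far-right component) rather than
splitting an existing component; the choice is recorded per sample in the
provenance, and `k_type1 = 3` or `4` can be forced for diagnostics.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| EM initial means | $(-4, 0, 4)$ | M | the natural positions of the U/H/F modes on real arrays; the fit is insensitive to ±0.5 perturbations |
| EM initial SDs / weights | $(1,1,1)$, uniform | M / — | weakly informative; weights are not part of the canonical initialization and start uniform |
| `tol` | $10^{-8}$ | relative log-likelihood change | at $10^{-6}$, an initialization perturbed by ±0.5 still moves fitted parameters by $\sim 2\times10^{-3}$ at $n = 2\times10^5$; $10^{-8}$ brings that below $10^{-4}$ (about 20 instead of 8 iterations), making the fit effectively initialization-free as the method intends |
| `max_iter` | 500 | iterations | cap for pathological inputs; convergence is typically 10–30 iterations |
| `sigma_floor` | $10^{-4}$ | M | prevents component collapse onto near-duplicate values; hitting the floor warns rather than errors |
| β clamp `eps` | $10^{-6}$ | β | β ∈ {0, 1} has no finite M; the clamp keeps the β↔M pair exact inverses on $[\epsilon, 1-\epsilon]$ |
| `alpha` (β, M from intensities) | 100, 1 | counts | regularize low-intensity ratios; negligible for the >95% of probes with intensities above ~1,000 |
| DMP FDR | 0.35 | — | the threshold used for the published DMP validation counts this package's PPV helpers mirror |
| `tau_p`, `tau_r` | user-set, $\tau_r \le 0.3$ | — | a probe is bad when detection p **>** $\tau_p$; a sample is dropped when its bad fraction **>** $\tau_r$ (both strict, so a sample exactly at the threshold is kept); more than 30% bad probes makes a sample untrustworthy |

## Numerical choices

- **Quantile map.** The CDF/inverse-CDF composition is evaluated on the log
  scale of the nearer Gaussian tail. This matches the affine closed form to
  ~$5\times10^{-15}$ out to 13 source SDs — a linear-scale tail probability
  underflows its precision beyond ~8 SDs — and a floor at $\log(10^{-300})$
  keeps even absurd outliers finite.
- **Side boundary.** A value exactly at its component mean counts as
  right-side (R).
- **Degenerate middle set.** If $maxG = minG$ the dilation factor is
  undefined; all of G maps to the midpoint of the target range, with a
  warning.
- **Non-contiguous posterior regions.** When component SDs differ
  substantially, the posterior-argmax region of a component need not be an
  interval (a wide H component can reclaim the far tail beyond F). Probes
  are still transformed as assigned, the empirical gap can then be negative,
  and cross-piece rank preservation is no longer guaranteed; the per-sample
  `noncontiguous_runs` diagnostic counts state-run changes along sorted
  values beyond the expected one per component, and is exposed in `tidy()`
  output so such samples are visible.
- **Missing values** are excluded from a sample's fit and propagated as `NA`.
  A sample with fewer than 30 non-missing probes of either type is flagged
  and passed through unnormalized instead of failing the whole matrix.
- **Determinism.** EM is deterministic given its initialization; there are
  no random restarts. Identical inputs and configuration give bit-identical
  output.

## The synthetic generator

`simulation_spec()` / `simulate_array()` generate 450K-like matrices with
known truth. Per probe and replicate group, a true M-value is drawn from the
probe type's three-component mixture; each sample column adds i.i.d.
$\mathcal{N}(0, \text{replicate\_noise\_sd}^2)$ noise; spiked probes are
shifted by `effect_size` in the second phenotype group. Defaults are the
study conditions used throughout the package's own validation: 20,000
type I and 50,000 type II probes (roughly the real 450K type I:II ratio,
scaled down), $\pi = (0.3, 0.3, 0.4)$, $\sigma = 1$, type I means
$(-4, 0, 4)$, type II outer means compressed to $\pm 2.6$, replicate noise
SD 0.3 M-units.

The compression is modelled on the component means only (an affine shrink by
0.65), keeping component SDs at 1 for both types — compressing draws
directly would shrink the type II component SDs to 0.65 and silently change
the noise geometry. A saturating alternative (`compression = "sigmoid"`,
$m \mapsto L\tanh(m/L)$) is available to emulate tail-squashing rather than
mean-shift compression.

What the generator does **not** emulate: intensity-level chemistry
(background, dye bias, detection p-values), spatial artifacts, batch
structure, and — importantly — replicate-specific *distributional* shifts;
its technical noise is a single i.i.d. Gaussian per cell. Passing tests on
this generator therefore demonstrate the transform's mathematical
properties, not end-to-end performance on real arrays.

## Validation, problem sizes, and two honest caveats

The test suite and `scripts/acceptance.R` compute, at the sizes stated:
quantile-map exactness (10,000 random tuples); EM recovery within 0.05
(means, SDs) and 0.01 (weights) plus ±0.5-initialization robustness within
$10^{-3}$ (200,000 draws, 5 seeds); structural invariants — type I
bit-identical, gaps conserved to $10^{-9}$, type II ranks preserved,
back-converted β strictly inside (0, 1) — and a ≥50% KS-distance reduction
at the default 50,000-type II simulation; replicate-variation metrics on 3
technical replicates; DMP null behaviour over 20 seeds and ≥90% spike
recovery (5 vs 5, effect 2.0, noise SD 0.5); and the published PPV worked
examples (16/51 → 0.31, 37/220 → 0.17, 3/51 → 0.06, 27/220 → 0.12).

Two results deserve explicit framing:

1. **Self-map.** When type II values are drawn from the *same* mixture as
   type I, the transform should be near-identity. It is (median absolute
   change ≈ 0.01 M at n = 50,000) — *with matched component counts*
   ($K_I = 3$). Under the automatic escalation rule, exact parameter
   equality places $\mu_I^F - \sigma_I^F$ vs $\mu_{II}^F - \sigma_{II}^F$ on
   a knife edge: sampling noise alone decides whether the rule fires, and
   when it does, the refit intentionally pushes the type I hypermethylated
   mean rightward, shifting the $F_{IIR}$ map by design. The self-map check
   therefore fixes $K_I = 3$; real arrays, where type II is genuinely
   compressed, sit far from this edge.
2. **Mean absolute β difference between replicates.** The median per-probe
   type II β-SD across replicates decreases after normalization (outer-state
   probes move to flatter regions of the β sigmoid). The probe-*mean*
   absolute β difference, however, *increases* slightly (~+7%) under this
   generator: the dilation ($df \approx 1.4$) amplifies i.i.d. M-noise for
   probes near the sigmoid's steep center, and those probes dominate the
   mean. On real replicates the analogous reduction comes largely from
   aligning replicate-specific distributional shifts — a noise structure a
   single i.i.d. noise SD cannot express. The package reports both raw and
   normalized values of this metric rather than claiming a reduction it
   does not produce here.

## Known limitations

- 450K-oriented: no EPIC/850K manifest handling, no IDAT or intensity-level
  preprocessing, no batch correction — the method consumes β/M matrices.
- Per-sample independence: no information is pooled across samples, so very
  small or low-quality samples (see `qc_filter_samples()`) fit noisily;
  heavily degenerate samples are flagged rather than repaired.
- The EM can find local optima when the compressed type II modes overlap
  strongly (small fixtures occasionally fit a too-wide H component); the
  `noncontiguous_runs` diagnostic and the per-sample provenance exist to
  make such fits auditable.
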