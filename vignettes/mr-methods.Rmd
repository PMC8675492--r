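---
title: "Methods: two-sample Mendelian randomization with gwasmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization with gwasmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The design

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure. Because alleles are fixed at
conception, a variant that robustly raises, say, systolic blood pressure
is not confounded by the social and behavioural factors that plague
observational exposure–outcome associations. In the two-sample setting the
SNP–exposure associations $\hat\beta_{Xk} \pm \sigma_{Xk}$ and the
SNP–outcome associations $\hat\beta_{Yk} \pm \sigma_{Yk}$ come from
separate GWAS summary tables; no individual-level data are needed. For a
binary outcome the $\hat\beta_{Yk}$ are log-odds per effect allele.

Under the instrumental-variable assumptions each variant gives a Wald
ratio $\hat\theta_k = \hat\beta_{Yk}/\hat\beta_{Xk}$ for the causal effect
$\theta$ of the exposure (per SD or per measurement unit) on the outcome,
and the package's estimators are different ways of pooling these ratios
under different failure modes of the "no pleiotropy" assumption.

# Harmonization

Exposure and outcome tables must refer to the same effect allele.
`harmonize_dataset()` resolves, per variant:

* identical allele pairs (kept as-is), swapped pairs (outcome effect
  negated, EAF reflected), strand-flipped pairs (reverse complements,
  values unchanged), and swapped-and-flipped pairs;
* palindromic variants (A/T, C/G), whose strand cannot be read off the
  alleles. If the effect-allele frequency is outside the exclusive window
  (0.42, 0.58) the orientation is inferred by frequency matching — the
  outcome record is aligned so its EAF falls on the same side of 0.5 as
  the exposure's. Inside the window the variant is ambiguous: a proxy is
  tried first, otherwise it is dropped. The endpoints are exclusive, so a
  variant at exactly 0.42 is treated as inferable. A palindromic variant
  with missing EAF is conservatively ambiguous.
* variants missing from the outcome (or ambiguous as above), replaced from
  a file-based proxy map: the highest-r² proxy with r² ≥ 0.8 that is
  present in the outcome table and carries a usable allele correspondence.
  A proxy that is itself palindromic-ambiguous in the outcome is skipped —
  substituting it would reintroduce exactly the ambiguity the proxy is
  meant to remove. Online LD services are deliberately out of scope; proxy
  maps are plain TSV inputs so the pipeline is hermetic.

Retained plus dropped variants always partition the requested instrument
list, retained order follows the exposure table, and every decision is
recorded in an audit log.

# Instrument diagnostics

* **Per-SNP F** $= (\hat\beta_{Xk}/\sigma_{Xk})^2$; below ~10 flags a weak
  instrument.
* **I²** of instrument strength (the NOME diagnostic):
  $Q_{GX} = \sum_k w_k(\hat\beta_{Xk}-\bar\beta)^2$ with $w_k =
  1/\sigma_{Xk}^2$, $I^2 = \max\{0, (Q_{GX}-(L-1))/Q_{GX}\}$, truncated at
  zero when $Q_{GX} < L-1$ (a standard convention; the quantity is a
  proportion). Below 0.90 the no-measurement-error assumption behind
  MR-Egger is doubtful; above 0.97 sample-overlap bias is minimal.
* **Variance explained** $r^2 = \sum_k (\beta_k/\mathrm{SD})^2 \cdot
  2\,\mathrm{MAF}_k(1-\mathrm{MAF}_k)$, with effects standardized by the
  phenotypic SD (e.g. 20.1 mm Hg for systolic, 11.2 for diastolic BP) and
  MAF the folded frequency.
* **Power (binary outcome).** The effective MR sample size is the outcome
  GWAS size discounted by $r^2$; with case fraction $c$ the
  non-centrality is $\mathrm{NCP} = n r^2 c(1-c) (\ln \mathrm{OR})^2$,
  power $= \Phi(\sqrt{\mathrm{NCP}} - z_{1-\alpha/2})$, and the detectable
  OR at target power inverts this. This closed normal-approximation form
  reproduces the published total-cancer detectable OR (~1.09); the exact
  formula behind the published per-site values is not stated, and the
  thyroid-type extremes are not expected to match exactly.

Selection helpers implement the usual genome-wide filters: strict
$p < 5\times10^{-8}$ significance and greedy LD clumping at $r^2 < 0.001$
(most significant SNP first; ties break lexicographically on variant id so
the selection is deterministic).

# Estimators

**IVW.** With $w_k = 1/\sigma_{Yk}^2$,
$\hat\theta = \sum w_k \hat\beta_{Xk}\hat\beta_{Yk} / \sum w_k
\hat\beta_{Xk}^2$ — algebraically the precision-weighted mean of Wald
ratios and the no-intercept weighted regression of outcome on exposure
effects. The multiplicative random-effects variant (the default, and the
main analysis in the intended workflow) scales the fixed-effect SE by
$\sqrt{\varphi}$, $\varphi = \max\{1, Q/(L-1)\}$ with Cochran's $Q$ at
$\hat\theta$: overdispersion widens the intervals, but they never shrink
below fixed-effect (the truncation at 1 is a deliberate, conservative
choice; the source analysis does not state one).

**Weighted median.** Consistent when ≥50% of the weight
($w_k = \hat\beta_{Xk}^2/\sigma_{Yk}^2$) comes from valid instruments. The
estimate interpolates the weighted empirical quantile function of the
ratios at 0.5; its SE is a parametric bootstrap (default 1000 replicates)
resampling both $\hat\beta_X$ and $\hat\beta_Y$, with a mandatory explicit
seed — there is no silent RNG state.

**MR-Egger.** Weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ *with*
an intercept, after orienting each variant so $\hat\beta_{Xk} \ge 0$ (the
intercept is only interpretable on a consistently oriented panel). The
slope is the causal estimate under InSIDE (pleiotropy independent of
instrument strength); the intercept estimates average directional
pleiotropy and a zero intercept is evidence against it. SEs are inflated
by $\sqrt{\max\{1, Q'/(L-2)\}}$.

CIs and p-values are normal-based throughout (not t-based): the target
workflow reports symmetric 95% CIs from panels of ~270 instruments, where
the distinction is invisible at the reported precision. Estimates are
produced per exposure unit and rescaled linearly (`rescale_estimate()`)
to per-SD or per-10/per-5 mm Hg increments; p-values are scale-invariant.

# Multivariable MR

With two exposures (e.g. blood pressure adjusted for BMI or for
ever-smoking), `mv_ivw()` regresses $\hat\beta_Y$ on both columns of
$\hat\beta_X$ without intercept, weights $1/\sigma_{Yk}^2$; each
coefficient is a direct effect. `mv_egger()` adds an intercept after
orienting on the primary exposure. Instruments shared between exposures
(or cross-correlated at $r^2 \ge 0.001$, the same threshold used for
instrument independence — the source analysis names the rule but not the
threshold) are dropped before estimation. An all-zero exposure column is
aliased, not an error: its coefficient is NA with a warning and the
remaining coefficients reduce to the lower-dimensional fit, which is what
the nested-model identity requires.

**Conditional strength (Sanderson–Windmeijer).** For exposure $j$ given
$m$, $Q_j(\delta) = \sum_k (\hat\beta_{Xjk} - \delta\hat\beta_{Xmk})^2 /
(\sigma_{Xjk}^2 + \delta^2\sigma_{Xmk}^2 - 2\delta\rho\,\sigma_{Xjk}
\sigma_{Xmk})$, minimized over $\delta \in [-10, 10]$ (1-D golden-section
search, tolerance 1e-8), with $\rho$ the phenotypic correlation between
exposures (supplied via configuration — the published values are cited to
a biobank but not printed, so they are an input, not a constant).
Conditional F $= Q_j(\hat\delta)/(L-1)$, matching the univariable
denominator. When the other exposure's effects are identically zero the
profiled denominator is unbounded in $\delta$ and the natural $\delta = 0$
limit is returned — the marginal mean-F analogue.

**Modified Q.** Residual heterogeneity at $(\theta_1,\theta_2)$ with
per-variant variances propagating exposure uncertainty and the phenotypic
correlation; reported at the minimizing $\theta$ when none is supplied
(Nelder–Mead from the MV-IVW solution).

# The synthetic world

`simulate_pair()` generates summary tables with known truth, so that every
estimator is testable hermetically:

* MAF uniform on (0.05, 0.5); standardized effect magnitudes from a
  half-normal **left-truncated at 0.5**, rescaled so the panel explains
  exactly `target_r2`. The truncation mimics a significance-selected,
  externally replicated instrument panel: real panels have a hard F floor
  (genome-wide significance implies per-SNP F ≳ 29), and without it the
  generator produces near-zero instruments whose observed effects flip
  sign under noise, which corrupts MR-Egger's orientation step with a
  bias that no real instrument panel would exhibit. The truncation point
  reproduces a min-F/mean-F ratio of ~0.3, as seen in published panels.
* analytic SEs: $\sigma_{Xk} = (2p_kq_kn_X)^{-1/2}$,
  $\sigma_{Yk} = (2p_kq_kn_Yc(1-c))^{-1/2}$ (log-odds scale).
* pleiotropy on an `invalid_fraction` of SNPs with mean `mu_alpha`, SD
  `sigma_alpha`, and optional correlation `inside_rho` with instrument
  strength (an InSIDE violation).
* alleles: a configurable fraction palindromic; effect-allele frequency is
  MAF or 1−MAF at random; everything deterministic given the seed, with
  the caller's RNG state restored.

Outcome effects are generated directly on the log-odds scale rather than
through individual-level logistic sampling: fast, adequate for estimator
calibration, and the main reason a green calibration does **not**
establish behaviour under non-collapsibility, case-control ascertainment
quirks, LD between instruments, or sample overlap — none of which the
generator emulates.

Defaults (L = 100 instruments, exposure GWAS of 450,000 explaining 2.6%
of variance, binary outcome GWAS of 400,000 with 9% cases) describe a
desk-scale version of a contemporary biobank analysis of blood pressure
and total cancer.

`calibrate()` runs simulate → harmonize → estimate over independently
seeded replicates (each reproducible in isolation) and reports bias,
empirical vs model SE, RMSE, 95% coverage and rejection at α = 0.05.

## What the calibrations establish — and one honest failure

At 1000 replicates (fixed seed): the null scenario gives IVW rejection
0.040 and coverage 0.960 (the `max(1, Q/df)` truncation makes
multiplicative random effects slightly conservative under the null — by
design); balanced pleiotropy leaves IVW unbiased within Monte-Carlo
error; directional pleiotropy satisfying InSIDE leaves the Egger slope
unbiased with intercept equal to the mean pleiotropy, while IVW is biased
by `mu_alpha` divided by the weighted mean instrument effect.

The weighted median in the same directional world with 30% invalid SNPs
is **not** unbiased at Monte-Carlo resolution (bias ≈ +0.12 vs IVW's
+0.20): with the configured pleiotropy (~4× the typical per-SNP outcome
effect) and Wald-ratio noise of the same order, the valid and invalid
ratio distributions overlap, and the weighted median's 50%-breakdown
guarantee — an asymptotic statement as ratio noise vanishes — does not
bind in finite samples. The corresponding acceptance assertion is left
failing rather than widened: partial robustness (median bias strictly
smaller than IVW's) is what this world actually supports, and that is
asserted instead alongside it.

# Numerical and interface choices

* P-values are parsed from text and preserved to 1e-300; below that a
  z-score must be supplied (`se_from_pvalue()` refuses to divide by a
  saturated quantile). Reconstructed SEs round-trip the p-value to 1e-10
  relative.
* Result tables serialize at full double precision; write → read → write
  is byte-stable.
* Effect sizes for odds-ratio-scale sources are log-transformed at read
  time behind an explicit per-source flag — never guessed.
* Rounding happens only at serialization; the Bonferroni comparison uses
  the exact `alpha/(exposures × outcomes)`, with the familiar 0.0014 being
  a 2-significant-figure display of 0.05/36.
* Study configuration is YAML (or JSON); per-cell failures in a study grid
  are isolated and logged, and a run log records version, seed and the
  exact threshold.

# Known limitations

No MR-PRESSO/mode-based/SIMEX/radial estimators; K ≥ 3 multivariable
models unsupported (the two-exposure case covers BP + BMI and BP +
smoking); no LD computation from genotypes (proxy maps and LD matrices
are file inputs); no VCF or coordinate-aware parsing; the power formula is
a normal approximation whose per-site extremes need not match tools using
exact binomial variance; the generator does not simulate LD, overlap, or
selection effects such as winner's curse — which is also why the
generator's mean F obeys the analytic identity mean(F) ≈ N·r²/L + 1 while
published panels, whose SEs reflect covariate adjustment and
meta-analysis, can sit above it.
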