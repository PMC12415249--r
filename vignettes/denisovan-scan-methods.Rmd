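---
title: "Scanning hominin crania against a directional Denisovan profile: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning hominin crania against a directional Denisovan profile: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deniscan)
```

## The problem

Denisovans are an extinct hominin lineage defined genetically, with very few
morphologically informative fossils. Gene-regulatory comparisons between the
Denisovan, Neanderthal and modern-human genomes yield *directional* phenotype
predictions — statements that a cranial trait is expected to be higher or
lower in Denisovans than in a named reference group, with no magnitude
attached. `deniscan` implements a pipeline that scores how well candidate
Middle-Pleistocene crania match such a profile against empirical reference
distributions (anatomically modern humans, AMH, and Neanderthals), assesses
significance with a constraint-preserving permutation null, differentiates
Denisovan-like from Neanderthal-like morphology, and places specimens in a
PCA morphospace.

The packaged default profile holds 18 directional predictions over 12
phenotypes: every phenotype is tested against AMHs and six are additionally
tested against Neanderthals; 14 predictions concern linear measurements (mm
or mm²) and 4 concern nonlinear ones (angles/indices).

## Quantiles and the phenotypic distance

For a measurement value $t$ of a test subject and reference values
$t_1 \le \dots \le t_N$:

1. Tukey-fence outliers (outside $Q_1 - 1.5\,\mathrm{IQR}$,
   $Q_3 + 1.5\,\mathrm{IQR}$) are removed from the *reference* sample only.
   Quartiles use linear interpolation of order statistics at positions
   $1 + (N-1)p$ — the default convention of mainstream statistical software;
   the convention is isolated in one function so it can be swapped.
2. The $i$-th order statistic estimates the $(i - 0.5)/N$ quantile; tied
   values share the mean of their quantiles.
3. Quantiles between support points are linearly interpolated.
4. Outside the support, the quantile clamps to $[0.5/N,\; 1 - 0.5/N]$.
   Clamping (rather than returning 0/1 or missing) keeps every downstream
   distance strictly inside $(-1, 1)$ and matches
   extrapolation-by-nearest-value; an all-identical reference sample is
   flagged degenerate and returns 0.5 at the support point.

With $s = +1$ when the trait is predicted higher in Denisovans and $-1$
otherwise, the phenotypic distance is $D = 2s(q - \tfrac12)$: positive
distances agree with the Denisovan prediction.

## Profile scores

Given distances $d_1,\dots,d_k$ for a subject (one per testable prediction):

* **Binomial score.** A one-sided test of whether the number of strictly
  positive distances exceeds the $\mathrm{Bin}(k, \tfrac12)$ expectation.
  The default is the **mid-p** variant, $P = P(X > n_+) + \tfrac12 P(X = n_+)$,
  which is the continuity-handled one-sided binomial probability; for 16
  positive of 18 it gives $P = 95.5/2^{18}$ and a score of 3.44. The plain
  exact tail and the continuity-corrected normal approximation remain
  available behind a `method` flag (they give 3.18 and 2.96 on the same
  count). A zero distance counts as a non-match: compatibility requires a
  strictly positive distance.
* **Wilcoxon score.** A one-sided signed-rank test of whether the median
  distance exceeds zero: asymptotic normal approximation with mean ranks for
  tied $|d|$ and Pratt handling of zeros (zeros are ranked, then dropped),
  with tie-corrected variance. An exact sign-flip enumeration
  (`wilcoxon_exact_p()`) cross-checks it for small $k$. All-zero distances
  return $p = 0.5$, flagged degenerate.
* Scores are $S = -\log_{10} P$ with $P$ floored at $10^{-300}$; the combined
  statistic is $S_{\mathrm{obs}} = \sqrt{S_b^2 + S_w^2}$.

Because the underlying measurements are correlated, these p-values are
similarity **scores**, not calibrated significance; calibration comes from
the permutation test. Benjamini–Hochberg adjustment is applied across test
subjects only — reference specimens, scored leave-one-out against their own
group as controls, are never "discoveries".

## The permutation null

Each permutation replaces the profile's measurements with random ones from
the pool of measurements observed for the specimen, conserving (i) the
number of testable predictions, (ii) the count tested against each reference
group, and (iii) the linear/nonlinear split. Because a measurement's raw
direction is an arbitrary artifact of its definition, every measurement is
sign-aligned to a size-proxy anchor (biorbital breadth, `EKB`) by the sign
of its Pearson correlation (pairwise-complete; Spearman behind a flag); a
sampled measurement inherits the slot's predicted direction times its
orientation sign. Numerical choices:

* sampling is without replacement within one permuted profile and with
  replacement across permutations; the slot's original measurement stays in
  the pool and may be redrawn;
* $p_{\mathrm{raw}}$ is the fraction of permuted combined scores
  $\ge$ the observed one — ties count toward the numerator (conservative);
  an add-one smoothed estimator is available behind a flag, off by default;
* a zero anchor correlation orients $+1$ with a warning, and orientations
  with $|r| < 0.1$ are flagged as unreliable;
* BH adjustment spans the test subjects with at least five testable
  predictions.

## The synthetic study generator

`generate_study()` emulates the study design the scan assumes: reference
groups of 20 *H. erectus*, 18 *H. sapiens* and 15 Neanderthal crania plus
configurable test subjects; 150 continuous measurements (126 linear, of
which 24 negatively size-loaded, mirroring the published 118:24 positive-to-
negative anchor-correlation split; 24 nonlinear); roughly 10%
missing-at-random cells mimicking differential preservation, with an
optional contiguous-block pattern for whole missing anatomical regions.

Measurements are generated from a latent-factor model: a shared size factor
(the anchor loads strongly and positively), three "anatomical region"
factors producing correlated residuals — the correlation structure that
violates the independence assumptions of the binomial and signed-rank tests
and motivates the permutation design — and diagonal noise. Group structure
is deliberately carried **only by channels the permutation design
conserves**: Neanderthals are large and *H. erectus* small on the size
factor; all nonlinear measurements share an orientation-aligned archaic
"robusticity" shift in Neanderthals; and every measurement receives a small
idiosyncratic group shift. Under the null, profile measurements are then
statistically exchangeable with random pool draws, which is exactly the
condition under which the permutation p-value is uniform. Denisovan-specific
directional signal exists only in planted specimens. A consequence worth
knowing: the generator does not reproduce trait-specific lineage signatures
(e.g., a Neanderthal-only change on one named trait) — such signal is
invisible to a measurement-resampling null by construction and would make
every specimen's p-value anticonservative.

Nonlinear measurements carry weak size loadings ($|\beta| \in [0.15, 0.35]$,
half negative) rather than none: angles and indices correlate weakly but
genuinely with size in real craniometric data, and a strictly size-free
angle would have a pure-noise anchor orientation, leaving the
class-conserving permutation nothing real to mirror.

`plant_denisovan_like()` appends a specimen drawn from a base group's
distribution and displaces each profile measurement by
$s \times \mathrm{effect}$ within-group (empirical base-group) standard
deviations. The default base group is Neanderthal: Denisovans are the
Neanderthal sister lineage, so a Denisovan-like cranium is modeled as a
Neanderthal-distributed specimen displaced toward the predicted Denisovan
state. For a measurement carrying two predictions of opposite sign (the
Neanderthal-derived phenotypes, where the Denisovan is predicted above the
AMH median but below the Neanderthal one) a single shift cannot satisfy
both, so the planted value is placed at the midpoint of the two reference
medians when that interval is nonempty, with the literal shift rule as
fallback. At the default planted effect of 1.5 SD the planted specimen
matches at least 14 of 18 predictions in ~97% of simulated studies and is
recovered as the top-ranked, permutation-significant subject in 10 of 10
test seeds.

Null test subjects default to *H. erectus* draws (archaic candidate crania);
the null-calibration analysis instead draws subjects from the AMH reference
distribution, across 10 independently generated studies of 20 subjects each
so that the idiosyncrasies of any one simulated study average out.

## PCA morphospace

Measurements with more than 20% missing values are dropped, then specimens
with more than 15% (both thresholds strict; the reverse order and a
nonlinear-only variant with a 30% measurement threshold are supported).
Remaining holes are filled by plain iterative-PCA (EM-PCA): initialize with
column means, then alternate center/scale, rank-2 SVD truncation and
refilling of the missing cells until the relative mean-squared change of
the imputed values drops below $10^{-14}$ (error decays linearly, so
imputed values are accurate well beyond the square root of the tolerance)
or 2000 iterations, warning and returning the best iterate on
non-convergence. Observed cells are never altered. No ridge regularization
is applied; a regularized variant is version-dependent in the packages that
popularized it, and the plain scheme is the reproducible core.

Imputation runs on all specimens jointly (matching the description order:
impute, then fit, then project); the PCA itself — centering, scaling by the
population (ddof 0) standard deviation, and loadings — is fit on the
reference individuals only, and test subjects are projected onto that
plane. Loading signs follow the convention that each component's
largest-magnitude element is positive, making outputs reproducible despite
the inherent sign arbitrariness of SVD.

## Differentiation and mandibular validation

Denisovan–Neanderthal differentiation re-scores subjects on the six
predictions derived on either of those lineages (parietal breadth,
maxilloalveolar length, facial breadth, facial protrusion, glenoid fossa
size, malar flattening), optionally adding M2 molar crown area — computed
as the standard odontometric rectangle product, mesiodistal length ×
buccolingual width — as a seventh, and places the subject's combined score
within the leave-one-out Neanderthal score distribution using the same
empirical-CDF machinery (restricted to Neanderthals with at least five
testable differentiation predictions). The percentile is exactly invariant
under increasing affine transforms of all scores and invariant at support
points under general monotone transforms; between support points linear
interpolation is deliberately scale-dependent.

Mandibular validation evaluates the packaged table of published Xiahe 1 /
Penghu 1 checks: six predictions over five measurements, with the
comparator type (median or mean) stored per row because the sources mix
both, and figure-based comparisons stored as reported qualitative relations.
Condylar head area is approximated as an ellipse,
$\pi/4 \times \mathrm{ML} \times \mathrm{AP}$. The packaged table yields
4/4 confirmed for Xiahe 1 and 5/6 for Penghu 1 (90% jointly; 89% when
pooled with the Harbin cranium's 16/18).

## Problem sizes used by the test-suite

The statistical properties are exercised at sizes chosen to give stable
verdicts at interactive cost: quantile oracles on 200 random reference sets;
enumeration oracles up to $k = 12$ (binomial) and $k = 10$ (signed-rank);
constraint conservation over 10,000 permutations; null calibration on 200
synthetic subjects at 500 permutations each (Kolmogorov–Smirnov against
uniform); planted-subject recovery over 10 seeds at 1000 permutations.

## Known limitations

* The generator's covariance is a low-rank factor model, not an
  anatomically estimated covariance; passing tests demonstrate correctness
  of the machinery under the stated model, not performance on real crania.
* Group separation in the generator is size- and factor-mediated; the
  empirical observation that Neanderthal reference specimens score somewhat
  higher than AMHs against the profile is only weakly reproduced.
* Reproducing the published per-specimen results (adjusted permutation
  p-values, Neanderthal percentiles, PCA coordinates of named specimens)
  requires the original specimen database, which is an optional input, not
  a packaged one.
* No growth/ontogeny or geometric-morphometric (landmark) support.
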