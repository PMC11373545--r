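---
title: "From a serum protein screen to causal inference: the protmr methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a serum protein screen to causal inference: the protmr methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protmr)
options(protmr.verbose = FALSE)
```

protmr implements a complete analysis path from a two-group serum
protein-array experiment to causal effect estimates on a binary disease
outcome: a differential-expression screen proposes candidate proteins,
protein quantitative trait loci (pQTLs) supply genetic instruments, a
two-sample Mendelian randomization (MR) suite estimates each protein's
causal effect with sensitivity analyses, network MR decomposes a detected
effect through metabolic mediators, and an analytic power calculation
quantifies what the design could detect. A synthetic-data module generates
every input with known ground truth, so the whole pipeline is testable
without access to individual-level data.

## Differential-expression screen

Intensities are log2-transformed and the fold change for protein $g$ is
the difference of group means on that scale,
$\mathrm{log2FC}_g = \overline{\log_2 x}_{g,\mathrm{case}} -
\overline{\log_2 x}_{g,\mathrm{control}}$, i.e. the log2 ratio of
geometric means. An arithmetic-mean-ratio variant is available via
`log2_fold_change(method = "mean_ratio")` for users whose upstream
software reports that form. A protein is called differentially expressed
when $p < 0.05$ and $|\mathrm{log2FC}| > 0.263$; the fold-change cut
corresponds to a 1.2-fold change ($2^{0.263} \approx 1.20$). Note the
deliberate choice that classification uses the raw p-value — the
conventional array screen rule — while Benjamini–Hochberg q-values are
reported alongside. A consequence worth knowing: with ~5% of null
proteins clearing both raw-p and fold-change cuts by chance, the raw-p
DEP list does not control the false discovery rate; the q-value column
does.

Two tests are provided. `"welch"` is the unequal-variance t-test.
`"moderated"` is an empirical-Bayes test in the spirit of array DE
tools: the pooled per-protein variance $s_g^2$ (on $d = n_1+n_2-2$
degrees of freedom) is shrunk toward a common prior $s_0^2$ with weight
$d_0/(d_0+d)$, and the moderated t is referred to $d + d_0$ degrees of
freedom. The prior parameters are fit by method of moments on
$\log s_g^2$: $\operatorname{trigamma}(d_0/2)$ is matched to the excess
of $\operatorname{var}(\log s_g^2)$ over
$\operatorname{trigamma}(d/2)$, inverting trigamma by Newton iteration.
When the observed spread of log variances is no larger than expected
from sampling alone, $d_0 = \infty$ and all proteins share the prior
variance. The test suite cross-checks this fit against an independent
empirical-Bayes implementation on simulated matrices.

Chip background adjustment and inter-chip normalization are assumed done
upstream by the array vendor's software; a per-sample median-centering
utility (`median_center()`) is provided but off by default.

## Instrument selection and harmonization

Candidate instruments for a protein are its pQTLs passing three filters,
applied in order (each variant is labelled with the first failing
criterion): exposure significance ($p <$ a Bonferroni threshold that
defaults to $0.05/54{,}469/4{,}782 \approx 1.9\times10^{-10}$, the
correction for an exome-array pQTL discovery panel of 54,469 variants by
4,782 proteins — configurable), instrument strength
($F = (\hat\beta/\mathrm{se})^2 > 10$), and minor allele frequency
($\min(\mathrm{EAF}, 1-\mathrm{EAF}) > 0.001$).

LD pruning is greedy clumping against a local r² matrix: variants are
ranked by descending F (ties by id, making the result independent of
input order) and accepted unless r² exceeds 0.2 with an already-accepted
variant on the same chromosome within 500 kb. A missing r² entry for a
required pair is a hard error rather than a silent pass. Instruments
absent from the outcome GWAS can be replaced by the most-correlated
outcome-present proxy with $r^2 \ge 0.8$ (ties broken by position, then
id). Because an r² matrix carries no allele-sign information, the
proxy's outcome estimate is oriented by matching effect-allele
frequencies — a documented approximation that degrades for variants near
EAF 0.5.

Harmonization joins exposure and outcome estimates per variant on the
exposure's effect-allele orientation: records with swapped alleles have
the outcome beta negated and EAF reflected. Palindromic (A/T, C/G)
variants cannot be resolved from alleles alone; the default policy drops
them when either EAF is missing or falls in (0.42, 0.58) and otherwise
infers orientation from frequency agreement. The window is a common
harmonization default; the width trades discarded variants against
strand-flip mistakes, and both the policy and window are configurable.

## The MR estimator suite

With harmonized per-variant estimates
$(\hat\beta_{Xj}, \hat\beta_{Yj})$ and Wald ratios
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$:

* **Wald ratio** (single instrument): first-order delta SE
  $\mathrm{se}(\hat\theta) = \mathrm{se}_{Yj}/|\hat\beta_{Xj}|$, with a
  second-order option adding the exposure-noise term. The first-order
  form is the default in standard implementations and ignores exposure
  noise, which is negligible for $F \gg 10$.
* **IVW**: precision-weighted mean of ratios with
  $w_j = \hat\beta_{Xj}^2/\mathrm{se}_{Yj}^2$, identical to the
  zero-intercept weighted least-squares slope of outcome on exposure
  effects. Fixed-effect SE $(\sum w_j)^{-1/2}$; the random-effects model
  is multiplicative, inflating the SE by $\max(1, \sqrt{Q/(J-1)})$
  rather than adding a $\tau^2$ — the simplest model consistent with
  switching to random effects under heterogeneity. The default `"auto"`
  model uses random effects when Cochran's Q has $p \le 0.05$.
* **MR-Egger**: weighted regression with intercept after orienting all
  variants exposure-positive; the intercept estimates directional
  pleiotropy under the InSIDE assumption. SEs are inflated by
  $\max(1, \sqrt{Q_e/(J-2)})$ and p-values use $t_{J-2}$, the small-J
  regression convention; IVW keeps normal p-values.
* **Weighted median**: the ratio at probability 1/2 of the
  inverse-variance-weighted empirical distribution (cumulative midpoint
  weights, linear interpolation); consistent when valid instruments
  carry at least half the weight.
* **Weighted mode**: argmax of a weighted normal-kernel density of the
  ratios with bandwidth $0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)
  J^{-1/5}$ (a modified Silverman rule; the multiplier is configurable
  since published analyses rarely state theirs), evaluated on a
  512-point grid spanning the ratios ± 3 bandwidths.

Median and mode SEs come from a seeded parametric bootstrap (default
1000 replicates) that perturbs both summary statistics by their SEs.
Bootstrap-replicate modes are evaluated on a 128-point grid — one
quarter of the point-estimate resolution, which resolves a standard
error comfortably at a quarter of the cost. `estimate_all()` runs every
method applicable to the instrument count (Wald at $J = 1$, IVW at
$J \ge 2$, the rest at $J \ge 3$), splitting bootstrap seeds
deterministically from one root seed via an integer-hash derivation
(linearly related derived seeds are a known hazard for RNG
initialization, so the derivation is a multiply-xor hash rather than a
linear map).

## Sensitivity suite

Leave-one-out re-estimates IVW with each variant removed. The
residual-sum-of-squares outlier test simulates the no-pleiotropy model:
each variant's expected outcome effect is
$\hat\theta_{(-j)}\hat\beta_{Xj}$ with $\hat\theta_{(-j)}$ the IVW slope
excluding it, the observed weighted RSS is referred to its simulated
null distribution (global test), per-variant residuals give
Bonferroni-adjusted outlier p-values, an outlier-corrected IVW is
reported, and an optional distortion test compares the corrected-minus-
original shift against random removals of the same number of variants.
Empirical p-values use the $(1+k)/(n+1)$ correction, so they can never
be zero and are bounded below by $1/(n_\mathrm{sim}+1)$. This mirrors
the published MR-PRESSO construction at summary scale; exact replication
of that implementation's internal constants is not claimed. The funnel
table pairs each ratio with its precision, and the pleiotropy report
re-exports the Egger intercept.

## Network MR and mediation

Candidate mediators are screened in two steps, each leg estimated by
IVW (auto model): exposure→mediator using the protein's instruments, and
mediator→outcome using the mediator's own instruments (selected at a
genome-wide threshold, default $5\times10^{-8}$). A mediator passes when
both leg p-values fall below the screening alpha (0.05). The
decomposition is product-of-coefficients on the log-odds scale:
indirect $= \beta_{EM}\beta_{MO}$ with delta SE
$\sqrt{\beta_{EM}^2\mathrm{se}_{MO}^2 + \beta_{MO}^2\mathrm{se}_{EM}^2}$,
and the proportion mediated is the indirect effect over the directly
estimated total effect (not a direct+indirect reconstruction), with a
first-order delta SE treating legs and total as independent — an
assumption appropriate when the underlying GWAS samples do not overlap,
and stated as such. ORs are exponentiated for reporting only; all
arithmetic stays on the log scale.

## Analytic power

For a binary outcome the causal OR per exposure SD is attenuated to the
observed linear-probability scale,
$b = K\left(\frac{\mathrm{OR}}{1+K(\mathrm{OR}-1)} - 1\right)$ with $K$
the case fraction; with outcome variance $v = K(1-K) - b^2$ the
non-centrality parameter is
$\mathrm{NCP} = nR^2b^2/(v(1-R^2))$ and power is
$\Phi(-z_{1-\alpha/2}+\sqrt{\mathrm{NCP}}) +
\Phi(-z_{1-\alpha/2}-\sqrt{\mathrm{NCP}})$. At $\mathrm{OR} = 1$ this
returns exactly $\alpha$. Binary-outcome variance conventions differ
between published calculators, so the test suite validates this variant
against an individual-level logistic simulation (n = 20,000, 2000
replicates, score test), requiring agreement within ±0.05.

```{r}
mr_power_binary(n_total = 184305, case_fraction = 0.33,
                or_per_sd = 1.11, rsq_xz = 0.11, alpha = 0.05)
```

## The synthetic-data model

`simulate_mr_dataset()` draws true instrument effects
$\gamma_j \sim N(0, \sigma_\gamma^2)$ truncated to
$|\gamma_j| \ge 0.5\sigma_\gamma$ (the bound is a design choice: it
keeps every simulated instrument relevant without making them
unrealistically uniform), observed effects
$\hat\beta_{Xj} \sim N(\gamma_j, \mathrm{se}_X^2)$, pleiotropic paths
$\alpha_j$ that are zero with probability $1-\pi$ and
$N(\mu_\alpha, \sigma_\alpha^2)$ otherwise, and
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \mathrm{se}_Y^2)$.
Alleles are drawn non-palindromic, EAF uniform on (0.05, 0.5), and
variants are spaced 1 Mb apart across chromosomes, so simulated
instruments are unlinked (LD pruning is exercised on hand-built LD
matrices instead). With `orient_gamma = TRUE` effect alleles are coded
exposure-increasing, the convention under which directional pleiotropy
is directional and the Egger intercept identifies $\mu_\alpha$.
`simulate_mediation_trio()` builds three independent leg datasets whose
total effect is $\theta_{dir} + \theta_{EM}\theta_{MO}$, so the true
proportion mediated is known exactly.

`simulate_protein_matrix()` emulates the protein-array experiment: 640
proteins by 33 cases and 31 controls by default, log2-scale baselines
uniform on (8, 14), within-group noise SD 0.5 (typical of normalized
cytokine arrays), and case means shifted by assigned log2 fold changes
for spiked proteins.

`simulate_study_bundle()` writes the complete file set `run_pipeline()`
consumes. Its defaults define a study-sized recovery experiment: 30
spiked proteins at |log2FC| = 1 among 640, one of which carries a causal
effect $\theta = 0.3$ on the outcome, five instruments per protein with
$\sigma_\gamma = 0.3$, $\mathrm{se}_X = 0.01$ (F-statistics in the
hundreds, within the range seen for strong pQTLs) and
$\mathrm{se}_Y = 0.03$ (the scale of a large case-control GWAS). Under
these conditions the causal protein is detected essentially always;
whether it is the *unique* FDR hit is governed by Benjamini–Hochberg
itself — with one overwhelming true positive among $m$ tests, the chance
that at least one null protein also clears FDR 0.05 is
$\approx 1-(1-2\cdot 0.05/m)^{m-1} \approx 9\text{–}10\%$ regardless of
$m$. That is a property of FDR control at 0.05, not of this
implementation; runs of the bundled recovery experiment should be read
with that base rate in mind.

What the generators do not emulate: LD between instruments of one
protein, sample overlap between exposure and outcome GWAS, winner's
curse in instrument selection, non-normal intensity noise, and
between-protein correlation on the array. Passing recovery tests
therefore demonstrate correctness of the estimators under the stated
structural model, not robustness to those real-data complications.

## Pipeline and reproducibility

`run_pipeline()` executes: DE screen → per-DEP instrument selection,
pruning, proxying and harmonization → `estimate_all()` per protein →
BH correction across the proteins actually tested by MR (not across the
whole array — multiplicity is paid where inference happens) →
sensitivity suite for FDR-significant proteins (all proteins via
`sensitivity_all`) → mediation for configured mediator traits → power
report. Every stage writes TSV; the manifest records the config hash,
seed, package version and per-stage counts. DEPs without an exposure
summary file are reported as skipped, mirroring the common situation
that only a subset of screened proteins have usable pQTLs. Identical
config and seed give byte-identical outputs; all randomness (bootstrap
SEs, outlier simulations) derives from the single config seed through
the hash-based splitter.

Numerical choices collected in one place: CI multiplier
$z_{0.975} = \Phi^{-1}(0.975)$; reported p-values floored at the
smallest positive double; volcano $-\log_{10}p$ clamped at $10^{-300}$
with a flag; Egger refuses exactly collinear exposure effects; the
weighted mode returns the common ratio (logged) when all ratios
coincide; BH q-values come from `stats::p.adjust`. Problem sizes used by
the test suite — 2000 null replicates for type-I calibration, 200
replicates for CI coverage and mediation recovery, 100 seeds for
outlier detection, 50 end-to-end bundle runs — were chosen to put
Monte-Carlo error well inside the tested margins.

## Known limitations

Proxy orientation by EAF matching can mis-sign near-0.5-EAF variants;
multivariable MR, Steiger filtering and radial-MR outlier frameworks are
out of scope; the mediation SE ignores leg covariance (valid for
non-overlapping samples); the moderated test emulates the standard
empirical-Bayes construction but is not a drop-in reimplementation of
any specific tool; and the power formula's variance convention, while
simulation-validated at the tested operating points, is one of several
in circulation.
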