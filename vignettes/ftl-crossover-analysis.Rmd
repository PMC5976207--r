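---
title: "Models and methods behind ftlmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ftlmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftlmap)
```

# Scope

`ftlmap` analyses meiotic crossovers scored as fluorescent pollen tetrads
and the cytological and qPCR measurements that usually accompany such
experiments. It deliberately starts *after* image analysis: inputs are
scored grain phenotypes (or PD/T/NPD tallies), per-cell focus counts, and
CT values. This vignette explains the statistical models, the simulator
that stands in for real data in all tests, the parameters that matter, and
the numerical and design choices a careful user should know about.

# The two-pathway crossover model

Crossovers in Arabidopsis form through two pathways: a major interfering
pathway (Type I, ZMM/MSH4-dependent, marked cytologically by MLH1 foci)
and a minor non-interfering pathway (Type II, MUS81-dependent). The
simulator models chiasmata on the bivalent as the superposition of two
point processes on the genetic scale:

* **Type I** — a *stationary gamma-renewal* process: inter-event distances
  are Gamma(shape $\nu$, rate $\nu\lambda_1$), so the mean spacing is
  $1/\lambda_1$ and the spacing coefficient of variation is $1/\sqrt\nu$.
  $\nu = 1$ is an exact Poisson process (no interference); larger $\nu$
  spaces events more evenly, which is precisely positive crossover
  interference. The first event is drawn from the equilibrium
  (length-biased) forward-recurrence distribution, which makes counts on
  any window exactly stationary — without this, short intervals would be
  systematically depleted at $\nu > 1$.
* **Type II** — a homogeneous Poisson process, interference-free by
  construction.

**Calibration.** Intensities are set so that the expected chiasma count on
a region of genetic length $X$ cM is $X/50$ at baseline: each chiasma
recombines two of the four chromatids, so a spore is recombinant with
probability $1/2$ per chiasma and the single-spore recombination fraction
matches $X/100$ for small $X$. Configured marker positions are therefore
recovered by tetrad analysis, which every parameter-recovery test relies
on. At baseline the Type I and Type II pathways carry 85% and 15% of the
intensity (`type1_weight`, `type2_weight`), the canonical split for
Arabidopsis.

**Tetrad resolution.** Chiasmata are resolved on the standard
four-chromatid bivalent. One subtlety matters: at each chiasma the two
participating strands are one of the two strands carrying each *parental
origin at that position*, chosen uniformly (no chromatid interference) —
i.e. non-sister strands at the chiasma. Choosing strands by centromere
identity instead looks equivalent but is wrong: after an earlier crossover
it allows "exchanges" between strands that are identical distally, which
silently cancels crossovers and induces a spurious negative association
between adjacent intervals (we measured an apparent interference ratio of
about 1.6 in a $\nu = 1$ simulation before fixing this). Under the correct
rule, $\nu = 1$ gives class independence across intervals and $R \approx 1$,
and two chiasmata between a marker pair give the textbook PD:T:NPD = 1:2:1.

**Scenario switches.** Temperature acts purely as a multiplier on the
Type I intensity (`type1_rate_factor`); the package's default elevated-
temperature scenario uses 1.22, the ratio of MLH1 focus means observed
between 28 °C and 20 °C. Mutants are switches: `type1_active = FALSE`
(*msh4*), `type2_active = FALSE` (*mus81*), `type2_scale > 1` (*fancm*-like
Type II gain), `spo11 = TRUE` (DSB mean scaled by `dsb_scale_spo11`, default
0.1). Because the model is linear in the intensities, temperature and
Type II perturbations combine additively in the recovered distances. DSB
formation is homeostatic by construction: `dsb_mean` (default 200 per
meiocyte) never depends on `type1_rate_factor`.

**Focus counts.** γH2AX and RAD51 counts are Poisson around the DSB mean
(RAD51 with detection efficiency 0.9, which reproduces the relative means
of the two antibodies); MLH1 counts are the number of Type I events of the
renewal process over a whole-genome map of `genome_length_cM` (default
540 cM) plus a Poisson(0.5) background of off-pathway foci. The background
avoids a degenerate zero-variance distribution in pathway-null scenarios;
540 cM × 85% + 0.5 puts the baseline MLH1 mean at ≈ 9.7 and the total CO
count near 10–11, matching the study conditions the generator emulates.

**What the simulator does not emulate.** Real tetrad data contain
transgene silencing and aborted grains (the `OTHER` class), day-to-day
scoring batches, plant-to-plant variation, and possibly position-dependent
interference; the generator produces none of these (its `OTHER` count is
always zero). Passing tests therefore demonstrate correctness of the
estimators and calibration of the tests *under the assumed model*, not
robustness to every artefact of microscopy data. The `OTHER`-handling code
paths are exercised with hand-built tetrads instead.

# Linkage statistics

The Perkins estimator
$$X = 100\,\frac{T/2 + 3\,\mathrm{NPD}}{n}, \qquad n = \mathrm{PD} + T + \mathrm{NPD}$$
is implemented in exact arithmetic up to the final division. Its standard
error is the multinomial delta-method SE, equivalently the population SD
of the per-tetrad score $s \in \{0, \tfrac12, 3\}$ over $\sqrt n$:
$$\mathrm{SE} = 100\sqrt{\frac{E[s^2] - E[s]^2}{n}}.$$
The tool traditionally used for these SEs does not publish its formula, so
the delta-method choice is guarded by a test against a 100,000-replicate
parametric bootstrap (agreement within 2%). `OTHER` tetrads (patterns
impossible for a coupling heterozygote, e.g. 3:1 channel segregation) are
tallied but excluded from $n$, because the estimator's sampling theory
needs a clean PD/T/NPD multinomial.

Two-condition comparison: the primary test is the normal
$Z = (X_A - X_B)/\sqrt{SE_A^2 + SE_B^2}$ with a two-sided p-value; a
chi-square homogeneity test on the (PD, T, NPD) table is reported alongside
because published analyses are often ambiguous about which convention was
used. Under null simulations the Z-test's p-values are uniform and its
size is nominal (checked by KS test and rejection-rate bounds).

# Interference

With three linked markers, tetrads are partitioned by crossover status in
the conditioning interval; the test-interval distance among tetrads
*without* an adjacent CO ($X_{wo}$) over that among tetrads *with* one
($X_{wi}$) is the interference ratio $R = X_{wo}/X_{wi}$, oriented so that
positive interference gives $R > 1$. Choices made here:

* **NPD tetrads count as "CO present"** in the conditioning interval: an
  NPD requires two crossovers, so excluding it would misclassify the
  strongest evidence of a crossover. (Published descriptions often do not
  state their rule; this is ours.)
* **Ratio variance** uses first-order propagation with zero covariance —
  the two partitions are disjoint sets of tetrads:
  $\mathrm{Var}(R) = R^2(\mathrm{Var}(X_{wo})/X_{wo}^2 +
  \mathrm{Var}(X_{wi})/X_{wi}^2)$, computed internally in the
  algebraically equivalent form $(\mathrm{Var}(X_{wo}) +
  R^2\mathrm{Var}(X_{wi}))/X_{wi}^2$, which stays finite when $X_{wo} = 0$.
  The variance inputs are the squared delta-method SEs, keeping one error
  model end-to-end. A Monte-Carlo test (100,000 multinomial resamples at
  $n = 1000$ per partition) confirms the formula within 5%.
* **Comparison between conditions** uses
  $Z = |R_1 - R_2|/\sqrt{\mathrm{Var}R_1 + \mathrm{Var}R_2}$ with a
  two-sided normal p-value. Sidedness is not universally stated in the
  literature; two-sided is the conservative default.
* $X_{wi} = 0$ raises an informative error rather than propagating NaN:
  an undefined ratio is a property of the dataset (too few conditioned
  tetrads), and the remedy is more data, not a number.

The delta-method Z-test is asymptotic; its null calibration is verified at
1,500 tetrads per condition (rejection rate within 0.03–0.07 at
$\alpha = 0.05$ over 1,000 replicate experiments). Below a few hundred
tetrads per *partition* the normal approximation for a ratio should not be
trusted.

# Group statistics and qPCR

Focus counts and pollen-viability counts share one statistical shape and
go through the same path: group means via `summarize_foci()` and Welch's
unequal-variance t-test (`stats::t.test`) with Welch–Satterthwaite degrees
of freedom. The comparative-CT analysis averages technical replicates to
one CT per sample × gene *before* subtraction (standard practice, rarely
stated), takes ΔCT = CT(target) − CT(control) per biological sample,
ΔΔCT against the reference treatment's mean, and fold change $2^{-\Delta\Delta CT}$
(reference exactly 1). Treatment differences are tested by one-way ANOVA on
ΔCT followed by Tukey's HSD (`stats::aov` + `stats::TukeyHSD`). A perfectly
constant ΔCT vector makes the ANOVA degenerate; `anova_tukey()` refuses it
with an explicit error, while `ddct_fold_change()` still reports the fold
changes (a gene normalised against itself is the canonical harmless case).

The qPCR generator separates a per-sample offset (template amount; shifts
all genes equally and must cancel in ΔCT — a property the tests assert) from
gene-level biological noise (SD 0.25 cycles) and technical noise (SD 0.15
cycles), values typical of SYBR-green instruments. Default treatment
effects emulate a NaCl-dose marker-gene experiment (fold changes 1.2/1.6 at
100 mM and 8.2/10.5 at 200 mM for the two targets, control gene flat), with
3 biological × 3 technical replicates as is conventional.

Significance labels printed by the package mirror the figure-legend
convention of the source experiments *as printed*, including its quirk:
`ns` is attached only for p > 0.5, so p-values between 0.05 and 0.5 get no
label.

# Numerical choices

* **Equilibrium renewal start.** The forward-recurrence CDF has the closed
  form $F_e(x) = F_{\nu+1}(x) + (\beta x/\nu)S_\nu(x)$ (with $F_k$/$S_k$
  the Gamma CDF/survival at shape $k$ and rate $\beta$); it is inverted by
  monotone bisection (80 iterations, vectorised over draws) bracketed by
  Gamma($\nu+1$) quantiles, since $F_e \ge F_{\nu+1}$. At $\nu = 1$ the
  equilibrium distribution is the exponential itself and is sampled
  directly.
* **Bulk tetrad resolution** groups meioses by chiasma count and applies
  the strand-exchange sweep with matrix indexing, so datasets of $10^5$
  meioses resolve in well under a second; the scalar `resolve_tetrad()`
  implements the identical model and serves as the readable reference.
* **Seeding.** `sim_config(seed = )` makes every generator reproducible;
  identical configuration and seed give bit-identical datasets (asserted
  in tests). Derived seeds used by scripts stay well below $2^{31}$.
* **Degenerate inputs.** $n = 0$ count records, empty groups, zero-variance
  Welch inputs, missing control-gene wells, and two-marker maps passed to
  the interference stage all raise informative errors at the boundary
  rather than NaNs downstream.

# Problem sizes used by the test-suite and acceptance script

Simulation sizes are chosen so each check has comfortable power while the
whole suite stays quick to run: 10,000 tetrads for parameter recovery,
1,000 replicate experiments of 2 × 1,500 tetrads for null calibration, 200
replicates of 5,000 tetrads for the interference-direction check, 3,000 –
10,000 cells for focus-count distributional checks, and the study's own
group sizes (n = 57/41 cells, 22/28 anthers, 3 biological replicates) where
the point is to reproduce its summary statistics under realistic sampling
noise.

# Known limitations

* The interference model is phenomenological (gamma renewal on the genetic
  scale); it does not model the physical chromosome, obligate-CO enforcement
  is only available as a resampling flag on the simulated segment, and the
  two pathways are assumed independent.
* The delta-method SEs and Z-tests are asymptotic; small partitions (tens
  of tetrads) need exact or bootstrap methods the package does not provide.
* Temperature and mutant effects are scenario labels with intensity
  multipliers, not mechanistic models; nothing is implied about *why* the
  Type I intensity changes.
* Readers accept delimited text only; spreadsheet files should be exported
  to CSV/TSV first.
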