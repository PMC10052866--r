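---
title: "Anticipating abrupt shifts in microbiome time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anticipating abrupt shifts in microbiome time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbshift)
```

mbshift analyses replicated, densely sampled (near-daily) microbial
community time series with two goals: *describing* abrupt compositional
shifts, and *anticipating* them with per-day warning indices. This vignette
is the package's own account of the models it implements, the parameters
that matter, the synthetic data it validates against, and the numerical
decisions taken where the design was genuinely open.

## 1. From reads to absolute abundance

Population-level analysis (embedding, Jacobians) needs *absolute* abundance:
relative abundances confound a taxon's increase with its neighbors'
decline. The package assumes quantitative amplicon sequencing with internal
spike-in standards — artificial 16S sequences added to each PCR at known
copy concentrations.

`fit_standard_curve()` regresses spike reads on spike concentration by least
squares **through the origin**: zero copies must imply zero expected reads,
and an intercept would let PCR-inhibitor effects masquerade as baseline
signal. The literature is not uniform on intercept handling, so this is a
deliberate, documented convention (an intercept-free fit also makes the
calibration a single scale factor, `reads / slope`). The per-sample Pearson
correlation between spike reads and concentrations doubles as a calibration
quality score; the correlation of a constant vector is defined as 0 rather
than NaN so that a flat (failed) spike gradient is dropped instead of
propagating missing values.

Quality filters use strict inequalities: samples with r < 0.7 or total
taxon reads < 350 are removed, and boundary samples (exactly 0.7, exactly
350) are kept. Missing days are filled so embeddings stay contiguous:
single interior gaps by the mean of flanking days, runs of missing days by
linear interpolation between the flanks, and series ends by copying the
nearest observation (`zoo::na.approx(rule = 2)` semantics). Interpolated
points are flagged and observed values are never altered. Taxa are retained
when present in at least 5 samples of *some* replicate — the rule is per
replicate, not pooled, so a taxon consistently rare everywhere does not
slip through on its total.

## 2. Abruptness

For a replicate community, day *t* and horizon *p* (days),

$$\mathrm{abruptness}(t, p) = \mathrm{BC}\!\left(\bar{x}_{[t-4,\,t]},\;
\bar{x}_{[t+p,\,t+p+4]}\right)$$

where BC is Bray-Curtis dissimilarity and the bars are means of *relative*
compositions over 5-day windows. Averaging suppresses day-to-day noise so
only sustained turnover scores highly; a value above 0.5 (strictly) flags
replacement of more than half the community and defines the positive event
label used by all diagnostics. Windows must fit entirely inside the series
— a day for which either window is incomplete is invalid, never silently
shortened.

Two conventions were open and are configurable: window means are computed
on relative (not raw) compositions, because abruptness is a statement about
compositional turnover, not biomass; and Shannon diversity uses natural
logarithms (the base is rarely stated in the field; nats keep entropy
comparable with the stable-state entropy below).

## 3. Pairwise maximum-entropy energy landscapes

Presence/absence community states $\sigma \in \{0,1\}^S$ are modeled by the
least-structured distribution matching the observed occurrence and
co-occurrence frequencies:

$$H(\sigma) = -\sum_i h_i \sigma_i - \sum_i \sum_{j>i} J_{ij}\sigma_i\sigma_j,
\qquad p(\sigma) = e^{-H(\sigma)}/Z .$$

$h_i$ absorbs net abiotic suitability for taxon *i*; $J_{ij}$ is the
pairwise association. Fitting iterates
$h_i \leftarrow h_i + \alpha \log(\langle\sigma_i\rangle /
\langle\sigma_i\rangle^*)$ (and likewise for pairs) with model moments
$\langle\cdot\rangle^*$ from exact enumeration of all $2^S$ states;
$\alpha = 0.1$, at most 50,000 iterations, stopping early when the largest
absolute log moment ratio falls below `tol = 1e-4` (the explicit tolerance
makes "converged" a checkable property; the diagnostics record iterations
and residual). Model moments are probability-weighted sums
$\sum_k \sigma_i^{(k)} p(\sigma^{(k)})$ — the normalization lives entirely
in $p$. Empirical moments are regularized as $(\mathrm{count} + 0.5)/(n+1)$:
a pair that never co-occurs would otherwise send its log-ratio update to
$-\infty$. The fit is initialized at the independent-taxon solution
($h_i = \mathrm{logit}\,\langle\sigma_i\rangle$, $J = 0$), which shortens
convergence without changing the fixed point.

Binarization targets taxa observed in 2–98% of samples (inclusive bounds):
taxa essentially always or almost never present carry no landscape
information. Presence means abundance strictly above `presence_threshold`
(default 0); a zero in calibrated data means *not detected*, not
necessarily absent, and the threshold is exposed for sensitivity analysis.

On the assembly graph (states adjacent iff they differ in exactly one
taxon), **stable states** are strict minima — energy lower than all $S$
neighbors; exact ties make a state non-minimal, so a perfectly flat
landscape has none. **Basins** come from steepest descent: always move to
the lowest-energy neighbor while it is strictly lower, ties among equally
lowest neighbors broken toward the lowest flipped taxon index
(deterministic, so basins are a partition). Exact enumeration is capped at
S = 20 ($2^{20} \approx 10^6$ states); larger communities must be reduced
first (the pipeline keeps the top-prevalence taxa, capped at 14, for speed).

Two per-day warning indices follow. The **energy gap**
$H(\sigma_t) - H(\mathrm{basin\ bottom}(\sigma_t)) \ge 0$ measures how far
the community is inflated above its local optimum. The **stable-state
entropy** runs `n_walks` stochastic walks from $\sigma_t$ — each step
proposes a uniformly random single-taxon flip, accepted with Metropolis
probability $\min(1, e^{-\Delta H})$; a walk stops at a strict minimum or
after `max_steps` (then mapped down by steepest descent) — and reports the
Shannon entropy (nats) of the destination distribution: 0 when the outcome
is certain, up to $\log(\#\text{minima})$ on a ridge. The walk protocol
(Metropolis acceptance, minimum-terminated, 1000 walks, 1000-step cap) is
the package's own specification of a procedure the source literature leaves
to its references, and all of it is configurable. For warning signals the
landscape for a target replicate is always fit on the *other* replicates of
the same treatment, mirroring the forecasting design below.

## 4. Empirical dynamic modeling

Per-taxon, per-replicate series are z-standardized (constant series are
flagged and excluded rather than turned into NaNs) and embedded with delay
coordinates $z(t) = (x(t), x(t-1), \dots, x(t-E+1))$, $\tau = 1$. Embedding
vectors never span replicate boundaries. E is chosen in 1–20 by minimizing
RMSE of pre-run 1-step forecasts; near-ties (within floating-point noise)
break toward the smallest E, and the same rule breaks θ ties toward 0
(linearity) — on exactly linear data all θ values tie and 0 must win.

**Simplex projection** predicts a target point's *p*-step future as the
weighted mean of the futures of its E+1 nearest reference neighbors, with
weights $e^{-d_i/d_{\min}}$. When the target coincides with reference
points ($d_{\min} = 0$) the zero-distance neighbors share uniform weight —
the limiting behavior of the kernel.

**S-map** uses all reference points, weighted by
$w(d) = e^{-\theta d / \bar d}$ with $\bar d$ the mean distance to the
target; the weighted linear system (with a constant column) is solved by
SVD with singular values below $10^{-10}$ of the largest zeroed, giving the
minimum-norm solution for collinear designs. At θ = 0 every weight is 1
and the S-map *is* one global linear regression — a property the tests
exploit as an oracle. θ is tuned over {0, 0.001, 0.01, 0.05, 0.1, 0.2,
0.5, 1, 2, 4, 8}; the fraction of (taxon, replicate) series with θ* > 0
summarizes how prevalent nonlinear (state-dependent) dynamics are.

Forecasting is leave-one-replicate-out: the reference database for a
target replicate contains only the other replicates, so skill measures
generalization across communities, not memorization. A persistence null
model (predict no change) provides the skill baseline. Skill is
$R^2 = 1 - SS_{res}/SS_{tot}$ — a true coefficient of determination that
can go negative, chosen over squared correlation because a forecast that
is well-correlated but biased should not score highly. Forecasts are made
on the standardized scale and de-standardized for reporting; community
assembly floors negative de-standardized predictions at 0 before
renormalizing to compositions (the model knows nothing about
nonnegativity), and the community-level error is Bray-Curtis between
predicted and observed compositions.

**Jacobians.** For a chosen taxon set (default: top `m = 8` by mean
relative abundance — the selection rule is not standardized in the
literature, so it is explicit and configurable, optionally intersected
with CCM-screened interactions), a multivariate S-map regresses each
$x_i(t+1)$ on the full state $(x_1(t), \dots, x_m(t))$ with weights
centered on the state at *t*; row *i* of $J(t)$ is the coefficient vector.
**Local Lyapunov stability** is the dominant eigenvalue modulus of $J(t)$
(< 1 converging, > 1 diverging — 1 is the theoretical tipping value);
**local structural stability** is the trace. The CCM screen accepts a
driver when cross-map skill rises with library size by ≥ 0.1 and ends
above 0.2 — conventional but ultimately arbitrary margins, exposed as
configuration. Jacobians are estimated on z-standardized coordinates;
eigenvalues are only approximately invariant to per-variable rescaling,
a documented caveat.

## 5. Diagnostics

Each index at day *t* is paired with abruptness(*t*, *p* = 7 by default).
Per-replicate OLS regressions of abruptness on index value are screened
with Benjamini-Hochberg FDR at 0.05 across the replicate × index grid
within a treatment (the multiple-testing procedure is stated here because
"FDR" alone underdetermines it); regressions are on raw values, not ranks.
ROC analysis predicts an event when index ≥ threshold — all four indices
signal instability when *high*. Candidate thresholds are midpoints between
adjacent distinct scores (plus sentinels beyond the extremes), so a
perfect classifier returns the midpoint of its separating gap; AUC is
trapezoidal and equals the Mann-Whitney statistic
$P(\text{score}^+ > \text{score}^-) + \tfrac12 P(\text{tie})$ exactly, a
property the tests verify by exhaustive pair comparison. The Youden
threshold maximizes sensitivity + specificity − 1, ties resolved toward
the lower (more sensitive) threshold. Thresholds can be computed per
treatment or after pooling treatments; ROC analysis refuses single-class
inputs (naming the class counts) rather than returning a vacuous curve.

## 6. What the simulator emulates — and what it does not

`simulate_glv()` advances $N_i$ by one Euler-Maruyama step of
$\dot N_i = N_i (r_i + \sum_j a_{ij} N_j)$ per day, applies multiplicative
lognormal noise (keeping abundances nonnegative), then multiplies by
$1 - \mathrm{dilution}$ (default 0.2, mirroring daily batch transfer of
one fifth of the culture). Abundances below $10^{-10}$ become exact zeros:
this avoids denormal drift and produces genuine absences for binarization.
`simulate_reads()` draws multinomial reads over taxa plus the five spike
standards, so detection noise near the read limit — central to
presence/absence flicker — is modeled.

The three frozen fixtures pin the dynamical regimes the analysis
distinguishes. `stable`: six weakly competing taxa relaxing to one
equilibrium. `chaotic4`: the classic four-species competitive
parameterization known to produce a chaotic attractor, time-rescaled by
0.8 so the daily Euler step stays bounded, started on-attractor (random
starts often fall into non-chaotic basins); positivity of its Lyapunov
exponent is verified by a two-trajectory divergence test, not assumed.
`bistable`: two guilds where a slow invader eventually excludes the
resident — shifts between two alternative community states whose timing
varies across replicates (roughly days 21–61 under the frozen seed), with
one resident taxon placed near the sequencing detection limit so that its
presence flickers increasingly as the invasion erodes the guild. That
detection-limit taxon is what gives the landscape indices their pre-shift
elevation at this scale; it emulates the common empirical situation where
rare community members blink out first.

What the simulator does **not** emulate: 16S copy-number variation across
taxa (copy concentration is the tracked quantity throughout), PCR
chimeras and primer bias, immigration (an extinct taxon never returns, so
noise-driven *back*-shifts cannot occur), environmental forcing (the
landscape is fixed by construction), and taxonomic structure. Passing
tests on these fixtures therefore demonstrate internal correctness and
the qualitative behavior of the indices — not field performance on real
microbiomes, where detection processes, copy-number variation and
environmental nonstationarity all intrude.

## 7. Numerical conventions and problem sizes

Degenerate inputs fail loudly and specifically: Bray-Curtis of two empty
communities, Shannon diversity of an all-zero sample, abruptness with
incomplete windows (naming the missing days), S-map with a degenerate
(zero-spread) reference, ROC with one class, random walks on a landscape
without minima, and gLV blow-ups (naming taxon and day). Determinism is a
contract: every stochastic operation takes an explicit seed, and the
pipeline writes byte-identical artifacts for a fixed configuration — a
property the test suite asserts.

The test suite runs everything at desk scale, sized so the full suite
completes in about a minute: landscape oracles at S ≤ 8 (100 random
models against exhaustive enumeration), parameter recovery at S = 6 with
20,000 exact samples, forecasting on 4 replicates × 60 days of the chaotic
fixture, Jacobian recovery on 500-step planar systems, and the full
pipeline on 3 replicates × 40 days. These sizes are choices, not limits:
the same code paths run the 8 × 110 fixtures (a full-pipeline run on one
takes on the order of minutes on a laptop).

## 8. Known limitations

- Exact enumeration bounds the landscape at 20 taxa; beyond that the
  pipeline pre-selects by prevalence, which discards rare-taxon structure.
- Steepest descent ignores "forbidden" transitions (extinction is
  irreversible in closed systems); the assembly graph treats 0→1 and 1→0
  flips symmetrically.
- The S-map Jacobian is a local linear summary; its eigenvalues inherit
  estimation noise that grows with taxon-set size m relative to series
  length.
- Warning-signal AUCs at desk scale are noisy; the package's guarantees
  are the exact machinery properties (oracle equivalences, threshold
  optimality) and directional behavior on the fixtures, not headline
  diagnostic performance, which requires experiment-scale data.
- No surrogate-based significance testing of warning indices is included.
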