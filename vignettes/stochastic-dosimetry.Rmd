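---
title: "Sparse polynomial chaos surrogates for magnetic-field orientation dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse polynomial chaos surrogates for magnetic-field orientation dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdosim)
```

## The model

`pcdosim` quantifies how the orientation of a uniform 50 Hz magnetic flux
density influences the induced electric field in fetal tissues.  The
random inputs are the two spherical angles of the field direction,
$\theta \sim U(0^\circ, 180^\circ)$ and $\varphi \sim U(-180^\circ,
180^\circ)$, assumed independent; the output is the tissue-wise
99th-percentile induced field $E_{99th}(\theta, \varphi)$, a smooth,
strictly positive scalar in the mV/m range at the 200 µT / 50 Hz
reference exposure.  The output is approximated by a polynomial chaos
expansion
$$ Y = \sum_{j} a_j\,\psi_j(\xi_1, \xi_2) + e, $$
where the $\psi_j$ are tensor products of *orthonormal* Legendre
polynomials $\sqrt{2n+1}\,P_n$ on the standardized angles
$\xi_1 = \theta/90 - 1$, $\xi_2 = \varphi/180$, truncated at total degree
$p$ (basis size $P = \binom{p+K}{K}$, $K = 2$).

Orthonormality is a deliberate choice: with it, the mean and variance of
the output are exactly $\mu = a_0$ and $\sigma^2 = \sum_{j \ge 1} a_j^2$,
so all moment-based exposure statistics follow from the coefficients with
no further sampling.  Basis terms are ordered graded-lexicographically
(constant first) so that serialized models and regression paths are
reproducible byte for byte.

### Axis convention

All modules share one convention, chosen here and stated wherever angles
appear, because it cannot be deduced from the exposure statistics alone:
$z$ is the vertical (head-to-toe) axis of the standing body, $x$ points
front-to-back, $y$ right-to-left, and the field direction is
$u(\theta,\varphi) = (\sin\theta\cos\varphi,\ \sin\theta\sin\varphi,\
\cos\theta)$.  Thus $\theta = 0$ is a top-to-bottom field,
$(90^\circ, 0^\circ)$ front-to-back, $(90^\circ, \pm 90^\circ)$ lateral.

## Fitting: hybrid LAR with leave-one-out selection

Given $N$ observations on a quasi-Monte-Carlo design (2-D Sobol sequence,
origin skipped, no scrambling — deterministic designs make every fit
bit-reproducible, and growing $N$ reuses the earlier points because the
sequence is nested):

1. Least-angle regression on the centered, unit-norm basis columns orders
   the non-constant terms by relevance.  LARS is used *only* for
   selection.
2. Every candidate along the path (intercept-only model included, so
   there are $m = \min(P, N-1)$ candidates) is refit by ordinary least
   squares on the original basis — the "hybrid" estimate whose
   coefficients are unbiased and feed the moment identities.
3. The candidate minimizing the leave-one-out error is selected.  For a
   linear least-squares fit the LOO error needs no refits:
   $$ \mathrm{err} = \frac{\sum_i \left((y_i - \hat y_i)/(1 - h_i)\right)^2}
                          {\sum_i (y_i - \bar y)^2}, $$
   with $h_i$ the hat-matrix diagonal.  The relative (variance-normalized)
   form makes the error scale-free.  Ties break toward the smaller model;
   candidates with leverage-one observations or rank-deficient active
   sets are skipped.  The corrected (finite-sample penalized) LOO variant
   is not applied; plain LOO suffices at the design sizes used here.
4. The selected surrogate is validated on $S = N/2$ *independent* random
   orientations through the percentage mean-square error
   $$ \mathrm{pMSE} = \frac{100}{S} \sum_{i=1}^S
      \left(\frac{Y_{val}^{(i)} - Y'^{(i)}}{Y_{val}^{(i)}}\right)^2 , $$
   and the whole procedure is repeated along ascending ladders of $N$ and
   $p$ until $\mathrm{pMSE} < \tau$.  Defaults: $N \in \{75, 150, 300\}$,
   $p \in \{5, 10, 15\}$, $\tau = 0.5\%$.  The grids are a choice — the
   convergence point for the reference whole-body case is $(N, p) =
   (300, 15)$ at much smaller pMSE, and easier tissues converge earlier
   on the same ladder.  For odd $N$ the validation size rounds.

Degenerate responses that are constant across the design (for instance a
perfectly spherical geometry) short-circuit to the intercept-only model
instead of tripping the undefined variance normalization.

## The virtual solver

The anatomical electromagnetic simulations that would normally supply the
observations are replaced by a physics-faithful closed form: the interior
eddy-current field of a homogeneous triaxial ellipsoid (semi-axes $a, b,
c$) in a uniform sinusoidal field.  For the $z$ component of
$\mathbf{B} = B_{rms} u$,
$$ \mathbf{E}^{(z)} = \frac{\omega B_z}{a^2 + b^2}\,(-a^2 y,\ b^2 x,\ 0),
   \qquad \omega = 2\pi f, $$
and cyclically for the $x$ and $y$ components; the superposition
satisfies $\nabla \times \mathbf{E} = -\partial \mathbf{B}/\partial t$
and zero normal current on the boundary exactly, and reduces to the
classical loop-induction law $|E| = \pi f B r$ in the spherical case.
$E_{99th}$ is the 99th percentile (linear-interpolation definition) of
$|\mathbf{E}|$ over a regular point cloud clipped to the tissue ellipsoid
(default spacing 2 mm, refined for small organs so every cloud keeps at
least 500 points).  Optional multiplicative log-normal noise with CV up
to 5 % emulates numerical solver uncertainty; it is off by default and
seeded per tissue when on.

Two structural properties follow immediately and are exploited by the
test suite: $E_{99th}$ is exactly linear in $B_{rms}$ and $f$, and
antipodally symmetric, $E_{99th}(u) = E_{99th}(-u)$ — which is why
high-exposure orientation regions always come in $\pm$ pairs.

## The gestational-age fixtures

Three fixtures stand in for segmented pregnant-body models.  Their tissue
*lists* (15, 17, 26 tissues at 3, 7, 9 months) use standard fetal-tissue
names; at 9 months a few generic entries (pancreas, thymus, cartilage,
tendon) pad the list, and all geometry is synthetic.  Design decisions:

* **Sizes.**  Whole-body volumes correspond to ≈ 15 g, 1.7 kg and 2.7 kg
  at unit density, so exposure grows with gestational age as organ
  conduction loops grow.
* **Worst-case orientations.**  The torso semi-axes and fetus placement
  are set so a brute-force sweep of whole-body $E_{99th}$ peaks for a
  front-to-back field at 3 and 9 months and a lateral field at 7 months.
* **Smoothness.**  For any *single point* of a conductor there exists a
  field orientation with zero induced field there (the orientation-to-field
  matrix of a point is singular), so a small fetus far from the torso
  center would show a deep, sharp directional minimum that degrades
  polynomial convergence.  The 3-month fetus is therefore centered in the
  (uterus-centered) torso with anisotropic semi-axes; on a 5° grid the
  whole-body response then changes by well under 10 % between neighboring
  orientations at every age, the precondition for the degree-15 fit to
  validate below 0.5 %.  Small *organs* offset inside the larger fetuses
  retain sharper responses; they may need more of the $N \times p$ ladder
  and are flagged per tissue if they fail to converge.
* **CNS flags.**  Brain and CSF carry `is_cns_head` (0.02 V/m limit);
  the spinal cord does not (not "of the head"), nor does the eye lens
  (not CNS tissue).

What passing tests on these fixtures show — and what they do not: the
pipeline demonstrably reconstructs smooth quasi-static orientation
responses to fractions of a percent and turns them into correct
statistics, but the fixtures do not reproduce anatomical tissue
morphology, heterogeneous conductivity, the 2 mm³ vector averaging of the
regulatory metric, or fetal-posture variability.  Tissue-specific numbers
(means, CVs, WS%, steradians) are therefore properties of the synthetic
geometry, not predictions for real anatomies.

## Exposure statistics

After fitting, each tissue summary combines: the analytic moments and CV
(in percent); a 10,000-orientation random sweep of the surrogate giving
the worst case $mE_{99th}$ and the worst-case ratio
$\mathrm{WS\%} = 100 \cdot mE_{99th} / E_{lim}$ against the applicable
basic restriction (0.02 or 0.4 V/m); and, for the whole body, the
orientation bands at ≥ 70/80/90 % of $mE_{99th}$.  The 70 % threshold is
the 3 dB amplitude reduction point ($20\log_{10}(1/0.7) \approx 3.1$).

The sweep is uniform *in the angles* — the input distribution of the
surrogate — not uniform on the sphere.  Band areas in steradians are
therefore estimated with $\sin\theta$ importance weights,
$\Omega \approx (2\pi^2/M) \sum_{i \in \text{band}} \sin\theta_i$, with a
Monte-Carlo standard error reported alongside; band areas add up to
$4\pi$ within that error.  Both sides of each antipodal pair are counted.
Because the maximum over a finite random sweep slightly underestimates the
true maximum, the pipeline also reports the surrogate's maximum on a dense
1° deterministic grid (including the clamped support boundary) as a
cross-check — cheap on a polynomial.

## Numerical choices and edge cases

* Open angle supports: endpoint values are clamped inward by one machine
  epsilon rather than rejected, since unit-square designs map onto the
  closed interval.
* LARS correlations use centered unit-norm columns; near-constant columns
  are excluded from candidacy; a numerically singular active Gram matrix
  stops the path early (reported, not fatal).
* pMSE requires strictly positive validation responses; observation I/O
  rejects non-positive values at parse time, naming row and column.
* All randomness is explicit: validation, sweep and noise seeds are
  separate, derived offsets keep streams independent across tissues and
  ladder steps, and package functions restore the caller's RNG state.
* Determinism contract: identical configuration and seeds produce
  byte-identical CSV/JSON artifacts.

## Problem sizes

The reference validation case (300-point Sobol build, degree 15, three
150-point validation sets, whole-body region of ≈ 3·10⁵ cloud points)
runs in well under a minute on one CPU; the full 27-tissue 9-month
pipeline at default settings takes about half a minute.  Test-suite
simulations use reduced sizes of the same structure (designs of tens of
points, sweeps of a few thousand) chosen to keep each property check
sharp but quick.

## Limitations

Only $K = 2$ uniform inputs are exercised (the basis machinery is generic
in $K$, but other input distributions from the classical
polynomial-family correspondence are not implemented); no alternative
sparse solvers (LASSO, OMP) or cross-validation schemes; no
heterogeneous conductivity or tissue-interface corrections in the virtual
solver; solid angles are Monte-Carlo estimates, not geometric
integrations.
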