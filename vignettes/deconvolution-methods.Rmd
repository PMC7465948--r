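---
title: "Deconvolution of GC/MS co-elution with PARAFAC2 on pseudo-replicate sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolution of GC/MS co-elution with PARAFAC2 on pseudo-replicate sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcdeconv)
```

## The problem

Qualitative GC/MS analysis of complex matrices (soils, sediments,
packaging extracts) routinely produces co-eluting peaks: several
semi-volatile compounds — PAHs, PCBs, organochlorine and organophosphorus
pesticides — leave the column within a fraction of a peak width of each
other, so their electron-ionization spectra overlap and a plain library
search fails. Multi-way deconvolution with PARAFAC2 resolves such
intervals into per-compound elution profiles and mass spectra, but it
needs *several* chromatograms of the same sample with independent small
variations — typically at least five. For environmental work, where one
to three injections per extract is the norm, that requirement is the
blocking constraint.

`gcdeconv` implements the pragmatic workaround: derive the missing
chromatograms mathematically from a single run. Each pseudo-replicate is
the original chromatogram with (i) all intensities multiplied by a
constant factor (drawn from [0.5, 1.5]) and (ii) the retention-time axis
shifted by a signed sub-scan offset (drawn from [−0.003, 0.003] min),
then resampled back onto the original scan grid. At 3.6 scans/s one scan
is ≈ 0.0046 min, so the offsets are deliberately smaller than one scan
and linear interpolation — not index rolling — is essential. The five
co-registered members then feed interval-wise PARAFAC2 models, library
matching, and report aggregation.

## The model

For one retention interval, member $k$ contributes a slab
$X_k \in \mathbb{R}^{I \times J}$ (scans × m/z bins). PARAFAC2 states

$$X_k \approx B_k\, \mathrm{diag}(c_k)\, S^\top,
  \qquad B_k = P_k H,\; P_k^\top P_k = I_R,$$

with $S$ ($J \times R$) the resolved spectra shared by all members,
$c_k$ the per-member component amounts, and $B_k$ ($I \times R$) the
member-specific elution profiles constrained to share the cross-product
$B_k^\top B_k = H^\top H$. The cross-product constraint is what lets
elution profiles shift between members while keeping the factorization
well determined.

### Why the elution mode is non-negative here

The textbook direct-fitting algorithm constrains only the spectral and
sample modes to be non-negative and leaves the elution mode as an
unconstrained orthonormal basis. That is adequate when the samples carry
*independent* concentration variation. Pseudo-replicates do not: every
component in member $k$ is scaled by the same multiplier $m_k$, so the
sample-loading matrix $C$ has (numerically) proportional columns. In
that regime the model $X_k = m_k\,P_k(HS^\top)$ is invariant under any
invertible mixing $H \mapsto HT$, $S \mapsto S T^{-\top}$: the fit is
perfect at every mixing, and the resolved "spectra" come out as arbitrary
non-negative combinations of the true ones. We observed exactly this
with the unconstrained-elution algorithm: essentially perfect fit with
badly mixed spectra.

Chromatographic elution profiles are physically non-negative, and
imposing that on $B_k$ removes the ambiguity: mixing two overlapping
profiles with the (necessarily sign-indefinite) inverse of a non-trivial
non-negative $T$ drives profile entries negative, so only near-pure
solutions remain feasible. `gcdeconv` therefore fits, by default, a
flexible-coupling ALS: $B_k \ge 0$ with a quadratic penalty
$\mu \sum_k \lVert B_k - P_k H\rVert^2$ whose weight is ramped up
geometrically until the PARAFAC2 coupling is tight (relative coupling
residual below $10^{-8}$), after which the model is projected onto the
exact constraint and the spectra and amounts re-polished once. The
classic unconstrained-elution algorithm remains available via
`fit_settings(nonneg_elution = FALSE)`; its alternating updates are
exact conditional minimizers, so its SSE trace is non-increasing — a
property the test suite asserts.

### Initialization and numerical choices

* **Pure-channel start.** The first (deterministic) start selects $R$
  "key" m/z channels greedily: each next channel maximizes the elution-
  pattern norm orthogonal to the span of the already-chosen channels on
  the member-mean slab. The raw profiles of those channels initialize
  $B_k$. For co-eluting compounds with distinct base peaks this starts
  the search near the chemically meaningful solution. Additional starts
  (default total: 3) use seeded random factors; the lowest SSE wins,
  ties to the lower start index.
* **Non-negative least squares.** Every constrained update shares one
  small ($R \times R$) Gram matrix across hundreds of right-hand sides.
  The unconstrained solution is accepted wherever it is already
  feasible; violating columns are refined together by projected cyclic
  coordinate descent (strictly convex after a relative ridge of
  $10^{-12}$), warm-started from the previous block value so the ALS
  objective cannot increase.
* **Convergence.** Iterations stop when the SSE change falls below
  `convergence_tol` (default $10^{-8}$) times the cube's total sum of
  squares and the coupling is tight, or at `max_iterations` (default
  50,000). Measuring the change against the total — rather than the
  current SSE — lets exact fits (noiseless synthetic data) terminate.
* **Scale convention.** After fitting, spectral and common-factor
  columns are normalized to unit Euclidean norm and all magnitude is
  absorbed into the sample loadings, fixing the scale indeterminacy.
* **Degenerate inputs.** All-zero cubes and component counts above
  $\min(I, J)$ are rejected with informative errors; sweeps record
  per-candidate failures without aborting.

## Model adequacy: fit and core consistency

A candidate component count is accepted when the model fit
$100(1 - \mathrm{SSE}/\mathrm{SS}_{\mathrm{tot}})$ exceeds 90%, the core
consistency exceeds 90, the fit converged, no member is a residual
outlier, and no component is degenerate (an all-zero sample loading).
The *smallest* passing count is chosen: overfactoring splits real
spectra, and parsimony mirrors how an analyst inspects models manually.

Core consistency (CORCONDIA) diagnoses overfactoring by comparing the
free least-squares interaction core, given the fitted loadings, with the
diagonal core the model claims. The textbook three-way form inverts all
three loading matrices — including the sample loadings $C$. Under
pseudo-replication $C$ is near-collinear *by construction*, and
$\mathrm{pinv}(C)$ amplifies the small interpolation/noise residual
essentially without bound, making the textbook value meaningless —
arbitrarily large and negative — for exactly the data this workflow
targets, even on correct, essentially exact models. The default
diagnostic here is therefore computed slab-wise on the projected array
$Y_k = P_k^\top X_k$:

$$\mathrm{CC} = 100\left(1 -
  \frac{\sum_k \lVert \mathrm{pinv}(H)\,Y_k\,\mathrm{pinv}(S)^\top -
        \mathrm{diag}(c_k) \rVert^2}
       {\sum_k \lVert \mathrm{diag}(c_k) \rVert^2}\right).$$

This form never inverts the sample mode, reduces to the same idea
(deviation of the free core from the model's diagonal target), is
exactly 100 for $R = 1$ at any stationary point, and stays near 100 for
correctly specified models on pseudo-replicate cubes while dropping well
below 90 when components are split. The textbook form is kept as
`core_consistency(model, cube, method = "tucker3")` and remains the more
sensitive overfactoring detector when the fitted extra components die
out entirely (their zero loadings make the three-way core spread mass
off the superdiagonal).

## Identification and aggregation

Resolved spectra are rescaled to base peak 999 and searched against an
MSP library with a Stein–Scott-style weighted cosine: both spectra are
weighted by $w(m, I) = m \cdot \sqrt{I}$ on the union m/z grid and the
match factor is $999\cos^2$, rounded to an integer. The reverse match
factor first deletes query peaks at m/z values absent from the library
entry, so impurity ions do not penalize the comparison; removing
unmatched query mass can only raise the cosine, hence
$\mathrm{RMF} \ge \mathrm{MF}$ always. These scores are *not* numerically
identical to the NIST search engine's proprietary composite, but they
rank and classify comparably. Quality bands: ≥ 900 excellent, 800–899
good, 700–799 fair, 600–699 poor (this band is unnamed in the usual
quotation of the bands; "poor" is this package's convention), below 600
very poor.

Per compound, AMF/ARMF are the half-up-rounded means of MF/RMF over all
positive hits; study totals are means over identified compounds, and the
ARMF−AMF difference is computed on the unrounded means and rounded last
(rounding first can shift it by one unit — the bundled 40-compound
fixture exercises exactly that edge). Compounds with zero hits are
excluded from study means.

## What the simulator emulates — and what it does not

`simulate_chromatogram()` emulates a quadrupole EI full-scan acquisition:
3.6 scans/s, unit-spaced m/z 50–450, Gaussian peaks (area-normalized so
a component's summed signal equals its `amount`), each multiplied by its
normalized spectrum, plus a constant baseline and i.i.d. Gaussian noise
clamped at zero. Options exist for exponentially-modified-Gaussian
tails and flat-top clipping (to mimic overloaded matrix peaks such as
large phthalate signals that swallow nearby analytes). It does not model
matrix-induced signal enhancement, spectral skew across a peak, ion
statistics (shot noise), retention drift beyond a constant shift, or
mass-accuracy effects — so passing tests demonstrate correctness of the
algorithms under the stated model, not instrument-grade realism. Default
test problems use 0.4-min windows (≈ 87 scans), m/z 50–350 or narrower,
two components 0.01 min apart with σ = 0.01 min, and five-member sets —
sizes chosen so the full suite exercises every code path at desk scale.

## Known limitations

* With a *global* multiplier the sample mode carries no independent
  concentration variation; identifiability rests entirely on elution
  non-negativity (and, implicitly, on the components' profiles not being
  identical). Compounds with truly identical spectra in one interval
  cannot be separated — the workflow's answer, as in practice, is to
  re-cover such regions with several overlapping intervals.
* The member-residual outlier rule uses relative residuals with a 5%
  floor; the unshifted original member fits almost exactly on noiseless
  data, so a bare max/median ratio would reject every correct model.
* Match factors are comparable to, but not identical with, commercial
  search engines; published per-compound values are treated as
  aggregation inputs, not as match-engine targets.
* CSV is the only report export format; the tables open directly in
  spreadsheet software.
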