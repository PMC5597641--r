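---
title: "Evaluating structural connectomes with a sparse tensor-encoded linear fascicle model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating structural connectomes with a sparse tensor-encoded linear fascicle model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifet)
```

## The problem

Tractography converts diffusion-weighted MRI (dMRI) into a set of candidate
white-matter fascicles — polylines in scanner space, each a hypothesis about
an axon bundle trajectory. Different tracking algorithms and parameter
settings produce substantially different candidate sets, so a principled way
to ask *which candidates the measured data actually support* is needed
before a connectome is interpreted anatomically. The Linear Fascicle
Evaluation (LiFE) approach answers this by building a linear forward model
that predicts the diffusion signal from the candidate fascicles and by
keeping only fascicles that earn a positive weight in a non-negative
least-squares fit.

This package implements the evaluation machinery around a sparse three-way
array ("tensor") encoding of the connectome, which makes the model small
enough to handle interactively and turns anatomical queries — which voxels
does a tract touch, which fascicles share them, at what angles do they cross
— into index operations on the array.

## Forward model

For gradient direction $\theta$ at diffusion sensitization $b$, the signal
in voxel $v$ is modelled as an isotropic compartment plus one anisotropic
"stick" compartment per fascicle $f$ traversing the voxel:

$$
S(\theta, v) \;\approx\; S_0(v)\Big(w_0 e^{-A_0} +
\sum_{f \in v} w_f\, e^{-b\,\theta^{\mathsf T} Q_{f,v}\, \theta}\Big),
$$

where $Q_{f,v}$ is a prolate diffusion tensor aligned with the fascicle's
local orientation in that voxel, with axial and radial diffusivities
$\lambda_{ax}$ and $\lambda_{rad}$ (defaults $1.5\times10^{-3}$ mm$^2$/s and
$0$, a "stick"; both configurable and recorded in the model container —
single-shell acquisitions do not pin them down, so they are model
parameters, not estimates).

Subtracting the per-voxel mean over the $N_\theta$ diffusion-weighted
directions removes the isotropic term, which is constant across directions.
The model therefore predicts the *demeaned* signal, and we additionally
divide by $S_0(v)$ so everything is expressed as diffusion attenuation:

$$
y(\theta, v) = \frac{S(\theta,v) - I_v}{S_0(v)}, \qquad
y \approx M w, \quad w \ge 0,
$$

with $I_v$ the per-voxel mean over the $b>0$ directions. Column $f$ of $M$
holds the demeaned attenuation kernel

$$
O_f(\theta,v) = e^{-b\theta^{\mathsf T} Q_{f,v}\theta}
- \tfrac{1}{N_\theta}\textstyle\sum_\theta e^{-b\theta^{\mathsf T} Q_{f,v}\theta}
$$

of fascicle $f$ stacked over the voxels it traverses (voxel-major ordering,
fixed and recorded in the container). Working on the attenuation scale
means the per-voxel r.m.s. prediction error is directly comparable across
scanners and that the fitted weights are scanner-unit free; the
$S_0$-scaled convention is recovered by multiplying each voxel block by
$S_0(v)$. Note $w_0$ and $A_0$ never appear in the demeaned model; the
phantom exposes them purely as simulation inputs.

## Sparse tensor encoding

The explicit matrix $M$ has $N_\theta N_v$ rows and one column per
fascicle; at whole-brain scale it reaches tens of gigabytes. The package
instead stores:

* an **orientation dictionary**: $L$ canonical axial orientations
  ("atoms") on the upper hemisphere with their kernel columns collected in
  a $N_\theta \times L$ matrix $D$, and
* a **sparse three-way array** $\Phi$ with modes (atom, voxel, fascicle),
  holding the coefficients that express every fascicle-voxel kernel in the
  dictionary.

Prediction contracts $\Phi$'s fascicle mode with $w$, then multiplies by
$D$ — $M$ is never materialized. Frontal slices of $\Phi$ are fascicles
(so a tract is a set of frontal slices), lateral slices are voxels; support
queries (`touched_voxels()`, `fascicles_through()`), virtual lesions and
crossing-angle analyses are index operations on the coordinate list.

### One orientation per fascicle-voxel pair

Streamlines are resampled at half the smallest voxel dimension (so no
traversed voxel can be skipped between consecutive nodes), tangents are
computed by central differences, nodes are binned by the voxel-center
convention (a continuous voxel coordinate $p$ belongs to voxel
$\lfloor p + 0.5\rfloor$), and the tangents within a voxel are sign-aligned
to the first one, averaged and renormalized. Fascicle orientation is an
axis, not a vector, so all of this is antipodally symmetric, and traversing
a streamline backwards changes nothing. A fascicle curving inside a single
voxel is thus represented by its mean (chord) direction; this is a
deliberate simplification — one $Q_{f,v}$ per pair — and it is what the
exact explicit matrix uses too, so the factorization error quoted below is
purely the dictionary-representation error.

### Dictionary atoms

Atoms are placed by a spherical Fibonacci lattice on the upper hemisphere
($z_i = 1 - (i - 0.5)/L$, azimuths advancing by the golden angle):
deterministic for every $L$, quasi-uniform, free of antipodal duplicates,
and with covering radius shrinking monotonically in $L$ (the test suite
checks this at $L \in \{42, 162, 362\}$). The default $L = 362$ keeps the
dictionary above the resolution where the factorization error plateaus
while staying small ($90 \times 362$ doubles). At $L = 362$ the minimum
pairwise axial angle stays above $3^\circ$ and the worst-case quantization
angle is a few degrees.

### Entry values: projection, not plain quantization

The obvious encoding — one entry of value 1 at the nearest atom per
fascicle-voxel pair — incurs the full orientation-quantization error. At
$L = 362$ the nearest atom is a few degrees away, and because the stick
kernel at $b\lambda_{ax} = 3$ is steep, that orientation error translates
into a relative kernel error of order 10%: plain quantization caps the
fidelity of the factorized model at the percent level no matter how the
entries are weighted (the monotone-in-$L$ error test shows exactly this
regime).

The default encoding (`method = "interp"`) therefore *projects* each exact
fascicle-voxel kernel onto the span of the kernels of its $k = 16$ nearest
atoms by least squares. The kernels are smooth zonal functions, locally
well approximated within the dictionary's span, and the projection drives
the representation error down by more than two orders of magnitude — which
is why the factorized model reproduces the explicit matrix to better than
0.1% in relative Frobenius norm on the standard phantom, as the acceptance
checks compute. The cost is up to $k$
(signed) entries per fascicle-voxel pair instead of one. An orientation
lying exactly on an atom yields the single unit entry regardless of method,
and `method = "nearest"` provides the pure quantization scheme for exact
atom-aligned oracles and for tests. Support queries, lesions and geometry
read the per-incidence record (one nearest-atom index and one tangent per
fascicle-voxel pair), so they are unaffected by the choice.

## Fitting: projected-gradient Barzilai-Borwein NNLS

Weights solve $\min_{w\ge 0}\tfrac12\|y - Mw\|^2$ using only the
factorized forward/adjoint operators. The solver alternates the two
Barzilai-Borwein step lengths, projects onto the non-negative orthant, and
guards steps with a non-monotone Armijo test over a 10-iteration window of
accepted objective values; the first step is an exact line-search (Cauchy)
step along the projected steepest-descent direction from $w = 0$. It stops
when the projected-gradient infinity norm falls below `tol` times its
initial value, when the relative objective decrease over 5 iterations falls
below `tol`, or at `max_iter`. There is no randomness: identical inputs
give bitwise-identical weights.

Two numerical points deserve emphasis:

* **Support identification.** Projected-gradient iterates approach inactive
  bounds asymptotically; weights of unsupported fascicles end many orders
  of magnitude below the solution scale but not at exact zero. After
  convergence the solver therefore zeroes weights at or below
  `support_tol` ($10^{-6}$ by default) times the largest weight — a
  conventional active-set identification step. The optimized connectome
  (and "connectome resolution") is the set of fascicles with strictly
  positive weight after this step.
* **Near-degeneracy and solver pairing.** Parallel fascicles with
  overlapping supports make the NNLS optimum nearly (or exactly)
  non-unique: two different algorithms can return weight vectors that
  differ substantially while fitting equally well. Comparing weights fitted
  against the explicit matrix with weights fitted against the factorized
  model is therefore only meaningful when *both* fits use the same
  algorithm run to deep convergence; that is how the package's acceptance
  checks compute the weight-fidelity error $e_w$ (BB on both models,
  `tol = 1e-10`, `max_iter = 2000`). A small Lawson-Hanson active-set
  solver on the normal equations (`nnls_ref()`) serves as the independent
  reference for *objective values* on small instances.

## Evaluation metrics

Per voxel, $e_{rms}(v)$ is the root mean square of the residual over the
$b>0$ directions on the attenuation scale; the global error averages
$e_{rms}(v)$ over voxels containing at least one tensor entry (in a voxel
no fascicle traverses the model predicts identically zero, so including
empty voxels would mix a modelling error with a masking choice; the
all-voxel average and the empty-voxel count are reported alongside).
Model fidelity is quantified by
$e_M = \|M - \hat M\|_F / \|M\|_F$ and weight fidelity by
$e_w = \|w - \hat w\| / \|w\|$; both are scale-invariant and zero exactly
at equality.

## Virtual lesions

For a tract $F$, the touched voxels $V_F$ and the path-neighborhood $P_F$
(all fascicles through $V_F$, minus $F$) come straight off the tensor
support. The lesioned model zeroes the weights of $F$ and keeps everything
else — deliberately *no refit*, so the comparison isolates the tract's
marginal contribution. Both models' per-voxel r.m.s. errors on $V_F$ form
two distributions, compared by:

* the **earth mover distance**, computed exactly on the empirical samples
  as the integral of the absolute ECDF difference (no histogram, hence no
  bin-width sensitivity), and
* a **strength of evidence**: each sample's mean is bootstrapped
  ($10^4$ replicates by default, seed recorded), and the difference of the
  two bootstrap means is standardized by the pooled bootstrap standard
  deviation $\sqrt{(\mathrm{Var}[m_1]+\mathrm{Var}[m_2])/2}$. The pooled
  form (rather than a joint-distribution standard deviation) was chosen
  for symmetry — swapping the samples exactly negates the statistic — and
  is isolated in one function should a different normalization be needed.

## Crossing-angle geometry

For two disjoint tracts, every voxel they share contributes all pairs of
their per-incidence atom indices; each pair's axial angle is
$\arccos|U_{a_1} \cdot U_{a_2}| \in [0^\circ, 90^\circ]$. When a fit is
available, only fascicles with positive weight contribute. The sample is
summarized by a histogram over $[0^\circ, 90^\circ]$ (default bin
$1^\circ$, matched to the atom resolution), with peak $\mu$ the center of
the modal bin (ties to the smaller angle) and $\sigma$ the full width at
half the modal count, linearly interpolated between bin centers and clamped
to the domain; secondary local maxima reaching half the modal count are
reported as additional modes, so bimodal tract-versus-neighborhood
distributions keep both peaks visible. Summaries are computed per
connectome; pooling across repeated connectomes or subjects is left to the
caller, since the package cannot know the sampling design.

## The synthetic phantom

All tests and the acceptance script run on a synthetic phantom rather than
brain data. The default configuration mirrors a high-quality single-shell
acquisition at desk scale: a $15^3$ grid of 1.25 mm isotropic voxels, 90
quasi-uniform gradient directions at $b = 2000$ s/mm$^2$ plus 10 $b=0$
volumes, three 60-fascicle bundles crossing the reference bundle at
$0/45/90^\circ$ (parallel jittered copies of a straight or arched
centerline, bundle radius 2.5 mm), 20 zero-weight "spurious" smooth random
curves, ground-truth weights $w^\ast = 0.06$ per bundle fascicle (about
five fascicles per voxel, giving realistic attenuation levels together
with $w_0 = 0.4$, $A_0 = 2$), $S_0 = 100$, and Rician noise at
SNR $= S_0/\sigma = 20$ (Gaussian noise is available for analytic noise
checks, SNR $=\infty$ for noiseless oracles). Every random element flows
from a single seed, so a phantom is a pure function of its configuration.

The phantom emulates controlled crossing geometry, known ground-truth
support, the exact forward model, and measurement noise. It does **not**
emulate curving anatomy at brain scale, partial voluming against gray
matter or CSF, multi-shell acquisitions, susceptibility or motion
artifacts, or tractography errors other than the spurious curves. Passing
tests therefore demonstrate the correctness and internal consistency of
the encoding, solver and inference machinery under the stated model — not
tractography accuracy on real brains.

For parameter-recovery oracles the simulator can snap every fascicle-voxel
orientation to its nearest dictionary atom (`snap_to_atoms`); paired with
`method = "nearest"` encoding this makes the factorized model *exact*, so
the NNLS fit must recover $w^\ast$ up to solver tolerance and prune the
spurious fascicles — which is what the recovery tests assert.

## Problem sizes and defaults

The shipped checks use the $15^3$ standard phantom (~200 fascicles, ~2,000
mask voxels, 90 directions), where the explicit matrix is still cheap to
build in sparse form; these sizes were chosen so the entire suite and the
acceptance script run in seconds on a single core while exercising every
code path at realistic parameter values. Solver defaults are
`tol = 1e-6`, `max_iter = 500` for routine fits; fidelity comparisons use
`tol = 1e-10`, `max_iter = 2000` as discussed above. The explicit-matrix
builder refuses problems above a configurable element budget
(`budget = 5e8`) and points to the factorized path instead.

## Known limitations

* Single-shell only: the dictionary is built for one $b$; multi-shell
  input is rejected rather than approximated.
* One orientation per fascicle-voxel pair: fascicles that bend sharply
  within a voxel are represented by their chord direction.
* The interpolated encoding stores signed projection coefficients;
  `nnz(Phi)` equals the fascicle-voxel incidence count only under
  `method = "nearest"`.
* The isotropic compartment is eliminated by demeaning, not estimated;
  $w_0$ and $A_0$ are simulation inputs only.
* Virtual-lesion inference uses the no-refit contract; refit-after-lesion
  variants are out of scope.
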