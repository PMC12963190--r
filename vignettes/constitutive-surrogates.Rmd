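---
title: "Gaussian-process surrogate constitutive models for visco-hyperelastic solids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-process surrogate constitutive models for visco-hyperelastic solids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscogpr)
```

## The modelling problem

Soft materials (hydrogels, elastomers, biological tissues) deform to large
strains, respond nonlinearly, and — at high loading rates — stiffen or
soften with strain rate through viscous dissipation. The classical route to
a constitutive model is to pick a volumetric energy $U(J)$, a hyperelastic
energy $\bar W_h(\bar I_1,\bar I_2)$, and a viscous dissipation potential
$\bar W_v(\bar I_1,\bar I_2,\bar J_1,\dots,\bar J_7)$ from the literature
and calibrate their parameters. That choice caps the attainable accuracy
and requires expert judgement. The alternative at the other extreme — a
black-box regression from strain components to stress components — needs
data the experiments cannot provide and extrapolates unphysically.

This package takes the middle road. The representation theory of isotropic
tensor functions says that, whatever the potentials are, the three stress
components are *linear* in a fixed integrity basis,

$$
\mathbb G_1 = C^{-1},\quad
\mathbb G_2 = \mathrm{Dev}(I),\quad
\mathbb G_3 = \mathrm{Dev}(\bar C),\quad
\mathbb G_4 = \mathrm{Dev}(\bar C^{-1}),\quad
\mathbb G_5 = \mathrm{Dev}(\dot{\bar C}),
$$
$$
\mathbb G_6 = \mathrm{Dev}(\dot{\bar C}^{-1}),\quad
\mathbb G_7 = \mathrm{Dev}(\bar C\dot{\bar C}+\dot{\bar C}\bar C),\quad
\mathbb G_8 = \mathrm{Dev}(\bar C^2\dot{\bar C}+\dot{\bar C}\bar C^2),
$$

with scalar coefficients that are functions of invariants only. The model
discovery problem therefore reduces to learning three scalar-vector maps

$$
[J] \mapsto [\zeta_1],\qquad
[\bar I_1, \bar I_2] \mapsto [\Gamma_1, \Gamma_2],\qquad
[\bar I_1, \bar I_2, \bar J_1, \bar J_4, \bar J_6] \mapsto
[\Phi_1,\dots,\Phi_7],
$$

which is done with Gaussian-process regression. Everything a constitutive
model must satisfy structurally — objectivity, isotropy, symmetry of $S$,
causality, locality — is inherited from the representation, not learned.

The rate invariants $\bar J_2, \bar J_3, \bar J_5, \bar J_7$ are omitted
from the viscous map's inputs deliberately: the retained $\bar J_1, \bar
J_4, \bar J_6$ all vanish at $C = I$ for *every* rate tensor, so the
undeformed state corresponds to the single input $[3,3,0,0,0]$ and a single
zero-output training record pins the whole stress-free reference manifold.
Including the other four invariants would scatter the reference state over
infinitely many inputs and break that mechanism.

## From stress data to coefficient data

Each record $(C, \dot C, S)$ yields a $6\times k$ linear system
$\mathrm{vec}(S / J^{-2/3}) = A\,x$ whose columns are the Voigt vectors of
the relevant generators ($k = 1, 2, 7$). The solves are per point — never
pooled — and use singular-value-thresholded minimum-norm least squares
(relative threshold `rcond = 1e-10`).

Two identifiability facts matter and are easy to miss:

* On **uniaxial** paths every generator is a diagonal tensor that is
  C-orthogonal with equal transverse components, a one-dimensional space.
  The $k = 2$ hyperelastic system therefore has rank 1 and the $k = 7$
  viscous system rank $\le 2$: the individual coefficients are not unique
  there. The minimum-norm solution makes them deterministic and
  permutation-stable, and the *reconstructed stress* is unique regardless —
  the round trip is exact to $10^{-8}$ in the tests. Where the generators
  are independent (shear, general states) the solves recover the
  closed-form coefficients of the generating laws exactly.
* $\mathbb G_6$ requires inverting $\dot{\bar C}$, which is singular in
  simple shear and in quasi-statics. Rather than a pseudo-inverse — whose
  unbounded magnitude would dominate both the solve and the prediction —
  the package zeroes $\mathbb G_6$ and flags it (`g6_valid = FALSE`),
  forcing $\Phi_5 = 0$ at such states, identically at training and
  prediction time. The relative determinant tolerance is $10^{-10}$.

## The Gaussian-process layer

All three maps use a Matérn-3/2 kernel with hyperparameters
$\theta = (\sigma_f, \ell)$ shared across a surrogate's output columns (the
dissipation constraint below couples all seven $\Phi_i$, so they must share
one $\theta$), plus a per-point stabilisation noise $\alpha$:

* $\alpha = 10^{-4}$ at every volumetric record;
* $\alpha = 10^{-5}$ at stress-free reference records and $10^{-2}$
  elsewhere for the two isochoric surrogates.

The small reference-state $\alpha$ exploits the exact-inference property of
GPR: as $\alpha \to 0$ the posterior mean interpolates the training output,
so the zero-stress reference record enforces the normalization condition to
within $10^{-3}$ of the training stress scale (asserted in the tests).

Numerical choices, all fixed before any benchmark was scored:

* **Input standardisation** to zero mean and unit variance per dimension
  (training statistics). A single $\ell$ must serve inputs as different as
  $\bar I_1 \approx 3$ and $\bar J_4$ up to hundreds.
* **Output scaling** per column by the training standard deviation,
  *without centring*. Centring would break the zero-mean prior, whose
  far-field decay sends coefficients — hence stresses — to zero away from
  data. Scaling makes the $\alpha$ values act as relative noise levels, the
  convention of mainstream GPR implementations; without it the fixed
  $\alpha = 10^{-2}$ would be large against the small minimum-norm viscous
  coefficients and over-smooth the fit.
* **Hyperparameter search** by maximising the log marginal likelihood in
  $\log\theta$ within a box of $\pm 10^3$ around data-driven initial values
  ($\ell_0$ = median pairwise distance of standardised inputs, $\sigma_{f,0}$
  = pooled output standard deviation), L-BFGS-B with 5 seeded restarts.
  Refits under the same seed are bit-identical.
* **Duplicate reference rows** (one per training rate in the viscous set,
  all mapping to $[3,3,0,0,0]$) are collapsed to one so the covariance
  matrix stays invertible.

## Enforcing the second law

The viscous overstress must dissipate:
$\Xi = S_{v,\mathrm{iso}} : \dot C \ge 0$. For a given $\theta$ the
prediction at a constraint state is a known linear functional of the GP
outputs, $\Xi(\theta) = \sum_i \tilde\Phi_i(\theta)\, J^{-2/3}(\mathbb
G_{i+1} : \dot C)$, so the constraint set restricts the *hyperparameter*
search, not the function space — a weak, pointwise enforcement, here at all
training states.

The constrained optimiser is derivative-free: it starts at the
unconstrained optimum (returned unchanged if already feasible, the typical
case when the generating law is itself dissipative), and otherwise runs
multi-start Nelder-Mead on $\log\theta$ with an escalating quadratic
penalty on scaled violations until every constraint holds within a
$10^{-8}$ slack. Feasible solutions can only have lower likelihood than the
unconstrained optimum, which the tests assert.

## What the synthetic data represent — and what they do not

The generator reproduces three virtual experiments, with the grids and
parameters of the benchmark studies as defaults:

| protocol | law (parameters) | grid |
|---|---|---|
| confined compression, $F = \mathrm{diag}(J,1,1)$ | Simo–Miehe, $\kappa = 10$ | $J \in [0.75, 1]$, 26 points |
| quasi-static isochoric uniaxial | Mooney–Rivlin, $A_{10}=1$, $A_{01}=0.5$ | $\lambda \in [1, 1.25]$, 26 points |
| dynamic isochoric uniaxial | USS, $k_{11}=k_{21}=1$, $c_{21}=0.75$ | $\lambda \in [1,1.5]$, 31 points $\times$ rates $\{10, 32.5, 55, 77.5, 100\}$ |

Quasi-static records carry exactly zero rate tensors. A noise hook applies
seeded multiplicative Gaussian perturbations component-wise (reference
states exempt), defaulting to zero. These data are idealised: noise-free
unless requested, perfectly on-protocol, and with the viscous overstress
observed directly rather than inferred by subtracting quasi-static from
dynamic measurements. Passing tests on them demonstrates that the
machinery recovers known laws from clean data of realistic *size*; it does
not demonstrate robustness to experimental artefacts, off-axis loading, or
long-time (creep/relaxation) viscoelasticity, which the short-time,
limited-memory formulation excludes by construction.

## Conventional baselines and error reporting

Each benchmark calibrates the comparison model of its study by least
squares — volumetric neo-Hookean ($\kappa_{NH}$, all Voigt rows),
two-parameter Yeoh ($C_1, C_2$, loading-direction component only), and
Pioletti ($\eta'$, loading-direction component across the full
stretch–rate grid; linear closed form, verified against an iterative
solve). Errors use the percent relative metric
$100\,\lVert\mathrm{vec}(\tilde S)-\mathrm{vec}(S)\rVert /
\lVert\mathrm{vec}(S)\rVert$ on the 6-entry Voigt vector (each distinct
component once — intentionally not the full-tensor Frobenius norm, which
would double shear terms), with stress-free reference states excluded and
means taken over all points and rates of a regime.

On the training grids above, `run_case()` reports (seed 1): surrogate mean
errors of about 0.05% (volumetric), 0.05% (hyperelastic), and 0.7%
(viscous, constrained); calibrated-baseline errors of about 5.1%, 0.50%,
and 40.6%. The large Pioletti error reflects its single-parameter form
against the two-term USS ground truth, not a calibration failure.

## Known limitations

* Isotropy is structural; anisotropic materials (fibrous tissues) are out
  of scope.
* The dissipation constraint is enforced at finitely many states; between
  them it is only encouraged by smoothness.
* Coefficient values learned from uniaxial-only data are minimum-norm
  representatives, not the generating law's coefficients; they reproduce
  stresses, and transfer to other modes through the invariant inputs, but
  should not be interpreted individually.
* Hydrostatic tension/compression beyond the data relies on the GP's decay
  to the zero-coefficient prior; predictions far outside the training hull
  revert to zero stress rather than diverging — safe, but not informative.
* Problem sizes: the shipped studies use 26-, 26-, and 155-point training
  sets; the GP layer is dense ($O(N^3)$) and comfortable to a few thousand
  records.
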