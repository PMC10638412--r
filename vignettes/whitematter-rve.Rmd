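---
title: "Methods: a histology-informed RVE model of brain white matter"
author: "wmrve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a histology-informed RVE model of brain white matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmrve)
```

## The model

White matter of the corpus callosum is represented as a cubic
representative volume element (RVE) of edge length $L_a$ containing a
soft, nearly incompressible ground matrix (extracellular matrix plus
non-neuronal cells) and an embedded network of one-dimensional axon
fibers. Three microstructural features enter through probability laws
fitted to histology:

* **Diameter** $d$ (µm): generalized extreme value density with location
  $\mu$, scale $\sigma$ and shape $\xi$. The reference corpus callosum
  set is $(0.426, 0.200, -0.305)$; the negative shape bounds the upper
  tail at $\mu - \sigma/\xi \approx 1.08$ µm.
* **Straightness** $P_s = L_0/L_f \in (0,1]$, the ratio of end-to-end to
  arc length of a wavy axon: beta density with shapes
  $(a, b) = (9.155, 1.275)$, mean $\approx 0.878$.
* **Orientation**: a bivariate von Mises density,
  $\rho(\Phi,\Theta) = \rho_{ip}(\Phi)\,\rho_{op}(\Theta)$, with
  concentrations $\alpha$ (in-plane azimuth) and $\beta$ (out-of-plane
  elevation). The reference case is perfect alignment with the $x$ axis
  ($\alpha, \beta \to \infty$), represented by an explicit aligned flag
  rather than large finite concentrations (avoids overflow in
  $\exp$ and $I_0$).

The target fiber volume fraction is $v_f = 0.400$.

### Constitutive laws

The matrix is a one-term Ogden solid evaluated in *deviatoric* principal
stretches $\bar\lambda_k = J^{-1/3}\lambda_k$ with a quadratic volumetric
penalty:
$$\Psi_m = \frac{2\mu_m}{\alpha_m^2}\left(\bar\lambda_1^{\alpha_m} +
\bar\lambda_2^{\alpha_m} + \bar\lambda_3^{\alpha_m} - 3\right) +
\frac{1}{D_m}(J-1)^2 .$$
The deviatoric split is the standard nearly incompressible form: it makes
the reference state stress-free, $\mu_m$ the initial shear modulus and
$K = 2/D_m$ the initial bulk modulus, so that the default
$D_m = 0.04/\mu_m$ yields an initial Poisson ratio of
`r round(initial_poisson(matrix_params(353.5, -21.5)), 4)` ≈ 0.49.
(Applying the Ogden term to total stretches would leave a spurious
hydrostatic stress $2\mu_m/\alpha_m\,\mathbf I$ at $\mathbf F = \mathbf I$
under the penalty formulation; on isochoric deformations the two forms
coincide, so every analytic curve below is unaffected.) An
`incompressible = TRUE` flag drops the penalty for closed-form work.

Fiber tortuosity enters the constitutive law, not the geometry: with
$\lambda = l/L_0 = \lambda_r\lambda_t$, a fiber is slack
($\lambda_t = 1$, zero stress) until $\lambda \ge 1/P_s$, after which
$\lambda_t = \lambda P_s$ and the *modified embedded* energy
$$\tilde\Psi_f = \frac{2\mu_f}{\alpha_f^2}\left(\lambda_t^{\alpha_f} +
2\lambda_t^{-\alpha_f/2} - 3\right)$$
applies. The fiber is one-dimensional and incompressible (the
$\lambda_t^{-\alpha_f/2}$ term carries the lateral contraction); it never
bears compressive load. Its nominal stress per reference (straight,
$L_0$-based) area is the derivative
$P_f = (2\mu_f/\alpha_f)(\lambda_t^{\alpha_f-1} -
\lambda_t^{-\alpha_f/2-1})\,P_s$, zero up to recruitment and continuous
there. Because the fibers are *embedded* (superposed on the matrix
continuum), $\tilde\Psi_f$ is the fiber energy *in excess of* the matrix
occupying the same volume; the total energy is
$W = \int_V \Psi_m\,dV + \sum_i \int_{V_f^{(i)}} \tilde\Psi_f\,dV$ and no
matrix volume is double-counted. Consequently $(\mu_f, \alpha_f)$ are
properties of the embedded fibers, not of an isolated axon.

### Homogenization

The homogenized nominal (first Piola–Kirchhoff) stress assembles by the
rule of mixtures, $\mathbf P = \bar{\mathbf P}_m + v_f\,\bar{\mathbf
P}_f$, with the matrix field averaged over the full cube (consistent with
the modified fiber energy) and the fiber average weighted by reference
truss volumes. Two interchangeable engines share this interface:

* **Affine (Taylor)**: every fiber stretches with the macroscopic
  gradient, $\lambda_i = \lVert \mathbf F \mathbf N_i \rVert$. An upper
  bound, exact for aligned fibers under fiber-direction stretch; fast
  enough for optimization loops.
* **Periodic finite elements**: trilinear hexahedra with $2\times2\times2$
  quadrature carry the matrix law; fibers become truss segments cut
  exactly at host-element faces, their nodes constrained to the trilinear
  interpolation of the host (no-slip embedding). Periodicity
  ($\tilde{\mathbf u}(\mathbf X^+) = \tilde{\mathbf u}(\mathbf X^-)$,
  all faces/edges/corners handled by an index-modulo pairing, one corner
  pinned) and embedding are imposed by exact linear-constraint
  elimination, keeping the reduced tangent symmetric; a sparse direct
  factorization solves each Newton step.

### Loading modes and the reported stress component

Seven canonical modes are supported: uniaxial compression/tension parallel
(FF) and transverse (TT) to the fiber axis and three simple shears (first
index = displacement direction, second = face-normal direction; fiber
axis = $x$): shear_FT $= \mathbf I + \gamma\,\mathbf e_1 \otimes \mathbf
e_2$, shear_TF $= \mathbf I + \gamma\,\mathbf e_2 \otimes \mathbf e_1$,
shear_TT $= \mathbf I + \gamma\,\mathbf e_2 \otimes \mathbf e_3$.

Uniaxial modes prescribe the full isochoric gradient
$\operatorname{diag}(\lambda, \lambda^{-1/2}, \lambda^{-1/2})$ rather than
solving for zero lateral macro-stress. This is exact in the
incompressible-matrix limit, and aligned fibers add no lateral stress; a
nested zero-lateral-stress solve would matter only for strongly dispersed
orientations and is deliberately out of the FE engine's scope (the choice
is recorded in run metadata). Response curves report the *work-conjugate*
component $P = \mathbf P : d\mathbf F/d(\text{amount})$: for uniaxial
modes this is the total stretch-derivative of the energy and coincides
with the analytic incompressible uniaxial nominal stress of the matrix,
$P = (2\mu/\alpha)(\lambda^{\alpha-1} - \lambda^{-\alpha/2-1})$; for
shear it is the $P_{ij}$ component conjugate to $\gamma$. This convention
is what makes the synthetic-data → identification loop close exactly.

### Two-step identification

Step 1 fits $(\mu_m, \alpha_m)$ jointly to compression-FF and tension-TT
data truncated at 10 % deformation using the analytic incompressible
uniaxial model — legitimate because aligned tortuous fibers contribute
nothing in either mode. Step 2 fixes the matrix and fits
$(\mu_f, \alpha_f)$ to tension-FF data (same truncation) through forward
homogenization runs on a fixed network. Both steps minimize the
unweighted $\chi^2 = \sum (P^{exp} - P^{sim})^2$ with bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) under
$\mu_m \in [50, 5000]$ Pa, $\alpha_m \in [-50, 50]$,
$\mu_f \in [20, 5000]$ Pa, $\alpha_f$ unbounded (soft-clamped at
$\pm 500$ to avoid overflow in $\lambda^{\alpha}$). Five deterministic
interior starting points guard against local minima; a solution on a
bound raises a warning, and a tension-FF range that recruits no fiber is
flagged non-identifiable (the objective is then flat in the fiber
parameters). An optional per-mode weighting flag exists for unbalanced
grids; the default objective is unweighted, matching its printed form.

## The synthetic-data generator

`make_experiment()` emulates quasi-static stress–stretch experiments on
corpus callosum: the affine forward model on a generated network,
evaluated on 21-point grids to 10 % deformation per mode, perturbed with
multiplicative Gaussian noise (default $\sigma = 5\,\%$ — chosen because
soft-tissue stress magnitudes span decades across modes, so relative
error is the natural scale; an additive option exists). The zero-stress
identity point is never perturbed (physical anchor). What it does *not*
emulate: inter-specimen variability structure, viscoelastic conditioning,
or measurement drift — so passing recovery tests demonstrate correctness
of the inverse machinery, not robustness to every artefact of real
rheometer data.

## Numerical choices

* **Distribution fitting** uses bounded quasi-Newton (`L-BFGS-B`)
  maximization of the log-likelihood from a moment-based start plus
  deterministic restarts; ties break by likelihood, then smallest
  parameter norm; $\xi$ is restricted to $[-0.95, 0.95]$ (finite mean and
  a usable information matrix). Because the diameter sampler rejects
  non-positive draws (≈ 0.6 % of mass for the reference parameters), the
  matching refit likelihood is the *zero-truncated* GEV
  (`gev_fit(x, truncation = 0)`); the untruncated fit carries a ≈ +0.004
  µm location bias.
* **Orientation sampling** is by rejection: azimuth against a uniform
  proposal, elevation against the uniform-on-the-sphere proposal, so the
  normalization constant cancels and isotropic concentrations give exactly
  uniform directions on the sphere. The printed density factors are each
  normalized against a uniform angular measure; the absolute constant
  against the spherical area measure is computed numerically once per
  parameter set when a normalized density value is requested.
* **Network generation** targets $v_f$ with chord-length (end-to-end)
  volume bookkeeping — tortuosity lives in the constitutive law, so using
  arc length $L_0/P_s$ would double-count it (an alternative bookkeeping
  is available behind a flag of the volume computation). Fibers are
  straight chords clipped to the cube; no periodic wrapping (the simplest
  consistent convention, recorded in network metadata). The achieved
  $v_f$ overshoots the target by at most one fiber volume
  ($\lesssim 10^{-3}$ at $L_a = 25$ µm). Chords shorter than $L_a/20$
  are rejected to keep FE embedding well-posed; fiber–fiber overlap is
  not checked (fibers are 1-D in the embedded formulation).
* **Ogden stress and tangent** are computed in principal axes from the
  SVD of $\mathbf F$. The stress expression is basis-invariant inside
  repeated singular-value subspaces, so coincident stretches need no
  special branch; the tangent's $(S_a - S_b)/(\lambda_a^2 - \lambda_b^2)$
  shear terms switch to the analytic limit when stretches differ by less
  than $10^{-8}$ relative (avoids catastrophic cancellation).
* **FE solver**: load stepping in 10 equal increments by default with
  automatic halving on divergence (max 4 cuts); Newton stops when the
  residual $\infty$-norm falls below $10^{-8}\mu_m L_a^2$ (absolute floor
  $10^{-12}$). Unrecruited/compressed truss segments contribute zero
  stress plus a small numerical stiffness $10^{-6}\mu_f A_0/L_0$ along
  their axis (switchable) so the embedding never leaves a zero row.
  Displacement-based hexes with the $\nu = 0.49$ penalty replace a mixed
  formulation; at this mild near-incompressibility and with $2^3$
  quadrature no locking was observed in the mesh-refinement checks.
* **Mesh sizes.** The test and example configurations use desk-scale
  problems: $L_a \le 10$ µm with $h = L_a/8$ or less, and mesh-refinement
  checks at $h \in \{2.5, 1.25\}$ µm on 5 µm cubes. The reference
  configuration $L_a = 25$ µm, $h = 1.25$ µm (8000 elements) is supported
  but long-running in this pure-R implementation; FE convergence groups
  above 25 µm are gated behind `allow_long = TRUE`. The affine engine,
  which needs no mesh, is the default for population studies and for
  step 2 of the identification (it is validated against the FE engine on
  small aligned RVEs, where the two agree to within a few percent at
  moderate stretch).
* **Seeds.** Every stochastic routine takes an explicit seed and restores
  the caller's RNG state; studies expand a base seed deterministically
  (`base + replicate index`), so any run is reproducible from its logged
  configuration.

## Design decisions that were genuinely open

* The fitting criterion behind the published distribution table is not
  stated; both maximum likelihood (default) and least squares on the
  histogram are provided.
* Whether the reference generator targets $v_f$ by chord or arc length,
  and whether fibers wrap periodically, is not stated; chord length and
  clipping were chosen and recorded.
* Whether step 1 fits the two modes sequentially or in one objective is
  ambiguous ("at the same time"); they are fitted jointly in a single
  $\chi^2$.
* The averaging domain of the matrix stress (matrix volume vs whole
  cube) is notationally ambiguous under embedding; the whole-cube
  average is used, which is the choice consistent with the modified
  fiber energy.
* Uniaxial RVE runs prescribe the full isochoric $\mathbf F$; a
  zero-lateral-stress control exists only for the affine engine, behind
  a flag.

## What the tests show — and what they don't

The suite verifies: densities integrate to one and refits recover
generating parameters (self-consistency at $n = 10^5$); generated
networks hit $v_f$ within one fiber volume; stress–energy consistency of
both laws by finite differences; exact zero fiber contribution for
aligned networks in compression-FF/tension-TT; recruitment continuity;
the FE engine against the homogeneous closed form (fiber-free) and
against the affine bound (single aligned fiber); Hill–Mandel consistency
of averaged stress power; mesh-size insensitivity; the dispersion-case
ordering of the tension-FF response (aligned stiffest, isotropic
softest); shrinking scatter of the homogenized response with growing RVE
size; near-equality of the three shear modes for aligned networks; and
closure of the two-step identification on noiseless and noisy synthetic
data. All of these are statements about the model's internal
consistency and its qualitative agreement with the experimental picture
of corpus callosum mechanics; none of them constitutes a fit to real
experimental curves, which would require the original digitized data.

## Known limitations

* Hyperelastic and time-independent only: no viscoelasticity, stress
  relaxation, damage, or fluid interaction.
* Single region (corpus callosum statistics); gray matter and other
  white-matter regions would need their own distribution fits.
* The FE engine is a compact pure-R implementation: displacement/penalty
  elements, prescribed macroscopic $\mathbf F$, structured meshes only.
  It is built for verification and small RVEs, not for production-scale
  50 µm cubes.
* Fibers are geometrically straight; waviness acts only through the
  recruitment law, so geometric effects of curvature (e.g. bending
  stiffness, contact) are outside the model.
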