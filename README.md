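# wmrve — multiscale homogenization of brain white matter

`wmrve` is an R package for histology-informed micromechanical modelling of
brain white matter (the corpus callosum in particular). White matter is
treated as a two-phase composite: a soft, nearly incompressible ground
matrix reinforced by a dense network of tortuous 1-D axon fibers. The
package covers the full modelling chain:

1. **Microstructure statistics.** Axon outer diameter follows a generalized
   extreme value (GEV) law, fiber straightness `P_s = L0/L_f` a beta law,
   and fiber orientation a bivariate von Mises law in the azimuth and
   elevation angles. All three can be evaluated, sampled, and fitted
   (maximum likelihood or least squares on histograms).
2. **RVE generation.** Random straight fiber chords are placed in a cubic
   representative volume element (RVE) until a target fiber volume fraction
   `v_f` is reached, each with its own diameter, straightness and direction.
3. **Constitutive laws.** The matrix is a one-term Ogden solid,
   `Psi_m = (2 mu_m / alpha_m^2) (lb1^a + lb2^a + lb3^a - 3) + (J-1)^2/D_m`,
   written in deviatoric principal stretches with a volumetric penalty
   (`D_m = 0.04/mu_m` gives an initial Poisson ratio of 0.49). Fibers carry
   a modified embedded one-term Ogden energy in the *true* stretch
   `lambda_t`: a tortuous fiber first unbends (recruitment stretch
   `lambda_r`, no load) and only bears load once `lambda >= 1/P_s`
   (`lambda = lambda_r lambda_t`). Fibers never carry compression.
4. **Homogenization.** Seven canonical loading modes (uniaxial
   compression/tension parallel FF and transverse TT to the fiber axis, and
   three simple shears) are homogenized by the rule of mixtures
   `P = P_matrix + v_f * P_fiber` with either affine (Taylor)
   micro-kinematics or a built-in periodic finite-element engine
   (trilinear hexes, embedded truss fibers cut exactly at element faces,
   periodic boundary constraints, total-Lagrangian Newton).
5. **Inverse identification.** A two-step bounded least-squares procedure:
   step 1 fits `(mu_m, alpha_m)` to compression-FF and tension-TT curves
   with the analytic incompressible uniaxial Ogden model; step 2 fits
   `(mu_f, alpha_f)` to the tension-FF curve through forward homogenization
   runs. A synthetic-data module generates noisy pseudo-experimental curves
   so the whole pipeline is testable end to end.

Stresses are nominal (first Piola–Kirchhoff), units are micrometres and
pascal throughout.

## Worked example

Generate the reference corpus callosum RVE and homogenize tension along
the fiber axis:

```r
library(wmrve)
sp  <- cc_structural_params()          # v_f = 0.400, GEV/beta/aligned laws
net <- generate_rve(sp, La = 25, seed = 1)
net
#> Fiber network: La = 25 um, N_f = 1113, v_f = 0.4002 (seed 1)

mat <- cc_material_params()            # mu_m 353.5 Pa, alpha_m -21.5; mu_f 80.8 Pa, alpha_f 62.3
cv <- response_curve(net, "tension_FF", max_amount = 1.2,
                     mp = mat$matrix, fp = mat$fiber, n_steps = 5)
cv
#>   amount P_total P_matrix   P_fiber recruited_fraction
#> 1   1.00    0.00     0.00     0.000             0.0000
#> 2   1.05   43.32    41.94     3.428             0.2607
#> 3   1.10  106.49    79.43    67.611             0.4536
#> 4   1.15  542.43   127.05  1038.054             0.6154
#> 5   1.20 5838.48   193.99 14105.745             0.7279
```

The columns are the work-conjugate nominal stress (Pa) of the homogenized
RVE and its matrix/fiber split, plus the volume-weighted fraction of
recruited fibers. The table shows the mechanism the model was built
around: up to ~10 % stretch the ground matrix dominates and the response
is nearly isotropic; beyond that, progressive recruitment of tortuous
axons produces the characteristic stiffening along the fiber direction.

Identification closes on the package's own synthetic data:

```r
cfg <- synthetic_config(mat$matrix, mat$fiber, sp, La = 10, noise_sd = 0, seed = 5)
ex  <- make_experiment(cfg)
identify_two_step(ex, attr(ex, "network"))
#> Two-step identification
#> Matrix fit: mu_m = 353.5 Pa, alpha_m = -21.5 (chi2 = 5.9e-26 Pa^2)
#> Fiber fit (affine engine): mu_f = 80.8 Pa, alpha_f = 62.3 (chi2 = 8.71e-28 Pa^2)
```

A thin command-line wrapper lives at `inst/cli/wmrve`
(`generate-rve | simulate | identify | convergence | make-synthetic`,
YAML-configured).

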