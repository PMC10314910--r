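---
title: "Coupled shape and in-plane nematic order on closed flexible shells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled shape and in-plane nematic order on closed flexible shells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemshell)
```

## The model

`nemshell` computes equilibrium shapes of closed, axisymmetric flexible
shells (lipid vesicles, liquid-crystal shells) whose surface is covered by
curved rod-like molecules with in-plane nematic order -- BAR-domain
proteins on membranes and bent-core mesogens on LC shells are the
motivating systems.  Two coupled fields live on the surface: the curvature
field of the shell and a surface Q-tensor

$$ Q = q_0\,(e_1\otimes e_1 - e_2\otimes e_2)
     + q_m\,(e_1\otimes e_2 + e_2\otimes e_1), $$

with $e_1$ along meridians and $e_2$ along parallels.  The ordering
amplitude $\lambda=\sqrt{q_0^2+q_m^2}\in[0,1/2]$ vanishes at topological
defects; the director angle $\eta$ (from the meridian) satisfies
$\cos2\eta = q_0/\lambda$, $\sin2\eta = q_m/\lambda$.

The free energy density is the sum of four terms:

* bending: $f_b = \tfrac{\kappa}{2}(C_1+C_2-C_0)^2$ — the classical
  spontaneous-curvature energy of the bare shell;
* condensation: $f_c = -\alpha\,\mathrm{Tr}Q^2 +
  \tfrac{\beta}{2}(\mathrm{Tr}Q^2)^2$ with
  $\mathrm{Tr}Q^2 = 2(q_0^2+q_m^2)$, which condenses nematic order below
  the transition ($\alpha>0$);
* intrinsic elasticity: $f_i = \tfrac{k_i}{2}\lvert\nabla_s Q\rvert^2$,
  penalizing texture gradients (tangential components only, see below);
* deviatoric coupling: $f_e = \tfrac{k_e}{2}(C - C_p)^2$, where
  $C = H + D\cos 2\eta$ is the normal curvature seen by a molecule tilted
  by $\eta$ (Euler relation), $H=(C_1+C_2)/2$, $D=(C_1-C_2)/2$, and $C_p$
  is the molecule's intrinsic curvature.

All lengths are in units of $R=\sqrt{A/4\pi}$ and all energies in units
of $k_i$.  The shape is a surface of revolution generated by a profile
curve whose tangent angle is a truncated Fourier series,
$\theta(s) = \pi s/L_s + \sum_i a_i \sin(\pi i s/L_s)$, so that
$\theta(0)=0$ and $\theta(L_s)=\pi$ hold identically; closure
$\rho(L_s)=0$ and the reduced volume $v = V/\tfrac{4\pi}{3}R^3$ are
constraints.  Equilibria are found by alternating Metropolis Monte Carlo
relaxation of $(q_0,q_m)$ on the fixed shape with derivative-free
minimization over the Fourier amplitudes at fixed texture, starting from
several seed branches (oblate, prolate, stomatocyte, dumbbell, phi) and
comparing branch energies — coincident energies of two branches mark a
discontinuous morphological transition.

## Parameters that matter

| parameter | meaning | unit | default |
|---|---|---|---|
| `v_target` | reduced volume constraint | — | 0.4 |
| `Cp` | intrinsic molecular curvature | $1/R$ | 0 |
| `ke` | deviatoric coupling | $k_i$ | 1/5 |
| `kappa` | bending rigidity | $k_i$ | 1/60 |
| `C0` | isotropic spontaneous curvature | $1/R$ | 0 |
| `R_over_xi` | shell size over nematic correlation length $\xi=\sqrt{k_i/\lvert\alpha\rvert}$ | — | 10 |

The Landau coefficients are closed from `R_over_xi`:
$\lvert\alpha\rvert = k_i (R/\xi)^2$ and $\beta = 2\lvert\alpha\rvert$, so
the equilibrium amplitude $\lambda_0=\sqrt{\alpha/2\beta}$ sits at the
upper bound $1/2$.  Two remarks.  First, the frequently quoted
$\lambda_0=\sqrt{\alpha/\beta}$ belongs to the alternative normalization
$\mathrm{Tr}Q^2=\lambda^2$; under the eigenvalue convention used here the
self-consistent minimizer of $f_c$ is $\sqrt{\alpha/2\beta}$, and that is
what `equilibrium_lambda()` returns.  Second, $\beta$ is **not** a
cosmetic choice: the director stiffness scales as $k_i\lambda_0^2$, so
$\beta$ sets the weight of defect cores and disordered necks relative to
the bending and deviatoric terms, and therefore moves phase boundaries
between shape branches.  Since no measurement pins $\beta$ here, the
package fixes $\lambda_0 = 1/2$ once and exposes `alpha`/`beta` overrides
in `model_params()` for sensitivity studies; the consequences are
discussed under *Limitations*.

A temperature quench across the order-disorder transition is a sign flip
of $\alpha$ (`nematic = FALSE`): in the isotropic phase all molecular
orientations are equally probable and $f_e$ reduces to its orientation
average $\tfrac{k_e}{2}[(H-C_p)^2 + D^2/2]$ — randomly oriented curved
molecules act as an isotropic spontaneous curvature.  The same average is
used inside defect cores, with a linear blend over
$\lambda/\lambda_0\in[0.05, 0.15]$ so the density is continuous.

## Numerical choices

**Geometry.**  The profile integrals $\rho=\int\cos\theta$,
$z=\int\sin\theta$ use per-interval 4-point Gauss–Legendre quadrature on
the analytic series — node values are accurate to ~1e-12, which keeps the
closure constraint free of quadrature noise.  Surface integrals use
composite Simpson in $s$ (odd node counts) and the periodic trapezoid in
$\varphi$.  $C_1 = d\theta/ds$ is differentiated analytically, never by
finite differences.  Both ends of the $s$ grid are poles: $C_2$ carries
its umbilic limit $C_1$ there, the geodesic curvature of parallels
$\kappa_{g2}=\cos\theta/\rho$ is `NA`, and pole rows never enter
$1/\rho$-weighted integrands (their area element vanishes).  After every
shape update the profile is rescaled so the area is exactly $4\pi$; this
also removes $L_s$ as an independent degree of freedom, so the shape
optimizer works on the amplitudes alone.

**Intrinsic elasticity on the lattice.**  Expanding $\nabla_s Q$ in the
principal frame and keeping tangential components gives
$$ f_i = k_i\Big[q_{0,s}^2 + q_{m,s}^2
  + \big(\tfrac{q_{0,\varphi}}{\rho} - 2\kappa_{g2} q_m\big)^2
  + \big(\tfrac{q_{m,\varphi}}{\rho} + 2\kappa_{g2} q_0\big)^2\Big]. $$
The discretization is *link-based*: derivatives live on lattice links
with geometric factors at link midpoints.  Centered differences were
rejected because they are blind to site-alternating (checkerboard) modes;
a Metropolis sampler fills those modes wherever the frame-spin
($\kappa_{g2}$) term is large — near the poles — and the measured
windings become meaningless.  Link differences penalize checkerboards and
are still second-order accurate at midpoints; the implementation is
cross-checked against a brute-force oracle that embeds $Q$ as an ambient
3×3 tensor field, finite-differences it along the surface, and projects
tangentially.

The normal components of the frame gradients
($-C_1\,v\otimes e_1$, $-C_2\,v\otimes e_2$) would contribute
$k_i(C_1^2+C_2^2)\lambda^2$ — an amplitude–curvature coupling.  They are
excluded by default because the deviatoric term already carries the
orientation–curvature coupling of the model and including both would
count curvature twice; `model_params(extrinsic = TRUE)` switches them on.

**Monte Carlo.**  Single-site Metropolis updates of $(q_0,q_m)$ with
Gaussian proposals; $\lambda\le 1/2$ enforced by rejection.  The starting
temperature is calibrated from the mean proposal energy change, cooling
is geometric (0.9 per 10-sweep stage by default), the proposal width
adapts between stages, and the final 20% of sweeps run greedily at $T=0$,
so the energy is non-increasing there.  At the end of every stage an
*exact line search over the global gauge rotation* of $(q_0,q_m)$ is
applied: $f_c$ and $f_i$ are exactly invariant under this rotation, so
only the deviatoric energy changes, and the collective tilt mode — which
single-site dynamics orders only logarithmically slowly because the
deviatoric scale is two orders of magnitude below the condensation scale
— equilibrates in one step.  Without it the director tilt on tubes never
reaches the Euler-relation optimum at feasible sweep counts.  The whole
trajectory is a deterministic function of the seed (a dedicated
xorshift64* stream in compiled code).

**Shape step.**  Nelder–Mead over blocks of ten amplitudes (low to high
frequency); the objective is the total free energy plus quadratic
penalties for closure, the reduced-volume target, the $\rho\ge 0$ barrier
and the optional minimal height (the stretching-force constraint), with
tenfold weight escalation per pass.  The objective is noisy through the
MC-relaxed texture, so gradients are unreliable; derivative-free moves
are kept only when they lower the penalized objective.  Trial profiles
with meaningfully negative $\rho$ are rejected outright: their area
element changes sign and would let positive densities lower the integral
without bound.  Self-intersection in $z$ (folds) is allowed — invaginated
shapes need it.

**Defect detection.**  Cores are connected regions with
$\lambda < 0.2\,\lambda_0$ plus the two poles.  Winding numbers come from
unwrapped increments of $2\eta$ along enclosing grid loops — rectangles
for off-pole cores, parallel rings for pole caps (where the meridian
frame itself winds once, adding $+1$) — snapped to multiples of $1/2$.
If the detected charges do not sum to the topological total 2
(Poincaré–Hopf), the threshold escalates stepwise to 0.7: on coarse grids
the correlation length is about one cell and cores do not always dip
below the default cut.  Merged cores report summed charge; angle jumps of
$\ge\pi/2$ between loop nodes mark a result low-confidence.

**Problem sizes.**  The reference discretization is a 101×101
$(s,\varphi)$ grid with 80 Fourier modes.  The test suite and the
acceptance script run the same pipeline at 41–61 nodes per direction,
16–20 modes, and a few thousand Monte Carlo sweeps per relaxation stage;
these sizes resolve the defect cores ($\xi = 0.1R$, one to two grid
cells) and keep a full three-branch comparison at a parameter point in
the minutes range on one CPU.

## What the synthetic fixtures emulate

`seed_profile()` generates the competing branches at a prescribed
reduced volume — sphere, spherocylinder-like prolate, biconcave oblate,
tube-plus-invagination stomatocyte, dumbbell, and a phi-shape (central
bulge with two thin protrusions) — by projecting a smooth target tangent
angle on the Fourier basis, solving one family parameter for the volume
and, for the asymmetric stomatocyte, projecting the amplitudes onto the
closure manifold with a minimal-norm Newton step.  `defect_texture()`
builds textures with prescribed defect positions and half-integer
charges through a stereographic phase-field construction, used to
validate detection by round-trip.  These fixtures are idealized: they
carry no thermal roughness, no density inhomogeneity of the molecules
(the model assumes homogeneous coverage throughout), and the seed shapes
are only qualitatively correct — passing tests demonstrates internal
consistency of the machinery at the study conditions, not agreement with
any experimental membrane.

## Design choices where the ground was open

* **Quadrature for the profile curve** is Gauss–Legendre on the analytic
  series rather than Simpson on node values: the closure residual then
  measures the shape, not the quadrature.
* **Tangential-only $\lvert\nabla_sQ\rvert^2$** (see above), with the
  extrinsic contribution behind a switch.
* **$f_e$ is not weighted by $\lambda/\lambda_0$** in the ordered phase;
  a weighting would make the deviatoric coupling vanish in defect cores
  and across the transition, which the isotropic-phase behavior of the
  model contradicts (randomly oriented molecules still couple to
  curvature).  The orientation-averaged form plus blending covers the
  disordered limit instead.
* **Area by exact rescale, volume and closure by penalty**: the rescale
  preserves the $R=1$ unit system exactly; penalties with escalation
  keep the optimizer stable on noisy objectives.
* **Branch seeds instead of one global search**: the shape families are
  separated by first-order transitions (phi-shapes do not nucleate from
  a smooth tube), so the multi-start protocol with energy comparison is
  structural, not an optimization convenience.

## Limitations

* The phase boundaries between oblate, stomatocyte and prolate branches
  at low reduced volume depend sensitively on the ordering strength
  $k_i\lambda_0^2$ relative to $\kappa$ and $k_e$ — equivalently on the
  Landau quartic coefficient, which is not fixed by $R/\xi$.  Under the
  default closure ($\lambda_0 = 1/2$) the prolate branch is favored over
  a wider $C_p$ range than the weak-ordering limit suggests, and the
  stomatocyte window can close entirely (its disordered neck ring costs
  a condensation deficit of several $k_i$).  Sensitivity studies should
  vary `beta` explicitly.
* Non-axisymmetric shapes, inhomogeneous molecular coverage, thermal
  shape fluctuations and defect-core structure below the grid scale are
  outside the model.
* The Monte Carlo + block Nelder–Mead search carries no global-optimality
  guarantee; near transitions, run several seeds per branch and compare
  (`branch_compare()` flags coexistence within a relative tolerance of
  1e-3).

## A short run

```{r example, eval = FALSE}
params <- model_params(v_target = 0.6, Cp = 1.0)   # ke = ki/5, kappa = ki/60
config <- run_config("test", seed = 1, branch = "prolate")
run <- alternate_minimize(config, params)
run                      # energy breakdown, class, defects
run$defects              # winding numbers and positions
save_run(run, "run1")    # CSV/JSON/VTK archive
```
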