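---
title: "Model and methods: agent-based in-stent restenosis with variance-based UQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelled system

In-stent restenosis is the renewed narrowing of a stented coronary artery
caused by excessive neointima formation: smooth muscle cells (SMCs),
activated by the injury of stent deployment, proliferate into the lumen
until a functional endothelium regrows and suppresses them. `isruq`
simulates a two-dimensional longitudinal section of a small (porcine-like)
coronary segment — 1.5 mm long, 1 mm lumen, a tunica media of five SMC
layers bounded by an internal elastic lamina (IEL), and one square
bare-metal stent strut per wall — and quantifies how uncertain inputs and
intrinsic stochasticity propagate into the neointimal area.

The model couples four submodels per time step:

1. **Tissue mechanics.** Cells, IEL elements and strut elements are
   off-lattice disks. Contact follows a Hertzian law
   $F = k_h\,\delta^{3/2}$ with a linear adhesive correction
   $-a\,k_h\,\delta$ inside contact, plus a tapered Hookean tether
   (extracellular matrix) over a finite gap range. The IEL is a chain of
   Hookean springs; strut elements interact by pure repulsion (bare
   metal). Equilibria are found by FIRE (fast inertial relaxation engine)
   with a per-agent velocity clamp — plain gradient descent two-cycles on
   stiff Hertzian contacts, and unclamped inertia can launch freshly
   divided, deeply overlapping cells through the tissue.
2. **Stent deployment.** Struts advance outward in equal increments; the
   tissue re-equilibrates after each, and agents above a contact-stress
   threshold (or, for the IEL, a chain-strain threshold) are removed.
   This ruptures the IEL around the strut and exposes SMCs to the flow.
3. **Flow and wall shear stress (WSS).** The agent domain is rasterized
   (a node is solid when its centre lies in a disk; the engine inflates
   radii by half a lattice spacing so sub-node throats between touching
   cells do not read as channels). The flow domain is the fluid connected
   to the lumen. Two solvers satisfy the same contract: a D2Q9 BGK
   lattice-Boltzmann reference (half-way bounce-back walls, Zou-He
   velocity inlet scaled to constant flux, Zou-He pressure outlet) and a
   quasi-1D lubrication mode (per-column Poiseuille over the local gap)
   used in campaigns. WSS at the interface is a one-sided finite
   difference, $\mu\,|u_t|/(\Delta x/2)$, averaged per cell.
4. **Cell biology.** Exposed SMCs switch from contractile to synthetic and
   traverse a stochastic cell cycle (Normal, mean 32 h, sd 2 h, truncated
   positive); mitosis places the daughter at one radius in a uniformly
   random direction. Growth is inhibited by crowding (contact-neighbour
   count) or by nitric oxide where a covered cell sees sufficient WSS.
   Re-endothelialization follows a scenario curve $c(t)$: Scenario 1
   recovers 59% of coverage in 3 days and completes at the uncertain
   regeneration time $T \in [15, 23]$ days; Scenario 2 is linear from 0
   to 1 over $[0, T]$. Each exposed uncovered cell becomes covered with
   probability $p = (c(t{+}\Delta t) - c(t))/(1 - c(t))$, which makes the
   covered fraction of an always-exposed cohort track $c(t)$ exactly.

The headline output is the neointimal area over time: the mean lumen
width (largest contiguous fluid run per column) defines an equivalent
circular lumen area, subtracted from the post-stenting baseline.
Restenosis is declared when the final neointimal area exceeds half the
original lumen area (0.39 mm² for a 1 mm vessel).

## Uncertainty quantification

The simulator is treated as $f(\xi, \mathbf{x})$ with stochastic seed
$\xi$ and three uncertain inputs (uniform): flow velocity 0.432–0.528
m/s, deployment depth 0.09–0.13 mm, regeneration time 15–23 days.
`build_design()` draws $M$ Sobol' points in $2n$ dimensions, splits the
columns into matrices A and B, and emits $M(2n+2)$ runs: A, a reseeded
copy of A (aleatory pairs), and per input the first-order block (B with
column $i$ from A) and the total block (A with column $i$ from B, fresh
seeds). Estimators:

* total variance, sd, CV ($\mathrm{sd}/|\mathrm{mean}| \times 100\%$);
* aleatory variance $\frac{1}{2M}\sum_j (f_A^j - f_{A'}^j)^2$, with
  Jensen's inequality bounding the mean conditional sd by its square root;
* first-order indices
  $\frac{1}{M}\sum_j (f_A^j - f_0)(f_{FO_i}^j - f_0) / \widehat{\mathrm{Var}}$
  with $f_0$ the A-block mean (negative estimates are reported raw);
* total indices $\frac{1}{2M}\sum_j (f_A^j - f_{TO_i}^j)^2 /
  \widehat{\mathrm{Var}}$, which include interactions with the seed
  because the TO block redraws it;
* bootstrap error bars from $K$ resamples of the design rows, keeping all
  blocks' row $j$ together so the pairings survive resampling.

The same estimators apply to the scalar final area, to every time point,
and sitewise to lattice presence indicators (`spatial_sensitivity_maps()`),
with zero-variance sites masked.

## Design choices and their reasons

* **A/B from dimension doubling, not row blocks.** With a plain Sobol'
  sequence, rows $j$ and $j+M$ are strongly correlated, which ruins the
  first-order estimator (an inert input can score ~50%). Drawing $M$
  points in $2n$ dimensions and splitting columns is the standard remedy
  and is what the package does.
* **Seeds.** Every design run gets a distinct seed from a stable hash of
  (root, block, input index, row); any two paired streams are
  independent, which is all the estimators require.
* **Force scales.** Contact stiffness must dominate tether/adhesion
  forces by orders of magnitude ($k_h = 10^4$, adhesion $a = 0.017$,
  tether 20): if it does not, cells squash through one another and the
  wall can invert. The adhesive correction is placed inside contact so an
  isolated pair has the closed-form equilibrium overlap $a^2$, which the
  two-body oracle test checks to $10^{-8}$ mm.
* **Boundary conditions.** Edge columns are clamped (the segment
  continues into unstented artery) and the outermost SMC row is fixed,
  standing in for the stiffer outer vessel layers. Without that backing
  the free-floating wall simply translates away from the strut and
  nothing ruptures; with it, deployment damage localizes at the strut as
  it should. Clamped boundary agents are exempt from overload removal
  and from the biology (their constraint stresses are artificial).
* **Removal thresholds** are not published for the original model; the
  defaults are calibrated once so that a nominal 110 µm deployment
  ruptures the IEL near the strut while zero depth removes nothing, and
  they scale with the Hertzian factor $(r/15\,\mu m)^{3/2}$ in the
  coarse configuration.
* **NO threshold 1 Pa.** With the threshold near the healthy-lumen WSS
  (11.5 Pa), covered cells in any recess (which see less shear) escape
  inhibition and growth never stops; a threshold well below the nominal
  wall value lets the re-endothelialization scenario control when growth
  ends, which is the mechanism the model is built around. The
  lubrication solver assigns connected side pockets ~10% of the local
  main-lumen WSS as a stand-in for recirculation shear.
* **Contact inhibition** uses a neighbour count (limit 5 within 1.3
  contact distances): interior and concave cells reach the limit, flat
  free surfaces do not. The original's free-area rule is not published
  in detail.
* **Struts** are built from elements of half the cell radius (a smoother
  indenter than the tissue it deforms) and the two struts are staggered
  by a quarter cell pitch in opposite directions; perfectly opposed
  coarse struts rupture both walls in lock-step and make the deployment
  depth response artificially steppy.
* **Model step 1 h** at full resolution (flow re-solved every step), 8 h
  in the coarse campaign configuration; deployment uses 10 (coarse: 8)
  increments.
* **Scenario 1's initial ramp** (0 to 59% over days 0–3) is linear; the
  source drawing is ambiguous between instantaneous and linear.
* **Degenerate inputs.** Coincident agent centres raise an error; a fully
  occluded lumen raises a typed closure condition which the engine turns
  into a truncated-and-held trajectory with the restenosis flag set.

## The coarse campaign world

Full-resolution runs (15 µm cells, 1 h steps, 30 days) take minutes;
campaigns use `coarse_config()`: 22.5 µm cells, a 1.2 mm segment, 20 µm
lattice, 8 h steps, 25 simulated days (past the largest regeneration
time, where the regeneration-time effect is expressed), about 1.5–2 s per
run. At this scale the model reproduces the qualitative structure of the
full study — Scenario 2 grows more than Scenario 1, growth forms an oval
around the strut, the aleatory variance is a minority share of the total,
and the regeneration time carries the largest total sensitivity index at
the final time — but not the published numbers, which came from 960
full-fidelity runs. Desk-scale checks treat those numbers as qualitative
echoes only. What a green test establishes is therefore: the estimators
are correct (validated on closed-form cases), the simulator respects its
invariants, and the coarse campaign reproduces the directionality of the
full study; it does not validate the model against histology, pulsatile
flow, drug elution or three-dimensional effects, none of which are
modelled.

Tests and the acceptance checks scale Monte Carlo sizes down (e.g. 12
paired scenario runs rather than 50, bootstrap K of a few hundred inside
campaign tests) to stay inside a CI time budget; the statistical margins
in the assertions account for that.

## Known limitations

* The 2D section cannot represent hoop stress; the IEL rupture mechanism
  relies on longitudinal stretch around the indenting strut.
* The lubrication mode has no recirculation; its side-pocket WSS proxy is
  a single-parameter stand-in.
* Steady flow only; no pulsatile WSS reversal.
* The drug-elution pathway is a no-op (bare metal stent).
* Coarse-lattice campaigns quantize the deployment-depth response: cells
  are 45 µm across while the depth range spans 40 µm.
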