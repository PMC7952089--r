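---
title: "Dimer-gel theory and simulation of two-component associative polymers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimer-gel theory and simulation of two-component associative polymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magicratio)
```

# The system

Two polymer species, A with $m$ stickers and B with $n$ stickers per chain,
interact exclusively through one-to-one sticker bonds between opposite
types.  Above a threshold concentration the mixture demixes into a dense,
network-like condensate coexisting with a dilute phase of small oligomers.
The quantity of interest is how the coexistence (binodal) boundaries depend
on valence, binding strength, and the stoichiometry of the two species.
The headline phenomenon is the *magic-ratio effect*: at strong binding the
dilute-phase boundary is sharply elevated when the polymer numbers are in a
rational ratio, because complete, saturated oligomers (1:1 dimers for
$m = n$, 1:2 trimers for $m = 2n$, ...) combine low energy with high
translational entropy and outcompete the condensate.

`magicratio` implements this physics twice and cross-checks the two routes:
a coarse-grained Langevin simulator of sticker–spacer chains, and an
analytical mean-field "dimer-gel" free energy whose phase diagrams are
extracted by convex-hull analysis.

# The coarse-grained model

Beads of diameter $\sigma = 2.5$ nm represent stickers; consecutive
stickers are joined by harmonic linkers $\tfrac12 k (r - r_0)^2$ with rest
length $r_0 = 4.7$ nm and stiffness $k = 10\,k_BT/\mathrm{nm}^2$ (the
stiffness is our choice; it fixes the bond-length fluctuation at
$\sim 0.3$ nm and the integration timestep at $2\pi/\sqrt{k}/50 \approx
0.04$ reduced time units, 50 steps per bond period).  Non-bonded
interactions:

* **cross-type attraction** $U(r) = -U_0 \cos^2\!\big(\pi r / (2 r_a)\big)$
  for $r < r_a$: a smooth well of depth $U_0$ at contact, flat-bottomed at
  $r = 0$ and vanishing with zero slope at the cutoff;
* **same-type repulsion** $U(r) = \tfrac12 E_r (1 + \cos(\pi r / r_r))$ for
  $r < r_r = 1.5\sigma$, with $E_r = 100\,k_BT$.  Its role is steric: a
  second A bead approaching a bound A–B pair within the bond criterion
  must come within $2 \times r_a/2 = r_a$ of the first A and pays
  $\gtrsim 40\,k_BT$, far more than any attraction gain, so binding is
  one-to-one in practice.  (At the *outer edge* of the well the exclusion
  is not strict for any finite repulsion; the one-to-one invariant is
  therefore stated and tested at the bond criterion $r \le r_a/2$, the
  well's outer inflection point, where it is robust.)

**Calibration of the attraction cutoff.**  The published anchor relating
well depth to affinity is a sticker–sticker dissociation constant of
0.4 mM at $U_0 = 9\,k_BT$, with $K_d^{-1} = \int_0^{r_a} e^{-U(r)}
4\pi r^2\,dr$.  With the cosine-squared well this fixes $r_a$; the value
$r_a = 0.8\,\sigma = 2.0$ nm reproduces the anchor to 0.5%
(`dissociation_constant_from_potential()` returns 0.402 mM) and was frozen
before any other result was produced.  Two consistency checks fall out:
the strong-binding reference $K_b = 3.8\times10^{-3}$ mM maps back to
$U_0 \approx 14.5\,k_BT$, matching the strong-binding simulations at
$U_0 = 14$; and the $U_0 = 0$ limit is exactly the inverse bound-region
volume.

**Dynamics.**  BAOAB splitting of Langevin dynamics at $k_BT = 1$, unit
bead mass, friction $\gamma = 1$ by default (the reference work does not
state thermostat parameters; ours are recorded in every run manifest).
With $\gamma = 0$ and no noise the integrator is velocity Verlet, which the
tests exploit for energy-conservation checks ($<10^{-4}$ relative drift
over $10^4$ steps).  Trajectories are bit-reproducible from `(spec, seed)`.

# Structure analysis

A sticker pair is *bonded* when closer than the bond cutoff $r_a/2$ (the
well's outer inflection; an energetic criterion made geometric).  Pairing
is greedy by increasing distance with deterministic tie-breaks, which on
physically separated bound pairs coincides with exhaustive minimum-weight
matching (tested against an enumeration oracle).  Clusters are connected
components over polymers; their composition in polymer counts drives the
oligomer bookkeeping: the minimal fully bonded oligomer of an
$A_m$:$B_n$ system is $(a, b) = (n, m)/\gcd(m, n)$ and a general
composition leaves $|am - bn|$ stickers unpaired.

Slab coexistence runs are analysed by binning sticker concentration along
$x$, aligning each frame's dense region to $x = 0$ by maximising a boxcar-
windowed density (circular cross-correlation; the reference describes the
alignment but not the method), averaging, and reading the dilute and dense
concentrations from the windows $|x| \ge 100\,\mathrm{nm} \times L_x/250$
and $|x| \le 10\,\mathrm{nm} \times L_x/250$.

One analysis convention deserves emphasis: when comparing *bond counts* to
the quadrature $K_d$, the counting cutoff must be the full attraction well
$r_a$ (the region the integral is taken over), not the $r_a/2$ cluster
criterion — about 30% of the bound-state integral lives in the outer half
of the well at moderate $U_0$.

# The dimer-gel free energy

Concentrations are in sticker units (mM); $\rho_i = c_i / L_i$ are
polymeric concentrations, $L_1 \ge L_2$.  The free-energy density per
$k_BT$ is $F = F_{ni} + F_s + F_{ns}$ with

$$F_{ni} = \frac{c_1}{L_1}\ln\frac{c_1}{e L_1} +
           \frac{c_2}{L_2}\ln\frac{c_2}{e L_2},$$

(conformational-entropy terms, being linear in the $c_i$, are dropped as
they cannot shift phase boundaries), and a specific part obtained from the
partition function of dimers plus independent bonds by Stirling's
approximation.  Writing $x(t) = t\ln t$, $\rho_d$ for the dimer
concentration, $q_i = c_i - L_i \rho_d$ for leftover stickers and
$h_i = q_i - c_b$ for free stickers,

$$F_s = -x(\rho_1) - x(\rho_2) + \rho_d \ln(e K_d \rho_d)
        + x(\rho_1 - \rho_d) + x(\rho_2 - \rho_d)
        - x(q_1) - x(q_2) + c_b \ln(e K_b c_b) + x(h_1) + x(h_2),$$

and a nonspecific part
$F_{ns} = \tfrac{v_b}{2}\max(c_1,c_2)^2 + \tfrac{w_b}{6}\max(c_1,c_2)^3$
acting on the majority species (the minority is fully absorbed into bonds
in the regime of interest).  $F_s(0,0,0) = 0$ by construction (no
association means the specific partition function is 1), and the
derivation reproduces, exactly, the published mass-action stationarity
conditions, their reductions $K_d\rho_d = (\rho_1-\rho_d)(\rho_2-\rho_d)$
and $K_b c_b = (c_1-c_b)(c_2-c_b)$ when one channel is switched off, the
all-dimer and all-bond limiting free energies, and the equal-stoichiometry
crossover
$$c_0 = e\,(K_b^L/(K_d L))^{1/(L-1)}, \qquad
  c_s = c_0\,(s-1)^{s-1} s^{-s}.$$
These identities are asserted in the test suite at $10^{-8}$–$10^{-10}$.
Note that the limiting states are *feasible points* of the minimisation, so
the full $F_s$ lies at or below the lower of the two limiting values and
converges to it (within 1%) in the strong-binding regime.

**Association solver.**  $F_s$ is minimised over $(\rho_d, c_b)$, not
root-found: the landscape is bistable in the strong-binding regime
(dimer-rich and bond-rich local minima).  Numerically the minimiser sits
exponentially close to a boundary, where forming $c - L\rho_d$ by
subtraction destroys all precision; the solver therefore parametrises by
the excess $e = \min(\rho_1,\rho_2) - \rho_d$ (and its logit), solves the
bond channel in closed form for every $e$ by a cancellation-free quadratic,
and reduces the problem to a guarded 1-D scan-plus-bisection whose every
stationary bracket is refined; the lowest-$F_s$ root wins.  A brute-force
grid minimiser serves as the oracle in 200-draw randomized tests.

# Theory parameters

* $L_1, L_2$: *effective* valences.  Stickers tethered by short linkers do
  not bind independently; segments of about 1.8 stickers do.  A simulation
  valence of 14 maps to a theory valence $14/1.8 \approx 8$
  (`effective_valence()`), which is why the reference phase diagrams are
  presented at valence 8.
* $K_b = 3.8\times10^{-3}$ mM: the strong-binding sticker-pair constant.
* $v_b = 9\times10^{-2}\,\mathrm{mM}^{-1}$,
  $w_b = 7\times10^{-3}\,\mathrm{mM}^{-2}$: nonspecific two- and three-body
  parameters of the bond solution.
* $K_d$: the whole-dimer constant is valence-dependent and, in the
  reference work, *fitted from simulations* (those fitted values are not
  reproduced here).  The package ships a clearly-labelled **synthetic
  stand-in**, a zipping model: one bimolecular contact ($K_b$) followed by
  $L_b - 1 = \min(L_1,L_2) - 1$ intramolecular closures with equilibrium
  constant $\kappa / K_b$, and a register multiplicity $g = L_1 - L_2 + 1$,
  giving $K_d = K_b^{L_b} / (g\,\kappa^{L_b-1})$.  The closure local
  concentration $\kappa$ is computed from the model's own geometry
  (`closure_local_concentration()`): two stickers at the ends of rigid
  spacers of length $1.8 \times 4.7$ nm — the correlation-length segment,
  consistent with the valence rescaling — attached to a bound pair, with
  the separation density weighted by the Boltzmann factor of the well.
  This gives $\kappa = 2.97$ mM, $K_d(L{=}8) = 2.2\times10^{-23}$ mM
  (polymeric), and a diagonal crossover $c_0 = 5.99$ mM.  These numbers
  were fixed once, from the geometry, before any phase diagram was
  computed.  Consequence to keep in mind: quantitative binodal positions
  inherit the uncertainty of this stand-in; the *structure* of the phase
  diagram (the magic-ratio peak, its location at $c_1/c_2 = L_1/L_2$, its
  disappearance at weak binding) is robust to it.

# Phase-diagram construction

$F(c_1, c_2)$ is evaluated on a uniform grid (default $200 \times 200$ up
to 30 mM — resolving the diagonal feature at tractable cost; grid and
tolerances are recorded in output metadata).  The lower convex hull of the
3-D point cloud is computed by an in-package quickhull; facets whose
projected area exceeds $\alpha = 1.5$ grid cells bridge non-convex regions
— ordinary triangulation facets have half-cell area, so the threshold
separates genuine coexistence facets from slivers.  The longest edge of
each coexistence facet is kept as its tie line (two-component systems have
two coexisting phases; three-vertex slivers are resolved by edge length),
endpoints ordered dilute-first by total concentration.  A node is
two-phase when the landscape sits measurably above the hull there.  A
perfectly planar landscape is reported as degenerate (all one-phase, with
a warning) rather than triangulated.

Grid resolution limits the dilute branch: off the magic ratio the true
dilute boundary is exponentially small and snaps to the nearest node
(possibly 0).  The diagonal peak's *tip* also converges more slowly than
the rest of the boundary (vertex snapping); the refinement-stability test
is therefore stated off-peak, where doubling the grid moves the binodal by
less than one coarse cell.

The `dilute_branch_scan()` convenience reproduces the standard scan: fix
the total global sticker concentration at 6.64 mM (the published global
concentration: 2500 stickers in a 250×50×50 nm box), sweep the
stoichiometry, and read off the dilute/dense totals of the tie line
through each global composition.  At strong binding the dilute branch
peaks exactly at $c_1/c_2 = L_1/L_2$ for both $A_8$:$B_8$ and $A_8$:$B_7$.
Raising $K_d$ and $K_b$ 100-fold (the prescribed weak-binding
perturbation) removes the maximum — in our parametrisation dimers then
dominate the entire window and the diagonal composition no longer phase
separates at all, so the peak disappears together with its tie line.

# What the synthetic fixtures do and do not establish

The planted generators emulate exactly the statistical structure each
analysis stage assumes: tanh slab profiles with known plateaus, plus
multiplicative Gaussian noise; clusters with prescribed composition and
bonding pattern at the attraction minimum; unbound dilute gases.  Green
tests on them establish that the *analysis chain* is correct (plateau
recovery, exact ground-truth pairing, composition bookkeeping, alignment
invariance) — they say nothing about whether the simulator's equilibrium
matches the theory.  That link is made separately, at desk scale, by the
stochastic experiments: Boltzmann statistics of a single bond, mass-action
recovery of the quadrature $K_d$ in a dilute A2:B2 gas, and the
self-assembly of a dilute A14:B7 gas into (1 A, 2 B) fully bonded trimers.
Published-scale slab coexistence values are out of reach at desk scale and
are not claimed.

Two experiment-design notes:

* **Avidity in the mass-action test.**  With the default 4.7 nm linker, a
  singly-bonded A2–B2 pair closes its second (ring) bond at an effective
  local concentration comparable to $K_d$ itself, so naive sticker-level
  mass action would be violated by tens of percent — correct physics, wrong
  oracle.  The test uses a 16 nm test linker (a legitimate per-experiment
  input), which suppresses the closure to a $\sim$12% channel, and adds the
  ring term to the prediction using the independently computed closure
  concentration; the residual discrepancy is then within $3\times$ the
  blocked Monte-Carlo standard error.
* **Kinetics of trimer formation.**  At $U_0 = 14$ bonds essentially never
  break on desk timescales, so equilibration proceeds by irreversible
  zipping; at 0.5 mM cluster–cluster collisions outrun zipping and produce
  fused (2 A, 4 B)-type aggregates.  At 0.1 mM zipping wins and the modal
  composition is the (1 A, 2 B) trimer across seeds.  This is a kinetic,
  not thermodynamic, limitation of the desk-scale experiment.

# Known limitations

* $K_d$ values are a synthetic stand-in (above), not the fitted ones.
* The mean-field independence assumption enters through the effective
  valence; no sequence-resolved sticker correlations beyond the scalar
  1.8-sticker rescaling.
* No conformational-entropy terms for non-interacting polymers (linear in
  concentration; irrelevant to boundaries).
* No percolation/gelation threshold, interfacial tension, or width
  analysis; no pressure observables; no multiple-to-one binding.
* The hull construction reports compositions on grid nodes; sub-cell
  precision would require local tangent-plane refinement, which is not
  implemented.
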