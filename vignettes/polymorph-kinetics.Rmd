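---
title: "Kinetics of competing parallel and antiparallel nanocrystal assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of competing parallel and antiparallel nanocrystal assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`zippersim` simulates hierarchical self-assembly of a short amyloid-forming
peptide (the reference parameterisation is the IFQINS hexapeptide from human
lysozyme) into rectangular nanocrystals, resolving the kinetic competition
between two polymorphs that interact only by competing for monomers:

* **AP** — an antiparallel beta-sheet lattice, plane group p1
  (rectangular), cell a = 20.0 Å, b = 19.1 Å;
* **P** — the parallel beta-sheet crystal form (PDB entry 4R0P), plane group
  p2 in the ab plane (herringbone): translation along a is accompanied by a
  180° rotation, so the effective a repeat is half the translational cell
  length (21.6 Å from a = 43.2 Å).

Every species is a polymorph tag plus an integer block shape
$(n_a, n_b, n_c)$ counting peptides along the backbone, sidechain-stacking
and hydrogen-bonding axes.  Aggregates are rigid rectangular blocks; twist
and bend are not represented (their kinetic consequences are discussed under
*Limitations*).  $n_b$ is restricted to 1 or an even integer: a species with
odd $n_b > 1$ would bury the weak inter-cell b interface while exposing a
broken steric zipper ("inside-out"), and all such species are excluded from
the network as a hard constraint, applied consistently to joins, splits and
cleavage products.

### Interface energetics

Binding free energies per buried peptide (kcal/mol) enter through an
`energy_table`.  For the rectangular AP lattice the energy of a buried plane
is linear in the peptides it buries:

$$\Delta G_a = n_b n_c\,\Delta G_a^\circ,\qquad
  \Delta G_{b} = n_a n_c\,\Delta G_b^\circ,\qquad
  \Delta G_{zip} = n_a n_c\,\Delta G_{zip}^\circ,\qquad
  \Delta G_c = n_a n_b\,\Delta G_c^\circ.$$

The herringbone P lattice has jagged edges and a ±c/2 step between adjacent
sheets, so its lateral (ab-plane) interfaces are composed from two
parameters $\varepsilon$ and $\varepsilon'$ and carry the overhang factor
$n_c - 1/2$:

$$\Delta G_a = (2 n_b - 1)\tfrac{\varepsilon}{2}(n_c - \tfrac12),\qquad
  \Delta G_b = \big((n_a - 1)\varepsilon + n_a \varepsilon'\big)(n_c - \tfrac12),$$

with $n_b = 1$ association burying half a steric zipper ($\varepsilon/2$ per
unit of $n_c - 1/2$).  The intra-cell zipper of P is a separately measured
interface, $\Delta G_{zip} = n_a\,\Delta G_{zip}^\circ (n_c - 1/2)$; the
hydrogen-bond interface stays $n_a n_b \Delta G_c^\circ$.  In the
large-aggregate limit the per-peptide lateral energies tend to
$\varepsilon/2$ (a direction) and $\varepsilon + \varepsilon'$ (b
direction); `large_aggregate_limits()` reports these.

A splitting event in the b direction is classified by parity
(`classify_b_split`): even $\to$ (1, 1) breaks the zipper, even $\to$
(even, even) breaks a b plane, and anything creating odd $n_b > 1$ is
forbidden.

The reference energies (AP: −9.2, −6.2, −16.4, −29.3; P: $\varepsilon$ =
−18.84, $\varepsilon'$ = −5.99, zipper and hydrogen bond −25.3) can also be
re-derived from block free-energy tables with `estimate_interface_energies`,
which applies finite-difference estimators at block sizes chosen to capture
cooperativity at the 20–40 Å scale, e.g.
$\Delta G_c^\circ = (G_{1,1,10} - 10\,G_{1,1,1})/9$.  The P zipper divisor
is 9.5 rather than 10, again because of the half-c overhang.

### Rates

Translational diffusion uses the cylinder mapping: the block's longest
dimension is the rod length, the equivalent-circle diameter of its
cross-section the rod diameter, with the end-effect interpolation
$\nu(p) = 0.312 + 0.565/p + 0.100/p^2$ and $p$ clamped below at 1 for
compact blocks.  Orientation–translation coupling is ignored.  The monomer
timescale $\tau_0 = \ell^2/6D$ (three-dimensional mean-squared-displacement
convention; ~1.8 ns for the AP monomer cell in water at 300 K) anchors all
Arrhenius rates.

* **Joins** of blocks with matching contact faces:
  $k = 2 e^{-3} (D_A + D_B)\sqrt{2A}$, with $A$ the contact-face area; the
  barrier $e^{-3}$ represents the translational/rotational entropy lost on
  docking (calorimetric barriers for small-peptide assembly are of order
  2–5 $k_BT$).  Propensities are $k N_A N_B/V$, with $N(N-1)/2$ for
  homodimerisation.
* **Splits** on any allowed plane:
  $k = \tau_0^{-1}\exp(\Delta G_{plane}/k_BT)$, multiplied at the propensity
  level by the number of equivalent parallel planes (e.g. $n_c - 1$ c
  planes); the fired plane position is drawn uniformly.
* **Compound collisions** let blocks with one or two mismatched contact
  dimensions react through a virtual non-rectangular intermediate: the pair
  joins on the overlap face and the overhanging material is cleaved so only
  rectangular products remain, at rate
  $k = k_{join}\prod_i \tau_0 k_{split,i}$ (one factor per cleavage plane).
  One mismatch gives a 2→2 reaction; two mismatches a 2→3 reaction, and when
  the doubly-overhanging block admits two cleavage-plane pairs both are
  evaluated and only the faster is kept.  The reverse 3→2 process is not
  constructed (its rates are uniformly negligible), while the 2→3 channel is
  retained to keep the network connected between shape classes.
* Two colliding monomers commit to P or AP with probability 1/2 each; a
  committed peptide becomes uncommitted only by leaving its assembly, and
  mixed P/AP blocks never form.  Because the collision kernel depends weakly
  on which polymorph's cell geometry is assumed, the monomer–monomer rate
  constant is the mean over the enabled polymorphs, which keeps the
  commitment exactly equiprobable.

### The sampler

The event-driven (Gillespie) sampler enumerates all channels among species
present, draws exponential waiting times from the total propensity and picks
channels proportionally to theirs.  Rate constants are computed once per
reactant signature, when a species first enters the system, and cached;
propensities are refreshed incrementally for the few species each event
touches, with bucketed partial sums for selection.  Peptide conservation is
asserted at every event.

Two numerical policies matter.  Channels with rate constants below the
pruning threshold (10⁻⁵⁰ in internal units: m³/s bimolecular, 1/s
unimolecular) are discarded from the system.  Bimolecular channels between
the prune threshold and a "live floor" (default 10⁻⁴⁰ m³/s) remain part of
the model but are served through an upper-bounded background group: the
bound $k_{floor} S^2/2V$ is added to the total propensity and, on the rare
selection of the group, the actual sub-floor channels are enumerated and the
surplus fires as a no-op.  This uniformization construction leaves the
sampled process exactly unchanged while keeping the hot channel array free
of dead weight; the firing-probability bound of the whole group is below
10⁻⁶ over any run at the study conditions.  Floating-point drift in the
incrementally maintained totals is controlled by periodic full rebuilds.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| temperature | 300 | K | comparison temperature of the energy model |
| viscosity | 0.89e-3 | Pa·s | water near room temperature |
| c repeat | 4.8 | Å | canonical cross-beta strand spacing; not fixed by the published lattice constants, so configurable |
| total_peptides | 10⁴ | — | desk-scale; all reported observables are intensive (fractions, ratios), and per-aggregate rates depend on concentration, not peptide count |
| concentration | — | mol/L | imposed through $V = N/(c\,N_A)$ |
| max_time | 10⁴ | s | past the plateau of the 1D+ fraction at 5 mM (the plateau is reached once free monomers deplete; verified directly on trajectories) |
| max_events | 25·N | — | second stop criterion; assembly to plateau needs ~1–2 events per peptide plus churn |
| prune_threshold | 1e-50 | m³/s or 1/s | channels slower than this are dropped |
| live_floor | 1e-40 | m³/s | hot-array admission; see above, exactness preserved |
| seed | — | — | replicate r runs with seed + r; identical seeds give bit-identical trajectories |

Energies are entered in kcal/mol (table units); $k_BT$ = 0.596 kcal/mol at
300 K.  The in-plane angle γ is carried in the lattice description but the
rate kernels use orthogonal box dimensions — a deliberate simplification,
since only relative face areas enter the kinetics.

## Synthetic block energies

`synthetic_block_energies()` emulates the upstream workflow that produces
reference block free energies $G_{ijk}$ (ensembles of minimised blocks cut
from relaxed molecular-dynamics nanocrystals): it composes each block
energy additively from per-interface terms — with the herringbone overhang
deficit on P zipper planes — and adds Gaussian noise of chosen σ.  At σ = 0
the estimators invert it exactly; at σ > 0 recovery is tested against
directly propagated uncertainties.  What the generator does *not* emulate:
cooperativity beyond pairwise additivity, finite-size drifts of the
per-peptide energies, or correlated sampling error between block sizes.
Tests passing on these fixtures therefore validate the estimator algebra,
not the physics of any particular force field.

## What the simulation reproduces, and what it does not

Under the reference energies the sweep over 5 nM–50 mM (10 replicates,
10⁴ peptides) shows the expected regime structure, computed by
`sweep_assembly()`/`final_polymorph_mass()` and checked in the test suite:

* strongest AP dominance of final aggregated mass at nanomolar
  concentration, where only the AP zipper and hydrogen-bond dimer channels
  survive reversal while the weak nascent herringbone edges of P revert;
* a near-parity window around 0.5–5 µM;
* rising P 2D/3D mass fractions towards millimolar and above, as the strong
  P lateral interfaces ($\varepsilon$) lock in once nascent edges are
  rescued by collisions faster than they revert.

A strict sign change — final P mass exceeding AP at high concentration — is
*not* produced by this model with these parameters, and the package's
crossover extractor then reports the one-sided outcome rather than a
concentration.  The reason is structural: commitment is equiprobable,
polymorphs interact only through the monomer pool, and with the tabulated
hydrogen-bond energies (−25.3 and −29.3 kcal/mol per buried peptide) the
Arrhenius split times of 1D chains of either polymorph (10⁹–10¹³ s) exceed
every collision timescale in the sweep by many orders, so AP aggregated
mass can never decline in favour of P.  A genuine takeover would require P
single sheets to be reversible on collision timescales, which these energy
magnitudes rule out under the stated rate law.  `crossover_concentration()`
itself is exercised on synthetic series with real crossings.

## Numerical and design choices

* Internal units: lengths m (Å at the surface), rates m³/s and 1/s; the
  pruning threshold applies to rate constants in those units.
* Fastest-choice tie-break for compound cleavage decompositions; ties cannot
  arise for distinct plane pairs with attractive tables except by exact
  energy coincidence, in which case the first decomposition is kept.
* Degenerate inputs: empty or monomer-only states have only
  monomer–monomer channels; a state whose total propensity underflows
  terminates with status `"exhausted"`; zero-energy interfaces split at the
  attempt frequency $1/\tau_0$.
* Statistical uncertainties of the energy table are carried as metadata but
  not propagated into rates (kinetic runs use point values).
* Monomer-to-block c-axis addition uses the simple join when cross-sections
  match and the compound channel otherwise; no separate secondary-nucleation
  channel is modelled — lateral growth is hierarchical.
* Report times are log-spaced (default 60 points from 1 ns to the horizon);
  the final state is always recorded.

## Limitations

* No spatial correlations: the solution is well mixed, and aggregate
  diffusion enters only through collision kernels.
* No elastic degrees of freedom: twist/bend coupling to aspect ratio, which
  hinders hierarchical assembly of ribbon-like aggregates in the physical
  system, is outside the state space; cross-sectional aspect ratios are
  reported so that the propensity to such shapes can still be read off.
* No heterogeneous cross-polymorph nucleation (P nucleating on AP or vice
  versa); polymorphs couple only through monomers.
* Rotational diffusion and bead-model hydrodynamics of non-cylindrical
  shapes are not treated.
* Detailed balance between join and split channels is not imposed; the
  barrier model is kinetic, not an equilibrium sampler.
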