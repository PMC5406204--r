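---
title: "Contact-map CVs and well-tempered PT-metadynamics at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-map CVs and well-tempered PT-metadynamics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtmetad)
```

## What the package models

Large conformational transitions — the opening and closing of a kinase
activation loop, say — are rare events on molecular-dynamics
timescales. Two ideas make them tractable. First, a pair of
low-dimensional *collective variables* (CVs) measures how far a
conformation has travelled from each of two reference states, using a
contact map rather than raw coordinates: contacts are robust to
irrelevant motion and capture the formation and rupture of specific
interactions. Second, *well-tempered metadynamics* deposits a
history-dependent repulsive bias along those CVs so the system is
pushed out of free-energy minima it has already explored; run under
*parallel tempering* (a ladder of replicas at increasing temperature
with Metropolis configuration swaps), barriers orthogonal to the CVs
are crossed too. The accumulated bias converges, up to the known factor
$-f/(f-1)$, to the negative free-energy surface (FES).

This package implements that entire loop — contact selection, CV
evaluation and gradients, the biased sampler, FES reconstruction,
basin and cluster analysis, and the crystallographic side-analyses —
as ordinary R functions operating on synthetic structures and analytic
model landscapes. It deliberately does *not* implement an all-atom MD
engine: the sampler is overdamped Langevin dynamics, which has the same
stationary distribution and is the right cost point for validating the
analysis machinery.

## The collective variables

For a contact $\gamma$ between two atoms at distance $r_\gamma$, the
degree of contact formation is the sigmoid

$$D_\gamma(R) \;=\; W_\gamma\,
  \frac{1-(r_\gamma/r_{\gamma 0})^{n}}{1-(r_\gamma/r_{\gamma 0})^{m}},
  \qquad n = 6,\; m = 10,$$

with $r_{\gamma0}$ the contact distance in the reference conformation
the contact is specific for, and weight $W_\gamma = 1$ (3 for salt
bridges). Each CV is the normalised squared contact-map distance from
one reference:

$$\mathrm{CV}_k(R) \;=\; \frac{1}{N}\sum_{\gamma\in\Gamma}
  \bigl(D_\gamma(R) - D_\gamma(R^{(k)}_\mathrm{ref})\bigr)^2 .$$

Decisions worth stating explicitly:

* **Normalisation.** $N$ is conventionally introduced just as "a
  normalization constant"; we take $N = \sum_\gamma
  W_\gamma^2$, which bounds both CVs in $[0,1]$ and matches the
  observed working range of such CVs. No square root is applied: the
  CV is the normalised *squared* distance.
* **One sum, two references.** Both CVs run over the *full* set
  $\Gamma$; they differ only in the reference against which $D_\gamma$
  is compared. The alternative (per-CV contact subsets) would break the
  exact mirror identity $\mathrm{CV}_1(R^{(2)}_\mathrm{ref}) =
  \mathrm{CV}_2(R^{(1)}_\mathrm{ref})$ that we test.
* **$D_\gamma(R_\mathrm{ref})$ is measured**, from the reference's
  actual coordinates, not assumed equal to $W_\gamma$.
* **Removable singularity.** At $r = r_{\gamma0}$ the sigmoid has a
  $0/0$ limit of $n/m = 0.6$; within $|r/r_0 - 1| < 10^{-6}$ we switch
  to the first-order series $\tfrac{n}{m}(1 + \tfrac{n-m}{2}(u-1))$
  (and the matching series for the derivative), avoiding catastrophic
  cancellation while keeping the gradient continuous.

### Contact selection

`build_contact_set()` implements the selection protocol: candidate
pairs are Cα, Cβ or backbone O atoms (glycine contributes Cα and O
only) within 5 Å in either minimised reference; a pair is kept as
state-specific when it is present (within the cutoff) in at least 5 of
10 equilibrated ensemble members of one state *and* fewer than 5 of the
other; pairs passing the presence rule in both states are common and
discarded; $r_{\gamma0}$ is then measured on the single reference of
the pair's state. Named salt-bridge pairs are appended with weight 3.
One choice is ours: candidate pairs must be at least 3 residues apart
in sequence (standard contact-map practice; trivially-always-formed
local contacts would otherwise be discarded anyway by the common-pair
rule, but excluding them up front keeps candidate sets small and the
planted-recovery tests exact).

## The sampling engine

The engine propagates one walker per ladder temperature with the
overdamped (Brownian) update

$$x \leftarrow x - \frac{\Delta t}{\gamma}\nabla\!\left(U + V\right)
  + \sqrt{\tfrac{2 k_B T \Delta t}{\gamma}}\;\xi,$$

either directly in CV space on an analytic model potential, or (in
structure mode) on a coarse bead structure where the bias force enters
through the chain rule with the analytic CV gradients and an elastic
network holds the beads together.

Key parameters (defaults in `engine_params()`):

| parameter | default | unit | why |
|---|---|---|---|
| temperature ladder | 300, 310, 320, 330, 341, 352, 363, 375, 387, 400 | K | the emulated protocol's 10-replica ladder |
| hill width σ | 0.05 per CV | CV units | the emulated protocol's Gaussian width |
| initial height W₀ | 5 kJ/mol = 1.195 kcal/mol | kcal/mol | the emulated protocol's value, converted once at the boundary |
| bias factor f | 10 | — | the emulated protocol's well-tempering factor |
| deposition period | 2 ps | ps | the emulated protocol's hill stride |
| timestep Δt | 0.02 | ps | stable for the stiffest default curvature |
| friction γ | 500 | 1/ps | walker diffuses one well width in a few deposition periods |

The height law is $W = W_0\,e^{-V/(k_B (f-1) T)}$; the denominator is
written with $k_B$ explicit so that it is an energy, as dimensional
consistency requires. Hills are deposited from the lowest-temperature replica
only and the single accumulated bias acts on every replica
(multiple-walker-style sharing); the exchange acceptance
$p = \min(1, e^{(\beta_i-\beta_j)(U_i^+ - U_j^+)})$ uses energies that
include all static bias terms. Exchange attempts alternate even/odd
neighbour pairs at a fixed stride (1 ps), the standard scheme when only
target rates are specified. A ladder-tuning utility rescales the
geometric spacing to a target acceptance.

The *well-tempered ensemble* preliminary stage
(`precompute_energy_bias()`) biases the potential energy alone with 1-D
hills, freezes the accumulated table, and applies it additively (never
updated) in production; its `scale` knob lowers the bias to tune the
production exchange rate downward. The protocol this stage emulates is
specified only by its purpose and its target exchange rates; 1-D
well-tempered hills on $U$ are the canonical realisation.

**Numerics.** The production inner loop is compiled (Rcpp). The bias
and its analytic gradient are accumulated on a grid (spacing 0.01 CV
units, Gaussians truncated at 6σ where the tail is below $10^{-7}$ of
the height) and interpolated bilinearly during dynamics — O(1) per
step instead of O(hills). The exact analytic sum
(`bias_potential_and_force()`) remains the reference implementation and
the oracle the grid cache is tested against. Randomness: each replica
owns a private compiled RNG stream derived from the root seed, and
exchange decisions use a separate stream, so every output is bitwise
reproducible from the seed and the base replica's unbiased path is
independent of the ladder size.

## FES reconstruction and analysis

`fes_from_hills()` evaluates $\hat F = -(f/(f-1))V$ on a regular grid
and shifts the minimum to zero; no time-dependent offset reweighting is
applied (none is described for the procedure we operationalise). 1-D
profiles are Boltzmann marginals at the grid temperature, computed with
a stabilised log-sum-exp. Convergence follows the trailing-window rule:
the surface (2-D and both 1-D projections, low-free-energy region only,
default cap 10 kcal/mol) must change by no more than 2 kcal/mol when
the trailing fraction of hills (default 10 % of deposition time,
generalising "the last stretch" of a μs-scale run) is added.

Minima are cells strictly below all 8 neighbours; equal-valued plateaus
count once (lowest cell index) and only when no plateau cell borders a
lower cell. Basins are 4-connected flood fills within a depth window
(default 2 kcal/mol) grown in ascending minimum order, so watershed
cells belong to the deeper basin; rectangular CV-space basins are
supported as the alternative reading of hand-drawn basin boundaries.
Basin free energies are $-k_BT\log$ Boltzmann cell sums, so a basin
twice the area at equal depth is $k_BT\ln 2$ lower — the worked README
example shows why a basin gap is smaller than the corresponding
minimum-depth gap.

Frames are assigned to basins with no reweighting, frames on a cell
boundary going to the lower-index cell. Clustering is the gromos
algorithm (iterative max-neighbour extraction at a 2 Å Cα-RMSD cutoff,
pairwise superposition per frame pair, ties to the lowest frame index),
medoids minimise the summed RMSD to the other members. Occupancy tables
classify interactions as strong above 75 % and weak at 60–75 %; the
underlying interaction criterion is a declared choice — minimal
distance ≤ 4 Å between side-chain N/O atoms, mirroring the 4 Å
crystal-contact criterion — because no explicit cutoff is stated for
the occupancy tables we emulate. It is configurable, and the coarse
test fixtures use an explicit Cβ filter instead since they carry no
side-chain N/O atoms.

## Crystal module

Symmetry operators act in fractional coordinates; REMARK 290 SMTRY
records (orthogonal convention) are converted through the cell on
input. A built-in table covers P1, P2₁ and P2₁2₁2₁ — the last provides
the four-operator case whose 2×2×1 supercell holds 16 molecules.
Contact maps list, per symmetry image (operator + lattice shift), all
residue pairs with any-atom minimal distance under 4 Å; image bounding
boxes are pruned at criterion + 2 Å, which cannot lose a true contact.
Both the per-neighbour detail and a merged residue-pair view are
provided, since published contact maps may show either.

## What the synthetic generators do and do not emulate

The generators plant *known* structure so every analysis step has a
closed-loop recovery test:

* `make_two_state_references()` builds two reference conformations on a
  12 Å residue grid with planted CA–CA contacts closed (4.5 Å) in one
  state and open (12 Å) in the other, residue triads collinear along
  the contact axis so exactly one atom pair per planted residue pair
  falls under the 5 Å candidate cutoff, plus Gaussian ensemble noise
  (0.15 Å). This makes contact-selection recovery exact by
  construction.
* `sample_landscape_trajectory()` is a Metropolis sampler on an
  analytic landscape with per-frame basin labels; its occupancies are
  checked against direct quadrature of the Boltzmann weights, and it is
  only a valid equilibrium sampler when barriers are of order $k_BT$.
* `make_crystal_fixture()` isolates planted residues geometrically so
  the contact map must recover exactly the planted inter-image pairs;
  infeasible plantings fail loudly rather than silently overlap.
* `make_harmonic_trajectory()` draws i.i.d. Gaussian displacements with
  per-coordinate variance $k_BT/k$, so RMSF $=\sqrt{3k_BT/k}$ exactly.

What they do **not** emulate: real protein geometry and chemistry
(side chains beyond a pseudo-Cβ, secondary structure, excluded volume
beyond the walk), correlated thermal motion (harmonic frames are
i.i.d., so fitted RMSF is biased low by the 6 removed rigid degrees of
freedom — about 2 % at 90 atoms, within the 5 % tolerance we test),
force-field energetics, and the actual contact list of any real kinase.
A green test suite therefore certifies the *machinery* — selection
rules, estimators, classifiers, symmetry algebra — not the biology of
any particular system.

## Problem sizes and runtimes

The packaged checks run the double-well recovery at $2\times10^6$ steps
(20 000 hills, a few seconds compiled), clustering oracles at 200
frames, occupancy recovery at 200 frames, exchange statistics at
$10^5$ trials, and RMSF recovery at $10^4$ frames of a 90-atom chain —
sizes chosen so the full suite and the acceptance script each finish in
minutes on one CPU while keeping every stochastic tolerance at 3σ or
tighter.

## Known limitations

* Overdamped dynamics means no kinetics: rates, committors and
  Markov-state analyses are out of scope by design.
* The FES estimator applies no reweighting of biased trajectories; all
  basin populations quoted from biased runs inherit that choice.
* The structure-mode sampler uses an elastic network, adequate for
  exercising the CV-gradient chain rule, not for folding realism.
* Whether hills are deposited from all replicas, and which salt
  bridges augment a given contact set, are left open by the emulated
  protocol; the first is a flag (single-walker default), the second an
  explicit input list.
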