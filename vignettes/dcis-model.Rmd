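---
title: "A lattice model of DCIS morphogenesis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lattice model of DCIS morphogenesis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(dcispotts)
```

## The model

`dcispotts` simulates the growth of ductal carcinoma in situ (DCIS) inside
a two-dimensional mammary duct with a cellular Potts model (CPM; the
Glazier–Graner lattice framework). Each cell is a domain of lattice pixels
sharing an integer index $\sigma$; the duct bilayer consists of luminal
epithelial cells (LEP) enclosed by myoepithelial cells (MEP), with culture
medium inside (the lumen) and outside. One Monte Carlo step (MCS) gives
every lattice pixel one chance to copy a neighbouring index over itself; a
copy attempt that changes the effective energy by $\Delta H$ is accepted
with probability $\min(1, e^{-\Delta H / T_m})$, where the temperature
$T_m$ sets the scale of the membrane fluctuations (the intrinsic cell
motility).

The effective energy is

$$H = \sum_{\text{neighbouring pixels } i,j} J\big(\tau(\sigma_i), \tau(\sigma_j)\big)\,\big[\sigma_i \neq \sigma_j\big]
  + \sum_{\text{cells}} \lambda_V (V - V_t)^2
  + \sum_{\text{cells}} \lambda_S (S - S_t)^2
  + \sum_{\text{links } ij} \lambda_{ij} (l_{ij} - L_{ij})^2 .$$

* **Adhesion.** $J(\tau_1,\tau_2)$ is the adhesion energy per unit contact
  area, negative for binding. The default hierarchy
  $J_{LL} = -20 < J_{LM} = -10 < J_{MM} = -5$ encodes differential
  E-cadherin expression and drives the sorted bilayer. Pairs involving
  medium or necrotic debris are always zero. The contact sum runs over
  first-order (4-neighbour) pixel faces; with negative $J$ a
  higher-order contact sum roughly doubles the drive toward boundary
  interdigitation against $\lambda_S = 1$ and destabilises the
  high-adhesion regime, so the first-order convention is used
  throughout.
* **Volume.** Every cell carries a target area $V_t = 78.5$ px (a disk of
  diameter 10 px at the model scale of 1 px = 1 µm) and a stiffness
  $\lambda_V$ (5 for LEP, 10 for MEP — atomic-force measurements put the
  MEP Young's modulus at about twice the LEP one).
* **Surface.** $S$ counts first-order (4-neighbour) boundary faces;
  $S_t = 31.4$ px is the circumference of the target disk and
  $\lambda_S = 1$ keeps cells cohesive without rigidifying them.
* **Contractile springs.** Focal-point-plasticity (FPP) links connect the
  centers of mass of neighbouring epithelial cells with target lengths
  *below* the resting distance (8 px for LEP–LEP and LEP–MEP, 5 px for
  MEP–MEP), so the springs model cell contraction; spring constants are
  50 for homotypic and 5 for heterotypic pairs (a 10-fold ratio). Each
  cell holds at most two links, which establishes planar polarity along
  the layer.

### The biological event layer

Three rules run on top of the Metropolis dynamics:

* **Mitosis.** Every `mitosis_interval` MCS, one quarter of the live LEP
  are chosen at random and divide by an instantaneous straight cut
  through the center of mass (daughters inherit the parent's targets; no
  growth phase is modelled, so a divided cell regrows toward $V_t$ under
  the volume constraint). Rounds fire at the *start* of each interval
  (MCS 0, $i$, $2i$, ...), the convention of scheduled steppables in
  lattice simulation platforms, so the final round's daughters integrate
  into the tissue before the run ends. Running 1000 MCS with intervals
  of 100 to 33 MCS gives the standard 10–30 mitotic events. The cut orientation is
  set relative to the local layer direction — the radial unit vector from
  the nearest point of the duct's medial axis: *perpendicular* divisions
  cut along the radial direction (both daughters stay in the layer),
  *parallel* divisions cut along the tangent (one daughter is pushed into
  the lumen), *random* divisions cut at a uniform angle.
* **Apoptosis.** Once per MCS, each live LEP counts the other live LEP
  whose centers of mass lie within 2.5 cell diameters (25 px). A cell
  with 10 or more such neighbours is overcrowded and is removed with a
  per-check probability of 0–1%; its pixels revert to medium immediately.
* **Necrosis.** A LEP whose center of mass lies 10 or more cell diameters
  (≥ 100 px, inclusive) from the nearest MEP pixel — roughly the oxygen
  diffusion limit from the nutrient source outside the duct — turns into
  necrotic debris: it stops adhering and linking but keeps occupying
  space.

### Morphology readout

A snapshot is classified by a fixed cascade: *comedo* if necrotic debris
is present; *solid* if the enclosed medium totals less than one cell
area; *cribriform* if at least two lumena remain **and** a path of
luminal (non-wall) LEP extends completely across the duct — two wall
cells touched by one 8-connected luminal component whose chord passes
within half a lumen radius of the duct axis; *micropapillary* if any
live LEP sits strictly inside the original monolayer (deeper than half a
cell diameter into the initial lumen, without MEP contact) while the
lumen is patent; otherwise *normal*. Lumena are 4-connected components
of enclosed medium, discarding pockets under half a cell area (50 px) as
lattice noise. Invasion is scored against the tissue periphery frozen at
MCS 0 and dilated by one cell diameter: a live LEP whose center of mass
lies beyond it is an invader, attributed to the end or duct region of
the nearest initial-footprint point; MEP-layer breaches without such a
cell are counted separately and are *not* invasion. Replicate sets are
summarised by the 80% consensus rule, with `mixed` otherwise.

## Parameters that matter, and how the defaults were set

All Table-style defaults above are exposed through `cpm_params()`. Three
quantities the model needs are not fixed by the printed parameter set;
they were chosen once, from control behaviour, and are documented here.

* **Temperature `temperature = 6`.** The printed energy scale leaves
  $T_m$ free. Two control behaviours pin its range: seeded squares must
  relax toward rounded cells within about 10 MCS, and an unperturbed duct
  (no proliferation) must keep a patent, uniform lumen over 3000 MCS. At
  $T_m \gtrsim 12$ the contractile rings creep inward by
  fluctuation-driven medium leakage until the monolayer spacing reaches
  the spring targets, at which point wall cells sit at the overcrowding
  threshold and any nonzero apoptosis erodes the duct — the control duct
  self-destructs, which contradicts its observed persistence. $T_m = 6$
  satisfies both controls with visible membrane fluctuation.
* **Link capture range `link_max_range = 20`** (two cell diameters).
  Springs are persistent junctions: a link breaks only when an endpoint
  dies or turns necrotic or the pair is stretched beyond this range, and
  free link slots rebind the nearest unlinked neighbours within it.
  Recomputing links from instantaneous contacts instead lets momentarily
  separated cells lose their springs permanently, and the MEP sheath
  visibly disintegrates within a few hundred MCS.
* **Crowding counts LEP only.** The overcrowding rule counts neighbours
  of the crowded luminal compartment. After the springs contract the
  monolayer to its equilibrium spacing (~8–9 px), including MEP in the
  count would put every wall cell of a *normal* duct at 11–13 neighbours,
  i.e. permanently above the overcrowding threshold of 10 — the control
  duct would dissolve at any nonzero apoptosis probability. Counting LEP
  only leaves the intact monolayer at about 6 and filled regions above
  20, which reproduces the persistent control.

Division cuts are exact pixel partitions, so volume is conserved at every
division; daughters enter at half the parent's area and regrow, which
makes each division inject one cell area of growth pressure over the
following MCS rather than instantaneously.

## Tissue geometries

`duct_circle()` builds the duct cross-section as a closed rectangular
ring of exactly 50 LEP squares (13 × 14 cell grid) inside a ring of 58
MEP squares — a square lattice cannot tile a circular ring with exact
10 × 10 squares, and the contractile springs round the ring within a few
hundred MCS anyway. `duct_cylinder()` is the longitudinal section: a
300 × 50 px lumen strip walled by LEP, capped at both tips, with MEP
outside; `duct_bifurcation()` joins three such half-ducts at 45°, with
cells obtained by k-means partition of the monolayer bands into ~100 px
compact clusters. Cylinder and bifurcation dimensions are not fixed by
the source material and are configurable; the defaults above match the
engineered-tissue aspect visually, and only region-relative quantities
(end versus duct) are ever compared. End regions extend one lumen
diameter (50 px) along the duct from each free tip; the circular duct is
all duct region.

## What the simulations do and do not show

The phase behaviour reproduced by the package — solid filling at high
proliferation without apoptosis, comedo once the filled duct outgrows
the oxygen distance, micropapillary maintenance under 1% apoptosis, and
occasional cribriform bridging that increases with division count — is
an emergent property of the energy function and the three event rules.
Two printed behaviours are *not* reproduced and are flagged as failing
checks in the test suite rather than hidden: under the default
parameters the tubular tissues develop MEP breaches but no cells escape
the sheath (so the reported preference for end-region invasion
degenerates), and the contractility presets invert — the soft,
spring-free limit disperses under division pressure where the published
tissues stay inert, while the stiff, strongly contractile limit stays
sealed where the published tissues invade from the duct. The published
invasion phenotype is attributed to contraction-generated mechanical
stress, an emergent effect that evidently depends on platform kinetics
not recoverable from the printed parameter set; the adhesion presets
(invasion everywhere with adhesion off, none with strong adhesion) do
reproduce. The model contains no
basement membrane, stroma, nutrient field, intraductal pressure, or 3D
structure; "invasion" here means LEP displaced beyond the tissue
periphery after a MEP breach, which in vivo would additionally require
basement-membrane degradation. Necrosis is a sharp distance rule, not a
reaction–diffusion computation. Synthetic tissues start from idealised
square cells; none of the image-analysis steps applied to real histology
are modelled. Consequently, agreement with printed phase diagrams shows
the *rules* suffice to generate the morphologies, not that the
parameters are calibrated to any patient tissue.

## Numerical choices and degenerate inputs

* Copy attempts draw the target pixel uniformly from the lattice interior
  and the source from its 8-neighbourhood; the one-pixel boundary frame
  is immutable medium (no periodic wrap — tissues are finite and
  surrounded by medium).
* The incremental $\Delta H$ is exact: unit tests compare it against a
  full recomputation to $10^{-9}$ over random proposals, including
  proposals that annihilate a cell (the volume and surface terms then
  reference zero size, and the cell's links retire with it; a retired
  index never reappears).
* A division cut that leaves one side empty (a degenerate direction)
  falls back to an ordered half-split of the pixels; cells below 2 px
  skip division with a warning.
* Link maintenance, lumen labelling and the classifier are deterministic;
  ties in link candidates break on distance then agent index, so a seeded
  trajectory is bitwise reproducible.
* With no MEP left the necrosis distance is undefined; the rule is
  skipped with a warning rather than guessed.

## Replicates and problem sizes

Morphology outcomes are stochastic; conditions are summarised over seeded
replicates with the 80% consensus rule. The package's own test suite runs
reduced designs chosen to finish quickly — typically 3–6 replicates per
condition for consensus checks, 10–20 for the cribriform fractions, runs
of 1000–2000 MCS, and a 200 px cylinder for invasion — while
`scripts/acceptance.R` rebuilds the headline cribriform fractions at 40
replicates per event level and 1000 MCS on the full circular duct. The
strict 20 < 25 < 30 ordering of the cribriform fractions is resolvable
only at the larger replicate counts; reduced designs assert the binomial
bands and the overall increase. All replicate seeds are derived
deterministically from a single base seed and logged in the results.

## Session info

```{r}
sessionInfo()
```
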