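---
title: "Modelling matrix-mediated vasculogenesis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling matrix-mediated vasculogenesis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculogen)
```

## The model

During early vasculogenesis, angioblasts — endothelial precursor cells —
coalesce into a polygonal network, the primary vascular plexus. The package
implements a two-scale model of that process built on a paracrine
hypothesis: VEGF is produced not by the angioblasts themselves but by an
adjacent tissue layer, uniformly over the domain, and acquires its spatial
information only by binding to extracellular-matrix (ECM) molecules that the
angioblasts deposit. Matrix-bound VEGF is immobile, protected from
degradation, and is the dominant chemotactic cue.

### Reaction-diffusion fields

Three co-registered fields live on the lattice: soluble VEGF $s$, free ECM
binding sites $e$, and bound VEGF $b$:

$$
\begin{aligned}
\partial_t s &= D \nabla^2 s + \alpha_V - k\, s\, e - \gamma_s s,\\
\partial_t e &= \alpha_E\, \theta(\sigma) - k\, s\, e,\\
\partial_t b &= k\, s\, e,
\end{aligned}
$$

where $\theta(\sigma) = 1$ at cell-occupied sites and $0$ elsewhere. Binding
follows mass action with a single effective second-order rate $k$; there is
no unbinding, no saturation, no enzymatic or cooperative kinetics, and bound
VEGF is never degraded. Only $s$ diffuses.

### Cellular Potts dynamics

Cells are spatially extended, deformable domains of a square lattice sharing
an integer index; index 0 is the medium. The Hamiltonian is

$$
H = \sum_{\langle i j \rangle} J\big(\tau(\sigma_i), \tau(\sigma_j)\big)
      \,[\sigma_i \ne \sigma_j]
  + \lambda \sum_{c > 0} (a_c - A)^2 ,
$$

with boundary energies $J_{cc}$ (cell-cell) and $J_{cm}$ (cell-medium)
summed once per unordered neighbor pair of the chosen neighborhood order,
and an area constraint of stiffness $\lambda$ about the target area $A$
(the medium has no area term). A modified Metropolis scheme drives the
dynamics: per attempt a random target site and a random neighbor are drawn,
and the neighbor's index is copied into the target with probability 1 if
the total energy change $\Delta H \le 0$ and $e^{-\Delta H/T}$ otherwise.
One Monte Carlo step (MCS) is one lattice-size worth of attempts and
represents one second. Chemotaxis enters as a bias

$$
\Delta H \leftarrow \Delta H
  - \mu_b\,\big(b(\mathbf{x}_t) - b(\mathbf{x}_s)\big)
  - \mu_s\,\big(s(\mathbf{x}_t) - s(\mathbf{x}_s)\big),
$$

so extensions up-gradient (and retractions down-gradient) of VEGF are
favored, with a stronger response to the bound form ($\mu_b > \mu_s$).

Each MCS of cell dynamics is followed by one MCS worth of field
integration with the updated cell mask.

## Parameters

All defaults are returned by `referenceParams()` and can be overridden
individually; `inst/extdata/reference.yaml` carries the same values as an
editable configuration. Concentrations are in arbitrary units (a.u.)
because only the products $\mu_b b$ and $\mu_s s$ are dynamically
meaningful.

```{r params}
referenceParams()
```

Rationale for the key choices:

* **Geometry.** 400 x 400 lattice at 2 um per pixel (0.64 mm^2 of
  tissue), 1 s per MCS, for a total simulated hour at 3600 MCS scale.
  The reference cell density is 1100 cells per domain (about 1720
  cells/mm^2, the density measured in quail-embryo micrographs); the
  dynamics scenario uses a constant population of 800 cells
  (1250 cells/mm^2).
* **Target area** `ATarget = 100` px (400 um^2, isotropic diameter
  11.3 px = 22.6 um). This is the area of a spread angioblast on a planar
  substrate and reproduces vascular coverage near one half at the
  reference density; substantially smaller cells leave the initial mesh
  too sparse for the fast single-component closure that characterizes the
  biological process.
* **Potts energies** follow the conventions of published Potts models of
  vascular patterning: `Jcc = 40` with `Jcm = Jcc/2` so the cell-medium
  surface tension $J_{cm} - J_{cc}/2$ vanishes (cells neither round up in
  isolation nor engulf one another for adhesive reasons — patterning must
  come from chemotaxis), `lambdaArea = 25`, and fluctuation energy
  `TFluct = 35`, which sets membrane fluctuation amplitude large enough
  for cells to explore and bridge inter-cell gaps while keeping cells
  cohesive.
* **Chemotaxis budget** `muTotal = 1000` split 80/20 between bound and
  soluble VEGF (`muB = 800`, `muS = 200`), encoding the stronger
  signalling of the matrix-anchored form.
* **Reaction rates.** `alphaV = alphaE = 1e-3` a.u./s with
  `kBind = 0.5` make binding fast relative to production (the
  half-life of a free binding site against binding is seconds to minutes
  once soluble VEGF accumulates, versus the hour-scale production), so
  bound-VEGF tracks form promptly where cells reside; `gammaS = 3e-4`/s
  gives soluble VEGF a ~40 min half-life. These magnitudes were fixed
  once, during model development, such that the reference scenario
  reproduces the qualitative phenomenology that defines the modelled
  process — prompt coalescence into a single percolative network within
  the first ~1000 MCS followed by slow remodelling — and were not tuned
  further afterwards.
* **Diffusivity** `D = 50` um^2/s is at the literature scale for soluble
  VEGF isoforms in tissue. Network morphology is insensitive to it (the
  diffusivity sweep exists to demonstrate precisely that), so its exact
  value is uncritical.

## Numerical scheme

* **Operator splitting.** Per PDE substep the pointwise mass-action
  reaction update is applied first, then transport of $s$ (forward-Euler
  5-point Laplacian, or homogenization in the well-mixed mode).
  `pdeSubsteps = 64` substeps per MCS gives $dt = 1/64$ s, safely inside
  the explicit-diffusion stability bound $dt \le h^2/(4D) = 0.02$ s;
  the bound is enforced at parameter validation and again at run time.
* **Boundaries.** Zero-flux (mirror) boundaries: the simulated patch is a
  piece of tissue, not a torus. The discrete scheme conserves mass
  identically, which the tests verify to $10^{-10}$ relative.
* **Positivity.** A reaction substep large enough to overshoot a field
  below zero is rejected up front via the heuristic
  $dt \cdot k \cdot \max e < 1$; any residual negative excursion would be
  clipped to zero with a warning rather than silently.
* **RNG.** One seeded stream per simulation; placement, site choice,
  neighbor choice and Metropolis acceptance consume it in documented
  order, so runs are bitwise reproducible and a resumed run continues an
  uninterrupted one exactly.
* **Cell integrity.** Copies that would remove a cell's last pixel are
  rejected (no proliferation or death is modelled, so the population is
  constant). Copies that would split a cell into disconnected pieces are
  also rejected, using the local Yokoi simple-point test on the
  retracting cell: cells are connected subdomains by definition, and
  without the test cells shed transient single-pixel fragments that
  corrupt both the component count of the mask and the inertia-tensor
  cell lengths. The test is local (3 x 3), so it can in rare
  configurations reject a globally safe retraction; this errs on the
  side of integrity.

## Morphometry

The analysis suite quantifies a binary vascular pattern (vascular = 1):

* **Betti numbers.** Components are 8-connected foreground; lacunae are
  4-connected enclosed background regions (the standard dual pairing).
  Border-touching background is not a lacuna by default (a flag includes
  it for cropped micrographs). Both counters are cross-checked in the
  tests against flood-fill and Euler-characteristic oracles. Network
  analyses (`analyzePattern()`, `trackDynamics()`) additionally apply a
  4 px (16 um^2) lacuna floor: membrane fluctuation leaves transient
  one-pixel holes inside cells that a segmented micrograph could never
  resolve, and scoring them as avascular zones would bias simulated
  counts upward relative to the experimental pipeline. The raw
  `countLacunae()` keeps floor 1 so the Euler identity
  `beta0 - beta1 = chi` holds exactly.
* **Lacuna geometry.** Area is the pixel count. The perimeter is the
  polygonal length of the Moore-traced contour through boundary pixel
  centers (diagonal steps count $\sqrt 2$), and the isoperimetric
  quotient $Q = 4\pi A_\mathrm{poly}/P^2$ uses the shoelace area of that
  same polygon, capped at 1. Under this pairing a square hole scores
  exactly $\pi/4$ and a large rasterized disk about 0.87 (the traced
  chain overestimates smooth perimeters by roughly 5%). Degenerate
  lacunae without polygon interior (single pixels, one-pixel slits) fall
  back to the pixel-edge contour with pixel-count area, keeping
  $Q \in (0, 1]$. $Q$ is estimator-sensitive; this convention is fixed
  and documented precisely so values are comparable across analyses.
* **Skeleton.** Guo-Hall parallel thinning iterated to stability; it
  preserves the connectivity of foreground and background and hence both
  Betti numbers (verified on fixtures and random masks). Spanning length
  is the skeleton pixel count. Cord half-widths are Euclidean distances
  from skeleton pixels to the nearest avascular pixel (the image border
  counts as avascular).
* **Node graph.** Raw branch points are skeleton pixels with at least 3
  skeleton neighbors; segments are traced between branch points and
  endpoints. Because thinning over-reports branch points on thick cords,
  connected raw nodes are merged agglomeratively whenever their
  separation is strictly smaller than the larger of their local
  half-widths; merged nodes take centroid positions, internal edges are
  dropped, and degrees count the surviving incident edges. Ties (equal
  separation and width) do not merge, keeping the strict inequality.
* **Fractal measures.** Box-counting dimension and gliding-box
  lacunarity ($\Lambda(r) = \mathrm{var}/\mathrm{mean}^2 + 1$ of the box
  mass, population variance) over box sizes $2, 4, 8, \dots$ up to a
  quarter of the image side; the scalar lacunarity is the mean of
  $\Lambda$ over the series and the full curve is kept in the record.
  Both are computed on the thinned network by default (flag for the
  filled mask), matching the practice of measuring the network's
  space-filling rather than the cords' thickness.
* **Cell lengths.** Per cell, the covariance matrix of occupied pixel
  coordinates defines the moment-equivalent ellipse; the length is
  $4\sqrt{\lambda_1}$ (full major axis), normalized by the isotropic
  diameter $2\sqrt{A/\pi}$. A one-pixel cell has length one pixel.

## Scenarios, sweeps and problem sizes

`scenarioPreset()` bundles the two headline scenarios (reference, 1100
cells; dynamics, 800 cells; both 400 x 400 and 3000 MCS) with
density-matched scaled presets used by the test-suite and the acceptance
script: a 200 x 200 quarter domain (275 or 200 cells, 1500 MCS) for
dynamics-type analyses and the same quarter domain (200 cells, 1500 MCS)
for the parameter sweeps. The scaled sizes were chosen as the smallest
domains that still develop multi-lacuna reticular networks (about twenty
distinct lacunae above the speckle floor at the sweep scale), so that
replicate sweeps (sensitivity 0.1x/10x on each reaction rate, the three
transport modes, the bound/soluble chemotaxis split, and a six-point
density sweep) complete in desk time; each sweep uses 3 replicate seeds,
mirroring the replicate count of the original sensitivity design, and
the dynamics checks use 5. The sweep preset's cell count matches the
coverage (about one half) of the reference morphology rather than the
nominal reference count: coverage is the dimensionless quantity that
controls how lacunae respond to signalling perturbations, and
near-confluent patterns would enclose holes for purely geometric
reasons. Sweeps run the full 1500 MCS because the premature
immobilization caused by matrix overproduction separates from the
reference only once the remodelling phase is underway.

Critical points of the density sweep are estimated as stated operations on
the replicate-averaged curves: the percolation onset is the midpoint
between the last density at which the majority of replicates fails to
percolate and the first at which it succeeds, and the node/lacuna optima
are argmaxima of the mean curves. With a six-point sweep these estimators
are deliberately coarse; they order the regimes robustly but do not locate
thresholds to better than the grid spacing.

## What the fixtures emulate — and what they do not

The fixture module generates binary patterns of *known* topology and
geometry (grid networks with exact hole counts, rasterized primitives,
smoothed-noise masks of exact coverage) so that every morphometric
operation is testable against construction values rather than against the
code under test. Passing those tests certifies the measurement apparatus,
not the biology: fixtures have none of the texture of QH1-stained
micrographs (uneven illumination, mediolateral density gradients,
segmentation noise), so agreement between simulated and real networks must
always be established on segmented experimental masks supplied by the
user, for which `readMask()` is the entry point.

Simulated networks themselves emulate the *in vivo* situation only up to
the model's idealizations: constant cell population (no proliferation or
death, no differentiation), a single cell type, two dimensions, spatially
uniform paracrine production, and a single effective binding reaction.
Spatial heterogeneity of the embryonic tissue — which raises lacunarity
and right-skews cord widths in real images — is deliberately absent.

## Known limitations

* Closure of the dynamics scenario into a single connected component is
  diagnosed from snapshots every 100 MCS; transient single-pixel debris
  would defeat a strict component count, which is one reason cell
  connectivity is enforced in the kernel.
* Late-stage cells in cords elongate strongly; the far tail of the length
  distribution is sensitive to the chemotaxis-to-adhesion balance, and
  the bound-VEGF landscape keeps deepening over the simulated hour
  because the model has no unbinding or bound decay by construction.
* In the shipped parameter regime binding at cord sites is supply-limited
  (the local binding rate exceeds production and decay of soluble VEGF),
  so the network morphology retains some sensitivity to how the soluble
  pool is transported: suppressing diffusion entirely lowers the lacuna
  count relative to normal or well-mixed transport. Regimes in which
  local production alone saturates binding would be less sensitive.
* The node-merge correction uses each node's local half-width; on
  patterns whose cords are much wider than their lacunae are distant,
  merging can be aggressive and the node count correspondingly
  conservative.
* Percolation is defined on the pixel lattice; patterns that span via a
  single diagonal pixel chain count as percolative.
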