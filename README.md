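# vasculogen

Simulation and morphometric analysis of early embryonic vasculogenesis
under matrix-mediated paracrine VEGF signalling.

## The scientific problem

In the early vertebrate embryo, endothelial precursor cells (angioblasts)
coalesce into a polygonal network, the primary vascular plexus. The VEGF
that guides them is produced *paracrinely* by the adjacent endoderm — not
by the angioblasts themselves — and a freely diffusing signal from a
nearby tissue cannot, by itself, carry the fine-grained spatial
information that a reticular pattern requires. This package implements and
analyzes a model of the resolution of that paradox: angioblasts deposit
extracellular-matrix (ECM) molecules with VEGF-binding domains, the
diffusible growth factor is immobilized where cells have been, and
chemotaxis toward this *matrix-bound* VEGF supplies the spatially
restricted cue that drives coalescence, cord formation and remodelling.

The model couples two scales per Monte Carlo step (MCS, one simulated
second):

* a **cellular Potts model** of N deformable, motile cells on a square
  lattice, with Hamiltonian
  `H = sum_pairs J(tau_i, tau_j) [sigma_i != sigma_j] + lambda sum_cells (a_c - A)^2`
  and modified Metropolis dynamics (`P = 1` if `dH <= 0`, else
  `exp(-dH/T)`), biased by
  `-mu_b (b_target - b_source) - mu_s (s_target - s_source)`;
* a **reaction–diffusion system** for soluble VEGF `s`, free matrix
  binding sites `e` and bound VEGF `b`:
  `ds/dt = D lap(s) + alpha_V - k s e - gamma_s s`,
  `de/dt = alpha_E theta(cell) - k s e`, `db/dt = k s e`.

A morphometric suite quantifies the resulting binary patterns the way
vascular-network images are quantified: Betti numbers (components and
lacunae), lacuna size/roundness, coverage, percolation, skeleton spanning
length and cord widths, merge-corrected branch-point graphs with degree
distributions, interface length, box-counting fractal dimension and
gliding-box lacunarity. Segmented micrograph masks can be analyzed with
the same functions (`readMask()` + `analyzePattern()`).

## Worked example

A desk-scale dynamics run (200 x 200 lattice = quarter of the reference
domain, 200 cells, reference parameters) that tracks coalescence:

```r
library(vasculogen)
sc  <- scenarioPreset("dynamics-scaled", seed = 1L)
run <- runSimulation(sc$params, sc$nCells, sc$initMode,
                     totalMcs = 1500L, snapshotEvery = 300L)
trackDynamics(run)$series
```

```
   mcs nComponents nLacunae percolative
1    0         200        0       FALSE
2  300           7        9       FALSE
3  600           4        8        TRUE
4  900           1       17        TRUE
5 1200           1       22        TRUE
6 1500           1       22        TRUE
```

Reading: the 200 initially isolated cells (`nComponents = 200`) coalesce
within a few hundred MCS into a handful of clusters, percolate, and close
into a **single connected network** by ~900 MCS; afterwards the component
count stays at 1 while the number of lacunae (enclosed avascular holes,
the pattern's first Betti number) keeps growing — the slow remodelling
phase in which cells bridge existing holes and subdivide them. Full
morphometrics of the final mask:

```r
analyzePattern(cellMask(run@state), state = run@state, params = sc$params)
```

```
MorphometricRecord
  components 1, lacunae 22, coverage 0.490, percolative TRUE
  spanning length 2647 px, nodes 126, interface 5484 px
  fractal dimension 1.268, lacunarity 2.994
```

Scenario presets for the full-size runs (`"reference"`: 1100 cells on
400 x 400, 3000 MCS; `"dynamics"`: 800 cells) and the sweep drivers
(`sweepSensitivity()`, `sweepDiffusivity()`, `sweepChemotaxisRatio()`,
`sweepDensity()`) are documented in the methods vignette
(`vignettes/vasculogen-methods.Rmd`), together with every parameter
default and numerical convention. A thin command-line front end lives at
`inst/cli/vasculogen.R`
(`simulate | analyze | sweep | dynamics | fixtures`).

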