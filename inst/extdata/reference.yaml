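# Reference configuration: the headline network-formation scenario.
# 400 x 400 lattice at 2 um/pixel (0.64 mm^2 of tissue), 1 s per MCS.
#
# PDE rates (concentrations in arbitrary units, a.u.)
D: 50.0          # VEGF diffusion coefficient, um^2/s
alphaV: 1.0e-3   # soluble VEGF production, a.u./s, uniform (paracrine)
alphaE: 1.0e-3   # matrix binding-site production, a.u./s, inside cells
kBind: 0.5       # second-order binding rate, 1/(a.u. s)
gammaS: 3.0e-4   # soluble VEGF degradation, 1/s (bound VEGF never decays)
#
# Cellular Potts energies
TFluct: 35.0     # fluctuation energy (cell motility)
ATarget: 100.0   # target area, pixels (400 um^2)
lambdaArea: 25.0 # area-constraint stiffness
Jcc: 40.0        # cell-cell boundary energy
Jcm: 20.0        # cell-medium boundary energy (= Jcc/2: zero surface tension)
muTotal: 1000.0  # total chemotaxis strength
muB: 800.0       # toward bound VEGF (dominant cue)
muS: 200.0       # toward soluble VEGF
neighborOrder: 2 # Moore neighborhood for boundary energies
copyOrder: 2     # Moore neighborhood for copy attempts
#
# Geometry and scheduling
latticeSide: 400
pixelSize: 2.0   # um per lattice site
mcsSeconds: 1.0  # one Monte Carlo step = one second
pdeSubsteps: 64  # dt = 1/64 s <= pixelSize^2/(4 D) = 0.02 s
seed: 1
#
# Scenario
nCells: 1100     # ~1720 cells/mm^2, the measured embryo density
initMode: regular
totalMcs: 3000
fieldMode: normal
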