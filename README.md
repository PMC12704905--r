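# cableRT

Reciprocity-based prediction of neural responses to electric brain
stimulation.

## What problem this solves

Extracellular electric stimulation — an intracranial microelectrode, deep
brain stimulation, or transcranial AC/DC stimulation from the scalp —
changes a neuron's membrane potential through the spatial gradient of the
imposed extracellular potential over its morphology. The traditional
simulation route inserts that potential as a boundary condition on a
compartmental cable model and requires one full solve *per stimulation
site*. For subthreshold (linear) responses the reciprocity theorem inverts
the workflow: the membrane-potential change `ΔVm` of a target compartment
caused by an extracellular current `I_stim` at location `r` equals the
extracellular potential `Ve(r)` caused by injecting `I_stim` into that
compartment. One intracellular solve per frequency therefore yields the
response to stimulation from *every* location at once.

cableRT is aimed at computational neuroscientists who want to map
subthreshold stimulation sensitivity across space, frequency and cell
parameters, validate the reciprocity shortcut against the traditional
solver, or couple the linear stimulation effect into point-neuron network
models.

## The model in brief

Passive compartmental cable in the frequency domain,

    (diag(G_n + jωC_n) + L) V_m = I e_site,

with outward-positive membrane currents `I_m,n` that include the stimulus
at the injected compartment (Σ I_m,n = 0). Extracellular potentials follow
the point-source sum `Ve(r) = Σ_n I_m,n / (4πσ|r − r_n|)`, with the
monopole (`~1/r`, frequency-flat) and current-dipole
(`p cosθ / (4πσ r²)`) limits exposed directly. For a ball-and-stick cell
the somatic-current and dipole transfer functions are available in closed
form (`q² = 1 + jωτ_m`, `Y = q d_s²/(dλ)`):

    T_Is = −sinh(ql/λ) / (Y cosh(ql/λ) + sinh(ql/λ))
    T_ps = (λ/q) (cosh(ql/λ) − 1) / (Y cosh(ql/λ) + sinh(ql/λ))

For transcranial stimulation the package carries the same logic through a
head model: a lead-field matrix calibrated in mV per nA·µm (equivalently,
mV/µm of cortical-normal field per nA of electrode current), a
download-free concentric four-sphere head model to generate physically
consistent miniature lead fields, and a quasi-uniform-field solver for the
detailed-morphology control.

## Worked example

```r
library(cableRT)
cell <- buildBallAndStick(somaDiameter = 10, stickDiameter = 2,
                          stickLength = 1000, nSegments = 200)
mem <- PassiveMembrane(rm = 30000, ra = 150, cm = 1)

## one solve at 10 Hz for a unit (1 nA) somatic injection
sol <- solveIntracellular(cell, mem, site = 1, sinusoidStimulus(10))

## membrane response to 1 uA stimulation 50 um outside the soma
dvm <- vmResponseMap(sol, cell, obs = c(50, 0, 0), sigma = 0.3, iStim = 1000)
Mod(dvm[1, 1])
#> peak dVm: 3.90 mV

## cross-check against the traditional boundary-condition solve
rtConsistencyCheck(cell, mem, target = 1, esPoint = c(50, 0, 0),
                   sigma = 0.3, frequency = 10)
#> relative discrepancy vs traditional solve: 1.1e-13

## current-dipole moment per nA of somatic input, and the tES response
p <- dipoleMoment(sol, cell)
Tps <- momentVectors(p)[3, 1] / injectedCurrent(sol)[1]
Mod(Tps)
#> |T_ps|(10 Hz) = 426 nA um per nA
lead <- makeLeadFieldFixture()          # four-sphere-derived miniature lead field
max(tesVmMap(lead, electrode = "E1", Tps, iTes = 1))
#> max somatic response to 1 mA tES: 124.70 uV
max(corticalField(lead, "E1", iTes = 1)@Ecn)
#> max E_cn: 0.292 mV/mm
```

Reading the numbers: a 1 µA, 10 Hz point source 50 µm from the soma moves
the somatic potential by ~3.9 mV — and the reciprocity route reproduces
the traditional solver to round-off. The same cell's dipole transfer (426
nA·µm per nA at 10 Hz) scales the head model's cortical-normal field map
into a membrane-response map: ~0.3 mV/mm of field becomes ~10² µV of
somatic polarization per mA of scalp current, far below spiking threshold.

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "cablert", package = "cableRT"))') \
    predict-es --ball-and-stick 10,2,1000,200 --es-point 50,0,0 \
    --frequency 10 --i-stim 1000
```

Subcommands: `predict-es`, `check-rt`, `ve-map`, `bas-analytic`,
`tes-map`, `make-fixtures`.

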