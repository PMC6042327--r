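# sgtadimer

Integrative biophysical analysis of open and closed states of the SGTA
homodimer — and of multidomain homodimers like it.

SGTA is a co-chaperone that captures hydrophobic clients in the cytosol. Each
313-residue protomer has a rigid N-terminal dimerization domain, a rigid
central TPR domain and a partially helical C-terminal substrate-binding
region, connected by flexible linkers. The N-terminal dimer contact is
obligate; the open question is whether the two C-terminal regions also
dimerize in the full-length protein, closing the dimer into a ring that could
grip substrates like tweezers. No single solution technique settles this, so
the evidence comes from the *joint* behaviour of four of them. This package
implements that entire cross-technique argument as testable code:

* **Conformer generation** — coarse-grained (one bead per residue) dimer
  ensembles with an open/closed switch: rigid domain templates, self-avoiding
  flexible linkers, an obligate N-terminal contact and a switchable
  C-terminal closure contact.
* **SAXS** — Debye forward model `I(s) = Σᵢⱼ wᵢwⱼ sinc(s·rᵢⱼ)`, Guinier fits
  (`Rg = √(−3·slope)` of ln I vs s²), regularized indirect transform to the
  pair-distance distribution P(r), Dmax estimation, Porod volume
  `Vp = 2π²I₀/Q`, Kratky transform, forward-scattering molecular weight, and
  EOM-style genetic-algorithm ensemble selection.
* **DEER/PELDOR** — powder-averaged dipolar kernel
  (`ν_dd = 52.04 MHz·nm³/r³`), four-pulse trace simulation with homogeneous
  3D background, background correction, and non-negative Tikhonov inversion
  `P = argmin ‖KP − S‖² + α²‖LP‖², P ≥ 0` with L-curve α selection.
* **NMR relaxation & shifts** — per-residue exponential T1/T2 fits, domain
  rotational correlation times `τc = (1/4πν_N)·√(6·T1/T2 − 7)`,
  heteronuclear NOE, chemical-shift perturbation
  `Δδ = √(ΔδH² + (0.14·ΔδN)²)`, and chemical-shift-index secondary-structure
  calls against a shipped random-coil reference.
* **Native MS** — positive-ion charge-series assignment, neutral-mass
  deconvolution, oligomer assignment, and detection of repeated-adduct mass
  ladders (the dimer + n × ~359 Da pattern).
* **Workbench** — a fully seeded virtual experiment that generates open and
  closed ensembles, simulates all four data types, and evaluates the four
  closed-state signatures.

## Worked example

```r
library(sgtadimer)
report <- run_virtual_experiment(
  default_experiment_config("closed", seed = 1, n_per_state = 40))
print(report)
```

```
Virtual experiment: closed vs open baseline (hash 12f3ce0c )
  pofr_peak  scenario   0.192  open   0.140  PASS
  eom_rg     scenario   3.216  open   3.625  PASS
  tpr_tc     scenario  12.006  open   9.417  PASS
  deer_mode  scenario   6.643  open   7.323  PASS
```

Reading the four lines: the closed ensemble's unit-area P(r) packing peak is
higher than the open baseline's (a more organized, compact particle); the
EOM-selected sub-ensemble's mean Rg (nm) falls well below the mixed pool's
average (only compact conformers fit closed-state scattering); the TPR
domain's rotational correlation time (ns) rises when the domain is clamped by
a closed C-terminus; and the C-proximal interspin DEER mode (nm) shortens.
Running the same experiment with `scenario = "open"` leaves all four
signatures unlit — the logic does not fire on a null comparison.

The numbered scripts under `analysis/` walk the same pipeline stage by stage
(ensembles → SAXS/EOM → DEER → NMR → native MS → virtual experiment), each
printing what it found and writing tables under `results/`.

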