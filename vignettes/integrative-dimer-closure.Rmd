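---
title: "Methods: integrative detection of C-terminal closure in a multidomain homodimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative detection of C-terminal closure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

SGTA is a homodimeric co-chaperone of 313-residue protomers: a rigid
N-terminal dimerization domain, a rigid central TPR (tetratricopeptide-repeat)
domain, and a partially helical C-terminal substrate-binding region, joined by
flexible linkers. The N-terminal dimer contact is obligate. The question this
package addresses computationally is whether the two C-terminal regions also
dimerize in the full-length protein — a "closed" conformation — and what
fingerprint such closure leaves in four solution techniques measured on the
same molecule: small-angle X-ray scattering (SAXS), pulsed dipolar EPR (DEER),
NMR spin relaxation, and native mass spectrometry.

No single technique is decisive, so the package implements each forward model
and each inverse analysis, plus a coarse-grained conformer generator whose
open/closed switch provides ground truth. The workbench then asks: starting
from simulated data alone, do the four published signatures of closure emerge?

1. a more pronounced domain-packing peak in the SAXS distance distribution;
2. an ensemble-optimization (EOM) selection whose mean radius of gyration
   falls below the conformer-pool average;
3. a larger rotational correlation time for the central TPR domain;
4. a shorter interspin distance between C-proximal spin-label sites.

## Coarse-grained conformer generation

One bead per residue at the CA position, uniform scattering weight, 0.38 nm
virtual bonds, 0.34 nm clash diameter. Rigid domains are placed as rigid-body
transforms of idealized helical-bundle templates (ideal alpha-helices at
exactly 0.38 nm CA spacing, joined by equal-chord circular arcs, laid out
deterministically); flexible segments grow as self-avoiding walks with uniform
direction proposals and limited backtracking out of dead ends. The default
architecture places explicit flexible linkers (rigid 1-65, linker 66-86, rigid
87-206, linker 207-212, flexible 213-313): relaxation and heteronuclear-NOE
data bound the rigid cores to roughly residues 5-65 and 87-205/206, so the
construct-boundary residues are modelled flexible. Templates are synthetic
stand-ins with the correct residue counts — crystallographic domain structures
can be substituted via the `templates` argument of the builders.

Dimers are assembled by building chain A through its last linker, sliding a
randomly oriented copy of the N-terminal template along a random direction
until just clash-free (accepted only inside the 1.5 nm centre-centre contact
distance), growing chain B likewise, and growing the two C-terminal tails
last. In the closed state both tails are steered towards a mutual rendezvous
point placed *beyond* the chain ends on the side away from the N-terminal
dimer — the closed molecule is a ring, not a collapsed globule — and the
conformer is accepted only if the two C-terminal segment centres fall within
the contact distance; otherwise the whole dimer is rebuilt, so closure
genuinely conditions the base geometry (chains whose TPR domains drifted far
apart rarely close). The 1.5 nm centre-distance contact criterion is a
modelling convention, not an inference: the geometry of the C-terminal dimer
interface is unknown, and the threshold is exposed in the architecture config.

Randomness: a single integer seed per pool; conformer *i* uses the derived
stream seed `(seed * 48271 + i) mod (2^31 - 1)`, so pools are bit-reproducible
and any single conformer can be regenerated in isolation.

**What the generator does and does not emulate.** It reproduces the
architecture's connectivity, excluded volume, the obligate/optional contact
logic, and realistic size scales; it does not model side chains, residual
helicity of the C-terminal tail, spin-label rotamers (labels sit on the CA),
or any energetics. Tests passing on this generator therefore validate the
*analysis pipelines* and the *logical structure* of the closure argument — not
atomic-level accuracy of any conformer.

## SAXS

Momentum transfer is `s = 4 pi sin(theta) / lambda` in 1/nm, distances in nm;
angstrom input is accepted behind an explicit flag. The forward model is the
Debye sum `I(s) = sum_ij w_i w_j sinc(s r_ij)` (exact by default; a 0.01 nm
pair-distance histogram evaluation for conformer pools, indistinguishable at
SAXS resolution). Guinier fits are weighted linear fits of `ln I` vs `s^2`
with a self-consistent range search capped at `s Rg <= 1.3` by default; the
conventional 1.3 cap carries a percent-level systematic on globular shapes, so
oracle tests that demand 0.1% agreement fit inside `s Rg <= 0.25`, where the
expansion is valid. The indirect transform solves a non-negative, endpoint-
anchored, second-difference-regularized least-squares problem on a 101-point
r grid via an in-package FNNLS solver (exact KKT at convergence); the
regularization weight defaults to the L-curve corner (triangle method on
axis-normalized log-log coordinates: the interior point farthest from the
endpoint chord on its convex side). `Dmax` is estimated by scanning candidate values
and taking the smallest one beyond which the back-transform fit quality
plateaus (10% relative slack plus a small absolute slack so the plateau is
detectable on near-noiseless data). The Porod invariant integrates `s^2 I`
with an `A/s^4 + B` tail fit over the last half-decade; `Vp = 2 pi^2 I0 / Q`.
EOM selection is a genetic algorithm over index multisets (population 100,
200 generations, mutation 0.05, elitism 10 at study scale; smaller,
config-recorded values at desk scale) minimizing reduced chi-squared after an
optimal multiplicative scale; when a curve carries no uncertainties, 1% of I
is assumed and flagged.

The synthetic noise model is Gaussian with `sigma = f (I + 0.01 max I)`: the
additive floor mimics detector/background noise and keeps weights finite at
form-factor minima, where a purely multiplicative model would assign
unphysical near-infinite weight.

## DEER

The dipolar kernel is the powder average
`K(t, r) = \int_0^1 cos[(1 - 3x^2) omega(r) t] dx` with
`omega(r)/2pi = 52.04 MHz nm^3 / r^3` (nitroxide, g ~ g_e). The integral is
evaluated in closed form through Fresnel integrals (exact at every phase; a
fixed 1001-point Gauss-Legendre rule is kept as an independent cross-check
method, but dephases for short distances combined with long evolution times)
and cached per grid pair. Traces follow
`V(t) = [1 - lambda + lambda (KP)(t)] exp(-k t)` (homogeneous 3D background)
with the four-pulse timing used for this system (16 ns steps, 7-8 us
windows). Background correction fits the log-linear tail (final 65% by
default), then performs one refinement pass: a coarse inversion supplies the
form factor, and `(k, lambda)` are re-fitted over the whole trace, removing
the depth bias caused by residual dipolar oscillation in the tail window.
Inversion is non-negative Tikhonov (second-difference penalty, FNNLS,
renormalized to unit integral) on a 1.5-10 nm, 201-point grid (reported
distances reach ~7.4 nm); the regularization parameter comes from the L-curve
corner unless fixed. Distribution statistics report local maxima above a 5%
prominence threshold with watershed mass splitting. Excitation-bandwidth and
orientation-selection corrections are omitted: published analyses of this system used
standard defaults and published no parameters for them.

## NMR relaxation and chemical shifts

Per-residue `I(t) = I0 exp(-t/T)` fits use Levenberg-Marquardt least squares
with log-linear starting values; the default delay schedules are the
published 11 inversion-recovery and 10 CPMG delays. Domain summaries average
converged T1 and T2 over an inclusive residue range (defaults NT 5-65 and TPR
87-206; published analyses of this system report both 206 and 205 as the upper TPR bound — the
equation paragraph's 206 is used, and the one-residue discrepancy changes
nothing at test tolerances) and convert via the isotropic-tumbling relation
`tau_c = (1/(4 pi nu_N)) sqrt(6 T1/T2 - 7)`, in ns. The 15N frequency `nu_N`
is always an explicit argument — data were recorded at several fields, so no
default is assumed. The synthetic generator inverts the relation exactly
(choose T1, solve for T2), making the noiseless round trip an identity.
Heteronuclear NOE is the saturated/equilibrium intensity ratio with explicit
exclusion lists. CSP uses the standard combined amide shift
`sqrt(dH^2 + (0.14 dN)^2)`; the 0.14 nitrogen weight is the conventional
choice — no single combination formula is standard — and it is exposed as
an argument. CSI compares Calpha/CO shifts with a shipped random-coil
reference table; a helix is called where a 4-residue fully assigned window
exceeds +0.7 ppm (Calpha) and +0.5 ppm (CO) on average — conventional
thresholds, config-exposed — and unassigned gaps are preserved as
"undetermined", never interpolated (the protein's NNP and Q-rich stretches
are exactly such gaps).

## Native MS

Positive-ion mode, proton mass 1.00728 Da, pre-centroided peak lists. Charge
series are seeded from every (peak, charge) pair, extended across adjacent
charges within a 50 ppm tolerance, deduplicated and reported as disjoint
series by decreasing intensity. Neutral masses are intensity-weighted means;
oligomers are assigned by rounding against a monomer mass within 1% (native
spectra retain adducts and solvent). Adduct ladders are fitted by a 1 Da grid
search over increments of 100-1000 Da, requiring at least three gap-free
rungs and a residual SD below 12 Da; on 1000 random five-mass draws the
false-positive rate is under 5% (a seeded test asserts this). The simulator
places charge envelopes at `z ~ 0.0778 sqrt(M)`, the empirical electrospray
charging of folded proteins.

## The virtual experiment and its thresholds

The workbench generates a baseline open ensemble and a scenario ensemble
(open, closed, or mixed) and runs all four analyses on both. Signature
thresholds are config values, since the underlying experiments establish directions, not
magnitudes: packing-peak ratio > 1.1, EOM Rg reduction > 0.5 pool SD, TPR
tau_c ratio > 1.05, DEER mode shift > 0.1 nm. The SAXS signature is the peak
density of the unit-area P(r) inside a 2-8 nm domain-packing window: at
one-bead-per-residue resolution the intra- and inter-domain peaks of the real
data (3 and 5 nm) are not separately resolved, but closure concentrates pair
distances into the packing window and raises that peak, which is the same
qualitative statement. The closed-like relaxation scenario uses TPR tau_c 12
ns versus 9.5 ns open-like (NT 10.5 ns in both), the reported range for the
full-length and truncated constructs.

## Problem sizes and numerical choices

Desk-scale defaults, chosen so the complete test suite and acceptance script
run comfortably on one CPU and stated here as the package's own study sizes:
ensembles of 40-60 dimers per state (the selection contrasts they must show
are already unambiguous at that size), EOM pools of 80-120 curves with GA
population 60 x 60 generations, DEER grids of 201 distances x ~500 time
points, 50-seed recovery batches, and 1000-draw false-positive simulations.
Study-scale settings (10,000-conformer pools, ensembles of 50, GA 100 x 200)
are the documented defaults of `generate_pool()` and `eom_select()` and can
be restored in any config. Other numerical choices: FNNLS tolerance scales
with machine epsilon times the normal-matrix norm; L-curve corners fall back
to the mid-grid alpha with a degeneracy flag when no curvature maximum
exists; non-decaying DEER backgrounds are clamped to rate 0 with a warning;
non-decaying relaxation series return `converged = FALSE` rather than
throwing; ties in mode detection are broken towards the first grid point.

## Known limitations

The generator's closed state is one plausible ring geometry, not an inference
about the real C-terminal interface. Correlation times use the isotropic
approximation throughout, as solution studies of this system have done. The SAXS forward model
has no hydration shell or excluded-volume contrast, so Porod volumes of bead
models are meaningful only against matched forward models (the sphere oracle
uses the analytic curve). Deposited-data reanalysis requires the two public
SAXS curves; in offline environments the corresponding test reports the
missing input explicitly rather than silently passing.
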