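---
title: "Tracking the excess-proton charge defect: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking the excess-proton charge defect: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cectrack)
```

## The physical picture

Excess-proton transport in water and around weak acids proceeds by the
Grotthuss mechanism: covalent and hydrogen bonds rearrange so that the
"proton" that moves is never one particular nucleus. What is conserved is
a net +1 e charge defect spread over the protonated species and its
solvation shells. `cectrack` represents that defect by a center of excess
charge (CEC), a continuous, differentiable function of the atomic
coordinates, built from a set of *diabatic states* — bonding topologies
that differ by proton hops.

The construction has three layers.

**Topology.** Every hydrogen is assigned to its nearest oxygen
(minimum-image; ties within 1e-9 Å go to the lower atom index — a
deterministic rule that is adequate for stored frames, where no
frame-to-frame hysteresis is needed). Oxygens with two hydrogens are
waters, with three a hydronium; a declared acid group (`acid_spec()`) is
neutral when one of its oxygens carries a hydrogen and anionic otherwise.
Exactly one protonated species (hydronium or neutral acid) must exist; it
defines the root state. Frames with zero or several excess protons are
rejected rather than guessed at, as is any oxygen with fewer than two
hydrogens (proton holes/hydroxide transport is out of scope).

**State enumeration.** From the root species, hops are generated to every
acceptor oxygen whose distance to a donatable hydrogen is within the
hydrogen-bond criterion (2.5 Å on the H···O distance — the standard
H-bond length cutoff; we read the criterion as shared-H-to-acceptor-O,
not O-to-O). Each hop transfers the shared hydrogen and produces a child
state one solvation shell further out; expansion is breadth-first and
stops at three shells by default, because state populations are already
negligible in the fourth. A path never revisits a molecule it has passed
through (a simple-path rule, which also prevents the transferred proton
from immediately hopping back), but different branches may reach the same
molecule: such ring-closure duplicates are kept as distinct states whose
weights add under normalization, which is the behaviour consistent with
path-product weighting. `merge_ring_paths = TRUE` collapses them into one
multi-path state; the CEC is identical either way because duplicate
states share their center of charge, so only the reported state count
changes. Whether the original condensed-phase implementations also
restricted hops by an O–O distance is not documented anywhere we know of;
we use the H···O criterion alone, and the cutoff is configurable.

**Weights and the CEC.** A hop from state i to j carries a
charge-transfer factor

$$ f_\mathrm{CT} = e^{\,k(\delta - \delta_0)}, \qquad
   \delta = |r_\mathrm{H} - r_{\mathrm{O,donor}}| -
            |r_\mathrm{H} - r_{\mathrm{O,acceptor}}| . $$

We fix the sign convention so that δ increases as the proton approaches
the acceptor and f_CT is the weight *ratio* c_j²/c_i² across the hop; a
factor above 1 simply means the acceptor state dominates, and
normalization handles it. (The ratio form is the one consistent with the
closed-form normalization c_1² = 1/(1 + Σ_paths Π f_CT); a symmetric
fraction would not reproduce that identity.) The gauge is fixed by two
physical anchors: for hydronium–water, equal sharing (δ = 0) must give
equal weights, hence δ0 = 0; for the weaker acid, δ0 > 0 means the proton
must sit substantially closer to the water before the weights equalize.
Each state's unnormalized weight is the product of f_CT along its hop
path (the root carries the empty product), normalized to Σ c_i² = 1. The
CEC is the weighted average of the per-state centers of charge, computed
with per-atom *excess* charges (protonated minus deprotonated-parent
charges, summing to +1 e) — never raw force-field charges of a neutral
species, whose zero net charge would make the center singular.

Reverse acid hops (a hydronium donating to a carboxylate) reuse the
acid–water parameters with δ0 negated: reversing donor and acceptor flips
δ, and the reverse weight ratio is 1/f_forward(−δ). The parameter lookup
derives this mirrored pair automatically.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 2.5 | Å | H···O hydrogen-bond criterion for hops |
| `max_shell` | 3 | — | solvation shells searched |
| `k`, `delta0` (hydronium–water) | 4.234, 0 | Å⁻¹, Å | BLYP-calibrated charge transfer (4.898, 0 for ωB97X) |
| `k`, `delta0` (acid–water) | 2.946, 0.5361 | Å⁻¹, Å | BLYP-calibrated, asymmetric pair |
| `kappa` | 40 | Å⁻¹ | softmin sharpness of the dissociation CV |
| hill `height0`, `width` | 0.2, 0.1 | kcal/mol, Å | well-tempered deposition |
| `stride_fs`, `gamma`, `temperature` | 50, 12, 300 | fs, —, K | deposition interval, bias factor, thermostat |

The BLYP parameter set is the default because it matches the functional
the underlying ab initio trajectories are typically propagated with; the
two shipped hydronium–water sets give very similar CEC spectra, so mixing
them is benign. The charge tables shipped as defaults are documented
stand-ins that spread the excess charge symmetrically (hydronium: 0.25 e
on each atom; carboxyl: 0.10/0.20/0.20/0.50 e on C/O/O/H); published
force-field-derived excess charges live in supplementary material we do
not redistribute, so any production analysis should supply its own table
via `read_charge_table()` — every result object records the charges
actually used through the per-atom excess charges it returns.

## Numerical choices

* **Exponent clipping.** The charge-transfer exponent is clipped to ±50
  before exponentiation. No physically reachable geometry comes close
  (|δ| < 2 Å and k ≤ 5 Å⁻¹ give |exponent| ≤ 10); the clip only protects
  degenerate inputs from overflow while keeping f_CT positive and
  monotone.
* **Periodic boxes.** Only orthorhombic boxes are supported (the systems
  this method targets are cubic); triclinic lattices and CRYST1 angles
  other than 90° are rejected loudly. All inter-atomic distances are
  minimum-image, and all species in one CEC evaluation are unwrapped
  about a single anchor (the root species' first atom), which makes the
  CEC exactly covariant when any molecule is translated by a lattice
  vector. `center_of_charge()` on a single state unwraps about the
  state's own first atom instead, which is the natural choice for a
  stand-alone species.
* **Softmin.** Evaluated as min(d1,d2) − log1p(exp(−κ|d1−d2|))/κ, which
  neither overflows nor underflows for any finite input; the gap to the
  hard minimum is at most ln(2)/κ, attained on the diagonal.
* **Gradients.** `cec_gradient()` is the analytic chain rule through the
  centers of charge and the weight normalization; it treats the state set
  as fixed, which is the correct derivative everywhere except at the
  measure-zero geometries where enumeration itself changes (a hop
  crossing the 2.5 Å cutoff). The test-suite validates it against central
  finite differences (step 1e-5 Å) at 1e-6 relative tolerance, including
  geometries pinned near δ = 0.
* **Degenerate inputs.** Coincident atoms in a transfer coordinate, a CEC
  on top of a carboxyl oxygen, non-positive charge-transfer factors, or a
  calibration table with no spread in δ raise immediate errors instead of
  propagating NaNs.
* **Fitting.** `fit_ct_parameters()` minimizes residuals of f_CT itself
  by default (a literal reading of least squares on the factor), with
  `log_space = TRUE` for ln f. Both start from the exact log-linear
  regression, so noiseless data are recovered to machine precision either
  way. Under multiplicative noise the log-space fit is the one with
  calibrated standard errors (its residuals are homoscedastic); the
  factor-space fit remains unbiased but its error bars are approximate —
  the suite checks both properties separately.

## The metadynamics demonstration

The package biases a 1-D model CV rather than live MD (coupling into an
MD engine is a different piece of software). `run_toy_metad()` integrates
overdamped Langevin dynamics, with mobility D/k_BT, on a polynomial
potential — by default the symmetric double well V(x) = B((x/a)² − 1)²
with B = 3 kcal/mol and a = 1 Å — while depositing well-tempered hills
with the default hill settings above (the bias factor γ = 12 is sized for
a proton-dissociation barrier of roughly 9 kcal/mol; ΔT = (γ−1)T in the
height damping). The free energy estimate is F(s) = −γ/(γ−1) V_bias(s).

The compiled integrator keeps the accumulated bias and its derivative on
a 0.001 Å interpolation grid, which costs about 1e-6 kcal/mol of
interpolation error for 0.1 Å hills — five orders below anything measured
on it — while the hills themselves are returned unmerged so
`evaluate_bias()` can reproduce the exact Gaussian sum (the suite checks
grid and exact sum against each other). A CV diffusion constant of
2e-5 Å²/fs with a 1 fs step makes the 50 fs deposition stride meaningful
(the in-well relaxation time is near 1 ps) and lets a 4 ns biased run
converge the 3 kcal/mol double-well barrier; the contrast run mirrors the
length scale of a typical unbiased ab initio trajectory (tens of
picoseconds) and stays in its starting well. Barrier read-out averages
the reconstructed profile over ±0.05 Å around each stationary point,
which suppresses hill-placement wiggles without the upward bias a global
max-minus-min would give.

## What the synthetic generators do and do not emulate

The fixtures module generates every input the package needs, so the whole
pipeline is testable without external data:

* `make_ideal_network()` builds a ring-free hydrogen-bond tree (hydronium
  donating 3, waters 2 onward, H···O = 1.6 Å) with tetrahedral branching;
  its three-shell enumeration yields exactly 1+3+6+12 = 22 states, inside
  the 20–30 band typical of the condensed phase.
* `make_zundel_scan()` and `make_shuttle_trajectory()` move a shared
  proton smoothly (the shuttle uses a minimum-jerk profile) so symmetry,
  monotonicity and continuity of the CEC can be asserted frame by frame.
* `make_oscillating_track()` provides tones at known wavenumbers for
  spectral peak-recovery checks.

All fixtures use idealized internal geometries (0.97 Å O–H bonds, fixed
angles) and are deterministic under a seed. They emulate the *topology*
and *kinematics* that the CEC machinery responds to — they do not emulate
thermal disorder, anharmonic couplings, polarization, or realistic
hydrogen-bond statistics. Passing tests on them therefore establishes the
correctness of the mathematics (normalization, locality, continuity,
gradients, transform identities), not the physical fidelity of any
particular trajectory; condensed-phase observables such as the full
excess-proton IR band shape require hundreds of picoseconds of ab initio
dynamics, which is outside what a desk-scale package can or should
reproduce.

Problem sizes used by the shipped tests: 67-atom networks and 7–17-atom
clusters for CEC/gradient checks, 100 jittered frames for the
conservation sweep, 4096-sample tracks for spectra, 63-point tables with
200 replicates for calibration, and 4 ns toy-metadynamics runs (three
seeds) for the double-well recovery — all chosen so the whole suite runs
in well under a minute on one core.

## Known limitations

* One excess proton; no hydroxide (proton-hole) transport; no automatic
  perception of titratable groups (acid oxygens are declared explicitly).
* Orthorhombic boxes only; no trajectory alignment or re-imaging beyond
  minimum-image distances.
* The spectrum is reported in arbitrary units with no frequency-dependent
  prefactor and no quantum correction; an optional ω² weighting flag
  exists but is off by default, since band *positions and shapes*, not
  absolute intensities, are the object of comparison.
* Live biasing of an MD engine is out of scope; `xi_atomic_gradient()`
  provides the full chain-rule force for analysis and for coupling by
  external code.
* The charge-transfer model is a single exponential per pair kind; pairs
  whose CDFT behaviour it fits poorly would need a different switching
  function, which the fitting module would accept as tabulated data but
  does not itself provide.
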