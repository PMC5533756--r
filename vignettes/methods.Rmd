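---
title: "Models and methods behind ibarlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ibarlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ibarlab` analyzes molecular-dynamics trajectories of a membrane-binding
protein (an I-BAR domain dimer) over a three-component bilayer. This
vignette records the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## System model and conventions

Coordinates are Angstrom throughout; curvatures are reported in nm⁻¹
(conversion ×10 at the reporting boundary, matching how membrane curvatures
are conventionally quoted); energies kcal/mol; times ns; temperatures K.
Boxes are orthorhombic only — the simulated systems this targets use
rectangular boxes, and the minimum-image arithmetic relies on it.

A system is one atom table: identity (name, element, residue, segment),
nonbonded parameters (mass, partial charge, LJ ε and r_min/2), and a
disjoint group label (`protein_A`/`protein_B` by chain or segment; `DOPC`,
`DOPE`, `DOPS`, `water`, `ion` by residue name). Nonbonded parameters come
from a sidecar TSV rather than force-field topology files: only those four
per-atom quantities are consumed, so full CHARMM topology parsing would be
dead weight. Hydrogens stay in the model and are excluded from heavy-atom
analyses by a selection flag.

PDB I/O goes through `bio3d`. Because the standard PDB residue field holds
three characters, the four-character lipid residue names are written to
disk as `DPC`/`DPE`/`DPS` and mapped back on load. The native trajectory
format is a plain-text frame list (`#atoms N box Lx Ly Lz time t` plus one
`id x y z` line per atom, six decimals) chosen so that fixtures remain
human-readable and round-trip byte-exactly.

**Headgroup definition.** Lipid position in every membrane profile is the
center of mass of the headgroup. Which atoms constitute "the headgroup" is
not uniquely defined; the default is the phosphate group plus the
choline/ethanolamine/serine moiety, configurable per lipid type
(`select_headgroups()`).

## Binding geometry

θ is the angle between the *second* principal axis of inertia of the
protein and the membrane normal Z, folded into [0°, 90°]. For an elongated,
flattened dimer the first axis is the long axis and the second axis is the
one that points at the membrane when the binding face is engaged, so θ → 0
on proper binding. Axes are eigenvectors of the inertia tensor about the
COM in ascending eigenvalue order, with signs fixed (non-negative Z, ties
broken toward non-negative X then Y) so θ is deterministic for symmetric
bodies; exactly collinear point sets are rejected.

Two distinct proximity observables are computed because both are used in
practice: the minimum 3D heavy-atom pair distance (minimum image), and the
Z-projected gap between the protein and membrane Z-intervals (zero when
they interpenetrate). `delta_d_z = d_z − reference` takes its reference
from configuration: the natural anchor is the bound-state free-energy
minimum, but runs that never reach it use e.g. their late-time average, so
the package does not hard-code either. Whether D_Z uses the whole membrane
or only the proximal leaflet COM is likewise configurable through the
selection; the default is the whole membrane.

## Interface census

A residue contacts a lipid when any heavy-atom pair is within 5 Å; a salt
bridge exists when any basic nitrogen is within 3.2 Å of any acidic oxygen.
Records deduplicate at the group-pair level, so a bidentate
arginine–phosphate interaction is one bridge — the choice that makes
"number of salt bridges" scale like the ~30 such interfaces support rather
than like atom-pair counts.

Default group definitions: Lys NZ, Arg NE/NH1/NH2, protonated His, and the
N-terminus as basic; Asp/Glu carboxylates and the C-terminus as acidic;
lipid phosphate oxygens and the PS serine carboxylate as acidic; and the
lipid amine/choline N as basic. The PC choline nitrogen counts as a basic
group even though it bears no hydrogen — without it a PC lipid could never
form a "salt bridge" with protein acidic oxygens, yet such contacts are a
real and reported feature of these interfaces. Whether His and the termini
belong in the census is genuinely ambiguous; both are defaults, both
configurable. Protonation states are inputs, never predicted.

The hydrogen-bond criterion (d(D···A) ≤ 3.5 Å and ∠D–H···A ≥ 130°) is a
standard geometric choice documented here because the underlying study does
not state one; both thresholds are arguments.

## Membrane profiles

Lipids are assigned to leaflets by headgroup-COM Z relative to the median
headgroup Z (ties go upper). The height field h(X) is the mean headgroup
Z per X bin within a Y slab (half-width 48.3 Å by default, i.e. the
central portion of the box where the protein sits), averaged over frames;
empty bins are linearly interpolated and flagged rather than silently
zeroed.

Curvature is the 1D profile curvature C = h″/(1+h′²)^(3/2) of the binding
leaflet's height field along X, by periodic central differences after an
odd-width moving average (default 5 bins). This is a reconstruction: the
plotted quantity in the source material is C versus X averaged over Y, and
its exact smoothing is not public, so the smoothing here is explicit and
configurable. The sign convention is positive when the membrane bends
toward the protein. `C_ave`/`C_max` are taken over the binding footprint,
defaulting to the protein's heavy-atom X-projection. Diameters are d = 2/C.
With noise-free generated surfaces, `smoothing_window = 1` measures pure
discretization error (<0.5% at 64 bins); the 5-bin default exists for noisy
data and costs a few percent of apex curvature at these bin widths —
acceptable for fluctuating surfaces, which is when it is used.

Lateral MSD unwraps coordinates by accumulating minimum-image steps between
consecutive frames, removes the leaflet-COM drift, and averages squared XY
displacements over lipids and multiple time origins (spacing configurable,
default 10 frames). A per-X-bin variant assigns each lipid to its
origin-frame bin.

## Energetics

Nonbonded energies use the CHARMM functional form and combination rules
with Coulomb constant 332.0636 kcal·Å/(mol·e²), dielectric 1. Analysis
energies use an energy-switched cutoff (switch 10 Å, cut 12 Å, C¹
continuous; `cutoff = Inf` supported) rather than particle-mesh Ewald:
these decompositions are interaction-energy proxies for comparing states,
not production Hamiltonians, and an Ewald reimplementation would dominate
the package for no analytical gain. The scheme is configurable and the
brute-force oracle runs at infinite cutoff.

Interaction-energy maps assign each lipid's whole-lipid protein interaction
to its headgroup-COM XY bin, time-averaged; the Y-integrated profile is the
row sum, so the map conserves the total protein–lipid energy by
construction.

## Free energy: umbrella sampling and MBAR

The reaction coordinate is the protein–membrane COM separation offset
ΔD_Z. Windows carry a harmonic bias `0.5·k(x−x₀)²` with k = 50 kcal/mol/Å²
and centers every 0.5 Å from −4.0 to 30.5 plus a 0.1 Å sweep at 3.6–3.9 Å;
T = 300 K; k_B = 0.0019872041 kcal/mol/K.

`mbar_solve()` solves the self-consistent MBAR equations for the window
free energies f_k (anchored f₁ = 0) to max|Δf| < 10⁻⁸ kcal/mol: a few
self-consistent sweeps, then Newton–Raphson on the equivalent convex
objective with Armijo backtracking; the iteration cap (1000) aborts with
the last gradient norm rather than returning an unconverged result. Only
bias energies enter — the unbiased potential is common to all states and
cancels. A window-overlap diagnostic warns when adjacent windows barely
share configuration space.

Two independent cross-checks exist because the solver is the scientific
core: (i) `mbar_objective_solve()` minimizes the same convex objective with
L-BFGS-B plus plain fixed-point polishing — a genuinely different algorithm
that must agree to ~10⁻⁸ kcal/mol on shared input (it is practical at
modest problem sizes; the polish is first-order); and (ii) `wham_pmf()`, a
separately-coded binned WHAM whose bias factors are bin-averaged by
quadrature. WHAM agrees with MBAR *on the same binned input* within
statistical error; against binless MBAR it additionally carries the binning
bias of the input, which grows along long window chains with stiff biases —
the reason the equivalence test snaps samples to bin centers first.

The PMF bins pooled samples (default width 0.5 Å, the window spacing) and
anchors the global minimum at exactly zero, which also defines the origin
of ΔD_Z. Empty bins are kept and flagged. Near sharply curved features the
0.5 Å default discretizes visibly (a bin's free energy is the bin-average,
not the midpoint value), so recovery checks against analytic potentials use
0.1 Å bins. Per-bin uncertainty defaults to a Kish effective-sample-size
counting estimate; `pmf_bootstrap()` implements the block bootstrap over
whole windows (200 seeded resamples) for when resampled errors are worth
200 re-solves — routine calls do not pay that cost. Convergence is probed
by recomputing the profile on cumulative time blocks (2/4/6/8/10 ns
pattern) and tabulating pairwise maximum deviations. Decorrelation of real
window data by statistical inefficiency is available at the generator level
(see below); within `pmf()` all retained samples are used.

## Entropy and the thermodynamic cycle

The binding free energy decomposes over a thermodynamic cycle as
ΔG_B = ΔE_protein − TΔS_protein + ΔΔμ, where the first two terms compare
the protein's conformational ensembles generated in the bound and unbound
states and ΔΔμ is the solvation (water + ions + lipids) difference. The
package assembles the cycle from supplied series (`assemble_cycle()`),
reporting the correlation between ΔΔμ and the total interaction energy when
both are given — the proxy relation that justifies reading solvation off
interaction energies. Neither Δμ term is ever computed individually:
solvation free energies are out of scope by design. ΔE_protein is accepted
as externally supplied per-frame energies (its intramolecular nonbonded
part is computable with `group_energy`); bonded force-field evaluation
would be disproportionate to its role.

S_protein = S_trans + S_rot + S_internal. The exact formulas behind the
original decomposition are in supplementary material that is not public, so
the package uses the standard reconstruction: Sackur–Tetrode translational
entropy at a configurable standard-state volume (default 1 M, 1660.5
Å³/molecule — the convention is not stated in the source, so it is explicit
here), the classical rigid rotor with symmetry number 1, and quantum
harmonic-oscillator entropy over quasi-harmonic modes,
S = k_B Σ[x/(eˣ−1) − ln(1−e⁻ˣ)], x = ħω/k_BT, with effective frequencies
ω = √(k_BT/λ) from the mass-weighted covariance eigenvalues λ. The quantum
form is standard quasi-harmonic practice; a classical flag exists. Six
rigid-body modes are removed after mass-weighted Kabsch superposition
(default fit on Cα — whether the original used Cα or all heavy atoms is
unstated, so it is an argument), and modes with λ < 10⁻⁸ Ų·amu are dropped
as numerical rank deficiency. Fewer frames than coordinates triggers a
rank-deficiency warning rather than silence.

## Synthetic data: what it shows and what it cannot

Every analysis stage has a seeded generator whose ground truth it must
recover; generators emit the native formats so the file path, not just the
in-memory path, is exercised. The defaults mirror the study conditions:
640/640/160 DOPC/DOPE/DOPS at 4:4:1 assigned by seeded shuffle, k = 50
kcal/mol/Å² with the −4.0…30.5 Å schedule, T = 300 K, box 470 × 90 × 150 Å³.
Where the study fixes no value the choice is made once here: bilayer
leaflet separation 40 Å (a typical phosphate-to-phosphate distance),
Gaussian-bump width 60 Å (a protein-sized deformation), lipid diffusion
~1 Ų/ns (the order measured for fluid-phase PC bilayers), Brownian time
step 0.01 ns.

The umbrella generator is vectorized random-walk Metropolis with burn-in
(500 steps), per-window step-size tuning to 30–60% acceptance (an error if
tuning fails), and thinning (default every 20th step), which at these
acceptance rates leaves chains effectively uncorrelated — the estimator
checks assume samples from the biased distributions, and thinning is the
standard way to approach that regime; retained sample counts are quoted
after thinning. Timestamps span 10 ns so block-convergence analysis works
on generated data. The membrane generator can pin its lattice columns to
the analysis bin grid (`nx`), which samples the surface exactly at bin
centers; curvature-recovery checks use this to measure discretization error
without confounding it with lattice aliasing.

Problem sizes in the shipped checks — 74 windows × 10⁴ samples for the PMF,
10⁴ frames for entropy recovery, 500 lipids × 10⁴ steps for diffusion, 64
bins for curvature, 100-atom systems for brute-force equivalence — were
chosen so the whole suite runs in minutes on one CPU while leaving the
statistical tolerances (0.3 kcal/mol barrier, 2% entropy, 2% curvature,
3 SE diffusion) comfortably above the expected estimator noise.

Passing these tests demonstrates that the estimators recover known
statistical structure. It does not demonstrate anything about force-field
realism: generated bilayers have no tails, no area-per-lipid coupling, no
protein-induced ordering; Brownian lipids have no hydrodynamics; Gaussian
ensembles have no anharmonicity (real quasi-harmonic entropies are upper
bounds); and the scripted binding trajectory has rigid-body kinematics, not
dynamics. Conclusions about real membranes require real trajectories.

## Known limitations

- Orthorhombic boxes only; no triclinic minimum image.
- Analysis energetics are switched-cutoff, not Ewald; absolute
  electrostatic energies are scheme-dependent even though state differences
  are the quantity of interest.
- The curvature estimator is a 1D height-field profile; it cannot represent
  overhangs, tubules or 2D curvature tensors.
- `mbar_objective_solve()`'s fixed-point polish converges slowly on long
  stiff window chains; it is a verification tool for modest inputs, not a
  replacement solver.
- Binary trajectory formats (DCD/XTC) are not read; the native text format
  and PDB are the interchange.
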