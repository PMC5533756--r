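# ibarlab

Trajectory analysis of I-BAR domain membrane binding and deformation.

The inverse-BAR (I-BAR) domain is a zeppelin-shaped homodimeric protein
module that binds the inner face of the plasma membrane and drives outward
protrusions such as filopodia. All-atom molecular dynamics of an I-BAR dimer
over a DOPC/DOPE/DOPS (4:4:1) bilayer shows spontaneous, strongly directed
binding stabilized by ~30 salt bridges between basic residues and lipid
headgroups, a local increase in lipid density under the protein, and bending
of the membrane toward the protein. `ibarlab` re-implements the complete
analysis pipeline behind that kind of study as a tested, reusable R package
for structural-bioinformatics practitioners:

- **Binding geometry** — centers of mass, principal axes of inertia, the
  orientation angle θ between the second principal axis and the membrane
  normal, the center-of-mass separation D_Z / ΔD_Z, the interfacial gap, and
  first-contact detection.
- **Interface census** — residue–lipid contacts (any heavy-atom pair ≤ 5 Å),
  salt bridges (basic N to acidic O ≤ 3.2 Å, deduplicated per group pair),
  hydrogen bonds, and per-residue-type / per-lipid-type tallies (mean ± sd
  over a frame window).
- **Membrane profiles** — leaflet assignment, the surface height field
  h(X) from headgroup centers of mass, the curvature profile
  C(X) = h″/(1+h′²)^(3/2) (nm⁻¹, positive toward the protein), C_ave/C_max
  over the binding footprint, curvature→tubule-diameter conversion d = 2/C,
  local lipid density N_lipid(X), and lateral mean-square displacement with
  unwrapping and COM-drift removal.
- **Energetics** — CHARMM-convention nonbonded pair energies
  (E = 332.0636·q_iq_j/r + ε_ij[(r_min,ij/r)¹² − 2(r_min,ij/r)⁶]), switched-
  cutoff group–group energies, per-lipid interaction-energy maps, and the
  ΔE_int decomposition by partner (water / ions / lipids).
- **Free energy** — umbrella-sampling windows (k = 50 kcal/mol/Å², centers
  −4.0…30.5 Å), a self-consistent/Newton multistate Bennett acceptance ratio
  (MBAR) solver with an independent convex-objective cross-check and a
  binned WHAM oracle, PMF binning anchored at the global minimum, block-wise
  convergence diagnostics, and window bootstrap uncertainties.
- **Thermodynamic decomposition** — Kabsch superposition, quasi-harmonic
  mode spectra from the mass-weighted covariance, quantum
  harmonic-oscillator internal entropy, Sackur–Tetrode + rigid-rotor
  translational/rotational entropy, and assembly of the cycle
  ΔG_B = ΔE_I-BAR − TΔS_I-BAR + ΔΔμ.
- **Synthetic data** — seeded generators with analytic ground truth for
  every stage: bilayer point clouds on flat/curved surfaces (640/640/160
  DOPC/DOPE/DOPS), planted salt-bridge/contact interfaces, 2D Brownian
  lipids, Gaussian conformational ensembles with known spectra, Metropolis
  umbrella samples, and a scripted end-to-end binding trajectory.

Everything is tidyverse-shaped: analyses return tibbles, fitted objects have
`tidy()`/`glance()` methods, and result types have `autoplot()` methods.

## Worked example

Generate a scripted binding event, run the pipeline, and read off the
summary:

```r
library(ibarlab)

bt <- gen_binding_trajectory(n_frames = 12, seed = 9)
dir.create("demo")
write_system_pdb(bt$system, "demo/system.pdb", bt$trajectory[[1]]$coordinates)
write_param_table(system_param_table(bt$system), "demo/params.tsv")
write_trajectory(bt$trajectory, "demo/traj.dat")

res <- run_pipeline(list(
  structure = "demo/system.pdb", parameters = "demo/params.tsv",
  trajectory = "demo/traj.dat", out_dir = "demo/out", n_bins = 24
))
str(res$summary)
#> List of 11
#>  $ n_frames               : int 12
#>  $ n_atoms                : int 855
#>  $ c_ave                  : num 0.00437
#>  $ c_max                  : num 0.00595
#>  $ diameter_ave_nm        : num 458
#>  $ diameter_max_nm        : num 336
#>  $ footprint              : num [1:2] 88 152
#>  $ salt_bridges_mean      : num 0
#>  $ salt_bridges_sd        : num 0
#>  $ theta_final            : num 0
#>  $ min_pair_distance_final: num 0.972
```

The scripted protein starts tilted (θ = 30°) and descends onto the bilayer;
by the final frame it lies flat (θ = 0) with a membrane bump forming under
it (`c_max` in nm⁻¹; at this early stage the induced curvature corresponds
to a ~340 nm tubule diameter). `demo/out/` holds the orientation time
series, the interface tallies and per-frame salt bridges, the membrane
h(X)/C(X)/N_lipid profiles, and the JSON summary above.

A free-energy profile from umbrella windows over an analytic double well:

```r
dw <- function(x) -8.6 * exp(-x^2 / 4.5) - 6 * exp(-(x - 3.5)^2 / 2)
ws <- gen_umbrella_samples(dw, umbrella_schedule(), n_per_window = 2000, seed = 1)
prof <- pmf(ws)
glance(prof)
#> # A tibble: 1 x 8
#>   n_bins n_empty n_windows n_samples iterations min_location dg_at_far_bin binding_dg
#>    <int>   <int>     <int>     <int>      <dbl>        <dbl>         <dbl>      <dbl>
#> 1     71       0        74    148000         10         0.25          7.92      -7.92
autoplot(prof)
```

`binding_dg` is the free energy of the bound minimum relative to the
farthest sampled separation — here −7.9 kcal/mol against the −8.6 kcal/mol
depth of the analytic well. The gap is the statistical error that
accumulates across the 74-window chain at only 2000 samples per window; at
10⁴ samples per window (the acceptance-script conditions) the recovered
depth is within ~0.2 kcal/mol.

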