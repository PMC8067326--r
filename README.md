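# chmito

Phase-field simulation of mitochondrial inner-membrane / matrix morphology,
including the effect of calcium phosphate granules, for computational
biophysicists studying cristae ultrastructure.

Under calcium overload, mitochondria form dense calcium phosphate granules in
the matrix and their cristae network remodels: the matrix expands and the
membrane-rich compartments contract around the granules. `chmito` models the
inner membrane and fluid matrix as the two phases of a conserved order
parameter Ψ (−1 membrane, +1 matrix) governed by the dimensionless
Cahn–Hilliard equation

    ∂Ψ/∂t = ½ ∇²(Ψ³ − Ψ − γ∇²Ψ)

on disk, ellipse, sphere and ellipsoid domains, with zero-flux outer
boundaries and granules represented as volume-excluded balls whose surfaces
pin Ψ to a constant (Dirichlet on Ψ, zero-flux on the chemical potential μ).
The package provides:

* **geometry** — background-grid simplicial meshing of the model shapes with
  granule holes, boundary snapping and tagging (`build_domain`, `granule`,
  `validate_granules`, `domain_measure`);
* **solver** — the mixed two-field (Ψ, μ) P1 finite-element discretization
  with theta-method stepping and exact Newton iteration (`solver_config`,
  `initialize_random`, `theta_step`, `run_simulation`);
* **energetics** — Ginzburg–Landau free energy, total mass and the
  dissipation identity dF/dt = −∫|∇μ|² as per-step diagnostics
  (`total_free_energy`, `total_mass`, `dissipation_rate`);
* **linear stability** — the dispersion relation ω(k) = ½(k² − γk⁴), its
  critical wavenumber 1/√γ, the tanh interface profile and its excess energy
  (2/3)√(2γ), plus an independent finite-difference growth-rate oracle
  (`dispersion_rate`, `measure_growth_rate_1d`, `fit_critical_wavenumber`,
  `uniform_state_stability`);
* **morphometry** — phase fractions by exact element splitting, Ψ = 0
  interface length/area, membrane component counts, spectral characteristic
  length, granule halo composition (`phase_fractions`, `interface_measure`,
  `count_phase_components`, `characteristic_length`, `granule_halo_report`);
* **I/O** — YAML run configs with validation and default provenance,
  ParaView-readable VTU snapshots, exact checkpoint/resume, deterministic
  time-series CSVs, and a thin CLI (`exec/chmito.R`).

## Worked example

```r
library(chmito)

# disk of radius 5 with one granule pinned to the matrix phase
d   <- build_domain("disk", 5, list(granule(c(2.5, 2.5), radius = 1, value = 1)),
                    h_target = 0.15)
cfg <- solver_config(gamma = 1, dt = 5e-3, record_every = 200L)
psi0 <- initialize_random(d, mean = 0, amplitude = 0.05, seed = 1)
run <- run_simulation(d, psi0, cfg, n_steps = 1400L)

tail(run$records[, c("step", "F_total", "membrane_fraction", "halo_mean_1")], 3)
#>   step  F_total membrane_fraction halo_mean_1
#> 6 1000 29.33917         0.4285178   0.9804897
#> 7 1200 28.12372         0.4346050   0.9826253
#> 8 1400 27.05476         0.4444584   0.9842936

granule_halo_report(d, run$state$psi, 1, shell_width = 0.5)$membrane_fraction
#> [1] 0
```

The free energy decreases monotonically (within 1e−10 per step); the mean of
Ψ in a 0.5-wide shell around the granule ends at 0.98 — a pure matrix halo —
and the membrane phase is completely displaced from the shell while still
occupying ~44% of the domain globally: the simulated counterpart of matrix
fluid filling the space around a granule. On granule-free domains mass is
conserved to ~1e−11 relative; a granule-pinned boundary injects mass as the
halo grows, and that drift is reported in the time series.

Example protocol configs for the bundled simulation geometries live in
`inst/extdata/configs/` and run end-to-end via

```r
cfg <- load_config(system.file("extdata", "configs", "disk_r4.yaml", package = "chmito"))
run <- simulate_config(cfg, output_dir = "out")   # writes timeseries.csv + config echo
```

or from a shell: `Rscript exec/chmito.R simulate --config ... --out out`.

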