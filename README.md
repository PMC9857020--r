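# ifacelec

Continuum electrostatics of protein–protein binding interfaces, in R.

Protein complexes such as the tubulin assemblies that build microtubules are
steered into place by long-range electrostatics and then held by short-range
polar contacts. `ifacelec` implements the three computations that
characterise this, for structural bioinformaticians who want a scriptable,
fully testable pipeline rather than a chain of external binaries:

1. **Poisson–Boltzmann potential maps.** A finite-difference solver for

   ∇·[ε(r) ∇φ(r)] = −4πC ρ(r) + ε_s κ²(r) sinh φ(r)

   with φ in kT/e, harmonic-mean face permittivities, trilinear charge
   spreading, Stern-layer ion exclusion, screened-Coulomb (per-atom or
   monopole+dipole) boundary conditions, and red–black SOR iteration
   (nonlinear mode keeps the sinh term via per-node Newton linearisation).
   Defaults are the standard protein setup: ε = 2 inside / 80 outside,
   150 mM salt, 300 K, 1.4 Å probe, 2.0 Å Stern shell, 70% box fill.
2. **Separation force scans.** The net electrostatic force one molecule
   exerts on another (two-solve scheme: source charges of A in the
   dielectric cavity of the full A+B complex, F = qE on B's atoms),
   evaluated while B is translated 14–40 Å in 2 Å steps along the
   center-of-mass axis, with each point classified attractive or repulsive.
3. **Interface contact occupancies.** Per-frame hydrogen-bond
   (D···A ≤ 3.2 Å, ≤ 20° from linearity) and salt-bridge (acidic O to basic
   N ≤ 4.0 Å) detection over a conformational ensemble, 15 Å interfacial
   residue selection, occupancy percentages with a ≥ 10% retention filter
   and > 40% / > 80% reporting tiers, and per-residue union
   occupancy/multi-partner aggregation.

A synthetic-data module generates analytically solvable fixtures (Born ion,
charge dumbbells) and trajectories with planted per-frame contact
probabilities, so the whole pipeline validates against closed forms and
known statistics with no external downloads.

## Worked example

Solve a Born ion (q = +1 e, radius 2 Å, ε 2/80, 150 mM salt) on a 65³ grid
and compare with the Debye–Hückel closed form:

```r
library(ifacelec)
ion <- make_born_ion(charge = 1, radius = 2)
s   <- solver_settings(stern_radius = 0, surface_inflation = 0)
sol <- solve_potential(ion, s, dims = 65, min_edge = 32)
#> iterations: 180, residual: 5.63e-07 kT/e
r <- c(3, 5, 10)
data.frame(r_A = r,
           phi_numeric  = trilinear_interp(sol$phi, cbind(r, 0, 0)),
           phi_analytic = born_ion_potential(r, 1, 2, s))
#>   r_A phi_numeric phi_analytic
#> 1   3      1.6463       1.6354
#> 2   5      0.7666       0.7631
#> 3  10      0.2037       0.2035
```

The potential is in kT/e (the ±1 kT/e window is the conventional surface
colour scale; `surface_potential(..., clamp = TRUE)` applies it). Agreement
is ~0.5% in the far field and ~1% two nodes off the sphere.

Force scan on an opposite-charge dumbbell 20 Å apart, in water with 150 mM
salt:

```r
db <- make_dumbbell(1, -1, 20)
su <- solver_settings(eps_solute = 80, stern_radius = 0, surface_inflation = 0)
run_separation_scan(chain_subset(db, "A"), chain_subset(db, "B"), su,
                    d_min = 14, d_max = 20, step = 2, dims = 49)
#>   separation          Fx  ...    magnitude classification
#> 1         14 -0.00045683       0.00045683     attractive
#> 2         16 -0.00033426       0.00033426     attractive
#> 3         18 -0.00024561       0.00024561     attractive
#> 4         20 -0.00017831       0.00017831     attractive
```

Forces are in kT/Å; the negative Fx points the force on B back toward A
(attractive), and magnitudes fall off with the screened-Coulomb envelope.

Occupancy analysis of a 200-frame trajectory with planted contact
probabilities 0.95 / 0.50 / 0.05 for three GLU–LYS pairs:

```r
base <- make_charged_interface_pair(3, 3.5)
ens  <- make_contact_trajectory(base, c("1" = 0.95, "2" = 0.5, "3" = 0.05),
                                n_frames = 200, seed = 42)
compute_occupancy(ens, "A", "B", "saltbridge")
#> occupancy_table (saltbridge): 2 retained pairs over 200 frames
#>            pair_id occupancy tier
#> 1 A:1:GLU--B:1:LYS      95.5  >80
#> 2 A:2:GLU--B:2:LYS      53.5  >40
```

The p = 0.05 pair falls below the 10% occupancy filter and is dropped, the
other two land in their expected tiers at their realised frame counts.

`run_pipeline()` composes all three stages over a list of binding modes
(e.g. the four pairings of two chain groups) from one config — YAML or
`run_config()` — writing per-mode DX potential maps, surface-potential CSVs,
force-scan tables, occupancy TSV/JSON reports and a ranked `summary.json`.
A thin command-line front end with `solve`, `force-scan`, `contacts`,
`synth` and `run` subcommands ships in `inst/scripts/ifacelec`.

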