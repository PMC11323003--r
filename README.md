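# lipofluct

Like-charge attraction of DNA duplexes confined in cationic lipid bilayers,
modelled as a statistical-thermodynamics problem. In ~50 mM MgCl2 two DNA
duplexes repel each other in solution, yet condense spontaneously between
DOPC/DOTAP membranes. `lipofluct` implements the charge-fluctuation
explanation of that contrast and the supporting analyses, exercised entirely
on synthetic configurations — no molecular-dynamics output required.

The core model treats the facing phosphates of the two duplexes as two
lattices of `N ≈ L/b` binding sites that are either occupied by Mg2+
(site charge `+1e`) or empty (`−1e`). Over all `2^(2N)` occupancy
configurations σ the grand-canonical free energy at interhelical spacing
`x` is

    F(x) = U_rod(x) − ln Σ_σ exp(−U_corr(σ; x) + μ n(σ))

with the correlation energy built from screened Coulomb pairs,
`U_corr = Σ c_i c_j l_B exp(−κ r_ij)/r_ij` over inter- and intra-strand
site pairs (`r` from the lattice geometry `r = sqrt(x² + b²Δi²)`), and the
mean-field repulsion of the partially neutralized duplexes as parallel
charged rods, `U_rod = 2 l_B λ(x)² L K₀(κx)`, `λ = ν_eff/L`. Energies are
in units of kBT via the Bjerrum length `l_B = e²/(4πε₀ε_r kBT)`.

Around the model sit four supporting modules:

* **electrolyte** — ionic strength, Bjerrum/Debye lengths, coupling
  parameter Γ = l_B/d;
* **traj_analysis** — concentration profiles, solvation-shell charge
  decomposition, coordination/contact/bridge censuses, radial distribution
  functions on labelled point-charge frames;
* **scattering** — axis-scan and Debye (powder) intensities from
  coordinates, first-Bragg-peak/lamellar-period readout;
* **synthetic_data** — idealized duplex/membrane/ion/lamellar-stack
  generator with exact electroneutrality and seeded reproducibility.

## Worked example

```r
library(lipofluct)

# Ion-ion coupling in the two environments (eps_r = 40.1 vs 92.2, 300 K)
coupling_parameter(2, 2, 2.97, lipid_condition())
#> [1] 1.870755
coupling_parameter(2, 2, 2.89, solution_condition())
#> [1] 0.836159

# Free-energy profiles of the two presets
x <- seq(2.2, 5, by = 0.1)
lip <- model_preset("lipid")
free_energy_profile(x, lip$lattice, lip$rods)
#> Free-energy profile over 29 spacings [2.20, 5.00] nm
#>   classification: attractive  (minimum at 3.10 nm, depth 1.83 kBT)
sol <- model_preset("solution")
free_energy_profile(x, sol$lattice, sol$rods)
#> Free-energy profile over 29 spacings [2.20, 5.00] nm
#>   classification: repulsive

# Lamellar repeat read back from scattering on the synthetic stack
stack <- build_lamellar_stack(system_recipe(seed = 1))
iq <- intensity(stack, scattering_spec(seq(0.05, 0.3, length.out = 300),
                                       direction = c(0, 1, 0)))
first_peak(iq, q_min = 0.05)$period
#> [1] 67.31824
```

Read together: Mg–Mg correlations are twice as strong in the
low-permittivity lipid phase (Γ ≈ 1.87 > 1, strongly coupled) as in
solution (Γ ≈ 0.84); correspondingly the lipid-bound pair has a bound
state ~1.8 kBT deep near 3.1 nm spacing while the same pair in solution is
repulsive at every spacing; and the synthetic bilayer+DNA stack scatters
with a first Bragg peak at 2π/q ≈ 67 Å, the combined bilayer + DNA
monolayer thickness it was built with.

## Analysis workflow

Numbered drivers under `analysis/` reproduce the full set of results and
write tables under `results/`:

```sh
Rscript analysis/01_electrolyte_quantities.R   # I, l_B, Debye length, Gamma
Rscript analysis/02_model_free_energy.R        # F(x) profiles, ground state
Rscript analysis/03_synthetic_frames.R         # shell charges, censuses, RDF
Rscript analysis/04_scattering_stack.R         # I(q), lamellar period
```

`run_pipeline()` chains the same stages programmatically from one config
(list or YAML) with a manifest.

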