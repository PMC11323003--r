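---
title: "A charge-fluctuation model of DNA condensation in cationic lipid bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A charge-fluctuation model of DNA condensation in cationic lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipofluct)
```

## The problem

Genomic DNA duplexes repel each other in aqueous MgCl2: divalent magnesium
screens but does not condense double-stranded DNA in bulk solution. Yet the
same ~50 mM Mg2+ condition drives spontaneous condensation when the duplexes
are confined between cationic DOPC/DOTAP bilayers, forming the lamellar
lipoplex phase in which 1-D DNA monolayers alternate with lipid bilayers.
`lipofluct` implements a statistical-thermodynamics account of that
contrast: positively charged lipid head groups (and membrane-bridging Mg2+)
nearly neutralize the duplexes, and the residual attraction is generated by
*correlated occupancy fluctuations* of discrete Mg2+ binding sites on the
facing phosphate strands — ions "ping-ponging" between the two DNAs. The
package combines:

* an exact two-strand lattice model of those fluctuations,
* a screened mean-field rod–rod repulsion for the residual duplex charge,
* closed-form electrolyte electrostatics (ionic strength, Bjerrum and Debye
  lengths, the coupling parameter Γ = l_B/d),
* frame-based observables (concentration profiles, solvation-shell charge
  decomposition, contact/bridge censuses, radial distribution functions),
* coordinate-based scattering with a lamellar Bragg-peak readout, and
* a synthetic-configuration generator so every analysis is testable without
  molecular-dynamics output.

## The model

### Binding lattice

Each duplex contributes `N` interface phosphate sites at spacing `b` along
its length `L`. Site occupation is a binary variable: a site holding a
divalent cation has net charge `+1e` (valence α = 2 minus the phosphate
`-1e`), an empty site `-1e` (`site_charge()`). A configuration of the two
strands has the screened-Coulomb energy (in units of kBT)

```
U_corr = Σ_{i,i'} c_i c_{i'} l_B exp(-κ r_ii') / r_ii' ,
r_ii' = sqrt(x² + b²(i-i')²)
```

summed over inter-strand pairs, plus the analogous intra-strand terms at
separations `b|i-j|`. `l_B` is the Bjerrum length of a unit-charge pair in
the medium, so dividing energies by kBT is built into the length scale.

**Why intra-strand terms are included by default.** With inter-strand
coupling alone, the minimum-energy state is the fully anti-aligned pattern
(one strand fully occupied, the other empty): every cross pair is then
attractive, and nothing penalizes placing like charges side by side along a
strand. The physically expected — and experimentally motivated — ground
state is the *alternating* (checkerboard) pattern, and it emerges exactly
when the intra-strand repulsion of like site charges is kept. The
`include_intra` flag in `lattice_params()` exposes the choice; the default
is `TRUE`.

### Rod repulsion

The partially neutralized duplexes additionally interact as two parallel
uniformly charged rods in the Debye–Hückel regime:

```
U_rod(x)/kBT = 2 l_B λ(x)² L K₀(κ x),     λ(x) = ν_eff(x)/L
```

with `K₀` the modified Bessel function. Because the rods are identical this
term is nonnegative and strictly decreasing in `x` (`rod_repulsion()`). The
effective charge ν_eff(x) varies linearly with spacing between a free-state
anchor and (when given) a condensed-state anchor (`effective_charge()`).

### Grand-canonical free energy

With the Hamiltonian `H(x) = U_rod(x) + U_corr(σ; x)` the free energy over
interhelical spacing is

```
F(x) = U_rod(x) − ln Σ_σ exp(−U_corr(σ; x) + μ n(σ))
```

summed over all `2^(2N)` occupancy configurations; `μ` is the chemical
potential per bound ion (kBT units) and `n` the number of occupied sites.
`partition_free_energy()` evaluates the sum exactly (the rod term is
configuration independent and factors out);
`transfer_matrix_free_energy()` gives the identical answer in `O(N)` time
whenever the interaction is truncated at a site-offset cutoff `k` (a
sliding window of `4^k` joint states; both routines accept the same cutoff
so each can check the other). `free_energy_profile()` evaluates `F` on a
spacing grid, subtracts the value at the largest spacing (profiles are
relative, as in the free-energy plots this model is meant to mirror), and
classifies the interaction **attractive** when an interior local minimum
dips more than 0.5 kBT below that gauge.

### Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `b` (site spacing) | 1.75 | nm | average interface phosphate spacing of the simulated duplex pair |
| `L` (strand length) | 6.8 | nm | 20 bp × 0.34 nm |
| `N` (sites/strand) | `round(L/b)` = 4 | — | integer site count implied by `b`, `L` |
| α (counterion valence) | 2 | e | Mg2+ |
| `ε_r` (lipid / solution) | 40.1 / 92.2 | — | dielectric permittivities of the two simulated environments, consumed as constants |
| `T` | 300 | K | standard bilayer-simulation temperature; exposed everywhere |
| ν_eff free state (lipid / solution) | −1 / −3.5 | e per 20 bp | effective duplex charges at d = 4.0 nm |
| ν_eff condensed (lipid) | +0.17 | e | half the residual ~+0.34e shell charge of the condensed two-duplex complex, split over the two duplexes; the solution preset has no condensed anchor and stays constant |
| κ (lipid preset) | 0.1 | nm⁻¹ | salt-depleted quasi-2D interbilayer gap: the region between the confined duplexes holds few free ions, so screening is weak |
| κ (solution preset) | `debye_kappa(solution_condition())` ≈ 1.171 | nm⁻¹ | bulk Debye screening of 50 mM MgCl2 at ε_r = 92.2, 300 K |
| μ | 0 | kBT | equal a priori occupancy weights; no independent estimate of the binding chemical potential is available, and the σ → 1−σ symmetry it preserves is itself informative (see below) |
| depth threshold | 0.5 | kBT | a minimum shallower than thermal energy is not a bound state |

**One screening constant per physical system.** An alternative design
screens the correlation term weakly while giving the rod term full bulk
screening in both systems. Under that split the lipid profile loses its
interior minimum entirely (the correlation attraction grows monotonically
as `x` shrinks while the strongly screened rod term is numerically
negligible at all relevant spacings, ~0.01–0.05 kBT), so the model cannot
reproduce the attractive-with-minimum lipid profile at all. Physically, the
two terms describe fields propagating through the *same* medium: in the
lamellar gap neither the site–site nor the rod–rod interaction passes
through bulk electrolyte, while in solution both do. The presets therefore
use κ = 0.1 nm⁻¹ for both terms in the lipid system and the bulk Debye κ
for both terms in solution. Both values are ordinary parameters
(`kappa_model` in `lattice_params()`, `kappa` in `rod_params()`).

What the default presets produce (computed, not asserted — these numbers
come from `analysis/02_model_free_energy.R` and are re-checked by the test
suite):

```{r}
x <- seq(2.2, 5, by = 0.1)
lip <- model_preset("lipid")
free_energy_profile(x, lip$lattice, lip$rods)
sol <- model_preset("solution")
free_energy_profile(x, sol$lattice, sol$rods)
ground_state(3.0, lip$lattice)$configuration
```

The lipid minimum falls near 3 nm — close to the condensed-state
interhelical distances this geometry is built around (2.97 nm simulated,
2.89 nm measured) — while the solution profile rises monotonically as the
duplexes approach. The gauged free-energy profile tracks the gauged
ground-state energy to well under 1 kBT at the minimum: fluctuation entropy
barely shifts the *relative* profile, i.e. the bilayer system sits close to
its electrostatic ground state. Note that the comparison is between gauged
profiles: the ungauged difference `E_gs − F` is bounded below by `ln 2`
because the μ = 0 model has an exact global occupancy-flip symmetry
(σ → 1−σ leaves every pair energy unchanged), making the alternating ground
state exactly doubly degenerate. That `ln 2` (plus small excited-state
terms) is nearly independent of spacing and cancels in the gauge.

### Numerical choices

* **Enumeration cap.** Exact enumeration is limited to 24 total sites
  (2²⁴ configurations, evaluated in chunks); beyond that the function
  redirects to the banded transfer matrix. The default system (N = 4 per
  strand, 256 configurations) is far below the cap.
* **Ground-state ties** are broken lexicographically on the concatenated
  occupancy vector, and the number of degenerate minima is reported
  (`n_tied`; 2 for the flip-symmetric default).
* **Log-sum-exp** is used for all partition sums, so large couplings do not
  overflow.
* **Degenerate inputs**: zero coupling (`coupling_scale = 0`) reduces
  `F` to `U_rod − 2N ln 2` (ideal lattice entropy) exactly; μ → −∞
  recovers the empty lattice; ν_eff = 0 removes the rod term.

## The synthetic generator

`system_recipe()` fixes the study conditions: two 20-bp duplexes
(sequence `GCATCTGGGCTATAAAAGGG` + complement) represented by their
backbone phosphates — `2 × 19` sites of `−1e` per duplex, because
unphosphorylated 5′ termini leave 19 phosphates per 20-nt strand, which is
the only count consistent with a two-duplex bare charge of exactly −76e —
on ideal B-DNA helical tracks (rise 0.34 nm, twist 36°, backbone radius
0.94 nm); two head-group planes with DOPC fraction 0.6 (each DOPC a paired
`PC_N`(+1e)/`PC_OP`(−1e), each DOTAP a `TAP_N`(+1e)) at a 3.0 nm gap so the
planes graze the DNA surface as in the lamellar phase; hexahydrated Mg2+ as
single `+2e` particles (~0.45 nm effective contact radius, no explicit
waters) at 50 mM, with Cl⁻ added to make every frame exactly electroneutral.
Axes follow the convention: DNA long axis z, interhelical axis x, membrane
normal y. Ion placement modes: `uniform`, `metropolis` (screened-Coulomb
Monte Carlo with a 0.2 nm soft core), and `lattice_sampler`, which draws a
binding configuration from the exact lattice-model distribution and places
Mg on the occupied interface sites — tying the 3-D generator to the model's
occupancy statistics.

The lamellar stack for scattering is one unit cell — a 42 Å membrane slab
and a 25 Å DNA slab filled at different scatterer densities — tiled 16
times, giving a 67 Å repeat by construction. The 42/25 split is arbitrary
within the fixed 67 Å sum and is configurable.

What the generator does **not** emulate: atomistic lipid geometry and
disorder, explicit water, helical charge patterns beyond the phosphate
lattice, force-field energetics, and thermal membrane undulations. Passing
tests therefore demonstrate the correctness of the *analyses* (counting,
normalization, periodicity, electrostatics) on data with known ground
truth — not that real MD trajectories would yield the same censuses.

## Scattering readout

`intensity()` computes `I(q) = ⟨|Σ_j f_j exp(i q·r_j)|²⟩` for axis scans
(orientation fixed, as appropriate for an oriented lamellar stack) or the
orientation-averaged Debye double sum in powder mode, with constant
per-species electron counts as form factors — no Cromer–Mann dispersion,
no solvent-excluded-volume or hydration corrections, so absolute
intensities are schematic while peak *positions* are exact.
`first_peak()` locates the first interior maximum above `q_min` and refines
it parabolically; a relative height floor (default 20% of the profile
range) rejects the N-slit sidelobes of the finite coherent stack, which
reach ~5% of the Bragg height on their own and ~15% where they ride the
tail of the forward-scattering lobe, far below any first-order lamellar
reflection. The lamellar period then follows as `2π/q_peak`:

```{r}
stack <- build_lamellar_stack(system_recipe(seed = 42))
iq <- intensity(stack, scattering_spec(seq(0.05, 0.3, length.out = 300),
                                       direction = c(0, 1, 0)))
first_peak(iq, q_min = 0.05)
```

## Frame observables

* `concentration_profile()` bins particles along a box axis and converts to
  mol/L; in slab mode the closure `Σ c(x) V_x N_A = count` holds exactly by
  construction, and `accessible` mode subtracts sphere-approximated solute
  volume (particle-in/out by center — no partial volumes, matching the
  simple union-of-spheres shell convention used throughout).
* `shell_net_charge()` reports the total and per-species charge within a
  10 Å union-of-spheres shell of the DNA surface; the decomposition always
  sums exactly to the total, so either a head-groups-only or an
  all-particles accounting can be read off the same result.
* `coordination_count()`, `contact_census()` (direct `TAP_N`/`PC_N`
  contacts at 0.6 nm; Mg bridges with 0.5 nm legs to a membrane anion and a
  phosphate — cutoffs are not prescribed by the source analyses, so they
  are configurable, with the first RDF minimum as the recommended guide)
  and `radial_distribution()` (minimum-image, orthorhombic boxes only)
  complete the census layer. All are oracle-tested against brute-force
  pair scans.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed and is bit-reproducible. The
default problem sizes — 256 lattice configurations per spacing, 57-point
spacing grids, ~700-particle frames, 6400-scatterer stacks, 10⁵ sampler
draws — were chosen so that each analysis is exact or statistically
saturated at desk scale; all are parameters, not limits.

## Known limitations

* The lattice is 1-D per strand: helical phasing of binding sites and
  azimuthal DNA rotations are outside the model.
* μ = 0 means ion-reservoir effects (condensation onset vs bulk
  concentration) are not predicted, only the fluctuation mechanism at
  fixed average occupancy.
* The ν_eff(x) line is extrapolated beyond its two anchors; at spacings far
  outside [3, 4] nm the rod term should be read qualitatively.
* Scattering ignores solvent contrast; comparing computed and measured
  absolute intensities is out of scope by design.
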