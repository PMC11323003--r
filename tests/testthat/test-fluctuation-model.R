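lat_small <- function(n, ..., eps = 40.1, kap = 0.1) {
  lattice_params(n_sites = n, epsilon_r = eps, kappa_model = kap, ...)
}

test_that("site charge is sigma*alpha - 1", {
  expect_equal(site_charge(1, 2), 1)
  expect_equal(site_charge(0, 2), -1)
  expect_equal(site_charge(1, 3), 2)
  expect_equal(site_charge(c(0, 1, 1), 2), c(-1, 1, 1))
  expect_error(site_charge(2, 2), "0 or 1")
})

test_that("n_sites defaults to round(L/b)", {
  lat <- lattice_params(site_spacing = 1.75, strand_length = 6.8)
  expect_identical(lat$n_sites, 4L)
})

test_that("correlation energy matches the loop oracle on random configs", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    s1 <- rbinom(n, 1, 0.5); s2 <- rbinom(n, 1, 0.5)
    x <- runif(1, 1.5, 5)
    for (intra in c(TRUE, FALSE)) {
      lat <- lat_small(n, include_intra = intra)
      got <- correlation_energy(binding_configuration(s1, s2), x, lat)
      want <- oracle_corr_energy(s1, s2, x, lat$site_spacing, 2,
                                 oracle_bjerrum_nm(1, 40.1, 300), 0.1,
                                 include_intra = intra)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("single unlike pair with no screening gives -l_B/x", {
  lat <- lat_small(1, kap = 0)
  x <- 2.5
  e <- correlation_energy(binding_configuration(1, 0), x, lat)
  expect_equal(e, -oracle_bjerrum_nm(1, 40.1, 300) / x, tolerance = 1e-12)
})

test_that("energy is invariant under global occupancy flip and strand swap", {
  set.seed(7)
  lat <- lat_small(4)
  for (rep in 1:20) {
    s1 <- rbinom(4, 1, 0.5); s2 <- rbinom(4, 1, 0.5)
    x <- runif(1, 2, 5)
    e <- correlation_energy(binding_configuration(s1, s2), x, lat)
    e_flip <- correlation_energy(binding_configuration(1 - s1, 1 - s2), x, lat)
    e_swap <- correlation_energy(binding_configuration(s2, s1), x, lat)
    expect_equal(e, e_flip, tolerance = 1e-12)
    expect_equal(e, e_swap, tolerance = 1e-12)
  }
})

test_that("alternating pattern beats all-occupied at N = 2 by enumeration", {
  lat <- lat_small(2)
  e_alt <- correlation_energy(binding_configuration(c(1, 0), c(0, 1)), 3, lat)
  e_all <- correlation_energy(binding_configuration(c(1, 1), c(1, 1)), 3, lat)
  expect_lt(e_alt, e_all)
  # and the alternating pair is the global minimum of all 16 configurations
  energies <- sapply(oracle_all_configs(2), function(cfg) {
    correlation_energy(binding_configuration(cfg$s1, cfg$s2), 3, lat)
  })
  expect_equal(min(energies), e_alt, tolerance = 1e-12)
})

test_that("effective charge interpolates linearly through its anchors", {
  rp <- rod_params(nu_eff_free = -1, d_free = 4, nu_eff_condensed = 0.17,
                   d_condensed = 3, kappa = 0.1, epsilon_r = 40.1)
  expect_equal(effective_charge(4, rp), -1)
  expect_equal(effective_charge(3, rp), 0.17)
  expect_equal(effective_charge(3.5, rp), (-1 + 0.17) / 2)
  rc <- rod_params(nu_eff_free = -3.5, d_free = 4, kappa = 1.17,
                   epsilon_r = 92.2)
  expect_equal(effective_charge(c(2, 3, 6), rc), rep(-3.5, 3))
})

test_that("rod repulsion: closed form, positivity, monotone decay", {
  kap <- debye_kappa(solution_condition())
  rp <- rod_params(nu_eff_free = -3.5, d_free = 4, strand_length = 6.8,
                   kappa = kap, epsilon_r = 92.2)
  x <- 3.0
  want <- 2 * oracle_bjerrum_nm(1, 92.2, 300) * (3.5 / 6.8)^2 * 6.8 *
    besselK(kap * x, 0)
  expect_equal(rod_repulsion(x, rp), want, tolerance = 1e-12)
  xs <- seq(2, 6, by = 0.25)
  u <- rod_repulsion(xs, rp)
  expect_true(all(u >= 0))
  expect_true(all(diff(u) < 0))
  r0 <- rod_params(nu_eff_free = 0, d_free = 4, kappa = kap, epsilon_r = 92.2)
  expect_equal(rod_repulsion(xs, r0), rep(0, length(xs)))
})

test_that("enumeration free energy equals the brute-force oracle", {
  rods <- model_preset("lipid")$rods
  for (n in c(1L, 2L)) {
    for (mu in c(0, 0.8)) {
      lat <- lat_small(n, chemical_potential = mu)
      got <- partition_free_energy(3.1, lat, rods)
      want <- oracle_free_energy(3.1, lat, urod = rod_repulsion(3.1, rods))
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("free energy limits: strong negative mu and zero coupling", {
  lat <- lat_small(3, chemical_potential = -60)
  rods <- model_preset("lipid")$rods
  e_empty <- correlation_energy(
    binding_configuration(rep(0, 3), rep(0, 3)), 3, lat)
  expect_equal(partition_free_energy(3, lat, rods),
               rod_repulsion(3, rods) + e_empty, tolerance = 1e-6)
  lat0 <- lat_small(3, coupling_scale = 0)
  expect_equal(partition_free_energy(3, lat0, rods),
               rod_repulsion(3, rods) - 6 * log(2), tolerance = 1e-12)
})

test_that("enumeration cap triggers a redirect to the transfer matrix", {
  lat <- lat_small(13)
  expect_error(partition_free_energy(3, lat), "transfer_matrix")
})

test_that("transfer matrix equals enumeration under a shared offset cutoff", {
  rods <- model_preset("lipid")$rods
  for (n in c(4L, 6L)) {
    for (k in 0:3) {
      for (mu in c(0, 0.5)) {
        lat <- lat_small(n, chemical_potential = mu)
        a <- partition_free_energy(3.0, lat, rods, offset_cutoff = k)
        b <- transfer_matrix_free_energy(3.0, lat, rods, offset_cutoff = k)
        expect_lt(abs(a - b), 1e-10)
      }
    }
  }
  # N = 1 degenerates to the 4-state enumeration
  lat1 <- lat_small(1)
  expect_equal(transfer_matrix_free_energy(2.8, lat1, rods, 1),
               partition_free_energy(2.8, lat1, rods), tolerance = 1e-12)
  # zero coupling -> ideal lattice entropy
  lat0 <- lat_small(5, coupling_scale = 0)
  expect_equal(transfer_matrix_free_energy(3, lat0, rods, 1),
               rod_repulsion(3, rods) - 10 * log(2), tolerance = 1e-12)
  expect_error(transfer_matrix_free_energy(3, lat_small(2), rods, 3),
               "exceed")
})

test_that("free energy is bracketed by the ground state and lattice entropy", {
  preset <- model_preset("lipid")
  for (x in c(2.4, 3.0, 4.2, 5.0)) {
    f_corr <- partition_free_energy(x, preset$lattice) # no rod term
    e_gs <- ground_state(x, preset$lattice)$energy
    expect_lte(f_corr, e_gs + 1e-12)
    expect_gte(f_corr, e_gs - 2 * 4 * log(2) - 1e-12)
  }
})

test_that("ground state is the alternating pattern for the lipid preset", {
  lat <- model_preset("lipid")$lattice
  gs <- ground_state(3.0, lat)
  s1 <- gs$configuration$occupancy_strand1
  s2 <- gs$configuration$occupancy_strand2
  expect_true(all(abs(diff(s1)) == 1))     # alternates along the strand
  expect_identical(s2, 1L - s1)            # anti-phase across strands
  expect_identical(gs$n_tied, 2L)          # global-flip degeneracy only
})

test_that("ground state beats random configurations and the N = 1 case", {
  lat <- lat_small(4)
  gs <- ground_state(3.4, lat)
  set.seed(5)
  for (rep in 1:1000) {
    s1 <- rbinom(4, 1, 0.5); s2 <- rbinom(4, 1, 0.5)
    e <- correlation_energy(binding_configuration(s1, s2), 3.4, lat)
    expect_gte(e, gs$energy - 1e-12)
  }
  gs1 <- ground_state(3.0, lat_small(1))
  expect_equal(gs1$configuration$occupancy_strand1 +
                 gs1$configuration$occupancy_strand2, 1L)
})

test_that("profile classification separates the two presets", {
  x <- seq(2.2, 5.0, by = 0.1)
  lip <- model_preset("lipid")
  sol <- model_preset("solution")
  pl <- free_energy_profile(x, lip$lattice, lip$rods)
  ps <- free_energy_profile(x, sol$lattice, sol$rods)
  expect_identical(pl$classification, "attractive")
  expect_identical(ps$classification, "repulsive")
  expect_equal(pl$free_energy[length(x)], 0)   # gauge
  # zero coupling + zero charge -> flat, repulsive
  lat0 <- lat_small(4, coupling_scale = 0)
  rod0 <- rod_params(nu_eff_free = 0, d_free = 4, kappa = 0.1,
                     epsilon_r = 40.1)
  p0 <- free_energy_profile(x, lat0, rod0)
  expect_identical(p0$classification, "repulsive")
  expect_lt(max(abs(p0$free_energy)), 1e-10)
  expect_error(free_energy_profile(c(2, 3), lat0, rod0), "3 points")
  expect_error(free_energy_profile(c(3, 2, 4), lat0, rod0), "increasing")
})

test_that("exact sampler reproduces enumeration marginals", {
  lat <- lat_small(3, chemical_potential = 0.6)
  draw <- sample_binding_configurations(20000, 3.0, lat)
  p <- draw$marginals
  emp <- colMeans(draw$occupancy)
  se <- sqrt(p * (1 - p) / nrow(draw$occupancy))
  expect_true(all(abs(emp - p) < 4 * se))
  # marginals respect the flip symmetry at mu = 0
  d0 <- sample_binding_configurations(10, 3.0, lat_small(3))
  expect_true(all(abs(d0$marginals - 0.5) < 1e-12))
})
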