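#' Lattice parameters for the two-strand binding-site model
#'
#' The interface phosphate groups of two apposed DNA duplexes are modelled as
#' two parallel 1-D lattices of `n_sites` sites at spacing `b`. Each site is
#' either occupied by a divalent counterion (net charge `alpha - 1 = +1e` for
#' Mg2+) or empty (`-1e`). All electrostatic energies are screened Coulomb
#' pair terms expressed in kB*T via the Bjerrum length of the medium.
#'
#' @param n_sites sites per strand `N`; when `NULL`, computed as
#'   `round(strand_length / site_spacing)`.
#' @param site_spacing `b`, nm, distance between adjacent interface phosphates
#'   along a strand.
#' @param strand_length `L`, nm.
#' @param counterion_valence `alpha` (>= 1); +2 for Mg2+.
#' @param epsilon_r relative permittivity of the medium.
#' @param kappa_model screening constant used inside the correlation term,
#'   nm^-1 (>= 0).
#' @param chemical_potential `mu` in kB*T per bound ion, grand-canonical
#'   weight `exp(mu * n_bound)`.
#' @param temperature kelvin.
#' @param include_intra include intra-strand site pairs in the correlation
#'   energy. Default TRUE: with inter-strand terms alone the minimum-energy
#'   state is the fully anti-aligned pattern, whereas the physical ground
#'   state of the fluctuating interface is the alternating (checkerboard)
#'   pattern, which requires the intra-strand contribution.
#' @param coupling_scale multiplies the Bjerrum length inside the correlation
#'   term; 0 switches correlations off (useful for limits and testing).
#' @return object of class `lattice_params`.
#' @export
lattice_params <- function(n_sites = NULL, site_spacing = 1.75,
                           strand_length = 6.8, counterion_valence = 2,
                           epsilon_r = 40.1, kappa_model = 0.1,
                           chemical_potential = 0, temperature = 300,
                           include_intra = TRUE, coupling_scale = 1) {
  if (is.null(n_sites)) n_sites <- round(strand_length / site_spacing)
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites >= 1L, site_spacing > 0, strand_length > 0,
            counterion_valence >= 1, kappa_model >= 0, epsilon_r > 0,
            temperature > 0, coupling_scale >= 0)
  structure(list(n_sites = n_sites, site_spacing = site_spacing,
                 strand_length = strand_length,
                 counterion_valence = as.integer(counterion_valence),
                 epsilon_r = epsilon_r, kappa_model = kappa_model,
                 chemical_potential = chemical_potential,
                 temperature = temperature, include_intra = include_intra,
                 coupling_scale = coupling_scale),
            class = "lattice_params")
}

#' Rod parameters for the mean-field duplex-duplex repulsion
#'
#' Each partially neutralized duplex is a uniformly charged rod of length `L`
#' and effective charge `nu_eff(x)` (units of e). The screened interaction of
#' two parallel rods at separation `x` is
#' `U_rod / kBT = 2 l_B(1e) * lambda1 * lambda2 * L * K0(kappa x)` with
#' `lambda = nu_eff / L`, always repulsive since the rods are identical.
#'
#' @param nu_eff_free effective charge (e) at the free-state spacing `d_free`.
#' @param d_free nm.
#' @param nu_eff_condensed optional effective charge at `d_condensed`; when
#'   supplied, `nu_eff(x)` interpolates/extrapolates linearly through the two
#'   anchors, otherwise it is constant at `nu_eff_free`.
#' @param d_condensed nm (must be < `d_free` when given).
#' @param strand_length `L`, nm.
#' @param kappa screening constant for the rod term, nm^-1.
#' @param epsilon_r relative permittivity.
#' @param temperature kelvin.
#' @return object of class `rod_params`.
#' @export
rod_params <- function(nu_eff_free, d_free = 4.0, nu_eff_condensed = NULL,
                       d_condensed = NULL, strand_length = 6.8, kappa,
                       epsilon_r, temperature = 300) {
  stopifnot(strand_length > 0, kappa >= 0, epsilon_r > 0, temperature > 0)
  if (!is.null(nu_eff_condensed)) {
    if (is.null(d_condensed)) stop("d_condensed required with nu_eff_condensed")
    if (d_free <= d_condensed) stop("d_free must exceed d_condensed")
  }
  structure(list(nu_eff_free = nu_eff_free, d_free = d_free,
                 nu_eff_condensed = nu_eff_condensed,
                 d_condensed = d_condensed, strand_length = strand_length,
                 kappa = kappa, epsilon_r = epsilon_r,
                 temperature = temperature),
            class = "rod_params")
}

# Bjerrum length (nm) of a 1e pair from any parameter object with
# epsilon_r / temperature fields.
.lb1 <- function(p) {
  num <- .const$e_C^2
  den <- 4 * pi * .const$eps0 * p$epsilon_r * .const$kB * p$temperature
  (num / den) * 1e9
}

#' Model presets for the lipid-bound and in-solution DNA pair
#'
#' The lipid preset uses eps_r = 40.1, weak screening
#' (kappa = 0.1 nm^-1, the salt-depleted interbilayer gap) in both the
#' correlation and rod terms, and effective-charge anchors
#' `nu_eff(4.0 nm) = -1e` (free state) and `nu_eff(3.0 nm) = +0.17e`
#' (condensed state, half the residual shell charge of the two-duplex
#' complex). The solution preset uses eps_r = 92.2, bulk Debye screening from
#' 50 mM MgCl2, and a constant `nu_eff = -3.5e` per 20-bp duplex.
#'
#' @param system `"lipid"` or `"solution"`.
#' @param temperature kelvin.
#' @return list with elements `lattice` ([lattice_params()]), `rods`
#'   ([rod_params()]) and `condition` ([electrolyte_condition()]).
#' @export
model_preset <- function(system = c("lipid", "solution"), temperature = 300) {
  system <- match.arg(system)
  if (system == "lipid") {
    cond <- lipid_condition(temperature = temperature)
    kap <- 0.1
    lat <- lattice_params(epsilon_r = 40.1, kappa_model = kap,
                          temperature = temperature)
    rod <- rod_params(nu_eff_free = -1, d_free = 4.0,
                      nu_eff_condensed = 0.17, d_condensed = 3.0,
                      strand_length = 6.8, kappa = kap, epsilon_r = 40.1,
                      temperature = temperature)
  } else {
    cond <- solution_condition(temperature = temperature)
    kap <- debye_kappa(cond)
    lat <- lattice_params(epsilon_r = 92.2, kappa_model = kap,
                          temperature = temperature)
    rod <- rod_params(nu_eff_free = -3.5, d_free = 4.0,
                      strand_length = 6.8, kappa = kap, epsilon_r = 92.2,
                      temperature = temperature)
  }
  list(lattice = lat, rods = rod, condition = cond)
}

#' Net charge of a binding site
#'
#' An occupied site carries the counterion valence minus the phosphate charge
#' (`sigma * alpha - 1`); +1e for Mg2+ on a phosphate, -1e when empty.
#'
#' @param sigma occupation variable, 0 or 1 (vectorized).
#' @param alpha counterion valence.
#' @return site charge in units of e.
#' @export
site_charge <- function(sigma, alpha = 2) {
  if (!all(sigma %in% c(0, 1))) stop("sigma must be 0 or 1")
  sigma * alpha - 1
}

#' Binding configuration of the two strands
#'
#' @param occupancy_strand1,occupancy_strand2 binary vectors of equal length.
#' @return object of class `binding_configuration`.
#' @export
binding_configuration <- function(occupancy_strand1, occupancy_strand2) {
  s1 <- as.integer(occupancy_strand1); s2 <- as.integer(occupancy_strand2)
  if (length(s1) != length(s2)) stop("strands must have equal length")
  if (!all(c(s1, s2) %in% c(0L, 1L))) stop("occupancies must be 0/1")
  structure(list(occupancy_strand1 = s1, occupancy_strand2 = s2),
            class = "binding_configuration")
}

# Screened-Coulomb kernels (kB*T for unit charges), distances in nm.
# v(k): inter-strand pair at site offset k; u(k): intra-strand offset k >= 1.
.inter_kernel <- function(offsets, spacing, params) {
  r <- sqrt(spacing^2 + (params$site_spacing * offsets)^2)
  params$coupling_scale * .lb1(params) * exp(-params$kappa_model * r) / r
}

.intra_kernel <- function(offsets, params) {
  r <- params$site_spacing * offsets
  params$coupling_scale * .lb1(params) * exp(-params$kappa_model * r) / r
}

#' Correlation energy of one binding configuration
#'
#' Pairwise screened Coulomb energy of the site charges, in kB*T:
#' inter-strand pairs interact over `r = sqrt(x^2 + b^2 (i - i')^2)`,
#' intra-strand pairs (included by default, see [lattice_params()]) over
#' `r = b |i - j|`.
#'
#' @param config a [binding_configuration()].
#' @param spacing interhelical spacing `x` in nm (> 0).
#' @param params a [lattice_params()].
#' @param offset_cutoff only site pairs with index offset `<=` this value
#'   interact (Inf = full range); shared by [transfer_matrix_free_energy()].
#' @return energy in kB*T.
#' @export
correlation_energy <- function(config, spacing, params, offset_cutoff = Inf) {
  stopifnot(inherits(config, "binding_configuration"),
            inherits(params, "lattice_params"))
  if (spacing <= 0) stop("spacing must be > 0")
  n <- length(config$occupancy_strand1)
  a <- params$counterion_valence
  c1 <- site_charge(config$occupancy_strand1, a)
  c2 <- site_charge(config$occupancy_strand2, a)
  idx <- seq_len(n)
  off <- abs(outer(idx, idx, "-"))
  vmat <- .inter_kernel(off, spacing, params)
  vmat[off > offset_cutoff] <- 0
  e <- as.numeric(t(c1) %*% vmat %*% c2)
  if (isTRUE(params$include_intra) && n > 1L) {
    umat <- matrix(0, n, n)
    pos <- off > 0 & off <= offset_cutoff
    umat[pos] <- .intra_kernel(off[pos], params)
    e <- e + 0.5 * (as.numeric(t(c1) %*% umat %*% c1) +
                    as.numeric(t(c2) %*% umat %*% c2))
  }
  e
}

#' Effective duplex charge at a given spacing
#'
#' Linear interpolation/extrapolation through the free-state anchor
#' `(d_free, nu_eff_free)` and, when present, the condensed-state anchor
#' `(d_condensed, nu_eff_condensed)`; constant otherwise.
#'
#' @param spacing nm (> 0), vectorized.
#' @param params a [rod_params()].
#' @return effective charge in units of e.
#' @export
effective_charge <- function(spacing, params) {
  stopifnot(inherits(params, "rod_params"))
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (is.null(params$nu_eff_condensed)) {
    return(rep(params$nu_eff_free, length(spacing)))
  }
  slope <- (params$nu_eff_free - params$nu_eff_condensed) /
    (params$d_free - params$d_condensed)
  params$nu_eff_free + slope * (spacing - params$d_free)
}

#' Mean-field rod-rod repulsion
#'
#' `U_rod / kBT = 2 l_B(1e) lambda(x)^2 L K0(kappa x)` with
#' `lambda(x) = nu_eff(x) / L`. Nonnegative by construction (identical rods)
#' and strictly decreasing in `x` for fixed `nu_eff`.
#'
#' @param spacing nm (> 0), vectorized.
#' @param params a [rod_params()].
#' @return energy in kB*T.
#' @export
rod_repulsion <- function(spacing, params) {
  stopifnot(inherits(params, "rod_params"))
  if (any(spacing <= 0)) stop("spacing must be > 0")
  lam <- effective_charge(spacing, params) / params$strand_length
  2 * .lb1(params) * lam^2 * params$strand_length *
    besselK(params$kappa * spacing, nu = 0)
}

# Enumerate all 2^(2N) configurations as occupancy matrices, chunked so the
# working set stays bounded. f(occ_chunk) is called with a (chunk x 2N)
# 0/1 matrix (strand 1 = columns 1..N, strand 2 = columns N+1..2N) and must
# return a numeric vector; results are concatenated in lexicographic order
# (site N+N varies fastest ... column 1 slowest).
.enumerate_apply <- function(n_sites, f, chunk_bits = 16L) {
  m <- 2L * n_sites
  total <- 2^m
  chunk <- 2^min(chunk_bits, m)
  out <- vector("list", total / chunk)
  for (k in seq_along(out)) {
    ids <- (k - 1L) * chunk + seq_len(chunk) - 1L
    occ <- matrix(0L, length(ids), m)
    for (b in seq_len(m)) {               # column 1 is the highest-order bit
      occ[, b] <- bitwAnd(ids %/% 2^(m - b), 1L)
    }
    out[[k]] <- f(occ)
  }
  unlist(out, use.names = FALSE)
}

# Correlation energies for a block of configurations (rows of `occ`).
.block_energy <- function(occ, spacing, params, offset_cutoff = Inf) {
  n <- params$n_sites
  a <- params$counterion_valence
  ch <- occ * a - 1
  c1 <- ch[, seq_len(n), drop = FALSE]
  c2 <- ch[, n + seq_len(n), drop = FALSE]
  idx <- seq_len(n)
  off <- abs(outer(idx, idx, "-"))
  vmat <- .inter_kernel(off, spacing, params)
  vmat[off > offset_cutoff] <- 0
  e <- rowSums((c1 %*% vmat) * c2)
  if (isTRUE(params$include_intra) && n > 1L) {
    umat <- matrix(0, n, n)
    pos <- off > 0 & off <= offset_cutoff
    umat[pos] <- .intra_kernel(off[pos], params)
    e <- e + 0.5 * (rowSums((c1 %*% umat) * c1) +
                    rowSums((c2 %*% umat) * c2))
  }
  e
}

.check_enumeration_cap <- function(params, cap = 24L) {
  if (2L * params$n_sites > cap) {
    stop(sprintf(paste0("2 x %d sites exceeds the enumeration cap of %d; ",
                        "use transfer_matrix_free_energy()"),
                 params$n_sites, cap))
  }
}

#' Grand-canonical free energy by exact enumeration
#'
#' `F(x) = U_rod(x) - ln sum_configs exp(-U_corr(config, x) + mu n_bound)`
#' over all `2^(2N)` occupancy configurations, energies in kB*T. The rod term
#' is configuration independent and factors out exactly.
#'
#' @param spacing interhelical spacing `x`, nm (> 0).
#' @param lattice a [lattice_params()].
#' @param rods a [rod_params()]; `NULL` drops the rod term.
#' @param offset_cutoff optional site-offset interaction cutoff shared with
#'   [transfer_matrix_free_energy()].
#' @param cap maximum total site count for enumeration (default 24).
#' @return free energy in kB*T.
#' @export
partition_free_energy <- function(spacing, lattice, rods = NULL,
                                  offset_cutoff = Inf, cap = 24L) {
  stopifnot(inherits(lattice, "lattice_params"))
  if (spacing <= 0) stop("spacing must be > 0")
  .check_enumeration_cap(lattice, cap)
  mu <- lattice$chemical_potential
  w <- .enumerate_apply(lattice$n_sites, function(occ) {
    -.block_energy(occ, spacing, lattice, offset_cutoff) + mu * rowSums(occ)
  })
  urod <- if (is.null(rods)) 0 else rod_repulsion(spacing, rods)
  wmax <- max(w)
  urod - (wmax + log(sum(exp(w - wmax))))
}

#' Grand-canonical free energy by banded transfer matrix
#'
#' Exact equivalent of [partition_free_energy()] for interactions truncated at
#' a site-offset cutoff `k`: the pair of strands is scanned site by site with
#' a sliding-window state space of `4^k` joint occupancy states, so the cost
#' is linear in `N` instead of `2^(2N)`.
#'
#' @param spacing nm (> 0).
#' @param lattice a [lattice_params()].
#' @param rods a [rod_params()] or `NULL`.
#' @param offset_cutoff interaction range in site offsets (0..3, default 1);
#'   must not exceed `n_sites`.
#' @return free energy in kB*T.
#' @export
transfer_matrix_free_energy <- function(spacing, lattice, rods = NULL,
                                        offset_cutoff = 1L) {
  stopifnot(inherits(lattice, "lattice_params"))
  if (spacing <= 0) stop("spacing must be > 0")
  k <- as.integer(offset_cutoff)
  n <- lattice$n_sites
  if (k > n) stop("offset_cutoff must not exceed n_sites")
  if (k < 0L || k > 3L) stop("offset_cutoff must be in 0..3")
  a <- lattice$counterion_valence
  mu <- lattice$chemical_potential
  v <- .inter_kernel(0:k, spacing, lattice)
  u <- if (k >= 1L) .intra_kernel(seq_len(max(k, 1L)), lattice) else numeric(0)
  intra <- isTRUE(lattice$include_intra)

  # column states: (sigma1, sigma2) in 0..3; charges of one column
  col_states <- expand.grid(s1 = 0:1, s2 = 0:1)
  cc1 <- col_states$s1 * a - 1
  cc2 <- col_states$s2 * a - 1
  nb  <- col_states$s1 + col_states$s2
  # log-weight of one column in isolation: onsite inter pair + mu term
  w_site <- -(cc1 * cc2 * v[1]) + mu * nb
  # pair coupling between columns at offset o (1..k)
  pair_lw <- function(sa, sb, o) {
    e <- cc1[sa] * cc2[sb] * v[o + 1] + cc2[sa] * cc1[sb] * v[o + 1]
    if (intra) e <- e + cc1[sa] * cc1[sb] * u[o] + cc2[sa] * cc2[sb] * u[o]
    -e
  }

  if (k == 0L) {
    lz <- n * log(sum(exp(w_site)))
  } else {
    # window = ordered tuple of the last k column states; 4^k window states
    grid <- as.matrix(expand.grid(rep(list(1:4), k)))  # col 1 = oldest
    nw <- nrow(grid)
    # initialize with the first k columns (all mutual interactions included)
    lw <- numeric(nw)
    for (s in seq_len(nw)) {
      e <- sum(w_site[grid[s, ]])
      if (k >= 2L) {
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
          e <- e + pair_lw(grid[s, i], grid[s, j], j - i)
        }
      }
      lw[s] <- e
    }
    if (n > k) {
      # transition: window (c_{i-k},...,c_{i-1}) -> append column c_i
      for (step in seq_len(n - k)) {
        new_lw <- rep(-Inf, nw)
        for (s in seq_len(nw)) {
          for (cnew in 1:4) {
            add <- w_site[cnew]
            for (o in seq_len(k)) {       # offset o to the o-th previous col
              add <- add + pair_lw(grid[s, k - o + 1L], cnew, o)
            }
            tgt <- which(colSums(t(grid) !=
                            c(grid[s, -1L, drop = TRUE], cnew)) == 0L)
            val <- lw[s] + add
            m <- max(new_lw[tgt], val)
            new_lw[tgt] <- m + log(exp(new_lw[tgt] - m) + exp(val - m))
          }
        }
        lw <- new_lw
      }
    }
    m <- max(lw)
    lz <- m + log(sum(exp(lw - m)))
  }
  urod <- if (is.null(rods)) 0 else rod_repulsion(spacing, rods)
  urod - lz
}

#' Minimum-energy binding configuration
#'
#' Enumerates all configurations and returns the one minimizing the
#' correlation energy `U_corr` at the given spacing (chemical potential does
#' not enter). Ties are broken lexicographically on the concatenated
#' occupancy vector and reported.
#'
#' @param spacing nm (> 0).
#' @param lattice a [lattice_params()].
#' @param cap enumeration cap on total sites.
#' @return list with `configuration` ([binding_configuration()]), `energy`
#'   (kB*T), `n_tied` (number of degenerate minima, ties broken
#'   lexicographically).
#' @export
ground_state <- function(spacing, lattice, cap = 24L) {
  stopifnot(inherits(lattice, "lattice_params"))
  if (spacing <= 0) stop("spacing must be > 0")
  .check_enumeration_cap(lattice, cap)
  n <- lattice$n_sites
  e <- .enumerate_apply(n, function(occ) .block_energy(occ, spacing, lattice))
  emin <- min(e)
  tied <- which(e <= emin + 1e-12)
  id <- tied[1] - 1L                      # lexicographically first
  m <- 2L * n
  occ <- vapply(seq_len(m), function(b) bitwAnd(id %/% 2^(m - b), 1L),
                integer(1))
  list(configuration = binding_configuration(occ[seq_len(n)],
                                             occ[n + seq_len(n)]),
       energy = emin, n_tied = length(tied))
}

#' Free-energy profile over interhelical spacing
#'
#' Evaluates the grand-canonical free energy on a grid of spacings, subtracts
#' the value at the largest spacing (the gauge used for plotting relative
#' profiles), and classifies the interaction: `attractive` iff an interior
#' local minimum lies below the gauge by more than `depth_threshold`.
#'
#' @param x_grid strictly increasing spacings, nm, length >= 3.
#' @param lattice a [lattice_params()].
#' @param rods a [rod_params()].
#' @param depth_threshold kB*T depth below the gauge required to call the
#'   profile attractive (default 0.5).
#' @return object of class `free_energy_profile`: list with `spacings`,
#'   `free_energy` (gauged, kB*T), `classification`, `x_min`, `depth`.
#' @export
free_energy_profile <- function(x_grid, lattice, rods,
                                depth_threshold = 0.5) {
  if (length(x_grid) < 3L) stop("x_grid needs at least 3 points")
  if (any(diff(x_grid) <= 0)) stop("x_grid must be strictly increasing")
  if (any(x_grid <= 0)) stop("spacings must be > 0")
  f <- vapply(x_grid, partition_free_energy, numeric(1),
              lattice = lattice, rods = rods)
  f <- f - f[length(f)]
  interior <- seq(2L, length(f) - 1L)
  is_min <- interior[f[interior] <= f[interior - 1L] &
                     f[interior] <= f[interior + 1L]]
  attract <- length(is_min) > 0 && min(f[is_min]) < -depth_threshold
  x_min <- NA_real_; depth <- NA_real_
  if (length(is_min) > 0) {
    i <- is_min[which.min(f[is_min])]
    x_min <- x_grid[i]; depth <- -f[i]
  }
  structure(list(spacings = x_grid, free_energy = f,
                 classification = if (attract) "attractive" else "repulsive",
                 x_min = x_min, depth = depth),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("Free-energy profile over %d spacings [%.2f, %.2f] nm\n",
              length(x$spacings), min(x$spacings), max(x$spacings)))
  cat(sprintf("  classification: %s", x$classification))
  if (!is.na(x$x_min)) {
    cat(sprintf("  (minimum at %.2f nm, depth %.2f kBT)", x$x_min, x$depth))
  }
  cat("\n")
  invisible(x)
}

#' Gauged ground-state energy profile
#'
#' `U_rod(x) + min_config U_corr(config, x)` on a grid, referenced to the
#' largest spacing: the zero-temperature counterpart of
#' [free_energy_profile()], used to check how closely the free energy tracks
#' the ground state.
#'
#' @inheritParams free_energy_profile
#' @return list with `spacings` and `energy` (gauged, kB*T).
#' @export
ground_state_profile <- function(x_grid, lattice, rods) {
  e <- vapply(x_grid, function(x) {
    ground_state(x, lattice)$energy + rod_repulsion(x, rods)
  }, numeric(1))
  list(spacings = x_grid, energy = e - e[length(e)])
}

#' Sample binding configurations from the exact Boltzmann distribution
#'
#' Draws occupancy configurations with probability proportional to
#' `exp(-U_corr + mu n_bound)` by enumerating the configuration weights
#' (exact, no Markov chain). Used by the synthetic generator's lattice
#' sampler and for marginal-occupancy checks.
#'
#' @param n_draws number of configurations to draw.
#' @param spacing nm (> 0).
#' @param lattice a [lattice_params()].
#' @return list with `occupancy` (`n_draws x 2N` 0/1 matrix; strand 1 in
#'   columns `1..N`) and `marginals` (exact per-site occupation
#'   probabilities, length `2N`).
#' @export
sample_binding_configurations <- function(n_draws, spacing, lattice) {
  stopifnot(inherits(lattice, "lattice_params"))
  .check_enumeration_cap(lattice)
  n <- lattice$n_sites
  m <- 2L * n
  mu <- lattice$chemical_potential
  lw <- .enumerate_apply(n, function(occ) {
    -.block_energy(occ, spacing, lattice) + mu * rowSums(occ)
  })
  w <- exp(lw - max(lw))
  p <- w / sum(w)
  ids <- sample.int(length(p), n_draws, replace = TRUE, prob = p) - 1L
  occ <- matrix(0L, n_draws, m)
  for (b in seq_len(m)) occ[, b] <- bitwAnd(ids %/% 2^(m - b), 1L)
  marg <- vapply(seq_len(m), function(b) {
    bits <- bitwAnd((seq_along(p) - 1L) %/% 2^(m - b), 1L)
    sum(p * bits)
  }, numeric(1))
  list(occupancy = occ, marginals = marg)
}
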