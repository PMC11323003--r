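# Independent oracles: deliberately naive loop-based implementations used to
# cross-check the vectorized package code.

# SI Bjerrum length, nm, written out from the constants directly.
oracle_bjerrum_nm <- function(q, eps_r, temp_k) {
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; kb <- 1.380649e-23
  (q * e)^2 / (4 * pi * eps0 * eps_r * kb * temp_k) * 1e9
}

# Correlation energy by explicit loops over every site pair.
oracle_corr_energy <- function(s1, s2, spacing, b, alpha, lb1, kappa,
                               include_intra = TRUE) {
  c1 <- s1 * alpha - 1; c2 <- s2 * alpha - 1
  n <- length(s1)
  e <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- sqrt(spacing^2 + (b * (i - j))^2)
    e <- e + c1[i] * c2[j] * lb1 * exp(-kappa * r) / r
  }
  if (include_intra && n > 1) {
    for (cc in list(c1, c2)) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        r <- b * (j - i)
        e <- e + cc[i] * cc[j] * lb1 * exp(-kappa * r) / r
      }
    }
  }
  e
}

# All 0/1 occupancy pairs for N sites per strand, as a list of (s1, s2).
oracle_all_configs <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(0:1), 2 * n)))
  lapply(seq_len(nrow(grid)), function(k) {
    list(s1 = grid[k, seq_len(n)], s2 = grid[k, n + seq_len(n)])
  })
}

# Grand-canonical free energy by direct summation over the oracle configs.
oracle_free_energy <- function(spacing, lat, urod = 0) {
  lb1 <- oracle_bjerrum_nm(1, lat$epsilon_r, lat$temperature) *
    lat$coupling_scale
  z <- 0
  for (cfg in oracle_all_configs(lat$n_sites)) {
    e <- oracle_corr_energy(cfg$s1, cfg$s2, spacing, lat$site_spacing,
                            lat$counterion_valence, lb1, lat$kappa_model,
                            lat$include_intra)
    z <- z + exp(-e + lat$chemical_potential * sum(cfg$s1, cfg$s2))
  }
  as.numeric(urod - log(z))
}

# Brute-force minimum-image distance between two points.
oracle_min_image_dist <- function(p, q, box) {
  d <- p - q
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# O(N^2) pair scans over a frame.
oracle_count_within <- function(fr, ctr_sp, prt_sp, cutoff) {
  ctr <- which(fr$species %in% ctr_sp)
  prt <- which(fr$species %in% prt_sp)
  n <- 0
  for (j in prt) {
    hit <- FALSE
    for (i in ctr) {
      if (oracle_min_image_dist(fr$positions[j, ], fr$positions[i, ],
                                fr$box) <= cutoff) hit <- TRUE
    }
    if (hit) n <- n + 1
  }
  n
}

oracle_rdf_hist <- function(fr, sp_a, sp_b, edges) {
  ia <- which(fr$species == sp_a); ib <- which(fr$species == sp_b)
  h <- numeric(length(edges) - 1)
  same <- identical(sp_a, sp_b)
  for (i in ia) for (j in ib) {
    if (same && j <= i) next
    d <- oracle_min_image_dist(fr$positions[i, ], fr$positions[j, ], fr$box)
    k <- findInterval(d, edges, left.open = TRUE)
    if (d > 0 && k >= 1 && k <= length(h)) h[k] <- h[k] + 1
  }
  h
}

# Direct double-sum axis-scan intensity.
oracle_axis_intensity <- function(fr, f_by_species, q, direction) {
  f <- f_by_species[fr$species]
  r_A <- fr$positions * 10
  proj <- as.numeric(r_A %*% (direction / sqrt(sum(direction^2))))
  sapply(q, function(qq) {
    s <- 0
    for (j in seq_along(f)) for (k in seq_along(f)) {
      s <- s + f[j] * f[k] * cos(qq * (proj[j] - proj[k]))
    }
    s
  })
}

# Small random frame of labelled charges for census tests.
random_frame <- function(n = 60, box = c(5, 5, 5),
                         species_pool = c("DNA_P", "MG", "CL", "PC_N",
                                          "PC_OP", "TAP_N"),
                         seed = 42) {
  set.seed(seed)
  sp <- sample(species_pool, n, replace = TRUE)
  q <- unname(default_charge_table()[sp])
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  frame(pos, sp, q, box)
}
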