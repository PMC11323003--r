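#' Recipe for a synthetic membrane-DNA-MgCl2 system
#'
#' Defines the idealized study conditions the generator emulates: two 20-bp
#' B-DNA duplexes (backbone phosphate sites only) with their long axes along
#' z at interhelical spacing along x, two membrane head-group planes normal
#' to y with DOPC/DOTAP composition `phi_dopc`, hexahydrated Mg2+ (+2e,
#' effective contact distance ~0.45 nm, no explicit waters) and Cl- (-1e) at
#' ~50 mM MgCl2, and a 1-D lamellar stack for scattering whose repeat is the
#' bilayer thickness plus the DNA-monolayer thickness.
#'
#' @param n_bp base pairs per duplex (default 20).
#' @param interhelical_spacing nm (default 3.0, near the condensed state).
#' @param box box lengths (x, y, z) in nm; the default z equals the duplex
#'   length `0.34 * n_bp` so the helices continue periodically.
#' @param mg_concentration mol/L (default 0.05).
#' @param phi_dopc DOPC mole fraction (default 0.6).
#' @param membrane_gap separation of the two head-group planes along y, nm
#'   (default 3.0: the head-group planes graze the DNA surface, as in the
#'   lamellar phase where direct head-group/backbone contacts occur).
#' @param lipids_per_plane head-group sites per plane.
#' @param bilayer_thickness,dna_layer_thickness lamellar-stack layer
#'   thicknesses, Angstrom (defaults 42 + 25 = 67 Angstrom repeat).
#' @param seed integer RNG seed used by the stochastic generator modes.
#' @return object of class `system_recipe`.
#' @export
system_recipe <- function(n_bp = 20L, interhelical_spacing = 3.0,
                          box = c(20, 10, 0.34 * n_bp),
                          mg_concentration = 0.05, phi_dopc = 0.6,
                          membrane_gap = 3.0, lipids_per_plane = 100L,
                          bilayer_thickness = 42, dna_layer_thickness = 25,
                          seed = 1L) {
  stopifnot(n_bp >= 1L, mg_concentration >= 0, phi_dopc >= 0, phi_dopc <= 1,
            all(box > 0), membrane_gap > 0, membrane_gap < box[2],
            bilayer_thickness > 0, dna_layer_thickness > 0)
  structure(list(n_bp = as.integer(n_bp),
                 interhelical_spacing = interhelical_spacing,
                 box = as.numeric(box), mg_concentration = mg_concentration,
                 phi_dopc = phi_dopc, membrane_gap = membrane_gap,
                 lipids_per_plane = as.integer(lipids_per_plane),
                 bilayer_thickness = bilayer_thickness,
                 dna_layer_thickness = dna_layer_thickness,
                 seed = as.integer(seed)),
            class = "system_recipe")
}

#' Idealized duplex backbone phosphate sites
#'
#' Places `2 * (n_bp - 1)` phosphate sites (unphosphorylated 5' termini, so
#' 19 phosphates per strand of a 20-mer) of charge -1e on two helical tracks
#' around the duplex axis (along z). Defaults are canonical B-DNA: rise
#' 0.34 nm/bp, twist 36 degrees/bp, backbone radius 0.94 nm; the second
#' strand is offset azimuthally by the minor-groove angle.
#'
#' @param n_bp base pairs.
#' @param axis_origin 3-vector, nm: position of the duplex axis at z = 0.
#' @param rise nm per bp.
#' @param twist degrees per bp.
#' @param radius nm.
#' @return data.frame with columns `x`, `y`, `z`, `species` (`DNA_P`),
#'   `charge`.
#' @export
build_duplex_sites <- function(n_bp, axis_origin = c(0, 0, 0), rise = 0.34,
                               twist = 36, radius = 0.94) {
  stopifnot(n_bp >= 1L)
  n_p <- n_bp - 1L
  if (n_p == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      species = character(0), charge = numeric(0)))
  }
  i <- seq_len(n_p)
  th1 <- (i - 1) * twist * pi / 180
  th2 <- th1 + 154 * pi / 180            # minor-groove offset
  z <- axis_origin[3] + (i - 0.5) * rise
  s1 <- data.frame(x = axis_origin[1] + radius * cos(th1),
                   y = axis_origin[2] + radius * sin(th1), z = z)
  s2 <- data.frame(x = axis_origin[1] + radius * cos(th2),
                   y = axis_origin[2] + radius * sin(th2), z = z)
  out <- rbind(s1, s2)
  out$species <- "DNA_P"
  out$charge <- -1
  out
}

#' Membrane head-group planes
#'
#' Two parallel planes of head-group sites at `y = y_center +/-
#' membrane_gap / 2` spanning the box in x and z. Composition follows
#' `phi_dopc`: each DOPC contributes a paired `PC_N` (+1e) / `PC_OP` (-1e)
#' site, each DOTAP a single `TAP_N` (+1e), so a plane's net charge equals
#' its DOTAP count.
#'
#' @param recipe a [system_recipe()].
#' @return data.frame with columns `x`, `y`, `z`, `species`, `charge`.
#' @export
build_membrane_planes <- function(recipe) {
  stopifnot(inherits(recipe, "system_recipe"))
  n <- recipe$lipids_per_plane
  n_pc <- round(recipe$phi_dopc * n)
  n_tap <- n - n_pc
  # lay lipids on a near-square grid in the x-z plane
  nx <- ceiling(sqrt(n * recipe$box[1] / recipe$box[3]))
  nz <- ceiling(n / nx)
  if (nx * nz < n) stop("plane grid construction failed")
  gx <- (rep(seq_len(nx), times = nz)[seq_len(n)] - 0.5) * recipe$box[1] / nx
  gz <- (rep(seq_len(nz), each = nx)[seq_len(n)] - 0.5) * recipe$box[3] / nz
  y_c <- recipe$box[2] / 2
  planes <- list()
  for (sgn in c(-1, 1)) {
    y0 <- y_c + sgn * recipe$membrane_gap / 2
    kind <- rep(c("PC", "TAP"), c(n_pc, n_tap))
    pc <- kind == "PC"
    # PC: choline N (+1) at the surface, phosphate OP (-1) slightly behind
    piece <- function(sel, sp, q, dy = 0) {
      if (!any(sel)) return(NULL)
      data.frame(x = gx[sel], y = y0 + dy, z = gz[sel],
                 species = sp, charge = q)
    }
    planes[[length(planes) + 1L]] <- rbind(
      piece(pc, "PC_N", 1),
      piece(pc, "PC_OP", -1, dy = sgn * 0.2),
      piece(!pc, "TAP_N", 1))
  }
  do.call(rbind, planes)
}

#' Fixed particle scaffold (DNA duplex pair + membrane planes)
#'
#' Convenience constructor of the immobile part of the synthetic system: two
#' duplexes at `+/- interhelical_spacing / 2` around the box center along x,
#' plus the two membrane planes.
#'
#' @param recipe a [system_recipe()].
#' @param membranes include membrane planes (default TRUE).
#' @return data.frame with columns `x`, `y`, `z`, `species`, `charge`.
#' @export
build_scaffold <- function(recipe, membranes = TRUE) {
  ctr <- recipe$box / 2
  half <- recipe$interhelical_spacing / 2
  d1 <- build_duplex_sites(recipe$n_bp,
                           axis_origin = c(ctr[1] - half, ctr[2], 0))
  d2 <- build_duplex_sites(recipe$n_bp,
                           axis_origin = c(ctr[1] + half, ctr[2], 0))
  out <- rbind(d1, d2)
  if (membranes) out <- rbind(out, build_membrane_planes(recipe))
  out
}

#' Add mobile ions and close the frame
#'
#' Adds Mg2+ (+2e) at the count implied by `mg_concentration` and the box
#' volume, then exactly enough Cl- (-1e) to make the full frame
#' electroneutral. Modes: `uniform` (ideal-gas placement), `metropolis`
#' (Metropolis Monte Carlo equilibration of the mobile ions under a screened
#' Coulomb pair energy) and `lattice_sampler` (one binding configuration is
#' drawn from the two-strand lattice model and Mg ions are placed at the
#' occupied interface phosphate sites; remaining ions uniform).
#'
#' @param recipe a [system_recipe()].
#' @param particles fixed-particle data.frame from [build_scaffold()] (or
#'   compatible); may be `NULL` for pure electrolyte boxes.
#' @param mode `"uniform"`, `"metropolis"` or `"lattice_sampler"`.
#' @param lattice a [lattice_params()] for `lattice_sampler` mode.
#' @param n_sweeps Metropolis sweeps over the mobile ions (default 200).
#' @param kappa screening constant of the Metropolis pair energy, nm^-1.
#' @param epsilon_r medium permittivity for the Metropolis energy.
#' @param max_step maximum Metropolis displacement per move, nm.
#' @param seed RNG seed; defaults to `recipe$seed`.
#' @return an electroneutral, wrapped [frame()].
#' @export
place_ions <- function(recipe, particles = NULL,
                       mode = c("uniform", "metropolis", "lattice_sampler"),
                       lattice = NULL, n_sweeps = 200L, kappa = 0.5,
                       epsilon_r = 40.1, max_step = 1.0, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(recipe, "system_recipe"))
  if (is.null(seed)) seed <- recipe$seed
  set.seed(seed)
  box <- recipe$box
  vol <- prod(box)
  n_mg <- round(recipe$mg_concentration * .molar_to_nm3(1) * vol)
  q_fixed <- if (is.null(particles)) 0 else sum(particles$charge)
  n_cl <- q_fixed + 2 * n_mg
  if (n_cl < 0) stop("implied Cl- count is negative; add Mg2+ or reduce ",
                     "fixed positive charge")
  runif_box <- function(n) {
    cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
          stats::runif(n, 0, box[3]))
  }
  mg_pos <- runif_box(n_mg)
  if (mode == "lattice_sampler") {
    if (is.null(lattice)) stop("lattice_sampler mode needs `lattice`")
    draw <- sample_binding_configurations(1L, recipe$interhelical_spacing,
                                          lattice)
    occ <- draw$occupancy[1, ]
    sites <- .interface_sites(recipe, lattice$n_sites)
    n_occ <- sum(occ)
    if (n_occ > n_mg) stop("fewer Mg ions than occupied lattice sites")
    if (n_occ > 0) mg_pos[seq_len(n_occ), ] <- sites[occ == 1L, , drop = FALSE]
  }
  cl_pos <- runif_box(n_cl)
  pos <- rbind(if (!is.null(particles)) as.matrix(particles[, c("x", "y", "z")]),
               mg_pos, cl_pos)
  species <- c(if (!is.null(particles)) particles$species,
               rep("MG", n_mg), rep("CL", n_cl))
  charges <- c(if (!is.null(particles)) particles$charge,
               rep(2, n_mg), rep(-1, n_cl))
  fr <- frame(pos, species, charges, box)
  if (mode == "metropolis" && (n_mg + n_cl) > 0) {
    fr <- .metropolis_ions(fr, mobile = species %in% c("MG", "CL"),
                           n_sweeps = n_sweeps, kappa = kappa,
                           epsilon_r = epsilon_r, max_step = max_step)
  }
  fr
}

# Interface phosphate lattice positions used by the lattice sampler:
# 2 * n_sites points on the facing flanks of the two duplexes, spaced b along
# z, strand 1 (columns 1..N of the occupancy) on the left duplex.
.interface_sites <- function(recipe, n_sites) {
  ctr <- recipe$box / 2
  half <- recipe$interhelical_spacing / 2
  b <- recipe$box[3] / n_sites
  z <- (seq_len(n_sites) - 0.5) * b
  rbind(cbind(ctr[1] - half + 0.94, ctr[2], z),
        cbind(ctr[1] + half - 0.94, ctr[2], z))
}

# Metropolis Monte Carlo over the mobile ions with screened-Coulomb pair
# energy E/kBT = lb1 * qi qj exp(-kappa r)/r against all other particles.
.metropolis_ions <- function(fr, mobile, n_sweeps, kappa, epsilon_r,
                             max_step) {
  lb1 <- .lb1(list(epsilon_r = epsilon_r, temperature = 300))
  pos <- fr$positions; q <- fr$charges; box <- fr$box
  idx_mobile <- which(mobile)
  pair_e <- function(i, p_i) {
    d <- .pair_dist(matrix(p_i, 1), pos[-i, , drop = FALSE], box)
    d <- pmax(d, 0.2)                    # soft core, avoids singularity
    sum(lb1 * q[i] * q[-i] * exp(-kappa * d) / d)
  }
  for (sweep in seq_len(n_sweeps)) {
    for (i in idx_mobile) {
      trial <- (pos[i, ] + stats::runif(3, -max_step, max_step)) %% box
      de <- pair_e(i, trial) - pair_e(i, pos[i, ])
      if (de <= 0 || stats::runif(1) < exp(-de)) pos[i, ] <- trial
    }
  }
  frame(pos, fr$species, q, box)
}

#' Lamellar membrane-DNA stack
#'
#' A 1-D periodic electron-density model of the lamellar phase along y:
#' one unit cell — a membrane slab (thickness `bilayer_thickness`) followed
#' by a DNA-monolayer slab (`dna_layer_thickness`), each filled with
#' uniformly placed scatterers at different number densities — tiled
#' `n_repeats` times, so particle y-positions repeat exactly modulo the
#' repeat distance `bilayer_thickness + dna_layer_thickness` (default
#' 67 Angstrom). The density contrast between the slabs carries the Bragg
#' signal.
#'
#' @param recipe a [system_recipe()].
#' @param n_repeats number of lamellar repeats (>= 2, default 16; enough
#'   coherent repeats that the first-order Bragg reflection dominates the
#'   finite-stack sidelobes).
#' @param n_mem,n_dna scatterers per membrane / DNA slab per repeat.
#' @param seed RNG seed; defaults to `recipe$seed`.
#' @return a [frame()] with species `MEM_E` and `DNA_E`; box y equals
#'   `n_repeats * repeat / 10` nm.
#' @export
build_lamellar_stack <- function(recipe, n_repeats = 16L, n_mem = 300L,
                                 n_dna = 100L, seed = NULL) {
  stopifnot(inherits(recipe, "system_recipe"))
  if (n_repeats < 2L) stop("n_repeats must be >= 2")
  if (is.null(seed)) seed <- recipe$seed
  set.seed(seed)
  rep_A <- recipe$bilayer_thickness + recipe$dna_layer_thickness
  rep_nm <- .angstrom_to_nm(rep_A)
  box <- c(recipe$box[1], n_repeats * rep_nm, recipe$box[3])
  if (rep_nm > box[2]) stop("repeat larger than box")
  t_mem <- .angstrom_to_nm(recipe$bilayer_thickness)
  cell <- data.frame(
    x = stats::runif(n_mem + n_dna, 0, box[1]),
    y = c(stats::runif(n_mem, 0, t_mem),
          stats::runif(n_dna, t_mem, rep_nm)),
    z = stats::runif(n_mem + n_dna, 0, box[3]),
    species = rep(c("MEM_E", "DNA_E"), c(n_mem, n_dna)),
    charge = 0)
  parts <- do.call(rbind, lapply(seq_len(n_repeats), function(k) {
    shifted <- cell
    shifted$y <- shifted$y + (k - 1L) * rep_nm
    shifted
  }))
  frame(as.matrix(parts[, c("x", "y", "z")]), parts$species, parts$charge,
        box)
}

#' The 20-bp duplex sequence emulated by the generator
#'
#' @return character scalar (5'->3' of strand 1).
#' @export
duplex_sequence <- function() "GCATCTGGGCTATAAAAGGG"
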