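#' Labelled point-charge frame
#'
#' A configuration of point particles (species label, charge, position) in an
#' orthorhombic periodic box. Coordinate convention: DNA long axis along z,
#' interhelical axis x, membrane normal y. Positions are wrapped into
#' `[0, box)` on construction.
#'
#' @param positions N x 3 matrix, nm.
#' @param species character vector of length N (e.g. `DNA_P`, `MG`, `CL`,
#'   `PC_N`, `PC_OP`, `PC_O`, `TAP_N`, `TAP_O`).
#' @param charges numeric vector of length N, units of e.
#' @param box lengths of the orthorhombic periodic box, nm (length 3).
#' @return object of class `frame`.
#' @export
frame <- function(positions, species, charges, box) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be N x 3")
  n <- nrow(positions)
  if (length(species) != n || length(charges) != n) {
    stop("species/charges/positions lengths differ")
  }
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive lengths")
  positions <- sweep(positions, 2, box, "%%")
  structure(list(positions = positions, species = as.character(species),
                 charges = as.numeric(charges), box = box),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  tab <- table(x$species)
  cat(sprintf("Frame: %d particles, box %.2f x %.2f x %.2f nm, net %+.3g e\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3],
              sum(x$charges)))
  cat("  ", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

#' Number of particles in a frame
#' @param x a [frame()].
#' @return integer count.
#' @export
n_particles <- function(x) nrow(x$positions)

.check_species <- function(fr, label) {
  missing <- setdiff(label, unique(fr$species))
  if (length(missing) > 0) {
    stop(sprintf("species %s not in frame; available: %s",
                 paste(missing, collapse = ", "),
                 paste(sort(unique(fr$species)), collapse = ", ")))
  }
}

# Minimum-image displacement component-wise for an orthorhombic box.
.min_image <- function(d, box_len) d - box_len * round(d / box_len)

# All minimum-image distances between rows of a (n x 3) and b (m x 3).
.pair_dist <- function(a, b, box) {
  dx <- .min_image(outer(a[, 1], b[, 1], "-"), box[1])
  dy <- .min_image(outer(a[, 2], b[, 2], "-"), box[2])
  dz <- .min_image(outer(a[, 3], b[, 3], "-"), box[3])
  sqrt(dx^2 + dy^2 + dz^2)
}

#' 1-D profile container
#'
#' @param bin_centers vector of bin centers.
#' @param values vector of values, same length.
#' @param units character label for `values`.
#' @param bin_width positive scalar.
#' @return object of class `profile1d`.
#' @export
profile1d <- function(bin_centers, values, units, bin_width) {
  if (length(bin_centers) != length(values)) stop("length mismatch")
  if (bin_width <= 0) stop("bin_width must be > 0")
  structure(list(bin_centers = bin_centers, values = values, units = units,
                 bin_width = bin_width), class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("Profile1D: %d bins (width %.4g), values in %s\n",
              length(x$bin_centers), x$bin_width, x$units))
  invisible(x)
}

#' @export
as.data.frame.profile1d <- function(x, ...) {
  data.frame(bin_center = x$bin_centers, value = x$values)
}

#' Concentration profile along a box axis
#'
#' `c(x) = <count in bin> / (N_A V_x)` averaged over frames, in mol/L. In
#' `slab` mode `V_x` is the geometric slab volume; in `accessible` mode the
#' volume of solute particles (approximated as spheres of `solute_radius`
#' assigned to the bin of their center) is subtracted.
#'
#' @param frames a [frame()] or list of frames (same box).
#' @param species label of the profiled species.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param bin_width nm.
#' @param volume_mode `"slab"` or `"accessible"`.
#' @param solute_species labels whose excluded volume is subtracted in
#'   accessible mode.
#' @param solute_radius nm, sphere radius per solute particle.
#' @return a [profile1d()] in mol/L.
#' @export
concentration_profile <- function(frames, species, axis = "x", bin_width = 0.2,
                                  volume_mode = c("slab", "accessible"),
                                  solute_species = "DNA_P",
                                  solute_radius = 0.3) {
  volume_mode <- match.arg(volume_mode)
  if (inherits(frames, "frame")) frames <- list(frames)
  if (length(frames) < 1L) stop("at least one frame required")
  if (bin_width <= 0) stop("bin_width must be > 0")
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  box <- frames[[1]]$box
  nbin <- max(1L, floor(box[ax] / bin_width))
  width <- box[ax] / nbin                     # exact tiling of the box
  edges <- seq(0, box[ax], length.out = nbin + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  slab_vol <- width * prod(box[-ax])          # nm^3
  counts <- numeric(nbin); excl <- numeric(nbin)
  for (fr in frames) {
    .check_species(fr, species)
    sel <- fr$species == species
    idx <- pmin(nbin, floor(fr$positions[sel, ax] / width) + 1L)
    counts <- counts + tabulate(idx, nbins = nbin)
    if (volume_mode == "accessible") {
      sol <- fr$species %in% solute_species
      if (any(sol)) {
        sidx <- pmin(nbin, floor(fr$positions[sol, ax] / width) + 1L)
        vsph <- 4 / 3 * pi * solute_radius^3
        excl <- excl + tabulate(sidx, nbins = nbin) * vsph
      }
    }
  }
  nf <- length(frames)
  vol <- pmax(slab_vol - excl / nf, 0.05 * slab_vol)  # guard tiny volumes
  conc <- (counts / nf) / (.const$avogadro * vol * 1e-24)  # mol/L
  profile1d(centers, conc, units = "mol/L", bin_width = width)
}

#' Net charge in the solvation shell around a core selection
#'
#' Sums the charges of all particles (core included) whose minimum-image
#' distance to any core particle is `<= cutoff` (union-of-spheres shell, in
#' or out by particle center), and decomposes the total by species.
#'
#' @param fr a [frame()].
#' @param core_species labels defining the core (e.g. `"DNA_P"`).
#' @param cutoff shell radius in nm (default 1.0, i.e. 10 Angstrom).
#' @return list with `Q_T` (total charge, e), `by_species` (named vector
#'   summing exactly to `Q_T`) and `n_in_shell`.
#' @export
shell_net_charge <- function(fr, core_species = "DNA_P", cutoff = 1.0) {
  stopifnot(inherits(fr, "frame"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  .check_species(fr, core_species)
  core <- fr$species %in% core_species
  if (!any(core)) stop("empty core selection")
  d <- .pair_dist(fr$positions, fr$positions[core, , drop = FALSE], fr$box)
  inshell <- apply(d, 1, min) <= cutoff
  by_sp <- tapply(fr$charges[inshell], fr$species[inshell], sum)
  by_sp <- stats::setNames(as.numeric(by_sp), names(by_sp))
  list(Q_T = sum(fr$charges[inshell]), by_species = by_sp,
       n_in_shell = sum(inshell))
}

#' Coordination count per normalization unit
#'
#' Number of distinct partner particles within `cutoff` of at least one
#' center particle, averaged over frames and divided by `normalize_per`
#' (e.g. 40 base pairs for a two-duplex system).
#'
#' @param frames a [frame()] or list of frames.
#' @param center_species,partner_species labels.
#' @param cutoff nm.
#' @param normalize_per positive integer divisor.
#' @return count per unit.
#' @export
coordination_count <- function(frames, center_species, partner_species,
                               cutoff, normalize_per = 1L) {
  if (inherits(frames, "frame")) frames <- list(frames)
  if (cutoff < 0) stop("cutoff must be >= 0")
  if (normalize_per <= 0) stop("normalize_per must be > 0")
  per_frame <- vapply(frames, function(fr) {
    .check_species(fr, c(center_species, partner_species))
    ctr <- fr$positions[fr$species %in% center_species, , drop = FALSE]
    prt <- fr$positions[fr$species %in% partner_species, , drop = FALSE]
    if (nrow(prt) == 0L || nrow(ctr) == 0L || cutoff == 0) return(0)
    d <- .pair_dist(prt, ctr, fr$box)
    sum(apply(d, 1, min) <= cutoff)
  }, numeric(1))
  mean(per_frame) / normalize_per
}

#' Direct-contact and cation-bridge census
#'
#' `n_direct`: cationic head-group sites (`TAP_N`, `PC_N`) within
#' `cutoff_direct` of any DNA phosphate. `n_bridge`: Mg ions simultaneously
#' within `cutoff_bridge` of at least one membrane anionic site (`PC_OP`,
#' `PC_O`, `TAP_O`) and at least one DNA phosphate.
#'
#' @param fr a [frame()].
#' @param cutoff_direct nm (default 0.6).
#' @param cutoff_bridge nm per leg (default 0.5, solvent-shared pairing of
#'   hexahydrated Mg).
#' @param dna_species,cation_head_species,anion_head_species,mg_species
#'   species labels, overridable for nonstandard frames.
#' @return list `n_direct`, `n_bridge` (zero counts are valid).
#' @export
contact_census <- function(fr, cutoff_direct = 0.6, cutoff_bridge = 0.5,
                           dna_species = "DNA_P",
                           cation_head_species = c("TAP_N", "PC_N"),
                           anion_head_species = c("PC_OP", "PC_O", "TAP_O"),
                           mg_species = "MG") {
  stopifnot(inherits(fr, "frame"))
  if (cutoff_direct <= 0 || cutoff_bridge <= 0) stop("cutoffs must be > 0")
  dna <- fr$positions[fr$species %in% dna_species, , drop = FALSE]
  cat_h <- fr$positions[fr$species %in% cation_head_species, , drop = FALSE]
  an_h <- fr$positions[fr$species %in% anion_head_species, , drop = FALSE]
  mg <- fr$positions[fr$species %in% mg_species, , drop = FALSE]
  n_direct <- 0L
  if (nrow(dna) > 0L && nrow(cat_h) > 0L) {
    d <- .pair_dist(cat_h, dna, fr$box)
    n_direct <- sum(apply(d, 1, min) <= cutoff_direct)
  }
  n_bridge <- 0L
  if (nrow(dna) > 0L && nrow(an_h) > 0L && nrow(mg) > 0L) {
    d1 <- apply(.pair_dist(mg, an_h, fr$box), 1, min) <= cutoff_bridge
    d2 <- apply(.pair_dist(mg, dna, fr$box), 1, min) <= cutoff_bridge
    n_bridge <- sum(d1 & d2)
  }
  list(n_direct = as.integer(n_direct), n_bridge = as.integer(n_bridge))
}

#' Radial distribution function
#'
#' Standard `g(r)` between two species in a periodic orthorhombic box,
#' normalized by the ideal-gas pair density, averaged over frames;
#' `g(r) -> 1` at large `r` for uncorrelated species.
#'
#' @param frames a [frame()] or list of frames.
#' @param species_a,species_b labels (may be equal).
#' @param r_max nm; must not exceed half the minimum box edge.
#' @param bin_width nm.
#' @return a [profile1d()] (dimensionless values).
#' @export
radial_distribution <- function(frames, species_a, species_b, r_max,
                                bin_width = 0.05) {
  if (inherits(frames, "frame")) frames <- list(frames)
  box <- frames[[1]]$box
  if (r_max > min(box) / 2 + 1e-9) {
    stop("r_max exceeds half the minimum box edge (minimum image invalid)")
  }
  nbin <- max(1L, floor(r_max / bin_width))
  width <- r_max / nbin
  edges <- seq(0, r_max, length.out = nbin + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  hist_tot <- numeric(nbin); norm_tot <- 0
  vbox <- prod(box)
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  for (fr in frames) {
    .check_species(fr, c(species_a, species_b))
    pa <- fr$positions[fr$species == species_a, , drop = FALSE]
    pb <- fr$positions[fr$species == species_b, , drop = FALSE]
    d <- .pair_dist(pa, pb, fr$box)
    same <- identical(species_a, species_b)
    if (same) d[upper.tri(d, diag = TRUE)] <- NA
    dv <- d[!is.na(d) & d <= r_max & d > 0]
    idx <- pmin(nbin, floor(dv / width) + 1L)
    hist_tot <- hist_tot + tabulate(idx, nbins = nbin)
    npairs <- if (same) nrow(pa) * (nrow(pa) - 1) / 2 else
      nrow(pa) * nrow(pb)
    norm_tot <- norm_tot + npairs
  }
  g <- (hist_tot / length(frames)) /
    ((norm_tot / length(frames)) * shell_vol / vbox)
  profile1d(centers, g, units = "g(r)", bin_width = width)
}

#' Mean nearest-neighbor separation of a species
#'
#' Mean minimum-image nearest-neighbor distance among the selected particles,
#' optionally restricted to an axis-aligned slab; supplies the `d` of the
#' coupling parameter `Gamma = l_B / d` from configurations.
#'
#' @param fr a [frame()].
#' @param species label.
#' @param region optional `list(axis = "x"|"y"|"z", min =, max =)` slab in nm.
#' @return nm.
#' @export
mean_ion_separation <- function(fr, species, region = NULL) {
  stopifnot(inherits(fr, "frame"))
  .check_species(fr, species)
  sel <- fr$species == species
  if (!is.null(region)) {
    ax <- match(match.arg(region$axis, c("x", "y", "z")), c("x", "y", "z"))
    sel <- sel & fr$positions[, ax] >= region$min &
      fr$positions[, ax] <= region$max
  }
  pos <- fr$positions[sel, , drop = FALSE]
  if (nrow(pos) < 2L) stop("fewer than 2 selected particles")
  d <- .pair_dist(pos, pos, fr$box)
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Charge-compensation fraction
#'
#' Percentage of the bare DNA charge compensated by one species'
#' solvation-shell contribution: `100 * q_contrib / |q_dna|`.
#'
#' @param q_contrib shell charge contribution of the species, e.
#' @param q_dna bare DNA charge, e (sign ignored).
#' @return percentage.
#' @export
charge_compensation <- function(q_contrib, q_dna) {
  if (q_dna == 0) stop("q_dna must be nonzero")
  100 * q_contrib / abs(q_dna)
}
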