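#' Default per-species electron counts
#'
#' Constant (q-independent) form factors: approximate electron counts of the
#' coarse particles used by the synthetic generator. Absolute intensities are
#' not meaningful at this level; peak positions are.
#'
#' @return named numeric vector.
#' @export
default_form_factors <- function() {
  c(DNA_P = 47,  # phosphate group
    MG = 10,     # Mg2+ core (hydration waters not represented)
    CL = 18,
    PC_N = 10, PC_OP = 47, PC_O = 8,
    TAP_N = 10, TAP_O = 8,
    MEM_E = 10, DNA_E = 10)
}

#' Scattering specification
#'
#' @param q_values strictly increasing scattering vector magnitudes, 1/Angstrom.
#' @param direction unit 3-vector for axis scans, or `NULL` for powder
#'   (orientation-averaged Debye) mode.
#' @param form_factors named vector mapping species to electron counts.
#' @return object of class `scattering_spec`.
#' @export
scattering_spec <- function(q_values = seq(0.01, 0.30, length.out = 300),
                            direction = c(0, 1, 0),
                            form_factors = default_form_factors()) {
  if (any(q_values < 0) || any(diff(q_values) <= 0)) {
    stop("q_values must be nonnegative and strictly increasing")
  }
  if (!is.null(direction)) {
    nrm <- sqrt(sum(direction^2))
    if (nrm == 0) stop("direction must be a nonzero vector")
    direction <- direction / nrm
  }
  structure(list(q_values = q_values, direction = direction,
                 form_factors = form_factors), class = "scattering_spec")
}

#' Scattering intensity from point-particle frames
#'
#' Axis scans: `I(q) = <|sum_j f_j exp(i q u . r_j)|^2>` over frames, with
#' `u` the scan direction (translational/rotational degrees fixed). Powder
#' mode: orientation-averaged Debye double sum
#' `I(q) = sum_jk f_j f_k sin(q r_jk)/(q r_jk)`. Coordinates are converted
#' from nm to Angstrom internally; `q` is in 1/Angstrom. Rigid translation of
#' a frame only multiplies the amplitude by a global phase, so I(q) is
#' invariant — exactly so at box-commensurate `q = 2 pi m / L` once periodic
#' wrapping is involved.
#'
#' @param frames a [frame()] or list of frames.
#' @param spec a [scattering_spec()].
#' @return a [profile1d()] of intensities (electron units squared) versus
#'   `q` (1/Angstrom).
#' @export
intensity <- function(frames, spec) {
  stopifnot(inherits(spec, "scattering_spec"))
  if (inherits(frames, "frame")) frames <- list(frames)
  q <- spec$q_values
  acc <- numeric(length(q))
  for (fr in frames) {
    missing <- setdiff(unique(fr$species), names(spec$form_factors))
    if (length(missing) > 0) {
      stop(sprintf("no form factor for species: %s",
                   paste(missing, collapse = ", ")))
    }
    f <- unname(spec$form_factors[fr$species])
    r <- .nm_to_angstrom(fr$positions)
    if (!is.null(spec$direction)) {
      proj <- as.numeric(r %*% spec$direction)
      ph <- outer(q, proj)                      # nq x N phase matrix
      acc <- acc + .mod2_amplitude(ph, f)
    } else {
      d <- sqrt(outer(rowSums(r^2), rowSums(r^2), "+") - 2 * r %*% t(r))
      d[d < 0 | !is.finite(d)] <- 0
      fij <- outer(f, f)
      acc <- acc + vapply(q, function(qq) {
        s <- fij * .sinc(qq * d)
        sum(s)
      }, numeric(1))
    }
  }
  profile1d(q, acc / length(frames), units = "intensity",
            bin_width = if (length(q) > 1) q[2] - q[1] else 1)
}

# |sum f exp(i phase)|^2 for a phase matrix (nq x N) and weights f
.mod2_amplitude <- function(ph, f) {
  re <- (cos(ph) %*% f)^2
  im <- (sin(ph) %*% f)^2
  as.numeric(re + im)
}

.sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' First Bragg peak and real-space period
#'
#' Locates the smallest-q interior local maximum of an intensity profile at
#' `q >= q_min`, ignoring maxima whose height above the profile minimum is
#' less than `min_prominence` of the full profile range, then refines the
#' position parabolically over the three bracketing samples. The lamellar
#' repeat follows as `period = 2 pi / q_peak`. The height floor rejects the
#' N-slit sidelobes of a finite coherent stack, which reach ~5% of the Bragg
#' peak on their own and ~15% where they interfere with the tail of the
#' forward-scattering lobe; first-order lamellar reflections sit far above
#' that.
#'
#' @param profile a [profile1d()] of I(q).
#' @param q_min smallest q considered, 1/Angstrom.
#' @param min_prominence fraction of the profile range (default 0.2).
#' @return list with `q_peak` (1/Angstrom) and `period` (Angstrom).
#' @export
first_peak <- function(profile, q_min = 0.05, min_prominence = 0.2) {
  stopifnot(inherits(profile, "profile1d"))
  q <- profile$bin_centers; v <- profile$values
  if (max(q) < q_min) stop("profile does not cover q_min")
  n <- length(v)
  if (n < 3L) stop("profile too short")
  interior <- 2:(n - 1L)
  is_max <- interior[v[interior] > v[interior - 1L] &
                     v[interior] >= v[interior + 1L]]
  is_max <- is_max[q[is_max] >= q_min]
  floor_h <- min(v) + min_prominence * (max(v) - min(v))
  is_max <- is_max[v[is_max] >= floor_h]
  if (length(is_max) == 0L) stop("no interior maximum found above q_min")
  i <- is_max[1]
  # parabolic refinement through (q[i-1], q[i], q[i+1])
  y1 <- v[i - 1L]; y2 <- v[i]; y3 <- v[i + 1L]
  denom <- y1 - 2 * y2 + y3
  dq <- (q[i + 1L] - q[i - 1L]) / 2
  shift <- if (denom == 0) 0 else 0.5 * (y1 - y3) / denom * dq
  q_peak <- q[i] + shift
  list(q_peak = q_peak, period = 2 * pi / q_peak)
}
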