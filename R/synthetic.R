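# Synthetic conformational ensembles with known ground truth.
#
# Real inputs to this kind of analysis are microsecond gaMD trajectories,
# which cannot ship with a package; these generators produce ensembles whose
# fluctuation statistics are known exactly, so every downstream estimate
# (RMSF, plasticity fields, PCA modes, reweighted free energies) can be
# checked against an analytic or Monte-Carlo target. Frames are i.i.d. in
# time: every analysis implemented here is time-order invariant, so kinetics
# are deliberately absent.

#' Generative specification for a harmonic-fluctuation ensemble
#'
#' Each atom fluctuates isotropically about a reference position with a
#' region-dependent per-coordinate standard deviation; optional collective
#' modes add correlated displacements along fixed unit directions with
#' Gaussian random amplitudes, mimicking low-frequency loop motions.
#'
#' @param reference A `structure_ensemble` (frame 1 used) or `N x 3` matrix
#'   of reference coordinates, Angstrom.
#' @param region_labels Integer vector, length N: region id per atom.
#' @param region_amplitudes Named numeric vector mapping region id to the
#'   isotropic per-coordinate s.d. sigma (Angstrom), all `>= 0`.
#' @param collective_modes List of `list(direction = <N x 3 unit matrix>,
#'   amplitude = <s.d. in Angstrom>)`; directions unit-norm in the Frobenius
#'   sense.
#' @param n_frames Number of frames to draw.
#' @param seed Integer RNG seed; identical specs give identical ensembles.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(reference, region_labels = NULL,
                           region_amplitudes = c("1" = 0.5),
                           collective_modes = list(),
                           n_frames = 1000L, seed = 1L) {
  ref <- if (inherits(reference, "structure_ensemble")) {
    frame_coords(reference, 1L)
  } else {
    matrix(reference, ncol = 3L)
  }
  atoms <- if (inherits(reference, "structure_ensemble")) {
    reference$atoms
  } else {
    NULL
  }
  n <- nrow(ref)
  if (is.null(region_labels)) region_labels <- rep(1L, n)
  if (length(region_labels) != n) {
    stop_surfplast("region_labels must have one entry per atom",
                   "dimension_error")
  }
  if (any(region_amplitudes < 0)) {
    stop_surfplast("region amplitudes must be non-negative", "domain_error")
  }
  missing_reg <- setdiff(as.character(unique(region_labels)),
                         names(region_amplitudes))
  if (length(missing_reg) > 0) {
    stop_surfplast(sprintf("no amplitude for region(s): %s",
                           paste(missing_reg, collapse = ", ")),
                   "key_error")
  }
  for (m in collective_modes) {
    nrm <- sqrt(sum(m$direction^2))
    if (abs(nrm - 1) > 1e-10) {
      stop_surfplast("mode directions must be unit Frobenius norm",
                     "domain_error")
    }
    if (m$amplitude < 0) {
      stop_surfplast("mode amplitudes must be non-negative", "domain_error")
    }
  }
  if (n_frames < 1L) {
    stop_surfplast("n_frames must be >= 1", "domain_error")
  }
  structure(list(reference = ref, atoms = atoms,
                 region_labels = as.integer(region_labels),
                 region_amplitudes = region_amplitudes,
                 collective_modes = collective_modes,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Ideal reference backbone for synthetic ensembles
#'
#' One CA atom per residue; `"helix"` places them on an ideal alpha-helix
#' (rise 1.5 A per residue, radius 2.3 A, 100 degree twist), `"extended"`
#' on a straight line with 3.8 A CA-CA spacing.
#'
#' @param n_residues Number of residues (`>= 2`).
#' @param geometry `"helix"` or `"extended"`.
#' @return A single-frame `structure_ensemble` of CA atoms.
#' @export
make_reference_structure <- function(n_residues,
                                     geometry = c("helix", "extended")) {
  geometry <- match.arg(geometry)
  if (n_residues < 2) {
    stop_surfplast("n_residues must be >= 2", "domain_error")
  }
  i <- seq_len(n_residues) - 1
  coords <- if (geometry == "extended") {
    cbind(3.8 * i, 0, 0)
  } else {
    phi <- i * 100 * pi / 180
    cbind(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * i)
  }
  atoms <- tibble(serial = seq_len(n_residues), name = "CA",
                  resname = "ALA", chain = "A",
                  resseq = seq_len(n_residues), icode = "", element = "C")
  structure_ensemble(atoms, coords)
}

#' Draw a harmonic-fluctuation ensemble from a synthetic spec
#'
#' `coords[t, i, ] = reference[i, ] + sigma_region(i) * eta +
#' sum_m c_m(t) * direction_m[i, ]` with `eta` i.i.d. standard normal per
#' coordinate and `c_m(t) ~ N(0, amplitude_m^2)`.
#'
#' @param spec A `synthetic_spec`.
#' @return A `structure_ensemble` with `spec$n_frames` frames.
#' @export
sample_harmonic_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- nrow(spec$reference)
  nt <- spec$n_frames
  sig <- spec$region_amplitudes[as.character(spec$region_labels)]
  if (any(is.na(sig))) {
    stop_surfplast("region label without amplitude", "key_error")
  }
  withr::with_seed(spec$seed, {
    coords <- array(rnorm(nt * n * 3), dim = c(nt, n, 3))
    coords <- sweep(coords, 2, sig, "*")
    for (m in spec$collective_modes) {
      cm <- rnorm(nt, 0, m$amplitude)
      for (d in 1:3) {
        coords[, , d] <- coords[, , d] + outer(cm, m$direction[, d])
      }
    }
    for (d in 1:3) {
      coords[, , d] <- sweep(coords[, , d], 2, spec$reference[, d], "+")
    }
  })
  atoms <- spec$atoms
  if (is.null(atoms)) {
    atoms <- tibble(serial = seq_len(n), name = "CA", resname = "ALA",
                    chain = "A", resseq = seq_len(n), icode = "",
                    element = "C")
  }
  structure_ensemble(atoms, coords)
}

#' Normalized collective mode localized on selected atoms
#'
#' Convenience builder: a displacement direction supported on `atom_idx`
#' along `axis`, normalized to unit Frobenius norm.
#'
#' @param n_atoms Total atom count.
#' @param atom_idx Atoms carrying the mode.
#' @param axis Length-3 displacement direction per supported atom.
#' @param amplitude Mode amplitude (s.d. of the random coefficient), Angstrom.
#' @return A `list(direction, amplitude)` usable in [synthetic_spec()].
#' @export
collective_mode <- function(n_atoms, atom_idx, axis = c(0, 0, 1),
                            amplitude = 1) {
  dir <- matrix(0, n_atoms, 3)
  dir[atom_idx, ] <- matrix(axis, length(atom_idx), 3, byrow = TRUE)
  dir <- dir / sqrt(sum(dir^2))
  list(direction = dir, amplitude = amplitude)
}

# ---- toy gaMD --------------------------------------------------------------

#' Specification of a 1-D toy gaMD sampler
#'
#' A Metropolis chain samples the boosted potential `V(x) + dV(x)` where
#' `dV(x) = 0.5 * k_boost * (e_threshold - V(x))^2` when `V(x) <
#' e_threshold` and 0 otherwise — the gaMD construction that raises the
#' wells and leaves barriers above the threshold untouched. Defaults
#' realize a double well `V(x) = (x^2 - 1)^2` kcal/mol with the threshold
#' at the barrier top (`e_threshold = 1`) and `k_boost = 1/(E - Vmin) = 1`.
#'
#' @param potential Polynomial coefficients of `V(x)` in ascending order,
#'   kcal/mol (default `c(1, 0, -2, 0, 1)`, i.e. `(x^2-1)^2`).
#' @param k_boost Harmonic boost constant, (kcal/mol)^-1, `>= 0`.
#' @param e_threshold Boost threshold energy, kcal/mol.
#' @param temperature Kelvin.
#' @param n_samples Number of retained samples (`>= 1`); an additional 10%
#'   burn-in is discarded.
#' @param seed Integer RNG seed.
#' @param mc_step Metropolis proposal s.d., Angstrom.
#' @param x0 Chain start.
#' @return A `toy_gamd_spec` object.
#' @export
toy_gamd_spec <- function(potential = c(1, 0, -2, 0, 1), k_boost = 1,
                          e_threshold = 1, temperature = 300,
                          n_samples = 10000L, seed = 1L, mc_step = 0.5,
                          x0 = 1) {
  if (n_samples < 1L) stop_surfplast("n_samples must be >= 1", "domain_error")
  if (temperature <= 0) {
    stop_surfplast("temperature must be positive", "domain_error")
  }
  if (k_boost < 0) stop_surfplast("k_boost must be >= 0", "domain_error")
  if (mc_step <= 0) stop_surfplast("mc_step must be positive", "domain_error")
  structure(list(potential = as.numeric(potential), k_boost = k_boost,
                 e_threshold = e_threshold, temperature = temperature,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 mc_step = mc_step, x0 = x0),
            class = "toy_gamd_spec")
}

# Horner evaluation of the potential, vectorized over x.
eval_potential <- function(coefs, x) {
  v <- rep(0, length(x))
  for (c_k in rev(coefs)) v <- v * x + c_k
  v
}

#' gaMD boost energy of the toy potential at positions x
#'
#' @param spec A `toy_gamd_spec`.
#' @param x Positions.
#' @return `dV(x)`, kcal/mol (non-negative, deterministic in `x`).
#' @export
toy_boost_energy <- function(spec, x) {
  v <- eval_potential(spec$potential, x)
  ifelse(v < spec$e_threshold,
         0.5 * spec$k_boost * (spec$e_threshold - v)^2, 0)
}

#' Sample the boosted toy potential by Metropolis Monte Carlo
#'
#' Runs a random-walk Metropolis chain on `exp(-beta (V + dV))`, discards a
#' 10% burn-in, and returns the retained positions together with the
#' per-sample boost-energy series needed for Boltzmann reweighting.
#'
#' @param spec A `toy_gamd_spec`.
#' @return List with `positions` (length `n_samples`) and `boost`
#'   (a [boost_series()]).
#' @export
sample_toy_gamd <- function(spec) {
  stopifnot(inherits(spec, "toy_gamd_spec"))
  beta <- 1 / (KB_KCAL * spec$temperature)
  burn <- ceiling(0.1 * spec$n_samples)
  ntot <- spec$n_samples + burn
  u_tot <- function(x) {
    v <- eval_potential(spec$potential, x)
    if (!is.finite(v)) {
      stop_surfplast(sprintf("non-finite potential at x = %g", x),
                     "numerical_error")
    }
    v + if (v < spec$e_threshold) {
      0.5 * spec$k_boost * (spec$e_threshold - v)^2
    } else 0
  }
  positions <- numeric(ntot)
  withr::with_seed(spec$seed, {
    prop <- rnorm(ntot, 0, spec$mc_step)
    logu <- log(runif(ntot))
    x <- spec$x0
    ux <- u_tot(x)
    for (i in seq_len(ntot)) {
      xp <- x + prop[i]
      up <- u_tot(xp)
      if (beta * (ux - up) >= logu[i]) {
        x <- xp
        ux <- up
      }
      positions[i] <- x
    }
  })
  kept <- positions[(burn + 1):ntot]
  list(positions = kept,
       boost = boost_series(toy_boost_energy(spec, kept), spec$temperature))
}
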