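# Surface-plasticity fields: per-frame Gaussian atom-density grids, their
# temporal mean and standard deviation, Gaussian smoothing of the SD field,
# residue-localized plasticity values, and isosurface extraction.
#
# Each atom contributes a unit-amplitude Gaussian exp(-||x - r||^2/(2 s^2))
# to a frame's density; the unit amplitude makes a given isovalue of the
# mean grid independent of atom count, so the same threshold draws a
# "typical surface" for any system. The temporal SD of the density is the
# plasticity field: large where the surface is sometimes protein, sometimes
# solvent. A further Gaussian smoothing emphasizes extended flexible
# regions over voxel noise. Because the magnitudes depend on the kernel
# width, all parameters are echoed into results and manifests.

#' Gaussian atom-density grid of a single frame
#'
#' `value(x) = sum_i exp(-||x - r_i||^2 / (2 kernel_sigma^2))` with unit
#' amplitude per atom; contributions are truncated beyond
#' `cutoff_sigmas * kernel_sigma` per axis (a box superset of the spherical
#' cutoff).
#'
#' @param coords `N x 3` coordinate matrix, Angstrom (may have zero rows).
#' @param geometry A `scalar_grid` giving origin/spacing/dims, e.g. from
#'   [grid_geometry()].
#' @param kernel_sigma Gaussian kernel s.d. per atom, Angstrom.
#' @param cutoff_sigmas Truncation radius in units of `kernel_sigma`.
#' @return A `scalar_grid` of densities.
#' @export
frame_density_grid <- function(coords, geometry, kernel_sigma = 1.5,
                               cutoff_sigmas = 4) {
  if (kernel_sigma <= 0) {
    stop_surfplast("kernel_sigma must be positive", "domain_error")
  }
  coords <- matrix(coords, ncol = 3L)
  if (nrow(coords) > 0) {
    pad <- cutoff_sigmas * kernel_sigma
    lo_ok <- all(apply(coords, 2, min) - geometry$origin >= pad - 1e-9)
    hi <- geometry$origin + (geometry$dims - 1) * geometry$spacing
    hi_ok <- all(hi - apply(coords, 2, max) >= pad - 1e-9)
    if (!(lo_ok && hi_ok)) {
      warn(paste("grid padding is smaller than the kernel cutoff radius;",
                 "density mass will be clipped at the boundary"))
    }
  }
  vals <- density_grid_cpp(coords, geometry$origin, geometry$spacing,
                           geometry$dims, kernel_sigma, cutoff_sigmas)
  scalar_grid(geometry$origin, geometry$spacing, geometry$dims,
              array(vals, dim = geometry$dims))
}

#' Temporal mean and SD of per-frame density grids over an ensemble
#'
#' Builds one density grid per frame on a shared geometry (the bounding box
#' of all frames plus `padding`) and accumulates the per-voxel mean and
#' population standard deviation with Welford's numerically stable
#' streaming update.
#'
#' @param ensemble An aligned `structure_ensemble`.
#' @param kernel_sigma Per-atom Gaussian s.d., Angstrom.
#' @param spacing Grid spacing, Angstrom.
#' @param padding Bounding-box margin, Angstrom.
#' @param cutoff_sigmas Kernel truncation, in sigmas.
#' @param geometry Optional `scalar_grid` geometry overriding the computed
#'   one (use to put several systems on a common grid).
#' @return A `grid_stats` object: list with `mean` and `sd` scalar grids
#'   (identical geometry) plus the parameters used.
#' @export
ensemble_grid_stats <- function(ensemble, kernel_sigma = 1.5, spacing = 0.5,
                                padding = 6, cutoff_sigmas = 4,
                                geometry = NULL) {
  if (n_frames(ensemble) < 1L) {
    stop_surfplast("ensemble has no frames", "empty_error")
  }
  if (kernel_sigma <= 0) {
    stop_surfplast("kernel_sigma must be positive", "domain_error")
  }
  if (is.null(geometry)) {
    geometry <- grid_geometry(ensemble, spacing = spacing, padding = padding)
  }
  if (n_frames(ensemble) < 2L) {
    warn("SD grid of a single frame is identically zero")
  }
  res <- ensemble_grid_stats_cpp(ensemble$coords, n_frames(ensemble),
                                 n_atoms(ensemble), geometry$origin,
                                 geometry$spacing, geometry$dims,
                                 kernel_sigma, cutoff_sigmas)
  mean_g <- scalar_grid(geometry$origin, geometry$spacing, geometry$dims,
                        array(res$mean, dim = geometry$dims))
  sd_vals <- sqrt(pmax(res$m2, 0) / n_frames(ensemble))
  sd_g <- scalar_grid(geometry$origin, geometry$spacing, geometry$dims,
                      array(sd_vals, dim = geometry$dims))
  structure(list(mean = mean_g, sd = sd_g,
                 params = list(kernel_sigma = kernel_sigma,
                               spacing = geometry$spacing,
                               padding = padding,
                               cutoff_sigmas = cutoff_sigmas,
                               n_frames = n_frames(ensemble))),
            class = "grid_stats")
}

#' @export
print.grid_stats <- function(x, ...) {
  cat(sprintf(
    "<grid_stats> %d x %d x %d voxels (spacing %g A, kernel sigma %g A)\n",
    x$mean$dims[1], x$mean$dims[2], x$mean$dims[3], x$mean$spacing,
    x$params$kernel_sigma))
  cat(sprintf("  mean density max %.4g; SD max %.4g\n",
              max(x$mean$values), max(x$sd$values)))
  invisible(x)
}

#' Gaussian smoothing of a scalar grid
#'
#' Separable convolution with a normalized Gaussian of s.d. `smooth_sigma`
#' (Angstrom, converted to voxels), zero-padded at the boundaries.
#' `smooth_sigma = 0` returns the input unchanged.
#'
#' @param grid A `scalar_grid`.
#' @param smooth_sigma Smoothing s.d., Angstrom (`>= 0`).
#' @return The smoothed `scalar_grid`.
#' @export
smooth_grid <- function(grid, smooth_sigma = 1.5) {
  if (smooth_sigma < 0) {
    stop_surfplast("smooth_sigma must be >= 0", "domain_error")
  }
  if (smooth_sigma == 0) return(grid)
  sv <- smooth_sigma / grid$spacing            # sigma in voxels
  r <- max(1L, as.integer(ceiling(4 * sv)))
  kern <- exp(-0.5 * ((-r:r) / sv)^2)
  kern <- kern / sum(kern)
  band <- function(n) {
    k <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      k[cbind(i[ok], j[ok])] <- kern[off + r + 1]
    }
    k
  }
  d <- grid$dims
  v <- grid$values
  # axis 1
  v <- array(band(d[1]) %*% matrix(v, d[1], d[2] * d[3]), dim = d)
  # axis 2
  v <- aperm(v, c(2, 1, 3))
  v <- array(band(d[2]) %*% matrix(v, d[2], d[1] * d[3]),
             dim = c(d[2], d[1], d[3]))
  v <- aperm(v, c(2, 1, 3))
  # axis 3
  v <- aperm(v, c(3, 2, 1))
  v <- array(band(d[3]) %*% matrix(v, d[3], d[2] * d[1]),
             dim = c(d[3], d[2], d[1]))
  v <- aperm(v, c(3, 2, 1))
  scalar_grid(grid$origin, grid$spacing, d, v)
}

#' Residue-localized surface plasticity
#'
#' Samples the smoothed SD field at each atom's time-averaged position
#' (trilinear interpolation) and averages per residue, yielding the
#' gradient-style localized plasticity values used to color structures.
#'
#' @param stats A `grid_stats` (mean/SD pair) from [ensemble_grid_stats()].
#' @param smoothed_sd The smoothed SD `scalar_grid` (same geometry).
#' @param ensemble The aligned `structure_ensemble` the grids came from.
#' @param isovalue Mean-density isovalue recorded for surface export
#'   (default 1, one kernel amplitude).
#' @return A `plasticity_result`: list with `smoothed_sd`, `per_atom`,
#'   `per_residue` (tibble `chain`, `resseq`, `resname`, `plasticity`),
#'   `isovalue_used`, and the grid parameters.
#' @export
localize_plasticity <- function(stats, smoothed_sd, ensemble, isovalue = 1) {
  if (!same_geometry(stats$sd, smoothed_sd)) {
    stop_surfplast("smoothed SD grid geometry differs from stats geometry",
                   "geometry_error")
  }
  mu <- mean_coords(ensemble)
  per_atom <- tryCatch(
    interp_trilinear(smoothed_sd, mu),
    surfplast_boundary_error = function(e) {
      stop_surfplast(paste0("mean atom position outside grid: ",
                            conditionMessage(e)), "boundary_error")
    })
  per_residue <- ensemble$atoms |>
    dplyr::mutate(plasticity = per_atom) |>
    dplyr::group_by(.data$chain, .data$resseq, .data$resname,
                    .data$icode) |>
    dplyr::summarise(plasticity = mean(.data$plasticity), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resseq, .data$icode) |>
    dplyr::select("chain", "resseq", "resname", "plasticity")
  structure(list(smoothed_sd = smoothed_sd, per_atom = per_atom,
                 per_residue = per_residue, isovalue_used = isovalue,
                 params = stats$params),
            class = "plasticity_result")
}

#' @export
print.plasticity_result <- function(x, ...) {
  cat(sprintf(
    "<plasticity_result> %d atoms, %d residues; plasticity %.4g-%.4g\n",
    length(x$per_atom), nrow(x$per_residue), min(x$per_atom),
    max(x$per_atom)))
  invisible(x)
}

#' One-call surface-plasticity analysis of an ensemble
#'
#' Aligns the ensemble (optional), accumulates the density mean/SD grids,
#' smooths the SD field, and localizes plasticity per atom and residue.
#'
#' @inheritParams ensemble_grid_stats
#' @param smooth_sigma Smoothing s.d. applied to the SD grid, Angstrom.
#' @param align Superpose frames first (default TRUE); gridding unaligned
#'   frames conflates global tumbling with plasticity.
#' @param fit_selection Selection used for the alignment fit.
#' @param isovalue Mean-density isovalue recorded for surface export.
#' @return A `plasticity_result` whose `stats` element carries the mean/SD
#'   grids and `ensemble` the aligned frames.
#' @export
surface_plasticity <- function(ensemble, kernel_sigma = 1.5, spacing = 0.5,
                               padding = 6, smooth_sigma = 1.5,
                               cutoff_sigmas = 4, align = TRUE,
                               fit_selection = "CA", geometry = NULL,
                               isovalue = 1) {
  if (align) {
    ensemble <- align_ensemble(ensemble, fit_selection = fit_selection)
  }
  stats <- ensemble_grid_stats(ensemble, kernel_sigma = kernel_sigma,
                               spacing = spacing, padding = padding,
                               cutoff_sigmas = cutoff_sigmas,
                               geometry = geometry)
  smoothed <- smooth_grid(stats$sd, smooth_sigma)
  res <- localize_plasticity(stats, smoothed, ensemble, isovalue = isovalue)
  res$params$smooth_sigma <- smooth_sigma
  res$stats <- stats
  res$ensemble <- ensemble
  res
}

#' Extract an isosurface mesh from a scalar grid
#'
#' Marching-tetrahedra triangulation (six tetrahedra per voxel sharing the
#' main diagonal) of the level set at `isovalue`, in world coordinates.
#'
#' @param grid A `scalar_grid`.
#' @param isovalue Level strictly between the grid minimum and maximum.
#' @return List with `vertices` (`M x 3`, Angstrom) and `faces`
#'   (`K x 3`, 1-based indices).
#' @export
extract_isosurface <- function(grid, isovalue) {
  rng <- range(grid$values)
  if (!(isovalue > rng[1] && isovalue < rng[2])) {
    stop_surfplast(sprintf(
      "isovalue %g outside grid value range [%g, %g]", isovalue,
      rng[1], rng[2]), "domain_error")
  }
  marching_tetrahedra_cpp(grid$values, grid$dims, grid$origin,
                          grid$spacing, isovalue)
}
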