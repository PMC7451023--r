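# Cartesian PCA of C-alpha coordinates, Maclaurin-series Boltzmann
# reweighting of gaMD samples, free-energy surfaces over principal
# components, and conformational-selection statistics.

#' Cartesian principal component analysis of an aligned ensemble
#'
#' Eigendecomposition (via SVD of the centered T x 3N coordinate matrix) of
#' the population-normalized coordinate covariance of the selected atoms.
#'
#' @param ensemble An aligned `structure_ensemble` with `T >= 2` frames.
#' @param n_components Number of components to keep (default 2, at most
#'   `min(T - 1, 3N)`).
#' @param selection Atom selection entering the PCA (default `"CA"`).
#' @return A `pca_model`: `mean_coords` (N x 3), `components`
#'   (K x 3N orthonormal rows, coordinate order x1 y1 z1 x2 ...),
#'   `eigenvalues` (descending, A^2), `projections` (T x K, centered),
#'   `total_variance` (trace of the covariance), and the selection mask.
#' @export
fit_pca <- function(ensemble, n_components = 2L, selection = "CA") {
  if (n_frames(ensemble) < 2L) {
    stop_surfplast("PCA needs at least 2 frames", "insufficient_frames")
  }
  sub <- select_atoms(ensemble, selection)
  nt <- n_frames(sub)
  n <- n_atoms(sub)
  kmax <- min(nt - 1L, 3L * n)
  if (n_components > kmax) {
    stop_surfplast(sprintf("n_components must be <= min(T-1, 3N) = %d",
                           kmax), "domain_error")
  }
  x <- matrix(0, nt, 3L * n)
  for (d in 1:3) x[, seq(d, 3L * n, by = 3L)] <- sub$coords[, , d]
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = n_components, nv = n_components)
  eig <- sv$d^2 / nt                       # population covariance spectrum
  k <- seq_len(n_components)
  proj <- xc %*% sv$v[, k, drop = FALSE]
  structure(list(
    mean_coords = matrix(mu, ncol = 3L, byrow = TRUE),
    components = t(sv$v[, k, drop = FALSE]),
    eigenvalues = eig[k],
    all_eigenvalues = eig,
    projections = proj,
    total_variance = sum(xc^2) / nt,
    selection = selection,
    atoms = sub$atoms), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  ve <- x$eigenvalues / x$total_variance
  cat(sprintf("<pca_model> %d components over %d frames x %d atoms\n",
              nrow(x$components), nrow(x$projections),
              nrow(x$mean_coords)))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve),
                    collapse = ", ")))
  invisible(x)
}

#' Project an ensemble onto a fitted PCA basis
#'
#' Centers the selected coordinates with the model's mean (not the new
#' ensemble's), so free and bound ensembles can share one basis.
#'
#' @param model A `pca_model`.
#' @param ensemble A `structure_ensemble` with the same selected atoms.
#' @return `T x K` projection matrix.
#' @export
project_ensemble <- function(model, ensemble) {
  sub <- select_atoms(ensemble, model$selection)
  n <- n_atoms(sub)
  if (3L * n != ncol(model$components)) {
    stop_surfplast("ensemble does not match the PCA basis dimension",
                   "dimension_error")
  }
  x <- matrix(0, n_frames(sub), 3L * n)
  for (d in 1:3) x[, seq(d, 3L * n, by = 3L)] <- sub$coords[, , d]
  xc <- sweep(x, 2, as.vector(t(model$mean_coords)))
  xc %*% t(model$components)
}

#' Maclaurin-series Boltzmann reweighting factors for gaMD frames
#'
#' The canonical weight of a gaMD frame is `exp(beta dV)`; the truncated
#' Maclaurin expansion `w = sum_{k=0}^{order} (beta dV)^k / k!` is the
#' standard noise-robust approximation. Weights are normalized to mean 1
#' unless `normalize = FALSE`.
#'
#' @param boost A [boost_series()].
#' @param order Expansion order (`>= 0`); `Inf` gives the exact
#'   exponential.
#' @param normalize Normalize to mean 1 (default TRUE).
#' @return Positive length-T weight vector.
#' @export
maclaurin_weights <- function(boost, order = 10, normalize = TRUE) {
  if (is.na(order) || order < 0) {
    stop_surfplast("order must be >= 0", "domain_error")
  }
  beta <- 1 / (KB_KCAL * boost$temperature)
  bdv <- beta * boost$delta_v
  if (is.infinite(order)) {
    w <- exp(bdv)
  } else {
    w <- rep(1, length(bdv))
    term <- rep(1, length(bdv))
    for (k in seq_len(order)) {
      term <- term * bdv / k
      w <- w + term
    }
  }
  if (normalize) w / mean(w) else w
}

#' Reweighted free-energy surface over 1-2 collective coordinates
#'
#' Weighted histogram of the projections; `F(bin) = -ln p(bin)` in units of
#' `k_B T`, shifted so the occupied minimum is 0. Empty bins are flagged
#' (free energy `NA`), never assigned an arbitrary constant.
#'
#' @param projections `T x D` matrix (or length-T vector), `D` in 1:2.
#' @param weights Positive per-frame weights (default uniform), e.g. from
#'   [maclaurin_weights()].
#' @param bins Bin count per dimension (single value recycled).
#' @param temperature Kelvin (recorded; free energies are in kBT units).
#' @param range Optional list (or vector for 1-D) of `c(lo, hi)` per
#'   dimension; defaults to the data range. Use a common range to compare
#'   surfaces bin-by-bin.
#' @param maclaurin_order Recorded expansion order (metadata only).
#' @return A `fes_result`: `bin_edges`, `bin_centers`, `probabilities`,
#'   `free_energy`, `empty` (logical array), `maclaurin_order`,
#'   `temperature`.
#' @export
reweighted_fes <- function(projections, weights = NULL, bins = 60,
                           temperature = 300, range = NULL,
                           maclaurin_order = NA) {
  proj <- as.matrix(projections)
  nd <- ncol(proj)
  nt <- nrow(proj)
  if (!nd %in% 1:2) {
    stop_surfplast("FES supports 1 or 2 dimensions", "domain_error")
  }
  if (any(bins < 2)) {
    stop_surfplast("need at least 2 bins per dimension", "domain_error")
  }
  bins <- rep(as.integer(bins), length.out = nd)
  if (is.null(weights)) weights <- rep(1, nt)
  if (length(weights) != nt) {
    stop_surfplast(sprintf("length of weights (%d) != frames (%d)",
                           length(weights), nt), "dimension_error")
  }
  if (any(weights <= 0)) {
    stop_surfplast("weights must be positive", "domain_error")
  }
  if (is.null(range)) {
    range <- lapply(seq_len(nd), function(d) base::range(proj[, d]))
  } else if (!is.list(range)) {
    range <- list(range)
  }
  edges <- lapply(seq_len(nd), function(d) {
    seq(range[[d]][1], range[[d]][2], length.out = bins[d] + 1L)
  })
  idx <- matrix(0L, nt, nd)
  for (d in seq_len(nd)) {
    idx[, d] <- findInterval(proj[, d], edges[[d]],
                             rightmost.closed = TRUE)
  }
  inside <- rowSums(idx >= 1 & idx <= matrix(bins, nt, nd, byrow = TRUE)) ==
    nd
  p <- array(0, dim = bins)
  flat <- if (nd == 1L) idx[inside, 1] else {
    idx[inside, 1] + bins[1] * (idx[inside, 2] - 1L)
  }
  tot <- sum(weights[inside])
  acc <- tapply(weights[inside], flat, sum)
  p[as.integer(names(acc))] <- acc / tot
  empty <- p == 0
  fe <- array(NA_real_, dim = bins)
  fe[!empty] <- -log(p[!empty])
  fe <- fe - min(fe, na.rm = TRUE)
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  structure(list(bin_edges = edges, bin_centers = centers,
                 probabilities = p, free_energy = fe, empty = empty,
                 maclaurin_order = maclaurin_order,
                 temperature = temperature),
            class = "fes_result")
}

#' @export
print.fes_result <- function(x, ...) {
  cat(sprintf(
    "<fes_result> %s bins, %d empty; max finite F = %.3g kBT\n",
    paste(dim(x$probabilities), collapse = " x "), sum(x$empty),
    max(x$free_energy, na.rm = TRUE)))
  invisible(x)
}

#' Binding-competent-state occupancy of a free ensemble
#'
#' Kabsch-fits each frame to a reference (e.g. the bound, binding-competent
#' conformation) on `fit_selection` and reports the fraction of frames
#' within `cutoff` Angstrom RMSD — the conformational-selection statistic:
#' a large fraction means the binding-competent shape pre-exists in the
#' free ensemble.
#'
#' @param free_ensemble A `structure_ensemble`.
#' @param reference A `structure_ensemble` (frame 1; atoms matched by
#'   chain/resseq/icode/name identity) or an `N x 3` matrix in the same
#'   atom order as `free_ensemble`.
#' @param cutoff RMSD cutoff, Angstrom (always echoed in the report).
#' @param fit_selection Atom selection for fit and RMSD (default `"CA"`).
#' @return A `selection_report`: `rmsd_to_reference` (length T, Angstrom),
#'   `competent_fraction`, `cutoff`, `n_frames`.
#' @export
binding_competence <- function(free_ensemble, reference, cutoff,
                               fit_selection = "CA") {
  if (inherits(reference, "structure_ensemble")) {
    key_e <- paste(free_ensemble$atoms$chain, free_ensemble$atoms$resseq,
                   free_ensemble$atoms$icode, free_ensemble$atoms$name)
    key_r <- paste(reference$atoms$chain, reference$atoms$resseq,
                   reference$atoms$icode, reference$atoms$name)
    pos <- match(key_e, key_r)
    if (all(is.na(pos))) {
      stop_surfplast("no atoms of the ensemble match the reference",
                     "correspondence_error")
    }
    keep <- !is.na(pos)
    ref <- frame_coords(reference, 1L)[pos[keep], , drop = FALSE]
    ens <- select_atoms(free_ensemble, which(keep))
  } else {
    ref <- matrix(reference, ncol = 3L)
    if (nrow(ref) != n_atoms(free_ensemble)) {
      stop_surfplast("reference coordinate count does not match ensemble",
                     "correspondence_error")
    }
    ens <- free_ensemble
  }
  mask <- atom_mask(ens, fit_selection)
  ref_sub <- ref[mask, , drop = FALSE]
  nt <- n_frames(ens)
  # validate geometry once, then use the singular-value RMSD on each frame
  invisible(kabsch_superpose(
    matrix(ens$coords[1, , ], ncol = 3L)[mask, , drop = FALSE], ref_sub))
  rmsd <- as.vector(frame_rmsd_cpp(ens$coords, which(mask) - 1L, ref_sub))
  structure(list(rmsd_to_reference = rmsd,
                 competent_fraction = mean(rmsd <= cutoff),
                 cutoff = cutoff, n_frames = nt),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "<selection_report> %.1f%% of %d frames within %.3g A of the reference\n",
    100 * x$competent_fraction, x$n_frames, x$cutoff))
  invisible(x)
}

#' Free-energy barrier read off a 1-D FES
#'
#' Free energy of the bin containing `at` minus the global (finite)
#' minimum, in kBT.
#'
#' @param fes A 1-D `fes_result`.
#' @param at Coordinate of the barrier (default 0).
#' @return Barrier height in kBT (`NA` if the bin at `at` is empty).
#' @export
fes_barrier <- function(fes, at = 0) {
  if (length(fes$bin_centers) != 1L) {
    stop_surfplast("fes_barrier requires a 1-D FES", "domain_error")
  }
  i <- which.min(abs(fes$bin_centers[[1]] - at))
  fes$free_energy[i]
}

# Count strict local minima of a free-energy array; empty bins act as
# infinitely high neighbors (they never block a minimum, and are never
# minima themselves). Plateaus are not minima (strict inequality). Only
# bins in the thermally occupied region (F <= f_cut) are candidates, so
# isolated single-count tail bins do not register as states.
count_local_minima <- function(fe, empty, f_cut = Inf) {
  v <- fe
  v[empty | is.na(v)] <- Inf
  d <- dim(v)
  if (length(d) == 1L || is.null(d)) {
    n <- length(v)
    pad <- c(Inf, v, Inf)
    sum(v <= f_cut & v < pad[seq_len(n)] & v < pad[seq_len(n) + 2L])
  } else {
    nr <- d[1]; nc <- d[2]
    pad <- matrix(Inf, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- v
    ok <- matrix(TRUE, nr, nc)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj, drop = FALSE]
      ok <- ok & (v < nb)
    }
    sum(ok & v <= f_cut, na.rm = TRUE)
  }
}

#' Population-shift summary between two free-energy surfaces
#'
#' Compares free and bound FES computed on identical bin edges (use a
#' shared PCA basis and a common `range`): per principal component, the
#' ratio of the occupied range (bins with `F <= f_cut`, projected onto that
#' axis) bound/free, and the difference (free - bound) in the number of
#' strict local minima. Minima are counted within the occupied region
#' (`F <= f_cut`) only, so single-count tail bins do not register as
#' conformational states.
#'
#' @param fes_free,fes_bound `fes_result` objects with identical bin edges.
#' @param f_cut Occupancy threshold, kBT (default 3).
#' @return A `population_shift` object: tibble `per_pc` (pc,
#'   `free_occupied_bins`, `bound_occupied_bins`, `range_ratio`), minima
#'   counts, their difference, and `f_cut`.
#' @export
population_shift <- function(fes_free, fes_bound, f_cut = 3) {
  nd <- length(fes_free$bin_edges)
  if (length(fes_bound$bin_edges) != nd ||
      !all(vapply(seq_len(nd), function(d) {
        length(fes_free$bin_edges[[d]]) == length(fes_bound$bin_edges[[d]]) &&
          all(abs(fes_free$bin_edges[[d]] - fes_bound$bin_edges[[d]]) < 1e-9)
      }, logical(1)))) {
    stop_surfplast("free and bound FES must share identical bin edges",
                   "geometry_error")
  }
  occupied_axis <- function(fes, d) {
    occ <- !fes$empty & !is.na(fes$free_energy) & fes$free_energy <= f_cut
    if (nd == 1L) sum(occ) else sum(apply(occ, d, any))
  }
  per_pc <- purrr::map_dfr(seq_len(nd), function(d) {
    fo <- occupied_axis(fes_free, d)
    bo <- occupied_axis(fes_bound, d)
    tibble(pc = d, free_occupied_bins = fo, bound_occupied_bins = bo,
           range_ratio = if (fo > 0) bo / fo else NA_real_)
  })
  fm <- count_local_minima(fes_free$free_energy, fes_free$empty, f_cut)
  bm <- count_local_minima(fes_bound$free_energy, fes_bound$empty, f_cut)
  structure(list(per_pc = per_pc, free_minima = fm, bound_minima = bm,
                 minima_difference = fm - bm, f_cut = f_cut),
            class = "population_shift")
}

#' @export
print.population_shift <- function(x, ...) {
  cat(sprintf(
    "<population_shift> minima free %d / bound %d (diff %d), F_cut %g kBT\n",
    x$free_minima, x$bound_minima, x$minima_difference, x$f_cut))
  print(x$per_pc)
  invisible(x)
}
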