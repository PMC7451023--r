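# Kabsch superposition, ensemble alignment, and RMSF profiles.
#
# Plasticity grids and Cartesian PCA both presuppose that global rotation
# and translation have been removed, otherwise rigid tumbling masquerades
# as internal flexibility. Superposition uses the sign-corrected SVD
# (Kabsch) solution; reflections are never permitted.

#' Optimal rigid superposition of two coordinate sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' (weighted) RMSD of `mobile %*% t(R) + t` to `target`.
#'
#' @param mobile,target `N x 3` coordinate matrices with `N >= 3`
#'   non-collinear points.
#' @param weights Optional non-negative per-atom weights (default uniform).
#' @return List with `rotation` (3 x 3, `det = +1`), `translation`
#'   (length 3) and `rmsd` (Angstrom). Apply with
#'   `mobile %*% t(rotation) + translation` (rows).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- matrix(mobile, ncol = 3L)
  target <- matrix(target, ncol = 3L)
  n <- nrow(mobile)
  if (nrow(target) != n) {
    stop_surfplast("mobile and target must have the same atom count",
                   "dimension_error")
  }
  if (n < 3L) {
    stop_surfplast("superposition needs at least 3 atoms", "geometry_error")
  }
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  a <- sweep(mobile, 2, cm)
  b <- sweep(target, 2, ct)
  # collinearity check: centered configurations must span a plane
  for (m in list(a, b)) {
    s <- svd(m, nu = 0, nv = 0)$d
    if (s[2] < 1e-8 * max(s[1], 1)) {
      stop_surfplast("degenerate (collinear) configuration", "geometry_error")
    }
  }
  r <- kabsch_rotation(a * w, b)
  trans <- ct - as.vector(r %*% cm)
  moved <- a %*% t(r)
  rmsd <- sqrt(sum(w * rowSums((moved - b)^2)))
  list(rotation = r, translation = trans, rmsd = rmsd)
}

# Minimal Kabsch core on pre-centered coordinates; no validity checks.
# Callers on hot paths (per-frame loops) validate once up front.
kabsch_rotation <- function(a, b) {
  sv <- svd(crossprod(a, b))
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  sv$v %*% (t(sv$u) * c(1, 1, d))
}
apply_rigid <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, "+")
}

#' Remove global rotation/translation from every frame of an ensemble
#'
#' Each frame is Kabsch-fit to the reference on `fit_selection`; with
#' `reference = "mean"` the reference is iterated (fit to the running mean
#' structure until the mean moves by less than `tol` or `max_iter` rounds),
#' the usual convention for trajectory analysis.
#'
#' @param ensemble A `structure_ensemble`.
#' @param reference `"mean"` (iterated mean structure) or `"frame1"`.
#' @param fit_selection Atom selection used for the fit (default `"CA"`;
#'   see [atom_mask()]); must select at least 3 atoms.
#' @param tol Convergence threshold on the mean structure, Angstrom. The
#'   tight default makes alignment idempotent to ~1e-9 A.
#' @param max_iter Maximum mean-reference iterations.
#' @return The aligned `structure_ensemble`.
#' @export
align_ensemble <- function(ensemble, reference = c("mean", "frame1"),
                           fit_selection = "CA", tol = 1e-10,
                           max_iter = 50L) {
  reference <- match.arg(reference)
  mask <- atom_mask(ensemble, fit_selection)
  if (sum(mask) < 3L) {
    stop_surfplast("fit selection must contain at least 3 atoms",
                   "selection_error")
  }
  coords <- ensemble$coords
  nt <- dim(coords)[1]
  # validate the fit geometry once (frame 1), then use the fast core
  invisible(kabsch_superpose(
    matrix(coords[1, , ], ncol = 3L)[mask, , drop = FALSE],
    matrix(coords[1, , ], ncol = 3L)[mask, , drop = FALSE]))
  midx <- which(mask) - 1L
  fit_all_to <- function(coords, ref_sub) {
    align_frames_cpp(coords, midx, ref_sub)
  }
  if (reference == "frame1") {
    ref_sub <- matrix(coords[1, , ], ncol = 3L)[mask, , drop = FALSE]
    coords <- fit_all_to(coords, ref_sub)
  } else {
    # start from the current mean so re-aligning an aligned ensemble is a
    # no-op; fall back to frame 1 if the raw mean is degenerate (wildly
    # rotated frames can average to a near-collinear blur)
    ref_sub <- apply(coords[, mask, , drop = FALSE], c(2, 3), mean)
    ok <- tryCatch({
      kabsch_superpose(ref_sub, ref_sub)
      TRUE
    }, surfplast_geometry_error = function(e) FALSE)
    if (!ok) ref_sub <- matrix(coords[1, , ], ncol = 3L)[mask,
                                                         , drop = FALSE]
    for (it in seq_len(max_iter)) {
      coords <- fit_all_to(coords, ref_sub)
      new_ref <- apply(coords[, mask, , drop = FALSE], c(2, 3), mean)
      if (max(abs(new_ref - ref_sub)) < tol) break
      ref_sub <- new_ref
    }
  }
  structure_ensemble(ensemble$atoms, coords, ensemble$frame_ids)
}

#' Per-atom and per-residue RMSF of an (aligned) ensemble
#'
#' `rmsf[i] = sqrt(mean_t ||r_i(t) - <r_i>||^2)` with population (1/T)
#' normalization. The ensemble is assumed already superposed; no fit is
#' performed here.
#'
#' @param ensemble A `structure_ensemble` with at least 2 frames.
#' @return An `rmsf_profile`: list with `per_atom` (length N, Angstrom) and
#'   `per_residue` (tibble `chain`, `resseq`, `resname`, `rmsf_A`, the mean
#'   over each residue's atoms).
#' @export
compute_rmsf <- function(ensemble) {
  if (n_frames(ensemble) < 2L) {
    stop_surfplast("RMSF needs at least 2 frames", "insufficient_frames")
  }
  mu <- mean_coords(ensemble)
  nt <- n_frames(ensemble)
  dev2 <- 0
  for (d in 1:3) {
    m <- matrix(ensemble$coords[, , d], nrow = nt)
    dev2 <- dev2 + sweep(m, 2, mu[, d])^2
  }
  per_atom <- sqrt(colMeans(dev2))
  per_residue <- ensemble$atoms |>
    dplyr::mutate(rmsf = per_atom) |>
    dplyr::group_by(.data$chain, .data$resseq, .data$resname,
                    .data$icode) |>
    dplyr::summarise(rmsf_A = mean(.data$rmsf), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resseq, .data$icode) |>
    dplyr::select("chain", "resseq", "resname", "rmsf_A")
  structure(list(per_atom = per_atom, per_residue = per_residue),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("<rmsf_profile> %d atoms, %d residues; mean RMSF %.3f A\n",
              length(x$per_atom), nrow(x$per_residue), mean(x$per_atom)))
  invisible(x)
}
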