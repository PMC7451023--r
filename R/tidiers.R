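# broom-style tidiers and ggplot2 autoplot methods for every result type,
# so results drop straight into dplyr/ggplot2 workflows.

#' @export
tidy.rmsf_profile <- function(x, ...) x$per_residue

#' @export
glance.rmsf_profile <- function(x, ...) {
  tibble(n_atoms = length(x$per_atom), n_residues = nrow(x$per_residue),
         mean_rmsf_A = mean(x$per_atom), max_rmsf_A = max(x$per_atom))
}

#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(object$per_residue,
                  ggplot2::aes(x = .data$resseq, y = .data$rmsf_A,
                               color = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Residue", y = "RMSF (Å)",
                  title = "Per-residue RMSF") +
    ggplot2::theme_minimal()
}

#' @export
tidy.plasticity_result <- function(x, ...) x$per_residue

#' @export
glance.plasticity_result <- function(x, ...) {
  tibble(n_residues = nrow(x$per_residue),
         mean_plasticity = mean(x$per_atom),
         max_plasticity = max(x$per_atom),
         kernel_sigma = x$params$kernel_sigma,
         smooth_sigma = x$params$smooth_sigma %||% NA_real_,
         isovalue_used = x$isovalue_used)
}

#' @export
autoplot.plasticity_result <- function(object, ...) {
  ggplot2::ggplot(object$per_residue,
                  ggplot2::aes(x = .data$resseq, y = .data$plasticity,
                               color = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Residue", y = "Localized surface plasticity",
                  title = "Residue-localized surface plasticity") +
    ggplot2::theme_minimal()
}

#' @export
tidy.pca_model <- function(x, ...) {
  ve <- x$eigenvalues / x$total_variance
  tibble(component = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         variance_explained = ve,
         cumulative = cumsum(ve))
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble(n_components = length(x$eigenvalues),
         n_frames = nrow(x$projections),
         total_variance = x$total_variance,
         variance_explained = sum(x$eigenvalues) / x$total_variance)
}

#' @export
autoplot.pca_model <- function(object, ...) {
  p <- as_tibble(object$projections, .name_repair = ~paste0("PC", seq_along(.x)))
  if (ncol(p) >= 2) {
    ggplot2::ggplot(p, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.6) +
      ggplot2::labs(title = "Cartesian PCA projections") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(p, ggplot2::aes(x = .data$PC1)) +
      ggplot2::geom_histogram(bins = 60) +
      ggplot2::theme_minimal()
  }
}

#' @export
tidy.fes_result <- function(x, ...) {
  nd <- length(x$bin_centers)
  if (nd == 1L) {
    tibble(pc1 = x$bin_centers[[1]],
           probability = as.vector(x$probabilities),
           free_energy_kbt = as.vector(x$free_energy),
           empty = as.vector(x$empty))
  } else {
    grid <- expand.grid(pc1 = x$bin_centers[[1]], pc2 = x$bin_centers[[2]])
    tibble(pc1 = grid$pc1, pc2 = grid$pc2,
           probability = as.vector(x$probabilities),
           free_energy_kbt = as.vector(x$free_energy),
           empty = as.vector(x$empty))
  }
}

#' @export
glance.fes_result <- function(x, ...) {
  tibble(n_bins = length(x$probabilities), n_empty = sum(x$empty),
         max_free_energy_kbt = max(x$free_energy, na.rm = TRUE),
         maclaurin_order = x$maclaurin_order,
         temperature_K = x$temperature)
}

#' @export
autoplot.fes_result <- function(object, ...) {
  df <- tidy(object)
  if (length(object$bin_centers) == 1L) {
    ggplot2::ggplot(dplyr::filter(df, !.data$empty),
                    ggplot2::aes(x = .data$pc1, y = .data$free_energy_kbt)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "PC1", y = expression(F ~ (k[B] * T)),
                    title = "Free-energy profile") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                     fill = .data$free_energy_kbt)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(na.value = "white", direction = -1) +
      ggplot2::labs(x = "PC1", y = "PC2", fill = expression(k[B] * T),
                    title = "Free-energy surface") +
      ggplot2::theme_minimal()
  }
}

#' @export
tidy.selection_report <- function(x, ...) {
  tibble(frame = seq_along(x$rmsd_to_reference),
         rmsd_A = x$rmsd_to_reference,
         competent = x$rmsd_to_reference <= x$cutoff)
}

#' @export
glance.selection_report <- function(x, ...) {
  tibble(competent_fraction = x$competent_fraction, cutoff_A = x$cutoff,
         n_frames = x$n_frames,
         mean_rmsd_A = mean(x$rmsd_to_reference))
}

#' @export
autoplot.selection_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$rmsd_A)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 2,
                        color = "red") +
    ggplot2::labs(x = "RMSD to binding-competent reference (Å)",
                  y = "Frames",
                  title = sprintf("Competent fraction: %.3f",
                                  object$competent_fraction)) +
    ggplot2::theme_minimal()
}

#' @export
tidy.population_shift <- function(x, ...) x$per_pc

#' @export
tidy.plasticity_comparison <- function(x, ...) as_tibble(x$per_residue)

#' @export
glance.plasticity_comparison <- function(x, ...) x$global

#' @export
autoplot.plasticity_comparison <- function(object, ...) {
  long <- object$per_residue |>
    tidyr::pivot_longer(dplyr::starts_with("plasticity_"),
                        names_to = "system", values_to = "plasticity",
                        names_prefix = "plasticity_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$resseq, y = .data$plasticity,
                                     color = .data$system)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Residue", y = "Localized surface plasticity") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
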