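# End-to-end orchestration: ensemble(s) -> alignment -> plasticity grids +
# RMSF + PCA/FES (+ reweighting, + conformational-selection report), with a
# JSON run manifest echoing every tunable parameter. When several labeled
# ensembles are supplied (e.g. free and bound) their grids share one
# geometry and their FES share a joint PCA basis and bin edges, so the
# surfaces are comparable bin-by-bin.

#' Validated pipeline configuration
#'
#' @param ensembles Named list (labels, e.g. `free`, `bound`) of
#'   multi-model PDB paths or `structure_ensemble` objects.
#' @param boosts Optional named list (same labels) of boost-table paths or
#'   [boost_series()] objects.
#' @param reference Optional reference structure (PDB path or
#'   `structure_ensemble`) for the conformational-selection report.
#' @param kernel_sigma,spacing,padding,smooth_sigma Grid parameters,
#'   Angstrom (see [surface_plasticity()]).
#' @param pca_components Number of principal components (1-2 used for FES).
#' @param fes_bins Histogram bins per FES dimension.
#' @param maclaurin_order Reweighting expansion order.
#' @param competence_cutoff RMSD cutoff (Angstrom) for the selection
#'   report; required when `reference` is given.
#' @param temperature Kelvin (used when a boost series lacks one).
#' @param seed Integer seed covering any stochastic stage.
#' @param output_dir Directory for all outputs (created if absent).
#' @return A validated `run_config` list.
#' @export
run_config <- function(ensembles, boosts = NULL, reference = NULL,
                       kernel_sigma = 1.5, spacing = 0.5, padding = 6,
                       smooth_sigma = 1.5, pca_components = 2L,
                       fes_bins = 60L, maclaurin_order = 10L,
                       competence_cutoff = NULL, temperature = 300,
                       seed = 1L, output_dir = tempfile("surfplast_run_")) {
  if (!is.list(ensembles) || length(ensembles) == 0L) {
    stop_surfplast("`ensembles` must be a non-empty named list",
                   "validation_error")
  }
  if (is.null(names(ensembles)) || any(names(ensembles) == "")) {
    names(ensembles) <- paste0("system", seq_along(ensembles))
  }
  for (e in ensembles) {
    if (is.character(e) && !file.exists(e)) {
      stop_surfplast(sprintf("ensemble input '%s' does not exist", e),
                     "validation_error")
    }
  }
  for (p in list(kernel_sigma = kernel_sigma, spacing = spacing,
                 smooth_sigma = smooth_sigma, temperature = temperature)) {
    if (!is.numeric(p) || p < 0) {
      stop_surfplast("physical parameters must be non-negative numbers",
                     "validation_error")
    }
  }
  if (kernel_sigma <= 0 || spacing <= 0) {
    stop_surfplast("kernel_sigma and spacing must be positive",
                   "validation_error")
  }
  if (!is.null(reference) && is.null(competence_cutoff)) {
    stop_surfplast(
      "competence_cutoff is required when a reference is supplied",
      "validation_error")
  }
  structure(list(ensembles = ensembles, boosts = boosts,
                 reference = reference, kernel_sigma = kernel_sigma,
                 spacing = spacing, padding = padding,
                 smooth_sigma = smooth_sigma,
                 pca_components = as.integer(pca_components),
                 fes_bins = as.integer(fes_bins),
                 maclaurin_order = maclaurin_order,
                 competence_cutoff = competence_cutoff,
                 temperature = temperature, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [run_config()] arguments; `ensembles`,
#' `boosts` and `reference` are paths. Arguments passed in `...` override
#' the file.
#'
#' @param path YAML file.
#' @param ... Overrides forwarded to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  do.call(run_config, y)
}

load_ensemble_input <- function(x) {
  if (inherits(x, "structure_ensemble")) x else read_multimodel_pdb(x)
}

load_boost_input <- function(x, temperature) {
  if (is.null(x)) NULL
  else if (inherits(x, "boost_series")) x
  else read_boost_series(x, temperature)
}

with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = c("surfplast_pipeline_error", "surfplast_error"))
  })
}

#' Run the full surface-plasticity pipeline
#'
#' Executes alignment, plasticity grids, RMSF, PCA/FES (reweighted when a
#' boost table is present), and the selection report, writing standard
#' output files plus `manifest.json` into `config$output_dir`. Deterministic
#' given the configuration.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list (also written as JSON). The
#'   `results` attribute carries the in-memory result objects per system.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, paste0(...))
  labels <- names(config$ensembles)
  multi <- length(labels) > 1L
  prefix <- function(lab, name) if (multi) paste0(lab, "_", name) else name

  ensembles <- with_stage("read_ensembles", {
    lapply(config$ensembles, load_ensemble_input)
  })
  aligned <- with_stage("align", {
    lapply(ensembles, align_ensemble, fit_selection = "CA")
  })

  # shared grid geometry across systems so plasticity fields are comparable
  geometry <- with_stage("grid_geometry", {
    lo <- do.call(pmin, lapply(aligned, function(e) apply(e$coords, 3, min)))
    hi <- do.call(pmax, lapply(aligned, function(e) apply(e$coords, 3, max)))
    grid_geometry_from_box(lo, hi, config$spacing, config$padding)
  })

  files <- list()
  results <- list()
  summary <- list()
  for (lab in labels) {
    ens <- aligned[[lab]]
    pl <- with_stage(paste0("plasticity:", lab), {
      surface_plasticity(ens, kernel_sigma = config$kernel_sigma,
                         spacing = config$spacing, padding = config$padding,
                         smooth_sigma = config$smooth_sigma, align = FALSE,
                         geometry = geometry)
    })
    rp <- with_stage(paste0("rmsf:", lab), compute_rmsf(ens))
    with_stage(paste0("export:", lab), {
      write_dx_grid(pl$stats$mean, out(prefix(lab, "mean.dx")))
      write_dx_grid(pl$stats$sd, out(prefix(lab, "sd.dx")))
      write_dx_grid(pl$smoothed_sd, out(prefix(lab, "sd_smoothed.dx")))
      readr::write_csv(pl$per_residue,
                       out(prefix(lab, "plasticity_per_residue.csv")))
      write_bfactor_pdb(ens, pl$per_atom,
                        out(prefix(lab, "plasticity_bfactor.pdb")))
      readr::write_csv(rp$per_residue, out(prefix(lab, "rmsf.csv")))
    })
    # manifest records paths relative to output_dir (determinism across
    # runs into different directories)
    files[[lab]] <- list(
      mean_dx = prefix(lab, "mean.dx"),
      sd_dx = prefix(lab, "sd.dx"),
      sd_smoothed_dx = prefix(lab, "sd_smoothed.dx"),
      plasticity_csv = prefix(lab, "plasticity_per_residue.csv"),
      plasticity_pdb = prefix(lab, "plasticity_bfactor.pdb"),
      rmsf_csv = prefix(lab, "rmsf.csv"))
    results[[lab]] <- list(plasticity = pl, rmsf = rp)
    summary[[lab]] <- list(
      n_frames = n_frames(ens), n_atoms = n_atoms(ens),
      mean_plasticity = mean(pl$per_atom),
      max_plasticity = max(pl$per_atom),
      mean_rmsf_A = mean(rp$per_atom))
  }

  # PCA on the joint (concatenated) aligned ensemble; every system is then
  # projected into the same basis and binned on the same edges.
  pca <- with_stage("pca", {
    joint <- if (multi) {
      base <- aligned[[1]]
      all_coords <- do.call(abind3, lapply(aligned, function(e) e$coords))
      structure_ensemble(base$atoms, all_coords)
    } else {
      aligned[[1]]
    }
    fit_pca(joint, n_components = config$pca_components)
  })
  projections <- lapply(aligned, function(e) project_ensemble(pca, e))
  proj_df <- purrr::imap_dfr(projections, function(p, lab) {
    colnames(p) <- paste0("PC", seq_len(ncol(p)))
    dplyr::mutate(as_tibble(p), system = lab, frame = dplyr::row_number(),
                  .before = 1)
  })
  readr::write_csv(proj_df, out("pca_projections.csv"))
  files$pca_projections <- "pca_projections.csv"

  nd <- min(2L, config$pca_components)
  shared_range <- lapply(seq_len(nd), function(d) {
    range(unlist(lapply(projections, function(p) p[, d])))
  })
  fes <- list()
  fes_rows <- list()
  for (lab in labels) {
    boost <- with_stage(paste0("boost:", lab), {
      b <- load_boost_input(config$boosts[[lab]], config$temperature)
      if (!is.null(b)) check_boost_pairing(ensembles[[lab]], b)
      b
    })
    w <- if (is.null(boost)) NULL else {
      maclaurin_weights(boost, order = config$maclaurin_order)
    }
    f <- with_stage(paste0("fes:", lab), {
      reweighted_fes(projections[[lab]][, seq_len(nd), drop = FALSE],
                     weights = w, bins = config$fes_bins,
                     temperature = config$temperature, range = shared_range,
                     maclaurin_order = if (is.null(w)) NA else
                       config$maclaurin_order)
    })
    fes[[lab]] <- f
    df <- tidy(f)
    df$system <- lab
    df$reweighted <- !is.null(w)
    fes_rows[[lab]] <- df
  }
  fes_df <- dplyr::bind_rows(fes_rows)
  readr::write_csv(dplyr::filter(fes_df, !.data$reweighted),
                   out("fes.csv"))
  files$fes <- "fes.csv"
  if (any(fes_df$reweighted)) {
    readr::write_csv(dplyr::filter(fes_df, .data$reweighted),
                     out("fes_reweighted.csv"))
    files$fes_reweighted <- "fes_reweighted.csv"
  }

  shift <- NULL
  if (multi) {
    shift <- with_stage("population_shift", {
      population_shift(fes[[1]], fes[[2]])
    })
    summary$population_shift <- list(
      per_pc = shift$per_pc, free_minima = shift$free_minima,
      bound_minima = shift$bound_minima,
      minima_difference = shift$minima_difference, f_cut = shift$f_cut)
  }

  selection <- NULL
  if (!is.null(config$reference)) {
    selection <- with_stage("binding_competence", {
      ref <- load_ensemble_input(config$reference)
      binding_competence(aligned[[1]], ref,
                         cutoff = config$competence_cutoff)
    })
    sel_json <- list(competent_fraction = selection$competent_fraction,
                     cutoff_A = selection$cutoff,
                     n_frames = selection$n_frames,
                     mean_rmsd_A = mean(selection$rmsd_to_reference))
    jsonlite::write_json(sel_json, out("selection_report.json"),
                         auto_unbox = TRUE, digits = NA)
    files$selection_report <- "selection_report.json"
    summary$selection <- sel_json
  }

  manifest <- list(
    schema_version = 1L,
    package = "surfplast",
    parameters = list(
      kernel_sigma = config$kernel_sigma, spacing = config$spacing,
      padding = config$padding, smooth_sigma = config$smooth_sigma,
      cutoff_sigmas = 4, pca_components = config$pca_components,
      fes_bins = config$fes_bins, maclaurin_order = config$maclaurin_order,
      competence_cutoff = config$competence_cutoff,
      temperature = config$temperature, seed = config$seed,
      fit_selection = "CA", reference = "mean"),
    systems = labels,
    inputs = lapply(config$ensembles, function(e) {
      if (is.character(e)) e else "<in-memory ensemble>"
    }),
    outputs = files,
    summary = summary)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(manifest, "results") <- list(plasticity = results, pca = pca,
                                    fes = fes, shift = shift,
                                    selection = selection)
  invisible(manifest)
}

# bind T x N x 3 arrays along the frame axis
abind3 <- function(...) {
  parts <- list(...)
  n <- dim(parts[[1]])[2]
  total <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  outarr <- array(0, dim = c(total, n, 3))
  at <- 0L
  for (p in parts) {
    outarr[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  outarr
}

#' Compare per-residue plasticity between labeled systems
#'
#' Systems must have been computed on a shared grid geometry and have
#' matching residue sets; deltas and ratios are reported relative to the
#' first label.
#'
#' @param results Named list (>= 2) of `plasticity_result` objects.
#' @return A `plasticity_comparison`: tibble `per_residue` (one plasticity
#'   column per label plus `delta_*` and `ratio_*` columns vs the first)
#'   and a `global` tibble of per-system mean plasticity.
#' @export
compare_systems <- function(results) {
  if (length(results) < 2L) {
    stop_surfplast("need at least two systems to compare",
                   "validation_error")
  }
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- paste0("system", seq_along(results))
  }
  labs <- names(results)
  keys <- lapply(results, function(r) {
    paste(r$per_residue$chain, r$per_residue$resseq, r$per_residue$resname)
  })
  for (i in seq_along(keys)[-1]) {
    mism <- c(setdiff(keys[[1]], keys[[i]]), setdiff(keys[[i]], keys[[1]]))
    if (length(mism) > 0) {
      stop_surfplast(sprintf(
        "residue sets of '%s' and '%s' differ: %s", labs[1], labs[i],
        paste(mism, collapse = "; ")), "correspondence_error")
    }
  }
  base <- results[[1]]$per_residue[, c("chain", "resseq", "resname")]
  per_res <- base
  for (lab in labs) {
    pr <- results[[lab]]$per_residue
    ord <- match(paste(base$chain, base$resseq, base$resname),
                 paste(pr$chain, pr$resseq, pr$resname))
    per_res[[paste0("plasticity_", lab)]] <- pr$plasticity[ord]
  }
  for (lab in labs[-1]) {
    per_res[[paste0("delta_", lab)]] <-
      per_res[[paste0("plasticity_", lab)]] -
      per_res[[paste0("plasticity_", labs[1])]]
    per_res[[paste0("ratio_", lab)]] <-
      per_res[[paste0("plasticity_", lab)]] /
      per_res[[paste0("plasticity_", labs[1])]]
  }
  global <- tibble(
    system = labs,
    mean_plasticity = vapply(results, function(r) {
      mean(r$per_residue$plasticity)
    }, numeric(1)))
  structure(list(per_residue = per_res, global = global,
                 reference_label = labs[1]),
            class = "plasticity_comparison")
}

#' @export
print.plasticity_comparison <- function(x, ...) {
  cat(sprintf("<plasticity_comparison> %d residues, systems: %s\n",
              nrow(x$per_residue), paste(x$global$system, collapse = ", ")))
  print(x$global)
  invisible(x)
}
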