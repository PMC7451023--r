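# Density grids, grid statistics, smoothing, localized plasticity,
# isosurfaces.

test_that("single-atom density follows the Gaussian kernel formula", {
  geom <- scalar_grid(c(-5, -5, -5), 1, c(11, 11, 11))
  g <- frame_density_grid(matrix(0, 1, 3), geom, kernel_sigma = 1)
  expect_equal(g$values[6, 6, 6], 1)
  expect_equal(g$values[7, 6, 6], exp(-0.5), tolerance = 1e-12)
  expect_error(frame_density_grid(matrix(0, 1, 3), geom, kernel_sigma = 0),
               class = "surfplast_domain_error")
})

test_that("empty coordinate sets give an all-zero grid", {
  geom <- scalar_grid(c(0, 0, 0), 0.5, c(5, 5, 5))
  g <- frame_density_grid(matrix(0, 0, 3), geom)
  expect_true(all(g$values == 0))
})

test_that("the density integral matches the analytic Gaussian mass", {
  geom <- grid_geometry(matrix(0, 1, 3), spacing = 0.25, padding = 5)
  g <- frame_density_grid(matrix(0, 1, 3), geom, kernel_sigma = 1,
                          cutoff_sigmas = 5)
  expect_equal(sum(g$values) * g$spacing^3, (2 * pi)^1.5,
               tolerance = 0.005)
})

test_that("insufficient padding triggers a clipping warning", {
  geom <- grid_geometry(matrix(0, 1, 3), spacing = 0.5, padding = 1)
  expect_warning(frame_density_grid(matrix(0, 1, 3), geom,
                                    kernel_sigma = 1.5),
                 "clipped")
})

test_that("static ensembles have an exactly zero SD field", {
  frame <- matrix(rnorm(12), 4, 3)
  ens <- toy_ensemble(array(rep(frame, each = 5), c(5, 4, 3)))
  gs <- ensemble_grid_stats(ens, kernel_sigma = 1, spacing = 0.75,
                            padding = 4.5)
  expect_true(all(gs$sd$values == 0))
  single <- frame_density_grid(frame, gs$mean, kernel_sigma = 1)
  expect_lt(max(abs(gs$mean$values - single$values)), 1e-12)
})

test_that("two-frame grid statistics match the hand-computed oracle", {
  co <- array(0, c(2, 1, 3))
  co[2, 1, 1] <- 2
  gs <- ensemble_grid_stats(toy_ensemble(co), kernel_sigma = 1, spacing = 1,
                            padding = 5)
  rho1 <- 1
  rho2 <- exp(-2)
  at0 <- matrix(0, 1, 3)
  expect_equal(interp_trilinear(gs$mean, at0), (rho1 + rho2) / 2,
               tolerance = 1e-9)
  expect_equal(interp_trilinear(gs$sd, at0), (rho1 - rho2) / 2,
               tolerance = 1e-9)
})

test_that("duplicating every frame leaves mean and SD unchanged", {
  set.seed(10)
  co <- array(rnorm(3 * 4 * 3), c(3, 4, 3))
  ens <- toy_ensemble(co)
  dup <- toy_ensemble(co[rep(1:3, 2), , , drop = FALSE])
  g1 <- ensemble_grid_stats(ens, kernel_sigma = 1, spacing = 1, padding = 5)
  g2 <- ensemble_grid_stats(dup, kernel_sigma = 1, spacing = 1, padding = 5,
                            geometry = g1$mean)
  expect_lt(max(abs(g1$mean$values - g2$mean$values)), 1e-12)
  expect_lt(max(abs(g1$sd$values - g2$sd$values)), 1e-12)
})

test_that("grids are invariant under atom permutation and translation", {
  set.seed(11)
  coords <- matrix(rnorm(30, sd = 2), 10, 3)
  geom <- grid_geometry(coords, spacing = 0.8, padding = 6)
  g1 <- frame_density_grid(coords, geom)
  g2 <- frame_density_grid(coords[sample(10), ], geom)
  # summation order differs, so equality holds to round-off
  expect_lt(max(abs(g1$values - g2$values)), 1e-12)

  shift <- c(3.21, -1.5, 0.77)
  geom2 <- scalar_grid(geom$origin + shift, geom$spacing, geom$dims)
  g3 <- frame_density_grid(sweep(coords, 2, shift, "+"), geom2)
  expect_lt(max(abs(g3$values - g1$values)), 1e-9)
})

test_that("Gaussian smoothing matches a directly constructed kernel", {
  g <- scalar_grid(c(0, 0, 0), 1, c(25, 25, 25))
  expect_identical(smooth_grid(g, 0), g)

  g$values[13, 13, 13] <- 1
  sm <- smooth_grid(g, 1.5)
  r <- ceiling(4 * 1.5)
  k1 <- exp(-0.5 * ((-r:r) / 1.5)^2)
  k1 <- k1 / sum(k1)
  expected <- outer(outer(k1, k1), k1)
  idx <- (13 - r):(13 + r)
  expect_lt(max(abs(sm$values[idx, idx, idx] - expected)), 1e-12)
  expect_lte(sum(sm$values), 1 + 1e-12)
  expect_gte(sum(sm$values), 0.99)

  expect_error(smooth_grid(g, -1), class = "surfplast_domain_error")
})

test_that("constant grids are unchanged by smoothing deep in the interior", {
  g <- scalar_grid(c(0, 0, 0), 1, c(21, 21, 21),
                   array(2.5, c(21, 21, 21)))
  sm <- smooth_grid(g, 1.5)
  r <- ceiling(4 * 1.5)
  core <- (r + 1):(21 - r)
  expect_lt(max(abs(sm$values[core, core, core] - 2.5)), 1e-6)
})

test_that("localized plasticity samples the smoothed SD field per residue", {
  set.seed(12)
  ens <- toy_ensemble(array(rnorm(2 * 5 * 3), c(2, 5, 3)))
  gs <- ensemble_grid_stats(ens, kernel_sigma = 1, spacing = 1, padding = 6)
  const <- scalar_grid(gs$sd$origin, gs$sd$spacing, gs$sd$dims,
                       array(3.7, gs$sd$dims))
  res <- localize_plasticity(gs, const, ens)
  expect_true(all(abs(res$per_atom - 3.7) < 1e-12))
  expect_true(all(abs(res$per_residue$plasticity - 3.7) < 1e-12))

  # static ensemble: plasticity identically zero
  frame <- matrix(rnorm(12), 4, 3)
  stat_ens <- toy_ensemble(array(rep(frame, each = 3), c(3, 4, 3)))
  pl <- surface_plasticity(stat_ens, kernel_sigma = 1, spacing = 1,
                           padding = 5, align = FALSE)
  expect_true(all(pl$per_atom == 0))
})

test_that("atom positions outside the grid raise a boundary error", {
  ens <- toy_ensemble(array(rnorm(2 * 4 * 3), c(2, 4, 3)))
  gs <- ensemble_grid_stats(ens, kernel_sigma = 1, spacing = 1, padding = 5)
  tiny <- scalar_grid(c(100, 100, 100), 1, gs$sd$dims,
                      array(0, gs$sd$dims))
  expect_error(localize_plasticity(
    list(sd = tiny, params = gs$params), tiny, ens),
    class = "surfplast_boundary_error")
})

test_that("a flexible middle segment shows higher plasticity than flanks", {
  for (seed in 1:5) {
    spec <- three_segment_spec(n_frames = 500, seed = seed)
    pl <- surface_plasticity(sample_harmonic_ensemble(spec),
                             spacing = 0.75, padding = 6)
    seg <- segment_means(pl)
    expect_gt(seg[2], seg[1])
    expect_gt(seg[2], seg[3])
  }
})

test_that("raising a region's amplitude never lowers its plasticity", {
  for (seed in 1:10) {
    lo <- three_segment_spec(amplitudes = c(0.2, 0.6, 0.2), n_frames = 400,
                             seed = seed)
    hi <- three_segment_spec(amplitudes = c(0.2, 1.2, 0.2), n_frames = 400,
                             seed = seed)
    pl_lo <- surface_plasticity(sample_harmonic_ensemble(lo),
                                spacing = 0.75, padding = 6)
    pl_hi <- surface_plasticity(sample_harmonic_ensemble(hi),
                                spacing = 0.75, padding = 6)
    expect_gte(segment_means(pl_hi)[2], segment_means(pl_lo)[2])
  }
})

test_that("isosurface vertices of a Gaussian atom sit at the level radius", {
  geom <- grid_geometry(matrix(0, 1, 3), spacing = 0.25, padding = 5)
  g <- frame_density_grid(matrix(0, 1, 3), geom, kernel_sigma = 1)
  mesh <- extract_isosurface(g, 0.5)
  expect_gt(nrow(mesh$vertices), 0)
  radii <- sqrt(rowSums(mesh$vertices^2))
  expect_true(all(abs(radii - sqrt(2 * log(2))) < g$spacing))
  # vertices inside the grid bounding box
  hi <- g$origin + (g$dims - 1) * g$spacing
  expect_true(all(sweep(mesh$vertices, 2, g$origin, ">=")))
  expect_true(all(sweep(mesh$vertices, 2, hi, "<=")))
  expect_error(extract_isosurface(g, 2), class = "surfplast_domain_error")
})

test_that("isosurface meshes export as Wavefront OBJ", {
  geom <- grid_geometry(matrix(0, 1, 3), spacing = 0.5, padding = 4)
  g <- frame_density_grid(matrix(0, 1, 3), geom, kernel_sigma = 1)
  mesh <- extract_isosurface(g, 0.5)
  p <- tempfile(fileext = ".obj")
  write_obj_mesh(mesh, p)
  lines <- readLines(p)
  expect_equal(sum(grepl("^v ", lines)), nrow(mesh$vertices))
  expect_equal(sum(grepl("^f ", lines)), nrow(mesh$faces))
})
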