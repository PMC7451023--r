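# Cartesian PCA, Maclaurin reweighting, free-energy surfaces,
# conformational-selection statistics.

test_that("PCA recovers a single planted collective mode", {
  n <- 20L
  ref <- make_reference_structure(n, "helix")
  mode <- collective_mode(n, 1:n, c(1, 0, 0), amplitude = 1)
  spec <- synthetic_spec(ref, region_amplitudes = c("1" = 0.05),
                         collective_modes = list(mode), n_frames = 2000,
                         seed = 21)
  model <- fit_pca(sample_harmonic_ensemble(spec), 2, selection = "all")
  cosine <- abs(sum(model$components[1, ] * as.vector(t(mode$direction))))
  expect_gt(cosine, 0.99)
  expect_equal(model$eigenvalues[1], 1, tolerance = 0.15)
  expect_true(all(diff(model$eigenvalues) <= 1e-10))
  expect_lt(max(abs(colMeans(model$projections))), 1e-10)
})

test_that("a rank-1 perturbation gives exactly one nonzero eigenvalue", {
  base <- matrix(rnorm(12), 4, 3)
  co <- array(rep(base, each = 6), c(6, 4, 3))
  co[6, 1, 1] <- co[6, 1, 1] + 2
  model <- fit_pca(toy_ensemble(co), 3)
  expect_gt(model$all_eigenvalues[1], 1e-4)
  expect_true(all(model$all_eigenvalues[-1] <= 1e-10))
})

test_that("PCA agrees with a brute-force covariance eigendecomposition", {
  set.seed(22)
  nt <- 200L
  n <- 20L
  co <- array(rnorm(nt * n * 3, sd = 0.5), c(nt, n, 3))
  ens <- toy_ensemble(co)
  model <- fit_pca(ens, 5)
  x <- matrix(0, nt, 3 * n)
  for (d in 1:3) x[, seq(d, 3 * n, by = 3)] <- co[, , d]
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(xc) / nt, symmetric = TRUE)
  expect_equal(model$eigenvalues, ev$values[1:5], tolerance = 1e-8)
  for (k in 1:5) {
    proj_oracle <- xc %*% ev$vectors[, k]
    # eigenvectors are sign-ambiguous
    err <- min(max(abs(model$projections[, k] - proj_oracle)),
               max(abs(model$projections[, k] + proj_oracle)))
    expect_lt(err, 1e-8)
  }
  # orthonormality and variance conservation
  expect_lt(max(abs(tcrossprod(model$components) - diag(5))), 1e-8)
  expect_equal(sum(model$all_eigenvalues), model$total_variance,
               tolerance = 1e-8)
  expect_error(fit_pca(toy_ensemble(co[1, , , drop = FALSE]), 1),
               class = "surfplast_insufficient_frames")
})

test_that("Maclaurin weights follow the truncated exponential series", {
  t300 <- 300
  beta <- 1 / (KB_KCAL * t300)
  zero <- boost_series(rep(0, 5), t300)
  expect_equal(maclaurin_weights(zero, 10), rep(1, 5))

  half <- boost_series(0.5 / beta, t300)          # beta dV = 0.5
  expect_equal(maclaurin_weights(half, 1, normalize = FALSE), 1.5)

  one <- boost_series(1 / beta, t300)             # beta dV = 1
  expect_equal(maclaurin_weights(one, 10, normalize = FALSE), exp(1),
               tolerance = 1e-7 / exp(1))

  expect_error(maclaurin_weights(one, -1), class = "surfplast_domain_error")
})

test_that("weights grow with order and are bounded by the exponential", {
  b <- boost_series(c(0.1, 0.5, 1.2, 2), 300)
  raw <- sapply(0:12, function(o) maclaurin_weights(b, o, normalize = FALSE))
  expect_true(all(diff(t(raw)) >= 0))
  exact <- maclaurin_weights(b, Inf, normalize = FALSE)
  expect_true(all(raw <= exact + 1e-12))
})

test_that("uniform samples give a flat free-energy profile", {
  withr::with_seed(23, {
    x <- runif(1e5, -1, 1)
  })
  fes <- reweighted_fes(x, bins = 4, range = c(-1, 1))
  expect_true(all(!fes$empty))
  expect_lt(max(fes$free_energy) - min(fes$free_energy), 0.1)
  expect_equal(sum(fes$probabilities), 1)
})

test_that("degenerate histograms flag empty bins instead of faking them", {
  fes <- reweighted_fes(rep(0.5, 100), bins = 4, range = c(0, 2))
  expect_equal(sum(!fes$empty), 1L)
  expect_equal(fes$free_energy[!fes$empty], 0)
  expect_true(all(is.na(fes$free_energy[fes$empty])))
})

test_that("zero boost makes reweighted and unweighted FES identical", {
  withr::with_seed(24, x <- rnorm(5000))
  b <- boost_series(rep(0, 5000), 300)
  w <- maclaurin_weights(b, 10)
  f1 <- reweighted_fes(x, w, bins = 30)
  f2 <- reweighted_fes(x, NULL, bins = 30)
  expect_equal(f1$probabilities, f2$probabilities)
  expect_equal(f1$free_energy, f2$free_energy)
})

test_that("FES normalization is a projection: min F = 0 always", {
  withr::with_seed(25, x <- cbind(rnorm(2000), rnorm(2000)))
  fes <- reweighted_fes(x, bins = c(10, 12))
  expect_equal(min(fes$free_energy, na.rm = TRUE), 0)
  expect_error(reweighted_fes(x, weights = rep(1, 5)),
               class = "surfplast_dimension_error")
  expect_error(reweighted_fes(cbind(x, x[, 1])),
               class = "surfplast_domain_error")
})

test_that("reweighting recovers the double-well barrier from biased samples", {
  spec <- toy_gamd_spec(n_samples = 100000L, seed = 26)
  s <- sample_toy_gamd(spec)
  w <- maclaurin_weights(s$boost, 10)
  rw <- reweighted_fes(s$positions, w, bins = 60, range = c(-2, 2))
  un <- reweighted_fes(s$positions, NULL, bins = 60, range = c(-2, 2))
  edges <- seq(-2, 2, length.out = 61)
  fa <- analytic_fes_1d(function(x) (x^2 - 1)^2, 1 / (KB_KCAL * 300), edges)
  centers <- (edges[-1] + edges[-61]) / 2
  barrier_analytic <- fa[which.min(abs(centers))]
  expect_lt(abs(fes_barrier(rw) - barrier_analytic), 0.5)
  expect_lt(fes_barrier(un), fes_barrier(rw))
})

test_that("increasing Maclaurin order reduces the mean barrier error", {
  # a strong boost (k = 3) makes the truncation bias of low orders visible
  # above sampling noise
  errs <- matrix(0, 10, 2)
  beta <- 1 / (KB_KCAL * 300)
  edges <- seq(-2, 2, length.out = 41)
  fa <- analytic_fes_1d(function(x) (x^2 - 1)^2, beta, edges)
  centers <- (edges[-1] + edges[-41]) / 2
  target <- fa[which.min(abs(centers))]
  for (seed in 1:10) {
    s <- sample_toy_gamd(toy_gamd_spec(k_boost = 3, n_samples = 50000L,
                                       seed = seed))
    for (oi in 1:2) {
      w <- maclaurin_weights(s$boost, c(2, 10)[oi])
      fes <- reweighted_fes(s$positions, w, bins = 40, range = c(-2, 2))
      errs[seed, oi] <- abs(fes_barrier(fes) - target)
    }
  }
  expect_lt(mean(errs[, 2]), mean(errs[, 1]))
})

test_that("binding competence is 1 on itself and 0 for disjoint shapes", {
  ref <- make_reference_structure(10, "helix")
  ident <- toy_ensemble(array(rep(frame_coords(ref, 1), each = 4),
                              c(4, 10, 3)))
  rep1 <- binding_competence(ident, ref, cutoff = 0.1)
  expect_equal(rep1$competent_fraction, 1)
  expect_true(all(rep1$rmsd_to_reference < 1e-8))

  scaled <- structure_ensemble(ref$atoms, frame_coords(ref, 1) * 100)
  rep2 <- binding_competence(ident, scaled, cutoff = 1)
  expect_equal(rep2$competent_fraction, 0)
})

test_that("atom correspondence is established by identity and can fail", {
  ref <- make_reference_structure(6, "extended")
  other <- ref
  other$atoms$chain <- "B"
  ens <- toy_ensemble(array(rep(frame_coords(ref, 1), each = 2),
                            c(2, 6, 3)))
  expect_error(binding_competence(ens, other, cutoff = 1),
               class = "surfplast_correspondence_error")
})

test_that("competent fraction matches the closed-form Monte-Carlo oracle", {
  n <- 50L
  sigma <- 0.3
  cutoff <- 0.55
  ref <- make_reference_structure(n, "helix")
  spec <- synthetic_spec(ref, region_amplitudes = c("1" = sigma),
                         n_frames = 5000, seed = 27)
  rep <- binding_competence(sample_harmonic_ensemble(spec), ref,
                            cutoff = cutoff)
  withr::with_seed(28, {
    p_oracle <- oracle_competent_fraction(frame_coords(ref, 1), sigma,
                                          cutoff, 2e5)
  })
  se <- sqrt(p_oracle * (1 - p_oracle) / 5000)
  expect_lt(abs(rep$competent_fraction - p_oracle), 3 * se)
})

test_that("the closed-form RMSD oracle agrees with direct Kabsch fits", {
  n <- 12L
  ref <- frame_coords(make_reference_structure(n, "helix"), 1)
  sigma <- 0.4
  withr::with_seed(29, {
    direct <- replicate(500, {
      kabsch_superpose(ref + matrix(rnorm(3 * n, 0, sigma), n, 3),
                       ref)$rmsd
    })
  })
  withr::with_seed(30, {
    p1 <- oracle_competent_fraction(ref, sigma, 0.7, 2e5)
  })
  expect_equal(mean(direct <= 0.7), p1, tolerance = 0.08)
})

test_that("population shift compares FES pairs on identical bins", {
  withr::with_seed(31, x <- rnorm(5000))
  f <- reweighted_fes(x, bins = 40, range = c(-4, 4))
  ps <- population_shift(f, f)
  expect_equal(ps$per_pc$range_ratio, 1)
  expect_equal(ps$minima_difference, 0)

  # bound occupies half of the free range
  withr::with_seed(32, {
    free_x <- runif(20000, -2, 2)
    bound_x <- runif(20000, -1, 1)
  })
  ff <- reweighted_fes(free_x, bins = 40, range = c(-2, 2))
  fb <- reweighted_fes(bound_x, bins = 40, range = c(-2, 2))
  ps2 <- population_shift(ff, fb)
  expect_equal(ps2$per_pc$range_ratio, 0.5, tolerance = 1 / 40)

  f2 <- reweighted_fes(x, bins = 40, range = c(-5, 5))
  expect_error(population_shift(f, f2), class = "surfplast_geometry_error")
})

test_that("a two-state free ensemble loses one minimum upon binding", {
  withr::with_seed(33, {
    free_x <- c(rnorm(5000, -1.5, 0.3), rnorm(5000, 1.5, 0.3))
    bound_x <- rnorm(10000, 1.5, 0.3)
  })
  ff <- reweighted_fes(free_x, bins = 50, range = c(-3, 3))
  fb <- reweighted_fes(bound_x, bins = 50, range = c(-3, 3))
  ps <- population_shift(ff, fb)
  expect_equal(ps$minima_difference, 1)
  expect_lt(ps$per_pc$range_ratio, 1)
})
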