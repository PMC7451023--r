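# Independent oracles and fixture builders used across the suite. Each
# oracle deliberately follows a different computational route than the
# package code it checks.

# small ensemble straight from an atom table and coordinate array
toy_ensemble <- function(coords, names = NULL) {
  n <- dim(coords)[2]
  atoms <- tibble::tibble(
    serial = seq_len(n), name = names %||% rep("CA", n), resname = "ALA",
    chain = "A", resseq = seq_len(n), icode = "", element = "C")
  structure_ensemble(atoms, coords)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# multi-model PDB fixture text: list of frames, each an N x 3 matrix
write_pdb_fixture <- function(frames, path, names = NULL) {
  n <- nrow(frames[[1]])
  if (is.null(names)) names <- rep("CA", n)
  lines <- character(0)
  for (m in seq_along(frames)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(n)) {
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, sprintf(" %-3s", names[i]), "ALA", "A", i,
        frames[[m]][i, 1], frames[[m]][i, 2], frames[[m]][i, 3],
        1, 0, substr(names[i], 1, 1)))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# random proper rotation from a random unit quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

euler_rotation <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
  rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rz1 %*% ry %*% rz2
}

# Brute-force superposition: minimize rmsd over a grid of Euler angles.
# Uses rmsd^2 = (|A|^2 + |B|^2 - 2 tr(R H)) / N with H the 3x3
# cross-covariance, so only tr(R H) is evaluated per rotation.
brute_force_rmsd <- function(mobile, target, step_deg = 2) {
  a0 <- sweep(mobile, 2, colMeans(mobile))
  b0 <- sweep(target, 2, colMeans(target))
  h <- crossprod(a0, b0)
  n <- nrow(mobile)
  const <- sum(a0^2) + sum(b0^2)
  step <- step_deg * pi / 180
  alphas <- seq(0, 2 * pi - step, by = step)
  betas <- seq(0, pi, by = step)
  gammas <- seq(0, 2 * pi - step, by = step)
  bg <- expand.grid(b = betas, g = gammas)
  best <- Inf
  for (a in alphas) {
    ca <- cos(a); sa <- sin(a)
    cb <- cos(bg$b); sb <- sin(bg$b); cg <- cos(bg$g); sg <- sin(bg$g)
    # R = Rz(a) Ry(b) Rz(g), entries vectorized over the beta/gamma grid
    r11 <- ca * cb * cg - sa * sg; r12 <- -ca * cb * sg - sa * cg
    r13 <- ca * sb
    r21 <- sa * cb * cg + ca * sg; r22 <- -sa * cb * sg + ca * cg
    r23 <- sa * sb
    r31 <- -sb * cg; r32 <- sb * sg; r33 <- cb
    # note: R is applied to mobile, so trace pairs R[i,j] with H[j,i]
    tr <- r11 * h[1, 1] + r12 * h[2, 1] + r13 * h[3, 1] +
          r21 * h[1, 2] + r22 * h[2, 2] + r23 * h[3, 2] +
          r31 * h[1, 3] + r32 * h[2, 3] + r33 * h[3, 3]
    best <- min(best, min(const - 2 * tr))
  }
  sqrt(max(best, 0) / n)
}

# Independent random-walk Metropolis chain on exp(-beta V), written apart
# from the package sampler.
metropolis_oracle <- function(vfun, beta, n, step = 0.5, x0 = 1,
                              burn = ceiling(0.1 * n)) {
  xs <- numeric(n + burn)
  x <- x0
  vx <- vfun(x)
  for (i in seq_len(n + burn)) {
    xp <- x + rnorm(1, 0, step)
    vp <- vfun(xp)
    if (log(runif(1)) <= beta * (vx - vp)) {
      x <- xp
      vx <- vp
    }
    xs[i] <- x
  }
  xs[(burn + 1):(n + burn)]
}

# Analytic binned free-energy profile of exp(-beta V) by quadrature.
analytic_fes_1d <- function(vfun, beta, edges) {
  p <- vapply(seq_len(length(edges) - 1L), function(i) {
    stats::integrate(function(x) exp(-beta * vfun(x)), edges[i],
                     edges[i + 1])$value
  }, numeric(1))
  p <- p / sum(p)
  fe <- -log(p)
  fe - min(fe)
}

# Vectorized Monte-Carlo oracle for the fitted-RMSD distribution of an
# isotropic Gaussian ensemble around a reference. Closed-form (trigonometric)
# eigenvalues of the symmetric 3x3 A A^T give the Kabsch singular values
# without any per-draw SVD, a different route from the package code.
oracle_competent_fraction <- function(ref, sigma, cutoff, ndraws,
                                      chunk = 50000L) {
  n <- nrow(ref)
  p0 <- sweep(ref, 2, colMeans(ref))
  np2 <- sum(p0^2)
  total <- 0L
  done <- 0L
  while (done < ndraws) {
    m <- min(chunk, ndraws - done)
    xs <- list()
    for (d in 1:3) {
      x <- matrix(rnorm(m * n, 0, sigma), m, n)
      x <- sweep(x, 2, ref[, d], "+")
      xs[[d]] <- x - rowMeans(x)
    }
    nq2 <- rowSums(xs[[1]]^2) + rowSums(xs[[2]]^2) + rowSums(xs[[3]]^2)
    a <- array(0, c(m, 3, 3))
    for (i in 1:3) for (j in 1:3) a[, i, j] <- xs[[j]] %*% p0[, i]
    deta <- a[, 1, 1] * (a[, 2, 2] * a[, 3, 3] - a[, 2, 3] * a[, 3, 2]) -
            a[, 1, 2] * (a[, 2, 1] * a[, 3, 3] - a[, 2, 3] * a[, 3, 1]) +
            a[, 1, 3] * (a[, 2, 1] * a[, 3, 2] - a[, 2, 2] * a[, 3, 1])
    mm <- array(0, c(m, 3, 3))
    for (i in 1:3) for (j in i:3) {
      mm[, i, j] <- a[, i, 1] * a[, j, 1] + a[, i, 2] * a[, j, 2] +
        a[, i, 3] * a[, j, 3]
      mm[, j, i] <- mm[, i, j]
    }
    q <- (mm[, 1, 1] + mm[, 2, 2] + mm[, 3, 3]) / 3
    p1 <- mm[, 1, 2]^2 + mm[, 1, 3]^2 + mm[, 2, 3]^2
    p2 <- (mm[, 1, 1] - q)^2 + (mm[, 2, 2] - q)^2 + (mm[, 3, 3] - q)^2 +
      2 * p1
    p <- sqrt(pmax(p2 / 6, 1e-300))
    b11 <- (mm[, 1, 1] - q) / p; b22 <- (mm[, 2, 2] - q) / p
    b33 <- (mm[, 3, 3] - q) / p
    b12 <- mm[, 1, 2] / p; b13 <- mm[, 1, 3] / p; b23 <- mm[, 2, 3] / p
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q + 2 * p * cos(phi)
    e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    e2 <- 3 * q - e1 - e3
    s1 <- sqrt(pmax(e1, 0)); s2 <- sqrt(pmax(e2, 0))
    s3 <- sqrt(pmax(e3, 0)) * sign(deta)
    rmsd <- sqrt(pmax(np2 + nq2 - 2 * (s1 + s2 + s3), 0) / n)
    total <- total + sum(rmsd <= cutoff)
    done <- done + m
  }
  total / ndraws
}

# three-segment peptide spec: low/high/low fluctuation amplitudes
three_segment_spec <- function(n_per_segment = 5L, amplitudes = c(0.2, 1, 0.2),
                               n_frames = 2000L, seed = 1L) {
  n <- 3L * n_per_segment
  ref <- make_reference_structure(n, "extended")
  labels <- rep(1:3, each = n_per_segment)
  synthetic_spec(ref, labels,
                 stats::setNames(amplitudes, as.character(1:3)),
                 n_frames = n_frames, seed = seed)
}

segment_means <- function(plast, n_per_segment = 5L) {
  pr <- plast$per_residue$plasticity
  vapply(1:3, function(s) {
    mean(pr[((s - 1) * n_per_segment + 1):(s * n_per_segment)])
  }, numeric(1))
}
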