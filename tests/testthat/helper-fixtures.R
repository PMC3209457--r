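# Shared fixtures and independent oracles, built in code at test time.

# a 2-site dimer within any reasonable cutoff
dimer_structure <- function(d = 3.8) {
  as_ca_structure(data.frame(chain = "A", resno = 1:2, resname = "GLY",
                             x = c(0, d), y = 0, z = 0))
}

dimer_stretch_mode <- function() c(1, 0, 0, -1, 0, 0) / sqrt(2)

# write a toy PDB by hand, wwPDB fixed columns, independent of bio3d
write_toy_pdb <- function(path, records) {
  writeLines(c(records, "END"), path)
  path
}

atom_record <- function(serial, elety, resname, chain, resno, x, y, z,
                        altloc = " ") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, paste0(" ", elety), altloc, resname, chain, resno, x, y, z)
}

# brute-force double-loop assembly of the anisotropic network Hessian
reference_hessian <- function(xyz, cutoff, gamma, scale_at = NULL) {
  n <- nrow(xyz)
  if (is.null(scale_at)) scale_at <- rep(1, n)
  h <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- xyz[j, ] - xyz[i, ]
      d2 <- sum(d^2)
      if (d2 > cutoff^2) next
      k_ij <- gamma * scale_at[i] * scale_at[j]
      block <- -k_ij * outer(d, d) / d2
      ri <- (3 * i - 2):(3 * i)
      rj <- (3 * j - 2):(3 * j)
      h[ri, rj] <- block
      h[ri, ri] <- h[ri, ri] - block
    }
  }
  h
}

# residue-level covariance via the Moore-Penrose pseudo-inverse (MASS),
# the independent route to the same physical quantity as mode_covariance
pinv_covariance <- function(hessian, n) {
  kfull <- MASS::ginv(hessian)
  k <- matrix(0, n, n)
  for (a in 1:3) {
    rows <- seq(a, 3 * n, by = 3)
    k <- k + kfull[rows, rows]
  }
  k
}

# brute-force superposition: axis-angle grid search plus Nelder-Mead
# polish, never touching the SVD path under test
rotation_from_axis_angle <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  a <- v / theta
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * k + (1 - cos(theta)) * (k %*% k)
}

grid_min_rmsd <- function(mobile, reference, n_axes = 150,
                          angle_step_deg = 2) {
  am <- sweep(mobile, 2, colMeans(mobile))
  bm <- sweep(reference, 2, colMeans(reference))
  fit_rmsd <- function(v) {
    r <- rotation_from_axis_angle(v)
    sqrt(mean(rowSums((am %*% t(r) - bm)^2)))
  }
  # golden-spiral axes x angle grid
  i <- seq_len(n_axes)
  phi <- acos(1 - 2 * (i - 0.5) / n_axes)
  lam <- pi * (1 + sqrt(5)) * (i - 0.5)
  axes <- cbind(sin(phi) * cos(lam), sin(phi) * sin(lam), cos(phi))
  angles <- seq(angle_step_deg, 180, by = angle_step_deg) * pi / 180
  best <- c(0, 0, 0)
  best_val <- fit_rmsd(best)
  for (ai in seq_len(n_axes)) {
    for (th in angles) {
      v <- axes[ai, ] * th
      val <- fit_rmsd(v)
      if (val < best_val) {
        best_val <- val
        best <- v
      }
    }
  }
  opt <- stats::optim(best, fit_rmsd, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  opt$value
}

# strip everything but the dim attribute for value-only matrix comparison
plain_matrix <- function(m) {
  m <- unclass(m)
  attributes(m) <- attributes(m)["dim"]
  m
}

# self-cleaning tempfile for PDB round trips
withr_local_tempfile <- function(env = parent.frame()) {
  path <- tempfile(fileext = ".pdb")
  withr::defer(unlink(path), envir = env)
  path
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3))) -> q
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
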