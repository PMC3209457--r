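#' Parameters for an overdamped Langevin run
#'
#' Reduced units throughout: the spring constant `gamma`, friction `zeta`
#' and thermal energy `kT` set the scales, so the natural time unit is
#' `zeta/gamma` and the natural length unit `sqrt(kT/gamma)`. The
#' defaults mirror common all-atom MD bookkeeping — many small steps with
#' coordinates saved every 100 steps and only a trailing window analysed
#' — at a desk-scale cost.
#'
#' @param timestep Integration step in reduced time (default 0.01; must
#'   satisfy `timestep < 2 * friction / lambda_max` for stability, which
#'   the simulator checks with a Gershgorin bound).
#' @param n_steps Total number of steps (default 200000).
#' @param save_every Save a frame every this many steps (default 100).
#' @param kT Thermal energy, reduced units (default 1; 0 gives pure
#'   gradient descent to the minimum).
#' @param friction Friction coefficient zeta, reduced units (default 1).
#' @param seed Integer RNG seed; recorded in the trajectory so any run is
#'   exactly reproducible.
#' @return A `sim_params` list.
#' @export
sim_params <- function(timestep = 0.01, n_steps = 200000L, save_every = 100L,
                       kT = 1, friction = 1, seed = 1L) {
  if (timestep <= 0) abort("`timestep` must be positive", class = "flexmotif_argument_error")
  if (save_every < 1) abort("`save_every` must be >= 1", class = "flexmotif_argument_error")
  if (n_steps < save_every) {
    abort("`n_steps` must be at least `save_every`", class = "flexmotif_argument_error")
  }
  if (kT < 0) abort("`kT` must be non-negative", class = "flexmotif_argument_error")
  if (friction <= 0) abort("`friction` must be positive", class = "flexmotif_argument_error")
  structure(
    list(timestep = timestep, n_steps = as.integer(n_steps),
         save_every = as.integer(save_every), kT = kT, friction = friction,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params: dt %g, %d steps, save every %d, kT %g, friction %g, seed %d>\n",
    x$timestep, x$n_steps, x$save_every, x$kT, x$friction, x$seed))
  invisible(x)
}

#' Simulate overdamped Langevin dynamics on an elastic network
#'
#' Euler-Maruyama integration of Brownian dynamics on the quadratic
#' network potential, starting from the model's input structure (its
#' energy minimum). The thermostat is the Langevin noise term itself: the
#' stationary distribution is exactly the Boltzmann distribution of the
#' harmonic model, which is what makes closed-form checks (equipartition,
#' mode variances) possible. Frame 0 is always the starting conformation.
#'
#' @param model An `enm_model`.
#' @param params A [sim_params()] object.
#' @param remove_rigid Project net translation and rotation out of every
#'   step increment (default `TRUE`), the Brownian analogue of MD
#'   centre-of-mass motion removal. The linearised rigid-body modes have
#'   no restoring force; left in, they diffuse without bound and their
#'   tangent-space "rotations" increasingly distort internal geometry,
#'   which no after-the-fact superposition can undo. With removal the
#'   trajectory stays in the internal subspace, where the windowed
#'   fluctuations converge to the network's thermal covariance.
#' @return An `enm_trajectory`: saved frames (rows of a frames x 3N
#'   matrix), `times` in reduced units, the `params` used, and the
#'   reference `ca_structure`.
#' @examples
#' mod <- build_hessian(make_structure(toy_spec("helix", 15)))
#' traj <- simulate_enm(mod, sim_params(n_steps = 2000, save_every = 100, seed = 7))
#' traj
#' @export
simulate_enm <- function(model, params = sim_params(), remove_rigid = TRUE) {
  stopifnot(inherits(model, "enm_model"), inherits(params, "sim_params"))
  # Gershgorin upper bound on the largest eigenvalue; Euler-Maruyama on a
  # quadratic potential is stable only for dt * lambda_max / zeta < 2.
  lam_bound <- max(rowSums(abs(model$hessian)))
  if (params$timestep * lam_bound / params$friction >= 2) {
    warn(sprintf(
      "timestep %g may be unstable (Gershgorin bound on dt*lambda_max/friction = %.3g >= 2)",
      params$timestep, params$timestep * lam_bound / params$friction))
  }
  xyz <- coords(model$structure)
  x0 <- as.vector(t(xyz))
  rigid <- if (remove_rigid) rigid_body_basis(xyz) else
    matrix(0, length(x0), 0)
  set.seed(params$seed)
  frames <- langevin_core(model$hessian, x0, rigid, params$timestep,
                          params$kT, params$friction, params$n_steps,
                          params$save_every)
  n_saved <- nrow(frames) - 1
  structure(
    list(frames = frames,
         times = (0:n_saved) * params$save_every * params$timestep,
         params = params, reference = model$structure),
    class = "enm_trajectory"
  )
}

#' @export
print.enm_trajectory <- function(x, ...) {
  cat(sprintf(
    "<enm_trajectory: %d frames x %d sites, t = 0..%g, seed %d>\n",
    nrow(x$frames), nrow(x$reference), max(x$times), x$params$seed))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `enm_trajectory`.
#' @return Integer frame count (including frame 0, the start).
#' @export
n_frames <- function(traj) nrow(traj$frames)

#' Coordinates of one trajectory frame
#' @param traj An `enm_trajectory`.
#' @param i Frame index, 1-based (frame 1 is the starting conformation).
#' @return N x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= nrow(traj$frames))
  matrix(traj$frames[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' RMSD time series of a trajectory against its starting conformation
#'
#' Per-frame least-squares-fitted RMSD to frame 0, over all sites or a
#' motif subset. For a motif, `fit_mode` chooses between fitting on the
#' whole molecule (`"fit_all"`, motion of the motif in the molecular
#' frame) and fitting on the motif itself (`"fit_motif"`, internal
#' deformation only); see [motif_rmsd()].
#'
#' @param traj An `enm_trajectory`.
#' @param selection Optional integer vector of 1-based site indices (the
#'   motif); `NULL` (default) uses all sites.
#' @param fit_mode `"fit_all"` (default) or `"fit_motif"`; ignored when
#'   `selection` is `NULL`.
#' @return An `rmsd_series` tibble with columns `time`, `rmsd`.
#' @export
trajectory_rmsd <- function(traj, selection = NULL,
                            fit_mode = c("fit_all", "fit_motif")) {
  stopifnot(inherits(traj, "enm_trajectory"))
  fit_mode <- match.arg(fit_mode)
  ref <- coords(traj$reference)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    f <- frame_coords(traj, i)
    if (is.null(selection)) {
      rmsd(f, ref, fit = TRUE)
    } else {
      motif_rmsd(f, ref, selection, fit_mode)
    }
  }, numeric(1))
  tibble::new_tibble(
    tibble::tibble(time = traj$times, rmsd = vals),
    selection = selection, fit_mode = if (is.null(selection)) NA_character_ else fit_mode,
    class = "rmsd_series"
  )
}

#' Mean of a time series over a trailing (or leading) window
#'
#' The convention of discarding the equilibration phase and averaging
#' only a trailing fraction of a trajectory: `window = 0.5, from_end =
#' TRUE` averages the second half.
#'
#' @param ts A tibble with columns `time` and `rmsd` (or any `values`
#'   column named by `column`), e.g. from [trajectory_rmsd()].
#' @param window Fraction of the series to average, in (0, 1].
#' @param from_end Take the trailing window (default) or the leading one.
#' @param column Name of the value column (default `"rmsd"`).
#' @return The arithmetic mean, a single number.
#' @export
mean_rmsd <- function(ts, window = 0.5, from_end = TRUE, column = "rmsd") {
  if (window <= 0 || window > 1) {
    abort("`window` must be in (0, 1]", class = "flexmotif_argument_error")
  }
  v <- ts[[column]]
  n_keep <- floor(window * length(v))
  if (n_keep < 1) {
    abort("window contains no samples", class = "flexmotif_argument_error")
  }
  mean(if (from_end) tail(v, n_keep) else head(v, n_keep))
}

#' B-factors from the trailing window of a trajectory
#'
#' Rigid-body motion is removed by superposing every window frame onto
#' the first window frame and then onto the iteratively refined mean
#' structure (superpose, re-average; 3 rounds), then \eqn{B_i = (8\pi^2/3) \langle |r_i - \langle r_i\rangle|^2 \rangle}
#' over the window. With a long enough run this converges to the
#' network's thermal covariance diagonal (equipartition), so trajectory
#' and NMA B-factors agree up to sampling error.
#'
#' @param traj An `enm_trajectory`.
#' @param window Trailing fraction of frames to use (default 0.5, i.e.
#'   the second half); must contain at least 10 frames.
#' @param n_fit_rounds Superpose/re-average iterations (default 3).
#' @return A `bfactor_profile` tibble with attribute `source = "trajectory"`.
#' @export
trajectory_bfactors <- function(traj, window = 0.5, n_fit_rounds = 3) {
  stopifnot(inherits(traj, "enm_trajectory"))
  nf <- n_frames(traj)
  n_keep <- floor(window * nf)
  if (n_keep < 10) {
    abort(sprintf("window of %d frame(s) is too short; need at least 10", n_keep),
          class = "flexmotif_argument_error")
  }
  idx <- (nf - n_keep + 1):nf
  frames <- lapply(idx, function(i) frame_coords(traj, i))
  # remove rigid-body drift/tumbling first by fitting every frame onto the
  # first window frame; averaging unaligned frames of a freely diffusing
  # molecule gives a degenerate mean that the refinement cannot recover from
  frames <- lapply(frames, function(f) {
    sp <- kabsch(f, frames[[1]])
    sweep(f %*% t(sp$rotation), 2, sp$translation, `+`)
  })
  mean_xyz <- Reduce(`+`, frames) / length(frames)
  for (round in seq_len(n_fit_rounds)) {
    frames <- lapply(frames, function(f) {
      sp <- kabsch(f, mean_xyz)
      sweep(f %*% t(sp$rotation), 2, sp$translation, `+`)
    })
    mean_xyz <- Reduce(`+`, frames) / length(frames)
  }
  msf <- Reduce(`+`, lapply(frames, function(f) rowSums((f - mean_xyz)^2))) /
    length(frames)
  new_bfactor_profile(traj$reference, (8 * pi^2 / 3) * msf,
                      source = "trajectory")
}

# Orthonormal basis of the rigid-body subspace at a configuration:
# three uniform translations plus the (up to) three infinitesimal
# rotations about the centroid; collinear configurations have rank 5.
rigid_body_basis <- function(xyz, tol = 1e-10) {
  n <- nrow(xyz)
  centered <- sweep(xyz, 2, colMeans(xyz))
  basis <- matrix(0, 3 * n, 6)
  for (a in 1:3) basis[seq(a, 3 * n, by = 3), a] <- 1
  axes <- diag(3)
  for (a in 1:3) {
    rot <- t(apply(centered, 1, function(r) crossprod_3(axes[a, ], r)))
    basis[, 3 + a] <- as.vector(t(rot))
  }
  sv <- svd(basis)
  keep <- sv$d > tol * max(sv$d)
  sv$u[, keep, drop = FALSE]
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Unguarded Kabsch fit: used internally where degenerate site counts
# (e.g. a 2-site dimer window) still have a well-defined minimiser.
kabsch <- function(a, b) {
  ca <- colMeans(a)
  cb <- colMeans(b)
  h <- crossprod(sweep(a, 2, ca), sweep(b, 2, cb))
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = rot, translation = as.numeric(cb - ca %*% t(rot)))
}

#' Persist a trajectory as a multi-model PDB plus metadata sidecar
#'
#' One MODEL block per saved frame, plus a plain-text key-value sidecar
#' (`<path>.meta`) recording the integration parameters and seed needed
#' to reproduce the run.
#'
#' @param traj An `enm_trajectory`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  s <- traj$reference
  bio3d::write.pdb(file = path, xyz = traj$frames,
                   resno = s$resno, chain = s$chain, resid = s$resname,
                   elety = rep("CA", nrow(s)))
  p <- traj$params
  writeLines(c(
    sprintf("n_frames %d", n_frames(traj)),
    sprintf("n_sites %d", nrow(s)),
    sprintf("timestep %.17g", p$timestep),
    sprintf("n_steps %d", p$n_steps),
    sprintf("save_every %d", p$save_every),
    sprintf("kT %.17g", p$kT),
    sprintf("friction %.17g", p$friction),
    sprintf("seed %d", p$seed)
  ), paste0(path, ".meta"))
  invisible(path)
}
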