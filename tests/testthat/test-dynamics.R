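test_that("simulation parameters are validated", {
  expect_error(sim_params(timestep = 0), class = "flexmotif_argument_error")
  expect_error(sim_params(save_every = 0), class = "flexmotif_argument_error")
  expect_error(sim_params(n_steps = 10, save_every = 100),
               class = "flexmotif_argument_error")
  expect_error(sim_params(kT = -1), class = "flexmotif_argument_error")
  expect_error(sim_params(friction = 0), class = "flexmotif_argument_error")
})

test_that("identical model, parameters and seed give bit-identical trajectories", {
  mod <- build_hessian(make_structure(toy_spec("helix", 15)))
  p <- sim_params(n_steps = 2000, save_every = 50, seed = 123)
  t1 <- simulate_enm(mod, p)
  t2 <- simulate_enm(mod, p)
  expect_identical(t1$frames, t2$frames)
  t3 <- simulate_enm(mod, sim_params(n_steps = 2000, save_every = 50, seed = 124))
  expect_false(identical(t1$frames, t3$frames))
})

test_that("frame 0 is the starting conformation and times follow the save interval", {
  mod <- build_hessian(make_structure(toy_spec("helix", 12)))
  p <- sim_params(timestep = 0.02, n_steps = 1000, save_every = 100, seed = 3)
  traj <- simulate_enm(mod, p)
  expect_equal(n_frames(traj), 11)
  expect_equal(frame_coords(traj, 1), coords(mod$structure),
               ignore_attr = TRUE)
  expect_equal(traj$times, seq(0, 20, by = 2))
})

test_that("at kT = 0 the system stays at its minimum and energy never increases", {
  mod <- build_hessian(make_structure(toy_spec("helix", 12)))
  traj <- simulate_enm(mod, sim_params(kT = 0, n_steps = 1000, save_every = 100,
                                       seed = 1))
  x0 <- as.vector(t(coords(mod$structure)))
  energies <- apply(traj$frames, 1, function(x) {
    dx <- x - x0
    0.5 * sum(dx * (mod$hessian %*% dx))
  })
  expect_true(all(diff(energies) <= 1e-12))
  series <- trajectory_rmsd(traj)
  expect_equal(series$rmsd, rep(0, n_frames(traj)), tolerance = 1e-12)
})

test_that("unstable timesteps are flagged and divergence stops with the step number", {
  mod <- build_hessian(make_structure(toy_spec("helix", 12)))
  expect_warning(
    expect_error(simulate_enm(mod, sim_params(timestep = 5, n_steps = 1000,
                                              save_every = 10, seed = 2)),
                 "step"),
    "unstable")
})

test_that("dimer bond-stretch mode variance matches the Ornstein-Uhlenbeck closed form", {
  gam <- 1; kT <- 1
  mod <- build_hessian(dimer_structure(), gamma = gam)
  u <- dimer_stretch_mode()
  vars <- vapply(1:3, function(seed) {
    traj <- simulate_enm(mod, sim_params(n_steps = 2e5, save_every = 20,
                                         kT = kT, seed = seed))
    q <- sweep(traj$frames, 2, traj$frames[1, ]) %*% u
    stats::var(as.vector(q))
  }, numeric(1))
  expect_equal(mean(vars), kT / (2 * gam), tolerance = 0.05)
})

test_that("trajectory RMSD of rigidly moved copies vanishes with fitting", {
  s <- make_structure(toy_spec("helix", 15))
  ref <- coords(s)
  set.seed(9)
  frames <- lapply(1:5, function(i) {
    r <- random_rotation()
    ref %*% t(r) + matrix(rep(rnorm(3, sd = 5), each = nrow(ref)), ncol = 3)
  })
  traj <- structure(list(
    frames = do.call(rbind, c(list(as.vector(t(ref))),
                              lapply(frames, function(f) as.vector(t(f))))),
    times = 0:5, params = sim_params(n_steps = 100, save_every = 100, seed = 1),
    reference = s), class = "enm_trajectory")
  series <- trajectory_rmsd(traj)
  expect_true(all(series$rmsd < 1e-6))
})

test_that("motif series with fit_motif never exceeds fit_all, frame by frame", {
  mod <- build_hessian(make_structure(toy_spec("helix_loop_helix", 24)))
  traj <- simulate_enm(mod, sim_params(n_steps = 3000, save_every = 100, seed = 5))
  motif <- resolve_selection(mod$structure, attr(mod$structure, "motif"))
  a <- trajectory_rmsd(traj, motif, "fit_all")
  m <- trajectory_rmsd(traj, motif, "fit_motif")
  expect_true(all(m$rmsd <= a$rmsd + 1e-12))
  expect_equal(a$rmsd[1], 0, tolerance = 1e-12)
})

test_that("mean_rmsd windows behave like direct slicing", {
  const <- tibble::tibble(time = 1:10, rmsd = 2)
  expect_equal(mean_rmsd(const, 0.5), 2)
  four <- tibble::tibble(time = 1:4, rmsd = c(0, 1, 2, 3))
  expect_equal(mean_rmsd(four, 0.5, from_end = TRUE), 2.5)
  expect_equal(mean_rmsd(four, 0.5, from_end = FALSE), 0.5)
  mod <- build_hessian(make_structure(toy_spec("helix", 12)))
  traj <- simulate_enm(mod, sim_params(n_steps = 4000, save_every = 100, seed = 8))
  series <- trajectory_rmsd(traj)
  n_keep <- floor(0.5 * nrow(series))
  expect_equal(mean_rmsd(series, 0.5),
               mean(utils::tail(series$rmsd, n_keep)))
  expect_error(mean_rmsd(four, 0), class = "flexmotif_argument_error")
  expect_error(mean_rmsd(tibble::tibble(time = 1, rmsd = 1), 0.5),
               class = "flexmotif_argument_error")
})

test_that("a frozen trajectory has zero B-factors", {
  mod <- build_hessian(make_structure(toy_spec("helix", 12)))
  traj <- simulate_enm(mod, sim_params(kT = 0, n_steps = 2000, save_every = 100,
                                       seed = 1))
  b <- trajectory_bfactors(traj)
  expect_equal(b$bfactor, rep(0, 12), tolerance = 1e-20)
  expect_error(trajectory_bfactors(traj, window = 0.1),
               class = "flexmotif_argument_error")
})

test_that("windowed trajectory B-factors converge to the NMA profile (equipartition)", {
  s <- make_structure(toy_spec("helix", 20))
  mod <- build_hessian(s)
  ms <- diagonalize(mod)
  traj <- simulate_enm(mod, sim_params(n_steps = 2e5, save_every = 100, seed = 21))
  b_traj <- trajectory_bfactors(traj)
  b_nma <- nma_bfactors(ms, n_modes = length(ms$values) - ms$n_zero)
  expect_gt(stats::cor(b_traj$bfactor, b_nma$bfactor), 0.9)
})

test_that("trajectories persist as multi-model PDB with a reproducibility sidecar", {
  mod <- build_hessian(make_structure(toy_spec("helix", 10)))
  p <- sim_params(n_steps = 500, save_every = 100, seed = 42)
  traj <- simulate_enm(mod, p)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(tf, paste0(tf, ".meta"))))
  write_trajectory(traj, tf)
  for (i in seq_len(n_frames(traj))) {
    s_i <- read_structure(tf, model = i)
    expect_equal(coords(s_i), frame_coords(traj, i), tolerance = 1e-3)
  }
  meta <- readLines(paste0(tf, ".meta"))
  expect_true(any(grepl("^seed 42$", meta)))
  expect_true(any(grepl("^n_frames 6$", meta)))
})
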