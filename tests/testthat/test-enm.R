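test_that("dimer closed forms: one stretch mode of stiffness 2*gamma", {
  for (gam in c(1, 2.5)) {
    mod <- build_hessian(dimer_structure(), gamma = gam)
    expect_equal(dim(mod$hessian), c(6, 6))
    ms <- diagonalize(mod)
    expect_equal(sort(abs(ms$values), decreasing = TRUE)[1], 2 * gam,
                 tolerance = 1e-12)
    expect_equal(ms$values[1:5], rep(0, 5), tolerance = 1e-10)
    cm <- suppressWarnings(cross_correlation(ms, n_modes = 1))
    expect_equal(unclass(cm)[1:2, 1:2],
                 matrix(c(1, -1, -1, 1), 2, dimnames = list(1:2, 1:2)))
    b <- suppressWarnings(nma_bfactors(ms, n_modes = 1))
    expect_equal(b$bfactor[1], b$bfactor[2])
  }
})

test_that("every 3-column Hessian block sums to zero (translational invariance)", {
  mod <- build_hessian(make_structure(toy_spec("helix", 20)))
  h <- mod$hessian
  n <- nrow(h) / 3
  for (j in seq_len(n)) {
    cols <- (3 * j - 2):(3 * j)
    expect_equal(colSums(h[, cols]), rep(0, 3), tolerance = 1e-12)
  }
  expect_equal(h, t(h), tolerance = 1e-12)
})

test_that("assembled Hessian matches the naive double-loop reference", {
  s <- make_structure(toy_spec("cloud", 30, seed = 4))
  mod <- build_hessian(s, cutoff = 13, gamma = 1)
  expect_equal(max(abs(mod$hessian - reference_hessian(coords(s), 13, 1))), 0,
               tolerance = 1e-12)
  # with a mutation perturbation at one site
  mut <- mutation_spec(7, spring_scale = 0.5)
  modm <- build_hessian(s, cutoff = 13, gamma = 2, mutations = mut)
  scale_at <- rep(1, 30); scale_at[7] <- 0.5
  expect_equal(max(abs(modm$hessian -
                         reference_hessian(coords(s), 13, 2, scale_at))), 0,
               tolerance = 1e-12)
})

test_that("disconnected contact graphs are rejected with a helpful error", {
  far <- as_ca_structure(data.frame(
    chain = "A", resno = 1:6, resname = "ALA",
    x = c(0, 3.8, 1, 100, 103.8, 101), y = c(0, 0, 3, 0, 0, 3), z = 0))
  expect_error(build_hessian(far, cutoff = 13),
               class = "flexmotif_connectivity_error")
  expect_error(build_hessian(far, cutoff = 13), "cutoff")
})

test_that("connected toys have exactly six zero modes", {
  ms <- diagonalize(build_hessian(make_structure(toy_spec("helix", 25))))
  expect_equal(ms$n_zero, 6)
  expect_true(all(ms$values >= -1e-8 * max(ms$values)))
})

test_that("spectral reconstruction reproduces the Hessian", {
  mod <- build_hessian(make_structure(toy_spec("cloud", 40, seed = 8)))
  ms <- diagonalize(mod)
  rebuilt <- ms$vectors %*% (ms$values * t(ms$vectors))
  expect_equal(max(abs(rebuilt - mod$hessian)), 0, tolerance = 1e-8)
  # orthonormality of the mode basis
  gram <- crossprod(ms$vectors)
  expect_equal(max(abs(gram - diag(nrow(gram)))), 0, tolerance = 1e-8)
})

test_that("all-nonzero-mode covariance equals the Hessian pseudo-inverse", {
  s <- make_structure(toy_spec("helix_loop_helix", 30, seed = 2))
  mod <- build_hessian(s)
  ms <- diagonalize(mod)
  k_modes <- mode_covariance(ms, n_modes = length(ms$values) - ms$n_zero)
  k_pinv <- pinv_covariance(mod$hessian, nrow(s))
  expect_lt(max(abs(k_modes - k_pinv)), 1e-8)

  cm <- cross_correlation(ms, n_modes = length(ms$values) - ms$n_zero)
  d <- sqrt(diag(k_pinv))
  expect_lt(max(abs(unclass(cm) - k_pinv / outer(d, d))), 1e-8)
})

test_that("NMA B-factors: floppy termini, pseudo-inverse oracle, mass-weighting identity", {
  s <- make_structure(toy_spec("helix", 30))
  mod <- build_hessian(s)
  ms <- diagonalize(mod)
  b <- nma_bfactors(ms, n_modes = length(ms$values) - ms$n_zero)
  expect_true(all(b$bfactor >= 0))
  expect_gt(min(b$bfactor[c(1, 30)]) / stats::median(b$bfactor), 1)

  k_pinv <- pinv_covariance(mod$hessian, 30)
  expect_lt(max(abs(b$bfactor - (8 * pi^2 / 3) * diag(k_pinv))), 1e-8)

  # uniform non-unit masses rescale time, not the mass-weighted spectrum shape
  mod_m <- build_hessian(s, masses = 2)
  ms_m <- diagonalize(mod_m)
  expect_equal(ms_m$values, ms$values / 2, tolerance = 1e-10)
})

test_that("weakening springs at a site never decreases its B-factor", {
  for (seed in 1:3) {
    s <- make_structure(toy_spec("cloud", 25, seed = seed))
    all_modes <- function(m) {
      ms <- diagonalize(m)
      nma_bfactors(ms, n_modes = length(ms$values) - ms$n_zero)
    }
    b_wt <- all_modes(build_hessian(s))
    site <- 12
    b_mt <- all_modes(build_hessian(
      s, mutations = mutation_spec(s$resno[site], spring_scale = 0.5)))
    expect_gte(b_mt$bfactor[site], b_wt$bfactor[site] - 1e-10)
  }
})

test_that("correlation maps are bounded, symmetric, unit-diagonal on generated models", {
  for (seed in 1:5) {
    kind <- c("helix", "cloud", "helix_loop_helix")[1 + seed %% 3]
    s <- make_structure(toy_spec(kind, 20 + 2 * seed, seed = seed))
    ms <- diagonalize(build_hessian(s))
    cm <- suppressWarnings(cross_correlation(ms, n_modes = 50))
    m <- unclass(cm)
    expect_true(all(m >= -1 - 1e-9 & m <= 1 + 1e-9))
    expect_equal(m, t(m), tolerance = 1e-9)
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
  }
})

test_that("requesting more modes than exist clamps with a warning", {
  ms <- diagonalize(build_hessian(make_structure(toy_spec("helix", 10))))
  expect_warning(cm <- cross_correlation(ms, n_modes = 50), "24")
  expect_equal(attr(cm, "n_modes_used"), 24)
  expect_error(mode_covariance(ms, n_modes = 0),
               class = "flexmotif_argument_error")
})

test_that("equal-weight mode averaging is available and differs from thermal weighting", {
  ms <- diagonalize(build_hessian(make_structure(toy_spec("helix_loop_helix", 24))))
  c_thermal <- cross_correlation(ms, n_modes = 10)
  c_equal <- cross_correlation(ms, n_modes = 10, weighting = "equal")
  expect_equal(attr(c_equal, "weighting"), "equal")
  expect_gt(max(abs(unclass(c_thermal) - unclass(c_equal))), 1e-3)
})

test_that("coupling_score summarises the site-motif row slice", {
  s <- make_structure(toy_spec("cloud", 30, seed = 6))
  ms <- diagonalize(build_hessian(s))
  cm <- cross_correlation(ms, n_modes = 30)
  # direct recomputation from the matrix row slice
  motif <- 10:20
  expected <- mean(abs(unclass(cm)[5, 10:20]))
  expect_equal(coupling_score(cm, site = 5, motif = motif), expected)
  # self-motif trivial cases
  expect_equal(coupling_score(cm, 5, 5, exclude_self = FALSE), 1)
  expect_error(coupling_score(cm, 5, 5, exclude_self = TRUE),
               class = "flexmotif_selection_error")
  dimer_cm <- suppressWarnings(
    cross_correlation(diagonalize(build_hessian(dimer_structure())), 1))
  expect_equal(coupling_score(dimer_cm, 1, 2), 1)
})

test_that("maps and modes export to plain-text files", {
  ms <- diagonalize(build_hessian(make_structure(toy_spec("helix", 12))))
  cm <- suppressWarnings(cross_correlation(ms))
  tf_csv <- tempfile(fileext = ".csv"); tf_mat <- tempfile(); tf_modes <- tempfile()
  on.exit(unlink(c(tf_csv, tf_mat, tf_modes)))
  write_correlation_map(cm, tf_csv, "csv")
  back <- utils::read.csv(tf_csv, row.names = 1)
  expect_equal(unname(as.matrix(back)), plain_matrix(cm), tolerance = 1e-12)
  write_correlation_map(cm, tf_mat, "matrix")
  dense <- as.matrix(utils::read.table(tf_mat))
  expect_equal(unname(dense), plain_matrix(cm), tolerance = 1e-8)
  write_modes(ms, tf_modes)
  tab <- as.matrix(utils::read.table(tf_modes))
  expect_equal(ncol(tab), 1 + length(ms$values))
  expect_equal(unname(tab[, 1]), ms$values, tolerance = 1e-8)
})
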