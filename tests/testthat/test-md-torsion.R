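test_that("planar arrangements give 0 and 180 degree dihedrals", {
  topo <- tibble::tibble(element = "C", molecule_id = 1L,
                         molecule_class = "small", site_role = "none",
                         parent = NA_integer_)
  topo <- topo[rep(1, 4), ]
  quads <- data.frame(molecule_id = 1L, i = 1L, j = 2L, k = 3L, l = 4L)
  cis <- matrix(c(1, 1, 0, 0, 0, 0, 0, 0, 1.5, 1, 1, 1.5), ncol = 3, byrow = TRUE)
  tr <- cis
  tr[4, ] <- c(-1, -1, 1.5)
  cis_traj <- as_trajectory(list(cis), topology = topo, box = c(50, 50, 50))
  trans_traj <- as_trajectory(list(tr), topology = topo, box = c(50, 50, 50))
  expect_equal(abs(torsion_series(cis_traj, quads)$angle_deg), 0)
  expect_equal(abs(torsion_series(trans_traj, quads)$angle_deg), 180)
})

test_that("dihedrals match the two-plane-normal oracle on random geometries", {
  withr::with_seed(41, {
    for (i in 1:25) {
      pts <- matrix(runif(12, 2, 8), ncol = 3)
      topo <- tibble::tibble(element = "C", molecule_id = 1L,
                             molecule_class = "small", site_role = "none",
                             parent = NA_integer_)[rep(1, 4), ]
      traj <- as_trajectory(list(pts), topology = topo, box = c(50, 50, 50))
      got <- torsion_series(traj, data.frame(molecule_id = 1L, i = 1L, j = 2L,
                                             k = 3L, l = 4L))$angle_deg
      want <- oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
      expect_equal(got, want, tolerance = 1e-6)
    }
  })
})

test_that("collinear quadruples are flagged undefined", {
  pts <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 1, 0), ncol = 3, byrow = TRUE)
  topo <- tibble::tibble(element = "C", molecule_id = 1L,
                         molecule_class = "small", site_role = "none",
                         parent = NA_integer_)[rep(1, 4), ]
  traj <- as_trajectory(list(pts), topology = topo, box = c(50, 50, 50))
  expect_warning(
    ts <- torsion_series(traj, data.frame(molecule_id = 1L, i = 1L, j = 2L,
                                          k = 3L, l = 4L)),
    "collinear"
  )
  expect_true(is.na(ts$angle_deg))
})

test_that("orientational distributions localise and normalise correctly", {
  const <- data.frame(angle_deg = rep(60, 500))
  odf <- orientation_distribution(const, bin_width = 5)
  expect_equal(sum(odf$p), 1)
  expect_equal(odf$angle_deg[odf$p > 0], 60)

  two_state <- gen_torsion_trajectory(torsion_jump_spec(
    jump_rate = 2, states = c(0, 180), n_molecules = 40, n_frames = 200, seed = 3
  ))
  series <- torsion_series(two_state, attr(two_state, "quadruples"))
  odf2 <- orientation_distribution(series, bin_width = 10)
  occupied <- odf2$angle_deg[odf2$p > 0.05]
  expect_setequal(occupied, c(0, -180))  # +180 wraps onto the -180 bin

  unif <- withr::with_seed(5, data.frame(angle_deg = runif(20000, -180, 180)))
  odf3 <- orientation_distribution(unif, bin_width = 20)
  expect_true(all(abs(odf3$p - 1 / 18) < 3 * sqrt((1 / 18) / 20000) + 1e-3))
})

test_that("a static trajectory has unit correlation at every lag", {
  traj <- gen_torsion_trajectory(torsion_jump_spec(
    jump_rate = 1e-9, n_molecules = 12, n_frames = 60, seed = 2
  ))
  acf <- angular_correlation(traj, attr(traj, "vectors"))
  expect_equal(acf$acf, rep(1, nrow(acf)), tolerance = 1e-12)
  expect_equal(acf$acf[1], 1)
})

test_that("the ACF is invariant under a global rotation of every frame", {
  traj <- gen_torsion_trajectory(torsion_jump_spec(
    jump_rate = 1, n_molecules = 20, n_frames = 100, seed = 6
  ))
  acf1 <- angular_correlation(traj, attr(traj, "vectors"), max_lag = 30)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- traj
  rotated$frames <- lapply(traj$frames, function(m) m %*% R)
  acf2 <- angular_correlation(rotated, attr(traj, "vectors"), max_lag = 30)
  expect_equal(acf1$acf, acf2$acf, tolerance = 1e-9)
})

test_that("two-state 180-degree flips decay as exp(-2kt)", {
  k <- 1
  traj <- gen_torsion_trajectory(torsion_jump_spec(
    jump_rate = k, states = c(0, 180), n_molecules = 120, n_frames = 5000,
    frame_interval = 0.05, seed = 11
  ))
  acf <- angular_correlation(traj, attr(traj, "vectors"), max_lag = 60)
  tau <- attr(acf, "tau_ns")
  expect_equal(tau, 1 / (2 * k), tolerance = 0.1)
  # pointwise agreement with the analytic curve over the first decade
  sel <- acf$lag_ns <= 1
  expect_equal(acf$acf[sel], exp(-2 * k * acf$lag_ns[sel]), tolerance = 0.08)
})

test_that("independently re-randomised vectors decorrelate immediately", {
  n <- 200
  topo <- tibble::tibble(element = "C", molecule_id = rep(seq_len(n), each = 2),
                         molecule_class = "small", site_role = "none",
                         parent = NA_integer_)
  frames <- withr::with_seed(8, {
    lapply(1:50, function(f) {
      base <- matrix(rep(runif(n * 3) * 40, each = 2), ncol = 3)
      u <- matrix(rnorm(n * 3), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      base[seq(2, 2 * n, 2), ] <- base[seq(2, 2 * n, 2), ] + u
      base
    })
  })
  traj <- as_trajectory(frames, topology = topo, box = c(40, 40, 40))
  vecs <- data.frame(molecule_id = seq_len(n),
                     from = seq(1, 2 * n, 2), to = seq(2, 2 * n, 2))
  acf <- angular_correlation(traj, vecs, max_lag = 10)
  expect_equal(acf$acf[1], 1)
  expect_true(all(abs(acf$acf[-1]) < 0.05))
})
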