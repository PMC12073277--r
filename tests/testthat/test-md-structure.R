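make_gas_trajectory <- function(n = 300, box = c(25, 25, 25), n_frames = 10,
                                seed = 5) {
  topo <- tibble::tibble(element = "Ar", molecule_id = seq_len(n),
                         molecule_class = "small", site_role = "none",
                         parent = NA_integer_)
  frames <- withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      matrix(runif(n * 3), ncol = 3) %*% diag(box)
    })
  })
  as_trajectory(frames, topology = topo, box = box)
}

test_that("an ideal gas is flat at g(r) = 1 beyond contact range", {
  traj <- make_gas_trajectory(n = 400, n_frames = 20)
  rdf <- pair_distribution(traj, 1:400, 1:400, bin_width = 0.25)
  sel <- rdf$r > 3
  # 3-sigma Poisson band on the pooled counts
  expect_true(all(abs(rdf$g[sel] - 1) <
                    3 / sqrt(pmax(rdf$n_pairs[sel] * 20, 1)) + 0.05))
  expect_lt(abs(mean(rdf$g[sel]) - 1), 0.02)
})

test_that("the RDF integrates to the expected neighbour count", {
  traj <- make_gas_trajectory(n = 400, n_frames = 20)
  rdf <- pair_distribution(traj, 1:400, 1:400, bin_width = 0.25)
  rho <- 400 / prod(traj$box)
  integral <- sum(rho * rdf$g * 4 * pi * rdf$r^2 * 0.25)
  expected <- rho * 4 / 3 * pi * attr(rdf, "r_max")^3
  expect_equal(integral, expected, tolerance = 0.02)
})

test_that("two planted atoms give a single occupied bin at their separation", {
  atoms <- data.frame(element = "O", x = c(1, 1 + 2.725), y = 1, z = 1,
                      molecule_id = 1:2, molecule_class = "small",
                      site_role = "none", parent = NA_integer_)
  cfg <- as_config(atoms, c(20, 20, 20))
  rdf <- pair_distribution(cfg, 1, 2, bin_width = 0.05, r_max = 6)
  expect_equal(rdf$r[rdf$g > 0], 2.725)
})

test_that("the histogram is bin-identical to a brute-force double loop", {
  traj <- make_gas_trajectory(n = 120, n_frames = 3, seed = 17)
  got <- pair_distribution(traj, 1:50, 51:120, bin_width = 0.4, r_max = 10)
  box <- traj$box
  counts <- rep(0, ceiling(10 / 0.4))
  for (f in 1:3) {
    xyz <- traj$frames[[f]]
    for (a in 1:50) {
      for (b in 51:120) {
        d <- min_image_d(xyz[a, ], xyz[b, ], box)
        if (d < 10) {
          i <- min(floor(d / 0.4) + 1, length(counts))
          counts[i] <- counts[i] + 1
        }
      }
    }
  }
  expect_equal(got$n_pairs, counts / 3)
})

test_that("intramolecular pairs are excluded when asked", {
  atoms <- data.frame(element = "C",
                      x = c(1, 2.2, 8), y = 1, z = 1,
                      molecule_id = c(1L, 1L, 2L), molecule_class = "small",
                      site_role = "none", parent = NA_integer_)
  cfg <- as_config(atoms, c(20, 20, 20))
  inter <- pair_distribution(cfg, 1:3, 1:3, bin_width = 0.1, r_max = 9)
  expect_equal(sum(inter$n_pairs), 4 / 1)  # only 1-3 and 2-3, both directions
  all_pairs <- pair_distribution(cfg, 1:3, 1:3, bin_width = 0.1, r_max = 9,
                                 intermolecular_only = FALSE)
  expect_equal(sum(all_pairs$n_pairs), 6)
})

test_that("r_max beyond the minimum-image range is refused by name", {
  traj <- make_gas_trajectory(n = 10, n_frames = 1)
  expect_error(pair_distribution(traj, 1:10, 1:10, r_max = 13),
               "half the smallest box edge", class = "asdkit_invalid")
})
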