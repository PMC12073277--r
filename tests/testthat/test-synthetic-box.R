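test_that("an all-zero plan yields a bond-free box", {
  cfg <- gen_box(box_spec(n_chains = 2, monomers_per_chain = 10,
                          n_small_molecules = 10, n_waters = 10,
                          box_edge = 35, seed = 1))
  expect_equal(nrow(detect_hbonds(cfg)), 0L)
  expect_equal(nrow(cfg$atoms), 2 * 10 + 10 * 6 + 10 * 3)
})

test_that("boxes are bit-identical under one seed and differ across seeds", {
  spec <- function(s) box_spec(n_small_molecules = 8, box_edge = 30,
                               planted_hbond_plan = list("small-small" = c(0.5, 0.5)),
                               seed = s)
  a <- gen_box(spec(4))
  b <- gen_box(spec(4))
  c <- gen_box(spec(5))
  expect_identical(a$atoms, b$atoms)
  expect_false(identical(a$atoms$x, c$atoms$x))
})

test_that("all non-bonded inter-site distances respect min_separation", {
  spec <- box_spec(n_chains = 2, monomers_per_chain = 15,
                   n_small_molecules = 12, n_waters = 10, box_edge = 32,
                   planted_hbond_plan = list(
                     "small-small" = c(0.25, 0.5, 0.25),
                     "water-small" = c(0.5, 0.5)
                   ),
                   min_separation = 2.0, seed = 6)
  cfg <- gen_box(spec)
  xyz <- as.matrix(cfg$atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- matrix(Inf, n, n)
  for (k in 1:3) {
    dk <- outer(xyz[, k], xyz[, k], "-")
    dk <- dk - cfg$box[k] * round(dk / cfg$box[k])
    d <- ifelse(is.infinite(d), dk^2, d + dk^2)
  }
  d <- sqrt(d)
  diag(d) <- Inf
  # pairs within one molecule may be closer, and so may the atoms of the two
  # sites forming a hydrogen bond (donor O-H group and the acceptor group
  # with its own hydrogens)
  same_mol <- outer(cfg$atoms$molecule_id, cfg$atoms$molecule_id, "==")
  bonds <- detect_hbonds(cfg)
  bonded <- matrix(FALSE, n, n)
  parent <- cfg$atoms$parent
  for (i in seq_len(nrow(bonds))) {
    acceptor_site <- c(bonds$acceptor[i],
                       which(!is.na(parent) & parent == bonds$acceptor[i]))
    pair_atoms <- c(bonds$donor_heavy[i], bonds$donor_h[i], acceptor_site)
    bonded[pair_atoms, pair_atoms] <- TRUE
  }
  free <- !same_mol & !bonded
  expect_gte(min(d[free]), 2.0)
})

test_that("a small-molecule network plan round-trips through the census", {
  plan <- c(0.2, 0.4, 0.3, 0.1)
  spec <- box_spec(n_small_molecules = 20, box_edge = 34,
                   planted_hbond_plan = list("small-small" = plan), seed = 9)
  cfg <- gen_box(spec)
  census <- hb_count_distribution(cfg, "small", "small", "either")
  realized <- attr(cfg, "realized_counts")[["small-small"]]
  want <- 100 * as.numeric(table(factor(pmin(realized, 4), levels = 0:4))) / 20
  expect_equal(census$percent, want)
  # realized counts honour the requested plan up to integer rounding
  cnt <- achievable_counts(plan, 20, pairwise = TRUE)
  expect_identical(sort(as.integer(realized)),
                   sort(rep(as.integer(names(cnt)), cnt)))
})

test_that("multi-class plans round-trip across all four bond classes", {
  spec <- box_spec(n_chains = 3, monomers_per_chain = 30,
                   n_small_molecules = 16, n_waters = 20, box_edge = 36,
                   planted_hbond_plan = list(
                     "small-small" = c(0.25, 0.5, 0.25),
                     "small-chain" = c(0.5, 0.5),
                     "water-chain" = c(0.5, 0.3, 0.2),
                     "water-small" = c(0.6, 0.4)
                   ), seed = 14)
  cfg <- gen_box(spec)
  checks <- list(
    list("small", "small", "either", "small-small", 16),
    list("small", "chain", "as-donor", "small-chain", 16),
    list("water", "chain", "as-donor", "water-chain", 20),
    list("water", "small", "as-donor", "water-small", 20)
  )
  for (ck in checks) {
    census <- hb_count_distribution(cfg, ck[[1]], ck[[2]], ck[[3]])
    realized <- attr(cfg, "realized_counts")[[ck[[4]]]]
    want <- 100 * as.numeric(table(factor(pmin(realized, 4), levels = 0:4))) / ck[[5]]
    expect_equal(census$percent, want, info = ck[[4]])
  }
})

test_that("infeasible plans are rejected up front", {
  expect_error(
    gen_box(box_spec(n_small_molecules = 4, box_edge = 25,
                     planted_hbond_plan = list("small-small" = c(0, 0, 0, 0, 1)))),
    "3 sites", class = "asdkit_invalid"
  )
  expect_error(
    gen_box(box_spec(n_small_molecules = 4, n_waters = 4, box_edge = 25,
                     planted_hbond_plan = list("water-small" = c(0, 0, 0, 1)))),
    class = "asdkit_invalid"
  )
  expect_error(
    gen_box(box_spec(n_chains = 1, monomers_per_chain = 2,
                     n_small_molecules = 6, box_edge = 25,
                     planted_hbond_plan = list("small-chain" = c(0, 0.5, 0.5)))),
    "chain acceptor sites", class = "asdkit_invalid"
  )
  expect_error(box_spec(n_small_molecules = 1000, box_edge = 10),
               "too small", class = "asdkit_invalid")
})
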