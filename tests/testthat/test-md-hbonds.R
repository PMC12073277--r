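# a minimal two-molecule configuration with one O-H...O triple at given
# donor-acceptor distance and angle (degrees) at the donor
planted_pair_config <- function(d, angle_deg, box = c(20, 20, 20)) {
  th <- angle_deg * pi / 180
  atoms <- data.frame(
    element = c("O", "H", "O"),
    x = c(5, 5 + 0.96 * cos(th), 5 + d),
    y = c(5, 5 + 0.96 * sin(th), 5),
    z = 5,
    molecule_id = c(1L, 1L, 2L),
    molecule_class = "small",
    site_role = c("donor-heavy+acceptor", "donor-H", "acceptor"),
    parent = c(NA_integer_, 1L, NA_integer_)
  )
  as_config(atoms, box)
}

test_that("the geometric criteria admit and reject bonds at their boundaries", {
  expect_equal(nrow(detect_hbonds(planted_pair_config(2.8, 10))), 1L)
  expect_equal(nrow(detect_hbonds(planted_pair_config(3.6, 10))), 0L)
  expect_equal(nrow(detect_hbonds(planted_pair_config(2.8, 35))), 0L)
  b <- detect_hbonds(planted_pair_config(2.8, 10))
  expect_equal(b$distance_A, 2.8, tolerance = 1e-9)
  expect_equal(b$angle_deg, 10, tolerance = 1e-9)
})

test_that("bonds across the periodic boundary are found", {
  atoms <- data.frame(
    element = c("O", "H", "O"),
    x = c(0.5, 0.5 - 0.96, 19.9),  # donor H points through the boundary
    y = 5, z = 5,
    molecule_id = c(1L, 1L, 2L), molecule_class = "small",
    site_role = c("donor-heavy+acceptor", "donor-H", "acceptor"),
    parent = c(NA_integer_, 1L, NA_integer_)
  )
  cfg <- as_config(atoms, c(20, 20, 20))
  b <- detect_hbonds(cfg)
  expect_equal(nrow(b), 1L)
  expect_equal(b$distance_A, 0.6, tolerance = 1e-9)
})

test_that("detection is set-identical to the triple-loop oracle on random boxes", {
  for (seed in 1:4) {
    cfg <- random_oh_config(n_mol = 50, seed = seed)
    got <- detect_hbonds(cfg)
    want <- oracle_hbonds(cfg)
    key_got <- sort(paste(got$donor_heavy, got$donor_h, got$acceptor))
    key_want <- sort(paste(want[, 1], want[, 2], want[, 3]))
    expect_identical(key_got, key_want)
  }
})

test_that("missing donor-heavy annotations raise an informative error", {
  atoms <- data.frame(
    element = c("H", "O"), x = c(1, 3), y = 1, z = 1,
    molecule_id = c(1L, 2L), molecule_class = "small",
    site_role = c("donor-H", "acceptor"), parent = NA_integer_
  )
  expect_error(as_config(atoms, c(10, 10, 10)), class = "asdkit_invalid")
})

test_that("census percentages include the 4+ bin and sum to 100", {
  cfg <- random_oh_config(n_mol = 60, box = c(16, 16, 16), seed = 9)
  census <- hb_count_distribution(cfg, "small", "small", "either")
  expect_identical(census$n_hb, c("0", "1", "2", "3", "4+"))
  expect_equal(sum(census$percent), 100, tolerance = 1e-9)
})

test_that("census directionality matches a per-molecule oracle count", {
  cfg <- random_oh_config(n_mol = 40, box = c(15, 15, 15), seed = 13)
  bonds <- detect_hbonds(cfg)
  for (dir in c("as-donor", "as-acceptor", "either")) {
    census <- hb_count_distribution(cfg, "small", "small", dir)
    counts <- rep(0L, 40)
    if (dir %in% c("as-donor", "either")) {
      t <- table(factor(bonds$donor_molecule, levels = 1:40))
      counts <- counts + as.integer(t)
    }
    if (dir %in% c("as-acceptor", "either")) {
      t <- table(factor(bonds$acceptor_molecule, levels = 1:40))
      counts <- counts + as.integer(t)
    }
    expected <- 100 * as.numeric(table(cut(counts, c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf)))) / 40
    expect_equal(census$percent, expected)
  }
})

test_that("clusters match a union-find oracle and classify oligomers", {
  # explicit A-B-C chain: one trimer
  th <- 0
  atoms <- NULL
  for (m in 1:3) {
    x0 <- 3 * (m - 1) + 1
    atoms <- rbind(atoms, data.frame(
      element = c("O", "H"), x = c(x0, x0 + 0.96), y = 1, z = 1,
      molecule_id = m, molecule_class = "small",
      site_role = c("donor-heavy+acceptor", "donor-H"),
      parent = c(NA_integer_, 2L * m - 1L)
    ))
  }
  cfg <- as_config(atoms, c(30, 30, 30))
  expect_equal(nrow(detect_hbonds(cfg)), 2L)
  cl <- hb_clusters(cfg, "small", "small")
  expect_equal(cl$percent_molecules[cl$cluster_size == "3"], 100)

  for (seed in 21:23) {
    cfgr <- random_oh_config(n_mol = 40, box = c(15, 15, 15), seed = seed)
    cl <- hb_clusters(cfgr, "small", "small")
    bonds <- detect_hbonds(cfgr)
    sizes <- oracle_components(40, cbind(bonds$donor_molecule, bonds$acceptor_molecule))
    want <- 100 * as.numeric(table(cut(rep(sizes, sizes),
                                       c(0.5, 1.5, 2.5, 3.5, Inf)))) / 40
    expect_equal(cl$percent_molecules, want)
  }
})

test_that("unbonded percentage counts molecules with no bonds of any kind", {
  cfg0 <- gen_box(box_spec(n_small_molecules = 8, box_edge = 30,
                           planted_hbond_plan = list("small-small" = 1), seed = 2))
  expect_equal(unbonded_molecules(cfg0), 100)
  cfg1 <- gen_box(box_spec(n_small_molecules = 8, box_edge = 30,
                           planted_hbond_plan = list("small-small" = c(0, 1)),
                           seed = 2))
  expect_equal(unbonded_molecules(cfg1), 0)
  cfg_half <- gen_box(box_spec(n_small_molecules = 8, box_edge = 30,
                               planted_hbond_plan = list("small-small" = c(0.5, 0.5)),
                               seed = 2))
  expect_equal(unbonded_molecules(cfg_half), 50)
})
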