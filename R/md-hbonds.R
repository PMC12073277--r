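# Geometric hydrogen-bond detection and network statistics.

#' Detect hydrogen bonds in a configuration
#'
#' A hydrogen bond is a (donor-heavy, donor-H, acceptor) triple with
#' minimum-image donor-acceptor distance below `d_max` and
#' acceptor-donor-hydrogen angle below `angle_max`. The angle is measured at
#' the donor heavy atom, between the donor-to-hydrogen and donor-to-acceptor
#' vectors, so small angles mean a near-linear D-H...A arrangement:
#'
#' ```
#'        H
#'       /          angle = acute angle at D between D->H and D->A
#'      D ----- A
#' ```
#'
#' @param config An [as_config()] configuration with site roles assigned.
#' @param d_max Donor-acceptor distance cutoff in angstroms (default 3.5).
#' @param angle_max Angle cutoff in degrees (default 30).
#' @param intramolecular Also report bonds within one molecule (default
#'   `FALSE`: only intermolecular bonds, the quantity used for network
#'   censuses).
#' @return A tibble with one row per bond: `donor_heavy`, `donor_h`,
#'   `acceptor` (atom row indices), `donor_molecule`, `acceptor_molecule`,
#'   `donor_class`, `acceptor_class`, `distance_A`, `angle_deg`.
#' @export
detect_hbonds <- function(config, d_max = 3.5, angle_max = 30,
                          intramolecular = FALSE) {
  stopifnot(inherits(config, "asd_config"))
  atoms <- config$atoms
  box <- config$box
  h_idx <- which(role_has(atoms$site_role, "donor-H"))
  a_idx <- which(role_has(atoms$site_role, "acceptor"))
  empty <- tibble(
    donor_heavy = integer(), donor_h = integer(), acceptor = integer(),
    donor_molecule = integer(), acceptor_molecule = integer(),
    donor_class = character(), acceptor_class = character(),
    distance_A = numeric(), angle_deg = numeric()
  )
  if (!length(h_idx) || !length(a_idx)) return(empty)
  if (anyNA(atoms$parent[h_idx])) {
    stop_invalid(sprintf(
      "donor-H atoms without a bonded donor-heavy atom: %s",
      paste(head(h_idx[is.na(atoms$parent[h_idx])], 10), collapse = ", ")
    ))
  }
  d_idx <- atoms$parent[h_idx]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dist_da <- min_image_cross_dist(xyz[d_idx, , drop = FALSE],
                                  xyz[a_idx, , drop = FALSE], box)
  cand <- which(dist_da < d_max, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  di <- d_idx[cand[, 1]]
  hi <- h_idx[cand[, 1]]
  ai <- a_idx[cand[, 2]]
  keep <- ai != di & ai != hi
  if (!intramolecular) {
    keep <- keep & atoms$molecule_id[ai] != atoms$molecule_id[di]
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  di <- di[keep]; hi <- hi[keep]; ai <- ai[keep]
  v_dh <- min_image_vec(xyz[di, , drop = FALSE], xyz[hi, , drop = FALSE], box)
  v_da <- min_image_vec(xyz[di, , drop = FALSE], xyz[ai, , drop = FALSE], box)
  cosang <- rowSums(v_dh * v_da) /
    (sqrt(rowSums(v_dh^2)) * sqrt(rowSums(v_da^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ok <- ang < angle_max
  tibble(
    donor_heavy = di[ok], donor_h = hi[ok], acceptor = ai[ok],
    donor_molecule = atoms$molecule_id[di[ok]],
    acceptor_molecule = atoms$molecule_id[ai[ok]],
    donor_class = atoms$molecule_class[di[ok]],
    acceptor_class = atoms$molecule_class[ai[ok]],
    distance_A = dist_da[cand][ok],
    angle_deg = ang[ok]
  )
}

# Per-molecule bond counts of one class/direction for a single frame's bonds.
hb_counts_frame <- function(bonds, focal_ids, donor_class, acceptor_class,
                            directionality) {
  cls <- bonds$donor_class == donor_class & bonds$acceptor_class == acceptor_class
  b <- bonds[cls, , drop = FALSE]
  counts <- setNames(rep(0L, length(focal_ids)), focal_ids)
  add <- function(mols) {
    t <- table(factor(mols, levels = focal_ids))
    counts <<- counts + as.integer(t)
  }
  if (directionality %in% c("as-donor", "either")) add(b$donor_molecule)
  if (directionality %in% c("as-acceptor", "either")) add(b$acceptor_molecule)
  counts
}

#' Hydrogen-bond count census
#'
#' Time-averaged percentage of focal-class molecules having 0, 1, 2, 3 or 4+
#' hydrogen bonds of a given class (donor class -> acceptor class) and
#' direction. This is the layout of published per-molecule H-bond tables;
#' the `"4+"` bin is always reported so each column sums to 100.
#'
#' @param traj An `asd_trajectory` or a single `asd_config`.
#' @param donor_class,acceptor_class Molecule classes (`"chain"`, `"small"`,
#'   `"water"`) of the bond's donor and acceptor side.
#' @param directionality How the focal molecule participates: `"as-donor"`,
#'   `"as-acceptor"`, or `"either"` (the union of the two bond sets; a bond
#'   between two focal molecules then counts once for each end).
#' @param focal_class Class whose molecules are censused. Defaults to the
#'   donor class for `"as-donor"`/`"either"` and the acceptor class for
#'   `"as-acceptor"`.
#' @param d_max,angle_max Geometric criteria passed to [detect_hbonds()].
#' @return A tibble with columns `n_hb` (`"0"`, `"1"`, `"2"`, `"3"`, `"4+"`)
#'   and `percent` (mean over frames of per-frame percentages, equally
#'   weighted). Per-frame per-molecule counts are in the `per_frame`
#'   attribute.
#' @export
hb_count_distribution <- function(traj, donor_class, acceptor_class,
                                  directionality = c("either", "as-donor", "as-acceptor"),
                                  focal_class = NULL,
                                  d_max = 3.5, angle_max = 30) {
  directionality <- match.arg(directionality)
  if (inherits(traj, "asd_config")) traj <- as_trajectory(traj)
  stopifnot(inherits(traj, "asd_trajectory"))
  focal_class <- focal_class %||%
    if (directionality == "as-acceptor") acceptor_class else donor_class
  topo <- traj$topology
  for (cl in unique(c(donor_class, acceptor_class, focal_class))) {
    if (!cl %in% topo$molecule_class) {
      stop_invalid(sprintf("no molecules of class '%s' in the topology", cl))
    }
  }
  focal_ids <- sort(unique(topo$molecule_id[topo$molecule_class == focal_class]))
  per_frame <- purrr::imap(traj$frames, function(xyz, i) {
    bonds <- detect_hbonds(get_frame(traj, i), d_max, angle_max)
    hb_counts_frame(bonds, focal_ids, donor_class, acceptor_class, directionality)
  })
  bins <- c("0", "1", "2", "3", "4+")
  pct <- vapply(per_frame, function(counts) {
    binned <- cut(counts, breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf), labels = bins)
    100 * as.numeric(table(binned)) / length(counts)
  }, numeric(5))
  out <- tibble(n_hb = bins, percent = rowMeans(matrix(pct, nrow = 5)))
  attr(out, "per_frame") <- per_frame
  attr(out, "focal_class") <- focal_class
  out
}

#' Hydrogen-bond cluster (oligomer) analysis
#'
#' Builds the molecule-level graph whose edges are hydrogen bonds of one
#' class and reports the percentage of involved-class molecules sitting in
#' connected components of size 1 (monomer), 2 (dimer), 3 (trimer) and 4+.
#'
#' @inheritParams hb_count_distribution
#' @param config An `asd_config`.
#' @return A tibble with `cluster_size` (`"1"`, `"2"`, `"3"`, `"4+"`) and
#'   `percent_molecules`; component membership in the `membership` attribute.
#' @export
hb_clusters <- function(config, donor_class, acceptor_class,
                        d_max = 3.5, angle_max = 30) {
  stopifnot(inherits(config, "asd_config"))
  topo <- config$atoms
  classes <- unique(c(donor_class, acceptor_class))
  mol_ids <- sort(unique(topo$molecule_id[topo$molecule_class %in% classes]))
  if (!length(mol_ids)) stop_invalid("no molecules of the requested classes")
  bonds <- detect_hbonds(config, d_max, angle_max)
  bonds <- bonds[bonds$donor_class == donor_class &
                   bonds$acceptor_class == acceptor_class, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(mol_ids), directed = FALSE)
  if (nrow(bonds)) {
    e <- rbind(match(bonds$donor_molecule, mol_ids),
               match(bonds$acceptor_molecule, mol_ids))
    g <- igraph::add_edges(g, as.vector(e))
    g <- igraph::simplify(g)
  }
  comp <- igraph::components(g)
  size_of <- comp$csize[comp$membership]
  bins <- c("1", "2", "3", "4+")
  binned <- cut(size_of, breaks = c(0.5, 1.5, 2.5, 3.5, Inf), labels = bins)
  out <- tibble(
    cluster_size = bins,
    percent_molecules = 100 * as.numeric(table(binned)) / length(mol_ids)
  )
  attr(out, "membership") <- tibble(molecule_id = mol_ids,
                                    component = comp$membership,
                                    component_size = size_of)
  out
}

#' Percentage of molecules with no hydrogen bonds at all
#'
#' Fraction of focal-class molecules forming zero hydrogen bonds of any
#' class, in any direction, with any partner — the "fully unbonded" figure
#' whose vanishing indicates a fully developed hydrogen-bond network.
#'
#' @inheritParams hb_count_distribution
#' @param focal_class Molecule class censused (default `"small"`).
#' @return A single percentage (mean over frames).
#' @export
unbonded_molecules <- function(traj, focal_class = "small",
                               d_max = 3.5, angle_max = 30) {
  if (inherits(traj, "asd_config")) traj <- as_trajectory(traj)
  stopifnot(inherits(traj, "asd_trajectory"))
  topo <- traj$topology
  focal_ids <- unique(topo$molecule_id[topo$molecule_class == focal_class])
  if (!length(focal_ids)) stop_invalid(sprintf("no '%s' molecules", focal_class))
  pct <- purrr::imap_dbl(traj$frames, function(xyz, i) {
    bonds <- detect_hbonds(get_frame(traj, i), d_max, angle_max)
    bonded <- unique(c(bonds$donor_molecule, bonds$acceptor_molecule))
    100 * sum(!focal_ids %in% bonded) / length(focal_ids)
  })
  mean(pct)
}
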