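# Synthetic amorphous boxes with planted hydrogen-bond networks.
#
# The generator builds a periodic configuration of schematic molecules --
# polymer chains carrying one carbonyl-like acceptor site per monomer, small
# molecules carrying three hydroxyl-like donor/acceptor sites, and waters
# (two donor hydrogens, one acceptor oxygen) -- such that the per-molecule
# hydrogen-bond count distribution measured by detect_hbonds() with the
# standard 3.5 A / 30 degree criteria reproduces a requested plan EXACTLY.
# Chemistry is schematic: site counts, roles and bond geometry are correct;
# polymer conformations and packing realism are not attempted.
#
# Construction: requested per-molecule percentages are converted to integer
# count assignments (largest-remainder rounding, parity-fixed); within-class
# bonds are realised as a forest (tree embedding is always geometrically
# consistent); bonded molecules are embedded by breadth-first placement with
# exact donor-H -> acceptor geometry (D-A 2.8 A, angle 0); every placement is
# rejected unless it creates exactly the planted bonds and no others, and
# keeps all non-bonded inter-site distances above min_separation (plus a
# stricter 3.55 A oxygen-oxygen clearance that makes accidental bonds
# impossible). Chain acceptor sites involved in bonds materialise at the
# reserved positions; remaining chain sites are placed freely. The finished
# box is re-measured with detect_hbonds and regenerated from a derived seed
# if any discrepancy remains.

.OH_BOND <- 0.96    # donor O-H bond length, A
.HB_DA <- 2.8       # planted donor-acceptor distance, A
.OO_CLEAR <- 3.55   # minimum non-bonded O-O distance, A (> 3.5 cutoff)

#' Specification of a synthetic amorphous box
#'
#' @param n_chains Number of polymer chains.
#' @param monomers_per_chain Acceptor sites per chain (one carbonyl-like
#'   oxygen per monomer).
#' @param n_small_molecules Number of small (drug-like) molecules, each with
#'   three hydroxyl-like sites that can donate and accept.
#' @param n_waters Number of water molecules (two donor H, one acceptor O).
#' @param box_edge Orthorhombic box edge length(s) in angstroms.
#' @param planted_hbond_plan Named list of per-molecule bond-count
#'   distributions, with names among `"small-small"`, `"small-chain"`,
#'   `"water-chain"`, `"water-small"`. Each entry is a probability vector
#'   over counts 0, 1, 2, ... for the focal molecule (the small molecule for
#'   the first two classes, the water for the last two; waters donate, so
#'   their counts may not exceed 2, and a small molecule's total over all
#'   classes may not exceed its three sites).
#' @param min_separation Minimum allowed distance between non-bonded sites of
#'   different molecules, in angstroms. Atoms of the two groups forming a
#'   planted hydrogen bond (the donor O-H and the acceptor oxygen with its
#'   own hydrogens) are necessarily closer; every other inter-molecular pair
#'   respects this floor, and non-bonded oxygen pairs additionally respect a
#'   3.55 A clearance that rules out accidental bonds.
#' @param seed Integer RNG seed.
#' @return A validated `box_spec`.
#' @export
box_spec <- function(n_chains = 0, monomers_per_chain = 0,
                     n_small_molecules = 0, n_waters = 0,
                     box_edge = 50, planted_hbond_plan = list(),
                     min_separation = 2.0, seed = 1L) {
  for (nm in c("n_chains", "monomers_per_chain", "n_small_molecules", "n_waters")) {
    check_number(get(nm), nm, lower = 0)
  }
  box_edge <- rep(as.numeric(box_edge), length.out = 3)
  check_positive_vector(box_edge, "box_edge")
  check_number(min_separation, "min_separation", lower = 0.5)
  known <- c("small-small", "small-chain", "water-chain", "water-small")
  if (length(planted_hbond_plan)) {
    if (is.null(names(planted_hbond_plan)) ||
        !all(names(planted_hbond_plan) %in% known)) {
      stop_invalid(paste0("plan names must be among: ", paste(known, collapse = ", ")))
    }
    for (nm in names(planted_hbond_plan)) {
      p <- planted_hbond_plan[[nm]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
        stop_invalid(sprintf("plan '%s' must be a probability vector", nm))
      }
    }
  }
  n_atoms <- n_chains * monomers_per_chain + 6 * n_small_molecules + 3 * n_waters
  if (n_atoms < 1) stop_invalid("the box contains no atoms")
  if (n_atoms * (4 / 3) * pi * (min_separation / 2)^3 > 0.25 * prod(box_edge)) {
    stop_invalid("box too small to place all atoms at min_separation")
  }
  structure(
    list(n_chains = as.integer(n_chains),
         monomers_per_chain = as.integer(monomers_per_chain),
         n_small_molecules = as.integer(n_small_molecules),
         n_waters = as.integer(n_waters),
         box_edge = box_edge, planted_hbond_plan = planted_hbond_plan,
         min_separation = min_separation, seed = as.integer(seed)),
    class = "box_spec"
  )
}

#' Convert plan percentages to achievable integer counts
#'
#' Largest-remainder rounding of `p * n` to integers summing to `n`; for
#' within-class plans (`pairwise = TRUE`) the total number of bond ends is
#' additionally made even by moving one molecule from the lowest occupied
#' odd-count bin down one bin.
#'
#' @param p Probability vector over counts 0, 1, 2, ...
#' @param n Number of focal molecules.
#' @param pairwise Whether bond ends must pair up within the class.
#' @return Integer vector of molecule counts per bin (names = bond counts).
#' @export
achievable_counts <- function(p, n, pairwise = FALSE) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) stop_invalid("`p` must be a probability vector")
  check_number(n, "n", lower = 1)
  raw <- p * n
  cnt <- floor(raw)
  short <- round(n - sum(cnt))
  if (short > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(short)]] <- cnt[ord[seq_len(short)]] + 1
  }
  k <- seq_along(cnt) - 1
  if (pairwise && sum(cnt * k) %% 2 == 1) {
    odd <- which(k %% 2 == 1 & cnt > 0 & k > 0)
    if (!length(odd)) stop_invalid("cannot fix bond-end parity for this plan")
    cnt[odd[1]] <- cnt[odd[1]] - 1
    cnt[odd[1] - 1] <- cnt[odd[1] - 1] + 1
  }
  setNames(as.integer(cnt), k)
}

# expand bin counts into a per-molecule count vector (molecule 1..n)
counts_to_assignment <- function(cnt) {
  rep(as.integer(names(cnt)), cnt)
}

#' Generate a periodic configuration with a planted hydrogen-bond network
#'
#' @param spec A [box_spec()].
#' @param max_attempts Number of full regeneration attempts before failing.
#' @return An `asd_config`. Attributes: `planted` (tibble of planted bonds:
#'   class, donor/acceptor molecule ids), `realized_counts` (named list of
#'   per-molecule bond-count vectors per plan class, the ground truth that
#'   [hb_count_distribution()] must reproduce).
#' @export
gen_box <- function(spec, max_attempts = 25) {
  stopifnot(inherits(spec, "box_spec"))
  plan_counts <- plan_assignments(spec)
  for (attempt in seq_len(max_attempts)) {
    seed <- derive_seed(spec$seed, paste0("gen_box_attempt_", attempt))
    result <- with_seed_(seed, tryCatch(
      plant_box(spec, plan_counts),
      asdkit_retry = function(e) NULL
    ))
    if (is.null(result)) next
    if (verify_planted(result, plan_counts)) return(result)
  }
  stop_invalid(sprintf("gen_box failed to realise the plan in %d attempts", max_attempts),
               class = "asdkit_generation_failure")
}

retry_placement <- function(msg) {
  abort(msg, class = c("asdkit_retry", "asdkit_error"))
}

# Convert the plan into per-molecule target counts and check feasibility.
plan_assignments <- function(spec) {
  plan <- spec$planted_hbond_plan
  out <- list()
  if ("small-small" %in% names(plan)) {
    cnt <- achievable_counts(plan[["small-small"]], spec$n_small_molecules, pairwise = TRUE)
    out[["small-small"]] <- counts_to_assignment(cnt)
  } else if (spec$n_small_molecules > 0) {
    out[["small-small"]] <- rep(0L, spec$n_small_molecules)
  }
  if ("small-chain" %in% names(plan)) {
    cnt <- achievable_counts(plan[["small-chain"]], spec$n_small_molecules)
    out[["small-chain"]] <- counts_to_assignment(cnt)
  } else if (spec$n_small_molecules > 0) {
    out[["small-chain"]] <- rep(0L, spec$n_small_molecules)
  }
  if ("water-chain" %in% names(plan)) {
    cnt <- achievable_counts(plan[["water-chain"]], spec$n_waters)
    out[["water-chain"]] <- counts_to_assignment(cnt)
  } else if (spec$n_waters > 0) {
    out[["water-chain"]] <- rep(0L, spec$n_waters)
  }
  if ("water-small" %in% names(plan)) {
    cnt <- achievable_counts(plan[["water-small"]], spec$n_waters)
    out[["water-small"]] <- counts_to_assignment(cnt)
  } else if (spec$n_waters > 0) {
    out[["water-small"]] <- rep(0L, spec$n_waters)
  }

  n_small <- spec$n_small_molecules
  if (n_small > 0) {
    # smalls sorted so the heaviest small-small degrees meet the lightest
    # small-chain loads: assign small-chain counts in reverse order
    ss <- sort(out[["small-small"]], decreasing = TRUE)
    sc <- sort(out[["small-chain"]])
    if (any(ss + sc > 3L)) {
      stop_invalid("infeasible plan: a small molecule would need more than its 3 sites")
    }
    out[["small-small"]] <- ss
    out[["small-chain"]] <- sc
  }
  if (spec$n_waters > 0) {
    # pair heavy chain loads with light small loads across the water pool
    out[["water-small"]] <- sort(out[["water-small"]], decreasing = TRUE)
    out[["water-chain"]] <- sort(out[["water-chain"]])
    if (any(out[["water-chain"]] + out[["water-small"]] > 2L)) {
      stop_invalid("infeasible plan: a water molecule has only 2 donor hydrogens")
    }
    if (any(out[["water-small"]] > 2L)) {
      stop_invalid("infeasible plan: waters donate at most 2 bonds")
    }
  }
  chain_cap <- spec$n_chains * spec$monomers_per_chain
  chain_load <- sum(out[["small-chain"]] %||% 0L) + sum(out[["water-chain"]] %||% 0L)
  if (chain_load > chain_cap) {
    stop_invalid("infeasible plan: more chain-bound bonds than chain acceptor sites")
  }
  ws_load <- sum(out[["water-small"]] %||% 0L)
  if (n_small > 0 && ws_load > sum(3L - out[["small-small"]] - out[["small-chain"]])) {
    stop_invalid("infeasible plan: not enough free small-molecule acceptor sites for waters")
  }
  out
}

# Realise the small-small degree sequence as a forest (edge list of molecule
# indices). Trees embed exactly; edges between components never close cycles.
forest_edges <- function(degrees) {
  n <- length(degrees)
  rem <- as.integer(degrees)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i] <- comp[comp[i]]; i }
  edges <- matrix(integer(0), ncol = 2)
  ord <- order(rem, decreasing = TRUE)
  placed <- logical(n)
  for (i in ord) {
    if (rem[i] == 0L) next
    if (!placed[i]) {
      cand <- which(placed & rem > 0)
      if (length(cand)) {
        j <- cand[which.max(rem[cand])]
        edges <- rbind(edges, c(j, i))
        rem[i] <- rem[i] - 1L
        rem[j] <- rem[j] - 1L
        comp[find(i)] <- find(j)
      }
      placed[i] <- TRUE
    }
  }
  # join leftover stubs across components
  guard <- 0L
  while (sum(rem) > 0) {
    guard <- guard + 1L
    if (guard > 10L * n) stop_invalid("degree sequence not realisable as a forest")
    open <- which(rem > 0)
    roots <- vapply(open, find, integer(1))
    if (length(unique(roots)) < 2L) {
      stop_invalid("degree sequence not realisable as a forest (single component left)")
    }
    i <- open[which.max(rem[open])]
    other <- open[roots != find(i)]
    j <- other[which.max(rem[other])]
    edges <- rbind(edges, c(i, j))
    rem[i] <- rem[i] - 1L
    rem[j] <- rem[j] - 1L
    comp[find(i)] <- find(j)
  }
  edges
}
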