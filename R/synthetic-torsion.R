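# Synthetic two-state torsional jump trajectories: controlled dynamics with
# a known analytic correlation function for testing the orientational
# analyses. Each molecule is a four-atom dihedral jig whose terminal atom
# hops between two torsional states as a Poisson process.

#' Specification of a two-state torsional jump trajectory
#'
#' Each molecule carries a tagged bond whose torsional angle flips between
#' `states[1]` and `states[2]` with exponential waiting times (a Poisson
#' process at `jump_rate`). For 180-degree flips the bond-vector correlation
#' function is exactly \eqn{ACF(t) = e^{-2kt}}, the analytic benchmark used
#' to validate [angular_correlation()].
#'
#' @param jump_rate Jump rate k in 1/ns (> 0).
#' @param states Length-2 vector of torsional states in degrees.
#' @param n_molecules Number of independent molecules.
#' @param n_frames Number of saved frames (>= 2).
#' @param frame_interval Time between frames in ns.
#' @param seed Integer RNG seed.
#' @return A validated `torsion_jump_spec`.
#' @export
torsion_jump_spec <- function(jump_rate = 1, states = c(0, 180),
                              n_molecules = 50, n_frames = 200,
                              frame_interval = 0.1, seed = 1L) {
  check_number(jump_rate, "jump_rate", lower = 0, strict_lower = TRUE)
  if (length(states) != 2L || !is.numeric(states)) {
    stop_invalid("`states` must be two angles in degrees")
  }
  check_number(n_molecules, "n_molecules", lower = 1)
  check_number(n_frames, "n_frames", lower = 2)
  check_number(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  structure(
    list(jump_rate = jump_rate, states = as.numeric(states),
         n_molecules = as.integer(n_molecules), n_frames = as.integer(n_frames),
         frame_interval = frame_interval, seed = as.integer(seed)),
    class = "torsion_jump_spec"
  )
}

#' Generate a two-state torsional jump trajectory
#'
#' Molecules are four-atom jigs A-B-C-D on a cubic grid; atoms A, B, C are
#' static and D sits at the dihedral angle of the molecule's current state,
#' so the A-B-C-D torsion equals the state angle exactly and the C-D bond
#' vector is the tagged reorienting vector. Jumps are counted per frame
#' interval from Poisson draws, preserving the exact waiting-time statistics
#' of the two-state model at the frame resolution.
#'
#' @param spec A [torsion_jump_spec()].
#' @return An `asd_trajectory` with attributes `quadruples` (for
#'   [torsion_series()]), `vectors` (the C-D bonds, for
#'   [angular_correlation()]) and `states` (the ground-truth state index
#'   matrix, frames x molecules).
#' @export
gen_torsion_trajectory <- function(spec) {
  stopifnot(inherits(spec, "torsion_jump_spec"))
  n_mol <- spec$n_molecules
  n_frames <- spec$n_frames
  grid_n <- ceiling(n_mol^(1 / 3))
  spacing <- 10
  box <- rep(max(grid_n * spacing, 20), 3)
  gidx <- seq_len(n_mol) - 1L
  origin <- cbind((gidx %% grid_n),
                  ((gidx %/% grid_n) %% grid_n),
                  (gidx %/% (grid_n^2))) * spacing + spacing / 2

  # static part of each jig: A = B + x, B, C = B + 1.5 z
  a_loc <- c(1.5, 0, 0); b_loc <- c(0, 0, 0); c_loc <- c(0, 0, 1.5)
  d_loc <- function(theta_deg) {
    th <- theta_deg * pi / 180
    c_loc + 1.5 * c(cos(th), sin(th), 0)
  }
  d_states <- rbind(d_loc(spec$states[1]), d_loc(spec$states[2]))

  sim <- with_seed_(spec$seed, {
    state <- sample(1:2, n_mol, replace = TRUE)
    states <- matrix(NA_integer_, n_frames, n_mol)
    states[1, ] <- state
    if (n_frames > 1) {
      lam <- spec$jump_rate * spec$frame_interval
      for (f in 2:n_frames) {
        flips <- rpois(n_mol, lam)
        state <- ifelse(flips %% 2 == 1, 3L - state, state)
        states[f, ] <- state
      }
    }
    states
  })

  topo <- tibble(
    element = rep(c("C", "C", "C", "C"), n_mol),
    molecule_id = rep(seq_len(n_mol), each = 4L),
    molecule_class = "small",
    site_role = "none",
    parent = NA_integer_
  )
  base <- matrix(NA_real_, 4L * n_mol, 3)
  for (m in seq_len(n_mol)) {
    r0 <- 4L * (m - 1L)
    base[r0 + 1L, ] <- origin[m, ] + a_loc
    base[r0 + 2L, ] <- origin[m, ] + b_loc
    base[r0 + 3L, ] <- origin[m, ] + c_loc
  }
  frames <- purrr::map(seq_len(n_frames), function(f) {
    xyz <- base
    d_rows <- 4L * (seq_len(n_mol) - 1L) + 4L
    xyz[d_rows, ] <- origin + d_states[sim[f, ], , drop = FALSE]
    xyz
  })
  traj <- as_trajectory(frames, topology = topo, box = box,
                        times = (seq_len(n_frames) - 1L) * spec$frame_interval)
  attr(traj, "quadruples") <- tibble(
    molecule_id = seq_len(n_mol),
    i = 4L * (seq_len(n_mol) - 1L) + 1L,
    j = 4L * (seq_len(n_mol) - 1L) + 2L,
    k = 4L * (seq_len(n_mol) - 1L) + 3L,
    l = 4L * (seq_len(n_mol) - 1L) + 4L
  )
  attr(traj, "vectors") <- tibble(
    molecule_id = seq_len(n_mol),
    from = 4L * (seq_len(n_mol) - 1L) + 3L,
    to = 4L * (seq_len(n_mol) - 1L) + 4L
  )
  attr(traj, "states") <- sim
  attr(traj, "ground_truth") <- spec
  traj
}
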