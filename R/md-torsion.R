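# Torsional angles, orientational distributions and angular correlation
# functions of trajectories.

#' Dihedral angle time series
#'
#' Signed dihedral angle of one atom quadruple per molecule, per frame, in
#' (-180, 180] degrees (IUPAC sign convention: looking down the j-k bond,
#' positive when the far bond rotates clockwise from the near bond). Bond
#' vectors are taken minimum-image, so quadruples may straddle the periodic
#' boundary. Frames where a bonded triple is collinear have an undefined
#' angle and yield `NA` with a warning.
#'
#' @param traj An `asd_trajectory`.
#' @param quadruples Data frame with columns `molecule_id` and atom row
#'   indices `i`, `j`, `k`, `l` defining the dihedral i-j-k-l.
#' @return A tibble with `frame`, `time_ns`, `molecule_id`, `angle_deg`.
#' @export
torsion_series <- function(traj, quadruples) {
  stopifnot(inherits(traj, "asd_trajectory"))
  need <- c("molecule_id", "i", "j", "k", "l")
  if (!is.data.frame(quadruples) || !all(need %in% names(quadruples))) {
    stop_invalid("`quadruples` needs columns molecule_id, i, j, k, l")
  }
  box <- traj$box
  n_undef <- 0L
  rows <- purrr::imap(traj$frames, function(xyz, f) {
    b1 <- min_image_vec(xyz[quadruples$i, , drop = FALSE],
                        xyz[quadruples$j, , drop = FALSE], box)
    b2 <- min_image_vec(xyz[quadruples$j, , drop = FALSE],
                        xyz[quadruples$k, , drop = FALSE], box)
    b3 <- min_image_vec(xyz[quadruples$k, , drop = FALSE],
                        xyz[quadruples$l, , drop = FALSE], box)
    n1 <- cross_rows(b1, b2)
    n2 <- cross_rows(b2, b3)
    b2n <- sqrt(rowSums(b2^2))
    x <- rowSums(n1 * n2)
    y <- rowSums(cross_rows(n1, n2) * b2) / b2n
    ang <- atan2(y, x) * 180 / pi
    undef <- rowSums(n1^2) < 1e-12 | rowSums(n2^2) < 1e-12
    n_undef <<- n_undef + sum(undef)
    ang[undef] <- NA_real_
    ang[!is.na(ang) & ang <= -180] <- 180
    tibble(frame = f, time_ns = traj$times[f],
           molecule_id = quadruples$molecule_id, angle_deg = ang)
  })
  if (n_undef > 0) {
    warn(sprintf("%d frame/molecule dihedrals undefined (collinear atoms)", n_undef))
  }
  dplyr::bind_rows(rows)
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Orientational distribution function P(theta)
#'
#' Normalised histogram of a torsion-angle series over all molecules and
#' frames: the probability of finding the group at orientation theta,
#' \eqn{\sum_b P(\theta_b) = 1}.
#'
#' @param series A [torsion_series()] result (columns `angle_deg`, others
#'   ignored), or any data frame with an `angle_deg` column.
#' @param bin_width Bin width in degrees (must divide 360 evenly).
#' @return A tibble with `angle_deg` (bin centers, spanning (-180, 180]) and
#'   `p` (probabilities summing to 1).
#' @export
orientation_distribution <- function(series, bin_width = 5) {
  if (!is.data.frame(series) || !"angle_deg" %in% names(series)) {
    stop_invalid("`series` needs an `angle_deg` column")
  }
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE, upper = 360)
  if (abs(360 / bin_width - round(360 / bin_width)) > 1e-9) {
    stop_invalid("`bin_width` must divide 360 degrees evenly")
  }
  ang <- series$angle_deg
  ang <- ang[!is.na(ang)]
  if (!length(ang)) stop_invalid("no defined angles in `series`")
  n_bins <- round(360 / bin_width)
  # bins centered on -180, -180 + w, ...: round angles (0, 60, 180, ...)
  # fall on bin centers; +180 wraps onto the -180 bin
  idx <- (round((ang + 180) / bin_width) %% n_bins) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  tibble(
    angle_deg = -180 + (seq_len(n_bins) - 1L) * bin_width,
    p = counts / sum(counts)
  )
}

#' Angular (bond-vector) correlation function
#'
#' \deqn{ACF(t) = \langle \hat u(t_0)\cdot \hat u(t_0+t) \rangle}
#' averaged over all molecules and all time origins (overlapping windows; no
#' independence correction, so successive lags share data). Vectors are
#' normalised per frame, making ACF(0) = 1 exactly and the function
#' invariant under global rotations. An exponential decay time tau is fitted
#' by log-linear regression over the lags where the ACF remains above
#' `fit_floor`.
#'
#' @param traj An `asd_trajectory`.
#' @param vectors Data frame with columns `molecule_id`, `from`, `to`: the
#'   atom pair whose unit vector is followed for each molecule (e.g. a C-C
#'   bond of a phenyl ring).
#' @param max_lag Maximum lag in frames (default `min(n_frames - 1, 500)`).
#' @param fit_floor ACF level below which points are excluded from the
#'   exponential fit (default 0.05).
#' @return A tibble with `lag_ns` and `acf`; attributes `tau_ns` (fitted
#'   correlation time, `NA` if the ACF never decays below 1) and `n_vectors`.
#' @export
angular_correlation <- function(traj, vectors, max_lag = NULL, fit_floor = 0.05) {
  stopifnot(inherits(traj, "asd_trajectory"))
  need <- c("molecule_id", "from", "to")
  if (!is.data.frame(vectors) || !all(need %in% names(vectors))) {
    stop_invalid("`vectors` needs columns molecule_id, from, to")
  }
  n_frames <- length(traj$frames)
  if (n_frames < 2L) stop_invalid("need at least two frames")
  max_lag <- max_lag %||% min(n_frames - 1L, 500L)
  check_number(max_lag, "max_lag", lower = 1, upper = n_frames - 1)
  box <- traj$box
  n_vec <- nrow(vectors)
  # U: frames x (3 * n_vec) matrix of unit vectors
  U <- matrix(NA_real_, n_frames, 3L * n_vec)
  for (f in seq_len(n_frames)) {
    xyz <- traj$frames[[f]]
    v <- min_image_vec(xyz[vectors$from, , drop = FALSE],
                       xyz[vectors$to, , drop = FALSE], box)
    nrm <- sqrt(rowSums(v^2))
    if (any(nrm < 1e-12)) {
      stop_invalid(sprintf("zero-length bond vector(s) in frame %d", f))
    }
    U[f, ] <- as.vector(v / nrm)
  }
  lags <- 0:max_lag
  # rowSums over the 3*n_vec columns adds up the dot products of all
  # vectors at one origin; dividing by n_vec averages over molecules
  acf_vals <- vapply(lags, function(L) {
    n_orig <- n_frames - L
    mean(rowSums(matrix(
      U[seq_len(n_orig), , drop = FALSE] *
        U[L + seq_len(n_orig), , drop = FALSE],
      nrow = n_orig
    ))) / n_vec
  }, numeric(1))
  dt <- if (n_frames > 1) diff(traj$times)[1] else 1
  out <- tibble(lag_ns = lags * dt, acf = acf_vals)
  tau <- NA_real_
  usable <- which(out$acf > fit_floor & out$acf < 1 - 1e-12 & out$lag_ns > 0)
  if (length(usable) >= 2L) {
    fit <- lm(log(acf) ~ lag_ns, data = out[usable, ])
    slope <- coef(fit)[["lag_ns"]]
    if (slope < 0) tau <- -1 / slope
  }
  attr(out, "tau_ns") <- tau
  attr(out, "n_vectors") <- n_vec
  out
}
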