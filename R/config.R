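# Molecular configurations and trajectories.
#
# A configuration is an atom table plus an orthorhombic periodic box. The atom
# table carries the topology needed by the hydrogen-bond machinery: molecule
# membership, a molecule class (chain / small / water), and a per-atom site
# role (donor-H, donor-heavy, acceptor, none). Every donor-H is bonded to
# exactly one donor-heavy atom, recorded in `parent`.

.SITE_ROLES <- c("donor-H", "donor-heavy", "acceptor", "none")

#' Build a molecular configuration
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` (angstroms),
#'   `molecule_id` (integer), `molecule_class` (`"chain"`, `"small"`,
#'   `"water"`), `site_role` (one of `"donor-H"`, `"donor-heavy"`,
#'   `"acceptor"`, `"none"`; a site may also be both donor-heavy and acceptor,
#'   written `"donor-heavy+acceptor"`), and optionally `parent` (row index of
#'   the bonded donor-heavy atom, required for `"donor-H"` rows; if missing it
#'   is inferred as the nearest donor-heavy atom of the same molecule).
#' @param box Orthorhombic box edge lengths in angstroms (length 3, or a
#'   single value recycled). Coordinates are wrapped into `[0, box)` on
#'   construction; all distance computations use the minimum-image convention.
#' @param wrap Wrap coordinates into the box (default `TRUE`).
#' @return An `asd_config`: list with `atoms` (tibble) and `box`.
#' @export
as_config <- function(atoms, box, wrap = TRUE) {
  required <- c("element", "x", "y", "z", "molecule_id", "molecule_class", "site_role")
  if (!is.data.frame(atoms) || !all(required %in% names(atoms))) {
    stop_invalid(paste0("`atoms` needs columns ", paste(required, collapse = ", ")))
  }
  box <- rep(as.numeric(box), length.out = 3)
  check_positive_vector(box, "box")
  atoms <- as_tibble(atoms)
  bad_role <- !vapply(strsplit(atoms$site_role, "+", fixed = TRUE),
                      function(r) all(r %in% .SITE_ROLES), logical(1))
  if (any(bad_role)) {
    stop_invalid(sprintf("invalid site_role for atom(s) %s",
                         paste(head(which(bad_role), 10), collapse = ", ")))
  }
  if (wrap) {
    atoms$x <- atoms$x %% box[1]
    atoms$y <- atoms$y %% box[2]
    atoms$z <- atoms$z %% box[3]
  }
  is_h <- role_has(atoms$site_role, "donor-H")
  if (!"parent" %in% names(atoms)) atoms$parent <- NA_integer_
  need_parent <- which(is_h & is.na(atoms$parent))
  if (length(need_parent)) {
    heavy_idx <- which(role_has(atoms$site_role, "donor-heavy"))
    for (i in need_parent) {
      cand <- heavy_idx[atoms$molecule_id[heavy_idx] == atoms$molecule_id[i]]
      if (!length(cand)) {
        stop_invalid(sprintf("donor-H atom %d has no donor-heavy atom in its molecule", i))
      }
      d <- min_image_dist(as.matrix(atoms[i, c("x", "y", "z")]),
                          as.matrix(atoms[cand, c("x", "y", "z")]), box)
      atoms$parent[i] <- cand[which.min(d)]
    }
  }
  structure(list(atoms = atoms, box = box), class = "asd_config")
}

# role strings may be composites like "donor-heavy+acceptor"
role_has <- function(role, what) {
  vapply(strsplit(role, "+", fixed = TRUE), function(r) what %in% r, logical(1))
}

#' @export
print.asd_config <- function(x, ...) {
  cat(sprintf("<asd_config> %d atoms, %d molecules, box %.2f x %.2f x %.2f A\n",
              nrow(x$atoms), length(unique(x$atoms$molecule_id)),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Build a trajectory from configurations or coordinate frames
#'
#' @param frames List of N x 3 coordinate matrices (consistent atom order), or
#'   a list of `asd_config`s sharing one topology.
#' @param topology Atom table as in [as_config()] (ignored when `frames` are
#'   configurations).
#' @param box Box edges (angstroms).
#' @param times Frame times in ns; defaults to `0, 1, 2, ...`.
#' @return An `asd_trajectory`: list with `topology`, `frames`, `box`, `times`.
#' @export
as_trajectory <- function(frames, topology = NULL, box = NULL, times = NULL) {
  if (inherits(frames, "asd_config")) frames <- list(frames)
  if (length(frames) == 0L) stop_invalid("a trajectory needs at least one frame")
  if (inherits(frames[[1]], "asd_config")) {
    topology <- frames[[1]]$atoms
    box <- frames[[1]]$box
    frames <- purrr::map(frames, function(cf) as.matrix(cf$atoms[, c("x", "y", "z")]))
  }
  if (is.null(topology) || is.null(box)) {
    stop_invalid("`topology` and `box` are required for raw coordinate frames")
  }
  n <- nrow(topology)
  ok <- purrr::map_lgl(frames, function(m) is.matrix(m) && nrow(m) == n && ncol(m) == 3)
  if (!all(ok)) stop_invalid("all frames must be N x 3 matrices with constant atom count")
  times <- times %||% (seq_along(frames) - 1)
  if (length(times) != length(frames)) stop_invalid("`times` must match frame count")
  structure(
    list(topology = as_tibble(topology), frames = frames,
         box = rep(as.numeric(box), length.out = 3), times = as.numeric(times)),
    class = "asd_trajectory"
  )
}

#' Extract one frame of a trajectory as a configuration
#'
#' @param traj An `asd_trajectory`.
#' @param i Frame index (1-based).
#' @return An `asd_config`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "asd_trajectory"))
  check_number(i, "i", lower = 1, upper = length(traj$frames))
  atoms <- traj$topology
  xyz <- traj$frames[[i]]
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  as_config(atoms, traj$box, wrap = FALSE)
}

#' @export
print.asd_trajectory <- function(x, ...) {
  cat(sprintf("<asd_trajectory> %d frames x %d atoms, %.4g-%.4g ns\n",
              length(x$frames), nrow(x$topology),
              min(x$times), max(x$times)))
  invisible(x)
}

# ---- periodic geometry -----------------------------------------------------

# Minimum-image displacement vectors from each row of `a` to each row of `b`
# (same number of rows), both N x 3. Returns N x 3.
min_image_vec <- function(a, b, box) {
  d <- b - a
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# Minimum-image distances between one point (1 x 3) or matched rows and the
# rows of `b`.
min_image_dist <- function(a, b, box) {
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  sqrt(rowSums(min_image_vec(a, b, box)^2))
}

# All pairwise minimum-image distances between rows of `a` (Na x 3) and rows
# of `b` (Nb x 3). Returns an Na x Nb matrix. Vectorised per dimension.
min_image_cross_dist <- function(a, b, box) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}
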