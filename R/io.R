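# Readers and writers for the package's plain-text formats: curve CSVs,
# extended XYZ (box on the comment line), PDB (CRYST1 record; atom records
# via bio3d), and the topology CSV that assigns molecules and H-bond roles.

#' Read and write relaxometry curve CSVs
#'
#' Column conventions: recovery curves `(delay_s, amplitude)`, FIDs
#' `(time_us, amplitude)`, T1 series `(temperature_K, t1_s)`.
#'
#' @param path File path.
#' @param curve,series The tibble to write.
#' @param larmor_frequency Larmor frequency in Hz attached to a T1 series on
#'   read (stored nowhere in the CSV).
#' @return Readers return the corresponding tibble; writers return the input
#'   invisibly.
#' @name curve_io
NULL

#' @rdname curve_io
#' @export
read_recovery_curve <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    delay_s = readr::col_double(), amplitude = readr::col_double()
  ))
  check_recovery_curve(x)
}

#' @rdname curve_io
#' @export
write_recovery_curve <- function(curve, path) {
  readr::write_csv(curve[c("delay_s", "amplitude")], path)
  invisible(curve)
}

#' @rdname curve_io
#' @export
read_fid_curve <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    time_us = readr::col_double(), amplitude = readr::col_double()
  ))
}

#' @rdname curve_io
#' @export
write_fid_curve <- function(curve, path) {
  readr::write_csv(curve[c("time_us", "amplitude")], path)
  invisible(curve)
}

#' @rdname curve_io
#' @export
read_t1_series <- function(path, larmor_frequency = NULL) {
  x <- readr::read_csv(path, col_types = readr::cols(
    temperature_K = readr::col_double(), t1_s = readr::col_double()
  ))
  attr(x, "larmor_frequency") <- larmor_frequency
  x
}

#' @rdname curve_io
#' @export
write_t1_series <- function(series, path) {
  readr::write_csv(series[c("temperature_K", "t1_s")], path)
  invisible(series)
}

#' Read and write diffraction peak lists
#'
#' CSV columns `two_theta_deg`, `fwhm_deg`, mapped to the internal
#' `two_theta` / `fwhm` names.
#'
#' @param path File path.
#' @param peaks Peak tibble with `two_theta` and `fwhm` (degrees).
#' @return Reader: tibble with `two_theta`, `fwhm`; writer: input, invisibly.
#' @name peak_io
NULL

#' @rdname peak_io
#' @export
read_peaks <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    two_theta_deg = readr::col_double(), fwhm_deg = readr::col_double()
  ))
  tibble(two_theta = x$two_theta_deg, fwhm = x$fwhm_deg)
}

#' @rdname peak_io
#' @export
write_peaks <- function(peaks, path) {
  readr::write_csv(
    tibble(two_theta_deg = peaks$two_theta, fwhm_deg = peaks$fwhm), path
  )
  invisible(peaks)
}

#' Write a configuration or trajectory as extended XYZ
#'
#' One block per frame: atom count, a comment line carrying the three box
#' edge lengths (`box <a> <b> <c>`), then `element x y z` records. Roles and
#' molecule membership do not fit in XYZ; pair the file with
#' [write_topology()].
#'
#' @param x An `asd_config` or `asd_trajectory`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_xyz <- function(x, path) {
  if (inherits(x, "asd_config")) x <- as_trajectory(x)
  stopifnot(inherits(x, "asd_trajectory"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  n <- nrow(x$topology)
  for (f in seq_along(x$frames)) {
    xyz <- x$frames[[f]]
    writeLines(as.character(n), con)
    writeLines(sprintf("box %.6f %.6f %.6f time_ns %.6f",
                       x$box[1], x$box[2], x$box[3], x$times[f]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", x$topology$element,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(x)
}

#' Read an extended XYZ file
#'
#' @param path Input path.
#' @param topology Optional topology tibble (from [read_topology()]) carrying
#'   molecule membership and site roles; without it all atoms become one
#'   `"none"`-role molecule of class `"small"`.
#' @return An `asd_trajectory` (possibly single-frame).
#' @export
read_xyz <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  box <- NULL
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop_invalid(sprintf("bad atom count at line %d", i))
    comment <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(comment) < 4L || comment[1] != "box") {
      stop_invalid("comment line must read 'box <a> <b> <c> [time_ns <t>]'")
    }
    box <- as.numeric(comment[2:4])
    t_ns <- if (length(comment) >= 6L && comment[5] == "time_ns") {
      as.numeric(comment[6])
    } else {
      length(frames)
    }
    rec <- do.call(rbind, strsplit(trimws(lines[i + 1L + seq_len(n)]), "\\s+"))
    elements <- rec[, 1]
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(rec[, 2:4]), ncol = 3)
    times <- c(times, t_ns)
    i <- i + 2L + n
  }
  topo <- topology %||% tibble(
    element = elements,
    molecule_id = seq_along(elements),
    molecule_class = "small",
    site_role = "none",
    parent = NA_integer_
  )
  topo$element <- elements
  as_trajectory(frames, topology = topo, box = box, times = times)
}

#' Write and read the topology table
#'
#' CSV with columns `atom_index`, `molecule_id`, `molecule_class`,
#' `site_role` and `parent` (the donor-heavy atom index of each donor-H).
#'
#' @param x An `asd_config` or `asd_trajectory`.
#' @param path File path.
#' @return Writer: `x`, invisibly. Reader: a topology tibble for
#'   [read_xyz()] / [as_config()].
#' @name topology_io
NULL

#' @rdname topology_io
#' @export
write_topology <- function(x, path) {
  topo <- if (inherits(x, "asd_config")) x$atoms else x$topology
  readr::write_csv(tibble(
    atom_index = seq_len(nrow(topo)),
    molecule_id = topo$molecule_id,
    molecule_class = topo$molecule_class,
    site_role = topo$site_role,
    parent = topo$parent %||% NA_integer_
  ), path)
  invisible(x)
}

#' @rdname topology_io
#' @export
read_topology <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    atom_index = readr::col_integer(),
    molecule_id = readr::col_integer(),
    molecule_class = readr::col_character(),
    site_role = readr::col_character(),
    parent = readr::col_integer()
  ))
  x[order(x$atom_index), c("molecule_id", "molecule_class", "site_role", "parent")]
}

#' Write and read PDB files with a CRYST1 record
#'
#' Atom records are handled by the bio3d package; the orthorhombic box is
#' written as a CRYST1 record (90-degree angles, P 1). Molecule ids map to
#' residue numbers and molecule classes to residue names (`CHN`, `SML`,
#' `HOH`); site roles do not fit in PDB, so pair the file with
#' [write_topology()] when roles matter. Atom numbering is 1-based in the
#' file, matching the PDB convention.
#'
#' @param config An `asd_config`.
#' @param path File path.
#' @param topology Optional topology tibble merged into the atoms on read.
#' @return Writer: `config`, invisibly. Reader: an `asd_config`.
#' @name pdb_io
NULL

.PDB_RESID <- c(chain = "CHN", small = "SML", water = "HOH")

#' @rdname pdb_io
#' @export
write_pdb <- function(config, path) {
  stopifnot(inherits(config, "asd_config"))
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop_invalid("the bio3d package is required for PDB output")
  }
  atoms <- config$atoms
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    config$box[1], config$box[2], config$box[3], 90, 90, 90
  ), path)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
    resno = atoms$molecule_id,
    resid = unname(.PDB_RESID[atoms$molecule_class]),
    elety = atoms$element,
    elesy = atoms$element,
    append = TRUE
  )
  invisible(config)
}

#' @rdname pdb_io
#' @export
read_pdb <- function(path, topology = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop_invalid("the bio3d package is required for PDB input")
  }
  cryst <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cryst)) stop_invalid("PDB file has no CRYST1 record (box unknown)")
  box <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                      substr(cryst[1], 25, 33)))
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  class_map <- setNames(names(.PDB_RESID), unname(.PDB_RESID))
  atoms <- tibble(
    element = a$elety,
    x = a$x, y = a$y, z = a$z,
    molecule_id = a$resno,
    molecule_class = unname(class_map[a$resid]) %||% "small",
    site_role = "none",
    parent = NA_integer_
  )
  if (!is.null(topology)) {
    atoms$molecule_id <- topology$molecule_id
    atoms$molecule_class <- topology$molecule_class
    atoms$site_role <- topology$site_role
    atoms$parent <- topology$parent
  }
  as_config(atoms, box)
}
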