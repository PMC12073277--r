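# Molecular formulas and proton bookkeeping.
#
# The amplitude of an NMR magnetization component is proportional to the number
# of protons in the corresponding phase, so converting weight fractions to
# expected magnetization fractions is mole arithmetic over 1H counts.

# Atomic weights (g/mol), frozen in the package so proton_fraction() is
# bit-stable across environments. CODATA/IUPAC conventional values.
.ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904
)

#' Parse a molecular formula
#'
#' Parses a Hill-notation formula string (e.g. `"C14H12O3"` for resveratrol, or
#' `"C6H9NO"` for one vinylpyrrolidone monomer) into element counts, molar mass
#' and hydrogen count. Polymers are passed as their repeat-unit formula: both
#' the proton count and the molar mass then refer to one monomer, and their
#' ratio — all that proton bookkeeping uses — is unaffected by chain length.
#'
#' @param formula A single formula string, elements as capitalised symbols
#'   followed by optional integer counts.
#' @return An object of class `molecular_formula`: a list with `formula`,
#'   `counts` (named integer vector), `molar_mass` (g/mol) and `h_count`.
#' @examples
#' molecular_formula("C14H12O3")
#' molecular_formula("C6H9NO")$molar_mass
#' @export
molecular_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop_invalid("`formula` must be a single non-empty string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop_invalid(sprintf("cannot parse formula '%s'", formula))
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- gsub("[0-9]+", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(.ATOMIC_WEIGHTS)) {
      stop_invalid(sprintf("unknown element '%s' in formula '%s'", sym, formula))
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  structure(
    list(
      formula = formula,
      counts = counts,
      molar_mass = sum(.ATOMIC_WEIGHTS[names(counts)] * counts),
      h_count = if ("H" %in% names(counts)) counts[["H"]] else 0L
    ),
    class = "molecular_formula"
  )
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(sprintf("<molecular_formula> %s  M = %.3f g/mol  H = %d\n",
              x$formula, x$molar_mass, x$h_count))
  invisible(x)
}

#' Proton fractions of a multi-component mixture
#'
#' Converts weight fractions of mixture components into the fraction of all
#' protons contributed by each component:
#' \deqn{f_i = \frac{w_i H_i / M_i}{\sum_j w_j H_j / M_j}}
#' where \eqn{w_i} is the weight fraction, \eqn{H_i} the hydrogen count and
#' \eqn{M_i} the molar mass of component \eqn{i} (monomer values for polymers).
#' Because magnetization amplitude is proportional to proton number, these are
#' the expected magnetization fractions of well-separated phases.
#'
#' For a 50/50 w/w resveratrol/PVP mixture this arithmetic gives a resveratrol
#' proton share of ~39.4%; reported experimental assignments for such systems
#' quote ~37%, plausibly because residual water in the polymer was included.
#' The function performs the exact arithmetic and leaves such corrections to
#' the caller (water can be passed as an explicit third component).
#'
#' @param components A data frame (or tibble) with columns `formula`
#'   (formula strings or `molecular_formula` objects in a list column) and
#'   `weight_fraction` (must sum to 1). An optional `label` column is carried
#'   through.
#' @return A tibble with `label`, `formula`, `weight_fraction`, `h_count`,
#'   `molar_mass`, and `proton_fraction` (sums to 1).
#' @examples
#' proton_fraction(data.frame(
#'   label = c("RSV", "PVP"),
#'   formula = c("C14H12O3", "C6H9NO"),
#'   weight_fraction = c(0.5, 0.5)
#' ))
#' @export
proton_fraction <- function(components) {
  if (!is.data.frame(components) ||
      !all(c("formula", "weight_fraction") %in% names(components))) {
    stop_invalid("`components` needs columns `formula` and `weight_fraction`")
  }
  w <- components$weight_fraction
  check_fractions(w, "weight_fraction")
  parsed <- purrr::map(components$formula, function(f) {
    if (inherits(f, "molecular_formula")) f else molecular_formula(f)
  })
  h <- purrr::map_dbl(parsed, "h_count")
  mass <- purrr::map_dbl(parsed, "molar_mass")
  if (all(h == 0)) {
    stop_invalid("all components are proton-free; proton fractions are undefined")
  }
  moles_h <- w * h / mass
  tibble(
    label = components$label %||% purrr::map_chr(parsed, "formula"),
    formula = purrr::map_chr(parsed, "formula"),
    weight_fraction = w,
    h_count = h,
    molar_mass = mass,
    proton_fraction = moles_h / sum(moles_h)
  )
}
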