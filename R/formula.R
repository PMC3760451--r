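# Elemental formulas and molar volumes.

# IUPAC standard atomic weights (2021 abridged), pinned. Covers every element
# that occurs in cuticular constituents and common agrochemicals plus the rest
# of the main-group block so user formulas do not fail gratuitously.
.atomic_weights <- c(
  H = 1.008, He = 4.0026,
  Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Ne = 20.180,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Cu = 63.546,
  Zn = 65.38, Br = 79.904, I = 126.90
)

#' Parse an elemental formula
#'
#' Splits a Hill-order elemental formula such as `"C29H60"` or `"CH4N2O"`
#' into element counts. Only plain element-count formulas are supported
#' (no brackets, hydrates or charges).
#'
#' @param formula Character vector of formulas.
#' @return A list (one entry per formula) of named integer vectors of element
#'   counts.
#' @examples
#' parse_formula("CH4N2O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula))
  purrr::map(formula, function(f) {
    f <- gsub("[[:space:]]", "", f)
    if (!nzchar(f)) {
      abort("empty formula", class = "phytosol_formula_error")
    }
    matches <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
    tokens <- regmatches(f, list(matches))[[1]]
    if (sum(attr(matches, "match.length")) != nchar(f)) {
      abort(paste0("cannot parse formula '", f, "'"),
            class = "phytosol_formula_error")
    }
    el <- sub("[0-9]*$", "", tokens)
    n <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                           sub("^[A-Za-z]+", "", tokens), "1"))
    unknown <- setdiff(el, names(.atomic_weights))
    if (length(unknown)) {
      abort(paste0("unknown element symbol(s): ",
                   paste(unknown, collapse = ", "), " in formula '", f, "'"),
            class = "phytosol_formula_error")
    }
    tapply(n, el, sum)[unique(el)]
  })
}

#' Molar mass from an elemental formula
#'
#' Sums pinned IUPAC standard atomic weights over the element counts of the
#' formula.
#'
#' @param formula Character vector of elemental formulas (Hill order).
#' @return Numeric vector of molar masses in g/mol.
#' @examples
#' molar_mass("CH4N2O") # urea, 60.06
#' molar_mass(c("H2", "C29H60"))
#' @export
molar_mass <- function(formula) {
  counts <- parse_formula(formula)
  purrr::map_dbl(counts, ~ sum(.atomic_weights[names(.x)] * .x))
}

#' Molar volume from mass and density
#'
#' @param mass Molar mass in g/mol.
#' @param density Density in g/cm^3; must be positive.
#' @return Molar volume in cm^3/mol.
#' @examples
#' molar_volume(60.06, 1.328) # urea, ~45.2
#' @export
molar_volume <- function(mass, density) {
  stopifnot(is.numeric(mass), is.numeric(density))
  if (any(!is.finite(density)) || any(density <= 0)) {
    abort("density must be positive", class = "phytosol_domain_error")
  }
  mass / density
}
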