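# van Oss-Chaudhury-Good surface energetics from three-liquid contact angles.
#
# For each probe liquid L on solid s the Young-Dupre work of adhesion
#   W_a = gamma_L (1 + cos theta)
# equals 2 [ sqrt(gamma_s^LW gamma_L^LW) + sqrt(gamma_s^+ gamma_L^-)
#            + sqrt(gamma_s^- gamma_L^+) ].
# An apolar probe (diiodomethane) isolates gamma_s^LW; the two polar probes
# (water, glycerol) then give a 2x2 linear system in sqrt(gamma_s^+),
# sqrt(gamma_s^-).

# Standard vOCG probe liquid set (mJ/m^2).
.default_liquids <- tibble::tribble(
  ~liquid,         ~gamma_total, ~gamma_lw, ~gamma_plus, ~gamma_minus,
  "water",                 72.8,      21.8,        25.5,         25.5,
  "glycerol",              64.0,      34.0,        3.92,         57.4,
  "diiodomethane",         50.8,      50.8,           0,            0
)

#' Probe liquid surface tension components
#'
#' The standard van Oss-Chaudhury-Good liquid set: total surface tension and
#' its Lifshitz-van der Waals, electron-acceptor (+) and electron-donor (-)
#' components, all in mJ/m^2. Rows can be overridden or new liquids added via
#' `override`; every row is validated against
#' `gamma_total = gamma_lw + 2 sqrt(gamma_plus gamma_minus)` within 2%.
#'
#' @param override Optional data frame with the same columns; rows replace
#'   (by `liquid`) or extend the defaults.
#' @return A tibble with columns `liquid`, `gamma_total`, `gamma_lw`,
#'   `gamma_plus`, `gamma_minus`.
#' @examples
#' probe_liquids()
#' @export
probe_liquids <- function(override = NULL) {
  liq <- .default_liquids
  if (!is.null(override)) {
    override <- tibble::as_tibble(override)
    stopifnot(all(c("liquid", "gamma_total", "gamma_lw", "gamma_plus",
                    "gamma_minus") %in% names(override)))
    liq <- dplyr::bind_rows(
      dplyr::anti_join(liq, override, by = "liquid"),
      override[names(liq)]
    )
  }
  recon <- liq$gamma_lw + 2 * sqrt(liq$gamma_plus * liq$gamma_minus)
  bad <- abs(recon - liq$gamma_total) > 0.02 * liq$gamma_total
  if (any(liq$gamma_total < 0 | liq$gamma_lw < 0 | liq$gamma_plus < 0 |
          liq$gamma_minus < 0) || any(bad)) {
    abort(paste0("inconsistent probe liquid constants: ",
                 paste(liq$liquid[bad], collapse = ", ")),
          class = "phytosol_liquid_error")
  }
  liq
}

check_angle <- function(theta) {
  if (any(!is.finite(theta)) || any(theta <= 0) || any(theta >= 180)) {
    abort("contact angles must lie strictly between 0 and 180 degrees",
          class = "phytosol_domain_error")
  }
}

#' Work of adhesion from a contact angle
#'
#' Young-Dupre relation `W_a = gamma_L (1 + cos theta)`; strictly decreasing
#' in the angle.
#'
#' @param theta Contact angle in degrees, strictly inside (0, 180).
#' @param gamma_l Total surface tension of the liquid in mJ/m^2.
#' @return Work of adhesion in mJ/m^2.
#' @examples
#' work_of_adhesion(83.4, 72.8) # water on pepper fruit, 81.2
#' @export
work_of_adhesion <- function(theta, gamma_l) {
  check_angle(theta)
  gamma_l * (1 + cospi(theta / 180))
}

#' Lifshitz-van der Waals component from an apolar probe
#'
#' For a fully dispersive liquid the vOCG equation collapses to
#' `gamma_s^LW = gamma_L (1 + cos theta)^2 / 4`.
#'
#' @param theta Contact angle of the apolar probe in degrees.
#' @param liquid One-row data frame (or list) with the probe's components;
#'   `gamma_plus` and `gamma_minus` must both be zero.
#' @return `gamma_s^LW` in mJ/m^2.
#' @examples
#' di <- dplyr::filter(probe_liquids(), liquid == "diiodomethane")
#' gamma_lw_apolar(60.8, di) # pepper fruit, 28.1
#' @export
gamma_lw_apolar <- function(theta, liquid) {
  check_angle(theta)
  if (liquid$gamma_plus != 0 || liquid$gamma_minus != 0) {
    abort(paste0("'", liquid$liquid %||% "liquid",
                 "' is not apolar: the closed form gamma_L (1+cos theta)^2/4",
                 " needs gamma_plus = gamma_minus = 0"),
          class = "phytosol_liquid_error")
  }
  liquid$gamma_total * (1 + cospi(theta / 180))^2 / 4
}

#' Acid-base components from two polar probe angles
#'
#' Solves the 2x2 linear system in `x = sqrt(gamma_s^+)`, `y =
#' sqrt(gamma_s^-)` set up by the vOCG equation for the two polar probes.
#' A negative root means the least-squares-free algebraic solution leaves the
#' physical domain (typical for very hydrophobic, rough surfaces); it is
#' squared anyway and flagged (`negative_root_plus`/`negative_root_minus`)
#' unless `negative_roots = "clamp"`, which zeroes it instead.
#'
#' @param theta_w,theta_g Water and glycerol contact angles in degrees.
#' @param gamma_lw Solid Lifshitz-van der Waals component in mJ/m^2.
#' @param water,glycerol One-row liquid records (see [probe_liquids()]).
#' @param negative_roots `"square"` (default) or `"clamp"`.
#' @return List with `gamma_plus`, `gamma_minus`, `flags` (character vector).
#' @examples
#' liq <- probe_liquids()
#' solve_acid_base(83.4, 68.6, 28.11,
#'                 liq[liq$liquid == "water", ],
#'                 liq[liq$liquid == "glycerol", ])
#' @export
solve_acid_base <- function(theta_w, theta_g, gamma_lw, water, glycerol,
                            negative_roots = c("square", "clamp")) {
  negative_roots <- match.arg(negative_roots)
  check_angle(c(theta_w, theta_g))
  if (gamma_lw < 0) {
    abort("gamma_lw must be non-negative", class = "phytosol_domain_error")
  }
  if (water$gamma_plus <= 0 || water$gamma_minus <= 0 ||
      glycerol$gamma_plus <= 0 || glycerol$gamma_minus <= 0) {
    abort("both polar probes need positive acid and base components",
          class = "phytosol_liquid_error")
  }
  a <- rbind(
    2 * c(sqrt(water$gamma_minus), sqrt(water$gamma_plus)),
    2 * c(sqrt(glycerol$gamma_minus), sqrt(glycerol$gamma_plus))
  )
  b <- c(
    work_of_adhesion(theta_w, water$gamma_total) -
      2 * sqrt(gamma_lw * water$gamma_lw),
    work_of_adhesion(theta_g, glycerol$gamma_total) -
      2 * sqrt(gamma_lw * glycerol$gamma_lw)
  )
  if (abs(det(a)) < 1e-8) {
    abort("degenerate probe liquid pair: acid-base system is singular",
          class = "phytosol_liquid_error")
  }
  xy <- solve(a, b)
  flags <- character()
  # ignore sub-nanoscale negatives from floating point noise
  if (xy[1] < -1e-9) flags <- c(flags, "negative_root_plus")
  if (xy[2] < -1e-9) flags <- c(flags, "negative_root_minus")
  if (negative_roots == "clamp") xy[xy < 0] <- 0
  list(gamma_plus = xy[1]^2, gamma_minus = xy[2]^2, flags = flags)
}

#' Acid-base surface energy component
#'
#' @param gamma_plus,gamma_minus Electron-acceptor and -donor components
#'   (mJ/m^2), both non-negative.
#' @return `2 sqrt(gamma_plus gamma_minus)` in mJ/m^2.
#' @examples
#' gamma_ab(1.37, 3.87) # pepper fruit, 4.6
#' @export
gamma_ab <- function(gamma_plus, gamma_minus) {
  stopifnot(all(gamma_plus >= 0), all(gamma_minus >= 0))
  2 * sqrt(gamma_plus * gamma_minus)
}

#' Surface polarity
#'
#' Percentage share of the acid-base component in the total surface free
#' energy, `100 gamma_AB / gamma`.
#'
#' @param g_ab Acid-base component in mJ/m^2.
#' @param gamma_total Total surface free energy in mJ/m^2, positive.
#' @return Polarity in percent.
#' @examples
#' surface_polarity(4.6, 32.7) # pepper fruit, ~14.1
#' @export
surface_polarity <- function(g_ab, gamma_total) {
  if (any(gamma_total <= 0)) {
    abort("gamma_total must be positive", class = "phytosol_domain_error")
  }
  stopifnot(all(g_ab >= 0), all(g_ab <= gamma_total + 1e-9))
  100 * g_ab / gamma_total
}

#' Cohesive energy density from surface free energy
#'
#' Empirical power law `e_c = (gamma_s / 0.75)^(3/2)` linking the surface
#' free energy per unit area (mJ/m^2) to the cohesive energy density
#' (MJ/m^3); monotone increasing.
#'
#' @param gamma_total Total surface free energy in mJ/m^2, positive.
#' @return Cohesive energy density in MJ/m^3.
#' @examples
#' cohesive_energy_density(17.4) # Eucalyptus leaf, 111.8
#' @export
cohesive_energy_density <- function(gamma_total) {
  if (any(!is.finite(gamma_total)) || any(gamma_total <= 0)) {
    abort("gamma_total must be positive", class = "phytosol_domain_error")
  }
  (gamma_total / 0.75)^1.5
}

#' Surface solubility parameter
#'
#' Square root of the cohesive energy density.
#'
#' @param e_c Cohesive energy density in MJ/m^3, non-negative.
#' @return Solubility parameter in MJ^(1/2) m^(-3/2).
#' @examples
#' delta_theta(cohesive_energy_density(32.7)) # pepper fruit, 17.0
#' @export
delta_theta <- function(e_c) {
  stopifnot(all(e_c >= 0))
  sqrt(e_c)
}
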