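# Built-in registry of cuticular constituents and agrochemicals.

registry_path <- function(file) {
  system.file("extdata", file, package = "phytosol", mustWork = TRUE)
}

.registry_env <- new.env(parent = emptyenv())

load_registry <- function() {
  if (is.null(.registry_env$compounds)) {
    raw <- jsonlite::fromJSON(registry_path("compounds.json"),
                              simplifyVector = FALSE)
    .registry_env$compounds <- purrr::map_dfr(raw$compounds, function(rec) {
      tibble::tibble(
        name = rec$name,
        formula = rec$formula,
        molar_volume = rec$molar_volume,
        role = rec$role,
        activity = rec$activity %||% NA_character_,
        symmetry_planes = rec$symmetry_planes,
        supplementary = isTRUE(rec$supplementary),
        surfaces = list(unlist(rec$surfaces) %||% character()),
        groups = list(unlist(rec$groups)),
        printed_d = rec$printed$delta_d %||% NA_real_,
        printed_p = rec$printed$delta_p %||% NA_real_,
        printed_h = rec$printed$delta_h %||% NA_real_,
        printed_total = rec$printed$delta_total %||% NA_real_,
        ester_sites = rec$ester_sites %||% NA_integer_,
        variant_names = list(rec$variant_names %||% NULL),
        variants_printed = list(rec$variants_printed %||% NULL),
        notes = rec$notes %||% ""
      )
    })
  }
  .registry_env$compounds
}

.roles <- c("wax", "agrochemical", "cutin_monomer", "polysaccharide_monomer",
            "other")

#' Built-in compound registry
#'
#' The packaged inventory of dominant epicuticular waxes, model cutin
#' monomers, cell wall polysaccharide monomers and agrochemicals: 30
#' canonical compounds, each with its elemental formula, molar volume,
#' explicit structural-group decomposition, symmetry plane count and the
#' reference (printed) solubility parameter values where reported.
#'
#' @param role Optional filter, one of `"wax"`, `"agrochemical"`,
#'   `"cutin_monomer"`, `"polysaccharide_monomer"`, `"other"`.
#' @param include_supplementary Also return supplementary cross-reference
#'   records (e.g. the C26 aldehyde hexacosanal) that sit outside the
#'   canonical inventory. Default `FALSE`.
#' @return A tibble, one row per compound, with list columns `groups`
#'   (named counts) and `surfaces` (model surfaces a wax belongs to),
#'   printed reference values in `printed_d`/`printed_p`/`printed_h`/
#'   `printed_total`, and esterification metadata for cutin monomers.
#' @examples
#' builtin_compounds("wax")
#' @export
builtin_compounds <- function(role = NULL, include_supplementary = FALSE) {
  reg <- load_registry()
  if (!include_supplementary) reg <- reg[!reg$supplementary, ]
  if (!is.null(role)) {
    if (!role %in% .roles) {
      abort(paste0("unknown role filter '", role, "'; valid roles: ",
                   paste(.roles, collapse = ", ")),
            class = "phytosol_registry_error")
    }
    reg <- reg[reg$role == role, ]
  }
  reg
}

#' Recompute the registry and check it against the printed values
#'
#' Runs the group-contribution engine over [builtin_compounds()] and joins
#' the printed reference values. A fixture is `verified` when its computed
#' total solubility parameter, rounded to 0.1 (the reference precision),
#' equals the printed total; per-component agreement is reported separately
#' in `match_d`/`match_p`/`match_h` because several printed rows are
#' internally inconsistent (see the registry notes).
#'
#' @inheritParams builtin_compounds
#' @inheritParams hansen_parameters
#' @return A `hansen_tbl` with the computed parameters plus `printed_*`
#'   columns, logical `match_*` columns (NA where nothing is printed) and
#'   `verification` in `{"verified", "non_verified"}`.
#' @examples
#' registry_parameters("wax")
#' @export
registry_parameters <- function(role = NULL, include_supplementary = FALSE,
                                table = group_contributions(),
                                symmetry_mode = c("on_delta_p",
                                                  "on_squared_sum")) {
  reg <- builtin_compounds(role, include_supplementary)
  out <- hansen_parameters(reg, table = table, symmetry_mode = symmetry_mode)
  r1 <- function(x) round(x, 1)
  out$match_d <- r1(out$delta_d) == out$printed_d
  out$match_p <- r1(out$delta_p) == out$printed_p
  out$match_h <- r1(out$delta_h) == out$printed_h
  out$match_total <- r1(out$delta_total) == out$printed_total
  out$verification <- ifelse(is.na(out$match_total), "non_verified",
                             ifelse(out$match_total, "verified",
                                    "non_verified"))
  out
}

# Reference surface energetics of the three model surfaces:
# delta_theta from the contact-angle pipeline (printed values) and the
# dominant-wax solubility parameter basis (beta-diketone for eucalyptus,
# n-hentriacontane for pepper, n-alkanes for peach).
.builtin_surfaces <- tibble::tribble(
  ~surface,      ~dominant_wax,                  ~delta_wax, ~delta_theta,
  "eucalyptus",  "n-Hentriacontan-14,16-dione",        16.6,         10.6,
  "pepper",      "n-Hentriacontane",                   16.1,         17.0,
  "peach",       "n-Nonacosane",                       16.0,         16.8
)

#' Built-in model surfaces
#'
#' The three model plant surfaces with their two solubility parameter bases:
#' `delta_wax` (dominant epicuticular wax compound) and `delta_theta`
#' (derived from contact angle measurements). Values in MJ^(1/2) m^(-3/2).
#'
#' @return A tibble with columns `surface`, `dominant_wax`, `delta_wax`,
#'   `delta_theta`.
#' @export
builtin_surfaces <- function() {
  .builtin_surfaces
}

#' Built-in contact angle measurements
#'
#' Advancing contact angles (mean, sd, n) of water, glycerol and
#' diiodomethane on the adaxial juvenile Eucalyptus globulus leaf, pepper
#' fruit and peach fruit surfaces.
#'
#' @return A tibble with columns `surface`, `liquid`, `theta_mean_deg`,
#'   `theta_sd_deg`, `n`.
#' @export
builtin_contact_angles <- function() {
  read_contact_angles(registry_path("contact_angles.csv"))
}
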