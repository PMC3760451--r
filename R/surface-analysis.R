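# Full surface characterisation from a three-liquid contact angle set.

#' Characterise one surface from its contact angles
#'
#' Chains the vOCG pipeline for a single surface: the apolar probe gives
#' `gamma_lw`, the two polar probes the acid-base pair, then the acid-base
#' component, total surface free energy, polarity, per-liquid work of
#' adhesion, cohesive energy density and the surface solubility parameter.
#'
#' When angle standard deviations are available, uncertainty on every derived
#' quantity is estimated by parametric resampling of the angles from
#' `Normal(mean, sd)` (a fixed seed and the number of draws are part of the
#' configuration; the defaults are 10,000 draws with seed 20121114).
#'
#' @param angles Data frame with one row per probe liquid: columns `liquid`,
#'   `theta_mean_deg`, and optionally `theta_sd_deg`, `n`. Exactly one apolar
#'   and two polar liquids (after matching against `liquids`) are required.
#' @param liquids Probe liquid constants, see [probe_liquids()].
#' @param surface_name Label carried into the result.
#' @param negative_roots Passed to [solve_acid_base()].
#' @param uncertainty Resample angle uncertainty? Default: yes, whenever
#'   every liquid has a finite `theta_sd_deg`.
#' @param n_draws,seed Resampling control.
#' @return A `surface_energy` object: a list with `surface`, `components`
#'   (gamma_lw/plus/minus/ab/total), `polarity`, `cohesive_energy_density`,
#'   `delta_theta`, `work_of_adhesion` (named by liquid), `flags`,
#'   `uncertainty` (NULL or a named vector of resampling sds), `angles`, and
#'   the `liquids` actually used.
#' @examples
#' pepper <- tibble::tibble(
#'   liquid = c("water", "glycerol", "diiodomethane"),
#'   theta_mean_deg = c(83.4, 68.6, 60.8)
#' )
#' analyze_surface(pepper, surface_name = "pepper")
#' @export
analyze_surface <- function(angles, liquids = probe_liquids(),
                            surface_name = "surface",
                            negative_roots = c("square", "clamp"),
                            uncertainty = NULL,
                            n_draws = 10000, seed = 20121114) {
  negative_roots <- match.arg(negative_roots)
  angles <- tibble::as_tibble(angles)
  stopifnot(all(c("liquid", "theta_mean_deg") %in% names(angles)))
  angles <- dplyr::inner_join(angles, liquids, by = "liquid")
  apolar <- angles$gamma_plus == 0 & angles$gamma_minus == 0
  if (sum(apolar) != 1 || sum(!apolar) != 2) {
    abort(paste0("surface '", surface_name, "': need contact angles for ",
                 "exactly one apolar and two polar probe liquids (got ",
                 sum(apolar), " apolar, ", sum(!apolar), " polar)"),
          class = "phytosol_angle_error")
  }
  # water-like probe = the polar liquid with the larger acid component product
  polar <- angles[!apolar, ]
  polar <- polar[order(polar$gamma_plus, decreasing = TRUE), ]
  apolar_row <- as.list(angles[apolar, ])
  polar1 <- as.list(polar[1, ])
  polar2 <- as.list(polar[2, ])

  profile_at <- function(th_apolar, th_w, th_g) {
    g_lw <- gamma_lw_apolar(th_apolar, apolar_row)
    ab <- solve_acid_base(th_w, th_g, g_lw, polar1, polar2,
                          negative_roots = negative_roots)
    g_ab <- gamma_ab(ab$gamma_plus, ab$gamma_minus)
    g_tot <- g_lw + g_ab
    e_c <- cohesive_energy_density(g_tot)
    list(
      gamma_lw = g_lw, gamma_plus = ab$gamma_plus,
      gamma_minus = ab$gamma_minus, gamma_ab = g_ab, gamma_total = g_tot,
      polarity = surface_polarity(g_ab, g_tot),
      cohesive_energy_density = e_c, delta_theta = delta_theta(e_c),
      flags = ab$flags
    )
  }

  th <- c(angles$theta_mean_deg[apolar], polar$theta_mean_deg)
  prof <- profile_at(th[1], th[2], th[3])
  w_a <- setNames(work_of_adhesion(angles$theta_mean_deg,
                                   angles$gamma_total), angles$liquid)

  unc <- NULL
  have_sd <- "theta_sd_deg" %in% names(angles) &&
    all(is.finite(angles$theta_sd_deg))
  if (is.null(uncertainty)) uncertainty <- have_sd
  if (uncertainty && have_sd) {
    sds <- c(angles$theta_sd_deg[apolar], polar$theta_sd_deg)
    draws <- withr_seed(seed, {
      vapply(seq_len(n_draws), function(i) {
        ths <- pmin(pmax(rnorm(3, th, sds), 0.5), 179.5)
        p <- profile_at(ths[1], ths[2], ths[3])
        c(gamma_lw = p$gamma_lw, gamma_plus = p$gamma_plus,
          gamma_minus = p$gamma_minus, gamma_ab = p$gamma_ab,
          gamma_total = p$gamma_total, polarity = p$polarity,
          delta_theta = p$delta_theta)
      }, numeric(7))
    })
    unc <- apply(draws, 1, sd)
  }

  structure(
    list(surface = surface_name,
         components = prof[c("gamma_lw", "gamma_plus", "gamma_minus",
                             "gamma_ab", "gamma_total")],
         polarity = prof$polarity,
         cohesive_energy_density = prof$cohesive_energy_density,
         delta_theta = prof$delta_theta,
         work_of_adhesion = w_a,
         flags = prof$flags,
         uncertainty = unc,
         angles = angles[, intersect(names(angles),
                                     c("liquid", "theta_mean_deg",
                                       "theta_sd_deg", "n"))],
         liquids = angles[, c("liquid", "gamma_total", "gamma_lw",
                              "gamma_plus", "gamma_minus")]),
    class = "surface_energy"
  )
}

# Evaluate an expression under a local RNG seed without touching the global
# RNG stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.surface_energy <- function(x, ...) {
  cmp <- x$components
  cat("Surface energetics of '", x$surface, "' (vOCG, mJ/m^2)\n", sep = "")
  cat(sprintf("  gamma_LW %.2f  gamma+ %.2f  gamma- %.2f  gamma_AB %.2f  gamma %.2f\n",
              cmp$gamma_lw, cmp$gamma_plus, cmp$gamma_minus, cmp$gamma_ab,
              cmp$gamma_total))
  cat(sprintf("  polarity %.1f %%   delta_theta %.1f MJ^1/2 m^-3/2\n",
              x$polarity, x$delta_theta))
  cat("  work of adhesion:",
      paste(sprintf("%s %.1f", names(x$work_of_adhesion),
                    x$work_of_adhesion), collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a surface energy profile
#'
#' @param x A `surface_energy` object.
#' @param ... Unused.
#' @return One row per derived quantity: `surface`, `quantity`, `value`,
#'   `unit`, and the resampling `sd` when available.
#' @method tidy surface_energy
#' @export
tidy.surface_energy <- function(x, ...) {
  q <- c(unlist(x$components), polarity = x$polarity,
         cohesive_energy_density = x$cohesive_energy_density,
         delta_theta = x$delta_theta,
         setNames(x$work_of_adhesion,
                  paste0("work_of_adhesion_", names(x$work_of_adhesion))))
  unit <- c(rep("mJ/m^2", 5), "%", "MJ/m^3", "MJ^1/2 m^-3/2",
            rep("mJ/m^2", length(x$work_of_adhesion)))
  out <- tibble::tibble(surface = x$surface, quantity = names(q),
                        value = unname(q), unit = unit)
  if (!is.null(x$uncertainty)) {
    out$sd <- unname(x$uncertainty[out$quantity])
  }
  out
}

#' One-row summary of a surface energy profile
#'
#' @param x A `surface_energy` object.
#' @param ... Unused.
#' @return A one-row tibble mirroring the canonical surface energetics table
#'   layout.
#' @method glance surface_energy
#' @export
glance.surface_energy <- function(x, ...) {
  cmp <- x$components
  w <- x$work_of_adhesion
  tibble::tibble(
    surface = x$surface,
    gamma_lw = cmp$gamma_lw, gamma_minus = cmp$gamma_minus,
    gamma_plus = cmp$gamma_plus, gamma_ab = cmp$gamma_ab,
    gamma_total = cmp$gamma_total, polarity = x$polarity,
    delta_theta = x$delta_theta,
    w_a_water = unname(w["water"] %|na|% NA_real_),
    w_a_glycerol = unname(w["glycerol"] %|na|% NA_real_),
    w_a_diiodomethane = unname(w["diiodomethane"] %|na|% NA_real_),
    delta_theta_sd = if (is.null(x$uncertainty)) NA_real_ else
      unname(x$uncertainty["delta_theta"]),
    flags = paste(x$flags, collapse = ";")
  )
}

#' Characterise many surfaces from a tidy contact angle table
#'
#' Applies [analyze_surface()] per surface and binds the one-row summaries.
#'
#' @param angles Data frame with columns `surface`, `liquid`,
#'   `theta_mean_deg` and optionally `theta_sd_deg`, `n` (the contact angle
#'   CSV layout, see [read_contact_angles()]).
#' @inheritParams analyze_surface
#' @return A tibble with one row per surface (columns as in
#'   [glance.surface_energy()]).
#' @examples
#' analyze_surfaces(builtin_contact_angles())
#' @export
analyze_surfaces <- function(angles, liquids = probe_liquids(),
                             negative_roots = c("square", "clamp"),
                             uncertainty = NULL, n_draws = 10000,
                             seed = 20121114) {
  angles <- tibble::as_tibble(angles)
  stopifnot("surface" %in% names(angles))
  purrr::map_dfr(split(angles, factor(angles$surface,
                                      levels = unique(angles$surface))),
                 function(a) {
    glance(analyze_surface(a, liquids = liquids, surface_name = a$surface[1],
                           negative_roots = negative_roots,
                           uncertainty = uncertainty, n_draws = n_draws,
                           seed = seed))
  })
}
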