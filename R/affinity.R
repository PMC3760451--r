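# Chemical-surface affinity by solubility parameter difference.

#' Solubility parameter difference
#'
#' `sqrt((delta_a - delta_b)^2) = |delta_a - delta_b|`; symmetric. The
#' smaller the difference, the higher the mutual affinity.
#'
#' @param delta_a,delta_b Total solubility parameters in MJ^(1/2) m^(-3/2),
#'   finite and non-negative.
#' @return Absolute difference, same units.
#' @examples
#' delta_difference(19.5, 17.0) # Genapol X-80 vs pepper fruit, 2.5
#' @export
delta_difference <- function(delta_a, delta_b) {
  stopifnot(all(is.finite(delta_a)), all(is.finite(delta_b)),
            all(delta_a >= 0), all(delta_b >= 0))
  sqrt((delta_a - delta_b)^2)
}

#' Classify miscibility from a solubility parameter difference
#'
#' Greenhalgh-style screening bands: a difference strictly below
#' `miscible_limit` (default 7 MJ^(1/2) m^(-3/2)) suggests miscibility, one
#' strictly above `immiscible_limit` (default 10) immiscibility; everything
#' between, boundaries included, is intermediate. Band boundaries can be
#' tuned but must stay ordered.
#'
#' @param delta_diff Non-negative difference(s) in MJ^(1/2) m^(-3/2).
#' @param miscible_limit,immiscible_limit Band edges, `0 < miscible_limit <
#'   immiscible_limit`.
#' @return Factor with levels `miscible`, `intermediate`, `immiscible`.
#' @examples
#' classify_miscibility(c(2.5, 8.5, 13))
#' @export
classify_miscibility <- function(delta_diff, miscible_limit = 7,
                                 immiscible_limit = 10) {
  if (any(!is.finite(delta_diff)) || any(delta_diff < 0)) {
    abort("delta_diff must be non-negative",
          class = "phytosol_domain_error")
  }
  stopifnot(miscible_limit > 0, immiscible_limit > miscible_limit)
  cls <- ifelse(delta_diff < miscible_limit, "miscible",
                ifelse(delta_diff > immiscible_limit, "immiscible",
                       "intermediate"))
  factor(cls, levels = c("miscible", "intermediate", "immiscible"))
}

#' Affinity screen of chemicals against surfaces
#'
#' Crosses every chemical with every surface/basis pair, computes the
#' solubility parameter difference and classifies it. Two bases are
#' supported per surface: `wax` (against the dominant epicuticular wax,
#' `delta_wax`) and `contact_angle` (against the contact-angle-derived
#' surface value, `delta_theta`); a surface may supply either or both.
#'
#' @param chemicals Data frame with columns `name` (or `chemical`) and
#'   `delta` (total solubility parameter); an optional `uncertainty` column
#'   is carried through.
#' @param surfaces Data frame with column `surface` and one or both of
#'   `delta_wax`, `delta_theta`; an optional `delta_theta_sd` feeds the
#'   record uncertainty on the contact-angle basis. Defaults to the built-in
#'   surfaces, see [builtin_surfaces()].
#' @param miscible_limit,immiscible_limit Screening bands, see
#'   [classify_miscibility()].
#' @return An `affinity_tbl` tibble with columns `chemical`, `surface`,
#'   `basis`, `delta_chemical`, `delta_surface`, `delta_diff`, `miscibility`,
#'   `uncertainty`.
#' @examples
#' chem <- tibble::tibble(name = c("urea", "Genapol X-80"),
#'                        delta = c(29.0, 19.5))
#' affinity_screen(chem)
#' @export
affinity_screen <- function(chemicals, surfaces = builtin_surfaces(),
                            miscible_limit = 7, immiscible_limit = 10) {
  chemicals <- tibble::as_tibble(chemicals)
  surfaces <- tibble::as_tibble(surfaces)
  if (!nrow(chemicals) || !nrow(surfaces)) {
    abort("affinity_screen needs at least one chemical and one surface",
          class = "phytosol_domain_error")
  }
  if ("chemical" %in% names(chemicals) && !"name" %in% names(chemicals)) {
    chemicals$name <- chemicals$chemical
  }
  if ("delta_total" %in% names(chemicals) && !"delta" %in% names(chemicals)) {
    chemicals$delta <- chemicals$delta_total
  }
  stopifnot(all(c("name", "delta") %in% names(chemicals)),
            "surface" %in% names(surfaces),
            any(c("delta_wax", "delta_theta") %in% names(surfaces)))

  basis_cols <- c(wax = "delta_wax", contact_angle = "delta_theta")
  basis_cols <- basis_cols[basis_cols %in% names(surfaces)]
  surf_long <- purrr::imap_dfr(basis_cols, function(col, basis_name) {
    sdv <- if (basis_name == "contact_angle" &&
               "delta_theta_sd" %in% names(surfaces)) {
      surfaces$delta_theta_sd
    } else {
      rep(NA_real_, nrow(surfaces))
    }
    tibble::tibble(
      surface = surfaces$surface, basis = basis_name,
      delta_surface = surfaces[[col]],
      delta_surface_sd = sdv
    )
  })
  surf_long <- surf_long[is.finite(surf_long$delta_surface), ]

  out <- tidyr::crossing(
    tibble::tibble(chemical = chemicals$name,
                   delta_chemical = chemicals$delta),
    surf_long
  )
  out$delta_diff <- delta_difference(out$delta_chemical, out$delta_surface)
  out$miscibility <- classify_miscibility(out$delta_diff, miscible_limit,
                                          immiscible_limit)
  out$uncertainty <- out$delta_surface_sd
  out$delta_surface_sd <- NULL
  out <- dplyr::arrange(out, .data$surface, .data$basis, .data$delta_diff)
  class(out) <- c("affinity_tbl", class(out))
  out
}

#' @export
print.affinity_tbl <- function(x, ...) {
  cat("# Affinity screen (delta differences, MJ^1/2 m^-3/2;",
      "smaller = higher affinity)\n")
  NextMethod()
}

#' Bar chart of an affinity screen
#'
#' One panel per surface; bars give the solubility parameter difference of
#' each chemical, coloured by basis (dominant-wax vs contact-angle), with
#' error bars where uncertainty is available and dashed lines at the
#' miscibility band edges.
#'
#' @param object An `affinity_tbl` from [affinity_screen()].
#' @param miscible_limit,immiscible_limit Band edges to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot affinity_tbl
#' @export
autoplot.affinity_tbl <- function(object, miscible_limit = 7,
                                  immiscible_limit = 10, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$chemical, .data$delta_diff),
    y = .data$delta_diff, fill = .data$basis
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$delta_diff - .data$uncertainty,
                   ymax = .data$delta_diff + .data$uncertainty),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3,
      na.rm = TRUE
    ) +
    ggplot2::geom_hline(yintercept = c(miscible_limit, immiscible_limit),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$surface)) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_grey(start = 0.7, end = 0.3) +
    ggplot2::labs(x = NULL, y = "delta difference (MJ^1/2 m^-3/2)",
                  fill = "basis")
}
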