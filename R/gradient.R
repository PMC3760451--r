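# Cuticle solubility parameter gradient report.
#
# The cuticle is layered: epicuticular wax layer (EWL) at the air interface,
# cuticle proper (CP: waxes + cutin), cuticular layer (CL: cutin + a high
# polysaccharide content) and finally the cell wall. Because waxes carry the
# lowest solubility parameters, cutin esterification variants intermediate
# ones, and polysaccharides by far the highest, the layer-wise delta ranges
# increase with depth - a solubility gradient from the hydrophobic surface
# towards the hydrophilic cell wall.

best_delta <- function(params) {
  ifelse(is.finite(params$printed_total), params$printed_total,
         round(params$delta_total, 1))
}

#' Cuticle solubility parameter gradient profile
#'
#' Builds the layer-by-layer delta ranges from registry values: EWL from the
#' wax fixtures, CP from waxes plus cutin esterification variants, CL from
#' cutin variants plus polysaccharide monomers, and the cell wall from the
#' polysaccharide monomers alone. Printed reference values are used where
#' available, computed ones otherwise (rounded to 0.1).
#'
#' @param waxes,cutin,polysaccharides Optional replacement tables carrying
#'   `delta_total` (and optionally `printed_total`) columns; defaults to the
#'   built-in registry and its esterification variants.
#' @return A `gradient_profile` tibble with columns `layer` (ordered factor:
#'   `epicuticular_wax`, `cuticle_proper`, `cuticular_layer`, `cell_wall`),
#'   `delta_min`, `delta_max`, `delta_mid`, `n_constituents`,
#'   `constituents` (list column of names). Degenerate registries (a single
#'   constituent class) yield a single-layer profile with a warning.
#' @examples
#' gradient_profile()
#' @export
gradient_profile <- function(waxes = registry_parameters("wax"),
                             cutin = all_esterification_variants(),
                             polysaccharides =
                               registry_parameters("polysaccharide_monomer")) {
  pools <- list(wax = waxes, cutin = cutin,
                polysaccharide = polysaccharides)
  pools <- purrr::map(pools, function(p) {
    if (is.null(p) || !nrow(p)) return(NULL)
    p <- tibble::as_tibble(p)
    if (!"printed_total" %in% names(p)) p$printed_total <- NA_real_
    tibble::tibble(name = p$name, delta = best_delta(p))
  })
  pools <- purrr::compact(pools)
  if (!length(pools)) {
    abort("empty registry: no constituents to build a gradient from",
          class = "phytosol_registry_error")
  }
  layer_members <- list(
    epicuticular_wax = "wax",
    cuticle_proper = c("wax", "cutin"),
    cuticular_layer = c("cutin", "polysaccharide"),
    cell_wall = "polysaccharide"
  )
  if (length(pools) == 1) {
    warn(paste0("only ", names(pools), " constituents available: ",
                "degenerate single-layer gradient profile"))
    layer_members <- switch(names(pools),
      wax = layer_members["epicuticular_wax"],
      cutin = layer_members["cuticle_proper"][1],
      polysaccharide = layer_members["cell_wall"]
    )
  }
  rows <- purrr::imap_dfr(layer_members, function(members, layer) {
    members <- intersect(members, names(pools))
    if (!length(members)) return(NULL)
    pool <- dplyr::bind_rows(pools[members])
    tibble::tibble(
      layer = layer,
      delta_min = min(pool$delta), delta_max = max(pool$delta),
      delta_mid = (min(pool$delta) + max(pool$delta)) / 2,
      n_constituents = nrow(pool),
      constituents = list(pool$name)
    )
  })
  rows$layer <- factor(rows$layer, levels = names(layer_members),
                       ordered = TRUE)
  class(rows) <- c("gradient_profile", class(rows))
  rows
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat("Cuticle solubility parameter gradient (MJ^1/2 m^-3/2),",
      "surface -> cell wall:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-18s delta in [%.1f, %.1f]  (%d constituents)\n",
                as.character(x$layer[i]), x$delta_min[i], x$delta_max[i],
                x$n_constituents[i]))
  }
  invisible(x)
}

#' Gradient profile as plain text
#'
#' @param x A `gradient_profile`.
#' @return The report lines, invisibly printable, as a character vector.
#' @export
format_gradient_report <- function(x) {
  c("Cuticle solubility parameter gradient (MJ^1/2 m^-3/2)",
    "layers ordered from the air interface towards the cell wall:",
    vapply(seq_len(nrow(x)), function(i) {
      sprintf("%-18s [%5.1f, %5.1f]  constituents: %s",
              as.character(x$layer[i]), x$delta_min[i], x$delta_max[i],
              paste(x$constituents[[i]], collapse = "; "))
    }, character(1)))
}

#' Layered range plot of the cuticle solubility gradient
#'
#' @param object A `gradient_profile` from [gradient_profile()].
#' @param ... Unused.
#' @return A ggplot object: one horizontal delta range per layer, depth
#'   increasing downwards.
#' @method autoplot gradient_profile
#' @export
autoplot.gradient_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$layer <- factor(df$layer, levels = rev(levels(object$layer)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$layer)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$delta_min, xmax = .data$delta_max),
      height = 0.25
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$delta_mid), size = 2) +
    ggplot2::labs(x = "solubility parameter (MJ^1/2 m^-3/2)", y = NULL,
                  title = "Solubility gradient across the cuticle")
}
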