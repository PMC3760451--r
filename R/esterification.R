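# Cutin monomer esterification variants.
#
# A cutin monomer with s esterifiable sites (the carboxylic acid plus its
# free hydroxyls) can take part in k = 2..s ester bonds inside the polyester
# network. Per monomer the k-bond variant is generated by replacing the
# -COOH with an ester -COO- (1 bond) and converting k-1 hydroxyls to ester
# oxygens -O- (the alkoxy half of a bond to a neighbouring monomer);
# remaining hydroxyls stay free. More ester bonds mean fewer free -OH, a
# lower hydrogen-bonding component and a strictly lower total solubility
# parameter. The free-acid molar volume is reused for every variant (no
# reference volumes exist for the esterified forms; an approximation).

#' Built-in cutin monomers
#'
#' The cutin monomer subset of the registry with esterification metadata.
#'
#' @return A tibble as in [builtin_compounds()] restricted to cutin
#'   monomers; `ester_sites` gives the esterifiable site count.
#' @export
cutin_monomers <- function() {
  builtin_compounds("cutin_monomer")
}

#' Esterification variants of a cutin monomer
#'
#' Generates the k = 2..sites ester-bond variants of a monomer and computes
#' their solubility parameters. Where the registry carries printed reference
#' values for a variant they are joined and checked (total at 0.1).
#'
#' @param monomer A single-row tibble as returned by [cutin_monomers()], or
#'   the name of a built-in cutin monomer.
#' @inheritParams hansen_parameters
#' @return A tibble with one row per variant: `monomer`, `k` (ester bonds),
#'   `variant` (name), `free_oh` (remaining free hydroxyls), the group
#'   inventory, the computed parameters, printed values and `verification`.
#' @examples
#' esterification_variants("16-Hydroxy-hexadecanoic acid")
#' @export
esterification_variants <- function(monomer,
                                    table = group_contributions(),
                                    symmetry_mode = c("on_delta_p",
                                                      "on_squared_sum")) {
  if (is.character(monomer)) {
    reg <- cutin_monomers()
    monomer <- reg[reg$name == monomer, ]
    if (!nrow(monomer)) {
      abort("unknown cutin monomer name", class = "phytosol_registry_error")
    }
  }
  monomer <- tibble::as_tibble(monomer)
  stopifnot(nrow(monomer) == 1)
  sites <- monomer$ester_sites
  if (is.na(sites) || sites < 2) {
    abort("monomer must expose at least two esterifiable sites",
          class = "phytosol_registry_error")
  }
  base <- as_group_counts(monomer$groups[[1]])
  if (!"-COOH" %in% names(base) || base["-COOH"] != 1) {
    abort("cutin monomer inventory must contain exactly one -COOH",
          class = "phytosol_registry_error")
  }
  n_oh <- if ("-OH" %in% names(base)) base[["-OH"]] else 0
  if (n_oh < sites - 1) {
    abort("inventory has fewer free hydroxyls than esterifiable sites",
          class = "phytosol_registry_error")
  }
  vnames <- monomer$variant_names[[1]]
  vprinted <- monomer$variants_printed[[1]]

  specs <- purrr::map_dfr(2:sites, function(k) {
    g <- base
    g["-COOH"] <- 0
    g["-COO-"] <- (if ("-COO-" %in% names(g)) g[["-COO-"]] else 0) + 1
    extra_o <- k - 1
    g["-OH"] <- n_oh - extra_o
    g["-O-"] <- (if ("-O-" %in% names(g)) g[["-O-"]] else 0) + extra_o
    g <- g[g > 0]
    pk <- vprinted[[as.character(k)]]
    tibble::tibble(
      name = vnames[[as.character(k)]] %||%
        paste0(monomer$name, " [", k, " ester bonds]"),
      k = k,
      free_oh = n_oh - extra_o,
      molar_volume = monomer$molar_volume,
      symmetry_planes = monomer$symmetry_planes,
      groups = list(g),
      printed_d = pk$delta_d %||% NA_real_,
      printed_p = pk$delta_p %||% NA_real_,
      printed_h = pk$delta_h %||% NA_real_,
      printed_total = pk$delta_total %||% NA_real_
    )
  })
  out <- hansen_parameters(specs, table = table,
                           symmetry_mode = symmetry_mode)
  out$monomer <- monomer$name
  out$verification <- ifelse(
    is.na(out$printed_total), "non_verified",
    ifelse(round(out$delta_total, 1) == out$printed_total, "verified",
           "non_verified")
  )
  dplyr::relocate(out, "monomer", "name", "k", "free_oh")
}

#' Esterification variants of every built-in cutin monomer
#'
#' @inheritParams esterification_variants
#' @return Row-bound [esterification_variants()] output for all built-in
#'   monomers.
#' @export
all_esterification_variants <- function(table = group_contributions(),
                                        symmetry_mode = c("on_delta_p",
                                                          "on_squared_sum")) {
  reg <- cutin_monomers()
  purrr::map_dfr(seq_len(nrow(reg)), function(i) {
    esterification_variants(reg[i, ], table = table,
                            symmetry_mode = symmetry_mode)
  })
}
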