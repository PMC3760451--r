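# van Krevelen-Hoftyzer structural group constants.

# Canonical labels follow the usual group-contribution notation. F_d and F_p
# are molar attraction constants in (MJ/m^3)^(1/2)/mol; E_h is a hydrogen-bond
# energy in J/mol. The two aromatic rows are phenyl (C6H5-) and phenylene
# (-C6H4-). F_d is negative only for the quaternary >C<.
.group_table <- tibble::tribble(
  ~group,       ~f_d, ~f_p, ~e_h,  ~n_c, ~n_n, ~n_o,
  "-CH3",        420,    0,     0,   1, 0, 0,
  "-CH2-",       270,    0,     0,   1, 0, 0,
  ">CH-",         80,    0,     0,   1, 0, 0,
  "=C<",          70,    0,     0,   1, 0, 0,
  "=CH-",        200,    0,     0,   1, 0, 0,
  ">C<",         -70,    0,     0,   1, 0, 0,
  "phenyl",     1430,  110,     0,   6, 0, 0,
  "phenylene",  1270,  110,     0,   6, 0, 0,
  "-F",          220,    0,     0,   0, 0, 0,
  "-Cl",         450,  550,   400,   0, 0, 0,
  "-OH",         210,  500, 20000,   0, 0, 1,
  "-O-",         100,  400,  3000,   0, 0, 1,
  "-CO-",        290,  770,  2000,   1, 0, 1,
  "-COO-",       390,  490,  7000,   1, 0, 2,
  "-COOH",       530,  420, 10000,   1, 0, 2,
  "-COH",        470,  800,  4500,   1, 0, 1,
  "-CN",         430, 1100,  2500,   1, 1, 0,
  ">N-",          20,  800,  5000,   0, 1, 0,
  "-NH2",        280,    0,  8400,   0, 1, 0,
  "-NH-",        160,  210,  3100,   0, 1, 0
)

# Undecorated aliases accepted in input files and group vectors.
.group_aliases <- c(
  "CH3" = "-CH3", "CH2" = "-CH2-", "CH" = ">CH-", "=C" = "=C<",
  "=CH" = "=CH-", "C" = ">C<", "Cq" = ">C<",
  "C6H5" = "phenyl", "C6H4" = "phenylene",
  "F" = "-F", "Cl" = "-Cl", "OH" = "-OH", "O" = "-O-",
  "CO" = "-CO-", "COO" = "-COO-", "COOH" = "-COOH",
  "COH" = "-COH", "CHO" = "-COH", "-CHO" = "-COH",
  "CN" = "-CN", "N" = ">N-", "NH2" = "-NH2", "NH" = "-NH-"
)

#' Structural group contribution table
#'
#' The 20 van Krevelen-Hoftyzer structural groups with their dispersion
#' (`f_d`) and polar (`f_p`) molar attraction constants in
#' (MJ/m^3)^(1/2)/mol and hydrogen-bond energies (`e_h`) in J/mol, plus the
#' carbon/nitrogen/oxygen atoms each group contributes (used for the
#' formula-consistency check). User groups may be appended via `extra`; they
#' are flagged `canonical = FALSE`.
#'
#' @param extra Optional data frame with columns `group`, `f_d`, `f_p`, `e_h`
#'   (and optionally `n_c`, `n_n`, `n_o`) of additional, non-canonical groups.
#' @return A tibble with columns `group`, `f_d`, `f_p`, `e_h`, `n_c`, `n_n`,
#'   `n_o`, `canonical`.
#' @examples
#' group_contributions()
#' @export
group_contributions <- function(extra = NULL) {
  tab <- dplyr::mutate(.group_table, canonical = TRUE)
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    stopifnot(all(c("group", "f_d", "f_p", "e_h") %in% names(extra)))
    if (any(extra$e_h < 0) || any(extra$f_p < 0)) {
      abort("extra groups must have e_h >= 0 and f_p >= 0",
            class = "phytosol_domain_error")
    }
    for (col in c("n_c", "n_n", "n_o")) {
      if (!col %in% names(extra)) extra[[col]] <- NA_real_
    }
    extra$canonical <- FALSE
    tab <- dplyr::bind_rows(tab, extra[names(tab)])
  }
  tab
}

#' Normalise structural group labels
#'
#' Maps shorthand labels (`"CH3"`, `"CO"`, `"C6H5"`, ...) onto the canonical
#' decorated labels of [group_contributions()]. Canonical labels pass through
#' unchanged; labels known to neither set raise an error naming the offender.
#'
#' @param labels Character vector of group labels.
#' @param table Group table the labels must resolve into.
#' @return Character vector of canonical labels.
#' @export
normalize_group <- function(labels, table = group_contributions()) {
  out <- ifelse(labels %in% names(.group_aliases),
                .group_aliases[labels], labels)
  bad <- setdiff(out, table$group)
  if (length(bad)) {
    abort(paste0("unknown structural group label(s): ",
                 paste(unique(bad), collapse = ", ")),
          class = "phytosol_group_error")
  }
  unname(out)
}

#' Symmetry reduction factor for the polar component
#'
#' Molecular symmetry damps the polar solubility parameter component: one
#' plane of symmetry halves it, two planes quarter it, and more planes cancel
#' it entirely.
#'
#' @param planes Number of symmetry planes: 0, 1, 2, or `Inf`/`"many"` for
#'   more than two.
#' @return Numeric multiplier in `{1, 0.5, 0.25, 0}`.
#' @examples
#' symmetry_factor(1)
#' @export
symmetry_factor <- function(planes) {
  purrr::map_dbl(planes, function(p) {
    if (identical(p, "many")) p <- Inf
    p <- suppressWarnings(as.numeric(p))
    if (is.na(p) || p < 0) {
      abort("symmetry_planes must be 0, 1, 2 or 'many'",
            class = "phytosol_domain_error")
    }
    if (p == 0) 1 else if (p == 1) 0.5 else if (p == 2) 0.25 else 0
  })
}

# Coerce a groups argument (named numeric vector, named list, or two-column
# data frame) to a named count vector with canonical labels.
as_group_counts <- function(groups, table = group_contributions()) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "count") %in% names(groups)))
    groups <- setNames(groups$count, groups$group)
  }
  if (is.list(groups)) groups <- unlist(groups)
  if (length(groups) == 0) {
    abort("empty group inventory", class = "phytosol_group_error")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("groups must be named by structural group label",
          class = "phytosol_group_error")
  }
  if (any(!is.finite(groups)) || any(groups < 1)) {
    abort("group counts must be >= 1", class = "phytosol_group_error")
  }
  labels <- normalize_group(names(groups), table)
  tapply(as.numeric(groups), labels, sum)
}

# C/N/O atoms implied by a group inventory (NA if any group lacks counts).
group_atom_counts <- function(counts, table = group_contributions()) {
  idx <- match(names(counts), table$group)
  c(C = sum(table$n_c[idx] * counts),
    N = sum(table$n_n[idx] * counts),
    O = sum(table$n_o[idx] * counts))
}
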