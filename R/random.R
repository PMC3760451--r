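# Random molecule generator for property-based testing.

#' Generate random molecule specifications
#'
#' Draws reproducible random group inventories for property-based checks:
#' groups sampled from `groups_allowed`, counts uniform on `count_range`,
#' molar volumes uniform on `v_range`, symmetry planes from
#' `symmetry_choices`. No elemental formula is attached (these are abstract
#' inventories, not real molecules).
#'
#' @param n Number of specifications.
#' @param seed Optional seed; the draw is a pure function of it.
#' @param groups_allowed Candidate structural group labels.
#' @param count_range Integer range for per-group counts.
#' @param v_range Molar volume range in cm^3/mol.
#' @param max_groups Maximum number of distinct groups per molecule.
#' @param symmetry_choices Symmetry plane counts to sample from.
#' @return A compounds tibble for [hansen_parameters()].
#' @examples
#' random_molecule(3, seed = 1)
#' @export
random_molecule <- function(n = 1, seed = NULL,
                            groups_allowed = group_contributions()$group,
                            count_range = c(1, 10),
                            v_range = c(50, 600),
                            max_groups = 6,
                            symmetry_choices = c(0, 1, 2)) {
  groups_allowed <- normalize_group(groups_allowed)
  stopifnot(length(groups_allowed) >= 1, count_range[1] >= 1,
            count_range[2] >= count_range[1],
            v_range[1] > 0, v_range[2] >= v_range[1], max_groups >= 1)
  draw <- function() {
    k <- sample(seq_len(min(max_groups, length(groups_allowed))), 1)
    labels <- sample(groups_allowed, k)
    counts <- sample(seq(count_range[1], count_range[2]), k, replace = TRUE)
    tibble::tibble(
      molar_volume = stats::runif(1, v_range[1], v_range[2]),
      symmetry_planes = sample(symmetry_choices, 1),
      groups = list(setNames(as.numeric(counts), labels))
    )
  }
  gen <- function() {
    out <- purrr::map_dfr(seq_len(n), ~ draw())
    out$name <- sprintf("random_%03d", seq_len(n))
    dplyr::relocate(out, "name")
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}
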