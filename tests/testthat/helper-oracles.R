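# Independent oracle implementations used to cross-check the production
# code paths. Deliberately naive: explicit loops, per-row table lookups.

# Group-contribution oracle: loop over every (group, count) pair one unit at
# a time, accumulating the three sums, then assemble the components.
naive_hansen <- function(groups, volume, symmetry_planes = 0,
                         symmetry_mode = "on_delta_p") {
  tab <- as.data.frame(phytosol::group_contributions())
  labels <- phytosol::normalize_group(names(groups))
  sum_fd <- 0
  sum_fp2 <- 0
  sum_eh <- 0
  for (i in seq_along(groups)) {
    row <- tab[tab$group == labels[i], ]
    for (unit in seq_len(groups[[i]])) {
      sum_fd <- sum_fd + row$f_d
      sum_fp2 <- sum_fp2 + row$f_p^2
      sum_eh <- sum_eh + row$e_h
    }
  }
  fac <- if (symmetry_planes == 0) 1 else if (symmetry_planes == 1) 0.5 else
    if (symmetry_planes == 2) 0.25 else 0
  dd <- sum_fd / volume
  dp <- if (symmetry_mode == "on_squared_sum") {
    sqrt(sum_fp2 * fac) / volume
  } else {
    fac * sqrt(sum_fp2) / volume
  }
  dh <- sqrt(sum_eh / volume)
  c(delta_d = dd, delta_p = dp, delta_h = dh,
    delta_total = sqrt(dd^2 + dp^2 + dh^2))
}

# Forward vOCG model: contact angles a surface with the given component
# triple would show against the standard probe liquids.
vocg_forward_angles <- function(gamma_lw, gamma_plus, gamma_minus,
                                liquids = phytosol::probe_liquids()) {
  cos_theta <- vapply(seq_len(nrow(liquids)), function(i) {
    l <- liquids[i, ]
    w <- 2 * (sqrt(gamma_lw * l$gamma_lw) +
                sqrt(gamma_plus * l$gamma_minus) +
                sqrt(gamma_minus * l$gamma_plus))
    w / l$gamma_total - 1
  }, numeric(1))
  stopifnot(all(cos_theta > -1), all(cos_theta < 1))
  tibble::tibble(liquid = liquids$liquid,
                 theta_mean_deg = acos(cos_theta) * 180 / pi)
}

# n-alkane specs (CnH2n+2 = 2 CH3 + (n-2) CH2) with molar volumes on the
# homologous-series line through the packaged C23..C31 values.
alkane_series <- function(n_carbons) {
  v <- 408.1 + (n_carbons - 23) * (540.2 - 408.1) / 8
  tibble::tibble(
    name = paste0("C", n_carbons, "_alkane"),
    formula = paste0("C", n_carbons, "H", 2 * n_carbons + 2),
    molar_volume = v,
    symmetry_planes = 0,
    groups = purrr::map(n_carbons, ~ c(CH3 = 2, CH2 = .x - 2))
  )
}
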