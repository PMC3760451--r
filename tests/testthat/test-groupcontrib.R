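# Group-contribution engine: components, totals, conventions, properties.

r1 <- function(x) round(x, 1)

test_that("the group table carries the canonical constants", {
  tab <- group_contributions()
  expect_equal(nrow(tab), 20)
  expect_true(all(tab$e_h >= 0))
  expect_true(all(tab$f_p >= 0))
  expect_identical(tab$group[tab$f_d < 0], ">C<")
  expect_equal(tab$f_d[tab$group == ">C<"], -70)
  # user extensions are accepted but flagged non-canonical
  ext <- group_contributions(extra = data.frame(group = "-S-", f_d = 440,
                                                f_p = 0, e_h = 0))
  expect_false(ext$canonical[ext$group == "-S-"])
  expect_error(group_contributions(extra = data.frame(group = "bad",
                                                      f_d = 1, f_p = -1,
                                                      e_h = 0)),
               class = "phytosol_domain_error")
})

test_that("dispersion component reproduces reference molecules", {
  expect_equal(r1(delta_dispersion(c(CH3 = 2, CH2 = 27), 507.2)), 16.0)
  expect_equal(r1(delta_dispersion(c(NH2 = 2, CO = 1), 45.2)), 18.8)
  expect_equal(delta_dispersion(c(CH2 = 1), 270), 1.0)
  expect_error(delta_dispersion(c(XYZ = 1), 100), "XYZ",
               class = "phytosol_group_error")
  expect_error(delta_dispersion(numeric(), 100),
               class = "phytosol_group_error")
  expect_error(delta_dispersion(c(CH2 = 1), -5),
               class = "phytosol_domain_error")
})

test_that("polar component applies the symmetry factor per convention", {
  # urea: one plane of symmetry halves an unscaled 17.0 to 8.5
  expect_equal(r1(delta_polar(c(CO = 1), 45.2, symmetry_planes = 1)), 8.5)
  expect_equal(r1(delta_polar(c(CO = 1), 45.2, symmetry_planes = 0)), 17.0)
  # any pure alkane inventory has no polar contribution
  expect_equal(delta_polar(c(CH3 = 2, CH2 = 40), 600), 0)
  # beta-diketone fragment, no symmetry: sqrt(2 * 770^2) / 534.4
  expect_equal(delta_polar(c(CO = 2), 534.4), sqrt(2 * 770^2) / 534.4)
  expect_equal(r1(delta_polar(c(CO = 2), 534.4)), 2.0)
  # alternative convention scales the squared sum instead
  expect_equal(delta_polar(c(CO = 2), 534.4, symmetry_planes = 1,
                           symmetry_mode = "on_squared_sum"),
               sqrt(0.5) * sqrt(2 * 770^2) / 534.4)
  expect_equal(symmetry_factor(c(0, 1, 2, Inf)), c(1, 0.5, 0.25, 0))
  expect_equal(symmetry_factor("many"), 0)
})

test_that("hydrogen-bonding component reproduces reference molecules", {
  expect_equal(r1(delta_hbond(c(NH2 = 2, CO = 1), 45.2)), 20.4)
  expect_equal(delta_hbond(c(CH3 = 2, CH2 = 20), 400), 0)
  expect_equal(r1(delta_hbond(c(CO = 2), 534.4)), 2.7)
})

test_that("total combines components in quadrature", {
  expect_equal(r1(delta_total(18.8, 8.5, 20.4)), 29.0)
  expect_equal(delta_total(16, 0, 0), 16)
  expect_equal(delta_total(3, 4, 12), 13)
})

test_that("hansen_parameters chains the engine over a compound table", {
  compounds <- tibble::tibble(
    name = c("n-heptacosane", "urea"),
    formula = c("C27H56", "CH4N2O"),
    molar_volume = c(474.2, 45.2),
    symmetry_planes = c(0, 1),
    groups = list(c(CH3 = 2, CH2 = 25), c(NH2 = 2, CO = 1))
  )
  out <- hansen_parameters(compounds)
  expect_s3_class(out, "hansen_tbl")
  expect_equal(r1(out$delta_total), c(16.0, 29.0))
  expect_equal(r1(out$delta_d[2]), 18.8)
  expect_equal(out$symmetry_factor, c(1, 0.5))
  expect_identical(out$flags, c("", ""))
})

test_that("negative dispersion components are flagged, not clamped", {
  spec <- tibble::tibble(name = "quaternary", molar_volume = 100,
                         groups = list(c(C = 10, CH3 = 1)))
  out <- hansen_parameters(spec)
  expect_lt(out$delta_d, 0)
  expect_match(out$flags, "negative_delta_d")
})

test_that("formula/group element mismatches warn via a flag", {
  spec <- tibble::tibble(name = "bad", formula = "C2H6O",
                         molar_volume = 50, groups = list(c(CH3 = 2)))
  expect_match(hansen_parameters(spec)$flags, "group_formula_mismatch")
  ok <- tibble::tibble(name = "ethanol", formula = "C2H6O",
                       molar_volume = 58.4,
                       groups = list(c(CH3 = 1, CH2 = 1, OH = 1)))
  expect_identical(hansen_parameters(ok)$flags, "")
})

test_that("explicit molar volume overrides density with a mismatch flag", {
  spec <- tibble::tibble(name = "urea", formula = "CH4N2O",
                         molar_volume = 45.2, density = 1.60,
                         groups = list(c(NH2 = 2, CO = 1)),
                         symmetry_planes = 1)
  out <- hansen_parameters(spec)
  expect_equal(out$molar_volume, 45.2)
  expect_match(out$flags, "volume_density_mismatch")
})

test_that("Pythagorean identity holds on random inventories", {
  specs <- random_molecule(200, seed = 42)
  out <- hansen_parameters(specs)
  expect_equal(out$delta_total^2,
               out$delta_d^2 + out$delta_p^2 + out$delta_h^2,
               tolerance = 1e-9)
})

test_that("n-alkane series is apolar with tightly confined delta_d", {
  series <- hansen_parameters(alkane_series(20:40))
  expect_true(all(series$delta_p == 0))
  expect_true(all(series$delta_h == 0))
  expect_true(all(diff(series$delta_d) > 0))
  # confined to [15.9, 16.4] at the 0.1 reporting precision
  expect_true(all(r1(series$delta_d) >= 15.9 & r1(series$delta_d) <= 16.4))
})

test_that("doubling counts and volume scales components as dimensioned", {
  base <- c(CH3 = 2, CH2 = 10, OH = 1, CO = 1)
  v <- 250
  # dispersion and H-bonding are intensive under joint doubling
  expect_equal(delta_dispersion(base * 2, v * 2), delta_dispersion(base, v))
  expect_equal(delta_hbond(base * 2, v * 2), delta_hbond(base, v))
  # the polar sum of squares doubles under the root, so delta_p shrinks by
  # sqrt(2) - dilution of uncorrelated dipoles
  expect_equal(delta_polar(base * 2, v * 2),
               delta_polar(base, v) / sqrt(2), tolerance = 1e-12)
})

test_that("naive per-unit summation oracle matches the engine exactly", {
  specs <- random_molecule(1000, seed = 20121114)
  out <- hansen_parameters(specs)
  for (i in seq_len(nrow(specs))) {
    oracle <- naive_hansen(specs$groups[[i]], specs$molar_volume[i],
                           specs$symmetry_planes[i])
    expect_equal(out$delta_d[i], oracle[["delta_d"]], tolerance = 1e-12)
    expect_equal(out$delta_p[i], oracle[["delta_p"]], tolerance = 1e-12)
    expect_equal(out$delta_h[i], oracle[["delta_h"]], tolerance = 1e-12)
    expect_equal(out$delta_total[i], oracle[["delta_total"]],
                 tolerance = 1e-12)
  }
})
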