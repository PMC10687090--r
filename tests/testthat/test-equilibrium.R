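test_that("molar conversion handles the mg/ml to mol/L bookkeeping", {
  expect_equal(molar_from_mass_conc(30.5, 30500), 1e-3, tolerance = 1e-12)
  expect_equal(molar_from_mass_conc(1, 30500), 3.279e-5, tolerance = 1e-4)
  expect_equal(molar_from_mass_conc(6.38, 30500), 2.092e-4, tolerance = 1e-3)
  expect_error(molar_from_mass_conc(0), "positive")
  expect_error(molar_from_mass_conc(1, -1), "positive")
})

test_that("mass action: conservation, equilibrium constant and limits", {
  withr::with_seed(42, {
    kd <- 10^runif(200, -8, -2)
    m0 <- 10^runif(200, -7, -1)
    M <- monomer_conc(kd, m0)
    D <- (m0 - M) / 2
    expect_lt(max(abs(M + 2 * D - m0) / m0), 1e-12)     # [M] + 2[D] = [M]0
    expect_lt(max(abs(M^2 / D - kd) / kd), 1e-10)       # [M]^2/[D] = KD
  })
  expect_equal(monomer_conc(1e-5, 1e-5), 0.5e-5, tolerance = 1e-12)
  expect_equal(monomer_fraction(1e-5, 1e-5), 0.5, tolerance = 1e-12)
  expect_equal(monomer_conc(1e-5, 1e-12), 1e-12, tolerance = 1e-5)
  expect_equal(monomer_fraction(1e2, 1e-6), 1, tolerance = 1e-6)
  expect_lt(monomer_fraction(1e-12, 1e-3), 1e-4)
  # frozen oracle: numerical root of 2x^2 + K x - K m0 at kd=30uM, m0=209.2uM
  expect_equal(monomer_conc(30e-6, 209.2e-6), 4.901769e-5, tolerance = 1e-6)
})

test_that("apparent Rg^2 interpolates between the species values", {
  pair <- glyco_pairs$double
  expect_equal(apparent_rg2(1, pair), pair$rg_m^2)
  expect_equal(apparent_rg2(0, pair), pair$rg_d^2)
  expect_equal(sqrt(apparent_rg2(0.1206, pair)), 30.40, tolerance = 1e-4)
  f <- seq(0, 1, length.out = 101)
  r2 <- apparent_rg2(f, pair)
  expect_true(all(diff(r2) < 0))                        # monotone decreasing
  expect_true(all(r2 >= pair$rg_m^2 & r2 <= pair$rg_d^2))
  expect_error(apparent_rg2(1.2, pair), "f_m")
})

test_that("closed-form Rg^2(c) equals the composed model path", {
  withr::with_seed(7, {
    for (pname in names(glyco_pairs)) {
      kd <- 10^runif(100, -8, -3)
      m0 <- 10^runif(100, -7, -2)
      direct <- rg2_vs_concentration(m0, kd, pname)
      composed <- apparent_rg2(monomer_fraction(kd, m0), pname)
      expect_lt(max(abs(direct - composed) / composed), 1e-10)
    }
  })
  # limits
  expect_equal(rg2_vs_concentration(1e3, 1e-6, "double"),
               glyco_pairs$double$rg_d^2, tolerance = 1e-3)
  expect_equal(rg2_vs_concentration(1e-12, 1e-3, "double"),
               glyco_pairs$double$rg_m^2, tolerance = 1e-3)
  # monotone in m0 and in 1/kd
  m0 <- 10^seq(-7, -2, length.out = 50)
  expect_true(all(diff(rg2_vs_concentration(m0, 2e-5, "single")) > 0))
  kd <- 10^seq(-8, -3, length.out = 50)
  expect_true(all(diff(rg2_vs_concentration(1e-4, kd, "single")) < 0))
})

test_that("dimer fraction inversion reproduces the published worked example", {
  # observed Rg 30.4 A with the fully glycosylated pool values -> 88%
  expect_equal(dimer_mass_fraction_from_rg(30.4, "double"), 0.879,
               tolerance = 1e-3)
  expect_equal(dimer_mass_fraction_from_rg(glyco_pairs$double$rg_m, "double"), 0)
  expect_equal(dimer_mass_fraction_from_rg(glyco_pairs$double$rg_d, "double"), 1)
})

test_that("inversion is the inverse of the forward mixture relation", {
  withr::with_seed(1, {
    f <- runif(100)
    for (pname in names(glyco_pairs)) {
      rg <- sqrt(apparent_rg2(f, pname))
      back <- vapply(rg, dimer_mass_fraction_from_rg, numeric(1), pair = pname)
      expect_lt(max(abs(back - (1 - f))), 1e-10)
    }
  })
})

test_that("out-of-range observed Rg clamps within 2% and errors beyond", {
  pair <- glyco_pairs$none  # rg_d = 29.55
  expect_warning(v <- dimer_mass_fraction_from_rg(29.9, pair), "clamped")
  expect_equal(v, 1)
  expect_error(dimer_mass_fraction_from_rg(31.0, pair), "outside")
  expect_error(dimer_mass_fraction_from_rg(20.0, pair), "outside")
})

test_that("dimer mole fraction: closed form equals species bookkeeping", {
  expect_equal(dimer_mole_fraction(1e-5, 1e-5), 1 / 3, tolerance = 1e-12)
  expect_equal(dimer_mole_fraction(1e-12, 1e-3), 1, tolerance = 1e-4)
  expect_equal(dimer_mole_fraction(30e-6, 209.2e-6), 0.620, tolerance = 1e-3)
  withr::with_seed(9, {
    kd <- 10^runif(100, -8, -3); m0 <- 10^runif(100, -7, -2)
    xdm <- runif(100, 0.2, 1)
    M <- monomer_conc(kd, m0); D <- (m0 - M) / 2
    via_species <- xdm * D / (M + D)
    expect_lt(max(abs(dimer_mole_fraction(kd, m0, xdm) - via_species) /
                    via_species), 1e-10)
  })
})

test_that("binding free energy follows RT ln KD on the 1 M standard state", {
  expect_equal(binding_free_energy(40e-6, 310.15), -26.1, tolerance = 1e-2)
  expect_equal(binding_free_energy(40e-6, 298.15), -25.1, tolerance = 1e-2)
  expect_equal(binding_free_energy(1, 310.15), 0)
})

test_that("extended chain span scales with residues and pitch", {
  expect_equal(extended_chain_span(2700, 2.5), 0.675)
  expect_equal(extended_chain_span(1, 2.5), 2.5e-4)
  expect_equal(extended_chain_span(2000, 4.0), 0.8)
})

test_that("glyco pair constructor and constants are validated", {
  expect_error(glyco_pair(30, 25), "rg_d > rg_m")
  for (p in glyco_pairs) expect_gt(p$rg_d, p$rg_m)
  expect_equal(glyco_pairs$none$rg_m, 21.94)
  expect_equal(glyco_pairs$single$rg_d, 30.38)
})
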