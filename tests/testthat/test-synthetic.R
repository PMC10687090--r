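test_that("globules hit their target Rg exactly and are seed-deterministic", {
  g1 <- make_globule(200, 22.5, seed = 1)
  expect_equal(coordinate_rg(g1), 22.5, tolerance = 1e-9)
  g2 <- make_globule(200, 22.5, seed = 1)
  expect_identical(g1$coordinates, g2$coordinates)
  g3 <- make_globule(200, 30.8, seed = 4)
  expect_equal(coordinate_rg(g3), 30.8, tolerance = 1e-9)
  expect_false(identical(g1$coordinates, make_globule(200, 22.5, seed = 2)$coordinates))
})

test_that("coordinate Rg matches closed forms", {
  expect_equal(coordinate_rg(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(coordinate_rg(matrix(c(0, 0, 0, 4, 0, 0), 2, byrow = TRUE)), 2)
  # uniform sampling in a sphere of radius R: Rg -> sqrt(3/5) R
  withr::with_seed(8, {
    v <- matrix(rnorm(3 * 20000), ncol = 3)
    v <- v / sqrt(rowSums(v^2)) * runif(20000)^(1 / 3) * 10
    expect_equal(coordinate_rg(v), sqrt(3 / 5) * 10, tolerance = 0.02)
  })
})

test_that("dimer construction doubles beads, grows Rg, warns on clash", {
  mono <- make_globule(100, 20, seed = 2)
  d <- make_dimer(mono, 40)
  expect_equal(nrow(d$coordinates), 200)
  expect_gt(coordinate_rg(d), coordinate_rg(mono))
  # a protomer with beads on the symmetry axis clashes with its mirror copy
  line <- structure(list(coordinates = cbind(seq(0, 11), 0, 0),
                         label = "rod"), class = "bead_model")
  expect_warning(make_dimer(line, 0.5), "steric")
  # separation tuned by bisection reaches the glycosylated-pool Rg ratio
  sep <- dimer_separation_for_ratio(mono, 30.84 / 23.05)
  dd <- suppressWarnings(make_dimer(mono, sep))
  expect_equal(coordinate_rg(dd) / coordinate_rg(mono), 30.84 / 23.05,
               tolerance = 1e-5)
})

test_that("Debye curves obey closed forms and the Guinier limit", {
  q <- seq(0.01, 0.5, length.out = 60)
  one <- structure(list(coordinates = matrix(0, 1, 3), label = "bead"),
                   class = "bead_model")
  expect_equal(debye_curve(one, q)$intensity, rep(1, 60))
  two <- structure(list(coordinates = matrix(c(0, 0, 0, 5, 0, 0), 2,
                                             byrow = TRUE), label = "pair"),
                   class = "bead_model")
  expect_equal(debye_curve(two, q)$intensity, 2 + 2 * sin(q * 5) / (q * 5),
               tolerance = 1e-12)
  # I(0) = N^2 and positivity for a compact globule
  glob <- make_globule(150, 25, seed = 3)
  cv <- debye_curve(glob, seq(0.001, 0.5, length.out = 200))
  expect_true(all(cv$intensity > 0))
  expect_equal(cv$intensity[1], 150^2, tolerance = 1e-3)
  # Guinier Rg of the curve vs coordinate Rg: sub-1% in the true Guinier
  # limit (qRg <= 0.9); the compact globule carries the hard-sphere-like
  # positive bias at the conventional qRg <= 1.3 window
  rgc <- coordinate_rg(glob)
  g <- guinier_fit(cv, c(1L, max(which(cv$q * rgc <= 0.9))))
  expect_equal(g$rg, rgc, tolerance = 0.01)
  expect_equal(auto_guinier(cv)$rg, rgc, tolerance = 0.02)
})

test_that("simulated series follows the mass-action z-average prediction", {
  pair <- make_test_pair(n_beads = 80)
  kd <- 3e-5
  sim <- simulate_series(kd, table1_concs, pair$monomer, pair$dimer,
                         noise = NULL,
                         q_grid = seq(0.005, 0.3, length.out = 256))
  eff <- glyco_pair(coordinate_rg(pair$monomer), coordinate_rg(pair$dimer))
  for (i in seq_along(sim$points)) {
    cv <- sim$points[[i]]$curve
    pred2 <- rg2_vs_concentration(
      molar_from_mass_conc(sim$points[[i]]$c), kd, eff)
    # Guinier-limit window (qRg <= 0.8): the z-average prediction is the
    # q -> 0 limit of the mixture curve
    g <- guinier_fit(cv, c(1L, max(which(cv$q * sqrt(pred2) <= 0.8))))
    expect_equal(g$rg^2, pred2, tolerance = 0.02)
  }
})

test_that("mixture forward scattering carries the (2 - f_M) weighting", {
  pair <- make_test_pair(n_beads = 80)
  sim <- simulate_series(3e-5, table1_concs, pair$monomer, pair$dimer,
                         noise = NULL,
                         q_grid = seq(0.002, 0.3, length.out = 256))
  f_m <- attr(sim, "truth")$f_m
  i0_per_mass <- vapply(seq_along(sim$points), function(i) {
    auto_guinier(sim$points[[i]]$curve)$i0 / sim$points[[i]]$c
  }, numeric(1))
  expect_equal(i0_per_mass / (2 - f_m),
               rep(mean(i0_per_mass / (2 - f_m)), 8), tolerance = 1e-3)
})

test_that("infinite-dilution limit reduces to the monomer curve", {
  pair <- make_test_pair(n_beads = 60)
  q <- seq(0.005, 0.3, length.out = 128)
  sim <- simulate_series(1e3, c(1, 2), pair$monomer, pair$dimer,
                         noise = NULL, q_grid = q)
  sm <- debye_curve(pair$monomer, q)$intensity
  I1 <- sim$points[[1]]$curve$intensity
  ratio <- I1 / sm
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-4)
})

test_that("noise is seed-deterministic and scales as stated", {
  pair <- make_test_pair(n_beads = 60)
  q <- seq(0.005, 0.3, length.out = 128)
  nm <- noise_model(a = 0.01, b = 0.002, seed = 99)
  s1 <- simulate_series(3e-5, c(1, 4), pair$monomer, pair$dimer, noise = nm,
                        q_grid = q)
  s2 <- simulate_series(3e-5, c(1, 4), pair$monomer, pair$dimer, noise = nm,
                        q_grid = q)
  expect_identical(s1$points[[1]]$curve$intensity,
                   s2$points[[1]]$curve$intensity)
  s0 <- simulate_series(3e-5, c(1, 4), pair$monomer, pair$dimer, noise = NULL,
                        q_grid = q)
  I <- s0$points[[2]]$curve$intensity
  expect_equal(s1$points[[2]]$curve$sigma, nm$a * sqrt(I / 4) + nm$b,
               tolerance = 1e-12)
})
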