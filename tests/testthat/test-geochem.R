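test_that("DepthProfile enforces its invariants", {
  expect_error(DepthProfile("O2", c(0, 1), c(1, 2)), "3 depth points")
  expect_error(DepthProfile("O2", c(0, 1, 0.5), c(1, 2, 3)), "increasing")
  expect_error(DepthProfile("O2", c(0, 1, 2), c(1, -2, 3)), "non-negative")
  expect_error(DepthProfile("pH", c(0, 1, 2), c(7, 15, 7)), "pH")
  expect_error(DepthProfile("O2", c(0, 1, 2), c(1, 2, 3), porosity = 1.2),
               "porosity")
  expect_s4_class(DepthProfile("O2", 0:2, c(250, 100, 0)), "DepthProfile")
})

test_that("total sulfide speciation follows the pH-dependent closed form", {
  d <- c(10, 12, 14)
  h2s <- DepthProfile("H2S", d, rep(10, 3))
  # at pH = pK1, H2S and HS- are equal: total doubles
  ph_eq <- DepthProfile("pH", d, rep(6.6, 3))
  expect_equal(profileValues(sumH2S(h2s, ph_eq, pK1 = 6.6)), rep(20, 3))
  # one pH unit above pK1: 10 * (1 + 10) = 110
  ph_hi <- DepthProfile("pH", d, rep(7.6, 3))
  expect_equal(profileValues(sumH2S(h2s, ph_hi, pK1 = 6.6)), rep(110, 3))
  # zero free sulfide stays zero at any pH
  zero <- DepthProfile("H2S", d, rep(0, 3))
  expect_equal(profileValues(sumH2S(zero, ph_hi)), rep(0, 3))
})

test_that("speciation dominates free sulfide and increases with pH", {
  set.seed(42)
  d <- seq(5, 20, by = 0.5)
  h2s <- DepthProfile("H2S", d, runif(length(d), 0, 50))
  for (ph_level in c(6, 7, 8)) {
    ph <- DepthProfile("pH", d, rep(ph_level, length(d)))
    tot <- profileValues(sumH2S(h2s, ph))
    expect_true(all(tot >= profileValues(h2s)))
  }
  ratio <- function(p) profileValues(sumH2S(h2s, DepthProfile("pH", d, rep(p, length(d))))) /
    pmax(profileValues(h2s), 1e-12)
  expect_true(all(ratio(8) > ratio(7) & ratio(7) > ratio(6)))
})

test_that("speciation requires overlapping depth grids and a finite pK1", {
  h2s <- DepthProfile("H2S", c(10, 12, 14), rep(5, 3))
  ph_far <- DepthProfile("pH", c(30, 32, 34), rep(7, 3))
  expect_error(sumH2S(h2s, ph_far), "overlap")
  ph <- DepthProfile("pH", c(10, 12, 14), rep(7, 3))
  expect_error(sumH2S(h2s, ph, pK1 = NULL), "pK1")
})

test_that("Fick flux reduces to free solution at porosity 1 and scales linearly", {
  d <- seq(0, 2, by = 0.1)
  D <- 1e-4
  s <- 30  # umol L-1 mm-1 decrease
  prof <- DepthProfile("O2", d, 100 - s * d + s * 2, porosity = 1)
  fl <- fickFlux(prof, D = D, window = c(0, 2))
  # phi = 1: tortuosity factor 1, J = D * |slope| (in SI units, downward +)
  expect_equal(fl@tortuosityFactor, 1)
  expect_equal(fluxValue(fl), D * s * 1000, tolerance = 1e-12)
  # linear in slope and D: doubling both quadruples J
  prof2 <- DepthProfile("O2", d, 2 * (100 - s * d + s * 2), porosity = 1)
  fl4 <- fickFlux(prof2, D = 2 * D, window = c(0, 2))
  expect_equal(fluxValue(fl4) / fluxValue(fl), 4, tolerance = 1e-12)
})

test_that("tortuosity factor matches the porosity formula and is monotone", {
  expect_equal(tortuosityFactor(0.88), 1 - 2 * log(0.88))
  expect_equal(tortuosityFactor(0.88), 1.2556667, tolerance = 1e-7)
  expect_equal(tortuosityFactor(1), 1)
  phis <- seq(0.3, 1, by = 0.05)
  expect_true(all(diff(tortuosityFactor(phis)) < 0))
  expect_error(tortuosityFactor(0), "porosity")
  expect_error(tortuosityFactor(1.1), "porosity")
})

test_that("a planted linear profile returns the analytic flux to 1e-9 relative", {
  # generator inversion: choose slope so that phi*D/(1-2 ln phi)*slope gives
  # the target uptake of 35.1 mmol O2 m-2 d-1
  phi <- 0.88; D <- diffusionCoefficient("O2"); target <- 35.1
  slope <- target * tortuosityFactor(phi) / (phi * D) / 1000  # umol L-1 mm-1
  d <- seq(0, 1, by = 0.05)
  prof <- DepthProfile("O2", d, slope * 1 - slope * d, porosity = phi)
  fl <- fickFlux(prof, D = D, window = c(0, 1))
  expect_equal(fluxValue(fl), target, tolerance = 1e-9)
  expect_equal(fl@r2, 1, tolerance = 1e-12)
})

test_that("flux fitting falls back to two points and validates inputs", {
  prof <- DepthProfile("O2", c(0, 0.5, 1), c(100, 75, 50), porosity = 1)
  fl <- fickFlux(prof, D = 1e-4, window = c(0, 0.5))
  expect_equal(fl@n, 2L)
  expect_equal(fl@slope, -50)
  expect_error(fickFlux(prof, D = 1e-4, window = c(0.6, 0.9)), "fewer than 2")
  expect_error(fickFlux(prof, D = -1, window = c(0, 1)), "D must")
  expect_equal(fluxValue(fickFlux(DepthProfile("O2", 0:2, rep(5, 3)),
                                  D = 1e-4, window = c(0, 2))), 0)
})

test_that("zonation recovers planted crossings and handles edge cases", {
  d <- seq(0, 30, by = 0.5)
  o2 <- DepthProfile("O2", d, pmax(0, 100 - 100 * d))       # zero from 1.0 mm
  sh <- DepthProfile("SumH2S", d, pmax(0, 50 * (d - 11)))   # rises at 11.0 mm
  ph <- DepthProfile("pH", d, 7.8 + 0.3 * exp(-(d - 1)^2) - 1.6 * exp(-((d - 12) / 5)^2))
  z <- detectZonation(o2, sh, ph, threshold = 1)
  expect_equal(z@opd, 0.99, tolerance = 0.06)           # crossing of the 1 uM level
  expect_equal(z@sulfideAppearance, 11.0, tolerance = 0.06)
  expect_equal(z@suboxicWidth, 10.0, tolerance = 0.12)
  expect_equal(z@phMin[2], min(profileValues(ph)))
  # oxygen never depleted: opd undefined, width undefined (not zero)
  o2_hi <- DepthProfile("O2", d, rep(200, length(d)))
  z2 <- detectZonation(o2_hi, sh, threshold = 1)
  expect_true(is.na(z2@opd) && is.na(z2@suboxicWidth))
  # sulfide present right at the opd: width collapses to zero
  sh_at <- DepthProfile("SumH2S", d, pmax(0, 50 * (d - 0.5)))
  z3 <- detectZonation(o2, sh_at, threshold = 1)
  expect_equal(z3@suboxicWidth, 0, tolerance = 0.12)
})

test_that("zonation ignores measurements below the sulfide appearance depth", {
  d <- seq(0, 20, by = 0.5)
  o2 <- DepthProfile("O2", d, pmax(0, 100 - 100 * d))
  sh <- DepthProfile("SumH2S", d, pmax(0, 50 * (d - 11)))
  z_ref <- detectZonation(o2, sh)
  # appending deeper sulfide measurements must not move any boundary
  d2 <- c(d, seq(20.5, 40, by = 0.5))
  sh2 <- DepthProfile("SumH2S", d2, pmax(0, 50 * (d2 - 11)))
  z_ext <- detectZonation(o2, sh2)
  expect_equal(z_ext@opd, z_ref@opd)
  expect_equal(z_ext@sulfideAppearance, z_ref@sulfideAppearance)
  expect_equal(z_ext@suboxicWidth, z_ref@suboxicWidth)
})

test_that("profile tables round-trip through the long TSV format", {
  spec <- scenarioSpec("electrogenic", seed = 7L)
  profs <- genPorewater(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeProfileTable(profs, path)
  back <- readProfileTable(path)
  expect_setequal(names(back), c("O2", "H2S", "SumH2S", "pH"))
  expect_equal(profileValues(back$O2), profileValues(profs$O2), tolerance = 1e-6)
  expect_equal(porosity(back$pH), porosity(profs$pH))
})
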