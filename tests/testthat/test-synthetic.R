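test_that("scenario specifications enforce regime consistency", {
  el <- scenarioSpec("electrogenic")
  expect_equal(el@opd, 1.0)
  expect_equal(el@suboxicWidth, 10)
  ne <- scenarioSpec("non_electrogenic")
  expect_equal(ne@suboxicWidth, 0)
  expect_error(scenarioSpec("non_electrogenic", suboxicWidth = 5), "non-electrogenic")
  expect_error(scenarioSpec("electrogenic", phPeakAmplitude = 0), "electrogenic")
})

test_that("noiseless pore-water profiles invert to the planted fluxes exactly", {
  spec <- scenarioSpec("electrogenic")
  profs <- genPorewater(spec)
  flux <- fickFlux(profs$O2, D = diffusionCoefficient("O2"),
                   window = c(0, spec@opd))
  expect_equal(fluxValue(flux), 35.1, tolerance = 1e-9)
  # sulfide gradient below the suboxic zone returns the planted upward flux
  sflux <- fickFlux(profs$SumH2S, D = diffusionCoefficient("H2S"),
                    window = c(11.05, 30))
  expect_equal(-fluxValue(sflux), spec@sulfideFlux, tolerance = 1e-9)
  # the default O2 window (interface to OPD) also recovers the planted value
  expect_equal(fluxValue(fickFlux(profs$O2, D = diffusionCoefficient("O2"))),
               35.1, tolerance = 1e-9)
})

test_that("zonation round-trips the planted fingerprint", {
  spec <- scenarioSpec("electrogenic")
  profs <- genPorewater(spec, step = 0.05)
  z <- detectZonation(profs$O2, profs$SumH2S, profs$pH)
  expect_equal(z@opd, spec@opd, tolerance = 0.06)
  expect_equal(z@suboxicWidth, spec@suboxicWidth, tolerance = 0.02)
  expect_equal(z@phMax[1], spec@opd, tolerance = 0.06)
  expect_equal(z@phMin[2], spec@phMin, tolerance = 0.01)
  # speciation of the emitted free H2S against pH reproduces total sulfide
  total <- sumH2S(profs$H2S, profs$pH, pK1 = 6.6)
  expect_equal(profileValues(total), profileValues(profs$SumH2S), tolerance = 1e-9)
  # non-electrogenic regime: sulfide appears at the OPD, no pH maximum
  ne <- genPorewater(scenarioSpec("non_electrogenic"))
  zn <- detectZonation(ne$O2, ne$SumH2S, ne$pH)
  expect_equal(zn@suboxicWidth, 0, tolerance = 0.05)
})

test_that("noiseless Cq tables quantify back to the planted copy densities", {
  spec <- scenarioSpec("electrogenic", cqNoiseSd = 0)
  qt <- genQpcr(spec)
  for (target in c("TB", "DSB", "CB")) {
    res <- quantifyTable(qt, target)
    expect_equal(res$curve@slope, unname(spec@curveParams[[target]]["slope"]),
                 tolerance = 1e-9)
    truth <- spec@copyProfiles[[target]]$copies_per_g
    expect_equal(res$profile$copies_per_g, truth, tolerance = 1e-9)
  }
  # a stepped cable-bacteria profile spans background-to-bloom densities
  cb <- quantifyTable(qt, "CB")$profile
  expect_equal(max(cb$copies_per_g), 3e8, tolerance = 1e-9)
  expect_lt(min(cb$copies_per_g), 1e7)
})

test_that("noisy Cq tables reproduce the first-order copy CV", {
  spec <- scenarioSpec("electrogenic", cqNoiseSd = 0.15, seed = 99L)
  slope <- unname(spec@curveParams[["CB"]]["slope"])
  set.seed(1234)
  cq0 <- 25
  copies <- 10^(((cq0 + rnorm(3000, sd = 0.15)) - 37) / slope)
  cv_obs <- sd(copies) / mean(copies)
  expect_equal(cv_obs, log(10) / abs(slope) * 0.15, tolerance = 0.15)
})

test_that("all generators are deterministic under the scenario seed", {
  s1 <- scenarioSpec("electrogenic", cqNoiseSd = 0.2, seed = 42L)
  s2 <- scenarioSpec("electrogenic", cqNoiseSd = 0.2, seed = 42L)
  expect_identical(genQpcr(s1), genQpcr(s2))
  expect_identical(genPorewater(s1, noiseSd = 2), genPorewater(s2, noiseSd = 2))
  prm <- qpcrPrimers()
  db1 <- genReferenceDb(5, 5, prm$ELF645wF, prm$CB836wR,
                        mismatchSpec = list(fwd = 2L), seed = 7L)
  db2 <- genReferenceDb(5, 5, prm$ELF645wF, prm$CB836wR,
                        mismatchSpec = list(fwd = 2L), seed = 7L)
  expect_identical(db1, db2)
  ra <- matrix(c(0.05, 0.03), nrow = 1, dimnames = list("CB", c("a", "b")))
  expect_identical(genCommunityReads(ra, seed = 5L), genCommunityReads(ra, seed = 5L))
})

test_that("community reads are multinomial around the planted fractions", {
  ra <- matrix(c(0.05, 0.02), nrow = 1, dimnames = list("CB", c("a", "b")))
  reads <- 1e6
  out <- genCommunityReads(ra, totalReads = reads, seed = 8L)
  for (j in 1:2) {
    p <- ra[1, j]
    obs <- out$counts["CB", j] / reads
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / reads))
  }
  # zero-abundance taxa receive zero reads; totals are conserved
  ra0 <- matrix(c(0, 0.1), nrow = 2, dimnames = list(c("X", "Y"), "a"))
  out0 <- genCommunityReads(ra0, totalReads = 5000, seed = 2L)
  expect_equal(out0$counts["X", "a"], 0)
  expect_equal(sum(out0$counts), 5000)
  expect_error(genCommunityReads(matrix(c(0.7, 0.7), 2, 1,
                                        dimnames = list(c("X", "Y"), "a"))),
               "at most 1")
})

test_that("planted community fractions flow through to the abundance comparison", {
  layers <- c("0-0.5", "0.5-1", "1-1.5")
  planted <- c(0.052, 0.03, 0.01)
  ra <- matrix(planted, nrow = 1, dimnames = list("Ca. Electrothrix", layers))
  out <- genCommunityReads(ra, totalReads = 2e5, seed = 3L)
  tb <- 5.4e9
  cp <- rbind(
    data.frame(layer = layers, target = "CB", copies_per_g = planted * tb),
    data.frame(layer = layers, target = "TB", copies_per_g = tb))
  pairs <- relativeAbundances(cp, out$counts, out$taxa)
  fit <- ratioRegression(pairs)
  expect_equal(fit$slope, 1, tolerance = 0.05)
  expect_gt(fit$r2, 0.98)
})
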