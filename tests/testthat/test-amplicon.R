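mkCopyProfile <- function(layers, cb, tb) {
  rbind(data.frame(layer = layers, target = "CB", copies_per_g = cb),
        data.frame(layer = layers, target = "TB", copies_per_g = tb))
}

test_that("paired relative abundances agree for a transparent community", {
  layers <- c("0-0.5", "0.5-1")
  cp <- mkCopyProfile(layers, cb = c(5, 10), tb = c(100, 100))
  counts <- matrix(c(5, 95, 10, 90), nrow = 2,
                   dimnames = list(NULL, layers))
  taxa <- c("Bacteria;Desulfobulbaceae;Ca. Electrothrix", "Bacteria;Other")
  ra <- relativeAbundances(cp, counts, taxa)
  expect_equal(ra$qpcr_rel, c(5, 10))
  expect_equal(ra$amplicon_rel, c(5, 10))
  # zero target reads with nonzero qPCR: retained, not dropped
  counts0 <- matrix(c(0, 100, 10, 90), nrow = 2, dimnames = list(NULL, layers))
  ra0 <- relativeAbundances(cp, counts0, taxa)
  expect_equal(ra0$amplicon_rel[1], 0)
  expect_equal(ra0$qpcr_rel[1], 5)
})

test_that("unclassified reads are excluded from the denominator by default", {
  layers <- "0-0.5"
  cp <- mkCopyProfile(layers, cb = 5, tb = 100)
  counts <- matrix(c(5, 45, 50), nrow = 3, dimnames = list(NULL, layers))
  taxa <- c("Bacteria;Ca. Electrothrix", "Bacteria;Other", "Unclassified")
  ra <- relativeAbundances(cp, counts, taxa)
  expect_equal(ra$amplicon_rel, 10)   # 5 of 50 classified reads
  ra_all <- relativeAbundances(cp, counts, taxa, includeUnclassified = TRUE)
  expect_equal(ra_all$amplicon_rel, 5)
  # layers missing one side are dropped with a message
  cp2 <- mkCopyProfile(c("0-0.5", "1-1.5"), cb = c(5, 7), tb = c(100, 100))
  expect_message(ra2 <- relativeAbundances(cp2, counts, taxa), "dropping")
  expect_equal(ra2$layer, "0-0.5")
})

test_that("relative abundances are invariant to uniform sequencing depth", {
  layers <- c("a", "b", "c")
  cp <- mkCopyProfile(layers, cb = c(1, 2, 3) * 1e7, tb = rep(1e9, 3))
  counts <- matrix(c(10, 990, 20, 980, 30, 970), nrow = 2,
                   dimnames = list(NULL, layers))
  taxa <- c("Ca. Electrothrix", "Bacteria;Other")
  ra1 <- relativeAbundances(cp, counts, taxa)
  ra2 <- relativeAbundances(cp, counts * 50, taxa)
  expect_equal(ra1$amplicon_rel, ra2$amplicon_rel)
})

test_that("ratio regression recovers exact proportionality either way", {
  pairs <- data.frame(amplicon_rel = c(1, 2, 4, 8),
                      qpcr_rel = c(1, 2, 4, 8))
  r <- ratioRegression(pairs)
  expect_equal(r$slope, 1)
  expect_equal(r$r2, 1)
  half <- transform(pairs, qpcr_rel = 0.5 * amplicon_rel)
  expect_equal(ratioRegression(half)$slope, 0.5)
  expect_equal(ratioRegression(half, throughOrigin = FALSE)$slope, 0.5)
  expect_equal(ratioRegression(half, throughOrigin = FALSE)$intercept, 0)
  expect_error(ratioRegression(pairs[1, , drop = FALSE]), "at least 2")
})

test_that("regression recovers a planted slope under multiplicative noise", {
  set.seed(31)
  planted <- 0.77
  slopes <- replicate(100, {
    x <- runif(8, 0.5, 6)
    y <- planted * x * exp(stats::rnorm(8, sd = 0.1))
    ratioRegression(data.frame(amplicon_rel = x, qpcr_rel = y))$slope
  })
  expect_lt(abs(mean(slopes) - planted), 0.1)
  expect_gt(mean(abs(slopes - planted) < 0.1), 0.8)
})

test_that("the ASV detection limit is one read's worth of copies", {
  expect_equal(asvDetectionLimit(1.3e10, 52000), 2.5e5)
  expect_equal(asvDetectionLimit(5.2e4, 52000), 1)
  expect_equal(asvDetectionLimit(1e10, 104000), asvDetectionLimit(1e10, 52000) / 2)
  # the study's read depth keeps the limit in the reported window
  lim <- asvDetectionLimit(c(5.4e9, 1.3e10), 52000)
  expect_true(all(lim >= 5e4 & lim <= 4e5))
  expect_error(asvDetectionLimit(1e9, 0), "reads")
})
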