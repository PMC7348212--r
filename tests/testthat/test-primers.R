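test_that("degenerate expansion enumerates exactly the coded variants", {
  p <- qpcrPrimers()
  # one R at position 10: two variants differing there
  v <- expandDegenerate(p$DSBB280wF)
  expect_setequal(v, c("CGATGGTTAACGGGTCTG", "CGATGGTTAGCGGGTCTG"))
  expect_equal(degeneracy(p$DSBB280wF), 2L)
  # non-degenerate primers expand to themselves
  expect_equal(expandDegenerate(p$Eub518), "ATTACCGCGGCTGCTGG")
  # an N multiplies the count by 4
  pn <- DegeneratePrimer("n1", "ACGTACGTACNT")
  expect_length(expandDegenerate(pn), 4L)
  expect_error(DegeneratePrimer("bad", "ACGTACGTACXT"), "IUPAC")
})

test_that("expansion count equals the analytic degeneracy product", {
  set.seed(5)
  for (i in 1:25) {
    p <- randomDegeneratePrimer()
    card <- vapply(strsplit(primerSequence(p), "")[[1]],
                   function(ch) nchar(IUPAC[[ch]]), numeric(1))
    expect_length(expandDegenerate(p), prod(card))
  }
})

test_that("mismatch counting is IUPAC-aware with 1-based primer positions", {
  p <- qpcrPrimers()
  # the wide variant of the cable-bacteria forward primer differs from the
  # original at position 2 (C instead of T)
  site_c2 <- sub("^CT", "CC", primerSequence(p$ELF645F))
  mm <- countMismatches(p$ELF645F, site_c2)
  expect_equal(mm$count, 1)
  expect_equal(mm$positions, 2L)
  # family primer: A-variant at position 10
  mm10 <- countMismatches(p$DSBB280F, "CGATGGTTAACGGGTCTG")
  expect_equal(mm10$positions, 10L)
  # a degenerate primer matches each of its own expansions exactly
  for (v in expandDegenerate(p$ELF645wF))
    expect_equal(countMismatches(p$ELF645wF, v)$count, 0)
  # template N cannot anneal: counted as a mismatch even against primer N
  pn <- DegeneratePrimer("n1", "ACGTACGTACNT")
  expect_equal(countMismatches(pn, "ACGTACGTACNT")$count, 1)
  expect_error(countMismatches(p$ELF645F, "ACGT"), "equal length")
})

test_that("binding-site search finds planted sites with exact coordinates", {
  set.seed(9)
  p <- qpcrPrimers()$ELF645wF
  site <- expandDegenerate(p)[1]
  tpl <- plantSite(randomSeq(400), site, 137)
  hits <- findBindingSites(p, tpl, maxMismatches = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 137L)
  expect_equal(hits$mismatches, 0L)
  # substitutions at primer positions 2, 3 and 5 need three tolerated
  # mismatches to be seen, and are reported at those positions
  mut <- mutateSite(site, p, c(2, 3, 5))
  tpl2 <- plantSite(randomSeq(400), mut, 55)
  expect_equal(nrow(findBindingSites(p, tpl2, maxMismatches = 2)), 0L)
  h3 <- findBindingSites(p, tpl2, maxMismatches = 3)
  expect_equal(nrow(h3), 1L)
  expect_equal(h3$mismatch_positions, "2,3,5")
})

test_that("reverse primers are searched in reverse-complement sense", {
  set.seed(10)
  p <- qpcrPrimers()$CB836wR
  variant <- expandDegenerate(p)[2]
  plus_site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(variant)))
  tpl <- plantSite(randomSeq(300), plus_site, 200)
  hits <- findBindingSites(p, tpl, maxMismatches = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 200L)
  expect_equal(hits$strand, "-")
  # a mismatch planted at primer position 2 maps back to primer coordinates
  mut <- mutateSite(variant, p, 2)
  mut_plus <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mut)))
  h <- findBindingSites(p, plantSite(randomSeq(300), mut_plus, 100),
                        maxMismatches = 1)
  expect_equal(h$mismatch_positions, "2")
})

test_that("zero-mismatch search equals exact search over the expanded set", {
  set.seed(33)
  for (i in 1:40) {
    p <- randomDegeneratePrimer(orientation = sample(c("forward", "reverse"), 1))
    tpl <- randomSeq(sample(150:400, 1))
    # occasionally plant a real site so hits exist
    if (i %% 3 == 0) {
      v <- sample(expandDegenerate(p), 1)
      site <- if (orientation(p) == "reverse")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(v))) else v
      tpl <- plantSite(tpl, site, sample(0:(nchar(tpl) - nchar(site)), 1))
    }
    got <- findBindingSites(p, tpl, maxMismatches = 0)$start
    expect_equal(sort(got), expandedSubstringStarts(p, tpl))
  }
})

test_that("hit counts are monotone in the mismatch allowance and match Biostrings", {
  set.seed(77)
  for (i in 1:10) {
    p <- randomDegeneratePrimer(orientation = "forward")
    tpl <- randomSeq(500)
    counts <- vapply(0:4, function(k)
      nrow(findBindingSites(p, tpl, maxMismatches = k)), numeric(1))
    expect_true(all(diff(counts) >= 0))
    # independent oracle: Biostrings fixed="subject" matching
    for (k in c(2, 4)) {
      bs <- Biostrings::matchPattern(primerSequence(p), Biostrings::DNAString(tpl),
                                     max.mismatch = k, fixed = "subject")
      expect_equal(counts[k + 1], length(bs))
    }
  }
})

test_that("screening is symmetric under reverse complementation", {
  set.seed(21)
  for (i in 1:10) {
    p <- randomDegeneratePrimer(orientation = "forward")
    tpl <- plantSite(randomSeq(300), sample(expandDegenerate(p), 1), 120)
    fwd_hits <- findBindingSites(p, tpl, maxMismatches = 1)
    rc_tpl <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tpl)))
    rp <- DegeneratePrimer(p@name, primerSequence(p), "reverse")
    rc_hits <- findBindingSites(rp, rc_tpl, maxMismatches = 1)
    expect_equal(nrow(fwd_hits), nrow(rc_hits))
    expect_equal(sort(nchar(tpl) - fwd_hits$end), sort(rc_hits$start))
  }
})

test_that("in-silico PCR respects orientation, length cap and enumerates pairs", {
  set.seed(55)
  prm <- qpcrPrimers()
  fwd <- prm$ELF645wF; rev <- prm$CB836wR
  fsite <- expandDegenerate(fwd)[1]
  rsite_plus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(expandDegenerate(rev)[1])))
  # planted product of exactly 191 bp starting at 0-based 150
  tpl <- randomSeq(500)
  tpl <- plantSite(tpl, fsite, 150)
  tpl <- plantSite(tpl, rsite_plus, 150 + 191 - nchar(rsite_plus))
  prods <- inSilicoPCR(fwd, rev, tpl, maxMismatches = 0, maxAmplicon = 200)
  expect_equal(nrow(prods), 1L)
  expect_equal(prods$length, 191L)
  expect_equal(prods$start, 150L)
  # too-tight length cap suppresses the product
  expect_equal(nrow(inSilicoPCR(fwd, rev, tpl, maxAmplicon = 100)), 0L)
  # reverse site upstream of the forward site: no product
  tpl_bad <- randomSeq(500)
  tpl_bad <- plantSite(tpl_bad, rsite_plus, 50)
  tpl_bad <- plantSite(tpl_bad, fsite, 300)
  expect_equal(nrow(inSilicoPCR(fwd, rev, tpl_bad, maxAmplicon = 500)), 0L)
  # two forward sites sharing one reverse site give two products
  tpl2 <- randomSeq(500)
  tpl2 <- plantSite(tpl2, fsite, 100)
  tpl2 <- plantSite(tpl2, fsite, 150)
  tpl2 <- plantSite(tpl2, rsite_plus, 230)
  expect_equal(nrow(inSilicoPCR(fwd, rev, tpl2, maxAmplicon = 200)), 2L)
})

test_that("primer QC applies the design rules", {
  prm <- qpcrPrimers()
  # 11 G/C of 17 bases: 64.7%, outside the 40-60% band
  qc <- primerQC(prm$Eub518)
  expect_equal(qc$gc_range[1], 100 * 11 / 17, tolerance = 1e-9)
  expect_false(qc$gc_ok)
  # degenerate primer reports one GC value per variant
  qc2 <- primerQC(prm$DSBB280wF)
  expect_equal(diff(qc2$gc_range), 100 / 18, tolerance = 1e-9)
  # a primer against its own reverse complement is a maximal hetero-dimer
  a <- DegeneratePrimer("a", "ACGGATTACCGTGCAATG", "forward")
  b <- DegeneratePrimer("b",
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(primerSequence(a)))),
    "reverse")
  qc3 <- primerQC(a, partner = b)
  expect_true(qc3$hetero_dimer)
  expect_equal(qc3$hetero_dimer_run, nchar(primerSequence(a)))
  # Tm ranges are finite and ordered
  expect_true(all(is.finite(qc$tm_range)))
  expect_lte(qc2$tm_range[1], qc2$tm_range[2])
})
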