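## Shared fixtures: everything is generated in code at test time.

BASES <- c("A", "C", "G", "T")
IUPAC <- Biostrings::IUPAC_CODE_MAP

qpcrPrimers <- function() {
  readPrimerTable(system.file("extdata", "qpcr_primers.tsv",
                              package = "cablecensus"))
}

randomSeq <- function(n) paste0(sample(BASES, n, replace = TRUE), collapse = "")

## Random primer with a few degenerate positions (degeneracy kept small so
## the exhaustive expansion oracle stays cheap).
randomDegeneratePrimer <- function(len = sample(12:20, 1), nDegen = sample(0:3, 1),
                                   orientation = "forward") {
  ch <- sample(BASES, len, replace = TRUE)
  if (nDegen > 0) {
    pos <- sample(len, nDegen)
    codes <- setdiff(names(IUPAC), BASES)
    ch[pos] <- sample(codes, nDegen, replace = TRUE)
  }
  DegeneratePrimer("rnd", paste0(ch, collapse = ""), orientation)
}

## Exhaustive-oracle binding-site search at 0 mismatches: exact substring
## positions of every expanded variant (0-based starts).
expandedSubstringStarts <- function(primer, template) {
  pattern <- if (orientation(primer) == "reverse")
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(primerSequence(primer))))
  else primerSequence(primer)
  variants <- expandDegenerate(DegeneratePrimer("x", pattern, "forward"))
  starts <- integer()
  for (v in variants) {
    hit <- gregexpr(v, template, fixed = TRUE)[[1]]
    if (hit[1] != -1) starts <- c(starts, as.integer(hit) - 1L)
  }
  sort(unique(starts))
}

## Plant a concrete site into a random template at a 0-based position.
plantSite <- function(template, site, start0) {
  paste0(substr(template, 1, start0),
         site,
         substr(template, start0 + nchar(site) + 1, nchar(template)))
}

## Mutate a concrete site at given 1-based primer positions to bases the
## primer cannot match.
mutateSite <- function(site, primer, positions) {
  ch <- strsplit(site, "")[[1]]
  codes <- strsplit(primerSequence(primer), "")[[1]]
  for (p in positions) {
    allowed <- strsplit(IUPAC[[codes[p]]], "")[[1]]
    ch[p] <- sample(setdiff(BASES, allowed), 1)
  }
  paste0(ch, collapse = "")
}
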