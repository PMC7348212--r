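#' Read a taxonomy sidecar table
#'
#' Two tab-separated columns: record id and a semicolon-delimited lineage
#' string (no header required; a `record_id` header line is tolerated).
#'
#' @param path path to the TSV.
#' @return named character vector mapping record id to lineage.
#' @export
readTaxonomyTable <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("record_id", "lineage"))
  if (df$record_id[1] == "record_id") df <- df[-1, , drop = FALSE]
  stats::setNames(df$lineage, df$record_id)
}

## Last rank of a semicolon-delimited lineage string: the reporting taxon.
.leafTaxon <- function(lineage) {
  parts <- strsplit(lineage, ";")
  vapply(parts, function(p) trimws(p[length(p)]), character(1))
}

#' Screen a primer or primer pair against a reference sequence set
#'
#' Emulates a TestProbe/TestPrime-style specificity screen on a local
#' reference set: for each mismatch level, counts how many templates of each
#' taxon are hit by each single primer, and -- when both a forward and a
#' reverse primer are supplied -- by the pair in productive orientation with
#' an amplicon no longer than `maxAmplicon`. A template counts once per
#' level regardless of how many sites it carries, so pair hits can never
#' exceed either single-primer count.
#'
#' @param primers a [DegeneratePrimer-class] or list of one forward and one
#'   reverse [DegeneratePrimer-class].
#' @param sequences named character vector of reference sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param taxonomy named character vector (record id to lineage), e.g. from
#'   [readTaxonomyTable()]. Records without taxonomy are excluded with a
#'   warning.
#' @param levels mismatch levels to screen (default `c(0, 1)`, per primer).
#' @param maxAmplicon maximum amplicon length for pair hits, bp.
#' @param byLeaf report taxa by the last lineage rank (default) or by the
#'   full lineage string.
#' @return a [SpecificityReport-class].
#' @export
specificityScreen <- function(primers, sequences, taxonomy,
                              levels = c(0L, 1L), maxAmplicon = 200,
                              byLeaf = TRUE) {
  if (is(primers, "DegeneratePrimer")) primers <- list(primers)
  stopifnot(all(vapply(primers, is, logical(1), "DegeneratePrimer")))
  if (methods::is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- stats::setNames(as.character(sequences), nm)
  }
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    stop("reference sequences must be named")
  levels <- sort(unique(as.integer(levels)))
  no_tax <- setdiff(names(sequences), names(taxonomy))
  if (length(no_tax)) {
    warning(length(no_tax), " record(s) lack taxonomy and are excluded: ",
            paste(utils::head(no_tax, 5), collapse = ", "))
    sequences <- sequences[setdiff(names(sequences), no_tax)]
  }
  taxa <- taxonomy[names(sequences)]
  if (byLeaf) taxa <- .leafTaxon(taxa)
  utaxa <- sort(unique(taxa))
  tax_total <- table(factor(taxa, levels = utaxa))

  emptySingle <- data.frame(primer = character(), taxon = character(),
                            max_mismatches = integer(),
                            templates_hit = integer(),
                            templates_total = integer(),
                            stringsAsFactors = FALSE)
  single <- list(emptySingle)
  for (p in if (length(utaxa)) primers else list()) {
    ## minimum mismatch count per template, then threshold per level
    minmm <- vapply(names(sequences), function(id) {
      sites <- findBindingSites(p, sequences[[id]],
                                maxMismatches = max(levels), templateId = id)
      if (nrow(sites) == 0L) Inf else min(sites$mismatches)
    }, numeric(1))
    for (lev in levels) {
      hit <- tapply(minmm <= lev, factor(taxa, levels = utaxa), sum)
      hit[is.na(hit)] <- 0
      single[[length(single) + 1L]] <- data.frame(
        primer = p@name, taxon = utaxa, max_mismatches = lev,
        templates_hit = as.integer(hit),
        templates_total = as.integer(tax_total),
        stringsAsFactors = FALSE)
    }
  }
  singleHits <- do.call(rbind, single)

  pairHits <- data.frame(taxon = character(), max_mismatches = integer(),
                         templates_hit = integer(), templates_total = integer(),
                         stringsAsFactors = FALSE)
  ori <- vapply(primers, orientation, character(1))
  if (length(primers) == 2L && all(c("forward", "reverse") %in% ori)) {
    fwd <- primers[[which(ori == "forward")]]
    rev <- primers[[which(ori == "reverse")]]
    minmm_pair <- vapply(names(sequences), function(id) {
      prods <- inSilicoPCR(fwd, rev, sequences[[id]],
                           maxMismatches = max(levels),
                           maxAmplicon = maxAmplicon, templateId = id)
      if (nrow(prods) == 0L) Inf
      else min(pmax(prods$mismatches_fwd, prods$mismatches_rev))
    }, numeric(1))
    rows <- lapply(levels, function(lev) {
      hit <- tapply(minmm_pair <= lev, factor(taxa, levels = utaxa), sum)
      hit[is.na(hit)] <- 0
      data.frame(taxon = utaxa, max_mismatches = lev,
                 templates_hit = as.integer(hit),
                 templates_total = as.integer(tax_total),
                 stringsAsFactors = FALSE)
    })
    pairHits <- do.call(rbind, rows)
  }
  new("SpecificityReport", singleHits = singleHits, pairHits = pairHits,
      levels = levels, maxAmplicon = maxAmplicon, excluded = no_tax)
}

setMethod("show", "SpecificityReport", function(object) {
  cat(sprintf("SpecificityReport: levels {%s}, amplicon cap %g bp\n",
              paste(object@levels, collapse = ","), object@maxAmplicon))
  if (length(object@excluded))
    cat(sprintf("  %d record(s) excluded for missing taxonomy\n",
                length(object@excluded)))
  cat("Single-primer hits:\n")
  print(object@singleHits, row.names = FALSE)
  if (nrow(object@pairHits)) {
    cat("Primer-pair hits (productive orientation):\n")
    print(object@pairHits, row.names = FALSE)
  }
})

#' Read reference sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` returning a named
#' character vector as consumed by [specificityScreen()].
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of sequences.
#' @export
readReferenceFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reference sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeReferenceFasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
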