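#' Construct a degenerate primer
#'
#' @param name primer name.
#' @param sequence IUPAC nucleotide string, written 5' to 3' (reverse primers
#'   on the reverse strand, the usual primer-table convention).
#' @param orientation `"forward"` or `"reverse"`.
#' @return a [DegeneratePrimer-class].
#' @examples
#' DegeneratePrimer("DSBB280wF", "CGATGGTTARCGGGTCTG", "forward")
#' @export
DegeneratePrimer <- function(name, sequence, orientation = "forward") {
  new("DegeneratePrimer", name = name,
      sequence = toupper(gsub("[ \t]", "", sequence)),
      orientation = orientation)
}

setMethod("show", "DegeneratePrimer", function(object) {
  cat(sprintf("DegeneratePrimer %s (%s): 5'-%s-3' (%d nt, degeneracy %d)\n",
              object@name, object@orientation, object@sequence,
              nchar(object@sequence), degeneracy(object)))
})

## Per-base IUPAC sets from Biostrings, split into character vectors.
.iupacSets <- local({
  map <- NULL
  function() {
    if (is.null(map)) map <<- strsplit(Biostrings::IUPAC_CODE_MAP, "")
    map
  }
})

.primerChars <- function(p) strsplit(p@sequence, "")[[1]]

#' @rdname accessors
setMethod("degeneracy", "DegeneratePrimer", function(x) {
  sets <- .iupacSets()
  prod(vapply(.primerChars(x), function(ch) length(sets[[ch]]), integer(1)))
})

#' Expand a degenerate primer into its concrete sequences
#'
#' Enumerates every concrete (A/C/G/T-only) sequence the IUPAC string
#' denotes; the count equals the product of per-position code cardinalities.
#'
#' @param primer a [DegeneratePrimer-class] (or IUPAC string).
#' @return character vector of concrete sequences.
#' @examples
#' expandDegenerate(DegeneratePrimer("DSBB280wF", "CGATGGTTARCGGGTCTG"))
#' @export
expandDegenerate <- function(primer) {
  if (is.character(primer))
    primer <- DegeneratePrimer("primer", primer, "forward")
  sets <- .iupacSets()[.primerChars(primer)]
  if (prod(lengths(sets)) > 1e6) stop("degeneracy too large to expand")
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste0, collapse = ""))
}

#' Count mismatches between a primer and an equal-length concrete site
#'
#' IUPAC-aware and asymmetric: each primer position denotes a set of bases
#' and matches when the template base belongs to that set; template bases
#' must be concrete, so a template `N` counts as a mismatch (reflecting that
#' an unknown base cannot be assumed to anneal). Positions are 1-based from
#' the primer 5' end. For a degenerate primer this equals the minimum
#' mismatch count over all expansions (best-variant semantics), since
#' positions are independent.
#'
#' @param primer a [DegeneratePrimer-class] or IUPAC string.
#' @param site concrete sequence of the same length as the primer.
#' @return list with `count` and sorted `positions`.
#' @examples
#' countMismatches("CTTGGCTTGAGTATCAGAGG", "CCTGGCTTGAGTATCAGAGG")
#' @export
countMismatches <- function(primer, site) {
  if (is.character(primer))
    primer <- DegeneratePrimer("primer", primer, "forward")
  site <- toupper(site)
  pch <- .primerChars(primer)
  sch <- strsplit(site, "")[[1]]
  if (length(pch) != length(sch))
    stop("primer and site must have equal length")
  sets <- .iupacSets()
  ok <- mapply(function(p, s) s %in% c("A", "C", "G", "T") && s %in% sets[[p]],
               pch, sch)
  pos <- which(!ok)
  list(count = length(pos), positions = as.integer(pos))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Mismatch count of every window of `template` against the primer pattern,
## via per-position logical match vectors (IUPAC sets on the primer side,
## concrete bases required on the template side).
.windowMismatches <- function(pattern, template) {
  sets <- .iupacSets()
  pch <- strsplit(pattern, "")[[1]]
  tch <- strsplit(toupper(template), "")[[1]]
  k <- length(pch); n <- length(tch)
  if (n < k) return(matrix(logical(0), nrow = 0, ncol = k))
  nw <- n - k + 1L
  m <- matrix(FALSE, nrow = nw, ncol = k)
  concrete <- tch %in% c("A", "C", "G", "T")
  for (j in seq_len(k)) {
    tj <- tch[seq.int(j, j + nw - 1L)]
    m[, j] <- concrete[seq.int(j, j + nw - 1L)] & tj %in% sets[[pch[j]]]
  }
  m
}

#' Find mismatch-tolerant binding sites of a primer on a template
#'
#' Slides the primer along the template and reports every window whose
#' mismatch count (IUPAC-aware, best-variant semantics as in
#' [countMismatches()]) does not exceed `maxMismatches`. Forward primers are
#' matched directly on the plus strand; reverse primers are matched in the
#' reverse-complement sense (the site is reported in plus-strand coordinates
#' with `strand = "-"`). Mismatch positions are 1-based from the primer's
#' own 5' end.
#'
#' @param primer a [DegeneratePrimer-class].
#' @param template template sequence (character or `DNAString`).
#' @param maxMismatches maximum mismatches allowed (default 0).
#' @param templateId identifier recorded in the result.
#' @return data.frame with columns `template_id`, `start` (0-based),
#'   `end` (half-open), `strand`, `mismatches`, `mismatch_positions`
#'   (comma-separated, 1-based in the primer), sorted by position then
#'   mismatch count. Zero rows when nothing binds.
#' @export
findBindingSites <- function(primer, template, maxMismatches = 0,
                             templateId = "template") {
  stopifnot(is(primer, "DegeneratePrimer"))
  template <- as.character(template)
  k <- nchar(primer@sequence)
  if (nchar(template) < k) stop("template shorter than primer")
  if (primer@orientation == "forward") {
    pattern <- primer@sequence
    matches <- .windowMismatches(pattern, template)
    primer_pos <- function(miss_cols) miss_cols            # window col = primer pos
    strand <- "+"
  } else {
    ## reverse primer anneals to the plus strand read 3'->5'; search its
    ## reverse complement on the plus strand
    pattern <- .revcomp(primer@sequence)
    matches <- .windowMismatches(pattern, template)
    primer_pos <- function(miss_cols) k + 1L - miss_cols   # back to primer 5'->3'
    strand <- "-"
  }
  if (nrow(matches) == 0L) return(.emptySites())
  mm <- rowSums(!matches)
  hit <- which(mm <= maxMismatches)
  if (!length(hit)) return(.emptySites())
  rows <- lapply(hit, function(i) {
    cols <- which(!matches[i, ])
    pos <- sort(primer_pos(cols))
    data.frame(template_id = templateId, start = i - 1L, end = i - 1L + k,
               strand = strand, mismatches = length(cols),
               mismatch_positions = paste(pos, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$start, out$mismatches), , drop = FALSE]
}

.emptySites <- function() {
  data.frame(template_id = character(), start = integer(), end = integer(),
             strand = character(), mismatches = integer(),
             mismatch_positions = character(), stringsAsFactors = FALSE)
}

#' In-silico PCR on a single template
#'
#' Pairs every forward binding site with every reverse site whose 3'
#' complement lies downstream, keeping products no longer than
#' `maxAmplicon`. Product length is counted from the forward primer's 5'
#' base to the reverse primer's 5' base inclusive on the plus strand (the
#' conventional amplicon length).
#'
#' @param fwd forward [DegeneratePrimer-class].
#' @param rev reverse [DegeneratePrimer-class] (5' to 3' on the reverse
#'   strand, as in primer tables).
#' @param template template sequence.
#' @param maxMismatches maximum mismatches allowed per primer.
#' @param maxAmplicon maximum product length, bp (default 200, the
#'   qPCR-suitable cap).
#' @param templateId identifier recorded in the result.
#' @return data.frame with columns `template_id`, `start` (0-based forward
#'   5'), `end` (half-open, reverse 5' + 1), `length`, `mismatches_fwd`,
#'   `mismatches_rev`, `mismatches_total`. Zero rows when no product forms.
#' @export
inSilicoPCR <- function(fwd, rev, template, maxMismatches = 0,
                        maxAmplicon = 200, templateId = "template") {
  stopifnot(is(fwd, "DegeneratePrimer"), is(rev, "DegeneratePrimer"))
  if (fwd@orientation != "forward" || rev@orientation != "reverse")
    stop("primer orientations must be forward/reverse as in a primer table")
  fsites <- findBindingSites(fwd, template, maxMismatches, templateId)
  rsites <- findBindingSites(rev, template, maxMismatches, templateId)
  empty <- data.frame(template_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      mismatches_fwd = integer(), mismatches_rev = integer(),
                      mismatches_total = integer(), stringsAsFactors = FALSE)
  if (nrow(fsites) == 0L || nrow(rsites) == 0L) return(empty)
  prods <- list()
  for (i in seq_len(nrow(fsites))) for (j in seq_len(nrow(rsites))) {
    fs <- fsites$start[i]                # fwd 5' (0-based)
    re <- rsites$end[j]                  # rev 5' + 1 on plus strand
    len <- re - fs
    if (rsites$start[j] >= fsites$end[i] && len <= maxAmplicon) {
      prods[[length(prods) + 1L]] <- data.frame(
        template_id = templateId, start = fs, end = re, length = len,
        mismatches_fwd = fsites$mismatches[i],
        mismatches_rev = rsites$mismatches[j],
        mismatches_total = fsites$mismatches[i] + rsites$mismatches[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(prods)) return(empty)
  out <- do.call(rbind, prods)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Read a primer table
#'
#' Reads a TSV with columns `name`, `sequence`, `orientation` into a list of
#' [DegeneratePrimer-class] objects. The qPCR primer set used throughout the
#' package examples ships as `system.file("extdata", "qpcr_primers.tsv",
#' package = "cablecensus")`.
#'
#' @param path path to the TSV.
#' @return named list of [DegeneratePrimer-class] objects.
#' @export
readPrimerTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  out <- mapply(function(n, s, o) DegeneratePrimer(n, s, o),
                df$name, df$sequence, df$orientation, SIMPLIFY = FALSE)
  names(out) <- df$name
  out
}
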