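## Nearest-neighbor duplex thermodynamics (SantaLucia 1998 unified
## parameters). dH in kcal/mol, dS in cal/(mol K). Supplied as config so the
## parameter set and salt correction can be swapped.
.NN_UNIFIED <- list(
  dH = c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
         GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
         TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0),
  dS = c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
         CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
         TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2, CC = -19.9),
  init_dH = 0.2, init_dS = -5.7,      # initiation
  term_AT_dH = 2.2, term_AT_dS = 6.9  # per terminal A/T penalty
)

#' Default nearest-neighbor thermodynamic configuration
#'
#' Unified nearest-neighbor parameters with a sodium-dependent entropy
#' salt correction. Pass a modified copy to [primerQC()] or [nnTm()] to change
#' the parameter table, primer concentration or ionic strength.
#'
#' @return list with elements `nn` (parameter table), `primer_nM` (primer
#'   concentration, nanomolar) and `Na_mM` (monovalent cation, millimolar).
#' @export
thermoConfig <- function() {
  list(nn = .NN_UNIFIED, primer_nM = 200, Na_mM = 50)
}

#' Nearest-neighbor melting temperature of a concrete oligonucleotide
#'
#' Two-state nearest-neighbor model: Tm = dH / (dS + R ln(C/4)) with the salt
#' correction dS' = dS + 0.368 * (N-1) * ln(Na+ molarity). Intended for primer QC
#' ranges, not as a reproduction of any particular vendor calculator.
#'
#' @param seq concrete A/C/G/T sequence.
#' @param thermo configuration from [thermoConfig()].
#' @return melting temperature, degrees C.
#' @export
nnTm <- function(seq, thermo = thermoConfig()) {
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1]]
  if (!all(ch %in% c("A", "C", "G", "T")))
    stop("nnTm needs a concrete sequence; expand degenerate primers first")
  n <- length(ch)
  pairs <- paste0(ch[-n], ch[-1])
  nn <- thermo$nn
  dH <- nn$init_dH + sum(nn$dH[pairs])
  dS <- nn$init_dS + sum(nn$dS[pairs])
  for (tb in c(ch[1], ch[n])) {
    if (tb %in% c("A", "T")) {
      dH <- dH + nn$term_AT_dH
      dS <- dS + nn$term_AT_dS
    }
  }
  dS <- dS + 0.368 * (n - 1) * log(thermo$Na_mM / 1000)
  R <- 1.98720425  # cal / (mol K)
  ct <- thermo$primer_nM * 1e-9
  dH * 1000 / (dS + R * log(ct / 4)) - 273.15
}

## Longest run of complementary (Watson-Crick) alignment between a and the
## reverse of b, over all offsets; returns the longest run and the longest
## run that reaches the 3' end of a.
.complementRuns <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ach <- strsplit(toupper(a), "")[[1]]
  bch <- rev(strsplit(toupper(b), "")[[1]])  # antiparallel alignment
  na <- length(ach); nb <- length(bch)
  best <- 0L; best3 <- 0L
  for (off in seq(-(nb - 1L), na - 1L)) {
    run <- 0L
    for (i in seq_len(nb)) {
      ai <- off + i
      if (ai < 1L || ai > na) { run <- 0L; next }
      if (!is.na(comp[ach[ai]]) && comp[ach[ai]] == bch[i]) {
        run <- run + 1L
        if (run > best) best <- run
        if (ai == na && run > best3) best3 <- run
      } else run <- 0L
    }
  }
  c(longest = best, longest_3prime = best3)
}

## Hairpin: any internal reverse-complementary seed of >= k bases separated
## by a loop of >= minLoop bases.
.hasHairpin <- function(seq, k = 4, minLoop = 3) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  if (n < 2 * k + minLoop) return(FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(n - 2 * k - minLoop + 1L)) {
    stem1 <- ch[i:(i + k - 1L)]
    for (j in seq(i + k + minLoop, n - k + 1L)) {
      stem2 <- ch[j:(j + k - 1L)]
      if (all(comp[stem1] == rev(stem2))) return(TRUE)
    }
  }
  FALSE
}

#' Design-rule quality control of a (degenerate) primer
#'
#' Applies the standard qPCR primer design rules: GC content in 40-60
#' percent, a 5' start with G or C preferred, no GC-rich 3' end (four or
#' more G/C among the last five bases), no hairpin (internal
#' reverse-complementary seed of at least `hairpinSeed` bases separated by a
#' loop of at least 3), no self-dimer, and -- when a partner primer is given
#' -- no hetero-dimer (longest antiparallel complementary run of at least
#' `dimerRun` bases; runs reaching a 3' end are reported separately since
#' 3'-anchored dimers are the ones extended by the polymerase). GC content
#' and Tm are reported as ranges over the primer's expansions.
#'
#' @param primer a [DegeneratePrimer-class].
#' @param partner optional partner [DegeneratePrimer-class] for hetero-dimer
#'   checks.
#' @param thermo thermodynamic configuration, see [thermoConfig()].
#' @param hairpinSeed minimum hairpin stem length (default 4).
#' @param dimerRun minimum complementary run flagged as a dimer (default 5).
#' @return list with elements `gc_range` (percent), `gc_ok`,
#'   `starts_gc`, `gc_rich_end`, `hairpin`, `self_dimer`, `self_dimer_run`,
#'   `hetero_dimer`, `hetero_dimer_run`, `hetero_dimer_3prime_run`,
#'   `tm_range` (degrees C).
#' @examples
#' primerQC(DegeneratePrimer("Eub518", "ATTACCGCGGCTGCTGG")) # GC 64.7%, flagged
#' @export
primerQC <- function(primer, partner = NULL, thermo = thermoConfig(),
                     hairpinSeed = 4, dimerRun = 5) {
  stopifnot(is(primer, "DegeneratePrimer"))
  variants <- expandDegenerate(primer)
  gc <- vapply(variants, function(v) {
    ch <- strsplit(v, "")[[1]]
    100 * sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1))
  tm <- vapply(variants, nnTm, numeric(1), thermo = thermo)
  first <- substr(primer@sequence, 1, 1)
  last5 <- vapply(variants, function(v) {
    tail_ch <- strsplit(substr(v, nchar(v) - 4L, nchar(v)), "")[[1]]
    sum(tail_ch %in% c("G", "C"))
  }, numeric(1))
  self <- max(vapply(variants, function(v)
    .complementRuns(v, v)["longest"], numeric(1)))
  hairpin <- any(vapply(variants, .hasHairpin, logical(1), k = hairpinSeed))
  out <- list(
    gc_range = range(gc),
    gc_ok = all(gc >= 40 & gc <= 60),
    starts_gc = first %in% c("G", "C", "S"),
    gc_rich_end = any(last5 >= 4),
    hairpin = hairpin,
    self_dimer = self >= dimerRun,
    self_dimer_run = self,
    hetero_dimer = NA,
    hetero_dimer_run = NA_real_,
    hetero_dimer_3prime_run = NA_real_,
    tm_range = range(tm)
  )
  if (!is.null(partner)) {
    stopifnot(is(partner, "DegeneratePrimer"))
    pvariants <- expandDegenerate(partner)
    runs <- do.call(rbind, lapply(variants, function(v)
      t(vapply(pvariants, function(w) .complementRuns(v, w), numeric(2)))))
    runmax <- max(runs[, "longest"])
    run3 <- max(runs[, "longest_3prime"])
    out$hetero_dimer <- runmax >= dimerRun
    out$hetero_dimer_run <- runmax
    out$hetero_dimer_3prime_run <- run3
  }
  out
}
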