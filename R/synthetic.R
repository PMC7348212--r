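#' Construct a synthetic-scenario specification
#'
#' Defaults describe the two incubation regimes the pipeline is built around.
#' The electrogenic scenario plants the cable-bacteria fingerprint with the
#' study conditions: oxygen penetration depth 1 mm, a 10 mm suboxic zone,
#' diffusive O2 uptake 35.1 mmol m-2 d-1, upward sulfide flux
#' 4.8 mmol m-2 d-1, a subsurface pH maximum 0.25 units above the overlying
#' water and a deep pH minimum of 6.2 at 12 mm. The non-electrogenic
#' scenario has a deeper OPD (1.6 mm), lower uptake (21.6), sulfide
#' appearing directly at the OPD and no pH excursions. Copy-density
#' profiles default to the observed magnitudes: total bacteria 1.3e10
#' copies g-1 in the top layer over 5.4e9 below; cable bacteria 3e8 within
#' the colonized 0-1.5 cm, declining to 1e6 at depth (electrogenic), versus
#' a uniform 9.1e4 background (non-electrogenic).
#'
#' @param regime `"electrogenic"` (default) or `"non_electrogenic"`.
#' @param opd,suboxicWidth,o2Uptake,sulfideFlux,phPeakAmplitude,phMin,phMinDepth,phBackground
#'   fingerprint parameters; see slots of [ScenarioSpec-class].
#' @param porosity,temperature,salinity environment metadata.
#' @param copyProfiles named list (TB/DSB/CB) of data.frames with columns
#'   `layer_top_cm`, `layer_bottom_cm`, `copies_per_g`; `NULL` for defaults.
#' @param curveParams named list (per target) of `c(slope, intercept)`.
#' @param cqNoiseSd Gaussian Cq noise, cycles (0 = noiseless).
#' @param seed master seed for all generator randomness.
#' @return a [ScenarioSpec-class].
#' @export
scenarioSpec <- function(regime = c("electrogenic", "non_electrogenic"),
                         opd = NULL, suboxicWidth = NULL, o2Uptake = NULL,
                         sulfideFlux = 4.8, phPeakAmplitude = NULL,
                         phMin = NULL, phMinDepth = 12, phBackground = 8.0,
                         porosity = 0.88, temperature = 16, salinity = 30,
                         copyProfiles = NULL, curveParams = NULL,
                         cqNoiseSd = 0, seed = 1L) {
  regime <- match.arg(regime)
  electro <- regime == "electrogenic"
  if (is.null(opd)) opd <- if (electro) 1.0 else 1.6
  if (is.null(suboxicWidth)) suboxicWidth <- if (electro) 10 else 0
  if (is.null(o2Uptake)) o2Uptake <- if (electro) 35.1 else 21.6
  if (is.null(phPeakAmplitude)) phPeakAmplitude <- if (electro) 0.25 else 0
  if (is.null(phMin)) phMin <- if (electro) 6.2 else 7.6
  if (is.null(copyProfiles)) copyProfiles <- .defaultCopyProfiles(electro)
  if (is.null(curveParams))
    curveParams <- list(TB = c(slope = -3.35, intercept = 36),
                        DSB = c(slope = -3.45, intercept = 37),
                        CB = c(slope = -3.40, intercept = 37))
  new("ScenarioSpec", regime = regime, opd = opd, suboxicWidth = suboxicWidth,
      o2Uptake = o2Uptake, sulfideFlux = sulfideFlux,
      phPeakAmplitude = phPeakAmplitude, phMin = phMin,
      phMinDepth = phMinDepth, phBackground = phBackground,
      porosity = porosity, temperature = temperature, salinity = salinity,
      copyProfiles = copyProfiles, curveParams = curveParams,
      cqNoiseSd = cqNoiseSd, seed = as.integer(seed))
}

.defaultCopyProfiles <- function(electro) {
  top <- seq(0, 2.5, by = 0.5); bottom <- top + 0.5
  nlay <- length(top)
  tb <- c(1.3e10, rep(5.4e9, nlay - 1))
  if (electro) {
    cb <- c(3e8, 3e8, 3e8, 1e7, 2e6, 1e6)
    dsb <- c(4.6e8, 4.6e8, 3e8, 1.6e8, 1.5e8, 1.5e8)
  } else {
    cb <- rep(9.1e4, nlay)
    dsb <- rep(1.5e8, nlay)
  }
  mk <- function(v) data.frame(layer_top_cm = top, layer_bottom_cm = bottom,
                               copies_per_g = v)
  list(TB = mk(tb), DSB = mk(dsb), CB = mk(cb))
}

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec <%s> (seed %d)\n", object@regime, object@seed))
  cat(sprintf("  OPD %g mm, suboxic width %g mm, O2 uptake %g, sulfide flux %g mmol m-2 d-1\n",
              object@opd, object@suboxicWidth, object@o2Uptake,
              object@sulfideFlux))
  cat(sprintf("  pH: background %g, peak +%g, min %g at %g mm\n",
              object@phBackground, object@phPeakAmplitude, object@phMin,
              object@phMinDepth))
})

#' Generate synthetic pore-water depth profiles
#'
#' Emits O2, free H2S, total sulfide and pH profiles on a regular microsensor
#' grid (default 50 um step to 30 mm, with 2 mm of overlying water). The O2
#' gradient is inverted from the planted diffusive uptake through the
#' tortuosity-corrected Fick expression, so that [fickFlux()] recovers the
#' planted flux exactly in the noiseless case; O2 reaches zero exactly at
#' the planted OPD, which fixes the interface concentration. Total sulfide
#' is zero through the suboxic zone and rises below it with the gradient
#' inverted from the planted upward flux. pH carries a subsurface maximum at
#' the OPD and a deep minimum (electrogenic regime only). Free H2S is
#' back-computed from total sulfide and pH so that [sumH2S()] reproduces the
#' planted total exactly.
#'
#' @param spec a [ScenarioSpec-class].
#' @param step grid step, mm (default 0.05).
#' @param maxDepth deepest grid point, mm (default 30).
#' @param noiseSd Gaussian concentration noise, umol L-1 (default 0);
#'   seeded from `spec@seed`, values floored at 0.
#' @param pK1 first dissociation exponent used to back-compute free H2S.
#' @param DO2,DH2S diffusion coefficients, m2 d-1.
#' @return named list of [DepthProfile-class] (`O2`, `H2S`, `SumH2S`, `pH`).
#' @export
genPorewater <- function(spec, step = 0.05, maxDepth = 30, noiseSd = 0,
                         pK1 = 6.6,
                         DO2 = diffusionCoefficient("O2"),
                         DH2S = diffusionCoefficient("H2S")) {
  stopifnot(is(spec, "ScenarioSpec"))
  depth <- seq(-2, maxDepth, by = step)
  phi <- spec@porosity
  tf <- tortuosityFactor(phi)
  ## invert J = phi * D / tf * slope(SI); slope in umol L-1 mm-1
  o2_slope <- spec@o2Uptake * tf / (phi * DO2) / 1000
  c0 <- o2_slope * spec@opd
  o2 <- ifelse(depth < 0, c0, pmax(0, c0 - o2_slope * depth))
  appearance <- spec@opd + spec@suboxicWidth
  s_slope <- spec@sulfideFlux * tf / (phi * DH2S) / 1000
  sumh2s <- pmax(0, s_slope * (depth - appearance))
  ph <- spec@phBackground +
    spec@phPeakAmplitude * exp(-((depth - spec@opd) / (spec@opd / 1.5))^2) -
    (spec@phBackground - spec@phMin) *
      exp(-((depth - spec@phMinDepth) / 5)^2)
  ph[depth < 0] <- spec@phBackground
  if (noiseSd > 0) {
    set.seed(spec@seed)
    o2 <- pmax(0, o2 + stats::rnorm(length(o2), sd = noiseSd))
    sumh2s <- pmax(0, sumh2s + stats::rnorm(length(sumh2s), sd = noiseSd))
  }
  h2s <- sumh2s / (1 + 10^(ph - pK1))
  mk <- function(an, v) DepthProfile(an, depth, v, temperature = spec@temperature,
                                     salinity = spec@salinity, porosity = phi)
  list(O2 = mk("O2", o2), H2S = mk("H2S", h2s),
       SumH2S = mk("SumH2S", sumh2s), pH = mk("pH", ph))
}

#' Generate a synthetic qPCR table (standards plus samples)
#'
#' Standards form a 10-fold dilution series per target (default 10 to 1e7
#' copies ul-1) with Cq from the planted log-linear curve. Sample Cq values
#' are computed from the planted layer copy densities through the curve,
#' dilution factor, elution volume and wet mass, with optional Gaussian Cq
#' noise; all randomness is seeded from `spec@seed`.
#'
#' @param spec a [ScenarioSpec-class].
#' @param decades standards span, log10 copies (default 1:7).
#' @param nReplicates sample replicate wells (default 2).
#' @param elutionVolume DNA elution volume, ul (default 50).
#' @param wetMass extracted wet sediment mass, g (default 0.5).
#' @param dilutionFactors named per-target fold dilutions (defaults: 1e4
#'   for TB, 1e2 for DSB and CB).
#' @return data.frame in the format read by [readQpcrTable()], with a
#'   `truth_copies_per_g` column on sample rows.
#' @export
genQpcr <- function(spec, decades = 1:7, nReplicates = 2,
                    elutionVolume = 50, wetMass = 0.5,
                    dilutionFactors = c(TB = 1e4, DSB = 1e2, CB = 1e2)) {
  stopifnot(is(spec, "ScenarioSpec"))
  set.seed(spec@seed + 1L)
  rows <- list()
  for (target in names(spec@copyProfiles)) {
    pars <- spec@curveParams[[target]]
    if (pars["slope"] >= 0) stop("curve slopes must be negative")
    cqOf <- function(copies) pars["intercept"] + pars["slope"] * log10(copies)
    std_copies <- 10^decades
    for (cp in std_copies) {
      cq <- cqOf(cp) + if (spec@cqNoiseSd > 0)
        stats::rnorm(1, sd = spec@cqNoiseSd) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        target = target, sample_id = sprintf("%s_std_%g", target, cp),
        depth_top_cm = NA_real_, depth_bottom_cm = NA_real_,
        cq = unname(cq), dilution_factor = 1,
        elution_volume_ul = NA_real_, wet_mass_g = NA_real_,
        role = "standard", copies_per_ul = cp,
        truth_copies_per_g = NA_real_, stringsAsFactors = FALSE)
    }
    prof <- spec@copyProfiles[[target]]
    dil <- unname(dilutionFactors[target])
    for (i in seq_len(nrow(prof))) {
      density <- prof$copies_per_g[i]
      copies_ul <- density * wetMass / (elutionVolume * dil)
      for (r in seq_len(nReplicates)) {
        cq <- cqOf(copies_ul) + if (spec@cqNoiseSd > 0)
          stats::rnorm(1, sd = spec@cqNoiseSd) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          target = target,
          sample_id = sprintf("%s_L%02d", target, i),
          depth_top_cm = prof$layer_top_cm[i],
          depth_bottom_cm = prof$layer_bottom_cm[i],
          cq = unname(cq), dilution_factor = dil,
          elution_volume_ul = elutionVolume, wet_mass_g = wetMass,
          role = "sample", copies_per_ul = NA_real_,
          truth_copies_per_g = density, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

.BASES <- c("A", "C", "G", "T")

## A concrete base NOT matched by the primer's IUPAC code at one position.
.mismatchBase <- function(code) {
  allowed <- .iupacSets()[[code]]
  sample(setdiff(.BASES, allowed), 1)
}

#' Generate a synthetic 16S reference set with planted primer sites
#'
#' Builds random 16S-length sequences. In-target records carry exact binding
#' sites for both primers in productive orientation with an amplicon length
#' drawn at most `maxAmplicon`; off-target records carry sites with
#' mismatches planted at the primer positions given in `mismatchSpec`.
#' Taxonomy labels are assigned by class. Used as a local stand-in for a
#' curated reference database in specificity screening.
#'
#' @param nInTarget number of in-target records.
#' @param nOffTarget number of off-target records.
#' @param fwd,rev the primer pair ([DegeneratePrimer-class]).
#' @param mismatchSpec list with integer vectors `fwd` and/or `rev`: 1-based
#'   primer positions mutated in off-target records.
#' @param seed integer seed.
#' @param seqLen template length, bp (default 800).
#' @param ampliconRange range the planted amplicon length is drawn from.
#' @param maxAmplicon upper bound enforced on planted amplicons.
#' @param inTaxon,offTaxon lineage strings for the two classes.
#' @return list with `sequences` (named character), `taxonomy` (named
#'   character) and `truth` (data.frame: record id, class, planted amplicon
#'   length).
#' @export
genReferenceDb <- function(nInTarget, nOffTarget, fwd, rev,
                           mismatchSpec = list(fwd = integer(), rev = integer()),
                           seed = 1L, seqLen = 800,
                           ampliconRange = c(150, 200), maxAmplicon = 200,
                           inTaxon = "Bacteria;Desulfobulbaceae;Ca. Electrothrix",
                           offTaxon = "Bacteria;Desulfobulbaceae;Desulfobulbus") {
  stopifnot(is(fwd, "DegeneratePrimer"), is(rev, "DegeneratePrimer"))
  kf <- nchar(fwd@sequence); kr <- nchar(rev@sequence)
  bad_pos <- c(mismatchSpec$fwd[mismatchSpec$fwd > kf],
               mismatchSpec$rev[mismatchSpec$rev > kr])
  if (length(bad_pos)) stop("mismatch positions exceed primer length")
  set.seed(seed)
  fvar <- expandDegenerate(fwd); rvar <- expandDegenerate(rev)
  fch_codes <- .primerChars(fwd); rch_codes <- .primerChars(rev)
  mk_record <- function(id, mismatched) {
    seq <- sample(.BASES, seqLen, replace = TRUE)
    len <- sample(seq(ampliconRange[1], min(ampliconRange[2], maxAmplicon)), 1)
    fstart <- sample(seq(50, seqLen - len - 50), 1)   # 1-based fwd 5'
    fsite <- strsplit(sample(fvar, 1), "")[[1]]
    rsite <- strsplit(sample(rvar, 1), "")[[1]]        # 5'->3' on reverse strand
    if (mismatched) {
      for (p in mismatchSpec$fwd) fsite[p] <- .mismatchBase(fch_codes[p])
      for (p in mismatchSpec$rev) rsite[p] <- .mismatchBase(rch_codes[p])
    }
    seq[fstart:(fstart + kf - 1L)] <- fsite
    rc <- base::rev(c(A = "T", C = "G", G = "C", T = "A")[rsite])  # plus strand
    rend <- fstart + len - 1L                                 # rev 5' position
    seq[(rend - kr + 1L):rend] <- rc
    list(seq = paste0(seq, collapse = ""), len = len)
  }
  ids <- c(sprintf("in_%03d", seq_len(nInTarget)),
           sprintf("off_%03d", seq_len(nOffTarget)))
  classes <- rep(c("in_target", "off_target"), c(nInTarget, nOffTarget))
  recs <- mapply(function(id, cl) mk_record(id, cl == "off_target"),
                 ids, classes, SIMPLIFY = FALSE)
  sequences <- vapply(recs, `[[`, character(1), "seq")
  names(sequences) <- ids
  taxonomy <- stats::setNames(ifelse(classes == "in_target", inTaxon, offTaxon),
                              ids)
  truth <- data.frame(record_id = ids, class = classes,
                      amplicon_length = vapply(recs, `[[`, numeric(1), "len"),
                      stringsAsFactors = FALSE)
  list(sequences = sequences, taxonomy = taxonomy, truth = truth)
}

#' Generate a depth-layered ASV count table by multinomial sampling
#'
#' Draws reads per taxon and layer from a multinomial with the planted
#' relative abundances; any probability mass not assigned to a named taxon
#' goes to an `Other_Bacteria` row.
#'
#' @param relAbundances numeric matrix of planted fractions, rows = taxa
#'   (rownames required), columns = layers; column sums must be <= 1.
#' @param totalReads reads per layer (single value or per-layer vector;
#'   default 52000).
#' @param seed integer seed.
#' @return list with `counts` (integer matrix including the
#'   `Other_Bacteria` row) and `taxa` (rowname vector).
#' @export
genCommunityReads <- function(relAbundances, totalReads = 52000, seed = 1L) {
  relAbundances <- as.matrix(relAbundances)
  if (is.null(rownames(relAbundances))) stop("relAbundances needs rownames")
  if (any(colSums(relAbundances) > 1 + 1e-12))
    stop("per-layer abundances must sum to at most 1")
  nl <- ncol(relAbundances)
  totalReads <- rep_len(totalReads, nl)
  set.seed(seed)
  counts <- sapply(seq_len(nl), function(j) {
    p <- c(relAbundances[, j], Other_Bacteria = 1 - sum(relAbundances[, j]))
    stats::rmultinom(1, totalReads[j], p)[, 1]
  })
  rownames(counts) <- c(rownames(relAbundances), "Other_Bacteria")
  colnames(counts) <- colnames(relAbundances)
  list(counts = counts, taxa = rownames(counts))
}
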