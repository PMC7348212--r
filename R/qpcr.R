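#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of Cq against log10(copies) for a dilution
#' series of standards (at least three distinct concentrations; practice is a
#' 10-fold series over four or more decades). The amplification efficiency is
#' `10^(-1/slope) - 1`; a slope of `-1/log10(2)` (about -3.3219) means exact
#' per-cycle doubling, i.e. 100 percent efficiency.
#'
#' @param copies template concentrations of the standards, copies ul-1 (> 0).
#' @param cq matching Cq values (replicates allowed: repeat concentrations).
#' @param target `"TB"`, `"DSB"` or `"CB"` (label only).
#' @return a [CalibrationCurve-class].
#' @examples
#' copies <- 10^(1:5)
#' fitStandardCurve(copies, 35 - 3.321928 * log10(copies))
#' @export
fitStandardCurve <- function(copies, cq, target = "CB") {
  if (length(copies) != length(cq)) stop("copies and cq must match in length")
  if (any(copies <= 0)) stop("standard copies must be > 0")
  if (length(unique(copies)) < 3L)
    stop("at least 3 distinct standard concentrations required")
  x <- log10(copies)
  fit <- stats::lm(cq ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("invalid standard curve: slope must be negative (Cq decreasing with copies)")
  new("CalibrationCurve", slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      efficiency = 10^(-1 / slope) - 1,
      r2 = suppressWarnings(summary(fit))$r.squared,
      nStandards = length(cq), target = target)
}

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve <%s>: Cq = %0.3f %+0.4f * log10(copies)\n",
              object@target, object@intercept, object@slope))
  cat(sprintf("  efficiency %0.1f%%, r2 = %0.4f, n = %d standards\n",
              100 * object@efficiency, object@r2, object@nStandards))
})

#' Quantify a sample from its Cq values
#'
#' Replicate Cq values are averaged on the Cq scale (the noise model is
#' log-domain), inverted through the standard curve to copies per microlitre
#' of the diluted template, and scaled to copies per gram of wet sediment:
#' `copy_density = copies_per_ul * dilution_factor * elution_volume / wet_mass`.
#' Samples whose mean Cq exceeds the no-template cutoff are flagged as below
#' detection (density `NA`, never imputed as zero).
#'
#' @param cq replicate Cq values.
#' @param curve a [CalibrationCurve-class].
#' @param dilutionFactor fold dilution of the template before qPCR.
#' @param elutionVolume DNA elution volume, microlitres.
#' @param wetMass wet sediment mass extracted, grams.
#' @param cqCutoff no-template Cq cutoff (default 38).
#' @return a [SampleQuant-class].
#' @examples
#' curve <- fitStandardCurve(10^(1:5), 35 - 3.321928 * log10(10^(1:5)))
#' quantifySample(c(24.0, 24.1), curve, dilutionFactor = 100,
#'                elutionVolume = 50, wetMass = 0.5)
#' @export
quantifySample <- function(cq, curve, dilutionFactor, elutionVolume, wetMass,
                           cqCutoff = 38) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (wetMass <= 0) stop("wet mass must be > 0")
  if (dilutionFactor <= 0 || elutionVolume <= 0)
    stop("dilution factor and elution volume must be > 0")
  mcq <- mean(cq)
  below <- mcq > cqCutoff
  scale <- dilutionFactor * elutionVolume / wetMass
  per_rep <- 10^((cq - curve@intercept) / curve@slope)
  cv <- if (length(cq) > 1L) stats::sd(per_rep) / mean(per_rep) else NA_real_
  copies <- if (below) NA_real_ else 10^((mcq - curve@intercept) / curve@slope)
  new("SampleQuant", cq = as.numeric(cq), dilutionFactor = dilutionFactor,
      elutionVolume = elutionVolume, wetMass = wetMass,
      copiesPerUl = if (below) NA_real_ else copies,
      copyDensity = if (below) NA_real_ else copies * scale,
      cv = cv, belowDetection = below, target = curve@target)
}

setMethod("show", "SampleQuant", function(object) {
  if (object@belowDetection) {
    cat(sprintf("SampleQuant <%s>: below detection (mean Cq %0.2f)\n",
                object@target, mean(object@cq)))
  } else {
    cat(sprintf("SampleQuant <%s>: %0.4g copies (g wet sediment)-1\n",
                object@target, object@copyDensity))
    cat(sprintf("  mean Cq %0.2f (%d replicates, CV %s), dilution %gx, %g ul / %g g\n",
                mean(object@cq), length(object@cq),
                ifelse(is.na(object@cv), "-", sprintf("%0.1f%%", 100 * object@cv)),
                object@dilutionFactor, object@elutionVolume, object@wetMass))
  }
})

#' qPCR detection limit in copies per gram of wet sediment
#'
#' Propagates the smallest copy concentration reliably detected in a reaction
#' through the same dilution, elution and mass factors as [quantifySample()]:
#' `limit = min_detectable * dilution_factor * elution_volume / wet_mass`.
#' All factors are explicit arguments, because the resulting limit depends on
#' every one of them.
#'
#' @param minDetectable minimum detectable concentration, copies ul-1.
#' @param dilutionFactor fold template dilution.
#' @param elutionVolume DNA elution volume, microlitres.
#' @param wetMass wet sediment mass, grams.
#' @return detection limit, copies per gram of wet sediment.
#' @examples
#' detectionLimit(10, 100, 50, 0.5) # 1e5 copies g-1
#' @export
detectionLimit <- function(minDetectable, dilutionFactor, elutionVolume, wetMass) {
  if (any(c(minDetectable, dilutionFactor, elutionVolume, wetMass) <= 0))
    stop("all inputs must be > 0")
  minDetectable * dilutionFactor * elutionVolume / wetMass
}

#' Read a combined qPCR standards-plus-samples table
#'
#' Expects a TSV with columns `target`, `sample_id`, `depth_top_cm`,
#' `depth_bottom_cm`, `cq`, `dilution_factor`, `elution_volume_ul`,
#' `wet_mass_g`, `role` (`standard` or `sample`) and `copies_per_ul`
#' (standards only).
#'
#' @param path path to the TSV file.
#' @return data.frame of the table.
#' @export
readQpcrTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  needed <- c("target", "sample_id", "cq", "role")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("qPCR table lacks columns: ", paste(missing, collapse = ", "))
  df
}

#' Copy-density depth profile from a qPCR table
#'
#' For one target, fits the standard curve from the table's `standard` rows
#' and quantifies every `sample` row, aggregating replicate wells by
#' `sample_id`. Below-detection samples are excluded from layer means.
#'
#' @param qtable data.frame from [readQpcrTable()].
#' @param target `"TB"`, `"DSB"` or `"CB"`.
#' @param cqCutoff no-template Cq cutoff passed to [quantifySample()].
#' @return list with `curve` (a [CalibrationCurve-class]) and `profile`
#'   (data.frame: `sample_id`, `layer_top_cm`, `layer_bottom_cm`, `target`,
#'   `copies_per_g`, `cv`, `below_detection`).
#' @export
quantifyTable <- function(qtable, target, cqCutoff = 38) {
  sub <- qtable[qtable$target == target, , drop = FALSE]
  std <- sub[sub$role == "standard", , drop = FALSE]
  smp <- sub[sub$role == "sample", , drop = FALSE]
  if (nrow(std) == 0L) stop("no standards for target ", target)
  curve <- fitStandardCurve(std$copies_per_ul, std$cq, target = target)
  ids <- unique(smp$sample_id)
  rows <- lapply(ids, function(id) {
    s <- smp[smp$sample_id == id, , drop = FALSE]
    q <- quantifySample(s$cq, curve,
                        dilutionFactor = s$dilution_factor[1],
                        elutionVolume = s$elution_volume_ul[1],
                        wetMass = s$wet_mass_g[1], cqCutoff = cqCutoff)
    data.frame(sample_id = id,
               layer_top_cm = s$depth_top_cm[1],
               layer_bottom_cm = s$depth_bottom_cm[1],
               target = target,
               copies_per_g = q@copyDensity,
               cv = q@cv,
               below_detection = q@belowDetection,
               stringsAsFactors = FALSE)
  })
  list(curve = curve, profile = do.call(rbind, rows))
}
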