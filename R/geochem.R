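#' Construct a DepthProfile
#'
#' @param analyte one of `"O2"`, `"H2S"`, `"SumH2S"`, `"pH"`.
#' @param depth depths in mm, strictly increasing (0 = sediment-water
#'   interface, positive downward), at least 3 points.
#' @param value concentrations (umol L-1) or pH values, same length.
#' @param temperature degrees C.
#' @param salinity practical salinity.
#' @param porosity sediment porosity, fraction in (0, 1].
#' @return a [DepthProfile-class] object.
#' @examples
#' o2 <- DepthProfile("O2", depth = c(0, 0.5, 1), value = c(250, 125, 0))
#' @export
DepthProfile <- function(analyte, depth, value,
                         temperature = 16, salinity = 30, porosity = 0.88) {
  new("DepthProfile", analyte = analyte, depth = as.numeric(depth),
      value = as.numeric(value), temperature = temperature,
      salinity = salinity, porosity = porosity)
}

setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile <%s>: %d points, %.2f to %.2f mm\n",
              object@analyte, length(object@depth),
              min(object@depth), max(object@depth)))
  cat(sprintf("  T = %g degC, S = %g, porosity = %g\n",
              object@temperature, object@salinity, object@porosity))
})

#' Read depth profiles from a delimited table
#'
#' Accepts one file per analyte (columns `depth_mm`, `value`) or a long table
#' with an extra `analyte` column. Metadata lines of the form
#' `# key: value` (keys `temperature`, `salinity`, `porosity`) preceding the
#' header are honoured.
#'
#' @param path path to a TSV/CSV file.
#' @param analyte analyte name, required for two-column files.
#' @param sep field separator (default tab).
#' @return a [DepthProfile-class], or a named list of them for long tables.
#' @export
readProfileTable <- function(path, analyte = NULL, sep = "\t") {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(temperature = 16, salinity = 30, porosity = 0.88)
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*([-0-9.eE]+)", ln))[[1]]
    if (length(m) == 3 && m[2] %in% names(meta)) meta[[m[2]]] <- as.numeric(m[3])
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  build <- function(sub, an) {
    sub <- sub[order(sub$depth_mm), , drop = FALSE]
    DepthProfile(an, sub$depth_mm, sub$value, temperature = meta$temperature,
                 salinity = meta$salinity, porosity = meta$porosity)
  }
  if ("analyte" %in% names(df)) {
    split_df <- split(df, df$analyte)
    out <- lapply(names(split_df), function(an) build(split_df[[an]], an))
    names(out) <- names(split_df)
    out
  } else {
    if (is.null(analyte)) stop("two-column profile tables need an 'analyte' argument")
    build(df, analyte)
  }
}

#' Write a set of depth profiles to a long-format TSV
#'
#' @param profiles a [DepthProfile-class] or list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProfileTable <- function(profiles, path) {
  if (is(profiles, "DepthProfile")) profiles <- list(profiles)
  p1 <- profiles[[1]]
  hdr <- sprintf("# %s: %g", c("temperature", "salinity", "porosity"),
                 c(p1@temperature, p1@salinity, p1@porosity))
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(analyte = p@analyte, depth_mm = p@depth, value = p@value)))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(rows, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

## Linear interpolation of a profile onto new depths; error if outside range.
.interpProfile <- function(profile, depth) {
  rng <- range(profile@depth)
  if (any(depth < rng[1] - 1e-9) || any(depth > rng[2] + 1e-9))
    stop("profiles do not overlap: cannot interpolate outside the measured range")
  stats::approx(profile@depth, profile@value, xout = depth, rule = 1)$y
}

#' Total dissolved sulfide from free H2S and pH
#'
#' Total sulfide is the sum of H2S and HS-; with the first dissociation
#' exponent pK1 of H2S, `SumH2S(z) = [H2S](z) * (1 + 10^(pH(z) - pK1))`.
#' The pH profile is interpolated linearly onto the H2S depth grid.
#'
#' @param h2s a [DepthProfile-class] of analyte `"H2S"`.
#' @param ph a [DepthProfile-class] of analyte `"pH"`, overlapping in depth.
#' @param pK1 first dissociation exponent of H2S; default 6.6, a typical
#'   seawater value near the incubation temperature and salinity.
#' @return a [DepthProfile-class] of analyte `"SumH2S"` on the H2S grid.
#' @examples
#' h2s <- DepthProfile("H2S", c(10, 12, 14), c(0, 10, 20))
#' ph <- DepthProfile("pH", c(10, 12, 14), c(6.6, 6.6, 6.6))
#' profileValues(sumH2S(h2s, ph)) # doubled: equal speciation at pH = pK1
#' @export
sumH2S <- function(h2s, ph, pK1 = 6.6) {
  stopifnot(is(h2s, "DepthProfile"), is(ph, "DepthProfile"))
  if (h2s@analyte != "H2S") stop("first profile must have analyte 'H2S'")
  if (ph@analyte != "pH") stop("second profile must have analyte 'pH'")
  if (is.null(pK1) || !is.finite(pK1)) stop("pK1 must be supplied as a finite number")
  ph_on_grid <- .interpProfile(ph, h2s@depth)
  total <- h2s@value * (1 + 10^(ph_on_grid - pK1))
  DepthProfile("SumH2S", h2s@depth, total, temperature = h2s@temperature,
               salinity = h2s@salinity, porosity = h2s@porosity)
}

#' Diffusive flux from a depth profile by Fick's first law
#'
#' Fits the concentration gradient over a depth window by ordinary least
#' squares and converts it into a diffusive flux with the tortuosity-corrected
#' Fick expression `J = -phi * D / (1 - 2 ln(phi)) * dC/dz`. The sign
#' convention is positive downward, so an O2 profile decreasing into the
#' sediment yields a positive diffusive uptake.
#'
#' @param profile a [DepthProfile-class]; porosity is taken from its metadata.
#' @param D molecular diffusion coefficient, m2 d-1
#'   (see [diffusionCoefficient()]).
#' @param window depth interval `c(top, bottom)` in mm over which to fit the
#'   slope. When `NULL`, defaults to the interface-to-OPD window for O2
#'   profiles and to the `nPoints` samples from the sulfide appearance depth
#'   for SumH2S profiles (both located with [detectZonation()] thresholds).
#' @param nPoints number of points used by the default SumH2S window.
#' @param threshold detection threshold (umol L-1) used by default windows.
#' @return a [FluxEstimate-class].
#' @examples
#' o2 <- DepthProfile("O2", seq(0, 1, by = 0.1), seq(300, 0, by = -30))
#' fickFlux(o2, D = diffusionCoefficient("O2"), window = c(0, 1))
#' @export
fickFlux <- function(profile, D, window = NULL, nPoints = 4, threshold = 1) {
  stopifnot(is(profile, "DepthProfile"))
  if (!is.numeric(D) || length(D) != 1L || D <= 0) stop("D must be a single value > 0")
  phi <- profile@porosity
  if (is.null(window)) window <- .defaultFitWindow(profile, nPoints, threshold)
  window <- sort(as.numeric(window))
  inw <- profile@depth >= window[1] - 1e-12 & profile@depth <= window[2] + 1e-12
  x <- profile@depth[inw]; y <- profile@value[inw]
  if (length(x) < 2L) stop("fewer than 2 points inside the fit window")
  if (length(x) == 2L) {
    slope <- (y[2] - y[1]) / (x[2] - x[1]); r2 <- 1
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    r2 <- suppressWarnings(summary(fit))$r.squared
  }
  tf <- tortuosityFactor(phi)
  ## slope is umol L-1 mm-1 = mmol m-3 mm-1; x1000 gives mmol m-4 (SI depth)
  J <- -phi * D / tf * slope * 1000
  new("FluxEstimate", J = J, slope = slope, D = D, tortuosityFactor = tf,
      window = window, r2 = r2, analyte = profile@analyte,
      n = length(x))
}

## Default fit windows: O2 from the interface to the OPD; SumH2S the first
## nPoints samples at/below the sulfide appearance depth (base of the suboxic
## zone). Window sizes are a package choice: the source measurements do not
## prescribe them, which is why `window` is always overridable.
.defaultFitWindow <- function(profile, nPoints, threshold) {
  if (profile@analyte == "O2") {
    opd <- .firstCrossing(profile@depth, profile@value, threshold, below = TRUE,
                          from_depth = 0)
    if (is.na(opd)) stop("O2 never falls below threshold: supply an explicit window")
    c(0, opd)
  } else if (profile@analyte == "SumH2S") {
    app <- .firstCrossing(profile@depth, profile@value, threshold, below = FALSE)
    if (is.na(app)) stop("sulfide never exceeds threshold: supply an explicit window")
    idx <- which(profile@depth >= app - 1e-9)
    idx <- idx[seq_len(min(nPoints, length(idx)))]
    range(profile@depth[idx])
  } else {
    stop("no default window for analyte '", profile@analyte,
         "': supply `window`")
  }
}

## Shallowest depth >= from_depth where the series first crosses `threshold`
## (below = TRUE: falls below; FALSE: exceeds), linearly interpolated between
## bracketing samples. NA when no crossing.
.firstCrossing <- function(depth, value, threshold, below, from_depth = -Inf) {
  keep <- depth >= from_depth
  depth <- depth[keep]; value <- value[keep]
  if (length(depth) < 1L) return(NA_real_)
  hit <- if (below) value < threshold else value > threshold
  if (!any(hit)) return(NA_real_)
  i <- which(hit)[1]
  if (i == 1L) return(depth[1])
  d0 <- depth[i - 1]; d1 <- depth[i]
  v0 <- value[i - 1]; v1 <- value[i]
  if (v1 == v0) return(d1)
  d0 + (threshold - v0) / (v1 - v0) * (d1 - d0)
}

#' Detect the oxic / suboxic / sulfidic zonation
#'
#' Locates the oxygen penetration depth (shallowest depth at or below the
#' interface where O2 first falls below the detection threshold, linearly
#' interpolated), the sulfide appearance depth (first exceedance of the
#' threshold by total sulfide), and the pH extremes on the measured grid.
#' The suboxic width is their difference, floored at zero. A wide suboxic
#' zone together with a subsurface pH maximum and deep pH minimum is the
#' pore-water fingerprint of electrogenic sulfur oxidation.
#'
#' @param o2 a [DepthProfile-class] of analyte `"O2"`.
#' @param sumh2s a [DepthProfile-class] of analyte `"SumH2S"` (or `"H2S"`).
#' @param ph optional [DepthProfile-class] of analyte `"pH"`.
#' @param threshold detection threshold, umol L-1 (default 1).
#' @return a [Zonation-class]; `opd` (and hence `suboxicWidth`) is `NA` when
#'   O2 never falls below the threshold.
#' @export
detectZonation <- function(o2, sumh2s, ph = NULL, threshold = 1) {
  stopifnot(is(o2, "DepthProfile"), is(sumh2s, "DepthProfile"))
  if (threshold <= 0) stop("threshold must be > 0")
  opd <- .firstCrossing(o2@depth, o2@value, threshold, below = TRUE,
                        from_depth = 0)
  app <- .firstCrossing(sumh2s@depth, sumh2s@value, threshold, below = FALSE)
  width <- if (is.na(opd) || is.na(app)) NA_real_ else max(app - opd, 0)
  if (!is.null(ph)) {
    stopifnot(is(ph, "DepthProfile"))
    imax <- which.max(ph@value); imin <- which.min(ph@value)
    phmax <- c(ph@depth[imax], ph@value[imax])
    phmin <- c(ph@depth[imin], ph@value[imin])
  } else {
    phmax <- c(NA_real_, NA_real_); phmin <- c(NA_real_, NA_real_)
  }
  new("Zonation", opd = opd,
      sulfideAppearance = if (is.na(app)) NA_real_ else app,
      suboxicWidth = width, phMax = phmax, phMin = phmin,
      threshold = threshold)
}

setMethod("show", "Zonation", function(object) {
  cat("Sediment zonation\n")
  cat(sprintf("  oxygen penetration depth: %s mm\n",
              format(object@opd, digits = 4)))
  cat(sprintf("  sulfide appearance depth: %s mm\n",
              format(object@sulfideAppearance, digits = 4)))
  cat(sprintf("  suboxic zone width:       %s mm\n",
              format(object@suboxicWidth, digits = 4)))
  if (!is.na(object@phMax[1]))
    cat(sprintf("  pH max %0.2f at %0.2f mm; pH min %0.2f at %0.2f mm\n",
                object@phMax[2], object@phMax[1],
                object@phMin[2], object@phMin[1]))
})

setMethod("show", "FluxEstimate", function(object) {
  cat(sprintf("FluxEstimate <%s>: J = %0.4g mmol m-2 d-1 (positive downward)\n",
              object@analyte, object@J))
  cat(sprintf("  slope %0.4g umol L-1 mm-1 over [%g, %g] mm (n = %d, r2 = %0.4f)\n",
              object@slope, object@window[1], object@window[2],
              object@n, object@r2))
  cat(sprintf("  D = %0.3g m2 d-1, tortuosity factor = %0.4f\n",
              object@D, object@tortuosityFactor))
})
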