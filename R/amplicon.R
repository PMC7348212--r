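#' Paired qPCR and amplicon relative abundances per depth layer
#'
#' For each sediment layer present in both data sets, computes the target's
#' relative abundance by qPCR (target copies / total-bacteria copies, in
#' percent) and by amplicon sequencing (target reads / reads classified as
#' Bacteria, in percent). Layers missing either measurement are dropped with
#' a message. The read denominator excludes unclassified reads by default,
#' mirroring the convention that only reads classified as Bacteria count.
#'
#' @param copyProfile data.frame with columns `layer`, `target`,
#'   `copies_per_g`; must contain rows for `"TB"` (total bacteria) and for
#'   `targetName` in each layer (e.g. built from [quantifyTable()] output
#'   with `layer = paste(layer_top_cm, layer_bottom_cm, sep = "-")`).
#' @param counts ASV count matrix, rows = ASVs, columns = layers (column
#'   names matching `copyProfile$layer`).
#' @param taxa character vector of taxonomy labels, one per row of `counts`.
#' @param targetName qPCR target to compare (default `"CB"`).
#' @param targetTaxon label (regular expression) identifying target reads.
#' @param unclassifiedLabel label (regular expression) of unclassified rows,
#'   excluded from the denominator unless `includeUnclassified`.
#' @param includeUnclassified keep unclassified reads in the denominator.
#' @return data.frame with columns `layer`, `qpcr_rel`, `amplicon_rel`
#'   (both percent).
#' @export
relativeAbundances <- function(copyProfile, counts, taxa,
                               targetName = "CB",
                               targetTaxon = "Electrothrix",
                               unclassifiedLabel = "^Unclassified",
                               includeUnclassified = FALSE) {
  stopifnot(nrow(counts) == length(taxa))
  ql <- copyProfile[copyProfile$target == targetName, , drop = FALSE]
  tb <- copyProfile[copyProfile$target == "TB", , drop = FALSE]
  layers <- intersect(intersect(ql$layer, tb$layer), colnames(counts))
  dropped <- setdiff(union(ql$layer, tb$layer), layers)
  if (length(dropped))
    message("dropping layers missing a measurement: ",
            paste(dropped, collapse = ", "))
  if (!length(layers)) stop("no shared layers between qPCR and amplicon data")
  is_target <- grepl(targetTaxon, taxa)
  keep <- if (includeUnclassified) rep(TRUE, length(taxa))
          else !grepl(unclassifiedLabel, taxa)
  rows <- lapply(layers, function(ly) {
    tot_reads <- sum(counts[keep, ly])
    if (tot_reads == 0) stop("zero classified reads in layer ", ly)
    q_t <- ql$copies_per_g[match(ly, ql$layer)]
    q_tb <- tb$copies_per_g[match(ly, tb$layer)]
    data.frame(layer = ly,
               qpcr_rel = 100 * q_t / q_tb,
               amplicon_rel = 100 * sum(counts[is_target & keep, ly]) / tot_reads,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Regression of qPCR on amplicon relative abundance
#'
#' Least-squares slope of the qPCR relative abundance on the amplicon
#' relative abundance across layers. Since the quantities are ratios of the
#' same population, the through-origin fit is the default; the
#' intercept variant is also available.
#'
#' @param pairs data.frame from [relativeAbundances()] (columns `qpcr_rel`,
#'   `amplicon_rel`).
#' @param throughOrigin force the line through the origin (default TRUE).
#' @return list with `slope`, `r2`, and `intercept` (0 for through-origin).
#' @export
ratioRegression <- function(pairs, throughOrigin = TRUE) {
  if (nrow(pairs) < 2L) stop("need at least 2 layer pairs")
  x <- pairs$amplicon_rel; y <- pairs$qpcr_rel
  if (stats::var(x) == 0 && !throughOrigin)
    stop("degenerate x-variance: amplicon abundances are constant")
  fit <- if (throughOrigin) stats::lm(y ~ 0 + x) else stats::lm(y ~ x)
  cf <- stats::coef(fit)
  list(slope = unname(cf[length(cf)]),
       intercept = if (throughOrigin) 0 else unname(cf[1]),
       r2 = suppressWarnings(summary(fit))$r.squared)
}

#' Copy-density detection limit of amplicon sequencing
#'
#' One read out of the layer's total corresponds to this many 16S copies per
#' gram of wet sediment, anchored by the qPCR total-bacteria copy density:
#' `limit = tb_copy_density / total_reads`. Taxa below this density cannot
#' be seen by the amplicon survey.
#'
#' @param tbCopyDensity total-bacteria 16S copy density, copies g-1.
#' @param totalReads total reads in the layer (>= 1).
#' @return detection limit, copies per gram wet sediment.
#' @examples
#' asvDetectionLimit(1.3e10, 52000)  # ~2.5e5 copies g-1
#' @export
asvDetectionLimit <- function(tbCopyDensity, totalReads) {
  if (any(totalReads < 1)) stop("total reads must be >= 1")
  if (any(tbCopyDensity < 0)) stop("copy density must be >= 0")
  tbCopyDensity / totalReads
}
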