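# qRT-PCR quantification: primer efficiencies from two-fold dilution
# series and 2^dCt relative expression normalised to the reference gene
# rpoB. Technical replicates are averaged before dCt; biological
# replicates are summarised by their min/max spread (the error-bar
# convention of the underlying study).

#' Assemble a qPCR Ct table
#'
#' @param data Data frame with columns `gene`, `strain`, `replicate`
#'   (biological replicate id) and `ct` (threshold cycles, > 0). Technical
#'   replicates may simply repeat the same `replicate` id.
#' @param reference_gene Housekeeping gene used for normalisation
#'   (default `"rpoB"`); must be measured in every strain.
#' @return Object of class `qpcr_table`.
#' @export
qpcr_table <- function(data, reference_gene = "rpoB") {
  need <- c("gene", "strain", "replicate", "ct")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("qPCR table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(data$ct)) || any(data$ct <= 0)) {
    stop("all Ct values must be finite and > 0")
  }
  for (s in unique(data$strain)) {
    if (!reference_gene %in% data$gene[data$strain == s]) {
      stop("reference gene '", reference_gene,
           "' not measured in strain '", s, "'")
    }
  }
  structure(list(data = data, reference_gene = reference_gene),
            class = "qpcr_table")
}

#' Standard curve from a dilution series
#'
#' @param log2_dilution Relative concentration on a log2 scale (e.g.
#'   0, -1, ..., -6 for a seven-point two-fold series).
#' @param ct Mean Ct at each dilution.
#' @return Object of class `standard_curve` with the fitted `slope`
#'   (Ct per log2 dilution) and `efficiency` (fold amplification per
#'   cycle).
#' @export
standard_curve <- function(log2_dilution, ct) {
  stopifnot(length(log2_dilution) == length(ct))
  if (length(ct) < 4) {
    stop("a standard curve needs at least 4 dilution points")
  }
  fit <- stats::lm(ct ~ log2_dilution)
  slope <- stats::coef(fit)[[2]]
  if (slope >= 0) {
    stop("standard-curve slope is non-negative; dilution series inverted?")
  }
  structure(
    list(log2_dilution = log2_dilution, ct = ct, slope = slope,
         efficiency = 2^(-1 / slope), fit = fit),
    class = "standard_curve"
  )
}

#' Primer efficiency from a standard curve
#'
#' With a two-fold dilution series the least-squares slope `m` of Ct
#' versus log2(concentration) gives the per-cycle amplification factor
#' `E = 2^(-1/m)`; perfect doubling (`m = -1`) gives `E = 2`. For
#' comparison with the ten-fold convention, `E = 10^(-1/m10)` with `m10`
#' the slope per log10 dilution; the attribute `slope_log10` carries the
#' converted slope.
#'
#' @param curve A [standard_curve()], or a data frame / list with
#'   `log2_dilution` and `ct` from which one is built.
#' @return Efficiency (fold per cycle), with attributes `slope` and
#'   `slope_log10`.
#' @examples
#' sc <- standard_curve(0:-6, 20 - (0:-6))
#' primer_efficiency(sc)   # 2
#' @export
primer_efficiency <- function(curve) {
  if (!inherits(curve, "standard_curve")) {
    curve <- standard_curve(curve$log2_dilution, curve$ct)
  }
  structure(curve$efficiency, slope = curve$slope,
            slope_log10 = curve$slope * log2(10))
}

#' Relative expression by the 2^dCt method
#'
#' Computes `2^(Ct_ref - Ct_gene)` per biological replicate after
#' averaging technical replicates, normalised to the reference gene
#' measured in the same strain (and replicate). The point estimate uses
#' the replicate-mean Cts; the spread across biological replicates is
#' reported as min/max.
#'
#' @param table A [qpcr_table()].
#' @param gene Target gene.
#' @param strain Strain to evaluate.
#' @return Fold expression (dimensionless) with attributes `min`, `max`
#'   and `n_replicates`.
#' @export
relative_expression <- function(table, gene, strain) {
  stopifnot(inherits(table, "qpcr_table"))
  d <- table$data
  dg <- d[d$gene == gene & d$strain == strain, ]
  dr <- d[d$gene == table$reference_gene & d$strain == strain, ]
  if (nrow(dg) == 0) {
    stop("gene '", gene, "' not measured in strain '", strain, "'")
  }
  if (nrow(dr) == 0) {
    stop("reference gene '", table$reference_gene,
         "' not measured in strain '", strain, "'")
  }
  # technical replicates -> mean Ct per biological replicate
  ctg <- tapply(dg$ct, dg$replicate, mean)
  ctr <- tapply(dr$ct, dr$replicate, mean)
  common <- intersect(names(ctg), names(ctr))
  folds <- if (length(common) > 0) {
    2^(ctr[common] - ctg[common])
  } else {
    2^(mean(ctr) - mean(ctg))
  }
  structure(2^(mean(ctr) - mean(ctg)),
            min = min(folds), max = max(folds),
            n_replicates = length(folds))
}
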