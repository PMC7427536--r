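# Fermentation analytics: OD/CDW conversion, growth rates, four-parameter
# logistic fits, and the yield suite (g/g, Cmol/Cmol, product-to-biomass,
# space-time, acetate-corrected).

#' Molar constants used by the yield arithmetic
#'
#' Carbon-mole masses and molecular weights of the species entering the
#' yield computations: HAA (C10-C10 di-lipid, C20H38O5, MW 358.5, 20 C),
#' mono-rhamnolipid (Rha-C10-C10, C26H48O9, MW 504.7, 26 C), ethanol
#' (23.03 g/Cmol), glucose (30.03 g/Cmol), acetate (59.04 g/mol as the
#' anion, 2 C), and the ethanol density 0.789 g/mL.
#'
#' @format Named list.
#' @export
rf_constants <- function() {
  list(
    mw_haa = molecular_weight("C20H38O5"),          # 358.5
    c_haa = 20,
    mw_rhl = molecular_weight("C26H48O9"),          # 504.7
    c_rhl = 26,
    g_per_cmol_etoh = molecular_weight("C2H6O") / 2,    # 23.03
    g_per_cmol_glc = molecular_weight("C6H12O6") / 6,   # 30.03
    mw_acetate = 59.04, c_acetate = 2,
    ethanol_density = 0.789,                        # g/mL at 20 degC
    od_to_cdw = 0.313                               # g CDW per OD600 unit
  )
}

#' Convert optical density to cell dry weight
#'
#' Uses the calibration OD600 1.0 = 313 mg CDW per L.
#'
#' @param od OD600 (>= 0, scalar or vector).
#' @return CDW in g/L.
#' @examples
#' od_to_cdw(1)   # 0.313
#' @export
od_to_cdw <- function(od) {
  if (any(od < 0)) stop("OD must be >= 0")
  od * rf_constants()$od_to_cdw
}

#' Mass of a volume of pure ethanol
#' @param volume Volume in mL (>= 0).
#' @return Mass in g (density 0.789 g/mL).
#' @examples
#' ethanol_mass(96)   # 75.7 g
#' @export
ethanol_mass <- function(volume) {
  if (any(volume < 0)) stop("volume must be >= 0")
  volume * rf_constants()$ethanol_density
}

#' Space-time yield
#' @param titer Product titer, g/L.
#' @param duration Process duration, h (> 0).
#' @return Yield in g/(L h).
#' @examples
#' space_time_yield(5.3, 23)   # 0.23
#' @export
space_time_yield <- function(titer, duration) {
  if (any(duration <= 0)) stop("duration must be > 0")
  titer / duration
}

#' Product-to-biomass yield
#' @param product Product concentration, g/L.
#' @param cdw Cell dry weight, g/L (> 0).
#' @return g product per g CDW.
#' @export
product_to_biomass <- function(product, cdw) {
  if (any(cdw <= 0)) stop("cdw must be > 0")
  product / cdw
}

#' Carbon-mole product-to-substrate yield
#'
#' Splits the biosurfactant mass into its HAA and mono-rhamnolipid shares,
#' converts each to carbon moles with the C10-C10 congener formulas
#' (HAA C20H38O5, mono-rhamnolipid C26H48O9), and divides by the substrate
#' carbon moles (ethanol 23.03 g/Cmol, glucose 30.03 g/Cmol).
#'
#' @param product_g Biosurfactant mass (or titer on a per-litre basis), g.
#' @param haa_fraction Mass fraction of HAAs in the product, 0..1.
#' @param substrate_g Substrate mass on the same basis, g (> 0).
#' @param substrate `"ethanol"` or `"glucose"`.
#' @return Cmol product per Cmol substrate.
#' @examples
#' cmol_yield(0.94, 0.23, 7.6, "ethanol")   # about 0.15
#' @export
cmol_yield <- function(product_g, haa_fraction, substrate_g,
                       substrate = c("ethanol", "glucose")) {
  substrate <- match.arg(substrate)
  if (haa_fraction < 0 || haa_fraction > 1) {
    stop("haa_fraction must be in [0, 1]")
  }
  if (substrate_g <= 0) stop("substrate mass must be > 0")
  k <- rf_constants()
  cmol_prod <- product_g * haa_fraction / (k$mw_haa / k$c_haa) +
    product_g * (1 - haa_fraction) / (k$mw_rhl / k$c_rhl)
  g_per_cmol <- if (substrate == "ethanol") k$g_per_cmol_etoh else
    k$g_per_cmol_glc
  cmol_prod / (substrate_g / g_per_cmol)
}

#' Acetate-corrected substrate yield
#'
#' Residual acetate could in principle still be converted to product, so
#' the effective substrate is reduced by the ethanol equivalent of the
#' accumulated acetate on a carbon-mole basis:
#' `substrate_g - acetate_g * (2 / 59.04) * 23.03`.
#'
#' @param product_g Product mass, g.
#' @param substrate_g Ethanol mass fed in total, g.
#' @param residual_acetate_g Accumulated acetate, g.
#' @return Corrected yield, g product per g ethanol.
#' @examples
#' acetate_corrected_yield(5.3, 83.3, 10)   # about 0.070
#' @export
acetate_corrected_yield <- function(product_g, substrate_g,
                                    residual_acetate_g) {
  if (residual_acetate_g < 0) stop("acetate mass must be >= 0")
  k <- rf_constants()
  eth_equiv <- residual_acetate_g * (k$c_acetate / k$mw_acetate) *
    k$g_per_cmol_etoh
  denom <- substrate_g - eth_equiv
  if (denom <= 0) {
    stop("acetate correction exceeds the substrate fed (denominator <= 0)")
  }
  product_g / denom
}

#' Specific growth rate from an OD time series
#'
#' Least-squares slope of ln(OD) versus time, either over a caller-chosen
#' window of consecutive points or over the automatically selected
#' maximum-slope window.
#'
#' @param t Time, h.
#' @param od OD (or CDW) values, > 0 inside the window.
#' @param window Number of consecutive points per window (default: a third
#'   of the series, at least 5). Must be >= 3.
#' @return Growth rate in 1/h, with attribute `window` = c(start, end)
#'   indices of the window used.
#' @export
growth_rate <- function(t, od, window = NULL) {
  stopifnot(length(t) == length(od), length(t) >= 3)
  if (is.null(window)) {
    window <- max(5L, ceiling(length(t) / 3))
  }
  window <- as.integer(window)
  if (window < 3) stop("window must span at least 3 points")
  if (window > length(t)) stop("window longer than the series")
  best <- -Inf; best_i <- 1L
  for (i in seq_len(length(t) - window + 1L)) {
    idx <- i:(i + window - 1L)
    if (any(od[idx] <= 0)) next
    sl <- stats::coef(stats::lm(log(od[idx]) ~ t[idx]))[[2]]
    if (sl > best) { best <- sl; best_i <- i }
  }
  if (!is.finite(best)) stop("no window with strictly positive OD")
  structure(best, window = c(best_i, best_i + window - 1L))
}

#' Four-parameter logistic fit
#'
#' Fits `y(t) = y_min + (y_max - y_min) / (1 + exp(-k (t - t_m)))` by
#' Levenberg-Marquardt least squares (via minpack.lm), with starting
#' values taken from the data quantiles and box constraints keeping the
#' asymptotes near the data range. Used for biomass, biosurfactant and
#' batch-phase ethanol trajectories.
#'
#' @param t Time, h (>= 5 points).
#' @param y Response (same length).
#' @return Object of class `logistic4_fit`: `y_min`, `y_max`, `k` (1/h),
#'   `t_m` (h), `rmse`, `converged`, `boundary` (TRUE when a parameter ran
#'   into its box, e.g. for non-sigmoid input), and the underlying `fit`.
#' @examples
#' t <- seq(0, 24, by = 0.5)
#' y <- 0 + 22 / (1 + exp(-0.4 * (t - 12)))
#' fit_logistic4(t, y)$k   # 0.4
#' @export
fit_logistic4 <- function(t, y) {
  stopifnot(length(t) == length(y))
  if (length(t) < 5) stop("need at least 5 points for a 4-parameter fit")
  ry <- range(y); span <- diff(ry)
  if (span <= 0) stop("response is constant; nothing to fit")
  rising <- stats::cor(t, y) >= 0
  # midpoint guess: crossing of the half range
  ymid <- mean(ry)
  t_m0 <- t[which.min(abs(y - ymid))]
  k0 <- (if (rising) 4 else -4) / max(diff(range(t)) / 4, 1e-6)
  start <- list(y_min = ry[1], y_max = ry[2], k = k0, t_m = t_m0)
  lower <- c(y_min = ry[1] - span, y_max = ry[1], k = -100,
             t_m = min(t) - 2 * diff(range(t)))
  upper <- c(y_min = ry[2], y_max = ry[2] + span, k = 100,
             t_m = max(t) + 2 * diff(range(t)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y_min + (y_max - y_min) / (1 + exp(-k * (t - t_m))),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("logistic fit did not converge: ", conditionMessage(fit))
  }
  cf <- stats::coef(fit)
  conv <- fit$convInfo$isConv
  at_box <- any(abs(cf - lower) < 1e-8 * pmax(1, abs(lower))) ||
    any(abs(cf - upper) < 1e-8 * pmax(1, abs(upper)))
  outside <- cf[["t_m"]] < min(t) || cf[["t_m"]] > max(t)
  structure(
    list(y_min = cf[["y_min"]], y_max = cf[["y_max"]], k = cf[["k"]],
         t_m = cf[["t_m"]],
         rmse = sqrt(mean(stats::residuals(fit)^2)),
         converged = isTRUE(conv),
         boundary = at_box || outside,
         fit = fit),
    class = "logistic4_fit"
  )
}

#' @export
print.logistic4_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic4_fit> y_min %.4g, y_max %.4g, k %.4g 1/h, t_m %.4g h (rmse %.3g%s)\n",
    x$y_min, x$y_max, x$k, x$t_m, x$rmse,
    if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' Assemble the full yield report of a fed-batch run
#'
#' Computes every derived yield from the primary measurements, echoing the
#' inputs and constants used: plain g/g yield on all ethanol fed
#' (batch charge + fed volume, with and without the manual prime),
#' Cmol/Cmol yield, product-to-biomass, space-time yield and the
#' acetate-corrected yield.
#'
#' @param titer Final biosurfactant titer, g/L.
#' @param haa_fraction HAA mass share of the product, 0..1.
#' @param cdw Final cell dry weight, g/L.
#' @param duration Fermentation duration, h.
#' @param batch_ethanol_g Batch-phase ethanol charge, g.
#' @param fed_ml Automatically fed ethanol, mL (pulses only).
#' @param prime_ml Manual prime, mL (default 6).
#' @param residual_acetate_g Accumulated acetate at the end, g.
#' @param volume Broth volume for titer-to-mass conversion, L.
#' @return Object of class `ferm_yield_report` (a list; printable).
#' @export
fermentation_yields <- function(titer, haa_fraction, cdw, duration,
                                batch_ethanol_g, fed_ml, prime_ml = 6,
                                residual_acetate_g = 0, volume = 1) {
  product_g <- titer * volume
  sub_auto <- batch_ethanol_g + ethanol_mass(fed_ml)
  sub_all <- batch_ethanol_g + ethanol_mass(fed_ml + prime_ml)
  structure(
    list(
      inputs = list(titer = titer, haa_fraction = haa_fraction, cdw = cdw,
                    duration = duration,
                    batch_ethanol_g = batch_ethanol_g, fed_ml = fed_ml,
                    prime_ml = prime_ml,
                    residual_acetate_g = residual_acetate_g,
                    volume = volume),
      constants = rf_constants(),
      yield_g_per_g = product_g / sub_all,
      yield_g_per_g_excl_prime = product_g / sub_auto,
      yield_cmol_per_cmol = cmol_yield(product_g, haa_fraction, sub_all,
                                       "ethanol"),
      product_to_biomass = product_to_biomass(titer, cdw),
      space_time_yield = space_time_yield(titer, duration),
      acetate_corrected_yield = acetate_corrected_yield(
        product_g, sub_all, residual_acetate_g)
    ),
    class = "ferm_yield_report"
  )
}

#' @export
print.ferm_yield_report <- function(x, ...) {
  cat("<ferm_yield_report>\n")
  cat(sprintf("  substrate: %.1f g batch + %.0f mL fed (+%.0f mL prime) ethanol\n",
              x$inputs$batch_ethanol_g, x$inputs$fed_ml, x$inputs$prime_ml))
  cat(sprintf("  yield:            %.3f g/g (excl. prime %.3f)\n",
              x$yield_g_per_g, x$yield_g_per_g_excl_prime))
  cat(sprintf("  acetate-corrected %.3f g/g\n", x$acetate_corrected_yield))
  cat(sprintf("  carbon yield:     %.3f Cmol/Cmol\n", x$yield_cmol_per_cmol))
  cat(sprintf("  product/biomass:  %.3f g/g\n", x$product_to_biomass))
  cat(sprintf("  space-time yield: %.3f g/(L h)\n", x$space_time_yield))
  invisible(x)
}
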