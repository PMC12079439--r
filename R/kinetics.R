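#' @include AllClasses.R
NULL

#' Construct a KineticsDataset
#'
#' @param substrate substrate loads, g/L (sorted ascending internally).
#' @param rate initial rates, uM/min.
#' @param truth optional named numeric (`vmax`, `km`) generator ground truth.
#' @return a [KineticsDataset-class].
#' @export
KineticsDataset <- function(substrate, rate, truth = numeric()) {
  ord <- order(substrate)
  new("KineticsDataset", substrate = as.numeric(substrate[ord]),
      rate = as.numeric(rate[ord]), truth = truth)
}

setMethod("show", "KineticsDataset", function(object) {
  cat(sprintf("KineticsDataset: %d points, S in [%.3g, %.3g] g/L\n",
              length(object@substrate), min(object@substrate),
              max(object@substrate)))
  invisible(object)
})

setMethod("show", "MMFit", function(object) {
  cat(sprintf("MMFit: Vmax = %.4g +/- %.2g uM/min, Km = %.4g +/- %.2g g/L (%s)\n",
              object@vmax, object@seVmax, object@km, object@seKm,
              if (object@converged) "converged" else "NOT converged"))
  invisible(object)
})

#' Fit the Michaelis-Menten model
#'
#' Nonlinear least squares on the untransformed model
#' `v = Vmax * S / (Km + S)` (Levenberg-Marquardt); no Lineweaver-Burk
#' linearization, which would bias the estimates. Default starting values
#' are `vmax0 = max(rate)` and `km0 =` the substrate load at half-maximal
#' rate. Standard errors come from the Jacobian at the optimum. An
#' identifiability warning is issued when no substrate load exceeds the
#' fitted Km (Vmax then extrapolates beyond the data).
#'
#' @param data a [KineticsDataset-class].
#' @param init optional numeric `(vmax0, km0)`.
#' @return an [MMFit-class]; on failure `converged` is `FALSE` with the
#'   fitter message retained.
#' @export
fitMichaelisMenten <- function(data, init = NULL) {
  S <- data@substrate; v <- data@rate
  if (is.null(init)) {
    vmax0 <- max(v)
    km0 <- S[which.min(abs(v - vmax0 / 2))]
    if (km0 <= 0) km0 <- stats::median(S[S > 0])
    init <- c(vmax0 = vmax0, km0 = km0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * S / (km + S),
                      start = list(vmax = init[[1]], km = init[[2]]),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new("MMFit", vmax = NA_real_, km = NA_real_, seVmax = NA_real_,
               seKm = NA_real_, rss = NA_real_, converged = FALSE,
               message = conditionMessage(fit)))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  nonphys <- est[["vmax"]] <= 0 || est[["km"]] <= 0
  if (max(S) < est[["km"]])
    warning("Km exceeds the largest substrate load; Vmax is extrapolated")
  new("MMFit", vmax = est[["vmax"]], km = est[["km"]],
      seVmax = as.numeric(se[["vmax"]]), seKm = as.numeric(se[["km"]]),
      rss = sum(stats::resid(fit)^2), converged = !nonphys,
      message = if (nonphys) "non-physical estimates" else "")
}

#' Catalytic efficiency Vmax/Km
#'
#' Defined here strictly as the ratio of the fitted parameters, in
#' (uM/min)/(g/L). Conversion to a kcat/Km-style efficiency would require
#' the enzyme concentration, which this artifact does not model.
#'
#' @param fit a converged [MMFit-class].
#' @return efficiency in (uM/min)/(g/L).
#' @export
catalyticEfficiency <- function(fit) {
  if (!isTRUE(fit@converged))
    stop("catalytic efficiency undefined for a non-converged fit", call. = FALSE)
  fit@vmax / fit@km
}

#' Predicted Michaelis-Menten rate
#'
#' @param fit an [MMFit-class].
#' @param S substrate loads, g/L.
#' @return rates, uM/min.
#' @export
predictRate <- function(fit, S) fit@vmax * S / (fit@km + S)

#' Read a kinetics CSV/TSV
#'
#' Expects columns `substrate` (g/L) and `rate` (uM/min); the delimiter is
#' inferred from the extension (`.tsv` = tab, otherwise comma).
#'
#' @param path file path.
#' @return a [KineticsDataset-class].
#' @export
readKineticsTable <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("substrate", "rate") %in% names(tab)))
    stop("kinetics table must have 'substrate' and 'rate' columns", call. = FALSE)
  KineticsDataset(tab$substrate, tab$rate)
}

#' Serialize an MM fit report as JSON
#'
#' @param fit an [MMFit-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFitReport <- function(fit, path) {
  rep <- list(vmax_uM_per_min = fit@vmax, km_g_per_L = fit@km,
              se_vmax = fit@seVmax, se_km = fit@seKm, rss = fit@rss,
              converged = fit@converged,
              efficiency_vmax_over_km = if (fit@converged)
                catalyticEfficiency(fit) else NA_real_)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
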