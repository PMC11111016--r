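# Isotopologue ratio estimation (regression slope or peak area) and
# forward/reverse isotope dilution quantification.

#' Regression-slope isotopologue ratio
#'
#' Ordinary least squares of the isotopic trace intensity on the
#' monoisotopomer (denominator channel) intensity across scans; the slope is
#' the isotopologue ratio. The default model includes an intercept, which
#' absorbs constant background in the trace channel -- the reason this
#' estimator is preferred over plain area ratios when background noise is
#' high relative to the analyte.
#'
#' @param trace,mono `eic` objects on identical RT grids.
#' @param rt_bounds Optional RT bounds (minutes) restricting the regression
#'   to the target's peak window.
#' @param intercept Include an intercept? (`FALSE` forces the line through
#'   the origin.)
#' @param weights Optional per-scan weights (default unweighted).
#' @return List of class `ratio_estimate`: `slope`, `intercept`, `se`
#'   (slope standard error), `r_squared`, `n`.
#' @export
regression_ratio <- function(trace, mono, rt_bounds = NULL, intercept = TRUE,
                             weights = NULL) {
  stopifnot(all(c("rt", "intensity") %in% names(trace)),
            all(c("rt", "intensity") %in% names(mono)))
  if (nrow(trace) != nrow(mono) ||
      max(abs(trace$rt - mono$rt)) > 1e-9)
    stop("trace and mono must share an identical RT grid", call. = FALSE)
  sel <- rep(TRUE, nrow(trace))
  if (!is.null(rt_bounds))
    sel <- trace$rt >= rt_bounds[1] & trace$rt <= rt_bounds[2]
  y <- trace$intensity[sel]
  x <- mono$intensity[sel]
  if (length(x) < 3L)
    stop("need >= 3 points for the regression, got ", length(x),
         call. = FALSE)
  if (all(x == 0))
    stop("monoisotopomer channel is identically zero: ratio undefined",
         call. = FALSE)
  fml <- if (intercept) y ~ x else y ~ x + 0
  fit <- stats::lm(fml, weights = weights)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- sm$coefficients
  slope_row <- if (intercept) 2L else 1L
  structure(list(
    slope = unname(stats::coef(fit)[["x"]]),
    intercept = if (intercept) unname(stats::coef(fit)[["(Intercept)"]]) else 0,
    se = unname(cf[slope_row, "Std. Error"]),
    r_squared = sm$r.squared,
    n = length(x)), class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("<ratio> slope %.6g (SE %.3g), intercept %.4g, r2 %.4f, n = %d\n",
              x$slope, x$se, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Peak-area ratio
#'
#' @param peak_a,peak_b [integrate_peak()] results, `ratio_estimate`s, or
#'   bare areas. `peak_b` must be positive.
#' @return Dimensionless ratio a/b.
#' @export
area_ratio <- function(peak_a, peak_b) {
  val <- function(p) if (inherits(p, "peak_integration")) p$area else
    as.numeric(p)
  a <- val(peak_a); b <- val(peak_b)
  if (!is.finite(b) || b <= 0)
    stop("denominator peak area must be positive", call. = FALSE)
  a / b
}

#' Isotope dilution quantification
#'
#' Converts an analyte/internal-standard signal ratio into a tissue
#' concentration: `concentration = ratio * q_is / fresh_weight`, in ng per g
#' fresh weight (fresh weight supplied in mg).
#'
#' @param ratio Analyte/IS ratio (area or regression slope), >= 0.
#' @param q_is_ng Internal standard spiked into the sample, in ng.
#' @param fresh_weight_mg Sample fresh weight, in mg.
#' @param compound,channel Optional labels.
#' @param ratio_se Optional standard error of the ratio, propagated to
#'   `conc_se` by the same scale factor.
#' @return One-row data frame: `compound`, `channel`, `ratio`, `q_is_ng`,
#'   `fresh_weight_mg`, `conc_ng_g`, `conc_se`.
#' @export
#' @examples
#' isotope_dilution_quant(1.0, q_is_ng = 0.2, fresh_weight_mg = 10)  # 20 ng/g
isotope_dilution_quant <- function(ratio, q_is_ng, fresh_weight_mg,
                                   compound = NA_character_,
                                   channel = NA_character_,
                                   ratio_se = NA_real_) {
  if (inherits(ratio, "ratio_estimate")) {
    ratio_se <- ratio$se
    ratio <- ratio$slope
  }
  if (!is.finite(q_is_ng) || q_is_ng <= 0)
    stop("internal standard amount must be positive", call. = FALSE)
  if (!is.finite(fresh_weight_mg) || fresh_weight_mg <= 0)
    stop("fresh weight must be positive", call. = FALSE)
  if (!is.finite(ratio) || ratio < 0)
    stop("ratio must be >= 0", call. = FALSE)
  scale <- q_is_ng / (fresh_weight_mg / 1000)
  data.frame(compound = compound, channel = channel, ratio = ratio,
             q_is_ng = q_is_ng, fresh_weight_mg = fresh_weight_mg,
             conc_ng_g = ratio * scale,
             conc_se = if (is.na(ratio_se)) NA_real_ else ratio_se * scale)
}

#' Reverse isotope dilution quantification
#'
#' With an unlabeled compound spiked as internal standard, every labeled
#' channel (endogenous heavy-nitrogen pool, tracer-derived pool) is
#' quantified concurrently against the same denominator.
#'
#' @param channel_ratios Named numeric vector of channel/standard ratios
#'   (e.g. `c(endogenous = 0.4, tracer = 0.1)`).
#' @param q_std_ng Unlabeled standard spiked, in ng.
#' @param fresh_weight_mg Sample fresh weight, in mg.
#' @param compound Optional label.
#' @return Data frame with one row per channel (see
#'   [isotope_dilution_quant()]).
#' @export
reverse_dilution_quant <- function(channel_ratios, q_std_ng, fresh_weight_mg,
                                   compound = NA_character_) {
  stopifnot(length(channel_ratios) >= 1L, !is.null(names(channel_ratios)))
  out <- do.call(rbind, lapply(names(channel_ratios), function(ch)
    isotope_dilution_quant(channel_ratios[[ch]], q_std_ng, fresh_weight_mg,
                           compound = compound, channel = ch)))
  rownames(out) <- NULL
  out
}

#' Fraction of a pool carrying the tracer label
#'
#' @param tracer_amount,endogenous_amount Non-negative amounts (same units);
#'   not both zero.
#' @return `tracer / (tracer + endogenous)`, in `[0, 1]`.
#' @export
label_fraction <- function(tracer_amount, endogenous_amount) {
  if (any(tracer_amount < 0) || any(endogenous_amount < 0))
    stop("amounts must be >= 0", call. = FALSE)
  tot <- tracer_amount + endogenous_amount
  if (any(tot == 0))
    stop("label fraction undefined: tracer and endogenous amounts both zero",
         call. = FALSE)
  tracer_amount / tot
}
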