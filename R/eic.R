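# Narrow-window extracted ion chromatograms and chromatographic peak
# integration.

#' Extract a narrow-window ion chromatogram
#'
#' One point per scan: the sum of centroid intensities whose m/z lies inside
#' the closed interval `[low, high]` (boundary ties included). Scans with no
#' matching centroid contribute intensity 0. If the window lies outside every
#' scan's acquired m/z range the result is all-zero with a warning.
#'
#' @param run An [ms_run()] (filter to the appropriate scan type first, see
#'   [filter_scans()]).
#' @param window An [mz_window()] or numeric `c(low, high)`.
#' @param rt_range Optional RT bounds (minutes, closed interval).
#' @param compound,channel Optional labels carried on the result.
#' @return Data frame of class `eic` with columns `rt`, `intensity` and
#'   attributes `window`, `compound`, `channel`.
#' @export
extract_eic <- function(run, window, rt_range = NULL, compound = NA_character_,
                        channel = NA_character_) {
  stopifnot(inherits(run, "ms_run"), length(window) == 2L)
  low <- unname(window[1]); high <- unname(window[2])
  if (!is.null(rt_range)) run <- filter_scans(run, rt_range = rt_range)
  rt <- .run_rts(run)
  intensity <- vapply(run$spectra, function(s) {
    if (!length(s$mz)) return(0)
    sum(s$intensity[s$mz >= low & s$mz <= high])
  }, numeric(1))
  covered <- any(vapply(run$spectra, function(s) {
    lo <- s$scan_low; hi <- s$scan_high
    if (is.null(lo) || is.na(lo) || is.null(hi) || is.na(hi)) TRUE
    else high >= lo && low <= hi
  }, logical(1)))
  if (length(run$spectra) && !covered)
    warning(sprintf("window [%.4f, %.4f] lies outside all scan m/z ranges",
                    low, high), call. = FALSE)
  out <- data.frame(rt = rt, intensity = intensity)
  attr(out, "window") <- c(low = low, high = high)
  attr(out, "covered") <- covered
  attr(out, "compound") <- compound
  attr(out, "channel") <- channel
  class(out) <- c("eic", "data.frame")
  out
}

#' @export
print.eic <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("<eic> %d points, window [%.4f, %.4f]", nrow(x), w[1], w[2]))
  if (!is.na(attr(x, "compound")))
    cat(sprintf(", %s/%s", attr(x, "compound"), attr(x, "channel")))
  cat(sprintf(", max intensity %.3g\n", if (nrow(x)) max(x$intensity) else NA))
  invisible(x)
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal area between RT bounds. With `baseline = "linear"` the chord
#' between the boundary intensities is subtracted first and negative
#' post-baseline values are clipped at 0 before summation. Peak bounds
#' normally come from the target's configured RT window; see
#' [find_peak_bounds()] for an apex-centered automatic mode.
#'
#' @param chrom An `eic` (or data frame with `rt`, `intensity`).
#' @param rt_bounds Numeric `c(low, high)` inside the chromatogram's span;
#'   `NULL` uses the full span.
#' @param baseline `"none"` (default; narrow windows already filter noise)
#'   or `"linear"`.
#' @return List of class `peak_integration`: `area` (intensity * min),
#'   `rt_bounds`, `baseline`, `apex_rt`, `apex_intensity`, `n_points`.
#' @export
integrate_peak <- function(chrom, rt_bounds = NULL,
                           baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  stopifnot(all(c("rt", "intensity") %in% names(chrom)))
  if (is.null(rt_bounds)) rt_bounds <- range(chrom$rt)
  if (rt_bounds[1] < min(chrom$rt) - 1e-9 ||
      rt_bounds[2] > max(chrom$rt) + 1e-9)
    stop("rt_bounds outside chromatogram span", call. = FALSE)
  sel <- chrom$rt >= rt_bounds[1] & chrom$rt <= rt_bounds[2]
  n <- sum(sel)
  if (n < 3L)
    stop("need >= 3 points inside rt_bounds, got ", n, call. = FALSE)
  t <- chrom$rt[sel]
  y <- chrom$intensity[sel]
  if (baseline == "linear") {
    chord <- y[1L] + (y[n] - y[1L]) * (t - t[1L]) / (t[n] - t[1L])
    y <- pmax(y - chord, 0)
  }
  area <- sum(diff(t) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  apex <- which.max(y)
  structure(list(area = area, rt_bounds = rt_bounds, baseline = baseline,
                 apex_rt = t[apex], apex_intensity = y[apex], n_points = n),
            class = "peak_integration")
}

#' @export
print.peak_integration <- function(x, ...) {
  cat(sprintf(
    "<peak> area %.6g (baseline %s), apex %.3f min @ %.3g, %d points in [%.3f, %.3f]\n",
    x$area, x$baseline, x$apex_rt, x$apex_intensity, x$n_points,
    x$rt_bounds[1], x$rt_bounds[2]))
  invisible(x)
}

#' Apex-centered automatic peak bounds
#'
#' Locates the apex, measures the full width at half maximum by linear
#' interpolation and returns `apex +/- k * FWHM`, clamped to the
#' chromatogram span. Intended for simulated runs; real targets use their
#' configured RT windows.
#'
#' @param chrom An `eic`.
#' @param k Half-window in FWHM units.
#' @return Numeric `c(low, high)` in minutes.
#' @export
find_peak_bounds <- function(chrom, k = 2) {
  stopifnot(nrow(chrom) >= 3L)
  apex <- which.max(chrom$intensity)
  ymax <- chrom$intensity[apex]
  if (ymax <= 0) stop("no peak: chromatogram has no positive intensity",
                      call. = FALSE)
  half <- ymax / 2
  cross <- function(idx) {
    # linear interpolation of the half-max crossing between idx and idx + 1
    y1 <- chrom$intensity[idx]; y2 <- chrom$intensity[idx + 1L]
    t1 <- chrom$rt[idx]; t2 <- chrom$rt[idx + 1L]
    t1 + (half - y1) * (t2 - t1) / (y2 - y1)
  }
  left <- chrom$rt[1L]
  for (i in rev(seq_len(apex - 1L)))
    if (chrom$intensity[i] < half) { left <- cross(i); break }
  right <- chrom$rt[nrow(chrom)]
  for (i in apex:(nrow(chrom) - 1L))
    if (chrom$intensity[i + 1L] < half) { right <- cross(i); break }
  fwhm <- right - left
  c(max(chrom$rt[apex] - k * fwhm, chrom$rt[1L]),
    min(chrom$rt[apex] + k * fwhm, chrom$rt[nrow(chrom)]))
}

#' Export chromatograms as tidy CSV
#'
#' @param eics List of `eic` objects.
#' @param path Output CSV path.
#' @param run_id Run identifier column value.
#' @return `path`, invisibly.
#' @export
write_eic_csv <- function(eics, path, run_id = NA_character_) {
  rows <- lapply(eics, function(e)
    data.frame(run = run_id, compound = attr(e, "compound"),
               channel = attr(e, "channel"), rt = e$rt,
               intensity = e$intensity))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
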