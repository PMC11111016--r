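# Uniform in-memory representation of centroided LC-MS runs, plus mzML/mzXML
# reading and mzML writing through mzR.

#' Construct an in-memory LC-MS run
#'
#' A run is an RT-ordered list of centroided spectra. Each spectrum is a list
#' with fields `rt` (minutes), `mz` (ascending), `intensity` (same length,
#' >= 0), `ms_level`, and optional `precursor_mz` (PRM) and `scan_low`/
#' `scan_high` (SIM segment bounds).
#'
#' @param spectra List of spectrum lists.
#' @param metadata Named list (source path, instrument, polarity, centroided).
#' @return Object of class `ms_run`.
#' @export
ms_run <- function(spectra, metadata = list()) {
  stopifnot(is.list(spectra))
  rts <- vapply(spectra, function(s) s$rt, numeric(1))
  if (is.unsorted(rts)) stop("spectra must be ordered by retention time",
                             call. = FALSE)
  if (any(rts < 0)) stop("retention times must be >= 0", call. = FALSE)
  for (s in spectra) {
    if (length(s$mz) != length(s$intensity))
      stop("m/z and intensity arrays differ in length", call. = FALSE)
    if (length(s$mz) > 1L && is.unsorted(s$mz, strictly = TRUE))
      stop("m/z array must be strictly increasing", call. = FALSE)
  }
  structure(list(spectra = spectra, metadata = metadata), class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  n <- length(x$spectra)
  rng <- if (n) range(vapply(x$spectra, `[[`, numeric(1), "rt")) else c(NA, NA)
  cat(sprintf("<ms_run> %d scans, RT %.2f-%.2f min", n, rng[1], rng[2]))
  if (!is.null(x$metadata$source)) cat(", source:", x$metadata$source)
  cat("\n")
  invisible(x)
}

#' @export
length.ms_run <- function(x) length(x$spectra)

.run_rts <- function(run) vapply(run$spectra, `[[`, numeric(1), "rt")

#' Load an LC-MS run from mzML or mzXML
#'
#' Reads a centroided run through mzR. Retention times are converted to
#' minutes. Profile-mode spectra are accepted with a warning and flagged in
#' the metadata (quantification here assumes centroid data).
#'
#' @param path Path to an mzML or mzXML file.
#' @param format `"auto"` (by extension), `"mzML"` or `"mzXML"`.
#' @return An [ms_run()].
#' @export
read_ms_run <- function(path, format = c("auto", "mzML", "mzXML")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("parse error: '", path, "' is empty (byte offset 0)", call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mzml = "mzML", mzxml = "mzXML",
                     stop("unsupported format: .", ext, call. = FALSE))
  }
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e)
                       stop("parse error in '", path, "': ",
                            conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) stop("parse error: no spectra in ", path, call. = FALSE)
  pks <- mzR::peaks(handle)
  if (is.matrix(pks)) pks <- list(pks)
  centroided <- hdr$centroided
  if (any(!is.na(centroided) & !centroided))
    warning("profile-mode spectra detected; quantification assumes ",
            "centroided data", call. = FALSE)
  spectra <- lapply(seq_len(nrow(hdr)), function(i) {
    p <- pks[[i]]
    prec <- hdr$precursorMZ[i]
    list(rt = hdr$retentionTime[i] / 60,
         mz = as.numeric(p[, 1]), intensity = as.numeric(p[, 2]),
         ms_level = as.integer(hdr$msLevel[i]),
         precursor_mz = if (!is.na(prec) && prec > 0) prec else NA_real_,
         scan_low = hdr$scanWindowLowerLimit[i],
         scan_high = hdr$scanWindowUpperLimit[i])
  })
  ord <- order(vapply(spectra, `[[`, numeric(1), "rt"))
  ms_run(spectra[ord],
         metadata = list(source = path, format = format,
                         centroided = !any(!is.na(centroided) & !centroided)))
}

#' Write a run to mzML
#'
#' Serializes an [ms_run()] through mzR's mzML writer. The file re-loads with
#' [read_ms_run()] to within float tolerance.
#'
#' @param run An [ms_run()], non-empty.
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_ms_run <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  if (!length(run$spectra)) stop("run is empty", call. = FALSE)
  n <- length(run$spectra)
  sp <- run$spectra
  num <- function(f, def) vapply(sp, function(s)
    if (is.null(s[[f]]) || is.na(s[[f]])) def else as.numeric(s[[f]]),
    numeric(1))
  pk <- lapply(sp, function(s) cbind(mz = s$mz, intensity = s$intensity))
  lows <- vapply(sp, function(s) if (length(s$mz)) min(s$mz) else 0, numeric(1))
  highs <- vapply(sp, function(s) if (length(s$mz)) max(s$mz) else 0, numeric(1))
  bpi <- vapply(sp, function(s) if (length(s$intensity)) max(s$intensity) else 0,
                numeric(1))
  bpm <- vapply(sp, function(s)
    if (length(s$intensity)) s$mz[which.max(s$intensity)] else 0, numeric(1))
  prec <- num("precursor_mz", 0)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(sp, function(s) as.integer(s$ms_level %||% 1L), integer(1)),
    polarity = 1L,
    peaksCount = vapply(sp, function(s) length(s$mz), integer(1)),
    totIonCurrent = vapply(sp, function(s) sum(s$intensity), numeric(1)),
    retentionTime = vapply(sp, `[[`, numeric(1), "rt") * 60,
    basePeakMZ = bpm, basePeakIntensity = bpi,
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = lows, highMZ = highs,
    precursorScanNum = 0L, precursorMZ = prec,
    precursorCharge = ifelse(prec > 0, 1L, 0L), precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(prec > 0, prec, NA_real_),
    isolationWindowLowerOffset = ifelse(prec > 0, 1.0, NA_real_),
    isolationWindowUpperOffset = ifelse(prec > 0, 1.0, NA_real_),
    scanWindowLowerLimit = num("scan_low", NA_real_),
    scanWindowUpperLimit = num("scan_high", NA_real_))
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter scans of a run
#'
#' Subsets a run by conjunctive criteria, preserving order. A scan matches a
#' SIM criterion (`sim_mz`) when its scan m/z range contains the queried m/z;
#' PRM scans match when their precursor is within `precursor_tol` of the
#' query (half of the typical 2.0 m/z isolation window).
#'
#' @param run An [ms_run()].
#' @param ms_level Keep scans of this MS level.
#' @param rt_range Numeric length-2, RT bounds in minutes (closed).
#' @param sim_mz Keep SIM scans whose scan range contains this m/z.
#' @param precursor_mz Keep PRM scans with precursor within tolerance.
#' @param precursor_tol Precursor match tolerance in m/z.
#' @return A filtered [ms_run()] (possibly empty).
#' @export
filter_scans <- function(run, ms_level = NULL, rt_range = NULL, sim_mz = NULL,
                         precursor_mz = NULL, precursor_tol = 1.0) {
  stopifnot(inherits(run, "ms_run"))
  keep <- rep(TRUE, length(run$spectra))
  for (i in seq_along(run$spectra)) {
    s <- run$spectra[[i]]
    if (!is.null(ms_level) && !identical(as.integer(s$ms_level %||% 1L),
                                         as.integer(ms_level)))
      keep[i] <- FALSE
    if (keep[i] && !is.null(rt_range) &&
        (s$rt < rt_range[1] || s$rt > rt_range[2]))
      keep[i] <- FALSE
    if (keep[i] && !is.null(sim_mz)) {
      lo <- s$scan_low; hi <- s$scan_high
      if (is.null(lo) || is.na(lo) || is.null(hi) || is.na(hi) ||
          sim_mz < lo || sim_mz > hi)
        keep[i] <- FALSE
    }
    if (keep[i] && !is.null(precursor_mz)) {
      p <- s$precursor_mz
      if (is.null(p) || is.na(p) || abs(p - precursor_mz) > precursor_tol)
        keep[i] <- FALSE
    }
  }
  ms_run(run$spectra[keep], metadata = run$metadata)
}
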