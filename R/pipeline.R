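# End-to-end orchestration: extraction -> ratio -> concentration per sample,
# then kinetic fits and per-timepoint group comparisons.

#' Quantify an experiment
#'
#' For every sample and every compound in the target table, extracts the
#' channel EICs, forms channel/internal-standard ratios (peak-area or
#' regression-slope mode) and converts them to concentrations by isotope
#' dilution. Samples are either in-memory runs or mzML/mzXML files listed in
#' a manifest. A missing channel (window outside the run's acquisition
#' ranges) or an unreadable file is recorded as flagged rows, not a failure.
#'
#' @param samples Either a data frame manifest with columns `file`,
#'   `treatment`, `timepoint`, `replicate`, `fresh_weight_mg`, `is_spike_ng`
#'   (paths relative to `dir`), or a list of entries
#'   `list(run = <ms_run>, treatment =, timepoint =, replicate =,
#'   fresh_weight_mg =, is_spike_ng =)`.
#' @param targets A `target_table` (see [build_target_table()],
#'   [network_targets()]). Each compound must include an
#'   `internal_standard` channel, the ratio denominator.
#' @param mode `"area"` (trapezoidal peak areas) or `"regression"`
#'   (regression-slope ratio, robust to constant background).
#' @param dir Directory that manifest file paths are relative to.
#' @param baseline Peak-integration baseline model in area mode.
#' @return Tidy data frame: one row per sample x compound x channel with
#'   `ratio`, `ratio_se`, `conc_ng_g` and a `flag` column (`""`, or a note
#'   for missing/unreadable data).
#' @export
run_quantify <- function(samples, targets, mode = c("area", "regression"),
                         dir = ".", baseline = "none") {
  mode <- match.arg(mode)
  if (is.data.frame(samples)) {
    if (nrow(samples) == 0L) {
      warning("empty sample manifest", call. = FALSE)
      return(data.frame())
    }
    entries <- lapply(seq_len(nrow(samples)), function(i) {
      row <- samples[i, ]
      run <- tryCatch(read_ms_run(file.path(dir, row$file)),
                      error = function(e) conditionMessage(e))
      list(run = run, id = row$file, treatment = row$treatment,
           timepoint = row$timepoint, replicate = row$replicate,
           fresh_weight_mg = row$fresh_weight_mg,
           is_spike_ng = row$is_spike_ng)
    })
  } else {
    entries <- lapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      s$id <- s$id %||% paste0("sample", i)
      s
    })
  }
  rows <- list()
  for (s in entries) {
    if (!inherits(s$run, "ms_run")) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s$id, treatment = s$treatment, timepoint = s$timepoint,
        replicate = s$replicate, compound = NA_character_,
        channel = NA_character_, ratio = NA_real_, ratio_se = NA_real_,
        conc_ng_g = NA_real_, flag = paste("unreadable:", s$run))
      next
    }
    for (cn in unique(targets$compound)) {
      tg <- targets[targets$compound == cn, ]
      is_row <- tg[tg$channel == "internal_standard", ]
      if (nrow(is_row) != 1L)
        stop("compound '", cn, "' needs exactly one internal_standard channel",
             call. = FALSE)
      rt_bounds <- c(tg$rt_min[1L], tg$rt_max[1L])
      eics <- lapply(seq_len(nrow(tg)), function(j)
        withCallingHandlers(
          extract_eic(s$run, c(tg$mz_low[j], tg$mz_high[j]),
                      rt_range = rt_bounds, compound = cn,
                      channel = tg$channel[j]),
          warning = function(w) invokeRestart("muffleWarning")))
      names(eics) <- tg$channel
      covered <- vapply(eics, function(e)
        nrow(e) > 0 && isTRUE(attr(e, "covered")), logical(1))
      is_eic <- eics[["internal_standard"]]
      for (j in seq_len(nrow(tg))) {
        ch <- tg$channel[j]
        if (ch == "internal_standard") next
        flag <- ""
        ratio <- ratio_se <- conc <- NA_real_
        if (!covered[[ch]] || !covered[["internal_standard"]]) {
          flag <- "missing: channel window outside acquisition"
        } else if (mode == "regression") {
          est <- tryCatch(regression_ratio(eics[[ch]], is_eic),
                          error = function(e) conditionMessage(e))
          if (inherits(est, "ratio_estimate")) {
            ratio <- max(est$slope, 0); ratio_se <- est$se
          } else flag <- est
        } else {
          pa <- tryCatch(integrate_peak(eics[[ch]], baseline = baseline),
                         error = function(e) NULL)
          pb <- tryCatch(integrate_peak(is_eic, baseline = baseline),
                         error = function(e) NULL)
          if (is.null(pa) || is.null(pb) || pb$area <= 0)
            flag <- "missing: unintegrable peak"
          else ratio <- area_ratio(pa, pb)
        }
        if (flag == "")
          conc <- ratio * s$is_spike_ng / (s$fresh_weight_mg / 1000)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s$id, treatment = s$treatment, timepoint = s$timepoint,
          replicate = s$replicate, compound = cn, channel = ch,
          ratio = ratio, ratio_se = ratio_se, conc_ng_g = conc, flag = flag)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit kinetics and compare treatment groups
#'
#' One kinetic fit per compound x channel x treatment from a tidy
#' quantification table, plus per-timepoint Student's t comparisons of every
#' treatment arm against the reference arm.
#'
#' @param quant_table Output of [run_quantify()] or
#'   [simulate_quant_table()] (columns `treatment`, `timepoint`,
#'   `replicate`, `compound`, `channel`, and the response column).
#' @param model Kinetic model passed to [fit_kinetics()].
#' @param value Response column name (default `"conc_ng_g"`).
#' @param reference Reference (mock) treatment arm for comparisons.
#' @return List with `fits` (data frame of parameter estimates, half-times
#'   and convergence flags; the fit objects in `$fit`) and `comparisons`
#'   (per-timepoint p-values per compound x channel x arm).
#' @export
run_kinetics <- function(quant_table, model = "first_order",
                         value = "conc_ng_g", reference = "mock") {
  qt <- quant_table[!is.na(quant_table[[value]]), ]
  groups <- unique(qt[c("compound", "channel", "treatment")])
  fits <- list(); fit_objs <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    d <- qt[qt$compound == g$compound & qt$channel == g$channel &
              qt$treatment == g$treatment, ]
    fit <- tryCatch(fit_kinetics(d$timepoint, d[[value]], model = model),
                    error = function(e) .flagged_fit(model, d$timepoint,
                                                     d[[value]],
                                                     conditionMessage(e)))
    key <- paste(g$compound, g$channel, g$treatment, sep = "|")
    fit_objs[[key]] <- fit
    fits[[i]] <- data.frame(
      compound = g$compound, channel = g$channel, treatment = g$treatment,
      model = fit$model, converged = fit$converged,
      k = if (fit$converged && "k" %in% names(fit$coefficients))
        fit$coefficients[["k"]] else NA_real_,
      half_time = fit$half_time,
      rss = fit$rss,
      flag = if (fit$converged) "" else fit$reason)
  }
  fits <- do.call(rbind, fits)
  comps <- list()
  arms <- setdiff(unique(qt$treatment), reference)
  for (arm in arms) {
    for (i in seq_len(nrow(unique(qt[c("compound", "channel")])))) {
      g <- unique(qt[c("compound", "channel")])[i, ]
      a <- qt[qt$compound == g$compound & qt$channel == g$channel &
                qt$treatment == reference, ]
      b <- qt[qt$compound == g$compound & qt$channel == g$channel &
                qt$treatment == arm, ]
      if (!nrow(a) || !nrow(b)) next
      cmp <- compare_timepoints(a$timepoint, a[[value]],
                                b$timepoint, b[[value]])
      cmp <- cbind(compound = g$compound, channel = g$channel,
                   treatment = arm, cmp)
      comps[[length(comps) + 1L]] <- cmp
    }
  }
  list(fits = fits, fit_objects = fit_objs,
       comparisons = if (length(comps)) do.call(rbind, comps) else NULL)
}
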