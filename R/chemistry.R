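# Exact-mass chemistry for targeted isotopologue analysis: elemental formulas,
# isotope masses and abundances, label schemes, narrow extraction windows and
# natural-abundance envelopes.

# Embedded isotope constants (CODATA/IUPAC atomic masses in Da, representative
# natural abundance fractions). One authoritative table; no external service.
.isotope_table <- local({
  tab <- rbind(
    data.frame(element = "H",  mass_number = c(1, 2),
               mass = c(1.00782503207, 2.01410177785),
               abundance = c(0.999885, 0.000115)),
    data.frame(element = "C",  mass_number = c(12, 13),
               mass = c(12.0, 13.00335483507),
               abundance = c(0.9893, 0.0107)),
    data.frame(element = "N",  mass_number = c(14, 15),
               mass = c(14.00307400443, 15.00010889888),
               abundance = c(0.99636, 0.00364)),
    data.frame(element = "O",  mass_number = c(16, 17, 18),
               mass = c(15.99491461957, 16.99913175650, 17.99915961286),
               abundance = c(0.99757, 0.00038, 0.00205)),
    data.frame(element = "P",  mass_number = 31,
               mass = 30.97376199842, abundance = 1.0),
    data.frame(element = "S",  mass_number = c(32, 33, 34, 36),
               mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
               abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
    data.frame(element = "F",  mass_number = 19,
               mass = 18.99840316273, abundance = 1.0),
    data.frame(element = "Cl", mass_number = c(35, 37),
               mass = c(34.968852682, 36.965902602),
               abundance = c(0.7576, 0.2424))
  )
  rownames(tab) <- NULL
  tab
})

#' Mass of the electron in Da, subtracted once per positive charge.
#' @keywords internal
ELECTRON_MASS <- 0.000548579909

#' Isotope constants table
#'
#' Exact masses (Da) and natural abundance fractions for the supported
#' elements (C, H, N, O, P, S, F, Cl). Per element, abundances sum to 1 and
#' masses increase with mass number.
#'
#' @return A data frame with columns `element`, `mass_number`, `mass`,
#'   `abundance`.
#' @export
#' @examples
#' subset(isotope_table(), element == "C")
isotope_table <- function() .isotope_table

.supported_elements <- function() unique(.isotope_table$element)

.element_isotopes <- function(element) {
  rows <- .isotope_table[.isotope_table$element == element, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("unknown element symbol: '", element, "'", call. = FALSE)
  rows[order(rows$mass_number), , drop = FALSE]
}

#' Parse an elemental formula
#'
#' Converts a Hill-style formula string such as `"C10H9NO2"` into a named
#' integer vector of atom counts. Elements are restricted to the supported
#' set (see [isotope_table()]); counts default to 1 when omitted. The empty
#' string is permitted and denotes the identity (zero-mass) formula.
#'
#' @param x A formula string, or an already-parsed named integer vector
#'   (returned unchanged after validation).
#' @return Named integer vector of atom counts.
#' @export
#' @examples
#' parse_formula("C9H8N")
parse_formula <- function(x) {
  if (is.numeric(x)) {
    counts <- x
    if (length(counts) && (is.null(names(counts)) || any(!nzchar(names(counts)))))
      stop("parsed formulas must be named by element symbol", call. = FALSE)
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    x <- gsub("[[:space:]]", "", x)
    if (!nzchar(x)) return(stats::setNames(integer(0), character(0)))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
    if (sum(attr(m, "match.length")) != nchar(x))
      stop("cannot parse formula: '", x, "'", call. = FALSE)
    el <- sub("[0-9]*$", "", toks)
    n <- sub("^[A-Za-z]+", "", toks)
    counts <- ifelse(nzchar(n), as.integer(n), 1L)
    counts <- tapply(counts, factor(el, levels = unique(el)), sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  bad <- setdiff(names(counts), .supported_elements())
  if (length(bad))
    stop("unknown element symbol: '", bad[1L], "'", call. = FALSE)
  if (any(counts < 1))
    stop("atom counts must be >= 1", call. = FALSE)
  counts
}

.formula_string <- function(counts) {
  if (!length(counts)) return("")
  paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum over atoms of the lightest-isotope exact masses.
#'
#' @param formula Formula string or named count vector (see [parse_formula()]).
#' @return Mass in Da. The empty formula returns 0.
#' @export
#' @examples
#' monoisotopic_mass("H2O")     # 18.010565
#' monoisotopic_mass("C9H8N")   # neutral quinolinium core, 130.065674
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (!length(counts)) return(0)
  m <- vapply(names(counts), function(el) .element_isotopes(el)$mass[1L],
              numeric(1))
  sum(m * counts)
}

#' Theoretical m/z of a singly charged cation
#'
#' For a protonated ion, one proton is added to the neutral mass; one
#' electron mass is subtracted per positive charge. Only charge +1 is
#' supported (the acquisition modes monitored here are singly charged).
#'
#' @param formula Ion formula. For `protonated = FALSE` this is the formula
#'   of the cation itself (e.g. the quinolinium fragment `"C9H8N"`); for
#'   `protonated = TRUE` it is the neutral molecule (e.g. `"C10H9NO2"`).
#' @param charge Integer, must be +1.
#' @param protonated Add one proton before the electron correction?
#' @return m/z in Th.
#' @export
#' @examples
#' ion_mz("C9H8N")                       # quinolinium cation, 130.0651
#' ion_mz("C10H9NO2", protonated = TRUE) # [IAA + H]+, 176.0706
ion_mz <- function(formula, charge = 1L, protonated = FALSE) {
  if (length(charge) != 1L || is.na(charge) || charge != 1L)
    stop("only singly charged cations (charge = +1) are supported",
         call. = FALSE)
  m <- monoisotopic_mass(formula)
  if (protonated)
    m <- m + monoisotopic_mass("H")  # proton = H atom; electron corrected below
  (m - ELECTRON_MASS) / 1
}

#' Parse a heavy-isotope label scheme
#'
#' A label scheme lists isotopic substitutions as `"<mass number><element
#' symbol><count>"` tokens separated by commas or spaces, e.g. `"13C6"`,
#' `"15N1"`, `"2H4"`, `"13C8,15N1"`. The empty string is the identity scheme.
#'
#' @param x Scheme string, or an already-parsed scheme data frame.
#' @return Data frame with columns `element`, `mass_number`, `count`, of
#'   class `label_scheme`.
#' @export
#' @examples
#' label_scheme("13C8,15N1")
label_scheme <- function(x) {
  if (inherits(x, "label_scheme")) return(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("element", "mass_number", "count") %in% names(x)))
    out <- x[c("element", "mass_number", "count")]
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    x <- gsub("[,;[:space:]]+", " ", trimws(x))
    if (!nzchar(x)) {
      out <- data.frame(element = character(0), mass_number = integer(0),
                        count = integer(0))
    } else {
      toks <- strsplit(x, " ", fixed = TRUE)[[1]]
      ok <- grepl("^[0-9]+[A-Z][a-z]?[0-9]*$", toks)
      if (!all(ok))
        stop("cannot parse label scheme token: '", toks[!ok][1L], "'",
             call. = FALSE)
      mn <- as.integer(sub("^([0-9]+).*$", "\\1", toks))
      el <- sub("^[0-9]+([A-Z][a-z]?).*$", "\\1", toks)
      n <- sub("^[0-9]+[A-Z][a-z]?", "", toks)
      out <- data.frame(element = el, mass_number = mn,
                        count = ifelse(nzchar(n), as.integer(n), 1L))
    }
  }
  for (i in seq_len(nrow(out))) {
    iso <- .element_isotopes(out$element[i])
    if (!out$mass_number[i] %in% iso$mass_number)
      stop("no isotope ", out$mass_number[i], out$element[i],
           " in the isotope table", call. = FALSE)
  }
  if (any(out$count < 1)) stop("substituted counts must be >= 1", call. = FALSE)
  class(out) <- c("label_scheme", "data.frame")
  out
}

#' Mass shift of a label scheme
#'
#' Sum of `count * (heavy isotope mass - lightest isotope mass)` over the
#' scheme's substitutions.
#'
#' @param scheme See [label_scheme()].
#' @return Shift in Da.
#' @export
#' @examples
#' mass_shift("13C6")  # 6 * 1.00335
mass_shift <- function(scheme) {
  scheme <- label_scheme(scheme)
  if (!nrow(scheme)) return(0)
  d <- vapply(seq_len(nrow(scheme)), function(i) {
    iso <- .element_isotopes(scheme$element[i])
    iso$mass[match(scheme$mass_number[i], iso$mass_number)] - iso$mass[1L]
  }, numeric(1))
  sum(d * scheme$count)
}

#' m/z of an isotopically labeled ion
#'
#' Adds the label scheme's mass shift to a base ion m/z; the charge is
#' unchanged. If the ion formula is supplied, substitution counts are
#' validated against the available atoms.
#'
#' @param base_mz Base (unlabeled) ion m/z.
#' @param scheme See [label_scheme()].
#' @param formula Optional ion formula for validation.
#' @return m/z in Th.
#' @export
#' @examples
#' labeled_mz(ion_mz("C9H8N"), "15N1")  # 131.0622
labeled_mz <- function(base_mz, scheme, formula = NULL) {
  scheme <- label_scheme(scheme)
  if (!is.null(formula)) {
    counts <- parse_formula(formula)
    for (i in seq_len(nrow(scheme))) {
      have <- counts[scheme$element[i]]
      if (is.na(have) || scheme$count[i] > have)
        stop("label scheme substitutes ", scheme$count[i], " ",
             scheme$element[i], " atoms but the formula has ",
             if (is.na(have)) 0L else have, call. = FALSE)
    }
  }
  base_mz + mass_shift(scheme)
}

#' Narrow extraction window around an m/z
#'
#' Symmetric window `[mz - half_width, mz + half_width]`, bounds reported
#' rounded (round-half-even) to `digits` decimal places. The default
#' half-width of 0.0010 m/z is absolute, not ppm; a ppm mode is available.
#'
#' @param mz Center m/z.
#' @param half_width Half-width, in m/z units (or in ppm if `ppm = TRUE`).
#' @param digits Decimal places for the reported bounds.
#' @param ppm Interpret `half_width` as parts-per-million of `mz`?
#' @return Named numeric vector `c(low, high)` of class `mz_window`.
#' @export
#' @examples
#' mz_window(ion_mz("C9H8N"))  # 130.0641 130.0661
mz_window <- function(mz, half_width = 0.0010, digits = 4, ppm = FALSE) {
  stopifnot(length(mz) == 1L, is.finite(mz))
  if (!is.finite(half_width) || half_width <= 0)
    stop("half_width must be positive", call. = FALSE)
  hw <- if (ppm) mz * half_width * 1e-6 else half_width
  w <- round(c(low = mz - hw, high = mz + hw), digits)
  class(w) <- "mz_window"
  w
}

#' @export
print.mz_window <- function(x, ...) {
  cat(sprintf("m/z window [%.4f, %.4f]\n", x[["low"]], x[["high"]]))
  invisible(x)
}

# Single-atom nominal-shift abundance distribution for one element:
# probability of shift s = mass_number - lightest mass number.
.atom_shift_dist <- function(element, max_shift) {
  iso <- .element_isotopes(element)
  shifts <- iso$mass_number - iso$mass_number[1L]
  p <- numeric(max_shift + 1L)
  keep <- shifts <= max_shift
  p[shifts[keep] + 1L] <- iso$abundance[keep]
  # mass renormalization is not applied: truncated tail mass is negligible for
  # the supported elements and max_shift >= 1
  p
}

.convolve_trunc <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  for (s in seq_len(n)) {
    i <- seq_len(s)
    out[s] <- sum(a[i] * b[s - i + 1L])
  }
  out
}

#' Natural-abundance isotopologue envelope
#'
#' Relative abundances of the M+0 .. M+`max_shift` isotopologue peaks of a
#' formula under natural isotopic abundances, computed by per-element
#' multinomial expansion (polynomial convolution of single-atom shift
#' distributions) aggregated by nominal mass shift and normalized to the
#' monoisotopic peak (M+0 = 100).
#'
#' @param formula Formula string or named count vector.
#' @param max_shift Largest shift to report (>= 1).
#' @return Numeric vector of length `max_shift + 1`, named `"M+0"` ...;
#'   `"M+0"` is 100.
#' @export
#' @examples
#' isotopologue_envelope("C10H9NO2")[["M+1"]]  # ~11.4% for IAA
isotopologue_envelope <- function(formula, max_shift = 3L) {
  counts <- parse_formula(formula)
  max_shift <- as.integer(max_shift)
  if (is.na(max_shift) || max_shift < 1L)
    stop("max_shift must be >= 1", call. = FALSE)
  env <- c(1, numeric(max_shift))
  for (el in names(counts)) {
    atom <- .atom_shift_dist(el, max_shift)
    for (i in seq_len(counts[[el]])) env <- .convolve_trunc(env, atom)
  }
  out <- 100 * env / env[1L]
  names(out) <- paste0("M+", 0:max_shift)
  out
}

# Formula of the atoms left at natural abundance after applying a label
# scheme (used for satellite peaks of labeled channels).
.residual_formula <- function(formula, scheme) {
  counts <- parse_formula(formula)
  scheme <- label_scheme(scheme)
  for (i in seq_len(nrow(scheme))) {
    el <- scheme$element[i]
    counts[el] <- counts[el] - scheme$count[i]
  }
  counts[counts > 0]
}

#' Build a monitored-channel target table
#'
#' Expands a compound list against a labeling design into one ion target per
#' compound x channel role, with exact m/z, narrow extraction window and
#' retention-time window. Channel windows closer than one full window width
#' are flagged (`crosstalk`) but kept quantifiable.
#'
#' @param compounds Data frame with columns `name`, `ion_formula`,
#'   `protonated` (logical), `rt_min`, `rt_max`, and optionally `segment`
#'   (acquisition filter label) and per-compound scheme overrides
#'   `baseline_label`, `tracer_label`, `is_label`.
#' @param design List with elements `baseline`, `tracer`, `internal_standard`
#'   (label scheme strings; `""` means the unlabeled monoisotopomer), and
#'   optionally `monoisotopomer = TRUE` to add an unlabeled channel.
#' @param half_width Window half-width in m/z (see [mz_window()]).
#' @return Data frame of class `target_table`: one row per target with
#'   columns `compound`, `channel`, `scheme`, `ion_formula`, `mz`, `mz_low`,
#'   `mz_high`, `rt_min`, `rt_max`, `segment`, `crosstalk`.
#' @export
#' @examples
#' cmp <- data.frame(name = "IAA", ion_formula = "C9H8N", protonated = FALSE,
#'                   rt_min = 5.0, rt_max = 5.5)
#' build_target_table(cmp, list(baseline = "15N1", tracer = "13C6",
#'                              internal_standard = "2H4"))
build_target_table <- function(compounds, design, half_width = 0.0010) {
  stopifnot(is.data.frame(compounds),
            all(c("name", "ion_formula", "rt_min", "rt_max") %in%
                  names(compounds)))
  if (is.null(compounds$protonated)) compounds$protonated <- FALSE
  if (is.null(compounds$segment)) compounds$segment <- NA_character_
  roles <- c(baseline = "endogenous", tracer = "tracer",
             internal_standard = "internal_standard")
  rows <- list()
  for (i in seq_len(nrow(compounds))) {
    cmp <- compounds[i, ]
    base <- ion_mz(cmp$ion_formula, protonated = isTRUE(cmp$protonated))
    schemes <- character(0)
    if (isTRUE(design$monoisotopomer))
      schemes <- c(monoisotopomer = "")
    for (key in names(roles)) {
      override <- cmp[[paste0(switch(key, baseline = "baseline",
                                     tracer = "tracer",
                                     internal_standard = "is"), "_label")]]
      sch <- if (!is.null(override) && !is.na(override)) override
             else design[[key]]
      if (is.null(sch)) next
      schemes[roles[[key]]] <- sch
    }
    for (ch in names(schemes)) {
      mz <- labeled_mz(base, schemes[[ch]], formula = cmp$ion_formula)
      w <- mz_window(mz, half_width = half_width)
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cmp$name, channel = ch, scheme = schemes[[ch]],
        ion_formula = cmp$ion_formula, protonated = isTRUE(cmp$protonated),
        mz = mz, mz_low = w[["low"]], mz_high = w[["high"]],
        rt_min = cmp$rt_min, rt_max = cmp$rt_max,
        segment = cmp$segment, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$crosstalk <- FALSE
  width <- 2 * half_width
  for (cn in unique(out$compound)) {
    idx <- which(out$compound == cn)
    if (length(idx) < 2L) next
    d <- abs(outer(out$mz[idx], out$mz[idx], "-"))
    diag(d) <- Inf
    clash <- apply(d, 1L, min) <= width
    if (any(clash)) {
      out$crosstalk[idx[clash]] <- TRUE
      warning("cross-talk: channel windows of '", cn,
              "' are separated by less than one window width", call. = FALSE)
    }
  }
  class(out) <- c("target_table", "data.frame")
  out
}

#' Read a target configuration file
#'
#' The configuration is a YAML document with a `design` block (label schemes
#' per channel role) and a `compounds` list (name, ion formula, protonation,
#' RT window, optional acquisition segment and per-compound scheme
#' overrides). See `system.file("extdata", "iaa_targets.yaml", package =
#' "silkr")` for the worked IAA pathway configuration.
#'
#' @param path Path to the YAML file.
#' @param half_width Window half-width passed to [build_target_table()].
#' @return A `target_table` (see [build_target_table()]).
#' @export
read_target_config <- function(path, half_width = 0.0010) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$compounds), !is.null(cfg$design))
  cols <- c("name", "ion_formula", "protonated", "rt_min", "rt_max",
            "segment", "baseline_label", "tracer_label", "is_label")
  cmp <- do.call(rbind, lapply(cfg$compounds, function(x) {
    row <- lapply(cols, function(cn) if (is.null(x[[cn]])) NA else x[[cn]])
    names(row) <- cols
    as.data.frame(row, stringsAsFactors = FALSE)
  }))
  cmp$protonated <- ifelse(is.na(cmp$protonated), FALSE,
                           as.logical(cmp$protonated))
  hw <- if (!is.null(cfg$design$half_width)) cfg$design$half_width else half_width
  build_target_table(cmp, cfg$design, half_width = hw)
}

#' Export a target table
#'
#' Writes the full target table as TSV, or a PRM-style inclusion list
#' (m/z, charge, RT start/end) for instrument import.
#'
#' @param targets A `target_table`.
#' @param path Output file path.
#' @param format `"tsv"` or `"inclusion"`.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(targets, path, format = c("tsv", "inclusion")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(targets), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    inc <- data.frame(mz = sprintf("%.4f", targets$mz), charge = 1L,
                      rt_start = targets$rt_min, rt_end = targets$rt_max,
                      comment = paste(targets$compound, targets$channel,
                                      sep = "_"))
    utils::write.table(inc, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
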