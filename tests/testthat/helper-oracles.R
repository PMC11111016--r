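# Independent oracles used across the suite.

# Brute-force isotopologue envelope: enumerate every isotope assignment of
# every atom, aggregate probability by total nominal shift, normalize M+0 to
# 100. Independent of the package's convolution implementation; only feasible
# for small molecules.
brute_force_envelope <- function(formula, max_shift = 3L) {
  counts <- silkr::parse_formula(formula)
  iso <- silkr::isotope_table()
  atoms <- rep(names(counts), counts)
  per_atom <- lapply(atoms, function(el) {
    rows <- iso[iso$element == el, ]
    rows <- rows[order(rows$mass_number), ]
    list(shift = rows$mass_number - rows$mass_number[1L], p = rows$abundance)
  })
  grid <- do.call(expand.grid, lapply(per_atom, function(a)
    seq_along(a$shift)))
  shift_tot <- rowSums(mapply(function(a, idx) a$shift[idx], per_atom,
                              grid, SIMPLIFY = TRUE))
  prob <- apply(mapply(function(a, idx) a$p[idx], per_atom, grid,
                       SIMPLIFY = TRUE), 1L, prod)
  env <- vapply(0:max_shift, function(s) sum(prob[shift_tot == s]),
                numeric(1))
  100 * env / env[1L]
}

# Closed-form label fraction of a linear cascade fed by a step-labeled
# source, via deSolve (independent of the matrix-exponential solver).
ode_label_fractions <- function(network, times, entry) {
  k_of <- silkr::pool_turnover(network)
  nm <- network$pools$name
  sizes <- stats::setNames(network$pools$pool_size, nm)
  e <- network$edges
  deriv <- function(t, L, parms) {
    dL <- stats::setNames(numeric(length(nm)), nm)
    for (i in seq_len(nrow(e))) {
      v <- e$to[i]; u <- e$from[i]
      w <- e$rate[i] * e$multiplier[i] * sizes[u] / sizes[v]
      Lu <- if (u == entry) 1 else L[u]
      dL[v] <- dL[v] + w * (Lu - L[v])
    }
    dL[entry] <- 0
    list(dL)
  }
  L0 <- stats::setNames(numeric(length(nm)), nm)
  L0[entry] <- 1
  out <- deSolve::lsoda(L0, c(0, times), deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  out[-1L, nm, drop = FALSE]
}

# Default sample entry list for in-memory quantification.
sample_entry <- function(run, timepoint, replicate = 1L, treatment = "mock",
                         fw = 10, spike = 0.2) {
  list(run = run, treatment = treatment, timepoint = timepoint,
       replicate = replicate, fresh_weight_mg = fw, is_spike_ng = spike)
}

# A tiny deterministic run: `n` scans at fixed RT spacing, each with the
# given centroid m/z vector and per-scan intensity rows.
toy_run <- function(mz, intensity_matrix, rt = NULL, scan_low = 100,
                    scan_high = 250) {
  n <- nrow(intensity_matrix)
  if (is.null(rt)) rt <- seq(0.1, by = 0.01, length.out = n)
  spectra <- lapply(seq_len(n), function(i) {
    ord <- order(mz)
    list(rt = rt[i], mz = mz[ord],
         intensity = as.numeric(intensity_matrix[i, ord]),
         ms_level = 1L, precursor_mz = NA_real_,
         scan_low = scan_low, scan_high = scan_high)
  })
  silkr::ms_run(spectra)
}
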