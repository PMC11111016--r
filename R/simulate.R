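# Synthetic SILK experiments: step-tracer kinetics through a metabolic pool
# network at steady state, rendered as centroided LC-MS runs with ground
# truth.

#' Construct a metabolic pool network
#'
#' Pools are at metabolic steady state (constant sizes); only label fractions
#' evolve. Edges carry first-order rate constants (min^-1) applied to the
#' upstream pool, so the flux through edge `u -> v` is
#' `rate * multiplier * pool_size[u]` (ng g^-1 min^-1) and the turnover rate
#' of pool `v` is its total inflow divided by its pool size.
#'
#' @param pools Data frame: `name`, `ion_formula`, `protonated` (logical),
#'   `pool_size` (ng/g), `rt` (min), `peak_sd` (min), and per-pool channel
#'   label schemes `baseline_label`, `tracer_label`, `is_label` (`""` = the
#'   unlabeled monoisotopomer).
#' @param edges Data frame: `from`, `to`, `rate` (min^-1, >= 0), and
#'   optionally `multiplier` (inhibitor factor in `[0, 1]`, default 1).
#' @return Object of class `pool_network`. The network must be acyclic.
#' @export
pool_network <- function(pools, edges) {
  stopifnot(is.data.frame(pools), is.data.frame(edges),
            all(c("name", "pool_size") %in% names(pools)),
            all(c("from", "to", "rate") %in% names(edges)))
  if (anyDuplicated(pools$name)) stop("duplicate pool names", call. = FALSE)
  if (!all(edges$from %in% pools$name) || !all(edges$to %in% pools$name))
    stop("edge endpoints must be pool names", call. = FALSE)
  if (any(edges$rate < 0)) stop("rate constants must be >= 0", call. = FALSE)
  if (is.null(edges$multiplier)) edges$multiplier <- 1
  if (any(edges$multiplier < 0 | edges$multiplier > 1))
    stop("inhibitor multipliers must lie in [0, 1]", call. = FALSE)
  if (any(pools$pool_size <= 0)) stop("pool sizes must be positive",
                                      call. = FALSE)
  net <- structure(list(pools = pools, edges = edges),
                   class = "pool_network")
  .topo_order(net)  # errors on cycles
  net
}

#' @export
print.pool_network <- function(x, ...) {
  cat(sprintf("<pool_network> %d pools, %d edges\n",
              nrow(x$pools), nrow(x$edges)))
  k <- pool_turnover(x)
  for (i in seq_len(nrow(x$pools)))
    cat(sprintf("  %-14s %8.3g ng/g   turnover %.3g /min\n",
                x$pools$name[i], x$pools$pool_size[i], k[[x$pools$name[i]]]))
  invisible(x)
}

# Kahn topological sort; errors on cycles.
.topo_order <- function(net) {
  nm <- net$pools$name
  indeg <- stats::setNames(integer(length(nm)), nm)
  for (v in net$edges$to) indeg[v] <- indeg[v] + 1L
  queue <- nm[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (i in which(net$edges$from == v)) {
      w <- net$edges$to[i]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(nm))
    stop("pool network contains a cycle", call. = FALSE)
  out
}

#' Per-pool turnover rate constants
#'
#' Total effective inflow (sum over inbound edges of
#' `rate * multiplier * upstream pool size`) divided by the pool size, in
#' min^-1. Pools with no inflow have turnover 0.
#'
#' @param network A [pool_network()].
#' @return Named numeric vector, min^-1.
#' @export
pool_turnover <- function(network) {
  p <- network$pools; e <- network$edges
  sizes <- stats::setNames(p$pool_size, p$name)
  k <- stats::setNames(numeric(nrow(p)), p$name)
  for (i in seq_len(nrow(e)))
    k[e$to[i]] <- k[e$to[i]] +
      e$rate[i] * e$multiplier[i] * sizes[e$from[i]] / sizes[e$to[i]]
  k
}

#' Apply inhibitor multipliers to a network
#'
#' Scales the named edges' rates by the given factors. With
#' `preincubated = TRUE` (the default, matching protocols where inhibitors
#' act for many pool-turnover times before the tracer is applied), the
#' steady-state pool sizes downstream of the inhibited steps are
#' re-equilibrated to the reduced flux: each pool's new size is its old size
#' scaled by the ratio of new to old inflow, resolved in topological order.
#' With `preincubated = FALSE` (acute inhibition at tracer time), pool sizes
#' stay fixed and only the label-fraction kinetics slow down.
#'
#' @param network A [pool_network()].
#' @param multipliers Named numeric vector, names `"from->to"`, values in
#'   `[0, 1]`.
#' @param preincubated Re-equilibrate steady-state pool sizes?
#' @return A modified [pool_network()].
#' @export
#' @examples
#' net <- iaa_network()
#' apply_inhibitors(net, c("Trp->IPyA" = 0.1))
apply_inhibitors <- function(network, multipliers, preincubated = TRUE) {
  if (is.null(multipliers) || !length(multipliers)) return(network)
  stopifnot(!is.null(names(multipliers)),
            all(multipliers >= 0 & multipliers <= 1))
  e <- network$edges
  ids <- paste0(e$from, "->", e$to)
  for (nm in names(multipliers)) {
    i <- match(nm, ids)
    if (is.na(i)) stop("no edge '", nm, "' in the network", call. = FALSE)
    e$multiplier[i] <- e$multiplier[i] * multipliers[[nm]]
  }
  out <- network
  out$edges <- e
  if (preincubated) {
    base_in <- .pool_inflow(network)
    ord <- .topo_order(out)
    sizes <- stats::setNames(out$pools$pool_size, out$pools$name)
    for (v in ord) {
      ein <- which(e$to == v)
      if (!length(ein) || base_in[[v]] == 0) next
      new_in <- sum(e$rate[ein] * e$multiplier[ein] * sizes[e$from[ein]])
      sizes[v] <- sizes[v] * new_in / base_in[[v]]
    }
    if (any(sizes <= 0)) {
      # fully blocked pools: keep an infinitesimal pool so concentrations
      # render as zero without degenerate rates
      sizes[sizes <= 0] <- .Machine$double.eps
    }
    out$pools$pool_size <- unname(sizes[out$pools$name])
  }
  out
}

.pool_inflow <- function(network) {
  p <- network$pools; e <- network$edges
  sizes <- stats::setNames(p$pool_size, p$name)
  infl <- stats::setNames(numeric(nrow(p)), p$name)
  for (i in seq_len(nrow(e)))
    infl[e$to[i]] <- infl[e$to[i]] +
      e$rate[i] * e$multiplier[i] * sizes[e$from[i]]
  infl
}

#' Solve step-labeling tracer kinetics on a pool network
#'
#' Under step labeling the tracer entry pool jumps to label fraction 1 at
#' t = 0 (or approaches it with a finite first-order `uptake_rate`). Every
#' other pool obeys the linear balance
#' `dL_v/dt = sum_e (flux_e / P_v) (L_source(e) - L_v)` over its inbound
#' edges, a constant-coefficient linear system solved here by matrix
#' exponential.
#'
#' @param network A [pool_network()].
#' @param times Times in minutes (>= 0).
#' @param entry Name of the tracer entry pool.
#' @param uptake_rate First-order uptake rate of the entry pool (min^-1);
#'   `Inf` (default) means an instantaneous step to fraction 1.
#' @return Object of class `label_state`: a matrix of label fractions, one
#'   row per time, one column per pool, with attributes `times`, `entry`.
#' @export
#' @examples
#' net <- iaa_network()
#' L <- solve_label_kinetics(net, times = c(1, 10, 100), entry = "anthranilate")
solve_label_kinetics <- function(network, times, entry, uptake_rate = Inf) {
  stopifnot(inherits(network, "pool_network"), all(times >= 0))
  nm <- network$pools$name
  if (!entry %in% nm) stop("unknown entry pool: ", entry, call. = FALSE)
  e <- network$edges
  sizes <- stats::setNames(network$pools$pool_size, nm)
  states <- if (is.finite(uptake_rate)) nm else setdiff(nm, entry)
  n <- length(states)
  A <- matrix(0, n, n, dimnames = list(states, states))
  b <- stats::setNames(numeric(n), states)
  for (i in seq_len(nrow(e))) {
    v <- e$to[i]
    if (!v %in% states) next
    u <- e$from[i]
    w <- e$rate[i] * e$multiplier[i] * sizes[u] / sizes[v]
    A[v, v] <- A[v, v] - w
    if (u %in% states) A[v, u] <- A[v, u] + w else b[v] <- b[v] + w
  }
  if (is.finite(uptake_rate)) {
    if (uptake_rate <= 0) stop("uptake_rate must be positive", call. = FALSE)
    A[entry, entry] <- A[entry, entry] - uptake_rate
    b[entry] <- b[entry] + uptake_rate
  }
  L <- matrix(0, length(times), length(nm), dimnames = list(NULL, nm))
  if (!is.finite(uptake_rate)) L[, entry] <- 1
  if (n > 0) {
    # particular solution: steady state L* solving A L* + b = 0; pools with
    # zero inflow have an all-zero row and stay at 0
    active <- which(abs(diag(A)) > 0)
    Lstar <- stats::setNames(numeric(n), states)
    if (length(active))
      Lstar[active] <- solve(A[active, active, drop = FALSE],
                             -b[active])
    for (j in seq_along(times)) {
      E <- as.matrix(Matrix::expm(A * times[j]))
      Lj <- Lstar + as.vector(E %*% (-Lstar))
      L[j, states] <- pmin(pmax(Lj, 0), 1)  # clamp 1e-9-level overshoot
    }
  }
  structure(L, class = c("label_state", "matrix"), times = times,
            entry = entry)
}

#' Simulation configuration
#'
#' Bundles the experiment design and noise model for the synthetic-run
#' generator. Defaults emulate a rapid-labeling seedling experiment: 9
#' timepoints doubling from 0.5 to 256 min, 3 replicates, 5% multiplicative
#' amplitude noise, 2 ppm mass error, 0.6 s scan interval, 0.2 ng unlabeled
#' or heavy internal standard per 10 mg fresh tissue.
#'
#' @param seed Integer random seed (mandatory).
#' @param timepoints Sampling times in minutes, non-negative ascending.
#' @param replicates Replicates per timepoint.
#' @param noise_cv Multiplicative (log-normal) sd fraction on peak
#'   amplitudes; 0 turns amplitude noise off.
#' @param baseline Additive baseline counts per channel centroid per scan.
#' @param poisson Apply Poisson counting noise to centroid intensities?
#' @param ppm_sd Mass error sd in ppm; 0 turns m/z jitter off.
#' @param scan_interval_s Scan interval in seconds.
#' @param run_length_min Run duration in minutes.
#' @param scan_range Acquired m/z range `c(low, high)`.
#' @param entry Tracer entry pool name.
#' @param uptake_rate Entry-pool uptake rate (min^-1, `Inf` = step).
#' @param is_spike_ng Internal standard spike per sample, ng.
#' @param fresh_weight_mg Sample fresh weight, mg.
#' @param response_factor Detector response, intensity counts * min per
#'   (ng/g) of analyte.
#' @param preincubated Inhibitor treatments re-equilibrate pool sizes before
#'   labeling? See [apply_inhibitors()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       timepoints = c(0.5, 1, 2, 4, 8, 16, 32, 64, 256),
                       replicates = 3L,
                       noise_cv = 0.05, baseline = 0, poisson = FALSE,
                       ppm_sd = 2, scan_interval_s = 0.6,
                       run_length_min = 8, scan_range = c(100, 250),
                       entry = "anthranilate", uptake_rate = Inf,
                       is_spike_ng = 0.2, fresh_weight_mg = 10,
                       response_factor = 1e4, preincubated = TRUE) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a random seed is mandatory", call. = FALSE)
  if (any(timepoints < 0) || is.unsorted(timepoints))
    stop("timepoints must be non-negative ascending", call. = FALSE)
  structure(list(seed = as.integer(seed), timepoints = timepoints,
                 replicates = as.integer(replicates), noise_cv = noise_cv,
                 baseline = baseline, poisson = poisson, ppm_sd = ppm_sd,
                 scan_interval_s = scan_interval_s,
                 run_length_min = run_length_min, scan_range = scan_range,
                 entry = entry, uptake_rate = uptake_rate,
                 is_spike_ng = is_spike_ng,
                 fresh_weight_mg = fresh_weight_mg,
                 response_factor = response_factor,
                 preincubated = preincubated),
            class = "sim_config")
}

# Deterministic per-sample seed below 2^31.
.sample_seed <- function(seed, timepoint_index, replicate, arm_index) {
  (seed * 7 + timepoint_index * 1009 + replicate * 101003 +
     arm_index * 11000003) %% 2147483629L
}

#' Render one synthetic LC-MS run
#'
#' For each pool, three channels are rendered as Gaussian elution profiles
#' at the pool's retention time: the endogenous (baseline-label) channel
#' scaled by `pool_size * (1 - L)`, the tracer channel by `pool_size * L`,
#' and the internal-standard channel by the spike amount. Each channel
#' additionally carries its natural-abundance M+1 satellite (computed from
#' the atoms left at natural abundance after labeling). Centroid m/z values
#' are jittered by the ppm error model, amplitudes by multiplicative
#' log-normal noise, and an optional additive baseline and Poisson counting
#' noise are applied. Deterministic given the config seed.
#'
#' @param network A [pool_network()] (already inhibited, if applicable; see
#'   [apply_inhibitors()]).
#' @param config A [sim_config()].
#' @param timepoint Sampling time (min).
#' @param replicate Replicate number.
#' @param arm Treatment arm label carried into the truth row (and into the
#'   per-sample seed).
#' @param label_state Optional pre-computed label fractions at `timepoint`
#'   (row of [solve_label_kinetics()] output); computed if omitted.
#' @return List: `run` (an [ms_run()]) and `truth` (data frame with one row
#'   per pool: label fraction, channel concentrations, turnover rate).
#' @export
synthesize_run <- function(network, config, timepoint, replicate = 1L,
                           arm = "mock", label_state = NULL) {
  stopifnot(inherits(network, "pool_network"), inherits(config, "sim_config"))
  if (is.null(label_state)) {
    L <- solve_label_kinetics(network, timepoint, entry = config$entry,
                              uptake_rate = config$uptake_rate)
    label_state <- L[1L, ]
  }
  tp_idx <- match(timepoint, config$timepoints)
  if (is.na(tp_idx)) tp_idx <- round(timepoint * 1000) %% 997L
  arm_idx <- utf8ToInt(substr(arm, 1L, 1L))
  set.seed(.sample_seed(config$seed, tp_idx, replicate, arm_idx))

  p <- network$pools
  k <- pool_turnover(network)
  is_conc <- config$is_spike_ng / (config$fresh_weight_mg / 1000)
  rt <- seq(0, config$run_length_min, by = config$scan_interval_s / 60)
  nscan <- length(rt)
  # accumulate centroids as (scan, mz, intensity) triplets
  cent_scan <- integer(0); cent_mz <- numeric(0); cent_int <- numeric(0)
  truth <- vector("list", nrow(p))

  for (i in seq_len(nrow(p))) {
    pool <- p[i, ]
    Lf <- unname(label_state[[pool$name]])
    base_mz <- ion_mz(pool$ion_formula, protonated = isTRUE(pool$protonated))
    channels <- data.frame(
      channel = c("endogenous", "tracer", "internal_standard"),
      scheme = c(pool$baseline_label, pool$tracer_label, pool$is_label),
      conc = c(pool$pool_size * (1 - Lf), pool$pool_size * Lf, is_conc),
      stringsAsFactors = FALSE)
    for (j in seq_len(nrow(channels))) {
      conc <- channels$conc[j]
      amp_noise <- if (config$noise_cv > 0)
        exp(stats::rnorm(1, -config$noise_cv^2 / 2, config$noise_cv)) else 1
      area <- conc * config$response_factor * amp_noise
      amp <- area / (pool$peak_sd * sqrt(2 * pi))
      mz0 <- labeled_mz(base_mz, channels$scheme[j],
                        formula = pool$ion_formula)
      resid <- .residual_formula(pool$ion_formula, channels$scheme[j])
      sat_ratio <- if (length(resid))
        isotopologue_envelope(resid, 1L)[["M+1"]] / 100 else 0
      d13 <- mass_shift("13C1")
      prof <- amp * exp(-(rt - pool$rt)^2 / (2 * pool$peak_sd^2))
      # additive baseline counts cover every scan of the channel, not just
      # the elution window
      keep <- if (config$baseline > 0) seq_along(rt)
              else which(prof > amp * 1e-6 & prof > 0)
      if (!length(keep)) next
      for (pk in list(c(mz0, 1), c(mz0 + d13, sat_ratio))) {
        if (pk[2] <= 0) next
        ints <- prof[keep] * pk[2] + config$baseline
        mzs <- rep(pk[1], length(keep))
        if (config$ppm_sd > 0)
          mzs <- mzs * (1 + stats::rnorm(length(keep), 0,
                                         config$ppm_sd * 1e-6))
        if (config$poisson) ints <- stats::rpois(length(ints), ints)
        cent_scan <- c(cent_scan, keep)
        cent_mz <- c(cent_mz, mzs)
        cent_int <- c(cent_int, ints)
      }
    }
    truth[[i]] <- data.frame(
      arm = arm, timepoint = timepoint, replicate = replicate,
      pool = pool$name, label_fraction = Lf,
      endogenous_conc = pool$pool_size * (1 - Lf),
      tracer_conc = pool$pool_size * Lf,
      is_conc = is_conc, turnover = unname(k[[pool$name]]))
  }

  spectra <- vector("list", nscan)
  idx_by_scan <- split(seq_along(cent_scan),
                       factor(cent_scan, levels = seq_len(nscan)))
  for (s in seq_len(nscan)) {
    idx <- idx_by_scan[[s]]
    ord <- idx[order(cent_mz[idx])]
    mzv <- cent_mz[ord]; iv <- cent_int[ord]
    if (length(mzv) > 1L) {
      # merge coincident centroids (window collisions after jitter)
      dup <- c(FALSE, diff(mzv) <= 0)
      if (any(dup)) {
        g <- cumsum(!dup)
        iv <- as.numeric(tapply(iv, g, sum))
        mzv <- as.numeric(tapply(mzv, g, min))
      }
    }
    spectra[[s]] <- list(rt = rt[s], mz = mzv, intensity = iv,
                         ms_level = 1L, precursor_mz = NA_real_,
                         scan_low = config$scan_range[1],
                         scan_high = config$scan_range[2])
  }
  list(run = ms_run(spectra, metadata = list(source = "simulated",
                                             centroided = TRUE)),
       truth = do.call(rbind, truth))
}

#' Generate a full synthetic experiment on disk
#'
#' One mzML run per (timepoint x replicate x treatment arm), plus a ground
#' truth table, a sample manifest and the serialized configuration.
#'
#' @param network A [pool_network()].
#' @param config A [sim_config()].
#' @param out_dir Output directory. Refuses to write into an existing
#'   non-empty directory unless `force = TRUE`.
#' @param treatments Named list of inhibitor multiplier vectors (see
#'   [apply_inhibitors()]); `NULL` entries are untreated arms. Default one
#'   untreated `mock` arm.
#' @param force Overwrite an existing non-empty directory?
#' @return Invisibly, a list with the `manifest` and `truth` data frames.
#' @export
generate_experiment <- function(network, config, out_dir,
                                treatments = list(mock = NULL),
                                force = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE)",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(); truth <- list()
  for (ai in seq_along(treatments)) {
    arm <- names(treatments)[ai]
    net_arm <- apply_inhibitors(network, treatments[[ai]],
                                preincubated = config$preincubated)
    Lmat <- solve_label_kinetics(net_arm, config$timepoints,
                                 entry = config$entry,
                                 uptake_rate = config$uptake_rate)
    for (ti in seq_along(config$timepoints)) {
      for (r in seq_len(config$replicates)) {
        sim <- synthesize_run(net_arm, config, config$timepoints[ti],
                              replicate = r, arm = arm,
                              label_state = Lmat[ti, ])
        file <- sprintf("%s_t%03d_r%d.mzML", arm, ti, r)
        write_ms_run(sim$run, file.path(out_dir, file))
        manifest[[length(manifest) + 1L]] <- data.frame(
          file = file, treatment = arm,
          timepoint = config$timepoints[ti], replicate = r,
          fresh_weight_mg = config$fresh_weight_mg,
          is_spike_ng = config$is_spike_ng)
        truth[[length(truth) + 1L]] <- sim$truth
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  cfg <- unclass(config)
  cfg$config_hash <- sum(utf8ToInt(paste(
    vapply(cfg, function(x) paste(format(x), collapse = ","), character(1)),
    collapse = ";")))
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(list(manifest = manifest, truth = truth))
}

#' Sample a quantification-level synthetic dataset
#'
#' Draws per-sample channel concentrations directly at the quantification
#' level: the ODE label truth scaled by the same multiplicative log-normal
#' amplitude noise the MS renderer applies. Used for large recovery studies
#' where rendering every run as spectra is unnecessary; noise-free it agrees
#' with the full render-extract-quantify path.
#'
#' @param network A [pool_network()].
#' @param config A [sim_config()].
#' @param treatments As in [generate_experiment()].
#' @return Data frame: `treatment`, `timepoint`, `replicate`, `compound`,
#'   `channel`, `true_conc`, `conc_ng_g`.
#' @export
simulate_quant_table <- function(network, config,
                                 treatments = list(mock = NULL)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rows <- list()
  for (ai in seq_along(treatments)) {
    arm <- names(treatments)[ai]
    net_arm <- apply_inhibitors(network, treatments[[ai]],
                                preincubated = config$preincubated)
    Lmat <- solve_label_kinetics(net_arm, config$timepoints,
                                 entry = config$entry,
                                 uptake_rate = config$uptake_rate)
    sizes <- stats::setNames(net_arm$pools$pool_size, net_arm$pools$name)
    for (ti in seq_along(config$timepoints)) {
      for (r in seq_len(config$replicates)) {
        for (pool in net_arm$pools$name) {
          Lf <- unname(Lmat[ti, pool])
          tc <- c(endogenous = unname(sizes[pool]) * (1 - Lf),
                  tracer = unname(sizes[pool]) * Lf)
          noise <- if (config$noise_cv > 0)
            exp(stats::rnorm(2, -config$noise_cv^2 / 2, config$noise_cv))
          else c(1, 1)
          rows[[length(rows) + 1L]] <- data.frame(
            treatment = arm, timepoint = config$timepoints[ti],
            replicate = r, compound = pool,
            channel = names(tc), true_conc = unname(tc),
            conc_ng_g = unname(tc) * noise)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default IAA biosynthesis network
#'
#' The anthranilate -> indole -> tryptophan -> indole-3-pyruvate -> IAA
#' cascade, with pool sizes, retention times and channel label schemes read
#' from the packaged configuration (`inst/extdata/iaa_network.yaml`).
#' Intermediate pools are small and turn over in seconds; the IAA pool turns
#' over with a half-time of about 14 min. An optional tryptophan-independent
#' `indole -> IAA` shunt can be enabled.
#'
#' @param shunt Add the indole -> IAA shunt edge?
#' @param path Alternative network YAML.
#' @return A [pool_network()].
#' @export
iaa_network <- function(shunt = FALSE, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "iaa_network.yaml", package = "silkr")
  cfg <- yaml::read_yaml(path)
  pools <- do.call(rbind, lapply(cfg$pools, as.data.frame))
  edges <- do.call(rbind, lapply(cfg$edges, as.data.frame))
  if (shunt && !is.null(cfg$shunt_edges))
    edges <- rbind(edges,
                   do.call(rbind, lapply(cfg$shunt_edges, as.data.frame)))
  pool_network(pools, edges)
}

#' Target table for a simulated network
#'
#' Builds the monitored-channel targets matching [synthesize_run()]'s
#' rendering: per pool, the endogenous, tracer and internal-standard
#' channels at the pool's configured label schemes and RT window.
#'
#' @param network A [pool_network()].
#' @param rt_halfwidth RT window half-width around each pool's apex (min).
#' @param half_width m/z window half-width.
#' @return A `target_table` (see [build_target_table()]).
#' @export
network_targets <- function(network, rt_halfwidth = 0.3,
                            half_width = 0.0010) {
  p <- network$pools
  cmp <- data.frame(name = p$name, ion_formula = p$ion_formula,
                    protonated = p$protonated,
                    rt_min = p$rt - rt_halfwidth,
                    rt_max = p$rt + rt_halfwidth,
                    baseline_label = p$baseline_label,
                    tracer_label = p$tracer_label,
                    is_label = p$is_label)
  build_target_table(cmp, design = list(baseline = NULL, tracer = NULL,
                                        internal_standard = NULL),
                     half_width = half_width)
}
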