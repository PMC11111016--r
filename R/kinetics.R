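# Label-incorporation kinetics: first-order, three-parameter sigmoid and
# four-parameter logistic fits, plus per-timepoint group comparisons.

.silk_models <- list(
  first_order = list(
    formula = y ~ ymax * (1 - exp(-k * t)),
    n_par = 2L, min_timepoints = 3L,
    init = function(t, y) {
      ymax0 <- max(y)
      if (ymax0 <= 0) return(NULL)
      # log-linear regression of log(1 - y/ymax) on t for a starting rate
      frac <- pmin(pmax(1 - y / (ymax0 * 1.05), 1e-6), 1)
      k0 <- tryCatch(max(-unname(stats::coef(
        stats::lm(log(frac) ~ t + 0))[1L]), 1e-6),
        error = function(e) 1e-3)
      list(ymax = ymax0, k = k0)
    },
    lower = c(ymax = 0, k = 0),
    predict = function(p, t) p[["ymax"]] * (1 - exp(-p[["k"]] * t))),
  sigmoid3 = list(
    formula = y ~ a / (1 + exp(-(t - t0) / b)),
    n_par = 3L, min_timepoints = 4L,
    init = function(t, y) {
      if (diff(range(y)) <= 0) return(NULL)
      a0 <- if (abs(max(y)) >= abs(min(y))) max(y) else min(y)
      t0 <- t[which.min(abs(y - a0 / 2))]
      b0 <- diff(range(t)) / 8
      if (stats::cor(t, y) * sign(a0) < 0) b0 <- -b0
      list(a = a0, t0 = t0, b = b0)
    },
    lower = c(a = -Inf, t0 = -Inf, b = -Inf),
    predict = function(p, t) p[["a"]] / (1 + exp(-(t - p[["t0"]]) / p[["b"]]))),
  logistic4 = list(
    formula = y ~ d + (a - d) / (1 + (t / c)^b),
    n_par = 4L, min_timepoints = 5L,
    init = function(t, y) {
      if (diff(range(y)) <= 0) return(NULL)
      # quartiles of the response range; c near mid-response time
      list(a = stats::quantile(y, 0.05, names = FALSE),
           d = stats::quantile(y, 0.95, names = FALSE),
           c = max(stats::median(t[t > 0]), min(t[t > 0])), b = 1)
    },
    lower = c(a = -Inf, d = -Inf, c = 1e-12, b = -Inf),
    predict = function(p, t)
      p[["d"]] + (p[["a"]] - p[["d"]]) / (1 + (t / p[["c"]])^p[["b"]]))
)

.aicc <- function(rss, n, k) {
  # k model parameters + 1 for the error variance
  p <- k + 1
  n * log(rss / n) + 2 * p + if (n - p - 1 > 0) 2 * p * (p + 1) / (n - p - 1)
  else Inf
}

.flagged_fit <- function(model, t, y, reason) {
  structure(list(model = model, converged = FALSE, reason = reason,
                 coefficients = NULL, se = NULL, rss = NA_real_,
                 half_time = NA_real_, aicc = Inf,
                 data = data.frame(t = t, y = y)),
            class = "silk_fit")
}

.fit_model <- function(model, t, y) {
  spec <- .silk_models[[model]]
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(unique(t)) < spec$min_timepoints)
    stop("'", model, "' needs >= ", spec$min_timepoints,
         " distinct timepoints, got ", length(unique(t)), call. = FALSE)
  start <- spec$init(t, y)
  if (is.null(start))
    return(.flagged_fit(model, t, y,
                        "degenerate series: parameters unidentifiable"))
  fit <- tryCatch(
    minpack.lm::nlsLM(spec$formula, data = data.frame(t = t, y = y),
                      start = start, lower = spec$lower,
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-8, ptol = 1e-8, maxiter = 1000,
                        maxfev = 10000)),
    error = function(e) NULL)
  if (is.null(fit))
    return(.flagged_fit(model, t, y, "nonlinear least squares did not converge"))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  rss <- sum(stats::resid(fit)^2)
  # unidentifiable rate: flat series fits with k ~ 0 and huge/NaN SE
  if (model == "first_order" && (cf[["k"]] <= 1e-12 ||
                                 stats::var(y) == 0))
    return(.flagged_fit(model, t, y, "rate constant unidentifiable"))
  if (model == "logistic4" && stats::var(y) == 0)
    return(.flagged_fit(model, t, y, "slope unidentifiable: constant series"))
  ht <- if (model == "first_order" && cf[["k"]] > 0) log(2) / cf[["k"]]
        else NA_real_
  structure(list(model = model, converged = TRUE, reason = NULL,
                 coefficients = cf, se = se, rss = rss, half_time = ht,
                 aicc = .aicc(rss, length(y), spec$n_par),
                 data = data.frame(t = t, y = y)),
            class = "silk_fit")
}

#' Fit a label-incorporation time course
#'
#' Least-squares fit of one of three canonical incorporation models to a
#' time series of concentrations or label fractions:
#' \describe{
#'   \item{first_order}{`y(t) = ymax * (1 - exp(-k t))`, `k >= 0`; the
#'     turnover half-time `ln 2 / k` is attached.}
#'   \item{sigmoid3}{`y(t) = a / (1 + exp(-(t - t0)/b))`; the inflection
#'     `t0` is reported, and `b < 0` is permitted for decreasing series.}
#'   \item{logistic4}{`y(t) = d + (a - d) / (1 + (t/c)^b)`, `c > 0`; both
#'     asymptotes are reported.}
#' }
#' With `model = "auto"` every model admissible for the number of distinct
#' timepoints is fitted and the lowest-AICc fit is returned. Fits are
#' invariant to data-point order; non-convergent or degenerate series come
#' back flagged (`converged = FALSE`) with parameters absent.
#'
#' @param time Times in minutes (>= 0).
#' @param value Response values (concentration in ng/g or label fraction).
#' @param model `"auto"`, `"first_order"`, `"sigmoid3"` or `"logistic4"`.
#' @return Object of class `silk_fit` with methods `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals` and `plot`.
#' @export
#' @examples
#' t <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
#' y <- 10 * (1 - exp(-0.05 * t))
#' fit_kinetics(t, y, "first_order")
fit_kinetics <- function(time, value,
                         model = c("auto", "first_order", "sigmoid3",
                                   "logistic4")) {
  model <- match.arg(model)
  stopifnot(length(time) == length(value))
  if (any(time < 0)) stop("times must be >= 0", call. = FALSE)
  if (length(unique(time)) < 2L)
    stop("need >= 2 distinct timepoints", call. = FALSE)
  if (model != "auto") return(.fit_model(model, time, value))
  nt <- length(unique(time))
  cands <- names(Filter(function(s) nt >= s$min_timepoints, .silk_models))
  if (!length(cands))
    stop("too few distinct timepoints for any model", call. = FALSE)
  fits <- lapply(cands, .fit_model, t = time, y = value)
  best <- which.min(vapply(fits, `[[`, numeric(1), "aicc"))
  fits[[best]]
}

#' @rdname fit_kinetics
#' @param ts Alternative interface: a data frame with columns `time` and
#'   `value`.
#' @export
fit_first_order <- function(time, value) .fit_model("first_order", time, value)

#' @rdname fit_kinetics
#' @export
fit_sigmoid3 <- function(time, value) .fit_model("sigmoid3", time, value)

#' @rdname fit_kinetics
#' @export
fit_logistic4 <- function(time, value) .fit_model("logistic4", time, value)

#' @export
print.silk_fit <- function(x, ...) {
  cat(sprintf("<silk_fit: %s>", x$model))
  if (!x$converged) {
    cat(" NOT CONVERGED:", x$reason, "\n")
    return(invisible(x))
  }
  cat("\n  ", paste(sprintf("%s = %.6g", names(x$coefficients),
                            x$coefficients), collapse = ", "), "\n", sep = "")
  if (!is.na(x$half_time))
    cat(sprintf("  half-time t1/2 = %.4g min\n", x$half_time))
  cat(sprintf("  RSS %.4g on %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
coef.silk_fit <- function(object, ...) object$coefficients

#' @export
summary.silk_fit <- function(object, ...) {
  if (!object$converged) return(print(object))
  tab <- data.frame(estimate = object$coefficients, se = object$se)
  cat(sprintf("Model: %s (AICc %.2f)\n", object$model, object$aicc))
  print(tab)
  if (!is.na(object$half_time))
    cat(sprintf("Turnover half-time: %.4g min\n", object$half_time))
  invisible(list(model = object$model, coefficients = tab,
                 half_time = object$half_time, rss = object$rss))
}

#' @export
predict.silk_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged)
    stop("cannot predict from a non-converged fit", call. = FALSE)
  t <- if (is.null(newdata)) object$data$t
       else if (is.data.frame(newdata)) newdata$t else as.numeric(newdata)
  .silk_models[[object$model]]$predict(as.list(object$coefficients), t)
}

#' @export
fitted.silk_fit <- function(object, ...) predict(object)

#' @export
residuals.silk_fit <- function(object, ...)
  object$data$y - predict(object)

#' @export
plot.silk_fit <- function(x, ...) {
  plot(x$data$t, x$data$y, xlab = "time (min)", ylab = "response",
       main = paste("silk_fit:", x$model), ...)
  if (x$converged) {
    tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
    graphics::lines(tt, predict(x, tt))
  }
  invisible(x)
}

#' Per-timepoint two-group comparison
#'
#' Two-sided two-sample Student's t test (equal variances by default,
#' matching the convention of per-timepoint significance calls on small
#' biological replicate sets) at every timepoint shared by the two groups.
#' No multiplicity correction is applied by default; Holm adjustment is
#' available. Timepoints with fewer than 2 replicates in either group are
#' skipped with a note.
#'
#' @param time_a,value_a Times and values of group A (replicates as repeated
#'   times).
#' @param time_b,value_b Group B.
#' @param var_equal Equal-variance Student's t (default) or Welch.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame: `time`, `n_a`, `n_b`, `mean_a`, `mean_b`, `t`, `p`,
#'   `note`.
#' @export
compare_timepoints <- function(time_a, value_a, time_b, value_b,
                               var_equal = TRUE,
                               adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(length(time_a) == length(value_a),
            length(time_b) == length(value_b))
  shared <- sort(intersect(unique(time_a), unique(time_b)))
  rows <- lapply(shared, function(tp) {
    a <- value_a[time_a == tp]
    b <- value_b[time_b == tp]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(time = tp, n_a = length(a), n_b = length(b),
                        mean_a = mean(a), mean_b = mean(b),
                        t = NA_real_, p = NA_real_,
                        note = "skipped: < 2 replicates"))
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
      return(data.frame(time = tp, n_a = length(a), n_b = length(b),
                        mean_a = mean(a), mean_b = mean(b), t = 0, p = 1,
                        note = ""))
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(time = tp, n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b),
               t = unname(tt$statistic), p = tt$p.value, note = "")
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  out
}
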