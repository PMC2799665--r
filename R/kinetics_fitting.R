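#' Convert a two-state equilibrium constant and relaxation time to
#' closing/opening times
#'
#' For an all-or-none open/closed equilibrium with `K = [open]/[closed]`
#' and mean relaxation time `tau_r` (so `1/tau_r = 1/tau_c + 1/tau_o`):
#' `tau_c = tau_r * (1 + K)`, `tau_o = tau_r * (1 + K) / K`, and the open
#' fraction is `K / (1 + K) = tau_c / (tau_c + tau_o)`. `tau_c` is the
#' mean dwell in the open state (time to close), `tau_o` the mean dwell in
#' the closed state (time to open).
#'
#' @param K equilibrium constant, open over closed (> 0).
#' @param tau_r relaxation time (ns, > 0).
#' @return list with `tau_c`, `tau_o`, `fraction_open`.
#' @examples
#' derive_times(K = 1, tau_r = 10)   # tau_c = tau_o = 20
#' @export
derive_times <- function(K, tau_r) {
  check_number(K, "K", positive = TRUE)
  check_number(tau_r, "tau_r", positive = TRUE)
  list(tau_c = tau_r * (1 + K),
       tau_o = tau_r * (1 + K) / K,
       fraction_open = K / (1 + K))
}

#' @rdname derive_times
#' @param tau_c,tau_o closing and opening times (ns, > 0).
#' @return `equilibrium_from_times()`: list with `K`, `tau_r`,
#'   `fraction_open` (the algebraic inverse of [derive_times()]).
#' @export
equilibrium_from_times <- function(tau_c, tau_o) {
  check_number(tau_c, "tau_c", positive = TRUE)
  check_number(tau_o, "tau_o", positive = TRUE)
  list(K = tau_c / tau_o,
       tau_r = tau_c * tau_o / (tau_c + tau_o),
       fraction_open = tau_c / (tau_c + tau_o))
}

#' Two-state (single-exponential) fit of a fluorescence autocorrelation
#'
#' Least-squares fit of `G(tau) = 1 + (1/K) exp(-tau/tau_r)` over a lag
#' window, followed by conversion to closing/opening times with
#' [derive_times()]. The amplitude convention `1/K` with
#' `K = [open]/[closed]` makes open fractions of flexible peptides land in
#' the expected 30-40% band; the reciprocal convention is available via
#' `k_convention = "closed_over_open"`.
#'
#' The default 6-300 ns window mirrors the time resolution of
#' nanosecond-FCS experiments; override it freely for synthetic data.
#'
#' @param curve a `corr_curve` of kind `"fluorescence_G"`.
#' @param window lag window (ns), default `c(6, 300)`.
#' @param series optional [state_series()]; when supplied, one-sigma errors
#'   are also estimated by splitting it into two halves and refitting
#'   ([split_half_errors()]).
#' @param k_convention `"open_over_closed"` (default) or
#'   `"closed_over_open"`.
#' @param min_points minimum number of lags inside the window (default 6).
#' @return object of class `two_state_fit`: `K`, `tau_r`, `tau_c`, `tau_o`,
#'   `fraction_open`, `window`, `r_correlation`, `errors` (one-sigma, from
#'   the fit covariance; plus `split_half` when `series` is given),
#'   `method`.
#' @export
fit_two_state <- function(curve, window = c(6, 300), series = NULL,
                          k_convention = c("open_over_closed",
                                           "closed_over_open"),
                          min_points = 6L) {
  k_convention <- match.arg(k_convention)
  stopifnot(inherits(curve, "corr_curve"))
  sel <- curve$lags >= window[1L] & curve$lags <= window[2L]
  if (sum(sel) < min_points)
    stop_looplab("looplab_fit_error",
                 "only %d lag points inside the window [%g, %g] ns (need %d)",
                 sum(sel), window[1L], window[2L], min_points)
  tau <- curve$lags[sel]
  g <- curve$values[sel]
  amp0 <- max(g) - 1
  if (!is.finite(amp0) || amp0 <= 1e-12 || diff(range(g)) <= 1e-12)
    stop_looplab("looplab_no_relaxation_error",
                 "no resolvable relaxation in the window (flat curve)")
  # log-linear start from the decaying part
  pos <- g - 1 > amp0 * 1e-3
  start <- if (sum(pos) >= 2L) {
    cf <- coef(lm(log(g[pos] - 1) ~ tau[pos]))
    list(A = exp(cf[[1L]]), tr = max(-1 / cf[[2L]], tau[2L] - tau[1L]))
  } else list(A = amp0, tr = mean(tau))
  if (!is.finite(start$tr) || start$tr <= 0) start$tr <- mean(tau)
  df <- data.frame(tau = tau, g = g)
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ 1 + A * exp(-tau / tr), data = df,
                      start = list(A = start$A, tr = start$tr),
                      lower = c(0, 0), control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop_looplab("looplab_fit_error", "two-state fit failed: %s",
                   conditionMessage(e)))
  cf <- coef(fit)
  A <- cf[["A"]]; tr <- cf[["tr"]]
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(A = NA, tr = NA))
  if (!is.finite(A) || A <= 0 || (is.finite(se[["A"]]) && A <= 2 * se[["A"]]))
    stop_looplab("looplab_no_relaxation_error",
                 "amplitude statistically indistinguishable from zero: no detectable process in the window")
  K <- if (k_convention == "open_over_closed") 1 / A else A
  dt_ <- derive_times(K, tr)
  # delta-method one-sigma errors
  sdK <- if (is.finite(se[["A"]])) se[["A"]] / A^2 else NA_real_
  sd_tc <- sqrt((ifelse(is.finite(se[["tr"]]), se[["tr"]], 0) * (1 + K))^2 +
                  (ifelse(is.finite(sdK), sdK, 0) * tr)^2)
  sd_to <- sqrt((ifelse(is.finite(se[["tr"]]), se[["tr"]], 0) * (1 + K) / K)^2 +
                  (ifelse(is.finite(sdK), sdK, 0) * tr / K^2)^2)
  errors <- list(K = sdK, tau_r = se[["tr"]], tau_c = sd_tc, tau_o = sd_to)
  if (!is.null(series)) {
    # supplementary error estimate; a half-record that loses the relaxation
    # must not invalidate the full-record fit
    errors$split_half <- tryCatch(
      split_half_errors(series, function(s) {
        cv <- fluorescence_autocorrelation(s, max_lag = max(curve$lags))
        f <- fit_two_state(cv, window = window, k_convention = k_convention,
                           min_points = min_points)
        c(K = f$K, tau_r = f$tau_r, tau_c = f$tau_c, tau_o = f$tau_o)
      }),
      looplab_error = function(e) {
        warning("split-half error estimate unavailable: ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
  }
  out <- list(K = K, tau_r = tr, tau_c = dt_$tau_c, tau_o = dt_$tau_o,
              fraction_open = dt_$fraction_open,
              window = window,
              r_correlation = cor(g, predict(fit)),
              errors = errors,
              method = sprintf("nls G=1+(1/K)exp(-tau/tau_r), K convention %s",
                               k_convention))
  class(out) <- "two_state_fit"
  out
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(paste0("<two-state fit> K = %.4g, tau_r = %.4g ns, ",
                     "tau_c = %.4g ns, tau_o = %.4g ns, open %.1f%% (r = %.4f)\n"),
              x$K, x$tau_r, x$tau_c, x$tau_o, 100 * x$fraction_open,
              x$r_correlation))
  invisible(x)
}

fit_multiexp_one <- function(t, y, n_exp, stretched, tau_starts,
                             tau1_max = NULL, T_min = NULL) {
  # deterministic multistart over log-spaced relaxation-time guesses
  amp <- max(y) - min(y)
  c00 <- min(y)
  best <- NULL
  for (ts in tau_starts) {
    start <- list(c0 = c00)
    lower <- c(c0 = 0)
    upper <- c(c0 = Inf)
    t1max <- tau1_max %||% max(t)
    tmin <- T_min %||% (t[1L] / 10)
    if (stretched) {
      start <- c(start, list(A1 = amp / 2, tau1 = min(ts[1L], t1max / 2),
                             beta = 0.7))
      lower <- c(lower, A1 = 0, tau1 = t[1L] / 10, beta = 0.05)
      upper <- c(upper, A1 = Inf, tau1 = t1max, beta = 1)
    }
    if (n_exp >= 1L) {
      start <- c(start, list(B1 = amp / 2, T1 = max(ts[2L], tmin * 2)))
      lower <- c(lower, B1 = 0, T1 = tmin)
      upper <- c(upper, B1 = Inf, T1 = max(t) * 100)
    }
    if (n_exp >= 2L) {
      start <- c(start, list(B2 = amp / 4, T2 = max(ts[3L], tmin * 4)))
      lower <- c(lower, B2 = 0, T2 = tmin)
      upper <- c(upper, B2 = Inf, T2 = max(t) * 100)
    }
    rhs <- "c0"
    if (stretched) rhs <- paste(rhs, "+ A1 * exp(-(t / tau1)^beta)")
    if (n_exp >= 1L) rhs <- paste(rhs, "+ B1 * exp(-t / T1)")
    if (n_exp >= 2L) rhs <- paste(rhs, "+ B2 * exp(-t / T2)")
    form <- stats::as.formula(paste("y ~", rhs))
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(t = t, y = y),
                        start = start, lower = unname(lower),
                        upper = unname(upper),
                        control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  best
}

aicc <- function(rss, n, k) {
  n * log(rss / n + 1e-300) + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
}

#' Multi-exponential fit with a stretched picosecond component
#'
#' Fits `baseline + A1 exp(-(t/tau1)^beta) + sum_i B_i exp(-t/T_i)` to a
#' correlation curve beyond a starting lag (3 ps by default), with one or
#' two nanosecond exponentials. `n_exp = "auto"` selects 1 vs 2 by the
#' small-sample corrected information criterion. Components whose
#' amplitude is statistically indistinguishable from zero are dropped with
#' a message and the reduced model refitted. Fits whose correlation
#' coefficient is 0.95 or less are flagged (`quality_flag`), not rejected.
#'
#' @param curve a `corr_curve`.
#' @param n_exp `"auto"`, 1 or 2 nanosecond exponentials.
#' @param window_start smallest lag used (ns); default 0.003 (3 ps).
#' @param stretched include the stretched component (default TRUE).
#' @return object of class `multiexp_fit`: `baseline`, `stretched`
#'   (amplitude, tau_ps, beta or NULL), `exponentials` (data.frame
#'   amplitude, tau_ns), `amplitudes_relative` (percent of `G(0) - 1`),
#'   `r_correlation`, `chi2`, `quality_flag`, `window_start`.
#' @export
fit_multiexp <- function(curve, n_exp = c("auto", "1", "2"),
                         window_start = 0.003, stretched = TRUE) {
  stopifnot(inherits(curve, "corr_curve"))
  n_exp <- as.character(n_exp[1L])
  n_exp <- match.arg(n_exp, c("auto", "1", "2"))
  sel <- curve$lags > window_start
  t <- curve$lags[sel]; y <- curve$values[sel]
  if (length(t) < 8L)
    stop_looplab("looplab_fit_error", "too few lags beyond %g ns", window_start)
  if (diff(range(y)) <= 1e-12)
    stop_looplab("looplab_no_relaxation_error", "flat curve")
  qs <- exp(seq(log(max(t[1L], 1e-6)), log(max(t)), length.out = 7L))
  grids <- list(c(qs[2L], qs[4L], qs[6L]), c(qs[1L], qs[3L], qs[6L]),
                c(qs[2L], qs[5L], qs[7L]), c(qs[3L], qs[5L], qs[7L]))
  fit_for <- function(ne) fit_multiexp_one(t, y, ne, stretched, grids)
  cand <- if (n_exp == "auto") {
    f1 <- fit_for(1L); f2 <- fit_for(2L)
    if (is.null(f1) && is.null(f2))
      stop_looplab("looplab_fit_error", "multi-exponential fit did not converge")
    k1 <- 2L + if (stretched) 3L else 0L + 2L
    n1 <- length(t)
    a1 <- if (is.null(f1)) Inf else aicc(f1$rss, n1, length(coef(f1$fit)))
    a2 <- if (is.null(f2)) Inf else aicc(f2$rss, n1, length(coef(f2$fit)))
    if (a2 < a1) list(fit = f2, ne = 2L) else list(fit = f1, ne = 1L)
  } else {
    ne <- as.integer(n_exp)
    f <- fit_for(ne)
    if (is.null(f))
      stop_looplab("looplab_fit_error", "multi-exponential fit did not converge")
    list(fit = f, ne = ne)
  }
  fit <- cand$fit$fit; ne <- cand$ne
  p <- as.list(coef(fit))
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, length(p)), names(p)))
  # drop components indistinguishable from zero
  drop_stretched <- stretched && is.finite(se["A1"]) &&
    p$A1 <= 2 * se[["A1"]] && p$A1 < 0.01 * (max(y) - min(y))
  if (drop_stretched) {
    message("stretched component amplitude indistinguishable from 0; dropped")
    f <- fit_multiexp_one(t, y, ne, FALSE, grids)
    if (!is.null(f)) { fit <- f$fit; p <- as.list(coef(fit)); stretched <- FALSE
      se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
        setNames(rep(NA_real_, length(p)), names(p))) }
  }
  exps <- data.frame(amplitude = p$B1, tau_ns = p$T1)
  if (ne >= 2L) exps <- rbind(exps, data.frame(amplitude = p$B2, tau_ns = p$T2))
  exps <- exps[order(exps$tau_ns), , drop = FALSE]
  g0 <- if (curve$lags[1L] == 0) curve$values[1L] else
    p$c0 + sum(exps$amplitude) + if (stretched) p$A1 else 0
  denom <- g0 - 1
  if (!is.finite(denom) || denom <= 0) denom <- sum(exps$amplitude) +
    if (stretched) p$A1 else 0
  rel <- 100 * exps$amplitude / denom
  rel_st <- if (stretched) 100 * p$A1 / denom else NULL
  rcor <- cor(y, predict(fit))
  out <- list(
    baseline = p$c0,
    stretched = if (stretched) list(amplitude = p$A1,
                                    tau_ps = p$tau1 * 1e3, beta = p$beta) else NULL,
    exponentials = exps,
    amplitudes_relative = list(stretched = rel_st, exponentials = rel),
    window_start = window_start,
    r_correlation = rcor, chi2 = sum(residuals(fit)^2),
    quality_flag = rcor <= 0.95,
    errors = as.list(se),
    n_exp = ne)
  class(out) <- "multiexp_fit"
  if (out$quality_flag)
    warning(sprintf("fit correlation coefficient %.3f <= 0.95: flagged", rcor))
  out
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat("<multi-exponential fit>\n")
  cat(sprintf("  baseline %.4g, r = %.4f%s\n", x$baseline, x$r_correlation,
              if (x$quality_flag) " [FLAGGED]" else ""))
  if (!is.null(x$stretched))
    cat(sprintf("  stretched: A = %.4g, tau1 = %.4g ps, beta = %.3f\n",
                x$stretched$amplitude, x$stretched$tau_ps, x$stretched$beta))
  for (i in seq_len(nrow(x$exponentials)))
    cat(sprintf("  exp %d: A = %.4g, tau = %.4g ns\n", i,
                x$exponentials$amplitude[i], x$exponentials$tau_ns[i]))
  invisible(x)
}

#' Hydrogen-bond lifetime from an existence autocorrelation curve
#'
#' Fits the sum of a stretched exponential (picosecond flicker) and a
#' single exponential (nanosecond breaking) plus a plateau; the relaxation
#' time of the nanosecond exponential is reported as the average
#' hydrogen-bond lifetime. When the stretched component is not supported
#' by the data the reduced plateau-plus-exponential model is selected by
#' the corrected information criterion.
#'
#' @param curve a `corr_curve` of kind `"hbond_C"`.
#' @param window_start smallest lag used (ns); default 0 (all positive lags).
#' @param split_ns boundary between the stretched (faster) and exponential
#'   (slower) components (ns, default 1): the stretched relaxation time is
#'   bounded above and the exponential one below by it, which keeps the
#'   two time ranges identifiable.
#' @return object of class `hbond_lifetime_fit`: `lifetime_ns`,
#'   `exponential` (amplitude, tau_ns), `stretched` (or NULL), `baseline`,
#'   `r_correlation`, `errors`.
#' @export
fit_hbond_lifetime <- function(curve, window_start = 0, split_ns = 1) {
  stopifnot(inherits(curve, "corr_curve"))
  sel <- curve$lags > window_start
  t <- curve$lags[sel]; y <- curve$values[sel]
  if (diff(range(y)) <= 1e-9)
    stop_looplab("looplab_no_relaxation_error",
                 "bond never relaxes (flat existence autocorrelation)")
  qs <- exp(seq(log(max(t[1L], 1e-6)), log(max(t)), length.out = 7L))
  grids <- list(c(qs[2L], qs[4L], qs[6L]), c(qs[1L], qs[3L], qs[6L]),
                c(qs[2L], qs[5L], qs[7L]))
  f_full <- fit_multiexp_one(t, y, 1L, TRUE, grids,
                             tau1_max = split_ns, T_min = split_ns)
  f_red  <- fit_multiexp_one(t, y, 1L, FALSE, grids, T_min = split_ns)
  if (is.null(f_full) && is.null(f_red))
    stop_looplab("looplab_fit_error", "lifetime fit did not converge")
  n <- length(t)
  a_full <- if (is.null(f_full)) Inf else aicc(f_full$rss, n, length(coef(f_full$fit)))
  a_red  <- if (is.null(f_red)) Inf else aicc(f_red$rss, n, length(coef(f_red$fit)))
  use_full <- a_full < a_red
  fit <- if (use_full) f_full$fit else f_red$fit
  p <- as.list(coef(fit))
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, length(p)), names(p)))
  out <- list(
    lifetime_ns = p$T1,
    exponential = list(amplitude = p$B1, tau_ns = p$T1),
    stretched = if (use_full) list(amplitude = p$A1, tau_ps = p$tau1 * 1e3,
                                   beta = p$beta) else NULL,
    baseline = p$c0,
    r_correlation = cor(y, predict(fit)),
    errors = as.list(se))
  class(out) <- "hbond_lifetime_fit"
  out
}

#' @export
print.hbond_lifetime_fit <- function(x, ...) {
  cat(sprintf("<H-bond lifetime fit> lifetime = %.4g ns (r = %.4f)\n",
              x$lifetime_ns, x$r_correlation))
  invisible(x)
}

#' Power-law scaling of closure rates with chain length
#'
#' Ordinary least squares of `ln k` on `ln n`; the slope is the scaling
#' exponent gamma of `k ~ n^gamma`. Optional inverse-variance weighting
#' uses supplied one-sigma rate errors. The exponent is invariant under
#' rescaling all rates by a constant.
#'
#' @param n chain lengths (number of peptide bonds), > 0.
#' @param rates closure rates (1/ns), > 0.
#' @param n_min inclusion threshold: only points with `n >= n_min` enter
#'   the fit (default 0 = all).
#' @param errors optional one-sigma errors of `rates` (same length).
#' @param weighted use `1/sigma_lnk^2` weights (requires `errors`).
#' @return object of class `scaling_fit`: `gamma`, `prefactor`,
#'   `stderr_gamma`, `n_values`, `n_min`, `weighted`.
#' @export
fit_powerlaw <- function(n, rates, n_min = 0, errors = NULL, weighted = FALSE) {
  if (length(n) != length(rates))
    stop_looplab("looplab_input_error", "n and rates length mismatch")
  keep <- is.finite(n) & is.finite(rates) & n >= n_min
  n <- n[keep]; rates <- rates[keep]
  if (!is.null(errors)) errors <- errors[keep]
  if (length(n) < 3L)
    stop_looplab("looplab_input_error",
                 "need >= 3 points with n >= %g (have %d)", n_min, length(n))
  if (any(n <= 0) || any(rates <= 0))
    stop_looplab("looplab_input_error", "n and rates must be > 0")
  w <- NULL
  if (weighted) {
    if (is.null(errors))
      stop_looplab("looplab_input_error", "weighted fit needs rate errors")
    w <- (rates / errors)^2  # var(ln k) = (sigma_k / k)^2
  }
  fit <- lm(log(rates) ~ log(n), weights = w)
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  out <- list(gamma = unname(cf[2L]), prefactor = exp(unname(cf[1L])),
              stderr_gamma = unname(se[2L]), n_values = n, n_min = n_min,
              weighted = weighted)
  class(out) <- "scaling_fit"
  out
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<power-law fit> k ~ n^gamma, gamma = %.3f +/- %.3f (%d points)\n",
              x$gamma, x$stderr_gamma, length(x$n_values)))
  invisible(x)
}

#' One-sigma errors by splitting a record into two halves
#'
#' Applies an analysis function to each half of the record and returns the
#' two-point sample standard deviation `|a - b| / sqrt(2)` (n-1 convention)
#' per component of the analysis result.
#'
#' @param series a [state_series()], [time_series()], `hbond_matrix`
#'   (split along frames), or plain numeric vector.
#' @param analysis function mapping a half-record of the same type to a
#'   numeric scalar or named vector.
#' @return named numeric vector of one-sigma estimates (with attribute
#'   `halves`, the two per-half results).
#' @export
split_half_errors <- function(series, analysis) {
  halves <- if (inherits(series, "state_series")) {
    n <- length(series$states); h <- n %/% 2L
    if (h < 2L) stop_looplab("looplab_input_error", "record too short to split")
    list(state_series(series$states[1:h], series$dt, series$cutoff_nm,
                      series$group_spec),
         state_series(series$states[(h + 1L):n], series$dt, series$cutoff_nm,
                      series$group_spec))
  } else if (inherits(series, "loop_ts")) {
    n <- length(series$values); h <- n %/% 2L
    if (h < 2L) stop_looplab("looplab_input_error", "record too short to split")
    list(time_series(series$values[1:h], series$dt, series$t0, series$label,
                     series$units),
         time_series(series$values[(h + 1L):n], series$dt,
                     series$t0 + h * series$dt, series$label, series$units))
  } else if (inherits(series, "hbond_matrix")) {
    n <- nrow(series); h <- n %/% 2L
    if (h < 2L) stop_looplab("looplab_input_error", "record too short to split")
    list(hbond_matrix(unclass(series)[1:h, , drop = FALSE], attr(series, "dt"),
                      attr(series, "labels")),
         hbond_matrix(unclass(series)[(h + 1L):n, , drop = FALSE],
                      attr(series, "dt"), attr(series, "labels")))
  } else if (is.numeric(series)) {
    n <- length(series); h <- n %/% 2L
    if (h < 2L) stop_looplab("looplab_input_error", "record too short to split")
    list(series[1:h], series[(h + 1L):n])
  } else stop_looplab("looplab_parameter_error", "cannot split this object")
  res <- lapply(seq_along(halves), function(i)
    tryCatch(analysis(halves[[i]]), error = function(e)
      stop_looplab("looplab_fit_error", "analysis failed on half %d: %s",
                   i, conditionMessage(e))))
  a <- res[[1L]]; b <- res[[2L]]
  if (length(a) != length(b))
    stop_looplab("looplab_fit_error", "halves returned different lengths")
  out <- abs(a - b) / sqrt(2)
  attr(out, "halves") <- res
  out
}
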