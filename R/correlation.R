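#' Logarithmic lag grid
#'
#' Lags spanning `dt` to `max_lag`, approximately `points_per_decade` per
#' decade, snapped down onto the `dt` grid and de-duplicated. Lag 0 is
#' always included. A log-spaced grid matches relaxations spanning the
#' picosecond-to-hundreds-of-nanoseconds range without wasting points.
#'
#' @param dt sampling interval (ns).
#' @param max_lag largest lag (ns).
#' @param points_per_decade grid density (default 30).
#' @param include_zero include lag 0 (default TRUE).
#' @return numeric vector of lags (ns) on the `dt` grid.
#' @export
lag_grid <- function(dt, max_lag, points_per_decade = 30, include_zero = TRUE) {
  check_number(dt, "dt", positive = TRUE)
  check_number(max_lag, "max_lag", positive = TRUE)
  if (max_lag < dt) return(if (include_zero) 0 else numeric(0))
  nd <- log10(max_lag / dt)
  raw <- 10^seq(log10(dt), log10(max_lag), length.out = max(2L, ceiling(nd * points_per_decade)))
  k <- unique(floor(raw / dt + 1e-9))
  k <- k[k >= 1]
  lags <- k * dt
  if (include_zero) lags <- c(0, lags)
  lags
}

snap_lags <- function(lags, dt, n) {
  k <- floor(lags / dt + 1e-9)
  if (any(abs(lags - k * dt) > 1e-9 * dt)) {
    warning("lags not on the dt grid were snapped down to multiples of dt")
  }
  k <- unique(k)
  if (any(k < 0)) stop_looplab("looplab_lag_error", "negative lag")
  if (any(k >= n))
    stop_looplab("looplab_lag_error",
                 "lag %g ns is not shorter than the series", max(k) * dt)
  sort(k)
}

#' Second-order fluorescence autocorrelation G(tau)
#'
#' For a binary fluorescence signal I(t), computes
#' `G(tau) = <I(t) I(t+tau)> / <I>^2`, the mean running over all starting
#' times t for which the pair (t, t+tau) lies inside the record. With this
#' normalization a mixing signal decays to 1 at long lag and the two-state
#' fit family `1 + (1/K) exp(-tau/tau_r)` applies directly; `G(0) = 1/<I>`
#' for a binary signal. A mean-subtracted convention
#' (`<dI(t) dI(t+tau)> / <I>^2`) is available via `mean_subtract = TRUE`.
#'
#' @param signal a [state_series()] (or [time_series()] of a non-negative
#'   signal).
#' @param lags lag grid (ns); default [lag_grid()] up to `max_lag`.
#' @param max_lag largest lag (ns); default one tenth of the record length.
#' @param mean_subtract use the mean-subtracted convention (default FALSE).
#' @return object of class `corr_curve` with fields `lags`, `values`,
#'   `n_pairs`, `kind`, `mean_signal`, `source_length`.
#' @export
fluorescence_autocorrelation <- function(signal, lags = NULL, max_lag = NULL,
                                         mean_subtract = FALSE) {
  if (inherits(signal, "state_series")) {
    x <- as.numeric(signal$states); dt <- signal$dt
  } else if (inherits(signal, "loop_ts")) {
    x <- signal$values; dt <- signal$dt
  } else stop_looplab("looplab_parameter_error",
                      "signal must be a state_series or time_series")
  n <- length(x)
  mu <- mean(x)
  if (mu == 0)
    stop_looplab("looplab_degenerate_signal_error",
                 "all-zero signal: G(tau) undefined")
  if (is.null(lags)) {
    if (is.null(max_lag)) max_lag <- (n - 1) * dt / 10
    lags <- lag_grid(dt, max_lag)
  }
  k <- snap_lags(lags, dt, n)
  res <- autocorr_lags_cpp(x, as.integer(k))
  vals <- if (mean_subtract) (res$mean_product - mu^2) / mu^2
          else res$mean_product / mu^2
  corr_curve(lags = k * dt, values = vals, n_pairs = res$n_pairs,
             kind = "fluorescence_G", mean_signal = mu,
             source_length = (n - 1) * dt)
}

#' Hydrogen-bond existence autocorrelation C(t)
#'
#' Probability that a bond intact at a starting time is intact a lag t
#' later, pooled over bonds and starting times:
#' `C(t) = sum_b sum_t0 h_b(t0) h_b(t0+t) / sum_b sum_t0 h_b(t0)`.
#' The default intermittent convention tolerates transient breaking; the
#' continuous mode additionally requires the bond to stay intact at every
#' intermediate frame, so it is non-increasing. `C(0) = 1` in both modes.
#'
#' @param matrix an `hbond_matrix` (frames x bonds) from
#'   [gen_hbond_series()] or [hbond_existence_matrix()].
#' @param lags lag grid (ns); default [lag_grid()].
#' @param mode `"intermittent"` (default) or `"continuous"`.
#' @param max_lag largest lag (ns); default one tenth of the record.
#' @param bonds optional column subset (indices or a logical mask), e.g.
#'   to average over a labelled group such as in-beta bonds only.
#' @return a `corr_curve` of kind `"hbond_C"`.
#' @export
hbond_existence_autocorrelation <- function(matrix, lags = NULL,
                                            mode = c("intermittent", "continuous"),
                                            max_lag = NULL, bonds = NULL) {
  mode <- match.arg(mode)
  if (!inherits(matrix, "hbond_matrix"))
    stop_looplab("looplab_parameter_error", "need an hbond_matrix")
  h <- unclass(matrix)
  dt <- attr(matrix, "dt")
  if (!is.null(bonds)) h <- h[, bonds, drop = FALSE]
  if (!ncol(h) || !nrow(h))
    stop_looplab("looplab_input_error", "empty existence matrix")
  if (!any(h == 1L))
    stop_looplab("looplab_input_error", "no intact frames in any bond")
  n <- nrow(h)
  if (is.null(lags)) {
    if (is.null(max_lag)) max_lag <- (n - 1) * dt / 10
    lags <- lag_grid(dt, max_lag)
  }
  k <- snap_lags(lags, dt, n)
  storage.mode(h) <- "integer"
  res <- hbond_corr_cpp(h, as.integer(k), mode == "continuous")
  corr_curve(lags = k * dt, values = res$value, n_pairs = res$n_pairs,
             kind = "hbond_C", mean_signal = mean(h),
             source_length = (n - 1) * dt)
}

#' Construct a correlation curve
#'
#' @param lags lag values (ns), strictly increasing, starting at 0 for
#'   curves that include the zero lag.
#' @param values correlation values.
#' @param n_pairs number of averaged pairs per lag.
#' @param kind `"fluorescence_G"` or `"hbond_C"`.
#' @param mean_signal mean of the underlying signal.
#' @param source_length record length (ns).
#' @return object of class `corr_curve`.
#' @export
corr_curve <- function(lags, values, n_pairs = NA_integer_,
                       kind = c("fluorescence_G", "hbond_C"),
                       mean_signal = NA_real_, source_length = NA_real_) {
  kind <- match.arg(kind)
  if (length(lags) != length(values))
    stop_looplab("looplab_parameter_error", "lags/values length mismatch")
  if (is.unsorted(lags, strictly = TRUE))
    stop_looplab("looplab_parameter_error", "lags must be strictly increasing")
  structure(list(lags = as.numeric(lags), values = as.numeric(values),
                 n_pairs = n_pairs, kind = kind, mean_signal = mean_signal,
                 source_length = source_length),
            class = "corr_curve")
}

#' @export
print.corr_curve <- function(x, ...) {
  cat(sprintf("<correlation curve> %s, %d lags in [%.4g, %.4g] ns\n",
              x$kind, length(x$lags), min(x$lags), max(x$lags)))
  invisible(x)
}

#' Write / read a correlation curve CSV (columns lag_ns, value, n_pairs)
#' @param curve a `corr_curve`.
#' @param path file path.
#' @return `path` (write) or a `corr_curve` (read).
#' @export
write_corr_curve <- function(curve, path) {
  df <- data.frame(lag_ns = format(curve$lags, digits = 15, trim = TRUE),
                   value = format(curve$values, digits = 15, trim = TRUE),
                   n_pairs = curve$n_pairs)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_corr_curve
#' @param kind curve kind used when reading.
#' @export
read_corr_curve <- function(path, kind = c("fluorescence_G", "hbond_C")) {
  df <- read.csv(path)
  corr_curve(df$lag_ns, df$value,
             n_pairs = if ("n_pairs" %in% names(df)) df$n_pairs else NA,
             kind = match.arg(kind))
}
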