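#' Probability-density-based free-energy profile along a distance
#'
#' Histograms the samples, converts the normalized density p(r) to
#' `F(r) = -kB*T*ln p(r)` and shifts the minimum to zero. Empty bins are
#' masked, never imputed. The Jacobian-corrected variant (`p(r)/r^2`) is
#' available behind a flag but is off by default: the plain
#' probability-density profile is the quantity whose barrier defines the
#' open/closed cutoff.
#'
#' @param distances a [time_series()] of distances (nm) or a numeric vector.
#' @param temperature K (default 293).
#' @param bin_width histogram bin width (nm, default 0.02).
#' @param jacobian divide p(r) by r^2 before taking the log (default FALSE).
#' @return object of class `fe_profile`: `bin_centers` (nm), `F` (kJ/mol,
#'   min-shifted, NA in empty bins), `counts`, `temperature`, `bin_width`.
#' @export
fe_profile <- function(distances, temperature = 293, bin_width = 0.02,
                       jacobian = FALSE) {
  x <- if (inherits(distances, "loop_ts")) distances$values else as.numeric(distances)
  check_number(temperature, "temperature", positive = TRUE)
  check_number(bin_width, "bin_width", positive = TRUE)
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0)
    stop_looplab("looplab_degenerate_profile_error",
                 "all samples identical: no profile")
  if (length(x) < 1000L)
    warning(sprintf("only %d samples; the profile will be noisy", length(x)))
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width + 1e-12) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  centers <- breaks[-length(breaks)] + bin_width / 2
  p <- counts / (length(x) * bin_width)
  if (jacobian) p <- ifelse(centers > 0, p / centers^2, NA_real_)
  F <- ifelse(counts > 0, -kB_kJ_mol_K * temperature * log(p), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  structure(list(bin_centers = centers, F = F, counts = counts,
                 temperature = temperature, bin_width = bin_width,
                 n_samples = length(x), jacobian = jacobian),
            class = "fe_profile")
}

#' @export
print.fe_profile <- function(x, ...) {
  cat(sprintf("<free-energy profile> %d bins of %.3g nm, T = %g K, %d samples\n",
              length(x$bin_centers), x$bin_width, x$temperature, x$n_samples))
  invisible(x)
}

# 3-bin moving average on the populated stretch; ties broken toward small r
smooth_profile <- function(F, k = 3L) {
  n <- length(F)
  out <- F
  half <- k %/% 2L
  for (i in seq_len(n)) {
    w <- max(1L, i - half):min(n, i + half)
    v <- F[w]
    out[i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

#' Location of a profile's global minimum
#'
#' Finds the global minimum of the smoothed profile and refines it with a
#' local parabolic fit over neighbouring populated bins, which suppresses
#' bin-level sampling noise where the profile is nearly flat.
#'
#' @param profile an [fe_profile()].
#' @param smooth_bins moving-average width used for the coarse search.
#' @param refine half-width (in bins) of the parabolic refinement window.
#' @return distance of the minimum (nm).
#' @export
profile_minimum <- function(profile, smooth_bins = 3L, refine = 5L) {
  stopifnot(inherits(profile, "fe_profile"))
  Fs <- smooth_profile(profile$F, smooth_bins)
  ok <- which(!is.na(Fs))
  if (!length(ok))
    stop_looplab("looplab_degenerate_profile_error", "empty profile")
  i0 <- ok[which.min(Fs[ok])]
  w <- max(1L, i0 - refine):min(length(Fs), i0 + refine)
  w <- w[!is.na(profile$F[w])]
  if (length(w) >= 5L) {
    r <- profile$bin_centers[w]; Fv <- profile$F[w]
    cf <- coef(lm(Fv ~ r + I(r^2)))
    if (is.finite(cf[[3L]]) && cf[[3L]] > 0) {
      v <- -cf[[2L]] / (2 * cf[[3L]])
      if (v >= min(r) && v <= max(r)) return(v)
    }
  }
  profile$bin_centers[i0]
}

#' Locate the closed/open minima and the closure barrier of a profile
#'
#' Smooths the profile with a 3-bin moving average, takes the global
#' minimum at short distance as the closed basin, walks toward larger
#' distances to the first local maximum (the barrier) and on to the next
#' local minimum (the open basin). Ties are broken toward smaller r.
#'
#' Bins with fewer than `min_count` samples are treated as unresolved and
#' masked, and a candidate barrier must rise at least `min_height` above
#' both flanking minima: sub-thermal wiggles in sparsely sampled tails are
#' sampling noise, not barriers.
#'
#' @param profile an [fe_profile()].
#' @param smooth_bins moving-average width (default 3).
#' @param min_count minimum per-bin sample count (default 10).
#' @param min_height minimum barrier height (kJ/mol, default 0.5, about
#'   0.2 kT at 293 K).
#' @return object of class `barrier_report`: `r_min_closed`, `r_barrier`,
#'   `r_min_open` (nm), `dF_closing` (barrier height from the open
#'   minimum), `dF_opening` (from the closed minimum), both kJ/mol.
#' @export
find_barrier <- function(profile, smooth_bins = 3L, min_count = 10L,
                         min_height = 0.5) {
  stopifnot(inherits(profile, "fe_profile"))
  ok <- !is.na(profile$F) & profile$counts >= min_count
  if (sum(ok) < 5L)
    stop_looplab("looplab_no_barrier_error", "too few populated bins")
  # restrict to the contiguous populated stretch containing the global minimum
  Fm <- ifelse(ok, profile$F, NA_real_)
  Fs <- smooth_profile(Fm, smooth_bins)
  r <- profile$bin_centers
  idx <- which(ok)
  # contiguous blocks of populated bins
  blocks <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  gmin_global <- idx[which.min(Fm[idx])]
  blk <- blocks[[which(vapply(blocks, function(b) gmin_global %in% b, TRUE))]]
  Fb <- Fs[blk]; rb <- r[blk]
  m <- length(blk)
  if (m < 5L)
    stop_looplab("looplab_no_barrier_error", "populated stretch too short")
  i_min <- which.min(Fb)  # which.min takes the first (smallest r) on ties
  # walk right: first strict local maximum
  i_bar <- NA_integer_
  i <- i_min
  while (i < m) {
    if (i + 1L <= m && Fb[i + 1L] < Fb[i] && i > i_min) { i_bar <- i; break }
    i <- i + 1L
  }
  if (is.na(i_bar) || i_bar >= m)
    stop_looplab("looplab_no_barrier_error",
                 "profile is monotone beyond the global minimum: no barrier")
  # walk right from the barrier: next local minimum
  j <- i_bar
  while (j < m && Fb[j + 1L] <= Fb[j]) j <- j + 1L
  if (j == i_bar)
    stop_looplab("looplab_no_barrier_error", "no open-state minimum found")
  i_open <- j
  if (Fb[i_bar] < Fb[i_min] + min_height || Fb[i_bar] < Fb[i_open] + min_height)
    stop_looplab("looplab_no_barrier_error",
                 "barrier rises less than %g kJ/mol above the minima",
                 min_height)
  out <- list(r_min_closed = rb[i_min], r_barrier = rb[i_bar],
              r_min_open = rb[i_open],
              dF_closing = Fb[i_bar] - Fb[i_open],
              dF_opening = Fb[i_bar] - Fb[i_min],
              smoothed = TRUE)
  class(out) <- "barrier_report"
  out
}

#' @export
print.barrier_report <- function(x, ...) {
  cat(sprintf(paste0("<barrier report> closed %.3g nm | barrier %.3g nm | ",
                     "open %.3g nm; dF closing %.3g, opening %.3g kJ/mol\n"),
              x$r_min_closed, x$r_barrier, x$r_min_open,
              x$dF_closing, x$dF_opening))
  invisible(x)
}

#' Select the open/closed cutoff from a free-energy profile
#'
#' Returns the distance of the free-energy barrier for escaping the
#' short-distance global minimum: the natural boundary between closed and
#' open states. Falls back with a `looplab_no_barrier_error` when the
#' profile has no interior barrier, in which case callers should use a
#' fixed cutoff (see [gs_cutoffs]).
#'
#' @param profile an [fe_profile()].
#' @param ... passed to [find_barrier()].
#' @return cutoff distance (nm).
#' @export
select_cutoff <- function(profile, ...) {
  find_barrier(profile, ...)$r_barrier
}
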