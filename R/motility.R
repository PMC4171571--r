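# --- internal helpers -------------------------------------------------

# Split one cell's frames into contiguous segments: a gap larger than
# 1.5 * dt breaks the chain. Returns an integer segment id per row.
segment_ids <- function(t, dt) {
  if (length(t) < 2L) return(rep(1L, length(t)))
  cumsum(c(TRUE, diff(t) > 1.5 * dt))
}

# Infer the frame interval when the track set does not carry one.
infer_dt <- function(tracks) {
  dt <- attr(tracks, "dt")
  if (!is.null(dt)) return(dt)
  d <- unlist(tapply(tracks$t_h, tracks$cell_id, function(t) diff(sort(t))),
              use.names = FALSE)
  d <- d[d > 0]
  if (length(d) == 0L) stop("cannot infer dt from tracks")
  stats::median(d)
}

split_cells <- function(tracks) split(tracks, tracks$cell_id)

# --- instant velocities ----------------------------------------------

#' Instant velocities (frame-to-frame speeds)
#'
#' The instant velocity of a cell is its frame-to-frame displacement
#' divided by the frame interval. Timestamps are the midpoints of each
#' frame pair; censored gaps (missing frames) break the track into
#' contiguous segments and produce no sample across the gap.
#'
#' @param tracks a `track_set` or a data frame with columns `cell_id`,
#'   `t_h`, `x_um`, `y_um`.
#' @param dt frame interval, h; inferred from the tracks when missing.
#' @return Data frame (class `velocity_series`) with columns `cell_id`,
#'   `t_h` (pair midpoint) and `v_umh`. Tracks with fewer than two frames
#'   contribute nothing; if all do, an empty series is returned with a
#'   warning.
#' @export
instant_velocities <- function(tracks, dt = NULL) {
  if (is.null(dt)) dt <- infer_dt(tracks)
  per_cell <- lapply(split_cells(tracks), function(tr) {
    tr <- tr[order(tr$t_h), , drop = FALSE]
    seg <- segment_ids(tr$t_h, dt)
    res <- lapply(split(seq_len(nrow(tr)), seg), function(ix) {
      if (length(ix) < 2L) return(NULL)
      t <- tr$t_h[ix]; x <- tr$x_um[ix]; y <- tr$y_um[ix]
      data.frame(cell_id = tr$cell_id[1],
                 t_h = (t[-1] + t[-length(t)]) / 2,
                 v_umh = sqrt(diff(x)^2 + diff(y)^2) / diff(t),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, per_cell)
  if (is.null(out) || nrow(out) == 0L) {
    warning("no track with >= 2 frames; empty velocity series")
    out <- data.frame(cell_id = character(), t_h = numeric(),
                      v_umh = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "dt") <- dt
  class(out) <- c("velocity_series", "data.frame")
  out
}

#' Bin velocity samples into time windows
#'
#' Assigns each velocity sample to the half-open bin `[lo, hi)` of
#' `bin_edges` containing its timestamp and summarizes each bin; samples
#' outside the edges are dropped.
#'
#' @param series a velocity series from [instant_velocities()].
#' @param bin_edges strictly increasing bin edges, h (default
#'   `c(0, 20, 40, 60)`, the three windows used for tracking-start
#'   binning).
#' @return List with `summary` (data frame: `bin_lo`, `bin_hi`, `n`,
#'   `mean_v`, `median_v`) and `samples` (list of per-bin velocity
#'   vectors).
#' @export
bin_velocities_by_start <- function(series, bin_edges = c(0, 20, 40, 60)) {
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing with >= 2 values")
  k <- length(bin_edges) - 1L
  bin <- findInterval(series$t_h, bin_edges, rightmost.closed = FALSE)
  inb <- bin >= 1L & bin <= k & series$t_h < bin_edges[k + 1L]
  samples <- lapply(seq_len(k), function(b) series$v_umh[inb & bin == b])
  summary <- data.frame(
    bin_lo = bin_edges[-(k + 1L)], bin_hi = bin_edges[-1L],
    n = vapply(samples, length, integer(1)),
    mean_v = vapply(samples, function(v) if (length(v)) mean(v) else NA_real_,
                    numeric(1)),
    median_v = vapply(samples,
                      function(v) if (length(v)) stats::median(v) else NA_real_,
                      numeric(1))
  )
  list(summary = summary, samples = samples)
}

#' Cumulative distance travelled along a track
#'
#' @param track a single cell's rows (columns `t_h`, `x_um`, `y_um`).
#' @return Numeric vector of running path length, um (first element 0).
#'   The final value is always at least the net displacement.
#' @export
cumulative_distance <- function(track) {
  if (nrow(track) < 2L) stop("track needs >= 2 frames")
  track <- track[order(track$t_h), , drop = FALSE]
  cumsum(c(0, sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)))
}

# --- MSD --------------------------------------------------------------

# Time-averaged MSD over overlapping pairs for one contiguous segment
# given as position matrices; returns msd sums and pair counts per lag.
msd_pairs <- function(x, y, max_k) {
  n <- length(x)
  ssum <- numeric(max_k)
  npair <- integer(max_k)
  for (k in seq_len(min(max_k, n - 1L))) {
    dx <- x[-seq_len(k)] - x[seq_len(n - k)]
    dy <- y[-seq_len(k)] - y[seq_len(n - k)]
    ssum[k] <- sum(dx^2 + dy^2)
    npair[k] <- n - k
  }
  list(ssum = ssum, npair = npair)
}

#' Time-averaged mean-squared displacement of one track
#'
#' Computes the time-averaged MSD with overlapping pairs,
#' `msd(k dt) = mean_i |r(t_i + k dt) - r(t_i)|^2`, pooling pairs across
#' contiguous segments when the track has gaps. Lag 0 is included with
#' MSD 0.
#'
#' @param track one cell's rows (columns `t_h`, `x_um`, `y_um`).
#' @param max_lag largest lag, h; must be at least `dt` and at most the
#'   track's time span.
#' @param dt frame interval, h (inferred when missing).
#' @return An `msd_curve`: data frame with `lag_h`, `msd_um2`, `n_pairs`,
#'   with attributes `scope = "cell"` and `interval_label`.
#' @export
msd_curve <- function(track, max_lag, dt = NULL) {
  if (is.null(dt)) dt <- infer_dt(track)
  if (max_lag < dt) stop("max_lag must be >= dt")
  track <- track[order(track$t_h), , drop = FALSE]
  span <- max(track$t_h) - min(track$t_h)
  if (max_lag > span + 1e-9) stop("max_lag exceeds track span")
  max_k <- floor(max_lag / dt + 1e-9)
  seg <- segment_ids(track$t_h, dt)
  ssum <- numeric(max_k); npair <- integer(max_k)
  for (ix in split(seq_len(nrow(track)), seg)) {
    p <- msd_pairs(track$x_um[ix], track$y_um[ix], max_k)
    ssum <- ssum + p$ssum
    npair <- npair + p$npair
  }
  out <- data.frame(lag_h = c(0, seq_len(max_k) * dt),
                    msd_um2 = c(0, ifelse(npair > 0, ssum / npair, NA_real_)),
                    n_pairs = c(nrow(track), npair))
  attr(out, "scope") <- "cell"
  attr(out, "interval_label") <- "all"
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Ensemble mean-squared displacement over a time interval
#'
#' Each track is clipped to the half-open interval `[lo, hi)`, its
#' time-averaged MSD is computed, and curves are averaged across cells
#' with equal weight per cell. At each lag, cells contributing fewer than
#' `min_pairs` overlapping pairs are dropped at that lag.
#'
#' @param tracks a `track_set`.
#' @param max_lag largest lag, h.
#' @param interval optional `c(lo, hi)` interval, h; `NULL` uses whole
#'   tracks.
#' @param dt frame interval, h (inferred when missing).
#' @param min_pairs minimum overlapping pairs per cell per lag (default 6).
#' @return An `msd_curve` data frame (`lag_h`, `msd_um2`, `n_pairs` =
#'   number of contributing cells) with `scope = "ensemble"`.
#' @export
ensemble_msd <- function(tracks, max_lag, interval = NULL, dt = NULL,
                         min_pairs = 6) {
  if (is.null(dt)) dt <- infer_dt(tracks)
  label <- "all"
  if (!is.null(interval)) {
    tracks <- tracks[tracks$t_h >= interval[1] & tracks$t_h < interval[2], ,
                     drop = FALSE]
    label <- sprintf("%g-%g h", interval[1], interval[2])
  }
  cells <- split_cells(tracks)
  cells <- Filter(function(tr) nrow(tr) >= 2L, cells)
  if (length(cells) == 0L)
    stop("no tracks overlap the requested interval")
  max_k <- floor(max_lag / dt + 1e-9)
  msum <- numeric(max_k); ncell <- integer(max_k)
  for (tr in cells) {
    span <- max(tr$t_h) - min(tr$t_h)
    if (span < dt) next
    m <- msd_curve(tr, max_lag = min(max_lag, span), dt = dt)
    m <- m[m$lag_h > 0, , drop = FALSE]
    ok <- which(m$n_pairs >= min_pairs & !is.na(m$msd_um2))
    k <- round(m$lag_h[ok] / dt)
    msum[k] <- msum[k] + m$msd_um2[ok]
    ncell[k] <- ncell[k] + 1L
  }
  out <- data.frame(lag_h = c(0, seq_len(max_k) * dt),
                    msd_um2 = c(0, ifelse(ncell > 0, msum / ncell, NA_real_)),
                    n_pairs = c(length(cells), ncell))
  attr(out, "scope") <- "ensemble"
  attr(out, "interval_label") <- label
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve (%s, interval %s): %d lags up to %.2f h\n",
              attr(x, "scope") %||% "?", attr(x, "interval_label") %||% "?",
              nrow(x) - 1L, max(x$lag_h)))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lag_h, x$msd_um2, type = "b", pch = 16, cex = 0.6,
                 xlab = "lag (h)", ylab = expression(MSD ~ (mu * m^2)), ...)
  invisible(x)
}

# --- effective diffusivity -------------------------------------------

#' Fit an effective diffusivity to an MSD curve
#'
#' Ordinary least squares of MSD on lag over the half-open fit window
#' `(tau_min, tau_max]`, intercept free; the effective diffusivity for
#' two-dimensional motion is `slope / 4`.
#'
#' @param msd an `msd_curve`.
#' @param fit_window `c(tau_min, tau_max)`, h; default `c(0, 2)`, inside
#'   the initial near-linear regime of the MSD.
#' @return A `diffusivity_fit` (S3): list with `D_eff` (um^2/h), `slope`,
#'   `slope_se`, `intercept`, `fit_window`, `interval_label`, `n_points`.
#'   Methods: `print`, `coef`, `predict`.
#' @export
fit_effective_diffusivity <- function(msd, fit_window = c(0, 2)) {
  sel <- msd$lag_h > fit_window[1] & msd$lag_h <= fit_window[2] &
    !is.na(msd$msd_um2)
  if (sum(sel) < 3L)
    stop("insufficient data: < 3 lag points inside the fit window")
  d <- msd[sel, , drop = FALSE]
  fit <- stats::lm(msd_um2 ~ lag_h, data = d)
  sl <- stats::coef(fit)[["lag_h"]]
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["lag_h", "Std. Error"]),
    error = function(e) NA_real_)
  out <- list(D_eff = sl / 4, slope = sl, slope_se = se,
              intercept = stats::coef(fit)[["(Intercept)"]],
              fit_window = fit_window,
              interval_label = attr(msd, "interval_label") %||% "all",
              n_points = nrow(d))
  class(out) <- "diffusivity_fit"
  out
}

#' @export
print.diffusivity_fit <- function(x, ...) {
  cat(sprintf(
    "Effective diffusivity (interval %s): D_eff = %.4g um^2/h\n",
    x$interval_label, x$D_eff))
  cat(sprintf("  slope %.4g +/- %.3g um^2/h over (%g, %g] h (%d points)\n",
              x$slope, x$slope_se, x$fit_window[1], x$fit_window[2],
              x$n_points))
  invisible(x)
}

#' @export
coef.diffusivity_fit <- function(object, ...) {
  c(D_eff = object$D_eff, slope = object$slope,
    intercept = object$intercept)
}

#' @export
predict.diffusivity_fit <- function(object, lag_h, ...) {
  object$intercept + object$slope * lag_h
}

#' Effective diffusivity over consecutive time windows
#'
#' Partitions experiment time into consecutive windows (default 10 h),
#' computes the ensemble MSD of the clipped tracks in each window and
#' fits an effective diffusivity. Windows without usable tracks yield a
#' missing-value row rather than an error.
#'
#' @param tracks a `track_set`.
#' @param window_len window length, h (must exceed the fit-window upper
#'   bound).
#' @param fit_window diffusivity fit window, h.
#' @param dt frame interval, h (inferred when missing).
#' @return Data frame with `window_lo`, `window_hi`, `D_eff`, `slope_se`,
#'   `n_cells`.
#' @export
diffusivity_timecourse <- function(tracks, window_len = 10,
                                   fit_window = c(0, 2), dt = NULL) {
  if (window_len <= fit_window[2])
    stop("window_len must exceed the fit-window upper bound")
  if (is.null(dt)) dt <- infer_dt(tracks)
  t_max <- max(tracks$t_h)
  lo <- seq(0, t_max, by = window_len)
  out <- lapply(lo, function(l) {
    res <- tryCatch({
      m <- ensemble_msd(tracks, max_lag = fit_window[2],
                        interval = c(l, l + window_len), dt = dt)
      f <- fit_effective_diffusivity(m, fit_window)
      data.frame(window_lo = l, window_hi = l + window_len,
                 D_eff = f$D_eff, slope_se = f$slope_se,
                 n_cells = m$n_pairs[1])
    }, error = function(e)
      data.frame(window_lo = l, window_hi = l + window_len,
                 D_eff = NA_real_, slope_se = NA_real_, n_cells = 0L))
    res
  })
  do.call(rbind, out)
}

# --- turning angles ---------------------------------------------------

#' Signed turning angles along a track
#'
#' For consecutive displacement vectors `d_i`, `d_{i+1}` that both have
#' length at least `min_step`, returns the signed angle from `d_i` to
#' `d_{i+1}` in `(-pi, pi]` (counter-clockwise positive in an x-right /
#' y-up frame; exact reversals map to `+pi`). Steps shorter than
#' `min_step` are skipped and the angle chain restarts after a skip, so
#' near-stationary jitter does not contribute angles.
#'
#' @param track one cell's rows (columns `t_h`, `x_um`, `y_um`), or a
#'   whole `track_set` (angles are pooled across cells).
#' @param min_step minimum step length, um (default 1).
#' @param dt frame interval, h (inferred when missing).
#' @return Numeric vector of angles in `(-pi, pi]` (possibly empty).
#' @export
turning_angles <- function(track, min_step = 1, dt = NULL) {
  if (length(unique(track$cell_id)) > 1L) {
    return(unlist(lapply(split_cells(track), turning_angles,
                         min_step = min_step, dt = dt), use.names = FALSE))
  }
  if (nrow(track) < 3L) return(numeric(0))
  if (is.null(dt)) dt <- infer_dt(track)
  track <- track[order(track$t_h), , drop = FALSE]
  seg <- segment_ids(track$t_h, dt)
  out <- lapply(split(seq_len(nrow(track)), seg), function(ix) {
    if (length(ix) < 3L) return(numeric(0))
    dx <- diff(track$x_um[ix]); dy <- diff(track$y_um[ix])
    len <- sqrt(dx^2 + dy^2)
    ok <- len >= min_step
    pair <- which(ok[-length(ok)] & ok[-1])
    if (length(pair) == 0L) return(numeric(0))
    dot <- dx[pair] * dx[pair + 1L] + dy[pair] * dy[pair + 1L]
    crs <- dx[pair] * dy[pair + 1L] - dy[pair] * dx[pair + 1L]
    a <- atan2(crs, dot)
    # tie-break: exact reversals to +pi
    a[a <= -pi + 1e-12] <- pi
    a
  })
  unlist(out, use.names = FALSE)
}

#' Kolmogorov-Smirnov test of turning-angle isotropy
#'
#' One-sample KS test of the pooled signed turning angles against the
#' uniform distribution on `(-pi, pi]`; a small p-value indicates
#' persistent (non-isotropic) motion.
#'
#' @param angles numeric vector of angles in `(-pi, pi]` (n >= 8).
#' @return A `turning_angle_test`: list with `ks_stat`, `p_value`, `n`,
#'   `angles`.
#' @export
ks_uniformity_test <- function(angles) {
  if (length(angles) < 8L)
    stop("insufficient data: need >= 8 angles")
  if (any(angles <= -pi - 1e-9 | angles > pi + 1e-9))
    stop("angles must lie in (-pi, pi]")
  kt <- suppressWarnings(stats::ks.test(angles, stats::punif,
                                        min = -pi, max = pi))
  out <- list(ks_stat = unname(kt$statistic), p_value = kt$p.value,
              n = length(angles), angles = angles)
  class(out) <- "turning_angle_test"
  out
}

#' @export
print.turning_angle_test <- function(x, ...) {
  cat(sprintf(
    "KS test vs Uniform(-pi, pi]: D = %.4f, p = %.3g (n = %d angles)\n",
    x$ks_stat, x$p_value, x$n))
  invisible(x)
}

# --- expression/motility association ---------------------------------

#' Association between reporter level and motility
#'
#' Quantifies the coupling between reporter intensity and movement in a
#' track set: (i) the Pearson correlation between per-sample reporter
#' level (mean of the two frames bounding each step) and instant
#' velocity; (ii) cells are split at the population mean of their peak
#' reporter level and the ratio of mean final cumulative distance
#' (above-mean over below-mean) is reported with a bootstrap CI over
#' cells.
#'
#' @param tracks a `track_set` with reporter column `g_afu` on at least
#'   10 cells.
#' @param n_boot bootstrap resamples for the distance-ratio CI.
#' @param seed seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return A `motility_association`: list with `r` (Pearson), `ratio`,
#'   `ratio_ci`, `n_cells`, `n_samples`.
#' @export
expression_motility_association <- function(tracks, n_boot = 1000, seed = 1,
                                            conf = 0.95) {
  if (!"g_afu" %in% names(tracks) || all(is.na(tracks$g_afu)))
    stop("missing reporter channel: tracks carry no g_afu")
  cells <- split_cells(tracks)
  cells <- Filter(function(tr) nrow(tr) >= 2L && !all(is.na(tr$g_afu)), cells)
  if (length(cells) < 10L)
    stop("need reporter intensities on >= 10 tracks")
  dt <- infer_dt(tracks)
  g_mid <- numeric(0); v <- numeric(0)
  peak_g <- numeric(length(cells)); final_d <- numeric(length(cells))
  for (i in seq_along(cells)) {
    tr <- cells[[i]][order(cells[[i]]$t_h), , drop = FALSE]
    seg <- segment_ids(tr$t_h, dt)
    for (ix in split(seq_len(nrow(tr)), seg)) {
      if (length(ix) < 2L) next
      vv <- sqrt(diff(tr$x_um[ix])^2 + diff(tr$y_um[ix])^2) /
        diff(tr$t_h[ix])
      gg <- (tr$g_afu[ix][-1] + tr$g_afu[ix][-length(ix)]) / 2
      v <- c(v, vv); g_mid <- c(g_mid, gg)
    }
    peak_g[i] <- max(tr$g_afu, na.rm = TRUE)
    final_d[i] <- max(cumulative_distance(tr))
  }
  r <- stats::cor(g_mid, v)
  hi <- peak_g > mean(peak_g)
  ratio_of <- function(idx) {
    h <- idx[hi[idx]]; l <- idx[!hi[idx]]
    if (length(h) == 0L || length(l) == 0L) return(NA_real_)
    mean(final_d[h]) / mean(final_d[l])
  }
  ratio <- ratio_of(seq_along(cells))
  set.seed(subseed(seed, 300000L))
  boots <- replicate(n_boot, ratio_of(
    sample(seq_along(cells), length(cells), replace = TRUE)))
  a <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  out <- list(r = r, ratio = ratio, ratio_ci = ci,
              n_cells = length(cells), n_samples = length(v))
  class(out) <- "motility_association"
  out
}

#' @export
print.motility_association <- function(x, ...) {
  cat(sprintf("Reporter/motility association over %d cells (%d samples)\n",
              x$n_cells, x$n_samples))
  cat(sprintf("  Pearson r(g, v)          : %.3f\n", x$r))
  cat(sprintf("  distance ratio (hi/lo g) : %.2f [%.2f, %.2f]\n",
              x$ratio, x$ratio_ci[1], x$ratio_ci[2]))
  invisible(x)
}

# --- MSD plateau onset ------------------------------------------------

#' Plateau-onset time of a confined MSD curve
#'
#' Fits the saturating-exponential model
#' `MSD(tau) = L (1 - exp(-tau / tau_c))` to an MSD curve, fits the
#' initial-slope line by OLS over lags up to `slope_window`, and returns
#' the time at which the initial-slope line intersects the fitted
#' asymptote `L`. For data generated by the model itself with a
#' zero-intercept slope line this equals `tau_c`.
#'
#' @param msd an `msd_curve`.
#' @param slope_window upper lag bound for the initial-slope fit, h
#'   (default 0.5).
#' @return List with `t_plateau` (h), `L` (um^2), `tau_c` (h), `slope`,
#'   `intercept`.
#' @export
msd_plateau_onset <- function(msd, slope_window = 0.5) {
  d <- msd[!is.na(msd$msd_um2), , drop = FALSE]
  early <- d[d$lag_h > 0 & d$lag_h <= slope_window, , drop = FALSE]
  if (nrow(early) < 2L) stop("too few lags for the initial-slope fit")
  line <- stats::lm(msd_um2 ~ lag_h, data = early)
  L0 <- max(d$msd_um2)
  tau0 <- d$lag_h[which.min(abs(d$msd_um2 - 0.632 * L0))]
  fit <- minpack.lm::nlsLM(
    msd_um2 ~ L * (1 - exp(-lag_h / tau_c)),
    data = d[d$lag_h > 0, , drop = FALSE],
    start = list(L = L0, tau_c = max(tau0, 0.1)),
    lower = c(1e-9, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  L <- stats::coef(fit)[["L"]]
  tau_c <- stats::coef(fit)[["tau_c"]]
  b <- stats::coef(line)[["(Intercept)"]]
  m <- stats::coef(line)[["lag_h"]]
  list(t_plateau = (L - b) / m, L = L, tau_c = tau_c,
       slope = m, intercept = b)
}
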