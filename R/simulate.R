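# Draw the per-cell latent variables that drive both trajectory and
# event simulation: expression flag, pulse onset/duration/peak, EMT time
# and baseline speed. Onset is truncated at >= 12 h, durations and EMT
# times at > 0.
draw_cell_params <- function(preset, n) {
  list(
    expresses = stats::runif(n) < preset$p_express,
    onset = rnorm_trunc(n, preset$expr_onset_mean, preset$expr_onset_sd, 12),
    dur = rnorm_trunc(n, preset$expr_dur_mean, preset$expr_dur_sd, 1e-3),
    peak = rlnorm_med(n, preset$expr_peak_median, preset$expr_peak_gsd),
    emt_time = rnorm_trunc(n, preset$emt_onset_mean, preset$emt_onset_sd, 0),
    s_base = rlnorm_med(n, preset$base_speed_median, preset$base_speed_gsd)
  )
}

#' Simulate single-cell trajectories under a condition preset
#'
#' Cells perform a confined persistent random walk: the heading evolves by
#' wrapped-normal increments of sd `turn_sd` per frame, and the speed is
#' the product of a log-normal per-cell baseline, an EMT ramp factor
#' (linear from 1 to `emt_speed_mult` over `mult_ramp` hours after the
#' cell's EMT onset; stays 1 when `motility_blocked`) and a
#' reporter-coupling factor `1 + beta * g(t)/g_peak`. Positions reflect at
#' the active confinement disk (pre-EMT radius before EMT onset, post-EMT
#' radius after), and a track is right-censored at the first frame whose
#' position leaves the square field of view (the out-of-view position is
#' not retained). Expressing cells carry a single piecewise-linear
#' reporter pulse (linear rise, plateau, linear fall).
#'
#' Each cell is simulated from its own sub-seed derived from `seed` by a
#' fixed counter scheme, so the first `k` cells of a larger simulation
#' reproduce a simulation of `k` cells exactly.
#'
#' @param preset a [condition_preset()].
#' @param n_cells number of cells (>= 0).
#' @param duration track duration, h.
#' @param dt frame interval, h (default 1/6 h = 10 min).
#' @param seed integer master seed.
#' @return A `track_set`: a data frame with columns `cell_id`, `t_h`,
#'   `x_um`, `y_um`, `g_afu`, plus attributes `preset` (name), `dt` and
#'   `truth` (per-cell data frame with `expresses`, `onset_h`, `dur_h`,
#'   `peak_afu`, `emt_h`, `base_speed`, `censored_at_h`).
#' @export
simulate_trajectories <- function(preset, n_cells, duration = 96, dt = 1 / 6,
                                  seed = 1) {
  validate_preset(preset)
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (n_cells < 0) stop("n_cells must be >= 0")
  times <- seq(0, duration, by = dt)
  nt <- length(times)
  rows <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(subseed(seed, i))
    cp <- draw_cell_params(preset, 1L)
    id <- sprintf("c%04d", i)
    g <- if (cp$expresses)
      pulse_value(times, cp$onset, cp$dur, preset$expr_rise, cp$peak)
    else numeric(nt)
    # EMT ramp factor per frame
    m_emt <- if (preset$motility_blocked) rep(1, nt) else
      1 + (preset$emt_speed_mult - 1) *
        pmin(pmax((times - cp$emt_time) / preset$mult_ramp, 0), 1)
    beta <- preset$expr_speed_coupling
    s <- cp$s_base * m_emt * (1 + beta * g / cp$peak)
    r_active <- ifelse(!preset$motility_blocked & times >= cp$emt_time,
                       preset$confine_radius_post, preset$confine_radius_pre)
    # initial position uniform in the pre-EMT disk
    u <- stats::runif(2)
    r0 <- preset$confine_radius_pre * sqrt(u[1])
    phi0 <- 2 * pi * u[2]
    x <- numeric(nt); y <- numeric(nt)
    x[1] <- r0 * cos(phi0); y[1] <- r0 * sin(phi0)
    theta <- stats::runif(1, -pi, pi)
    dtheta <- stats::rnorm(nt - 1L, 0, preset$turn_sd)
    censored_at <- NA_real_
    last <- nt
    for (j in seq_len(nt - 1L)) {
      theta <- theta + dtheta[j]
      nx <- x[j] + s[j] * dt * cos(theta)
      ny <- y[j] + s[j] * dt * sin(theta)
      rr <- sqrt(nx^2 + ny^2)
      R <- r_active[j + 1L]
      if (rr > R) {
        # radial reflection at the disk boundary; heading follows the
        # realized displacement so the walk does not re-enter the wall
        fac <- max(2 * R - rr, 0) / rr
        nx <- nx * fac
        ny <- ny * fac
        theta <- atan2(ny - y[j], nx - x[j])
      }
      if (abs(nx) > preset$fov_halfwidth || abs(ny) > preset$fov_halfwidth) {
        censored_at <- times[j + 1L]
        last <- j
        break
      }
      x[j + 1L] <- nx
      y[j + 1L] <- ny
    }
    keep <- seq_len(last)
    rows[[i]] <- data.frame(
      cell_id = id, t_h = times[keep], x_um = x[keep], y_um = y[keep],
      g_afu = g[keep], stringsAsFactors = FALSE
    )
    truth[[i]] <- data.frame(
      cell_id = id, expresses = cp$expresses, onset_h = cp$onset,
      dur_h = cp$dur, peak_afu = cp$peak, emt_h = cp$emt_time,
      base_speed = cp$s_base, censored_at_h = censored_at,
      stringsAsFactors = FALSE
    )
  }
  out <- if (n_cells > 0) do.call(rbind, rows) else
    data.frame(cell_id = character(), t_h = numeric(), x_um = numeric(),
               y_um = numeric(), g_afu = numeric(), stringsAsFactors = FALSE)
  attr(out, "preset") <- preset$name
  attr(out, "dt") <- dt
  attr(out, "duration") <- duration
  attr(out, "truth") <- if (n_cells > 0) do.call(rbind, truth) else
    data.frame(cell_id = character(), expresses = logical(),
               onset_h = numeric(), dur_h = numeric(), peak_afu = numeric(),
               emt_h = numeric(), base_speed = numeric(),
               censored_at_h = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("track_set", "data.frame")
  out
}

#' Track-set ground truth
#'
#' @param tracks a `track_set` from [simulate_trajectories()].
#' @return The per-cell truth data frame recorded by the simulator.
#' @export
track_truth <- function(tracks) attr(tracks, "truth")

#' @export
print.track_set <- function(x, ...) {
  ids <- unique(x$cell_id)
  cat(sprintf("Track set: %d cells, %d samples, dt = %.4g h (preset '%s')\n",
              length(ids), nrow(x), attr(x, "dt") %||% NA,
              attr(x, "preset") %||% "?"))
  if (nrow(x) > 0)
    cat(sprintf("  time range %.2f-%.2f h\n", min(x$t_h), max(x$t_h)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cytometry-like event table
#'
#' Each event is an independent cell drawn from the preset's pulse model
#' and evaluated at the requested timepoint: expressing cells in their
#' pulse window contribute `background + g(t)`, all others only the
#' log-normal autofluorescence background. A fraction `nonviable_frac` of
#' events is flagged non-viable. Replicates use sub-seeds derived from the
#' master seed, so replicate `r` is reproducible in isolation.
#'
#' @param preset a [condition_preset()].
#' @param timepoints timepoints, h (non-empty).
#' @param n_events events per replicate per timepoint.
#' @param n_replicates number of replicates (>= 1, default 3).
#' @param seed integer master seed.
#' @return Data frame with columns `condition`, `timepoint_h`,
#'   `replicate`, `intensity_afu`, `viable` and the simulation-only truth
#'   column `truth_expressing` (TRUE when the event's pulse is active at
#'   the timepoint).
#' @export
simulate_event_population <- function(preset, timepoints, n_events,
                                      n_replicates = 3, seed = 1) {
  validate_preset(preset)
  if (length(timepoints) == 0L) stop("timepoints must be non-empty")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  out <- list()
  for (r in seq_len(n_replicates)) {
    set.seed(subseed(seed, 100000L + r))
    for (tp in timepoints) {
      cp <- draw_cell_params(preset, n_events)
      g <- numeric(n_events)
      ex <- which(cp$expresses)
      if (length(ex) > 0)
        g[ex] <- pulse_value(rep(tp, length(ex)), cp$onset[ex], cp$dur[ex],
                             preset$expr_rise, cp$peak[ex])
      bg <- rlnorm_med(n_events, preset$bg_median, preset$bg_gsd)
      viable <- stats::runif(n_events) >= preset$nonviable_frac
      out[[length(out) + 1L]] <- data.frame(
        condition = preset$name, timepoint_h = tp, replicate = r,
        intensity_afu = bg + g, viable = viable,
        truth_expressing = g > 0, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Simulate replicate qPCR amplification curves
#'
#' Each replicate is the deterministic MAK2 forward curve
#' ([mak2_forward()]) plus i.i.d. Gaussian fluorescence noise; the default
#' of three replicates mirrors reactions run in triplicate.
#'
#' @param params a [mak2_params()] object.
#' @param n_cycles number of cycles (>= 5).
#' @param noise_sd Gaussian noise sd, AFU (>= 0).
#' @param n_rep number of technical replicates (default 3).
#' @param seed integer master seed.
#' @param gene,sample metadata labels attached to the curves.
#' @return Data frame with columns `gene`, `sample`, `replicate`, `cycle`,
#'   `fluor_afu`.
#' @export
simulate_qpcr_replicates <- function(params, n_cycles, noise_sd = 0,
                                     n_rep = 3, seed = 1,
                                     gene = "target", sample = "s1") {
  validate_mak2_params(params)
  if (n_cycles < 5) stop("n_cycles must be >= 5")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  fwd <- mak2_forward(params, n_cycles)
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(subseed(seed, 200000L + r))
    out[[r]] <- data.frame(
      gene = gene, sample = sample, replicate = r,
      cycle = fwd$cycle,
      fluor_afu = fwd$fluor_afu + stats::rnorm(n_cycles, 0, noise_sd),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
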