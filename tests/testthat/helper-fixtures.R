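# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

make_track <- function(t, x, y, g = NULL, cell_id = "c0001") {
  d <- data.frame(cell_id = cell_id, t_h = t, x_um = x, y_um = y,
                  stringsAsFactors = FALSE)
  if (!is.null(g)) d$g_afu <- g
  d
}

# Pure 2-D Brownian tracks with per-axis step variance 2*D*dt, built
# directly from Gaussian increments (independent of the package's
# persistent-walk simulator).
brownian_tracks <- function(n_cells, D, n_frames, dt = 1 / 6, seed = 1) {
  set.seed(seed)
  out <- lapply(seq_len(n_cells), function(i) {
    sdev <- sqrt(2 * D * dt)
    make_track(seq(0, by = dt, length.out = n_frames),
               cumsum(c(0, rnorm(n_frames - 1, 0, sdev))),
               cumsum(c(0, rnorm(n_frames - 1, 0, sdev))),
               cell_id = sprintf("b%04d", i))
  })
  d <- do.call(rbind, out)
  attr(d, "dt") <- dt
  class(d) <- c("track_set", "data.frame")
  d
}

# Brute-force time-averaged MSD: double loop over all index pairs of a
# gapless track. The independent oracle for msd_curve().
msd_brute_force <- function(x, y, max_k) {
  n <- length(x)
  vapply(seq_len(max_k), function(k) {
    if (k >= n) return(NA_real_)
    acc <- 0
    for (i in seq_len(n - k))
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
    acc / (n - k)
  }, numeric(1))
}

# A preset with no reporter and simple motion, handy for motility tests.
plain_preset <- function(...) {
  args <- utils::modifyList(list(
    name = "plain", p_express = 0,
    expr_onset_mean = 40, expr_onset_sd = 5,
    expr_dur_mean = 40, expr_dur_sd = 5,
    emt_onset_mean = 40, emt_onset_sd = 5,
    emt_speed_mult = 1
  ), list(...))
  do.call(condition_preset, args)
}

# Bivariate normal sample with correlation rho (oracle for the
# correlation-recovery property).
bvn_pair <- function(n, rho) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  list(a = z1, b = rho * z1 + sqrt(1 - rho^2) * z2)
}
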