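test_that("instant velocities follow the frame-to-frame definition", {
  # constant position
  tr <- make_track(c(0, 1 / 6, 2 / 6), c(5, 5, 5), c(2, 2, 2))
  v <- instant_velocities(tr, dt = 1 / 6)
  expect_equal(v$v_umh, c(0, 0))
  # 6 um in one 10-min frame is 36 um/h; timestamps are midpoints
  tr <- make_track(c(0, 1 / 6), c(0, 6), c(0, 0))
  v <- instant_velocities(tr, dt = 1 / 6)
  expect_equal(v$v_umh, 36)
  expect_equal(v$t_h, 1 / 12)
  # a 10-h track at 6 frames/h (61 frames) yields exactly 60 samples
  t10 <- seq(0, 10, by = 1 / 6)
  expect_equal(length(t10), 61)
  v <- instant_velocities(make_track(t10, cumsum(c(0, runif(60))),
                                     rep(0, 61)), dt = 1 / 6)
  expect_equal(nrow(v), 60)
  # a censored gap produces no sample bridging it
  tg <- make_track(c(0, 1 / 6, 5, 5 + 1 / 6), c(0, 1, 100, 101),
                   c(0, 0, 0, 0))
  v <- instant_velocities(tg, dt = 1 / 6)
  expect_equal(nrow(v), 2)
  expect_warning(instant_velocities(make_track(0, 0, 0), dt = 1 / 6),
                 "2 frames")
})

test_that("velocity binning partitions samples into half-open windows", {
  t <- seq(0.05, 59.95, length.out = 600)
  series <- data.frame(cell_id = "c1", t_h = t, v_umh = seq_along(t))
  b <- bin_velocities_by_start(series, c(0, 20, 40, 60))
  expect_equal(sum(b$summary$n), 600)
  # no sample lands in two bins: bins are [lo, hi)
  expect_equal(unname(unlist(lapply(b$samples, length))), b$summary$n)
  edge <- data.frame(cell_id = "c1", t_h = c(19.999, 20, 40, 59.999, 60),
                     v_umh = 1:5)
  b2 <- bin_velocities_by_start(edge, c(0, 20, 40, 60))
  expect_equal(b2$summary$n, c(1L, 1L, 2L))   # t = 60 falls outside
  # all samples before the first edge leave all bins empty
  b3 <- bin_velocities_by_start(
    data.frame(cell_id = "c1", t_h = c(-3, -1), v_umh = c(1, 2)),
    c(0, 20, 40, 60))
  expect_equal(b3$summary$n, c(0L, 0L, 0L))
  expect_error(bin_velocities_by_start(series, c(0, 20, 20)), "increasing")
})

test_that("cumulative distance dominates net displacement", {
  tr <- make_track(c(0, 0.5, 1), c(0, 0, 0), c(0, 0, 0))
  expect_equal(cumulative_distance(tr), c(0, 0, 0))
  # straight line at 36 um/h for 1 h
  tr <- make_track(seq(0, 1, by = 1 / 6), seq(0, 6, by = 1), rep(0, 7))
  cd <- cumulative_distance(tr)
  expect_equal(max(cd), 6)
  expect_equal(max(cd), sqrt(diff(range(tr$x_um))^2))
  # triangle inequality on 100 random tracks
  set.seed(42)
  for (i in 1:100) {
    tr <- make_track(seq(0, 5, by = 1 / 6), cumsum(rnorm(31)),
                     cumsum(rnorm(31)))
    cd <- cumulative_distance(tr)
    net <- sqrt((tr$x_um[31] - tr$x_um[1])^2 + (tr$y_um[31] - tr$y_um[1])^2)
    expect_gte(max(cd), net - 1e-12)
  }
})

test_that("msd_curve matches the brute-force pair average exactly", {
  set.seed(7)
  for (n in c(5, 12, 20)) {
    t <- seq(0, by = 1 / 6, length.out = n)
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    m <- msd_curve(make_track(t, x, y), max_lag = (n - 1) / 6, dt = 1 / 6)
    bf <- msd_brute_force(x, y, n - 1)
    expect_equal(m$msd_um2, c(0, bf))
    expect_equal(m$n_pairs[-1], (n - 1):1)
  }
  # msd(0) = 0 and non-negativity; n_pairs non-increasing
  expect_equal(msd_curve(make_track(c(0, 1 / 6), c(0, 1), c(0, 0)),
                         max_lag = 1 / 6)$msd_um2[1], 0)
})

test_that("msd_curve handles closed forms and degenerate input", {
  t <- seq(0, 10, by = 1 / 6)
  # stationary
  m0 <- msd_curve(make_track(t, rep(1, 61), rep(2, 61)), max_lag = 5)
  expect_true(all(m0$msd_um2 == 0))
  # ballistic at speed v: msd(tau) = v^2 tau^2 exactly
  v <- 36
  mb <- msd_curve(make_track(t, v * t, rep(0, 61)), max_lag = 5)
  expect_equal(mb$msd_um2, v^2 * mb$lag_h^2)
  # uncorrelated random walk with fixed step length l: msd ~ l^2 tau/dt
  set.seed(3)
  l <- 2; nfr <- 500
  ang <- runif(nfr - 1, -pi, pi)
  tr <- make_track(seq(0, by = 1 / 6, length.out = nfr),
                   cumsum(c(0, l * cos(ang))), cumsum(c(0, l * sin(ang))))
  mr <- msd_curve(tr, max_lag = 2, dt = 1 / 6)
  sel <- mr$lag_h > 0
  expect_equal(mr$msd_um2[sel], l^2 * mr$lag_h[sel] / (1 / 6),
               tolerance = 0.15)
  expect_error(msd_curve(tr, max_lag = 0.01, dt = 1 / 6), "max_lag")
  expect_error(msd_curve(make_track(c(0, 1 / 6), 0:1, 0:1), max_lag = 10),
               "span")
})

test_that("ensemble MSD averages per-cell curves with equal weight", {
  t <- seq(0, 10, by = 1 / 6)
  one <- make_track(t, 36 * t, rep(0, 61), cell_id = "a")
  single <- ensemble_msd(one, max_lag = 2)
  expect_equal(single$msd_um2, msd_curve(one, max_lag = 2)$msd_um2)
  # two identical tracks give the same curve as one
  two <- rbind(one, make_track(t, 36 * t, rep(0, 61), cell_id = "b"))
  attr(two, "dt") <- 1 / 6
  both <- ensemble_msd(two, max_lag = 2)
  expect_equal(both$msd_um2, single$msd_um2)
  expect_equal(both$n_pairs[-1], rep(2L, 12))
  expect_error(ensemble_msd(one, max_lag = 2, interval = c(100, 110)),
               "overlap")
  # heterogeneous diffusivities: ensemble slope/4 matches the mean D
  set.seed(21)
  Ds <- exp(rnorm(200, log(300), 0.5))
  trs <- do.call(rbind, lapply(seq_along(Ds), function(i) {
    tr <- brownian_tracks(1, Ds[i], 80, seed = 1000 + i)
    tr$cell_id <- sprintf("h%04d", i)
    tr
  }))
  attr(trs, "dt") <- 1 / 6
  fit <- fit_effective_diffusivity(ensemble_msd(trs, max_lag = 1),
                                   fit_window = c(0, 1))
  expect_equal(fit$D_eff, mean(Ds), tolerance = 0.1)
})

test_that("effective-diffusivity fits recover exact and simulated slopes", {
  lag <- seq(0, 2, by = 1 / 6)
  exact <- structure(
    data.frame(lag_h = lag, msd_um2 = 4 * lag, n_pairs = 100L),
    class = c("msd_curve", "data.frame"))
  f <- fit_effective_diffusivity(exact, fit_window = c(0, 2))
  expect_equal(f$D_eff, 1)
  expect_lt(f$slope_se, 1e-10)
  zero <- exact; zero$msd_um2 <- 0
  expect_equal(fit_effective_diffusivity(zero)$D_eff, 0)
  few <- exact[1:3, ]  # lags 0, 1/6, 2/6 -> only 2 usable points
  expect_error(fit_effective_diffusivity(few, fit_window = c(0, 2 / 6)),
               "insufficient")
  for (D in c(50, 450, 2000)) {
    tr <- brownian_tracks(500, D, 100, seed = round(D))
    fit <- fit_effective_diffusivity(ensemble_msd(tr, max_lag = 1),
                                     fit_window = c(0, 1))
    expect_equal(fit$D_eff, D, tolerance = 0.1)
  }
})

test_that("diffusivity timecourse is flat for time-homogeneous motion", {
  tr <- brownian_tracks(150, 400, 121, seed = 9)  # 20 h of frames
  tc <- diffusivity_timecourse(tr, window_len = 10, fit_window = c(0, 1))
  got <- tc$D_eff[tc$n_cells > 0]
  expect_gte(length(got), 2)
  expect_true(all(abs(got - 400) / 400 < 0.15))
  # stationary tracks give zero everywhere
  t <- seq(0, 25, by = 1 / 6)
  still <- make_track(t, rep(0, length(t)), rep(0, length(t)))
  attr(still, "dt") <- 1 / 6
  tc0 <- diffusivity_timecourse(still, window_len = 10,
                                fit_window = c(0, 1))
  expect_true(all(tc0$D_eff[tc0$n_cells > 0] == 0))
  expect_error(diffusivity_timecourse(tr, window_len = 1,
                                      fit_window = c(0, 2)), "window_len")
})

test_that("turning angles follow the signed y-up convention", {
  dt <- 1 / 6
  t3 <- c(0, dt, 2 * dt)
  # collinear forward motion
  expect_equal(turning_angles(make_track(t3, c(0, 2, 4), c(0, 0, 0))),
               0)
  # exact reversal maps to +pi
  expect_equal(turning_angles(make_track(t3, c(0, 2, 0), c(0, 0, 0))),
               pi)
  # right turn in the y-up frame is -pi/2
  expect_equal(turning_angles(make_track(t3, c(0, 2, 2), c(0, 0, -2))),
               -pi / 2)
  # left turn is +pi/2
  expect_equal(turning_angles(make_track(t3, c(0, 2, 2), c(0, 0, 2))),
               pi / 2)
  # sub-threshold steps are skipped and the chain restarts
  t5 <- seq(0, by = dt, length.out = 5)
  jitter <- make_track(t5, c(0, 2, 2.1, 4.1, 6.1), c(0, 0, 0, 0, 0))
  expect_equal(length(turning_angles(jitter, min_step = 1)), 1)
  expect_equal(length(turning_angles(make_track(t3, c(0, 0.1, 0.2),
                                                c(0, 0, 0)),
                                     min_step = 1)), 0)
})

test_that("KS uniformity test is calibrated and detects persistence", {
  expect_error(ks_uniformity_test(runif(5, -1, 1)), "insufficient|>= 8")
  # type-I error at alpha = 0.05 stays in [3%, 7%] (400 replicates)
  set.seed(13)
  rej <- mean(replicate(400, {
    ks_uniformity_test(runif(10000, -pi, pi))$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  # wrapped-normal(0, 0.6) angles: decisively non-uniform
  set.seed(14)
  a <- rnorm(5000, 0, 0.6)
  a <- atan2(sin(a), cos(a))
  expect_lt(ks_uniformity_test(a)$p_value, 1e-5)
  # degenerate: identical angles give KS statistic >= 0.5
  expect_gte(ks_uniformity_test(rep(0, 100))$ks_stat, 0.5)
})

test_that("field-of-view censoring biases long-lag MSD downwards", {
  base <- list(base_speed_median = 30, base_speed_gsd = 1.2,
               turn_sd = 0.3, emt_onset_mean = 0.5, emt_onset_sd = 0.1,
               emt_speed_mult = 1.01,
               confine_radius_pre = 50, confine_radius_post = 1000)
  free <- do.call(plain_preset, c(base, fov_halfwidth = 1e9))
  boxed <- do.call(plain_preset, c(base, fov_halfwidth = 100))
  tr_free <- simulate_trajectories(free, 60, duration = 20, seed = 17)
  tr_box <- simulate_trajectories(boxed, 60, duration = 20, seed = 17)
  expect_gt(sum(!is.na(track_truth(tr_box)$censored_at_h)), 5)
  m_free <- ensemble_msd(tr_free, max_lag = 10)
  m_box <- ensemble_msd(tr_box, max_lag = 10)
  long <- which(m_free$lag_h > 5 & !is.na(m_box$msd_um2))
  expect_true(mean(m_box$msd_um2[long]) <=
                mean(m_free$msd_um2[long]) * 1.02)
})

test_that("reporter-motility association detects built-in coupling", {
  tr <- simulate_trajectories(get_preset("act_chi"), 120, duration = 60,
                              seed = 19)
  assoc <- expression_motility_association(tr, n_boot = 200, seed = 1)
  expect_gt(assoc$r, 0)
  expect_gt(assoc$ratio, 1)
  # null case: reporter independent of motion
  set.seed(20)
  null_tracks <- do.call(rbind, lapply(1:40, function(i) {
    t <- seq(0, 10, by = 1 / 6)
    make_track(t, cumsum(c(0, rnorm(60))), cumsum(c(0, rnorm(60))),
               g = abs(rnorm(61, 50, 10)), cell_id = sprintf("n%03d", i))
  }))
  attr(null_tracks, "dt") <- 1 / 6
  a0 <- expression_motility_association(null_tracks, n_boot = 200,
                                        seed = 1)
  expect_lt(abs(a0$r), 0.1)
  expect_lt(abs(a0$ratio - 1), 0.35)
  # g tracking v exactly gives r = 1
  t <- seq(0, 5, by = 1 / 6)
  ramp <- do.call(rbind, lapply(1:12, function(i) {
    amp <- 1 + (i %% 2)               # two amplitude groups
    v <- amp * 6 * seq(1, 3, length.out = 30)   # step speeds, um/h
    x <- cumsum(c(0, v / 6))
    g <- numeric(31)
    g[1] <- v[1]
    for (j in 1:30) g[j + 1] <- 2 * v[j] - g[j]  # midpoint of g == v
    make_track(t[1:31], x, rep(0, 31), g = g,
               cell_id = sprintf("r%03d", i))
  }))
  attr(ramp, "dt") <- 1 / 6
  a1 <- expression_motility_association(ramp, n_boot = 50, seed = 1)
  expect_gt(a1$r, 0.999)
  expect_error(expression_motility_association(ramp[1:62, ]), ">= 10")
  no_g <- make_track(t, t, t)
  expect_error(expression_motility_association(no_g), "g_afu|reporter")
})
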