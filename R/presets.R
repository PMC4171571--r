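#' Condition presets for the synthetic-data generator
#'
#' A condition preset bundles the generative parameters describing one
#' experimental condition: the probability and timing of a transient
#' reporter pulse, the timing of the epithelial-to-mesenchymal transition
#' (EMT), baseline and post-EMT speeds, heading persistence, confinement
#' and field-of-view geometry, and the autofluorescence background used
#' for cytometry-like event simulation.
#'
#' @param name condition label.
#' @param p_express probability that a cell ever expresses the reporter,
#'   in `[0, 1]`.
#' @param expr_onset_mean,expr_onset_sd mean and sd (h) of the normal
#'   reporter-onset time; onsets are truncated at >= 12 h when sampled.
#' @param expr_dur_mean,expr_dur_sd mean and sd (h) of the pulse duration.
#' @param expr_rise linear rise (and fall) time of the pulse, h.
#' @param expr_peak_median,expr_peak_gsd median and geometric sd of the
#'   log-normal per-cell peak amplitude (AFU).
#' @param emt_onset_mean,emt_onset_sd mean and sd (h) of the EMT onset time.
#' @param base_speed_median,base_speed_gsd median and geometric sd of the
#'   log-normal per-cell baseline speed (um/h).
#' @param emt_speed_mult multiplicative speed factor reached over
#'   `mult_ramp` hours after EMT onset (1 = no speed-up).
#' @param mult_ramp ramp duration of the EMT speed-up, h.
#' @param expr_speed_coupling coupling beta: extra speed factor
#'   `1 + beta * g(t) / g_peak` for expressing cells.
#' @param turn_sd per-frame wrapped-normal heading increment sd, rad.
#' @param confine_radius_pre,confine_radius_post radii (um) of the
#'   reflecting confinement disk before and after EMT;
#'   `confine_radius_pre <= confine_radius_post`.
#' @param fov_halfwidth half-width (um) of the square field of view;
#'   tracks are right-censored when `|x|` or `|y|` exceeds it.
#' @param motility_blocked if `TRUE` the EMT never completes: speeds stay
#'   at baseline and the pre-EMT confinement stays active.
#' @param bg_median,bg_gsd median and geometric sd of the log-normal
#'   autofluorescence background (AFU) of non-expressing events.
#' @param nonviable_frac fraction of simulated cytometry events flagged
#'   non-viable (DAPI-positive stand-in).
#'
#' @return An object of class `condition_preset` (a named list).
#' @seealso [default_presets()], [simulate_trajectories()],
#'   [simulate_event_population()]
#' @export
condition_preset <- function(name,
                             p_express,
                             expr_onset_mean, expr_onset_sd,
                             expr_dur_mean, expr_dur_sd,
                             expr_rise = 6,
                             expr_peak_median = 5000, expr_peak_gsd = 2.5,
                             emt_onset_mean, emt_onset_sd,
                             base_speed_median = 16, base_speed_gsd = 1.5,
                             emt_speed_mult = 1, mult_ramp = 10,
                             expr_speed_coupling = 0,
                             turn_sd = 0.6,
                             confine_radius_pre = 40,
                             confine_radius_post = 65,
                             fov_halfwidth = 250,
                             motility_blocked = FALSE,
                             bg_median = 50, bg_gsd = 1.8,
                             nonviable_frac = 0.05) {
  p <- list(
    name = as.character(name),
    p_express = p_express,
    expr_onset_mean = expr_onset_mean, expr_onset_sd = expr_onset_sd,
    expr_dur_mean = expr_dur_mean, expr_dur_sd = expr_dur_sd,
    expr_rise = expr_rise,
    expr_peak_median = expr_peak_median, expr_peak_gsd = expr_peak_gsd,
    emt_onset_mean = emt_onset_mean, emt_onset_sd = emt_onset_sd,
    base_speed_median = base_speed_median, base_speed_gsd = base_speed_gsd,
    emt_speed_mult = emt_speed_mult, mult_ramp = mult_ramp,
    expr_speed_coupling = expr_speed_coupling,
    turn_sd = turn_sd,
    confine_radius_pre = confine_radius_pre,
    confine_radius_post = confine_radius_post,
    fov_halfwidth = fov_halfwidth,
    motility_blocked = isTRUE(motility_blocked),
    bg_median = bg_median, bg_gsd = bg_gsd,
    nonviable_frac = nonviable_frac
  )
  class(p) <- "condition_preset"
  validate_preset(p)
  p
}

#' Validate a condition preset
#'
#' Checks the preset invariants (probabilities in `[0,1]`, strictly
#' positive scales/times/radii/speeds, pre-EMT confinement not larger than
#' post-EMT confinement) and raises an error naming the offending field.
#'
#' @param preset a [condition_preset()].
#' @return The preset, invisibly, if valid.
#' @export
validate_preset <- function(preset) {
  if (!inherits(preset, "condition_preset"))
    stop("not a condition_preset object")
  chk <- function(cond, field, what) {
    if (!isTRUE(cond))
      stop(sprintf("invalid preset '%s': field '%s' %s",
                   preset$name, field, what), call. = FALSE)
  }
  num1 <- function(f) {
    v <- preset[[f]]
    chk(is.numeric(v) && length(v) == 1L && is.finite(v), f,
        "must be a finite number")
    v
  }
  for (f in c("p_express", "nonviable_frac")) {
    v <- num1(f)
    chk(v >= 0 && v <= 1, f, "must lie in [0, 1]")
  }
  pos <- c("expr_onset_sd", "expr_dur_sd", "expr_rise",
           "expr_peak_median", "emt_onset_sd",
           "base_speed_median", "emt_speed_mult", "mult_ramp",
           "turn_sd", "confine_radius_pre", "confine_radius_post",
           "fov_halfwidth", "bg_median",
           "expr_onset_mean", "expr_dur_mean", "emt_onset_mean")
  for (f in pos) chk(num1(f) > 0, f, "must be strictly positive")
  for (f in c("expr_peak_gsd", "base_speed_gsd", "bg_gsd"))
    chk(num1(f) >= 1, f, "must be >= 1 (geometric sd; 1 = no spread)")
  chk(num1("expr_speed_coupling") >= 0, "expr_speed_coupling",
      "must be non-negative")
  chk(preset$confine_radius_pre <= preset$confine_radius_post,
      "confine_radius_pre", "must not exceed confine_radius_post")
  chk(is.logical(preset$motility_blocked), "motility_blocked",
      "must be a flag")
  invisible(preset)
}

#' Built-in condition presets
#'
#' Default generative presets for the experimental conditions analysed by
#' the package: `act_chi` (activin + CHIR99021, strong early reporter wave
#' and the fastest, earliest motility), `chi` (earlier but shorter reporter
#' pulse, intermediate motility), `act` (late, small reporter peak, late
#' EMT), `lb` (LIF/BMP pluripotency control: no reporter, no EMT),
#' `csa` (cyclosporine-A EMT block: motility blocked, rare late
#' expression), `bcat_null` (beta-catenin mutant: motility blocked, almost
#' no expression) and `bra_null` (brachyury-null: EMT proceeds but with a
#' modest speed-up and no reporter/speed coupling).
#'
#' @return Named list of [condition_preset()] objects.
#' @export
default_presets <- function() {
  list(
    act_chi = condition_preset(
      "act_chi", p_express = 0.36,
      expr_onset_mean = 38, expr_onset_sd = 8,
      expr_dur_mean = 50, expr_dur_sd = 10,
      emt_onset_mean = 30, emt_onset_sd = 8,
      emt_speed_mult = 3.0, mult_ramp = 10,
      expr_speed_coupling = 0.6
    ),
    chi = condition_preset(
      "chi", p_express = 0.30,
      expr_onset_mean = 38, expr_onset_sd = 8,
      expr_dur_mean = 28, expr_dur_sd = 8,
      emt_onset_mean = 40, emt_onset_sd = 10,
      emt_speed_mult = 2.6, mult_ramp = 10,
      expr_speed_coupling = 0.6
    ),
    act = condition_preset(
      "act", p_express = 0.12,
      expr_onset_mean = 60, expr_onset_sd = 10,
      expr_dur_mean = 35, expr_dur_sd = 10,
      emt_onset_mean = 55, emt_onset_sd = 10,
      emt_speed_mult = 2.2, mult_ramp = 10,
      expr_speed_coupling = 0.6
    ),
    lb = condition_preset(
      "lb", p_express = 0,
      expr_onset_mean = 40, expr_onset_sd = 10,
      expr_dur_mean = 40, expr_dur_sd = 10,
      emt_onset_mean = 40, emt_onset_sd = 10,
      motility_blocked = TRUE
    ),
    csa = condition_preset(
      "csa", p_express = 0.08,
      expr_onset_mean = 70, expr_onset_sd = 12,
      expr_dur_mean = 30, expr_dur_sd = 10,
      emt_onset_mean = 40, emt_onset_sd = 10,
      motility_blocked = TRUE
    ),
    bcat_null = condition_preset(
      "bcat_null", p_express = 0.02,
      expr_onset_mean = 50, expr_onset_sd = 12,
      expr_dur_mean = 30, expr_dur_sd = 10,
      emt_onset_mean = 40, emt_onset_sd = 10,
      motility_blocked = TRUE
    ),
    bra_null = condition_preset(
      "bra_null", p_express = 0,
      expr_onset_mean = 40, expr_onset_sd = 10,
      expr_dur_mean = 40, expr_dur_sd = 10,
      emt_onset_mean = 30, emt_onset_sd = 8,
      emt_speed_mult = 1.4, mult_ramp = 10,
      expr_speed_coupling = 0
    )
  )
}

#' Fetch a built-in preset by name
#'
#' @param name one of the names of [default_presets()].
#' @return A [condition_preset()].
#' @export
get_preset <- function(name) {
  ps <- default_presets()
  if (!name %in% names(ps))
    stop(sprintf("unknown preset '%s'; available: %s",
                 name, paste(names(ps), collapse = ", ")), call. = FALSE)
  ps[[name]]
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf("Condition preset '%s'\n", x$name))
  cat(sprintf("  reporter : p_express %.2f, onset N(%g, %g) h (>= 12 h), duration N(%g, %g) h\n",
              x$p_express, x$expr_onset_mean, x$expr_onset_sd,
              x$expr_dur_mean, x$expr_dur_sd))
  cat(sprintf("  pulse    : rise/fall %g h, peak ~ logN(median %g, gsd %g) AFU\n",
              x$expr_rise, x$expr_peak_median, x$expr_peak_gsd))
  cat(sprintf("  motility : base speed logN(median %g, gsd %g) um/h, EMT N(%g, %g) h, mult %g over %g h%s\n",
              x$base_speed_median, x$base_speed_gsd,
              x$emt_onset_mean, x$emt_onset_sd,
              x$emt_speed_mult, x$mult_ramp,
              if (x$motility_blocked) " [EMT blocked]" else ""))
  cat(sprintf("  geometry : confinement %g -> %g um, FOV half-width %g um, turn sd %g rad\n",
              x$confine_radius_pre, x$confine_radius_post,
              x$fov_halfwidth, x$turn_sd))
  invisible(x)
}

#' Write condition presets to a YAML file
#'
#' Each preset is written as its own YAML document (separated by `---`),
#' one document per condition.
#'
#' @param presets a named list of [condition_preset()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_presets <- function(presets, path) {
  if (inherits(presets, "condition_preset")) presets <- list(presets)
  docs <- vapply(presets, function(p) {
    validate_preset(p)
    yaml::as.yaml(unclass(p))
  }, character(1))
  writeLines(paste0("---\n", paste(docs, collapse = "---\n")), path)
  invisible(path)
}

#' Read condition presets from a YAML file
#'
#' @param path file written by [write_presets()] (one YAML document per
#'   condition).
#' @return Named list of [condition_preset()] objects.
#' @export
read_presets <- function(path) {
  txt <- readLines(path, warn = FALSE)
  breaks <- grep("^---\\s*$", txt)
  if (length(breaks) == 0L) breaks <- 0L
  bounds <- c(breaks, length(txt) + 1L)
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    chunk <- txt[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    if (!any(nzchar(chunk))) next
    vals <- yaml::yaml.load(paste(chunk, collapse = "\n"))
    p <- do.call(condition_preset, vals)
    out[[p$name]] <- p
  }
  out
}

# Derive a reproducible sub-seed from a master seed and a counter.
# Keeps values inside the 32-bit signed range so set.seed() accepts them.
subseed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483647) * 48271 +
               as.numeric(counter) * 1009) %% 2147483646L + 1L
}

# Truncated-normal sampler (lower truncation only), by rejection.
rnorm_trunc <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

# Log-normal parameterized by median and geometric sd.
rlnorm_med <- function(n, median, gsd) {
  stats::rlnorm(n, meanlog = log(median), sdlog = log(gsd))
}

# Piecewise-linear reporter pulse: linear rise over `rise` h from onset,
# plateau, then linear fall over `rise` h ending at onset + dur. All
# arguments recycle elementwise; durations shorter than 2*rise give a
# triangular pulse that does not reach `peak`.
pulse_value <- function(t, onset, dur, rise, peak) {
  n <- max(length(t), length(onset), length(dur), length(peak))
  t <- rep_len(t, n); onset <- rep_len(onset, n)
  dur <- rep_len(dur, n); peak <- rep_len(peak, n)
  tt <- t - onset
  up <- pmin(tt / rise, 1)
  down <- pmin((dur - tt) / rise, 1)
  g <- peak * pmax(pmin(up, down), 0)
  g[tt < 0 | tt > dur] <- 0
  g
}
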