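#' Gate out non-viable events
#'
#' Removes events flagged non-viable (the stand-in for excluding
#' DAPI-positive cells from cytometry analysis) and records the counts.
#'
#' @param events event table with a logical `viable` column.
#' @return The viable events, with attributes `n_total` and `n_removed`.
#'   An all-non-viable input returns an empty table with a warning.
#' @export
gate_events <- function(events) {
  if (!"viable" %in% names(events))
    stop("missing column: events carry no 'viable' flag")
  keep <- events[events$viable, , drop = FALSE]
  if (nrow(keep) == 0L) warning("no viable events after gating")
  attr(keep, "n_total") <- nrow(events)
  attr(keep, "n_removed") <- nrow(events) - nrow(keep)
  keep
}

#' Positivity threshold from a negative control
#'
#' The empirical `q`-quantile (type 7) of the negative-control
#' intensities; by default the 99.9th percentile, so re-gating the
#' control against its own threshold leaves a positive fraction of about
#' `(1 - q) * 100` percent.
#'
#' @param control_intensities intensities of the negative control
#'   (n >= 100).
#' @param q quantile in `[0, 1]` (default 0.999; `q = 1` gives the
#'   maximum).
#' @return The threshold, AFU.
#' @export
threshold_from_control <- function(control_intensities, q = 0.999) {
  if (length(control_intensities) < 100L)
    stop("insufficient data: need >= 100 control intensities")
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  unname(stats::quantile(control_intensities, q, type = 7))
}

#' Reporter-positive fraction timecourse
#'
#' Per replicate, the percentage of events above the gate at each
#' condition/timepoint; replicate percentages are then summarized by
#' their mean and standard deviation.
#'
#' @param events gated event table (columns `condition`, `timepoint_h`,
#'   `replicate`, `intensity_afu`).
#' @param gate intensity threshold, AFU.
#' @return A `fraction_timecourse`: list with `replicates` (data frame
#'   `condition`, `timepoint_h`, `replicate`, `pct_positive`) and
#'   `summary` (`condition`, `timepoint_h`, `n_replicates`, `mean_pct`,
#'   `sd_pct`).
#' @export
fraction_positive_timecourse <- function(events, gate) {
  if (nrow(events) == 0L)
    return(structure(list(replicates = data.frame(), summary = data.frame()),
                     class = "fraction_timecourse"))
  pos <- events$intensity_afu > gate
  rep_df <- stats::aggregate(pos ~ condition + timepoint_h + replicate,
                             data = cbind(events, pos = pos), FUN = mean)
  names(rep_df)[names(rep_df) == "pos"] <- "pct_positive"
  rep_df$pct_positive <- 100 * rep_df$pct_positive
  summ <- do.call(rbind, lapply(
    split(rep_df, rep_df[c("condition", "timepoint_h")], drop = TRUE),
    function(d) data.frame(
      condition = d$condition[1], timepoint_h = d$timepoint_h[1],
      n_replicates = nrow(d), mean_pct = mean(d$pct_positive),
      sd_pct = if (nrow(d) > 1) stats::sd(d$pct_positive) else NA_real_,
      stringsAsFactors = FALSE)))
  summ <- summ[order(summ$condition, summ$timepoint_h), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(replicates = rep_df, summary = summ, gate = gate),
            class = "fraction_timecourse")
}

#' @export
print.fraction_timecourse <- function(x, ...) {
  cat(sprintf("Reporter-positive fractions (gate %.4g AFU)\n",
              x$gate %||% NA))
  print.data.frame(x$summary, digits = 3)
  invisible(x)
}

#' @export
plot.fraction_timecourse <- function(x, ...) {
  s <- x$summary
  conds <- unique(s$condition)
  graphics::plot(range(s$timepoint_h), c(0, max(s$mean_pct + ifelse(
    is.na(s$sd_pct), 0, s$sd_pct))), type = "n",
    xlab = "time (h)", ylab = "% reporter-positive", ...)
  for (i in seq_along(conds)) {
    d <- s[s$condition == conds[i], ]
    graphics::lines(d$timepoint_h, d$mean_pct, col = i, type = "b", pch = 16)
    graphics::arrows(d$timepoint_h, d$mean_pct - d$sd_pct,
                     d$timepoint_h, d$mean_pct + d$sd_pct,
                     angle = 90, code = 3, length = 0.03, col = i)
  }
  graphics::legend("topleft", legend = conds, col = seq_along(conds),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Condition-versus-control testing of positive fractions
#'
#' At each timepoint, a one-way ANOVA of replicate positive percentages
#' across conditions followed by Tukey HSD pairwise comparisons against
#' the time-matched control, with significance flags at the 0.05 and
#' 0.01 levels.
#'
#' @param fractions a `fraction_timecourse` (or its `replicates` data
#'   frame) covering at least two conditions with matched timepoints and
#'   at least two replicates each.
#' @param control control condition label.
#' @param alpha primary significance level (default 0.05).
#' @return Data frame with `timepoint_h`, `condition`, `diff_pct`,
#'   `p_anova`, `p_tukey`, `sig_05`, `sig_01`.
#' @export
compare_to_control <- function(fractions, control, alpha = 0.05) {
  reps <- if (inherits(fractions, "fraction_timecourse"))
    fractions$replicates else fractions
  conds <- unique(reps$condition)
  if (!control %in% conds) stop(sprintf("control '%s' not present", control))
  if (length(conds) < 2L) stop("need >= 2 conditions")
  tps <- lapply(split(reps, reps$condition),
                function(d) sort(unique(d$timepoint_h)))
  common <- Reduce(intersect, tps)
  missing <- lapply(names(tps), function(cn) setdiff(tps[[cn]], common))
  names(missing) <- names(tps)
  offenders <- Filter(length, missing)
  if (length(offenders) > 0)
    stop("unmatched timepoints: ",
         paste(sprintf("%s {%s}", names(offenders),
                       vapply(offenders, function(v)
                         paste(v, collapse = ","), character(1))),
               collapse = "; "))
  out <- list()
  for (tp in common) {
    d <- reps[reps$timepoint_h == tp, , drop = FALSE]
    if (any(table(d$condition) < 2L))
      stop("need >= 2 replicates per condition at every timepoint")
    d$condition <- factor(d$condition)
    fit <- stats::aov(pct_positive ~ condition, data = d)
    p_anova <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$condition
    for (cn in setdiff(levels(d$condition), control)) {
      key <- if (paste(cn, control, sep = "-") %in% rownames(tk))
        paste(cn, control, sep = "-") else paste(control, cn, sep = "-")
      sgn <- if (startsWith(key, cn)) 1 else -1
      out[[length(out) + 1L]] <- data.frame(
        timepoint_h = tp, condition = cn,
        diff_pct = sgn * tk[key, "diff"],
        p_anova = p_anova, p_tukey = tk[key, "p adj"],
        sig_05 = tk[key, "p adj"] < alpha,
        sig_01 = tk[key, "p adj"] < 0.01,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
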