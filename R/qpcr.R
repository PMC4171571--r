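#' MAK2 kinetic model parameters
#'
#' The MAK2 model describes PCR amplification mechanistically by the
#' recurrence `D_n = D_{n-1} + k * ln(1 + D_{n-1} / k)`: early cycles
#' double the product (`ln(1 + x) ~ x` for small `D/k`), and
#' amplification slows as `D` approaches the scale set by the kinetic
#' constant `k`. Observed fluorescence is `F_n = Fb + s * D_n`. With
#' `s = 1` (the default) the initial amount `D0` is expressed directly in
#' fluorescence-equivalent units; `(c*D0, c*k, s/c)` produce identical
#' curves, so `s` is held fixed during fitting.
#'
#' @param D0 initial target amount (AFU-equivalent, >= 0).
#' @param k kinetic constant, same units as `D0` (> 0).
#' @param Fb baseline fluorescence, AFU.
#' @param s fluorescence per unit product (> 0, default 1).
#' @return An object of class `mak2_params`.
#' @export
mak2_params <- function(D0, k, Fb = 0, s = 1) {
  p <- structure(list(D0 = D0, k = k, Fb = Fb, s = s),
                 class = "mak2_params")
  validate_mak2_params(p)
  p
}

#' Validate MAK2 parameters
#' @param params a [mak2_params()] object (or plain list).
#' @return The parameters, invisibly, if valid.
#' @export
validate_mak2_params <- function(params) {
  for (f in c("D0", "k", "Fb", "s")) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("invalid MAK2 params: field '%s' must be a finite number",
                   f), call. = FALSE)
  }
  if (params$D0 < 0) stop("invalid MAK2 params: field 'D0' must be >= 0",
                          call. = FALSE)
  if (params$k <= 0) stop("invalid MAK2 params: field 'k' must be > 0",
                          call. = FALSE)
  if (params$s <= 0) stop("invalid MAK2 params: field 's' must be > 0",
                          call. = FALSE)
  invisible(params)
}

#' MAK2 forward model
#'
#' Iterates the amplification recurrence for `n_cycles` cycles and maps
#' the product to fluorescence; `D_n` is non-decreasing, strictly
#' increasing when `D0 > 0`, and the per-cycle fold change decreases
#' monotonically from 2 towards 1.
#'
#' @param params a [mak2_params()] object.
#' @param n_cycles number of cycles (>= 1).
#' @return Data frame with `cycle`, `fluor_afu`, plus attribute `D`
#'   (product amounts after each cycle).
#' @export
mak2_forward <- function(params, n_cycles) {
  validate_mak2_params(params)
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  D <- numeric(n_cycles)
  d <- params$D0
  for (n in seq_len(n_cycles)) {
    d <- d + params$k * log1p(d / params$k)
    D[n] <- d
  }
  out <- data.frame(cycle = seq_len(n_cycles),
                    fluor_afu = params$Fb + params$s * D)
  attr(out, "D") <- D
  out
}

# Default fit-window rule: last cycle before fluorescence exceeds
# baseline + cutoff_frac of the total rise.
mak2_cutoff <- function(fluor, cutoff_frac) {
  fb <- mean(fluor[seq_len(min(5L, length(fluor)))])
  rise <- max(fluor) - fb
  above <- which(fluor > fb + cutoff_frac * rise)
  if (length(above) == 0L) return(length(fluor))
  max(min(above) - 1L, 1L)
}

#' Fit the MAK2 model to one amplification curve
#'
#' Nonlinear least squares of the MAK2 forward model against observed
#' fluorescence over cycles 1..cutoff, where the cutoff is the last
#' cycle before the curve exceeds the baseline plus `cutoff_frac` of the
#' total rise (the exponential-to-plateau transition is excluded because
#' MAK2 does not model plateau-phase chemistry). Optimization uses
#' Levenberg-Marquardt with a multi-start over log-spaced `D0`
#' initializations; the best residual wins, ties broken towards the
#' smaller `D0`. `s` is held fixed (see [mak2_params()]).
#'
#' @param curve data frame with columns `cycle` and `fluor_afu`
#'   (>= 8 cycles).
#' @param cutoff_frac fraction of the total rise defining the fit window
#'   (default 0.85).
#' @param n_starts number of `D0` multi-start initializations (default 7).
#' @param s fixed fluorescence-per-product scale (default 1).
#' @return A `mak2_fit`: list with `params` ([mak2_params()]), `resid_norm`,
#'   `cutoff_cycle`, `n_converged`, `data`. Methods: `print`, `coef`,
#'   `predict`, `residuals`, `fitted`.
#' @export
fit_mak2 <- function(curve, cutoff_frac = 0.85, n_starts = 7, s = 1) {
  if (nrow(curve) < 8L) stop("curve needs >= 8 cycles")
  fl <- curve$fluor_afu[order(curve$cycle)]
  fb0 <- mean(fl[1:5])
  noise <- max(stats::sd(fl[1:5]), 1e-6 * max(abs(fl), 1))
  rise <- max(fl) - fb0
  if (rise < 5 * noise)
    stop("no amplification: total rise below 5x baseline noise")
  cut <- mak2_cutoff(fl, cutoff_frac)
  if (cut < 8L) cut <- min(8L, length(fl))
  y <- fl[seq_len(cut)]
  cyc <- seq_len(cut)
  model_f <- function(lD0, lk, Fb) {
    Fb + s * attr(mak2_forward(mak2_params(exp(lD0), exp(lk), 0, 1),
                               cut), "D")
  }
  starts_D0 <- rise / s * 10^seq(-8, -2, length.out = n_starts)
  best <- NULL
  n_conv <- 0L
  for (d0 in starts_D0) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ model_f(lD0, lk, Fb),
        start = list(lD0 = log(d0), lk = log(rise / s / 4), Fb = fb0),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_conv <- n_conv + 1L
    rn <- sqrt(sum(stats::residuals(fit)^2))
    cf <- stats::coef(fit)
    if (is.null(best) || rn < best$rn * (1 - 1e-9) ||
        (abs(rn - best$rn) <= best$rn * 1e-9 && cf[["lD0"]] < best$lD0)) {
      best <- list(rn = rn, lD0 = cf[["lD0"]], lk = cf[["lk"]],
                   Fb = cf[["Fb"]])
    }
  }
  if (is.null(best))
    stop("fit failure: no MAK2 start converged (", n_starts, " starts)")
  out <- list(
    params = mak2_params(exp(best$lD0), exp(best$lk), best$Fb, s),
    resid_norm = best$rn, cutoff_cycle = cut, n_converged = n_conv,
    n_starts = n_starts, data = data.frame(cycle = cyc, fluor_afu = y)
  )
  class(out) <- "mak2_fit"
  out
}

#' @export
print.mak2_fit <- function(x, ...) {
  cat("MAK2 kinetic fit\n")
  cat(sprintf("  D0 = %.6g, k = %.6g, Fb = %.4g (s fixed at %g)\n",
              x$params$D0, x$params$k, x$params$Fb, x$params$s))
  cat(sprintf("  fit window: cycles 1-%d, residual norm %.4g (%d/%d starts converged)\n",
              x$cutoff_cycle, x$resid_norm, x$n_converged, x$n_starts))
  invisible(x)
}

#' @export
coef.mak2_fit <- function(object, ...) {
  c(D0 = object$params$D0, k = object$params$k, Fb = object$params$Fb)
}

#' @export
predict.mak2_fit <- function(object, n_cycles = NULL, ...) {
  if (is.null(n_cycles)) n_cycles <- object$cutoff_cycle
  mak2_forward(object$params, n_cycles)$fluor_afu
}

#' @export
fitted.mak2_fit <- function(object, ...) {
  stats::predict(object, object$cutoff_cycle)
}

#' @export
residuals.mak2_fit <- function(object, ...) {
  object$data$fluor_afu - stats::fitted(object)
}

#' Average technical-replicate quantities
#'
#' @param d0s numeric vector of per-replicate estimates (for qPCR, the
#'   fitted initial amounts).
#' @return List with `mean`, `se` (`sd/sqrt(n)`; `NA` with a flag for a
#'   singleton) and `n`.
#' @export
average_replicates <- function(d0s) {
  if (length(d0s) < 1L) stop("need >= 1 value")
  if (length(d0s) == 1L)
    return(list(mean = d0s, se = NA_real_, n = 1L,
                flag = "undefined SE (single replicate)"))
  list(mean = mean(d0s), se = stats::sd(d0s) / sqrt(length(d0s)),
       n = length(d0s))
}

#' Normalize a quantity to a reference gene with error propagation
#'
#' Ratio of target to reference mean with the first-order propagated
#' standard error
#' `SE = ratio * sqrt((SE_t/mu_t)^2 + (SE_r/mu_r)^2)`.
#'
#' @param target list with `mean` and `se` (as from
#'   [average_replicates()]).
#' @param reference same, for the reference gene; `mean` must be > 0.
#' @return List with `ratio` and `se`.
#' @export
normalize_to_reference <- function(target, reference) {
  if (!is.finite(reference$mean) || reference$mean <= 0)
    stop("reference mean must be > 0")
  ratio <- target$mean / reference$mean
  se_t <- if (is.na(target$se)) 0 else target$se
  se_r <- if (is.na(reference$se)) 0 else reference$se
  list(ratio = ratio,
       se = ratio * sqrt((se_t / target$mean)^2 +
                           (se_r / reference$mean)^2))
}

#' Quantify a table of qPCR curves
#'
#' Fits MAK2 per reaction (gene x sample x replicate), averages technical
#' replicates, and normalizes each gene to the reference gene within each
#' sample with propagated standard errors.
#'
#' @param curves data frame with columns `gene`, `sample`, `replicate`,
#'   `cycle`, `fluor_afu`.
#' @param reference_gene name of the reference gene (default `"gapdh"`).
#' @param ... passed to [fit_mak2()].
#' @return Data frame with one row per gene x sample: `gene`, `sample`,
#'   `d0_mean`, `d0_se`, `n_rep`, `ratio`, `ratio_se` (ratios `NA` for
#'   the reference gene itself is 1 with its own propagated error).
#' @export
quantify_qpcr <- function(curves, reference_gene = "gapdh", ...) {
  fits <- lapply(split(curves, curves[c("gene", "sample", "replicate")],
                       drop = TRUE),
                 function(d) {
                   f <- fit_mak2(d[order(d$cycle), c("cycle", "fluor_afu")],
                                 ...)
                   data.frame(gene = d$gene[1], sample = d$sample[1],
                              replicate = d$replicate[1],
                              D0 = f$params$D0, stringsAsFactors = FALSE)
                 })
  fits <- do.call(rbind, fits)
  out <- list()
  for (sm in unique(fits$sample)) {
    fs <- fits[fits$sample == sm, , drop = FALSE]
    ref <- average_replicates(fs$D0[fs$gene == reference_gene])
    for (gn in unique(fs$gene)) {
      tg <- average_replicates(fs$D0[fs$gene == gn])
      nm <- normalize_to_reference(tg, ref)
      out[[length(out) + 1L]] <- data.frame(
        gene = gn, sample = sm, d0_mean = tg$mean, d0_se = tg$se,
        n_rep = tg$n, ratio = nm$ratio, ratio_se = nm$se,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
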