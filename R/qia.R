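# --- synthetic image scenes ------------------------------------------

#' Channel model with independent per-nucleus means
#'
#' @param means named vector of per-nucleus mean intensities (AFU); names
#'   are channel names (a `hoechst` channel is added automatically by the
#'   renderer).
#' @param gsd geometric sd of the log-normal per-nucleus variation
#'   (applied to every channel).
#' @return A channel-model specification for [synthesize_image_series()].
#' @export
channel_model_independent <- function(means, gsd = 1.5) {
  stopifnot(length(names(means)) == length(means))
  structure(list(type = "independent", channels = names(means),
                 means = means, gsd = gsd),
            class = "channel_model")
}

#' Concordance channel model (correlated reporter and protein channels)
#'
#' Per-nucleus protein level `B` is log-normal; the reporter is
#' `G = B + eps + offset` with `eps ~ N(0, ratio * sd(B))` (theoretical
#' log-normal sd), so that `cor(G, B) = 1 / sqrt(1 + ratio^2)`. The
#' default `ratio = 0.822` gives a correlation of 0.7726, matching the
#' reporter-vs-immunostaining concordance this model emulates. The
#' constant offset keeps the reporter positive and does not affect the
#' correlation.
#'
#' @param b_median,b_gsd median and geometric sd of the protein channel.
#' @param ratio noise-to-signal sd ratio `sd(eps)/sd(B)`.
#' @param offset constant added to the reporter channel, AFU.
#' @return A channel-model specification with channels `gfp` (reporter)
#'   and `antibody` (protein).
#' @export
channel_model_concordance <- function(b_median = 200, b_gsd = 1.6,
                                      ratio = 0.822, offset = 300) {
  structure(list(type = "concordance", channels = c("gfp", "antibody"),
                 b_median = b_median, b_gsd = b_gsd, ratio = ratio,
                 offset = offset),
            class = "channel_model")
}

# Theoretical sd of a log-normal given median and geometric sd.
lnorm_sd <- function(median, gsd) {
  s2 <- log(gsd)^2
  median * exp(s2 / 2) * sqrt(exp(s2) - 1)
}

draw_channel_means <- function(model, n) {
  if (model$type == "independent") {
    out <- vapply(model$channels, function(ch)
      rlnorm_med(n, model$means[[ch]], model$gsd), numeric(n))
    out <- matrix(out, nrow = n,
                  dimnames = list(NULL, model$channels))
  } else if (model$type == "concordance") {
    b <- rlnorm_med(n, model$b_median, model$b_gsd)
    eps <- stats::rnorm(n, 0, model$ratio * lnorm_sd(model$b_median,
                                                     model$b_gsd))
    g <- pmax(b + eps + model$offset, 0)
    out <- cbind(gfp = g, antibody = b)
  } else stop("unknown channel model type")
  out
}

#' Synthesize a multi-channel nuclear image series
#'
#' Renders non-overlapping nuclei as filled disks: the `hoechst` channel
#' carries a per-nucleus log-normal stain level, the remaining channels
#' carry per-nucleus mean intensities drawn from `channel_model`.
#' Additive Gaussian pixel noise is applied (clamped at 0) and the
#' per-nucleus ground truth is recorded. Nuclei are distributed evenly
#' across `n_frames` frames (tiles/timepoints).
#'
#' @param n_nuclei total number of nuclei across all frames.
#' @param channel_model a [channel_model_independent()] or
#'   [channel_model_concordance()] specification.
#' @param noise_sd Gaussian pixel noise sd, AFU (>= 0).
#' @param pixel_size pixel size, um/px.
#' @param seed integer seed.
#' @param n_frames number of frames (default 1).
#' @param width,height frame size, px.
#' @param radius_range nucleus radius range, px.
#' @param hoechst_mean,hoechst_gsd per-nucleus Hoechst stain level.
#' @param max_tries placement retries per nucleus before a placement
#'   error is raised.
#' @return An `image_scene`: list with `stack` (T x C x H x W array),
#'   `channels` (first is `hoechst`), `pixel_size`, `times` and `truth`
#'   (data frame: `frame`, `label`, `cx_px`, `cy_px` 0-based centroids,
#'   `radius_px`, one `true_<channel>` column per channel).
#' @export
synthesize_image_series <- function(n_nuclei, channel_model,
                                    noise_sd = 2, pixel_size = 0.5,
                                    seed = 1, n_frames = 1,
                                    width = 256, height = 256,
                                    radius_range = c(6, 10),
                                    hoechst_mean = 120, hoechst_gsd = 1.2,
                                    max_tries = 200) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_nuclei < 0) stop("n_nuclei must be >= 0")
  channels <- c("hoechst", channel_model$channels)
  nC <- length(channels)
  stack <- array(0, dim = c(n_frames, nC, height, width),
                 dimnames = list(NULL, channels, NULL, NULL))
  per_frame <- diff(round(seq(0, n_nuclei, length.out = n_frames + 1L)))
  truth <- list()
  set.seed(subseed(seed, 400000L))
  for (f in seq_len(n_frames)) {
    n <- per_frame[f]
    cx <- numeric(n); cy <- numeric(n); rad <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r <- stats::runif(1, radius_range[1], radius_range[2])
        x <- stats::runif(1, r + 1, width - r - 2)
        y <- stats::runif(1, r + 1, height - r - 2)
        if (i == 1L ||
            all((cx[seq_len(i - 1L)] - x)^2 + (cy[seq_len(i - 1L)] - y)^2 >
                (rad[seq_len(i - 1L)] + r + 2)^2)) {
          cx[i] <- x; cy[i] <- y; rad[i] <- r
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("placement error: could not place nuclei at this density")
    }
    means <- if (n > 0) draw_channel_means(channel_model, n) else
      matrix(numeric(0), 0, nC - 1L,
             dimnames = list(NULL, channel_model$channels))
    hoechst <- rlnorm_med(n, hoechst_mean, hoechst_gsd)
    # rasterize: pixel centres at 0-based integer coordinates
    xs <- matrix(rep(seq_len(width) - 1L, each = height), height, width)
    ys <- matrix(rep(seq_len(height) - 1L, times = width), height, width)
    for (ch in seq_len(nC)) {
      img <- matrix(0, height, width)
      for (i in seq_len(n)) {
        inside <- (xs - cx[i])^2 + (ys - cy[i])^2 <= rad[i]^2
        img[inside] <- if (ch == 1L) hoechst[i] else means[i, ch - 1L]
      }
      if (noise_sd > 0)
        img <- pmax(img + stats::rnorm(length(img), 0, noise_sd), 0)
      stack[f, ch, , ] <- img
    }
    if (n > 0) {
      tf <- data.frame(frame = f, label = seq_len(n), cx_px = cx,
                       cy_px = cy, radius_px = rad)
      tf$true_hoechst <- hoechst
      for (ch in channel_model$channels)
        tf[[paste0("true_", ch)]] <- means[, ch]
      truth[[length(truth) + 1L]] <- tf
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(frame = integer(), label = integer(), cx_px = numeric(),
               cy_px = numeric(), radius_px = numeric())
  structure(list(stack = stack, channels = channels,
                 pixel_size = pixel_size, times = seq_len(n_frames) - 1,
                 truth = truth),
            class = "image_scene")
}

#' @export
print.image_scene <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf(
    "Image scene: %d frame(s) x %d channel(s) (%s), %d x %d px @ %g um/px, %d nuclei\n",
    d[1], d[2], paste(x$channels, collapse = "/"), d[3], d[4],
    x$pixel_size, nrow(x$truth)))
  invisible(x)
}

# --- segmentation -----------------------------------------------------

# 8-connected components of a logical mask, labels in raster order.
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  h <- nrow(mask)
  pos <- match(seq_along(mask), fg)   # linear index -> vertex id (or NA)
  edges <- list()
  for (off in c(h, 1L, h + 1L, h - 1L)) {  # right, down, down-right, up-right
    a <- fg
    b <- fg + off
    ok <- b >= 1L & b <= length(mask)
    # forbid wrap-around across matrix rows
    row_a <- (a - 1L) %% h
    if (off %in% c(1L, h + 1L)) ok <- ok & row_a < h - 1L
    if (off == h - 1L) ok <- ok & row_a > 0L
    ok <- ok & !is.na(pos[pmin(pmax(b, 1L), length(mask))]) & ok
    if (any(ok))
      edges[[length(edges) + 1L]] <- cbind(pos[a[ok]], pos[b[ok]])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  # relabel components in raster (column-major) order of first occurrence
  first <- tapply(seq_along(fg), comp, min)
  ord <- rank(first)
  lab[fg] <- as.integer(ord[comp])
  lab
}

#' Segment nuclei on a DNA-stain channel
#'
#' Gaussian smoothing, global Otsu threshold, 8-connected component
#' labeling and small-object removal: the standard recipe for segmenting
#' well-separated nuclei on a Hoechst image.
#'
#' @param hoechst_image 2-D non-negative intensity matrix.
#' @param smooth_sigma Gaussian smoothing sigma, px (default 2).
#' @param min_area minimum component area, px^2 (default 50).
#' @return Integer label matrix (background 0, nuclei 1..K). A constant
#'   image yields zero labels with a warning (the Otsu threshold is
#'   undefined), not an error.
#' @export
segment_nuclei <- function(hoechst_image, smooth_sigma = 2, min_area = 50) {
  if (!is.matrix(hoechst_image) || !is.numeric(hoechst_image))
    stop("hoechst_image must be a numeric matrix")
  if (any(hoechst_image < 0)) stop("hoechst_image must be non-negative")
  rng <- range(hoechst_image)
  if (diff(rng) == 0) {
    warning("constant image: Otsu threshold undefined, returning 0 labels")
    return(matrix(0L, nrow(hoechst_image), ncol(hoechst_image)))
  }
  im <- (hoechst_image - rng[1]) / diff(rng)
  sm <- if (smooth_sigma > 0)
    as.matrix(EBImage::gblur(EBImage::Image(im), sigma = smooth_sigma))
  else im
  th <- EBImage::otsu(EBImage::Image(sm))
  mask <- sm > th
  lab <- label_components8(mask)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_area)
    lab[] <- ifelse(lab > 0L & lab %in% keep, lab, 0L)
    # compact labels
    lab[] <- as.integer(match(lab, c(0L, sort(unique(lab[lab > 0L])))) - 1L)
  }
  lab
}

#' Per-nucleus mean intensities
#'
#' For every label and channel, the arithmetic mean of the pixel
#' intensities over the label's pixels; centroids (0-based pixel-centre
#' coordinates, origin top-left, y down) and areas are recorded.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param channels named list of intensity matrices, same shape as
#'   `labels`.
#' @param timepoint,condition metadata attached to every record.
#' @return Data frame with one row per nucleus: `label`, `timepoint_h`,
#'   `condition`, `centroid_x`, `centroid_y`, `area_px` and one
#'   `mean_<channel>` column per channel.
#' @export
extract_nuclear_intensities <- function(labels, channels,
                                        timepoint = NA_real_,
                                        condition = NA_character_) {
  if (!is.list(channels) || is.null(names(channels)))
    stop("channels must be a named list of matrices")
  for (ch in names(channels))
    if (!identical(dim(channels[[ch]]), dim(labels)))
      stop(sprintf("channel '%s' shape differs from label map", ch))
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) {
    out <- data.frame(label = integer(), timepoint_h = numeric(),
                      condition = character(), centroid_x = numeric(),
                      centroid_y = numeric(), area_px = numeric())
    for (ch in names(channels)) out[[paste0("mean_", ch)]] <- numeric()
    return(out)
  }
  px <- which(labels > 0L)
  lab <- labels[px]
  h <- nrow(labels)
  x0 <- (px - 1L) %/% h          # 0-based column = x
  y0 <- (px - 1L) %% h           # 0-based row = y
  area <- as.numeric(tabulate(match(lab, ids), nbins = length(ids)))
  cx <- rowsum(as.numeric(x0), lab)[, 1] / area
  cy <- rowsum(as.numeric(y0), lab)[, 1] / area
  out <- data.frame(label = ids, timepoint_h = timepoint,
                    condition = condition, centroid_x = unname(cx),
                    centroid_y = unname(cy), area_px = area,
                    stringsAsFactors = FALSE)
  for (ch in names(channels))
    out[[paste0("mean_", ch)]] <-
      unname(rowsum(as.numeric(channels[[ch]][px]), lab)[, 1]) / area
  out
}

#' Quantify every frame of an image scene
#'
#' Convenience wrapper: segments the `hoechst` channel of each frame and
#' extracts per-nucleus intensities for all channels.
#'
#' @param scene an `image_scene`.
#' @param smooth_sigma,min_area segmentation parameters.
#' @param timepoints optional per-frame timepoints (defaults to
#'   `scene$times`).
#' @param condition condition label.
#' @return Records data frame (see [extract_nuclear_intensities()]) with
#'   an extra `frame` column.
#' @export
quantify_scene <- function(scene, smooth_sigma = 2, min_area = 50,
                           timepoints = NULL, condition = NA_character_) {
  nT <- dim(scene$stack)[1]
  if (is.null(timepoints)) timepoints <- scene$times
  out <- list()
  for (f in seq_len(nT)) {
    lab <- segment_nuclei(scene$stack[f, "hoechst", , ],
                          smooth_sigma = smooth_sigma, min_area = min_area)
    chans <- lapply(setdiff(scene$channels, "hoechst"), function(ch)
      scene$stack[f, ch, , ])
    names(chans) <- setdiff(scene$channels, "hoechst")
    chans <- c(list(hoechst = scene$stack[f, "hoechst", , ]), chans)
    rec <- extract_nuclear_intensities(lab, chans,
                                       timepoint = timepoints[f],
                                       condition = condition)
    if (nrow(rec) > 0) rec$frame <- f
    out[[f]] <- rec
  }
  do.call(rbind, out)
}

# --- distribution and correlation timecourses ------------------------

#' Per-timepoint intensity distributions and means
#'
#' Histograms (shared per-channel range across all timepoints, so the
#' distribution timecourse is comparable) and arithmetic means of the
#' per-nucleus mean intensities.
#'
#' @param records nucleus records (from
#'   [extract_nuclear_intensities()]/[quantify_scene()]).
#' @param channels channel names (default: every `mean_*` column).
#' @param bins number of histogram bins (default 50).
#' @param timepoints timepoints to summarize (default: those present);
#'   requested timepoints with no records yield an `NA` mean.
#' @return List with `means` (data frame `channel`, `timepoint_h`, `n`,
#'   `mean`) and `histograms` (nested list
#'   `histograms[[channel]][[as.character(timepoint)]]` with `breaks` and
#'   `counts`).
#' @export
intensity_distribution_timecourse <- function(records, channels = NULL,
                                              bins = 50,
                                              timepoints = NULL) {
  mc <- grep("^mean_", names(records), value = TRUE)
  if (is.null(channels)) channels <- sub("^mean_", "", mc)
  if (is.null(timepoints)) timepoints <- sort(unique(records$timepoint_h))
  means <- list(); hists <- list()
  for (ch in channels) {
    col <- paste0("mean_", ch)
    if (!col %in% names(records)) stop(sprintf("no channel '%s'", ch))
    rng <- range(records[[col]], finite = TRUE)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
    hists[[ch]] <- list()
    for (tp in timepoints) {
      v <- records[[col]][records$timepoint_h == tp]
      means[[length(means) + 1L]] <- data.frame(
        channel = ch, timepoint_h = tp, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        stringsAsFactors = FALSE)
      hists[[ch]][[as.character(tp)]] <- if (length(v))
        list(breaks = breaks,
             counts = graphics::hist(pmin(pmax(v, rng[1]), rng[2]),
                                     breaks = breaks,
                                     plot = FALSE)$counts)
      else list(breaks = breaks, counts = rep(0L, bins))
    }
  }
  list(means = do.call(rbind, means), histograms = hists)
}

#' Pairwise per-nucleus correlation timecourse
#'
#' Pearson correlation of per-nucleus mean intensities for each named
#' channel pair at each timepoint, with an optional baseline correlation
#' computed once from a reference condition's records.
#'
#' @param records nucleus records.
#' @param pairs list of length-2 character vectors of channel names.
#' @param baseline_records optional records of the baseline condition.
#' @param min_n minimum nuclei per timepoint (default 3).
#' @return Data frame with `channel_a`, `channel_b`, `timepoint_h`, `r`,
#'   `n`, `baseline_r` and a `flag` column (`"ok"`,
#'   `"undefined-correlation"` for zero-variance input, `"too-few"`).
#' @export
pairwise_correlation_timecourse <- function(records, pairs,
                                            baseline_records = NULL,
                                            min_n = 3) {
  if (!is.list(pairs)) pairs <- list(pairs)
  cor_or_flag <- function(a, b) {
    if (length(a) < min_n) return(list(r = NA_real_, flag = "too-few"))
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      return(list(r = NA_real_, flag = "undefined-correlation"))
    list(r = stats::cor(a, b), flag = "ok")
  }
  out <- list()
  for (pr in pairs) {
    ca <- paste0("mean_", pr[1]); cb <- paste0("mean_", pr[2])
    base_r <- NA_real_
    if (!is.null(baseline_records)) {
      br <- cor_or_flag(baseline_records[[ca]], baseline_records[[cb]])
      base_r <- br$r
    }
    for (tp in sort(unique(records$timepoint_h))) {
      sel <- records$timepoint_h == tp
      cc <- cor_or_flag(records[[ca]][sel], records[[cb]][sel])
      out[[length(out) + 1L]] <- data.frame(
        channel_a = pr[1], channel_b = pr[2], timepoint_h = tp,
        r = cc$r, n = sum(sel), baseline_r = base_r, flag = cc$flag,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# --- track ROI readout ------------------------------------------------

#' Mean intensity in a circular ROI following a track
#'
#' For each frame of a time-lapse scene, the mean intensity of the pixels
#' whose centres lie within `radius_um` of the track position (a small
#' circular region of interest around the cell centre). ROIs clipped by
#' the image edge are flagged; positions fully outside the image give a
#' missing value.
#'
#' @param scene an `image_scene` whose frames align with the track's
#'   sample times.
#' @param track one cell's rows (`t_h`, `x_um`, `y_um`).
#' @param radius_um ROI radius, um (default 10).
#' @param channel channel name (default the first non-Hoechst channel).
#' @return Data frame with `t_h`, `mean_afu`, `n_px`, `clipped`.
#' @export
track_roi_intensity <- function(scene, track, radius_um = 10,
                                channel = NULL) {
  if (radius_um <= 0) stop("radius_um must be > 0")
  if (is.null(channel))
    channel <- setdiff(scene$channels, "hoechst")[1]
  nT <- dim(scene$stack)[1]
  track <- track[order(track$t_h), , drop = FALSE]
  if (nrow(track) != nT)
    stop("track sample count does not match scene frame count")
  h <- dim(scene$stack)[3]; w <- dim(scene$stack)[4]
  r_px <- radius_um / scene$pixel_size
  xs <- matrix(rep(seq_len(w) - 1L, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 1L, times = w), h, w)
  out <- data.frame(t_h = track$t_h, mean_afu = NA_real_, n_px = 0L,
                    clipped = FALSE)
  for (f in seq_len(nT)) {
    px <- track$x_um[f] / scene$pixel_size
    py <- track$y_um[f] / scene$pixel_size
    inside <- (xs - px)^2 + (ys - py)^2 <= r_px^2
    n_in <- sum(inside)
    clipped <- px < r_px | px > w - 1 - r_px | py < r_px | py > h - 1 - r_px
    if (n_in > 0) {
      out$mean_afu[f] <- mean(scene$stack[f, channel, , ][inside])
      out$n_px[f] <- n_in
      out$clipped[f] <- clipped
    }
  }
  out
}
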