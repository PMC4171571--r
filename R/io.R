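# Column-checked CSV helpers shared by the table readers/writers.
read_table_checked <- function(path, required) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss) > 0)
    stop(sprintf("'%s' is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  d
}

#' Read and write track tables
#'
#' Track CSVs hold one row per frame with columns `cell_id`, `t_h`,
#' `x_um`, `y_um` and optionally `g_afu`.
#'
#' @param tracks a `track_set` or compatible data frame.
#' @param path CSV file path.
#' @param dt frame interval attached on read (inferred when `NULL`).
#' @return `write_tracks` returns `path` invisibly; `read_tracks` a
#'   `track_set` data frame.
#' @export
write_tracks <- function(tracks, path) {
  cols <- intersect(c("cell_id", "t_h", "x_um", "y_um", "g_afu"),
                    names(tracks))
  utils::write.csv(as.data.frame(tracks)[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path, dt = NULL) {
  d <- read_table_checked(path, c("cell_id", "t_h", "x_um", "y_um"))
  class(d) <- c("track_set", "data.frame")
  attr(d, "dt") <- dt %||% infer_dt(d)
  d
}

#' Read and write event tables
#'
#' Event CSVs hold one cytometry-like event per row: `condition`,
#' `timepoint_h`, `replicate`, `intensity_afu`, `viable`.
#'
#' @param events event table.
#' @param path CSV file path.
#' @return `write_events` returns `path` invisibly; `read_events` the
#'   event data frame.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read_table_checked(path, c("condition", "timepoint_h", "replicate",
                             "intensity_afu", "viable"))
}

#' Read and write qPCR curve tables
#'
#' Per-cycle fluorescence CSVs with columns `gene`, `sample`,
#' `replicate`, `cycle`, `fluor_afu`.
#'
#' @param curves qPCR curve table.
#' @param path CSV file path.
#' @return `write_qpcr` returns `path` invisibly; `read_qpcr` the curve
#'   data frame.
#' @export
write_qpcr <- function(curves, path) {
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr
#' @export
read_qpcr <- function(path) {
  read_table_checked(path, c("gene", "sample", "replicate", "cycle",
                             "fluor_afu"))
}

#' Write an image scene as multi-page TIFF with sidecar metadata
#'
#' Pages are ordered frame-major then channel (page = (t-1)*C + c).
#' Intensities are stored as 32-bit float scaled into `[0, 1]`; the
#' scale factor, channel names, pixel size, frame times and frame count
#' are recorded in a YAML sidecar next to the TIFF.
#'
#' @param scene an `image_scene`.
#' @param path TIFF file path; the sidecar is `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_image_scene <- function(scene, path) {
  d <- dim(scene$stack)
  scale <- max(scene$stack, 1e-12)
  pages <- list()
  for (f in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      pages[[length(pages) + 1L]] <- scene$stack[f, ch, , ] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(channels = as.list(scene$channels),
               pixel_size_um = scene$pixel_size,
               n_frames = d[1],
               times_h = as.list(scene$times),
               intensity_scale = scale)
  writeLines(yaml::as.yaml(meta), paste0(path, ".yaml"))
  invisible(path)
}

#' Read an image scene written by [write_image_scene()]
#'
#' @param path TIFF file path (sidecar `<path>.yaml` must exist).
#' @return An `image_scene` (without ground truth).
#' @export
read_image_scene <- function(path) {
  meta <- yaml::yaml.load_file(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  nC <- length(meta$channels)
  nT <- meta$n_frames
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  stack <- array(0, dim = c(nT, nC, h, w),
                 dimnames = list(NULL, unlist(meta$channels), NULL, NULL))
  for (f in seq_len(nT))
    for (ch in seq_len(nC))
      stack[f, ch, , ] <- pages[[(f - 1L) * nC + ch]] * meta$intensity_scale
  structure(list(stack = stack, channels = unlist(meta$channels),
                 pixel_size = meta$pixel_size_um,
                 times = unlist(meta$times_h),
                 truth = NULL),
            class = "image_scene")
}
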