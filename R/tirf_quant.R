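# Minimal per-frame quantification of flow-stretched filaments in TIRF
# movies: thresholded segmentation, axis-aligned length and
# background-subtracted integrated intensity, and frame-to-frame linking of
# tethered (anchor-stationary) molecules. Validated on synthetic images;
# the module is an explicit stand-in for instrument-specific measurement
# pipelines.

#' Construct a frame stack
#'
#' Container for a single-channel TIRF movie: a list of equal-sized 2-D
#' intensity matrices plus calibration. The flow axis is the column axis by
#' convention (filaments extend along rows of constant row index, increasing
#' column = downstream).
#'
#' @param frames List of numeric matrices, all the same dimension.
#' @param pixel_size Pixel size in um/pixel (> 0).
#' @param frame_interval Frame interval in s (> 0).
#' @param channel Channel label.
#' @return A `frame_stack` list.
#' @export
frame_stack <- function(frames, pixel_size, frame_interval, channel = "ch1") {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1)
    stop("all frames must have the same dimensions", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, channel = channel),
            class = "frame_stack")
}

#' Read or write a frame stack as a multi-frame TIFF
#'
#' Thin wrappers around the \pkg{tiff} package for the movie interchange
#' format. TIFF stores intensities normalised to `[0, 1]`; `write` divides
#' by the stack maximum and `read` can rescale with `scale`. Segmentation
#' and photometry are invariant to this overall scale.
#'
#' @param path TIFF file path.
#' @param scale Multiplier applied to the `[0, 1]` pixel values on read.
#'   Default 1.
#' @inheritParams frame_stack
#' @return `read_frame_stack`: a [frame_stack()].
#' @export
read_frame_stack <- function(path, pixel_size, frame_interval,
                             channel = "ch1", scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF stacks", call. = FALSE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]
    f * scale
  })
  frame_stack(frames, pixel_size, frame_interval, channel)
}

#' @rdname read_frame_stack
#' @param stack A [frame_stack()].
#' @export
write_frame_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF stacks", call. = FALSE)
  stopifnot(inherits(stack, "frame_stack"))
  hi <- max(1, vapply(stack$frames, max, numeric(1)))
  tiff::writeTIFF(lapply(stack$frames, function(f) pmax(f, 0) / hi), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Segment one frame into filament measurements
#'
#' Background is estimated per frame as median + MAD; pixels above
#' median + `background_sigma_mult` x MAD form the foreground mask, which is
#' split into 8-connected components. Per component: length = extent along
#' the flow (column) axis times `pixel_size`; intensity = sum of
#' (pixel - background) over the component, clamped at 0; anchor = the
#' upstream-most pixel (minimum column, with its row).
#'
#' @param frame Numeric matrix.
#' @param pixel_size Pixel size in um/pixel.
#' @param background_sigma_mult Threshold multiplier k in median + k MAD.
#'   Default 3.
#' @param min_px Minimum component size in pixels; smaller specks are
#'   dropped. Default 3.
#' @param frame_index Frame index stored with each measurement. Default 1.
#' @return Data.frame with one row per segment: `anchor_row`, `anchor_col`,
#'   `length_um`, `intensity_au`, `n_px`, `frame_index`. Zero rows for a
#'   blank frame.
#' @export
segment_frame <- function(frame, pixel_size, background_sigma_mult = 3,
                          min_px = 3, frame_index = 1L) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  bg <- stats::median(frame)
  noise <- stats::mad(frame)
  # the median-based background requires a mostly-dark frame; when the bulk
  # of the frame is bright the median sits far above the darkest pixels
  if (bg - stats::quantile(frame, 0.01) >
      10 * max(noise, .Machine$double.eps))
    stop("background estimate unreliable (mostly-bright frame); segmentation refused",
         call. = FALSE)
  thr <- bg + background_sigma_mult * max(noise, .Machine$double.eps)
  mask <- frame > thr
  if (mean(mask) > 0.5)
    stop("more than half the frame is above threshold; segmentation unreliable (saturated frame?)",
         call. = FALSE)
  empty <- data.frame(anchor_row = integer(), anchor_col = integer(),
                      length_um = numeric(), intensity_au = numeric(),
                      n_px = integer(), frame_index = integer())
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask + 0)
  ids <- seq_len(max(lab))
  rows <- row(frame)[lab > 0]
  cols <- col(frame)[lab > 0]
  vals <- frame[lab > 0]
  labs <- lab[lab > 0]
  out <- do.call(rbind, lapply(ids, function(i) {
    sel <- labs == i
    if (sum(sel) < min_px) return(NULL)
    ci <- cols[sel]; ri <- rows[sel]; vi <- vals[sel]
    up <- which.min(ci)
    data.frame(
      anchor_row = ri[up], anchor_col = ci[up],
      length_um = (max(ci) - min(ci) + 1) * pixel_size,
      intensity_au = max(sum(vi - bg), 0),
      n_px = sum(sel), frame_index = as.integer(frame_index))
  }))
  if (is.null(out)) empty else out
}

#' Link per-frame segments into per-molecule traces
#'
#' Molecules are tethered, so their anchors are stationary up to jitter:
#' each segment is matched to the open track with the nearest anchor within
#' `max_shift_px` (Euclidean distance, greedy nearest-first); unmatched
#' segments open new tracks. Tracks observed in fewer than `min_frames`
#' frames are discarded.
#'
#' @param stack A [frame_stack()], or a list of per-frame segment
#'   data.frames from [segment_frame()] (then `pixel_size` and
#'   `frame_interval` must be given).
#' @param max_shift_px Maximum anchor displacement between frames in
#'   pixels. Default 3.
#' @param min_frames Minimum track length in frames. Default 3.
#' @param pixel_size,frame_interval Calibration, only needed when `stack`
#'   is a raw list of segment tables.
#' @param ... Passed to [segment_frame()] when `stack` is a [frame_stack()].
#' @return List of [molecule_trace()] objects, one per track, each with
#'   attributes `anchor_row`/`anchor_col` (mean anchor position).
#' @export
link_frames <- function(stack, max_shift_px = 3, min_frames = 3,
                        pixel_size = NULL, frame_interval = NULL, ...) {
  if (inherits(stack, "frame_stack")) {
    pixel_size <- stack$pixel_size
    frame_interval <- stack$frame_interval
    per_frame <- lapply(seq_along(stack$frames), function(i)
      segment_frame(stack$frames[[i]], pixel_size, frame_index = i, ...))
  } else {
    stopifnot(is.list(stack), !is.null(pixel_size), !is.null(frame_interval))
    per_frame <- stack
  }
  tracks <- list()   # each: list(rows of measurements, anchor)
  for (seg in per_frame) {
    if (!NROW(seg)) next
    open_anchor <- if (length(tracks))
      t(vapply(tracks, `[[`, numeric(2), "anchor")) else
      matrix(numeric(), ncol = 2)
    used <- rep(FALSE, NROW(seg))
    if (nrow(open_anchor)) {
      d <- outer(seq_len(NROW(seg)), seq_len(nrow(open_anchor)),
                 Vectorize(function(i, j)
                   sqrt((seg$anchor_row[i] - open_anchor[j, 1])^2 +
                        (seg$anchor_col[i] - open_anchor[j, 2])^2)))
      taken <- rep(FALSE, nrow(open_anchor))
      ord <- order(d)
      for (k in ord) {
        i <- (k - 1) %% NROW(seg) + 1
        j <- (k - 1) %/% NROW(seg) + 1
        if (d[i, j] > max_shift_px) break
        if (used[i] || taken[j]) next
        tracks[[j]]$rows <- rbind(tracks[[j]]$rows, seg[i, ])
        tracks[[j]]$anchor <- c(seg$anchor_row[i], seg$anchor_col[i])
        used[i] <- TRUE; taken[j] <- TRUE
      }
    }
    for (i in which(!used))
      tracks[[length(tracks) + 1]] <- list(rows = seg[i, ],
                                           anchor = c(seg$anchor_row[i],
                                                      seg$anchor_col[i]))
  }
  tracks <- Filter(function(tr) nrow(tr$rows) >= min_frames, tracks)
  lapply(seq_along(tracks), function(k) {
    df <- tracks[[k]]$rows
    tr <- molecule_trace(
      molecule_id = paste0("track", k),
      time = (df$frame_index - 1) * frame_interval,
      length = df$length_um,
      intensity = df$intensity_au)
    attr(tr, "anchor_row") <- mean(df$anchor_row)
    attr(tr, "anchor_col") <- mean(df$anchor_col)
    tr
  })
}
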