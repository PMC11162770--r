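# Two-color competition analysis: classify coated ssDNA molecules by the
# channels in which they are visible, quantify per-molecule composition on
# co-coated molecules, and summarise real-time exchange traces.

#' Classify two-color molecules and summarise class percentages
#'
#' Each molecule is classed by comparing its per-channel integrated
#' intensity against a per-channel detection threshold: visible only in A
#' (`A_only`), in both channels (`both`), or only in B (`B_only`). Molecules
#' below both thresholds are "uncoated" for fluorescence purposes; they
#' cannot be counted from fluorescence alone and are excluded from the
#' percentage base, with the exclusion count reported. A sensible default
#' threshold is 3x the background-intensity SD of each channel.
#'
#' @param records Data.frame with columns `molecule_id`, `I_A_au`, `I_B_au`
#'   (and optionally `ratio_condition`).
#' @param threshold_A,threshold_B Detection thresholds in a.u. (> 0).
#' @return A `competition_summary`: list with `n_total` (included base),
#'   `n_excluded`, `pct_A_only`, `pct_both`, `pct_B_only` (summing to 100
#'   over the base), and the per-record `classes` factor.
#' @export
classify_molecules <- function(records, threshold_A, threshold_B) {
  stopifnot(is.data.frame(records),
            all(c("I_A_au", "I_B_au") %in% names(records)))
  if (!nrow(records)) stop("empty record table", call. = FALSE)
  if (threshold_A <= 0 || threshold_B <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  if (any(records$I_A_au < 0) || any(records$I_B_au < 0))
    stop("intensities must be >= 0", call. = FALSE)
  inA <- records$I_A_au >= threshold_A
  inB <- records$I_B_au >= threshold_B
  cls <- rep("uncoated", nrow(records))
  cls[inA & !inB] <- "A_only"
  cls[inA & inB] <- "both"
  cls[!inA & inB] <- "B_only"
  cls <- factor(cls, levels = c("A_only", "both", "B_only", "uncoated"))
  base <- cls != "uncoated"
  n_total <- sum(base)
  if (n_total == 0)
    stop("no molecule visible in either channel; nothing to classify",
         call. = FALSE)
  tab <- table(cls[base])
  structure(list(
    n_total = n_total,
    n_excluded = sum(!base),
    pct_A_only = 100 * unname(tab["A_only"]) / n_total,
    pct_both = 100 * unname(tab["both"]) / n_total,
    pct_B_only = 100 * unname(tab["B_only"]) / n_total,
    classes = cls
  ), class = "competition_summary")
}

#' @export
print.competition_summary <- function(x, ...) {
  cat(sprintf(
    "Two-color classification of %d molecules (%d excluded as uncoated):\n",
    x$n_total, x$n_excluded))
  cat(sprintf("  A only: %.1f%%   both: %.1f%%   B only: %.1f%%\n",
              x$pct_A_only, x$pct_both, x$pct_B_only))
  invisible(x)
}

#' Per-molecule channel-A composition of co-coated molecules
#'
#' For molecules visible in both channels, converts each channel's intensity
#' to a monomer count via its single-fluorophore intensity and reports the
#' channel-A fraction, fraction_A = n_A / (n_A + n_B), per molecule and as
#' mean +/- SD. Invariant to a common rescaling of both single-fluorophore
#' intensities. Records with zero intensity in both channels are skipped
#' with a warning.
#'
#' @param co_records Data.frame of co-coated molecules with columns
#'   `I_A_au`, `I_B_au` (and optionally `molecule_id`).
#' @param I_single_A,I_single_B Single-fluorophore intensities (> 0).
#' @return List with `fraction_A` (per molecule), `mean`, `sd`, `n`,
#'   `n_skipped`.
#' @export
composition_fractions <- function(co_records, I_single_A, I_single_B) {
  stopifnot(is.data.frame(co_records),
            all(c("I_A_au", "I_B_au") %in% names(co_records)))
  if (I_single_A <= 0 || I_single_B <= 0)
    stop("single-fluorophore intensities must be > 0", call. = FALSE)
  nA <- co_records$I_A_au / I_single_A
  nB <- co_records$I_B_au / I_single_B
  zero <- (nA + nB) <= 0
  if (any(zero))
    warning(sum(zero), " record(s) with zero intensity in both channels skipped",
            call. = FALSE)
  frac <- (nA / (nA + nB))[!zero]
  list(fraction_A = frac, mean = mean(frac), sd = stats::sd(frac),
       n = length(frac), n_skipped = sum(zero))
}

#' Summarise real-time two-channel exchange traces
#'
#' Ensemble mean +/- SD of the integrated intensity per channel per time
#' point, with channels interpolated onto a shared time grid when their
#' time bases differ, plus the sign of a fitted linear slope per channel as
#' a monotone-trend summary (negative = that species leaves the DNA,
#' positive = it accumulates).
#'
#' @param traces_A,traces_B Lists of [molecule_trace()] objects (intensity
#'   is the summarised quantity); an empty channel is omitted with a
#'   warning.
#' @return List with per-channel data.frames (`time_s`, `mean`, `sd`, `n`)
#'   and `slope_sign` (named numeric, -1/0/1).
#' @export
realtime_exchange <- function(traces_A, traces_B) {
  summarise_channel <- function(traces, grid) {
    mat <- vapply(traces, function(tr)
      stats::approx(tr$time_s, tr$intensity_au, xout = grid, rule = 1,
                    ties = mean)$y,
      numeric(length(grid)))
    mat <- matrix(mat, nrow = length(grid))
    data.frame(time_s = grid,
               mean = rowMeans(mat, na.rm = TRUE),
               sd = apply(mat, 1, stats::sd, na.rm = TRUE),
               n = rowSums(!is.na(mat)))
  }
  channels <- list(A = traces_A, B = traces_B)
  channels <- Filter(length, channels)
  if (!length(channels)) stop("both channels empty", call. = FALSE)
  if (length(channels) < 2)
    warning("channel ", setdiff(c("A", "B"), names(channels)),
            " is empty and omitted", call. = FALSE)
  all_t <- unlist(lapply(unlist(channels, recursive = FALSE), `[[`, "time_s"))
  dt <- stats::median(unlist(lapply(unlist(channels, recursive = FALSE),
                                    function(tr) diff(tr$time_s))))
  grid <- seq(min(all_t), max(all_t), by = dt)
  out <- lapply(channels, summarise_channel, grid = grid)
  slope_sign <- vapply(out, function(df) {
    ok <- is.finite(df$mean)
    if (sum(ok) < 2) return(0)
    sl <- unname(stats::coef(stats::lm(mean ~ time_s, data = df[ok, ]))[2])
    tol <- 1e-9 * max(abs(df$mean[ok]), 1)
    if (abs(sl) * diff(range(df$time_s[ok])) < tol) 0 else sign(sl)
  }, numeric(1))
  c(out, list(slope_sign = slope_sign))
}
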