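# File-format contracts: plain CSV/JSON readers and writers for every
# assay table the analysis stages consume or produce.

#' Read and write force-distance curve tables
#'
#' Curve CSV columns: `ramp_id`, `phase`, `distance_um`, `force_pN`,
#' `condition` (header required). One [force_extension_curve()] is built
#' per (ramp_id, phase, condition) group.
#'
#' @param path CSV file path.
#' @return `read_curves_csv`: named list of [force_extension_curve()]
#'   objects (names `condition.ramp_id.phase`).
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ramp_id", "phase", "distance_um", "force_pN", "condition")
  if (!all(need %in% names(df)))
    stop("curve file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  groups <- split(df, interaction(df$condition, df$ramp_id, df$phase,
                                  drop = TRUE))
  lapply(groups, function(g)
    force_extension_curve(g$distance_um, g$force_pN, g$phase[1],
                          g$ramp_id[1], g$condition[1]))
}

#' @rdname read_curves_csv
#' @param curves List of [force_extension_curve()] objects.
#' @export
write_curves_csv <- function(curves, path) {
  rows <- lapply(curves, function(cu)
    data.frame(ramp_id = attr(cu, "ramp_id"), phase = attr(cu, "phase"),
               distance_um = cu$distance_um, force_pN = cu$force_pN,
               condition = attr(cu, "condition")))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and write long-format molecule trace tables
#'
#' Trace CSV columns: `molecule_id`, `frame`, `time_s`, `length_um`,
#' `intensity_au`. Per-molecule conditions (protein, salt_mM, channel) live
#' in a JSON sidecar mapping molecule_id to a condition object.
#'
#' @param path CSV file path.
#' @param conditions_path Optional JSON sidecar path.
#' @return `read_traces_csv`: list of [molecule_trace()] objects.
#' @export
read_traces_csv <- function(path, conditions_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "time_s", "length_um")
  if (!all(need %in% names(df)))
    stop("trace file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  cond <- if (!is.null(conditions_path))
    jsonlite::read_json(conditions_path) else list()
  lapply(split(df, df$molecule_id), function(g) {
    g <- g[order(g$time_s), ]
    ci <- cond[[as.character(g$molecule_id[1])]] %||% list()
    molecule_trace(g$molecule_id[1], g$time_s, g$length_um,
                   g$intensity_au %||% NA_real_,
                   salt_mM = ci$salt_mM %||% NA_real_,
                   protein = ci$protein %||% NA_character_,
                   channel = ci$channel %||% NA_character_)
  })
}

#' @rdname read_traces_csv
#' @param traces List of [molecule_trace()] objects.
#' @export
write_traces_csv <- function(traces, path, conditions_path = NULL) {
  rows <- lapply(traces, function(tr)
    data.frame(molecule_id = attr(tr, "molecule_id"),
               frame = seq_len(nrow(tr)), time_s = tr$time_s,
               length_um = tr$length_um, intensity_au = tr$intensity_au))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  if (!is.null(conditions_path)) {
    cond <- stats::setNames(lapply(traces, function(tr)
      list(protein = attr(tr, "protein"), salt_mM = attr(tr, "salt_mM"),
           channel = attr(tr, "channel"))),
      vapply(traces, function(tr) as.character(attr(tr, "molecule_id")), ""))
    jsonlite::write_json(cond, conditions_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write a fit object to JSON
#'
#' Serialises the scalar components of any fit object (parameter estimates,
#' uncertainties, diagnostics) to a JSON file.
#'
#' @param fit A fit object (any of the package's fit classes).
#' @param path Output JSON path.
#' @export
write_fit_json <- function(fit, path) {
  keep <- Filter(function(x) is.numeric(x) || is.character(x) ||
                   is.logical(x) || is.matrix(x), unclass(fit))
  keep <- lapply(keep, function(x) if (is.matrix(x)) as.data.frame(x) else x)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
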