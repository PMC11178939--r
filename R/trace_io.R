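## Trace containers and I/O for manually traced flagellum coordinates.
## Conventions: image coordinate frame (origin top-left, y increases
## downward); points are 0-based continuous coordinates, head first; point
## order is never reversed by any operation in the package.

MIN_TRACE_POINTS <- 21L

#' Construct a single-frame flagellum trace
#'
#' An ordered head-to-tip 2-D point sequence for one flagellum in one video
#' frame. Consecutive duplicate points (a common manual-tracing artifact)
#' are silently merged; the merge is recorded in the `"dedup"` attribute.
#'
#' @param x,y Numeric coordinate vectors, head first.
#' @param frame_index Integer frame number, >= 0.
#' @param time_s Time stamp in seconds (`NA` to derive from fps later).
#' @param unit `"pixel"` or `"micron"`.
#' @param validate If `TRUE`, require at least 21 distinct points so that at
#'   least one tangent window fits.
#' @return An object of class `flag_trace`.
#' @export
new_trace <- function(x, y, frame_index, time_s = NA_real_,
                      unit = c("pixel", "micron"), validate = TRUE) {
  unit <- match.arg(unit)
  stopifnot(length(x) == length(y), frame_index >= 0)
  if (anyNA(x) || anyNA(y)) {
    stop_flagwave("trace contains missing coordinates", "flagwave_bad_coords")
  }
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (validate && length(x) < MIN_TRACE_POINTS) {
    stop_flagwave(sprintf("trace has %d distinct points; >= %d required",
                          length(x), MIN_TRACE_POINTS), "flagwave_short_trace")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 frame_index = as.integer(frame_index),
                 time_s = as.numeric(time_s), unit = unit),
            dedup = n_dropped, class = "flag_trace")
}

#' @export
print.flag_trace <- function(x, ...) {
  cat(sprintf("<flag_trace> frame %d, %d points [%s], t = %s s\n",
              x$frame_index, length(x$x), x$unit, format(x$time_s)))
  invisible(x)
}

#' Construct a trace set (one flagellum across frames)
#'
#' @param traces List of [new_trace()] objects sharing one unit, with
#'   strictly increasing `frame_index`.
#' @param flagellum_id Identifier string.
#' @param fps Frame rate (frames/second, > 0).
#' @param pixel_size_um Physical pixel size (um/pixel, > 0).
#' @param condition,genotype Free-form labels (e.g. `"egta"`, `"wt"`).
#' @param qc_flags Character vector of quality-control notes.
#' @return An object of class `flag_trace_set`.
#' @export
new_trace_set <- function(traces, flagellum_id, fps, pixel_size_um,
                          condition = "", genotype = "",
                          qc_flags = character()) {
  if (fps <= 0) stop_flagwave("fps must be > 0", "flagwave_bad_meta")
  if (pixel_size_um <= 0) {
    stop_flagwave("pixel_size_um must be > 0", "flagwave_bad_meta")
  }
  if (length(traces)) {
    units <- vapply(traces, `[[`, "", "unit")
    if (length(unique(units)) > 1L) {
      stop_flagwave("all traces must share one unit", "flagwave_bad_meta")
    }
    fi <- vapply(traces, `[[`, 0L, "frame_index")
    if (is.unsorted(fi, strictly = TRUE)) {
      stop_flagwave("frame_index must be strictly increasing",
                    "flagwave_bad_meta")
    }
    traces <- lapply(traces, function(tr) {
      if (is.na(tr$time_s)) tr$time_s <- tr$frame_index / fps
      tr
    })
  }
  structure(list(flagellum_id = as.character(flagellum_id),
                 fps = fps, pixel_size_um = pixel_size_um,
                 traces = traces, condition = condition, genotype = genotype,
                 qc_flags = qc_flags),
            class = "flag_trace_set")
}

#' @export
print.flag_trace_set <- function(x, ...) {
  u <- if (length(x$traces)) x$traces[[1]]$unit else "?"
  cat(sprintf("<flag_trace_set> '%s' (%s/%s): %d frames [%s], %g fps, %g um/px\n",
              x$flagellum_id, x$genotype, x$condition, length(x$traces), u,
              x$fps, x$pixel_size_um))
  if (length(x$qc_flags)) cat("  qc:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}

trace_unit <- function(trace_set) {
  if (!length(trace_set$traces)) return(NA_character_)
  trace_set$traces[[1]]$unit
}

#' Read traced flagellum coordinates
#'
#' Ingests a delimited table with columns `flagellum_id,frame,x,y` (rows in
#' head-to-tip point order within each frame), or ImageJ ROI polylines
#' (`.roi` / `.zip` of `.roi`, one polyline per frame, named
#' `<flagellum_id>_<frame>`). Coordinates are returned in pixel units;
#' acquisition metadata (`fps`, `pixel_size_um`) must be supplied from a
#' sidecar configuration and is never inferred from the data.
#'
#' Frames containing missing coordinates, or with fewer than 21 distinct
#' points, are dropped and recorded in the set's `qc_flags`.
#'
#' @param file Path to the table or ROI container.
#' @param fps,pixel_size_um Acquisition metadata (see [waveform_config()]).
#' @param dialect `"csv"`, `"tsv"`, or `"roi"`.
#' @param condition,genotype Labels applied to every flagellum read.
#' @return A `flag_trace_set` when the input holds a single flagellum,
#'   otherwise a named list of `flag_trace_set` objects.
#' @export
read_trace_table <- function(file, fps, pixel_size_um,
                             dialect = c("csv", "tsv", "roi"),
                             condition = "", genotype = "") {
  dialect <- match.arg(dialect)
  if (dialect == "roi") {
    df <- read_imagej_rois(file)
  } else {
    sep <- if (dialect == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(file, header = TRUE, sep = sep,
                        stringsAsFactors = FALSE),
      error = function(e) {
        stop_flagwave(sprintf("cannot parse trace table '%s': %s",
                              file, conditionMessage(e)), "flagwave_io_error")
      })
  }
  need <- c("flagellum_id", "frame", "x", "y")
  if (!all(need %in% names(df))) {
    stop_flagwave(sprintf("trace table must have columns %s",
                          paste(need, collapse = ",")), "flagwave_io_error")
  }
  if (!nrow(df)) stop_flagwave("empty trace table", "flagwave_io_error")
  sets <- lapply(split(df, factor(df$flagellum_id,
                                  levels = unique(df$flagellum_id))),
                 build_trace_set, fps = fps, pixel_size_um = pixel_size_um,
                 condition = condition, genotype = genotype)
  if (length(sets) == 1L) sets[[1]] else sets
}

build_trace_set <- function(rows, fps, pixel_size_um, condition, genotype) {
  qc <- character()
  frames <- sort(unique(rows$frame))
  traces <- list()
  for (f in frames) {
    sub <- rows[rows$frame == f, , drop = FALSE]   # within-frame order kept
    if (anyNA(sub$x) || anyNA(sub$y) || any(is.nan(sub$x) | is.nan(sub$y))) {
      qc <- c(qc, sprintf("frame %d dropped: missing coordinates", f))
      next
    }
    tr <- tryCatch(new_trace(sub$x, sub$y, frame_index = f, unit = "pixel"),
                   flagwave_short_trace = function(e) e)
    if (inherits(tr, "condition")) {
      qc <- c(qc, sprintf("frame %d dropped: %s", f, conditionMessage(tr)))
      next
    }
    if (attr(tr, "dedup") > 0) {
      qc <- c(qc, sprintf("frame %d: merged %d duplicate points", f,
                          attr(tr, "dedup")))
    }
    traces <- c(traces, list(tr))
  }
  new_trace_set(traces, flagellum_id = rows$flagellum_id[1], fps = fps,
                pixel_size_um = pixel_size_um, condition = condition,
                genotype = genotype, qc_flags = qc)
}

#' Convert a trace set from pixel to micron units
#'
#' Multiplies every coordinate by `pixel_size_um`. Idempotent on
#' micron-unit input.
#'
#' @param trace_set A `flag_trace_set`.
#' @return The trace set with coordinates in um.
#' @export
to_microns <- function(trace_set) {
  stopifnot(inherits(trace_set, "flag_trace_set"))
  if (trace_set$pixel_size_um <= 0) {
    stop_flagwave("pixel_size_um must be > 0", "flagwave_bad_meta")
  }
  if (identical(trace_unit(trace_set), "micron")) return(trace_set)
  trace_set$traces <- lapply(trace_set$traces, function(tr) {
    tr$x <- tr$x * trace_set$pixel_size_um
    tr$y <- tr$y * trace_set$pixel_size_um
    tr$unit <- "micron"
    tr
  })
  trace_set
}

RESULT_COLUMNS <- c("flagellum_id", "genotype", "condition", "n_frames_used",
                    "basal_curvature_rad_per_um", "intercept_rad",
                    "asymmetry_index", "beat_frequency_hz", "qc_flags")

#' Write per-flagellum results to CSV
#'
#' One row per flagellum with a stable column order
#' (`flagellum_id,genotype,condition,n_frames_used,basal_curvature_rad_per_um,intercept_rad,asymmetry_index,beat_frequency_hz,qc_flags`).
#' Undefined quantities are written as the explicit sentinel `NA`, never as
#' blanks or zeros. The file round-trips losslessly through
#' [read_results()].
#'
#' @param results A list of `flagellum_result` objects (see
#'   [analyze_flagellum()]) or a data frame already in result layout.
#' @param file Output path.
#' @export
write_results <- function(results, file) {
  df <- if (is.data.frame(results)) results else results_to_df(results)
  if (!nrow(df)) stop_flagwave("no results to write", "flagwave_io_error")
  tryCatch(
    utils::write.csv(df[, RESULT_COLUMNS], file, row.names = FALSE, na = "NA"),
    error = function(e) {
      stop_flagwave(sprintf("cannot write results: %s", conditionMessage(e)),
                    "flagwave_io_error")
    })
  invisible(df)
}

#' Read a results CSV written by [write_results()]
#' @param file Path to the CSV.
#' @return A data frame with one row per flagellum.
#' @export
read_results <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(flagellum_id = "character",
                                       genotype = "character",
                                       condition = "character",
                                       qc_flags = "character"))
  if (!all(RESULT_COLUMNS %in% names(df))) {
    stop_flagwave("not a flagwave results file", "flagwave_io_error")
  }
  df
}

#' Convert a list of flagellum results to the canonical result table
#' @param results List of `flagellum_result` objects.
#' @return Data frame in [write_results()] column layout.
#' @export
results_to_df <- function(results) {
  rows <- lapply(results, function(r) {
    data.frame(flagellum_id = r$flagellum_id,
               genotype = r$genotype %||% "",
               condition = r$condition %||% "",
               n_frames_used = r$n_frames_used,
               basal_curvature_rad_per_um = r$basal_curvature,
               intercept_rad = r$intercept,
               asymmetry_index = r$asymmetry_index %||% NA_real_,
               beat_frequency_hz = r$beat_frequency_hz %||% NA_real_,
               qc_flags = paste(r$qc_flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## ---- ImageJ ROI ingestion -------------------------------------------------
## Minimal reader for the ImageJ binary ROI format (big-endian): magic
## "Iout", ROI type at byte offset 6, bounds at 8..15, n coordinates at 16,
## integer x then y offsets from the bounding box at offset 64. Polyline-like
## types only (polygon 0, freeline 4, polyline 5, freehand 7, traced 8).

read_imagej_rois <- function(file) {
  if (grepl("\\.zip$", file, ignore.case = TRUE)) {
    tmp <- tempfile("rois")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE))
    paths <- utils::unzip(file, exdir = tmp)
    paths <- paths[grepl("\\.roi$", paths, ignore.case = TRUE)]
    if (!length(paths)) stop_flagwave("zip holds no .roi entries",
                                      "flagwave_io_error")
  } else {
    paths <- file
  }
  rows <- lapply(paths, function(p) {
    co <- read_one_roi(p)
    name <- sub("\\.roi$", "", basename(p), ignore.case = TRUE)
    m <- regmatches(name, regexec("^(.*)_([0-9]+)$", name))[[1]]
    if (length(m) != 3L) {
      stop_flagwave(sprintf("ROI name '%s' is not <flagellum_id>_<frame>",
                            name), "flagwave_io_error")
    }
    data.frame(flagellum_id = m[2], frame = as.integer(m[3]),
               x = co$x, y = co$y, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

read_one_roi <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "Iout")) {
    stop_flagwave(sprintf("'%s' is not an ImageJ ROI", path),
                  "flagwave_io_error")
  }
  readBin(con, "integer", 1, size = 2, endian = "big")          # version
  type <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  readBin(con, "integer", 1, size = 1, signed = FALSE)          # pad
  top <- readBin(con, "integer", 1, size = 2, endian = "big")
  left <- readBin(con, "integer", 1, size = 2, endian = "big")
  readBin(con, "integer", 2, size = 2, endian = "big")          # bottom,right
  n <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "big")
  if (!type %in% c(0L, 4L, 5L, 7L, 8L)) {
    stop_flagwave(sprintf("ROI type %d in '%s' is not a polyline", type, path),
                  "flagwave_io_error")
  }
  seek(con, 64)
  xs <- readBin(con, "integer", n, size = 2, endian = "big")
  ys <- readBin(con, "integer", n, size = 2, endian = "big")
  list(x = xs + left, y = ys + top)
}
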