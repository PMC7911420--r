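# TimeCourse container: a sampled 1D signal with its sampling interval,
# optional phase-segment bounds (after temporal concatenation) and a free-text
# provenance tag.

#' Construct a time course
#'
#' A `timecourse` is a numeric vector with a sampling interval `dt_s`
#' (seconds), optional `segments` marking concatenated phases, and a
#' `provenance` string describing its origin (seed name, network name, ...).
#'
#' @param samples numeric vector of samples.
#' @param dt_s sampling interval in seconds.
#' @param segments optional data.frame with columns `phase`, `start`, `end`
#'   giving 0-based half-open index ranges `[start, end)` that tile
#'   `[0, length(samples))` without overlap.
#' @param provenance free-text origin of the signal.
#' @return an object of class `timecourse`.
#' @export
timecourse <- function(samples, dt_s, segments = NULL, provenance = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(dt_s) || length(dt_s) != 1L || dt_s <= 0)
    stop_mod("timecourse", "dt_s must be a positive scalar")
  if (!is.null(segments)) {
    segments <- as.data.frame(segments)
    stopifnot(all(c("phase", "start", "end") %in% names(segments)))
    o <- order(segments$start)
    segments <- segments[o, , drop = FALSE]
    ok <- segments$start[1] == 0 &&
      segments$end[nrow(segments)] == length(samples) &&
      all(segments$end > segments$start) &&
      (nrow(segments) == 1L ||
         all(segments$start[-1] == segments$end[-nrow(segments)]))
    if (!ok)
      stop_mod("timecourse", "segments must tile [0, n) without overlap")
    rownames(segments) <- NULL
  }
  structure(samples, dt_s = dt_s, segments = segments,
            provenance = provenance, class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  seg <- attr(x, "segments")
  cat(sprintf("<timecourse> n = %d, dt = %.4g s (%.4g s total)\n",
              length(x), attr(x, "dt_s"), length(x) * attr(x, "dt_s")))
  if (nzchar(attr(x, "provenance")))
    cat("  provenance:", attr(x, "provenance"), "\n")
  if (!is.null(seg))
    cat("  segments:", paste(sprintf("%s [%d,%d)", seg$phase, seg$start,
                                     seg$end), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.timecourse <- function(x, ...) {
  t <- (seq_along(x) - 1) * attr(x, "dt_s")
  graphics::plot(t, as.numeric(x), type = "l", xlab = "time (s)",
                 ylab = "signal", main = attr(x, "provenance"), ...)
  seg <- attr(x, "segments")
  if (!is.null(seg) && nrow(seg) > 1L)
    graphics::abline(v = seg$start[-1] * attr(x, "dt_s"), lty = 2,
                     col = "grey50")
  invisible(x)
}

tc_dt <- function(tc) attr(tc, "dt_s")
tc_segments <- function(tc) attr(tc, "segments")

#' Concatenate time courses in temporal order
#'
#' Joins phase-wise signals into one series (e.g., four 200-volume scans into
#' an 800-point session signal), recording each part's span in `segments`.
#'
#' @param parts list of `timecourse` objects with equal `dt_s`.
#' @param phase_names optional character vector naming each part; defaults to
#'   existing provenance strings or `part1`, `part2`, ...
#' @return a `timecourse` whose `segments` give each part's 0-based half-open
#'   index range.
#' @export
concatenate_timecourses <- function(parts, phase_names = NULL) {
  if (!is.list(parts) || length(parts) < 1L)
    stop_mod("concatenate", "need at least one timecourse")
  dts <- vapply(parts, tc_dt, numeric(1))
  if (any(abs(dts - dts[1]) > 1e-12))
    stop_mod("concatenate", "mismatched sampling intervals: %s",
             paste(unique(dts), collapse = ", "))
  if (is.null(phase_names)) {
    phase_names <- vapply(seq_along(parts), function(i) {
      p <- attr(parts[[i]], "provenance")
      if (nzchar(p)) p else sprintf("part%d", i)
    }, character(1))
  }
  lens <- vapply(parts, length, integer(1))
  ends <- cumsum(lens)
  segments <- data.frame(phase = phase_names, start = c(0L, ends[-length(ends)]),
                         end = ends, stringsAsFactors = FALSE)
  timecourse(unlist(lapply(parts, as.numeric), use.names = FALSE), dts[1],
             segments = segments,
             provenance = paste(phase_names, collapse = "+"))
}
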