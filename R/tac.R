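#' Time-activity curve
#'
#' Frame-integrated activity-concentration samples for one region or voxel:
#' one value per frame of a [frame_schedule()], in kBq/mL, with a flag
#' recording whether the values are corrected for physical decay.
#'
#' @param schedule a [frame_schedule()].
#' @param values numeric vector, one activity concentration per frame.
#' @param decay_corrected logical flag (default `TRUE`).
#' @return object of class `tac`.
#' @export
tac <- function(schedule, values, decay_corrected = TRUE) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(values) != nrow(schedule))
    stop_invalid("need one value per frame (%d frames, %d values)",
                 nrow(schedule), length(values))
  if (any(!is.finite(values))) stop_invalid("curve values must be finite")
  structure(list(schedule = schedule, values = as.numeric(values),
                 decay_corrected = isTRUE(decay_corrected)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d frames over %g s, peak %.3g kBq/mL, %s\n",
              nrow(x$schedule), schedule_total(x$schedule),
              max(x$values),
              if (x$decay_corrected) "decay-corrected" else "raw"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Piecewise-linear continuous curves. The input functions C_A(t), C_RV(t)
# driving the kinetic models are represented as piecewise-linear
# interpolants between sample points, zero before t = 0. This is the
# representation for which the exponential-convolution recursion in
# kinetics.R is exact.

#' Piecewise-linear continuous curve
#'
#' @param t sample times (seconds, non-negative, strictly increasing).
#' @param y values at the sample times.
#' @return object of class `plin_curve`. If the first node is at t > 0 a
#'   zero node at t = 0 is prepended, so the curve starts from zero.
#' @export
plin_curve <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 1L)
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop_invalid("curve nodes must be finite")
  if (is.unsorted(t, strictly = TRUE))
    stop_invalid("node times must be strictly increasing")
  if (t[1] < 0) stop_invalid("node times must be >= 0")
  if (t[1] > 0) { t <- c(0, t); y <- c(0, y) }
  structure(list(t = as.numeric(t), y = as.numeric(y)), class = "plin_curve")
}

#' Evaluate a piecewise-linear curve
#'
#' @param curve a [plin_curve()].
#' @param times evaluation times (seconds).
#' @param extend if `TRUE`, times beyond the last node hold the last value
#'   constant; otherwise they raise a domain error.
#' @return numeric vector of values.
#' @export
plin_eval <- function(curve, times, extend = FALSE) {
  stopifnot(inherits(curve, "plin_curve"))
  if (any(times < 0)) stop_domain("evaluation times must be >= 0")
  if (!extend && any(times > curve$t[length(curve$t)] + 1e-9))
    stop_domain("evaluation time %g beyond input support [0, %g]",
                max(times), curve$t[length(curve$t)])
  stats::approx(curve$t, curve$y, xout = pmin(times, max(curve$t)),
                rule = 2)$y
}

#' Piecewise-linear view of a time-activity curve
#'
#' Interprets the frame values as samples at the frame mid-times and builds
#' the piecewise-linear interpolant through them (zero before t = 0). This
#' is how a measured blood curve on the frame grid enters the kinetic
#' models.
#'
#' @param x a [tac()] or an object already of class `plin_curve`.
#' @return a [plin_curve()].
#' @export
as_plin <- function(x) {
  if (inherits(x, "plin_curve")) return(x)
  stopifnot(inherits(x, "tac"))
  mids <- frame_mid(x$schedule)
  ends <- frame_end(x$schedule)
  # hold the last value to the end of the last frame so the curve's support
  # covers the whole schedule
  plin_curve(c(mids, ends[length(ends)]),
             c(x$values, x$values[length(x$values)]))
}

# ---------------------------------------------------------------------------
# CSV I/O. Long format: frame_start_s, frame_duration_s, value_kBq_per_mL.
# Wide format: frame_start_s, frame_duration_s, then one column per region.

#' Write time-activity curves to CSV
#'
#' @param x a single [tac()] or a named list of `tac`s sharing one schedule
#'   (written in wide format, one column per region).
#' @param path output file path.
#' @export
write_tac_csv <- function(x, path) {
  if (inherits(x, "tac")) x <- list(value_kBq_per_mL = x)
  stopifnot(length(x) >= 1L, all(vapply(x, inherits, TRUE, "tac")))
  sch <- x[[1]]$schedule
  df <- data.frame(frame_start_s = sch$start_s,
                   frame_duration_s = sch$duration_s)
  for (nm in names(x)) df[[nm]] <- x[[nm]]$values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read time-activity curves from CSV
#'
#' @param path CSV file with columns `frame_start_s`, `frame_duration_s` and
#'   one or more value columns.
#' @param decay_corrected flag to stamp on the curves (the file format does
#'   not carry it).
#' @return a named list of [tac()] objects (one per value column).
#' @export
read_tac_csv <- function(path, decay_corrected = TRUE) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("frame_start_s", "frame_duration_s")
  if (!all(need %in% names(df)))
    stop_validate("CSV %s lacks columns %s", path,
                  paste(setdiff(need, names(df)), collapse = ", "))
  sch <- frame_schedule(df$frame_duration_s, df$frame_start_s)
  cols <- setdiff(names(df), need)
  out <- lapply(cols, function(nm) tac(sch, df[[nm]], decay_corrected))
  names(out) <- cols
  out
}
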