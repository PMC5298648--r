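# Wrench (force + moment) time series with an explicit moment reference
# point, plus the reference-point transfer used throughout distribution.

#' Wrench time series
#'
#' A force/moment pair over time with an explicit per-sample reference point
#' for the moment. Frames: `"global"` (sensor frame) or `"walking"`
#' (vertical shared, anterior axis along the walking direction).
#'
#' @param time numeric vector (s).
#' @param force n x 3 force (N).
#' @param moment n x 3 moment (N m) about `ref_point`; defaults to zero.
#' @param ref_point n x 3 (or length-3) reference point (m); defaults to the
#'   origin.
#' @param frame `"global"` or `"walking"`.
#' @return Object of class `wrench_series`.
#' @export
wrench_series <- function(time, force, moment = NULL, ref_point = c(0, 0, 0),
                          frame = c("global", "walking")) {
  frame <- match.arg(frame)
  n <- length(time)
  force <- as.matrix(force)
  moment <- if (is.null(moment)) matrix(0, n, 3) else as.matrix(moment)
  if (is.null(dim(ref_point)) || nrow(as.matrix(ref_point)) == 1)
    ref_point <- matrix(as.numeric(ref_point), n, 3, byrow = TRUE)
  if (nrow(force) != n || nrow(moment) != n || nrow(ref_point) != n)
    stopf("wrench_series: component lengths disagree with time")
  if (!all(is.finite(force)) || !all(is.finite(moment)))
    stopf("wrench_series: non-finite force or moment")
  structure(list(time = time, force = force, moment = moment,
                 ref_point = ref_point, frame = frame),
            class = "wrench_series")
}

#' @export
print.wrench_series <- function(x, ...) {
  cat(sprintf("<wrench_series> %d samples, frame '%s'\n", length(x$time), x$frame))
  cat(sprintf("  |F| range %.3g..%.3g N, |M| range %.3g..%.3g N m\n",
              min(row_norms(x$force)), max(row_norms(x$force)),
              min(row_norms(x$moment)), max(row_norms(x$moment))))
  invisible(x)
}

#' Re-express a wrench about a new reference point
#'
#' The force is unchanged; the moment gains `(old_ref - new_ref) x force`.
#' The operation is involutive: transferring back recovers the input.
#'
#' @param wrench a [wrench_series()].
#' @param new_ref_point length-3 vector or n x 3 matrix (m).
#' @return A `wrench_series` about `new_ref_point`.
#' @export
transfer_wrench <- function(wrench, new_ref_point) {
  n <- length(wrench$time)
  if (is.null(dim(new_ref_point)))
    new_ref_point <- matrix(new_ref_point, n, 3, byrow = TRUE)
  moment <- wrench$moment + cross3(wrench$ref_point - new_ref_point, wrench$force)
  wrench_series(wrench$time, wrench$force, moment, new_ref_point, wrench$frame)
}

#' Rotate a wrench by a fixed rotation about the global origin
#'
#' Used to express the total wrench in the walking frame: force, moment and
#' reference point are all rotated by `R`.
#'
#' @param wrench a [wrench_series()].
#' @param R 3 x 3 rotation matrix.
#' @param frame frame label of the result.
#' @return Rotated `wrench_series`.
#' @export
rotate_wrench <- function(wrench, R, frame = wrench$frame) {
  wrench_series(wrench$time,
                rotate_rows(wrench$force, R),
                rotate_rows(wrench$moment, R),
                rotate_rows(wrench$ref_point, R),
                frame)
}

#' Write a wrench series (with optional COP) to CSV
#'
#' Columns: `time, Fx, Fy, Fz, Mx, My, Mz[, COPx, COPy]`.
#'
#' @param wrench a [wrench_series()].
#' @param path output file.
#' @param cop optional [compute_cop()] result to append.
#' @export
write_wrench_csv <- function(wrench, path, cop = NULL) {
  df <- data.frame(time = wrench$time,
                   Fx = wrench$force[, 1], Fy = wrench$force[, 2],
                   Fz = wrench$force[, 3],
                   Mx = wrench$moment[, 1], My = wrench$moment[, 2],
                   Mz = wrench$moment[, 3])
  if (!is.null(cop)) {
    df$COPx <- cop$cop[, 1]
    df$COPy <- cop$cop[, 2]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a wrench series from CSV written by [write_wrench_csv()]
#' @param path input file.
#' @param frame frame label to attach.
#' @return A [wrench_series()].
#' @export
read_wrench_csv <- function(path, frame = "walking") {
  df <- utils::read.csv(path)
  wrench_series(df$time, as.matrix(df[, c("Fx", "Fy", "Fz")]),
                as.matrix(df[, c("Mx", "My", "Mz")]), frame = frame)
}
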