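# Plain-text interchange: wide kinematics CSV with a JSON sidecar declaring
# the sampling rate, segment list and point list.

seg_cols <- function(nm) {
  paste0(nm, "_", c("px", "py", "pz", "qw", "qx", "qy", "qz",
                    "ax", "ay", "az", "wx", "wy", "wz"))
}

#' Write a kinematics series to CSV + JSON sidecar
#'
#' One row per sample; columns `time` plus, per segment, position
#' (`px,py,pz`), quaternion (`qw..qz`), origin acceleration (`ax..az`),
#' angular velocity (`wx..wz`) and, when present, angular acceleration
#' (`dwx..dwz`); tracked points add `pt_<name>_{px,py,pz}` and, when
#' present, `pt_<name>_{vx,vy,vz}`. The sidecar records `fs`, the segment
#' and point lists and the unit system.
#'
#' @param kin a [segment_kinematics()].
#' @param csv_path,json_path output paths (default sidecar: `csv_path`
#'   with extension `.json`).
#' @export
write_kinematics_csv <- function(kin, csv_path,
                                 json_path = sub("\\.csv$", ".json", csv_path)) {
  df <- data.frame(time = kin$time)
  for (nm in names(kin$segments)) {
    s <- kin$segments[[nm]]
    block <- cbind(s$pos, s$quat, s$acc, s$angvel)
    cols <- seg_cols(nm)
    if (!is.null(s$angacc)) {
      block <- cbind(block, s$angacc)
      cols <- c(cols, paste0(nm, "_", c("dwx", "dwy", "dwz")))
    }
    colnames(block) <- cols
    df <- cbind(df, block)
  }
  for (nm in names(kin$points)) {
    p <- kin$points[[nm]]
    block <- p$pos
    cols <- paste0("pt_", nm, "_", c("px", "py", "pz"))
    if (!is.null(p$vel)) {
      block <- cbind(block, p$vel)
      cols <- c(cols, paste0("pt_", nm, "_", c("vx", "vy", "vz")))
    }
    colnames(block) <- cols
    df <- cbind(df, block)
  }
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = kin$fs, segments = names(kin$segments),
         points = names(kin$points), units = "SI (m, s, rad)"),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Read a kinematics series written by [write_kinematics_csv()]
#'
#' @param csv_path,json_path input paths.
#' @return A [segment_kinematics()].
#' @export
read_kinematics_csv <- function(csv_path,
                                json_path = sub("\\.csv$", ".json", csv_path)) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  df <- utils::read.csv(csv_path)
  grab <- function(cols) {
    missing <- setdiff(cols, names(df))
    if (length(missing))
      stopf("read_kinematics_csv: missing columns: %s", paste(missing, collapse = ", "))
    as.matrix(df[, cols])
  }
  segs <- list()
  for (nm in meta$segments) {
    cols <- seg_cols(nm)
    block <- grab(cols)
    s <- list(pos = unname(block[, 1:3]), quat = unname(block[, 4:7]),
              acc = unname(block[, 8:10]), angvel = unname(block[, 11:13]))
    dw <- paste0(nm, "_", c("dwx", "dwy", "dwz"))
    if (all(dw %in% names(df))) s$angacc <- unname(as.matrix(df[, dw]))
    segs[[nm]] <- s
  }
  points <- list()
  for (nm in meta$points %||% character(0)) {
    pcols <- paste0("pt_", nm, "_", c("px", "py", "pz"))
    p <- list(pos = grab(pcols))
    vcols <- paste0("pt_", nm, "_", c("vx", "vy", "vz"))
    if (all(vcols %in% names(df))) p$vel <- unname(as.matrix(df[, vcols]))
    points[[nm]] <- p
  }
  segment_kinematics(df$time, segs, points)
}

#' Write a gait event table to CSV
#' @param events a `gait_events` table.
#' @param path output file.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("foot", "event", "time", "index")],
                   path, row.names = FALSE)
  invisible(path)
}
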