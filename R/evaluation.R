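# Curve-comparison metrics used to judge predicted against measured GRF&M:
# RMSE and relative RMSE, Pearson correlation with categorical bands,
# Sprague-Geers magnitude/phase differences, sub-phase slices and the named
# stance-phase peak analysis.

#' RMSE and relative RMSE between two curves
#'
#' `rmse` is the root mean squared pointwise difference; `rrmse` divides it
#' by the mean of the two curves' peak-to-peak ranges and is reported in
#' percent. Invariant under a common affine rescaling of both curves.
#'
#' @param predicted,measured numeric vectors on the same grid.
#' @return List with `rmse` and `rrmse_percent` (`NA` with a warning when
#'   both curves are flat).
#' @export
rmse_rrmse <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stopf("rmse_rrmse: curves must share a grid")
  rmse <- sqrt(mean((predicted - measured)^2))
  denom <- (diff(range(predicted)) + diff(range(measured))) / 2
  if (denom == 0) {
    warnf("rmse_rrmse: both curves have zero range; rRMSE undefined")
    return(list(rmse = rmse, rrmse_percent = NA_real_))
  }
  list(rmse = rmse, rrmse_percent = 100 * rmse / denom)
}

#' Pearson correlation with agreement category
#'
#' Categories: weak (`rho <= 0.35`), moderate (`0.35 < rho <= 0.67`),
#' strong (`0.67 < rho <= 0.9`), excellent (`rho > 0.9`).
#'
#' @param predicted,measured numeric vectors on the same grid.
#' @return List with `rho` and `category` (`NA` with a warning for a
#'   constant input).
#' @export
pearson_with_category <- function(predicted, measured) {
  if (stats::sd(predicted) == 0 || stats::sd(measured) == 0) {
    warnf("pearson_with_category: constant input; correlation undefined")
    return(list(rho = NA_real_, category = NA_character_))
  }
  rho <- stats::cor(predicted, measured)
  list(rho = rho, category = correlation_category(rho))
}

#' @rdname pearson_with_category
#' @param rho correlation coefficient in `[-1, 1]`.
#' @export
correlation_category <- function(rho) {
  ifelse(rho <= 0.35, "weak",
         ifelse(rho <= 0.67, "moderate",
                ifelse(rho <= 0.9, "strong", "excellent")))
}

#' Sprague-Geers magnitude and phase differences
#'
#' With `psi_mm = mean(m^2)`, `psi_cc = mean(c^2)` and `psi_mc = mean(m c)`
#' over the comparison window (`m` measured, `c` predicted):
#' `M = (sqrt(psi_cc / psi_mm) - 1) * 100` and
#' `P = acos(psi_mc / sqrt(psi_mm psi_cc)) / pi * 100`.
#' `M` depends only on the amplitude ratio for proportional curves; `P` is
#' symmetric in its arguments and 50 for a quarter-period shift of a pure
#' sine.
#'
#' @param predicted,measured numeric vectors on the same grid.
#' @return List with `M_percent` and `P_percent`.
#' @export
sprague_geers <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stopf("sprague_geers: curves must share a grid")
  psi_mm <- mean(measured^2)
  psi_cc <- mean(predicted^2)
  psi_mc <- mean(measured * predicted)
  if (psi_mm == 0 || psi_cc == 0)
    stopf("sprague_geers: zero-energy curve")
  ratio <- max(-1, min(1, psi_mc / sqrt(psi_mm * psi_cc)))
  list(M_percent = (sqrt(psi_cc / psi_mm) - 1) * 100,
       P_percent = acos(ratio) / pi * 100)
}

#' All scalar metrics for one curve pair
#' @noRd
curve_metrics <- function(predicted, measured) {
  rr <- suppressWarnings(rmse_rrmse(predicted, measured))
  pc <- suppressWarnings(pearson_with_category(predicted, measured))
  sg <- tryCatch(sprague_geers(predicted, measured),
                 error = function(e) list(M_percent = NA_real_, P_percent = NA_real_))
  data.frame(rho = pc$rho, category = pc$category %||% NA_character_,
             rmse = rr$rmse, rrmse_percent = rr$rrmse_percent,
             M_percent = sg$M_percent, P_percent = sg$P_percent,
             stringsAsFactors = FALSE)
}

#' Metrics over gait sub-phases
#'
#' Recomputes correlation, RMSE and relative RMSE of a curve pair over the
#' samples of each sub-phase (DS1, SS, DS2 of the ipsilateral foot). Empty
#' sub-phases are omitted with a warning.
#'
#' @param predicted,measured numeric vectors on the same grid.
#' @param phase character vector of per-sample sub-phase labels (e.g.
#'   `"DS1"`, `"SS"`, `"DS2"`); samples labelled `NA` are ignored.
#' @return Data.frame, one row per sub-phase present, with `phase`, `rho`,
#'   `rmse`, `rrmse_percent`.
#' @export
subphase_metrics <- function(predicted, measured, phase) {
  out <- list()
  for (ph in c("DS1", "SS", "DS2")) {
    idx <- which(phase %in% ph)
    if (!length(idx)) {
      warnf("subphase_metrics: sub-phase %s empty; omitted", ph)
      next
    }
    rr <- suppressWarnings(rmse_rrmse(predicted[idx], measured[idx]))
    pc <- suppressWarnings(pearson_with_category(predicted[idx], measured[idx]))
    out[[length(out) + 1L]] <- data.frame(phase = ph, rho = pc$rho,
                                          rmse = rr$rmse,
                                          rrmse_percent = rr$rrmse_percent)
  }
  if (!length(out)) return(data.frame(phase = character(0), rho = numeric(0),
                                      rmse = numeric(0), rrmse_percent = numeric(0)))
  do.call(rbind, out)
}

#' Named stance-phase peaks
#'
#' The stance window is split into early (0-33%], middle (33-66%] and late
#' (66-100%] thirds; within each, specific extrema of the force and moment
#' components are sought: early stance - max lateral and max vertical GRF,
#' min anterior GRF; middle stance - min vertical GRF; late stance - max of
#' each GRF component and of the transverse GRM, min frontal and min
#' sagittal GRM.
#'
#' @return Data.frame with `name`, `component` (column index 1..6 in the
#'   order Fx, Fy, Fz, Mx, My, Mz), `window` and `type` ("max"/"min").
#' @export
peak_definitions <- function() {
  data.frame(
    name = c("anterior_GRF_min_ES", "lateral_GRF_max_ES", "vertical_GRF_max_ES",
             "vertical_GRF_min_MS",
             "anterior_GRF_max_LS", "lateral_GRF_max_LS", "vertical_GRF_max_LS",
             "transverse_GRM_max_LS", "frontal_GRM_min_LS", "sagittal_GRM_min_LS"),
    component = c(1L, 2L, 3L, 3L, 1L, 2L, 3L, 6L, 4L, 5L),
    window = c("ES", "ES", "ES", "MS", "LS", "LS", "LS", "LS", "LS", "LS"),
    type = c("min", "max", "max", "min", "max", "max", "max", "max", "min", "min"),
    stringsAsFactors = FALSE
  )
}

#' Peak comparison over the stance phase
#'
#' Locates each named extremum (see [peak_definitions()]) independently in
#' the predicted and measured curves within its stance-phase third and
#' reports the absolute (`predicted - measured`) and relative
#' (`/ measured`, percent) differences; a negative relative difference on a
#' maximum means under-estimation.
#'
#' @param predicted,measured n x 6 matrices of stance-phase curves, columns
#'   Fx, Fy, Fz, Mx, My, Mz, sampled uniformly over the stance duration.
#' @return Data.frame with one row per peak: `name`, `predicted`,
#'   `measured`, `abs_diff`, `rel_diff_percent`.
#' @export
peak_analysis <- function(predicted, measured) {
  n <- nrow(predicted)
  if (is.null(n) || n == 0) stopf("peak_analysis: empty stance window")
  frac <- seq_len(n) / n
  win_idx <- list(ES = which(frac <= 1 / 3),
                  MS = which(frac > 1 / 3 & frac <= 2 / 3),
                  LS = which(frac > 2 / 3))
  defs <- peak_definitions()
  rows <- lapply(seq_len(nrow(defs)), function(i) {
    d <- defs[i, ]
    idx <- win_idx[[d$window]]
    f <- if (d$type == "max") max else min
    p <- f(predicted[idx, d$component])
    m <- f(measured[idx, d$component])
    data.frame(name = d$name, predicted = p, measured = m,
               abs_diff = p - m,
               rel_diff_percent = if (m != 0) 100 * (p - m) / m else NA_real_)
  })
  do.call(rbind, rows)
}
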