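# Distribution of the total external wrench between the feet. During single
# support the grounded foot carries everything; during double support the
# trailing foot's wrench is the heel-strike value scaled by the STA curves
# and the leading foot receives the remainder, subtracted about a common
# reference point and then re-expressed about its own ankle projection.

#' Distribute the total external wrench between the feet
#'
#' Implements the phase table of the gait cycle: with `t_HS` the heel
#' strike of the leading (contralateral) foot and `t_TO` the toe-off of the
#' trailing foot, during double support
#' `F_trail(t) = F_ext(t_HS) * fF_STA(tau)` and
#' `F_lead(t) = F_ext(t) - F_trail(t)`, with
#' `tau = (t - t_HS) / (t_TO - t_HS)`; moments likewise with `fM_STA`,
#' scaled about the trailing foot's ankle projection at `t_HS`, with the
#' remainder transferred to the leading foot's ankle projection. During
#' single support the grounded foot receives the full wrench about its own
#' ankle projection, recomputed each sample.
#'
#' @param total a [wrench_series()] in the walking frame with moments about
#'   the global origin.
#' @param events a `gait_events` table on the same grid.
#' @param sta an [sta_function()].
#' @param ankle_l,ankle_r n x 3 ground projections of the left/right ankle
#'   joint in the walking frame (vertical coordinate 0).
#' @return List with `left` and `right` [wrench_series()], each about its
#'   own ankle projection, plus `phase` (the label vector).
#' @export
distribute_wrench <- function(total, events, sta, ankle_l, ankle_r) {
  time <- total$time
  n <- length(time)
  if (max(abs(total$ref_point)) > 1e-9)
    stopf("distribute_wrench: total wrench must be expressed about the origin")
  if (max(abs(ankle_l[, 3])) > 1e-9 || max(abs(ankle_r[, 3])) > 1e-9)
    stopf("distribute_wrench: ankle projections must lie on the ground plane")
  lab <- label_phases(events, time)
  FL <- matrix(0, n, 3); ML <- matrix(0, n, 3)
  FR <- matrix(0, n, 3); MR <- matrix(0, n, 3)

  moment_about <- function(i, O)  # total moment at sample i about point O
    total$moment[i, ] + crossprod_vec(-O, total$force[i, ])

  ss <- lab == "ss_left"
  if (any(ss)) {
    FL[ss, ] <- total$force[ss, , drop = FALSE]
    ML[ss, ] <- total$moment[ss, , drop = FALSE] +
      cross3(-ankle_l[ss, , drop = FALSE], total$force[ss, , drop = FALSE])
  }
  ss <- lab == "ss_right"
  if (any(ss)) {
    FR[ss, ] <- total$force[ss, , drop = FALSE]
    MR[ss, ] <- total$moment[ss, , drop = FALSE] +
      cross3(-ankle_r[ss, , drop = FALSE], total$force[ss, , drop = FALSE])
  }

  eps <- ds_episodes(events, time)
  for (k in seq_len(nrow(eps))) {
    i0 <- eps$start_index[k]; i1 <- eps$end_index[k]
    if (time[i1] - time[i0] <= 0)
      stopf("distribute_wrench: degenerate double-support interval at t = %g s", time[i0])
    trail_r <- eps$trailing[k] == "right"
    O_trail <- if (trail_r) ankle_r else ankle_l
    O_lead <- if (trail_r) ankle_l else ankle_r
    F_hs <- total$force[i0, ]
    M_hs <- moment_about(i0, O_trail[i0, ])
    idx <- i0:(i1 - 1L)  # toe-off sample itself belongs to the next phase
    tau <- (time[idx] - time[i0]) / (time[i1] - time[i0])
    s <- evaluate_sta(sta, tau)
    for (jj in seq_along(idx)) {
      i <- idx[jj]
      f_tr <- s[jj, 1:3] * F_hs
      # scaled moment about O_trail(i0), re-expressed about O_trail(i)
      m_tr <- s[jj, 4:6] * M_hs +
        crossprod_vec(O_trail[i0, ] - O_trail[i, ], f_tr)
      f_ld <- total$force[i, ] - f_tr
      m_ld <- moment_about(i, O_trail[i, ]) - m_tr +
        crossprod_vec(O_trail[i, ] - O_lead[i, ], f_ld)
      if (trail_r) {
        FR[i, ] <- f_tr; MR[i, ] <- m_tr
        FL[i, ] <- f_ld; ML[i, ] <- m_ld
      } else {
        FL[i, ] <- f_tr; ML[i, ] <- m_tr
        FR[i, ] <- f_ld; MR[i, ] <- m_ld
      }
    }
  }

  list(
    left = wrench_series(time, FL, ML, ankle_l, frame = total$frame),
    right = wrench_series(time, FR, MR, ankle_r, frame = total$frame),
    phase = lab
  )
}
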