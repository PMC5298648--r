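# Scaled anthropometric body model: 16 rigid segments with masses, centre of
# mass offsets and inertia tensors derived from the adjusted
# Zatsiorsky-Seluyanov ratios reported by De Leva (1996).

#' Body-segment inertial parameter table (De Leva, 16-segment model)
#'
#' Returns the per-segment mass ratios, longitudinal centre-of-mass position
#' and radii-of-gyration ratios of the 16-segment model, as fractions (the
#' shipped table stores the published percentages). Bilateral rows
#' (`bilateral = TRUE`) are instantiated twice (`_l`, `_r`) when a body is
#' scaled, so the mass fractions of the full model sum to 1.
#'
#' @return A data.frame with columns `segment`, `bilateral`, `mass_fraction`,
#'   `com_fraction`, `r_x`, `r_y`, `r_z` (all fractions in (0, 1)).
#' @export
#' @examples
#' tab <- deleva_table()
#' tab[tab$segment == "foot", "mass_fraction"]   # 0.0137
deleva_table <- function() {
  path <- system.file("extdata", "deleva_16segment.csv", package = "gaitwrench",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(
    segment = raw$segment,
    bilateral = raw$bilateral,
    mass_fraction = raw$mass_pct / 100,
    com_fraction = raw$com_pct / 100,
    r_x = raw$rx_pct / 100,
    r_y = raw$ry_pct / 100,
    r_z = raw$rz_pct / 100,
    stringsAsFactors = FALSE
  )
}

#' Segment inertia tensor from radii-of-gyration fractions
#'
#' Builds the diagonal inertia tensor about the segment centre of mass, in
#' the segment frame: `J_kk = mass * (fraction_k * length)^2`.
#'
#' @param mass_kg segment mass (kg), > 0.
#' @param length_m segment length (m), > 0.
#' @param gyration_fractions numeric length-3, radii of gyration as fractions
#'   of segment length (order x, y, z).
#' @return 3 x 3 symmetric positive semi-definite matrix (kg m^2).
#' @export
segment_inertia <- function(mass_kg, length_m, gyration_fractions) {
  if (mass_kg <= 0 || length_m <= 0)
    stopf("segment_inertia: mass and length must be positive")
  diag(mass_kg * (gyration_fractions * length_m)^2, nrow = 3)
}

#' Wearable instrumentation mass map of a 17-IMU motion capture suit
#'
#' Seventeen 10 g inertial measurement units distributed over the suit, one
#' 150 g communication pack and one 70 g battery (both carried on the
#' pelvis): 0.390 kg in total. Returned as a named vector of kilograms per
#' segment instance, usable as the `instrumentation` argument of
#' [scale_body()].
#'
#' @return Named numeric vector (kg) summing to 0.390.
#' @export
default_instrumentation <- function() {
  imu <- 0.010
  c(
    head = imu, upper_trunk = 3 * imu, pelvis = imu + 0.150 + 0.070,
    upper_arm_l = imu, upper_arm_r = imu,
    forearm_l = imu, forearm_r = imu,
    hand_l = imu, hand_r = imu,
    upper_leg_l = imu, upper_leg_r = imu,
    lower_leg_l = imu, lower_leg_r = imu,
    foot_l = imu, foot_r = imu
  )
}

#' Default segment lengths from stature
#'
#' Segment lengths as fixed fractions of body height (classical
#' anthropometric proportions), returned per segment instance. These are a
#' convenience for simulation and examples; measured lengths should be
#' supplied for real subjects.
#'
#' @param height_m subject stature (m).
#' @return Named numeric vector of lengths (m) for the 16 segment instances.
#' @export
default_segment_lengths <- function(height_m) {
  frac <- c(
    head = 0.182, upper_trunk = 0.170, middle_trunk = 0.120, pelvis = 0.105,
    upper_arm = 0.172, forearm = 0.157, hand = 0.108,
    upper_leg = 0.245, lower_leg = 0.246, foot = 0.152
  )
  tab <- deleva_table()
  out <- numeric(0)
  for (i in seq_len(nrow(tab))) {
    nm <- tab$segment[i]
    if (tab$bilateral[i]) {
      out[paste0(nm, "_l")] <- frac[[nm]] * height_m
      out[paste0(nm, "_r")] <- frac[[nm]] * height_m
    } else {
      out[nm] <- frac[[nm]] * height_m
    }
  }
  out
}

#' Expand the parameter table to the 16 segment instances
#' @noRd
segment_instances <- function(params = deleva_table()) {
  rows <- list()
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    if (p$bilateral) {
      for (side in c("_l", "_r")) {
        q <- p; q$instance <- paste0(p$segment, side); rows[[length(rows) + 1L]] <- q
      }
    } else {
      p$instance <- p$segment; rows[[length(rows) + 1L]] <- p
    }
  }
  do.call(rbind, rows)
}

#' Construct a body model from an explicit segment list
#'
#' Low-level constructor used both by [scale_body()] and by tests that need
#' non-anthropometric bodies (e.g. analytic pendulum chains). Each segment is
#' a list with `name`, `mass` (kg), `length` (m), `com_offset_local`
#' (3-vector, m, origin to centre of mass in the segment frame) and
#' `inertia_com_local` (3 x 3, kg m^2, about the CoM in the segment frame).
#'
#' @param segments list of segment lists as described above.
#' @param total_mass total measured mass the segment masses must sum to
#'   (kg); defaults to the sum of segment masses.
#' @param height subject stature (m), optional.
#' @param gravity gravity vector in the global frame (m/s^2), pointing down.
#' @return Object of class `body_model`.
#' @export
body_model <- function(segments, total_mass = NULL, height = NA_real_,
                       gravity = c(0, 0, -9.81)) {
  names(segments) <- vapply(segments, `[[`, character(1), "name")
  for (s in segments) {
    if (s$mass <= 0) stopf("body_model: segment '%s' has non-positive mass", s$name)
    J <- s$inertia_com_local
    if (max(abs(J - t(J))) > 1e-12 || any(eigen(J, symmetric = TRUE,
                                                only.values = TRUE)$values < -1e-12))
      stopf("body_model: segment '%s' inertia is not symmetric PSD", s$name)
  }
  msum <- sum(vapply(segments, `[[`, numeric(1), "mass"))
  total_mass <- total_mass %||% msum
  if (abs(msum - total_mass) > 1e-6)
    stopf("body_model: segment masses sum to %.8f kg, expected %.8f kg",
          msum, total_mass)
  structure(
    list(segments = segments, total_mass = total_mass, height = height,
         gravity = gravity),
    class = "body_model"
  )
}

#' Scale the 16-segment body model to a subject
#'
#' Distributes the subject's net body mass (total measured mass minus the
#' wearable instrumentation mass) over the 16 segments using the De Leva
#' mass fractions, then adds each instrumentation component back onto the
#' segment carrying it. The inertia tensor of each segment is built from its
#' resulting mass and the radii-of-gyration fractions; the instrumentation
#' is assumed not to alter the radii of gyration. The centre of mass sits on
#' the segment longitudinal axis (local z, proximal to distal) at
#' `com_fraction * length`.
#'
#' @param total_measured_mass_kg subject mass as weighed, including any worn
#'   instrumentation (kg).
#' @param height_m subject stature (m).
#' @param segment_lengths_m named numeric vector of lengths for all 16
#'   segment instances (see [default_segment_lengths()] for the names).
#' @param instrumentation named numeric vector of instrumentation masses per
#'   segment instance (kg), or `NULL` for none.
#' @param params parameter table, by default [deleva_table()].
#' @param gravity gravity vector (m/s^2).
#' @return A [body_model()] whose segment masses sum to
#'   `total_measured_mass_kg` within 1e-6 kg.
#' @export
#' @examples
#' body <- scale_body(70.39, 1.75, default_segment_lengths(1.75),
#'                    instrumentation = default_instrumentation())
#' body$segments$hand_l$mass   # 0.0061 * 70.0 + 0.010
scale_body <- function(total_measured_mass_kg, height_m, segment_lengths_m,
                       instrumentation = NULL, params = deleva_table(),
                       gravity = c(0, 0, -9.81)) {
  inst <- instrumentation %||% numeric(0)
  net_mass <- total_measured_mass_kg - sum(inst)
  if (net_mass <= 0)
    stopf("scale_body: net body mass is not positive (%.3f kg)", net_mass)
  tab <- segment_instances(params)
  unknown <- setdiff(names(inst), tab$instance)
  if (length(unknown))
    stopf("scale_body: instrumentation names not in model: %s",
          paste(unknown, collapse = ", "))
  segments <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- tab[i, ]
    if (!p$instance %in% names(segment_lengths_m))
      stopf("scale_body: missing length for segment '%s'", p$instance)
    len <- segment_lengths_m[[p$instance]]
    if (is.na(len))
      stopf("scale_body: missing length for segment '%s'", p$instance)
    if (len <= 0)
      stopf("scale_body: non-positive length for segment '%s'", p$instance)
    m_inst <- if (p$instance %in% names(inst)) inst[[p$instance]] else 0
    mass <- p$mass_fraction * net_mass + m_inst
    segments[[i]] <- list(
      name = p$instance,
      mass = mass,
      length = len,
      com_offset_local = c(0, 0, p$com_fraction * len),
      inertia_com_local = segment_inertia(mass, len, c(p$r_x, p$r_y, p$r_z)),
      endpoint_offsets_local = list(proximal = c(0, 0, 0), distal = c(0, 0, len))
    )
  }
  body_model(segments, total_mass = total_measured_mass_kg, height = height_m,
             gravity = gravity)
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model> %d segments, total mass %.3f kg, height %s m\n",
              length(x$segments), x$total_mass,
              ifelse(is.na(x$height), "?", format(x$height))))
  cat(sprintf("  gravity: (%g, %g, %g) m/s^2\n", x$gravity[1], x$gravity[2],
              x$gravity[3]))
  invisible(x)
}

#' Read an anthropometry configuration from JSON
#'
#' The file holds `total_mass_kg`, `height_m`, an optional named
#' `segment_lengths_m` map (missing entries fall back to
#' [default_segment_lengths()]) and an optional `instrumentation_kg` map.
#'
#' @param path path to a JSON file.
#' @return A [body_model()].
#' @export
read_anthropometry <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  lens <- default_segment_lengths(cfg$height_m)
  if (!is.null(cfg$segment_lengths_m))
    lens[names(cfg$segment_lengths_m)] <- unlist(cfg$segment_lengths_m)
  inst <- if (!is.null(cfg$instrumentation_kg)) unlist(cfg$instrumentation_kg) else NULL
  scale_body(cfg$total_mass_kg, cfg$height_m, lens, instrumentation = inst)
}
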