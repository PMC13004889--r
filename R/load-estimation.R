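# Moment-arm model converting the three plantar sensor forces to a
# body-weight-normalized Achilles tendon load time series. Each sensor force
# is assumed perpendicular to the sole and applied at a fixed per-sensor
# center of pressure; the net plantarflexion moment about the ankle is the
# sum of force-by-moment-arm products, and dividing by the Achilles tendon
# moment arm gives a proxy tendon force.

#' Sensor geometry for the moment-arm model
#'
#' Signed anterior-posterior moment arms of the three sensor pads about the
#' ankle joint axis (anterior positive, so a heel pad posterior to the axis
#' has a negative arm), plus the Achilles tendon moment arm. The default pad
#' arms are this package's defaults, calibrated so that synthetic walking
#' reproduces roughly 3xBW tendon load peaks; the tendon arm default of
#' 0.05 m is the standardized value commonly assumed in this model (its
#' inter-individual variation is under 10%).
#'
#' @param r_heel,r_mid,r_fore Pad moment arms in metres; must satisfy
#'   `r_fore > r_mid > r_heel`.
#' @param r_at Achilles tendon moment arm in metres (> 0).
#' @return A list of class `sensor_geometry`.
#' @export
#' @examples
#' sensor_geometry()
sensor_geometry <- function(r_heel = -0.02, r_mid = 0.05, r_fore = 0.12,
                            r_at = 0.05) {
  arms <- c(r_heel, r_mid, r_fore, r_at)
  if (!all(is.finite(arms))) {
    stop_tendonload("moment arms must be finite", "domain")
  }
  if (r_at <= 0) {
    stop_tendonload("tendon moment arm r_at must be > 0", "domain")
  }
  if (!(r_fore > r_mid && r_mid > r_heel)) {
    stop_tendonload("moment arms must satisfy r_fore > r_mid > r_heel",
                    "domain")
  }
  structure(list(r_heel = r_heel, r_mid = r_mid, r_fore = r_fore,
                 r_at = r_at),
            class = "sensor_geometry")
}

#' Net ankle plantarflexion moment from the three sensor forces
#'
#' `M_PF = f_heel * r_heel + f_mid * r_mid + f_fore * r_fore`, positive in
#' plantarflexion. Vectorized over samples.
#'
#' @param f_heel,f_mid,f_fore Sensor forces in Newtons.
#' @param geom A [sensor_geometry()].
#' @return Moment in Newton-metres.
#' @export
#' @examples
#' plantarflexion_moment(200, 300, 500,
#'                       sensor_geometry(-0.02, 0.05, 0.10))
plantarflexion_moment <- function(f_heel, f_mid, f_fore,
                                  geom = sensor_geometry()) {
  if (anyNA(f_heel) || anyNA(f_mid) || anyNA(f_fore) ||
      !all(is.finite(f_heel), is.finite(f_mid), is.finite(f_fore))) {
    stop_tendonload("forces must be finite", "domain")
  }
  f_heel * geom$r_heel + f_mid * geom$r_mid + f_fore * geom$r_fore
}

#' Achilles tendon load from the plantarflexion moment
#'
#' `F_AT = max(0, M_PF / r_AT) / body_weight`, in multiples of body weight
#' (xBW). Negative (dorsiflexion) net moments are clamped to zero tendon
#' load: the tendon cannot transmit compression.
#'
#' @param m_pf Plantarflexion moment in Newton-metres.
#' @param geom A [sensor_geometry()].
#' @param body_weight Body weight in Newtons (> 0).
#' @return Tendon load in xBW.
#' @export
#' @examples
#' tendon_load(70, sensor_geometry(), body_weight = 700) # 2 xBW
tendon_load <- function(m_pf, geom = sensor_geometry(), body_weight) {
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0) {
    stop_tendonload("body_weight must be > 0", "domain")
  }
  pmax(0, m_pf / geom$r_at) / body_weight
}

new_tendon_load_trace <- function(t, load, meta) {
  structure(
    tibble::tibble(t = t, load = load),
    participant_id = meta$participant_id,
    session_id = meta$session_id,
    start_time = meta$start_time,
    sample_rate = meta$sample_rate,
    day_index = meta$day_index,
    class = c("tendon_load_trace", class(tibble::tibble()))
  )
}

#' Estimate a tendon load trace from a recording
#'
#' Samplewise composition of [plantarflexion_moment()] and [tendon_load()].
#' Refuses recordings whose QC report marks them excluded.
#'
#' @param rec An [insole_recording()] that has passed QC.
#' @param geom A [sensor_geometry()].
#' @param profile The wearer's [participant_profile()] (for body weight).
#' @param qc Optional QC report row from [screen_recording()] /
#'   [qc_session()]; if its status is `excluded` the trace is refused.
#' @return A tibble of class `tendon_load_trace` with columns `t` (s) and
#'   `load` (xBW), carrying the session metadata as attributes.
#' @export
estimate_trace <- function(rec, geom = sensor_geometry(), profile,
                           qc = NULL) {
  if (!is.null(qc) && identical(qc$status, "excluded")) {
    stop_tendonload(
      paste0("recording ", attr(rec, "session_id"),
             " is QC-excluded (", qc$exclusion_reason,
             ") and cannot be estimated"),
      "integrity")
  }
  m <- plantarflexion_moment(rec$f_heel, rec$f_mid, rec$f_fore, geom)
  load <- tendon_load(m, geom, profile$body_weight)
  new_tendon_load_trace(rec$t, load, recording_meta(rec))
}

#' @describeIn estimate_trace Plot a tendon load trace with the overall and
#'   high-level thresholds marked.
#' @param object,... For `autoplot`: a `tendon_load_trace` and ignored
#'   arguments.
#' @param thresholds Named numeric, threshold lines in xBW.
#' @export
autoplot.tendon_load_trace <- function(object, ...,
                                       thresholds = c(overall = 0.3,
                                                      high = 3)) {
  ggplot(object, aes(x = .data$t / 3600, y = .data$load)) +
    geom_line(linewidth = 0.2) +
    geom_hline(yintercept = thresholds, linetype = "dashed",
               colour = c("#4477AA", "#EE6677")) +
    labs(x = "time (h)", y = "Achilles tendon load (xBW)",
         title = attr(object, "session_id")) +
    theme_minimal()
}
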