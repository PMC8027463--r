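#' Temporal mean frame of a stack
#'
#' The average of all (ideally stabilized) frames. Moving erythrocyte
#' columns average out, leaving the static vessel silhouette.
#'
#' @param stack A [frame_stack()].
#' @return Intensity matrix.
#' @export
temporal_mean <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  rowMeans(stack$frames, dims = 2)
}

#' Temporal low-quantile projection of a stack
#'
#' Per-pixel low quantile over time, a robust minimum-intensity
#' projection: each vessel pixel takes (close to) its value at the moment
#' an erythrocyte column passes, so the projected vessel is uniformly dark
#' along its length regardless of how the cell pattern happened to average
#' over the clip. This is the preferred image for measuring vessel width;
#' the plain mean is smoother but inherits any unevenness of the temporal
#' cell coverage.
#'
#' @param stack A [frame_stack()].
#' @param prob Quantile in (0, 0.5]; 0.1 by default (robust to noise,
#'   close to the minimum).
#' @return Intensity matrix.
#' @export
temporal_projection <- function(stack, prob = 0.1) {
  stopifnot(inherits(stack, "frame_stack"), prob > 0, prob <= 0.5)
  d <- dim(stack$frames)
  flat <- matrix(stack$frames, d[1] * d[2], d[3])
  k <- max(1L, round(prob * d[3]))
  matrix(apply(flat, 1, function(v) sort.int(v, partial = k)[k]), d[1], d[2])
}

#' Run the full single-video analysis pipeline
#'
#' Chains the stages: select the sharpest frame and register the stack to
#' it, map vessels on the temporal mean of the stabilized stack, build one
#' spatio-temporal image per segment and estimate axial velocities, then
#' derive the hemodynamic profile per segment.
#'
#' @param stack A calibrated [frame_stack()].
#' @param subject_id,view_id Labels attached to the resulting records.
#' @param search_range Velocity search bounds in mm/s.
#' @param quality_min Minimum velocimetry quality for a segment to count as
#'   having observable flow.
#' @param ... Passed on to [map_vessels()].
#' @return List with `records` (segment-record tibble), `segments`,
#'   `velocities`, `registration`, `mask`, `skeleton`.
#' @export
analyze_video <- function(stack, subject_id = NA_character_,
                          view_id = NA_character_,
                          search_range = c(0.05, 3.0), quality_min = 0.2,
                          ...) {
  reg <- register_stack(stack)
  vm <- map_vessels(temporal_mean(reg$stack), stack$calibration, ...)
  vel <- estimate_velocities(reg$stack, vm$segments,
                             search_range = search_range,
                             valid_mask = reg$registration$valid_mask)
  segs <- dplyr::mutate(vm$segments, subject_id = subject_id,
                        view_id = view_id)
  rec <- build_segment_records(segs, vel, quality_min = quality_min)
  list(records = rec, segments = vm$segments, velocities = vel,
       registration = reg$registration, mask = vm$mask,
       skeleton = vm$skeleton)
}
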