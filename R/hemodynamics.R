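#' Hemodynamic constants
#'
#' Constants of the centreline-to-mean velocity conversion: the reference
#' human erythrocyte diameter `Dc` (7.65 um), the profile-factor asymptote
#' (1.58), and the diameter ratio below which a vessel is too narrow for a
#' velocity profile, so the mean equals the centreline velocity (0.6).
#'
#' @param dc_um Reference erythrocyte diameter in micrometres.
#' @param asymptote Dimensionless profile-factor asymptote.
#' @param branch_ratio `D/Dc` threshold of the narrow-vessel branch.
#' @return Object of class `hemo_constants`.
#' @export
hemo_constants <- function(dc_um = 7.65, asymptote = 1.58, branch_ratio = 0.6) {
  stopifnot(dc_um > 0, asymptote > 0, branch_ratio > 0)
  structure(list(dc_um = dc_um, asymptote = asymptote,
                 branch_ratio = branch_ratio),
            class = "hemo_constants")
}

check_diameter <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("diameter must be positive")
}

#' Cross-sectional velocity from axial velocity
#'
#' Mean velocity over the vessel cross-section. For vessels narrower than
#' `branch_ratio * Dc` the erythrocytes fill the lumen and `Vs = Va`; for
#' wider vessels the centreline velocity overestimates the mean and is
#' divided by the profile factor
#' \deqn{1.58\,(1 - e^{-\sqrt{2D/D_c}}),}
#' which approaches 1.58 (the parabolic-profile limit of 2 tempered by the
#' blunted cell-velocity profile) as `D` grows. The piecewise form is kept
#' exactly as defined, including the finite jump at `D = 0.6 Dc`.
#'
#' @param va Axial velocity in mm/s (vectorized, non-negative).
#' @param d Diameter in micrometres (vectorized, positive).
#' @param constants A [hemo_constants()].
#' @return Cross-sectional velocity `Vs` in mm/s.
#' @export
cross_sectional_velocity <- function(va, d, constants = hemo_constants()) {
  stopifnot(all(va >= 0))
  check_diameter(d)
  ratio <- d / constants$dc_um
  pf <- constants$asymptote * (1 - exp(-sqrt(2 * ratio)))
  ifelse(ratio <= constants$branch_ratio, va, va / pf)
}

#' Blood volume flow
#'
#' Volumetric flow through a circular cross-section,
#' `Q = Vs * pi * D^2 / 4`, reported in picolitres per second
#' (1 pl/s = 1000 um^3/s).
#'
#' @param vs Cross-sectional velocity in mm/s.
#' @param d Diameter in micrometres.
#' @return Flow `Q` in pl/s.
#' @export
volume_flow <- function(vs, d) {
  stopifnot(all(vs >= 0))
  check_diameter(d)
  (vs * 1000) * pi * d^2 / 4 / 1000
}

#' Wall shear rate
#'
#' Velocity gradient at the vessel wall for Poiseuille-type flow,
#' `WSR = 8 Vs / D`, with `Vs` in um/s and `D` in um, reported in 1/s.
#'
#' @param vs Cross-sectional velocity in mm/s.
#' @param d Diameter in micrometres.
#' @return Wall shear rate in 1/s.
#' @export
wall_shear_rate <- function(vs, d) {
  stopifnot(all(vs >= 0))
  check_diameter(d)
  8 * (vs * 1000) / d
}

#' Assign a vessel diameter group
#'
#' Diameter bins used for stratified comparison: group 1 below 11 um,
#' group 2 from 11 to below 16 um, group 3 from 16 to below 22 um, group 4
#' from 22 um up. Intervals are half-open on the right so every diameter
#' maps to exactly one group.
#'
#' @param d Diameter in micrometres (vectorized, positive).
#' @param breaks Group boundaries, default `c(11, 16, 22)`.
#' @return Integer group in 1..4.
#' @export
assign_group <- function(d, breaks = c(11, 16, 22)) {
  check_diameter(d)
  findInterval(d, breaks) + 1L
}

#' Build per-segment hemodynamic records
#'
#' Joins segment diameters with velocity estimates by `segment_id` and
#' derives the full hemodynamic profile: cross-sectional velocity, volume
#' flow, wall shear rate and diameter group. Segments with quality below
#' `quality_min` carry no observable flow and are excluded (the count is
#' reported).
#'
#' @param segments Tibble from [split_segments()] (needs `segment_id`,
#'   `diameter_um`; optional `subject_id`, `view_id`).
#' @param velocities Tibble from [estimate_velocities()].
#' @param constants A [hemo_constants()].
#' @param quality_min Minimum quality for observable flow; records below it
#'   are dropped. Default keeps everything above zero.
#' @return Tibble: `subject_id`, `view_id`, `segment_id`, `diameter_um`,
#'   `va_mm_s`, `vs_mm_s`, `q_pl_s`, `wsr_per_s`, `group`, `quality`.
#' @export
build_segment_records <- function(segments, velocities,
                                  constants = hemo_constants(),
                                  quality_min = 0.2) {
  stopifnot(is.data.frame(segments), is.data.frame(velocities))
  if (nrow(segments) == 0) {
    return(tibble::tibble(subject_id = character(), view_id = character(),
                          segment_id = character(), diameter_um = numeric(),
                          va_mm_s = numeric(), quality = numeric(),
                          vs_mm_s = numeric(), q_pl_s = numeric(),
                          wsr_per_s = numeric(), group = integer()))
  }
  missing_v <- setdiff(segments$segment_id, velocities$segment_id)
  missing_s <- setdiff(velocities$segment_id, segments$segment_id)
  if (length(missing_v) || length(missing_s)) {
    stop("unmatched segment ids: ",
         paste(c(missing_v, missing_s), collapse = ", "))
  }
  if (!("subject_id" %in% names(segments))) segments$subject_id <- NA_character_
  if (!("view_id" %in% names(segments))) segments$view_id <- NA_character_
  rec <- dplyr::inner_join(
    dplyr::select(segments, dplyr::all_of(c("subject_id", "view_id",
                                            "segment_id", "diameter_um"))),
    dplyr::select(velocities, dplyr::all_of(c("segment_id", "va_mm_s",
                                              "quality"))),
    by = "segment_id"
  )
  n0 <- nrow(rec)
  rec <- dplyr::filter(rec, .data$quality >= quality_min, .data$quality > 0)
  if (nrow(rec) < n0) {
    message(n0 - nrow(rec), " segment(s) without observable flow excluded")
  }
  dplyr::mutate(
    rec,
    vs_mm_s = cross_sectional_velocity(.data$va_mm_s, .data$diameter_um,
                                       constants),
    q_pl_s = volume_flow(.data$vs_mm_s, .data$diameter_um),
    wsr_per_s = wall_shear_rate(.data$vs_mm_s, .data$diameter_um),
    group = assign_group(.data$diameter_um)
  )
}
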