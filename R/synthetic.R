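# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic vessel video
#'
#' Describes a ground-truthed slit-lamp-like clip: a bright scleral
#' background crossed by one dark curvilinear vessel whose erythrocyte
#' column (rendered as advected dark blobs) moves at a known axial
#' velocity, with per-frame rigid jitter and sensor noise. Defaults emulate
#' the acquisition this pipeline targets: vessels of 5-45 um, axial
#' velocities of 0.2-1.0 mm/s, small inter-frame motion.
#'
#' @param shape Centreline shape: `"straight"`, `"arc"` or `"sinusoid"`.
#' @param diameter_um True vessel diameter (rendered as the FWHM of a
#'   Gaussian cross-section).
#' @param va_mm_s True axial velocity of the advected pattern.
#' @param contrast Vessel darkness relative to background, in `[0, 1]`.
#' @param cell_spacing_um Mean spacing of the advected dark blobs.
#' @param jitter_sigma_px Per-frame rigid jitter standard deviation.
#' @param noise_sigma Additive Gaussian intensity noise.
#' @param background_texture Amplitude of optional static scleral texture
#'   (0 disables it, the default). On a perfectly featureless background,
#'   shifts parallel to a straight vessel are unobservable, so registration
#'   of such scenes is ill-posed along that axis; adding texture makes the
#'   stabilization problem well-posed when that is what a test needs.
#' @param angle_deg Orientation of a straight centreline.
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `synthetic_vessel_spec`.
#' @export
synthetic_vessel_spec <- function(shape = c("straight", "arc", "sinusoid"),
                                  diameter_um = 20, va_mm_s = 0.5,
                                  contrast = 0.5, cell_spacing_um = 40,
                                  jitter_sigma_px = 0.5, noise_sigma = 0.01,
                                  background_texture = 0,
                                  angle_deg = 30, seed = 1) {
  shape <- match.arg(shape)
  stopifnot(diameter_um > 0, va_mm_s >= 0, contrast > 0, contrast <= 1,
            cell_spacing_um > 0, jitter_sigma_px >= 0, noise_sigma >= 0,
            background_texture >= 0)
  structure(list(shape = shape, diameter_um = diameter_um, va_mm_s = va_mm_s,
                 contrast = contrast, cell_spacing_um = cell_spacing_um,
                 jitter_sigma_px = jitter_sigma_px, noise_sigma = noise_sigma,
                 background_texture = background_texture,
                 angle_deg = angle_deg, seed = as.integer(seed)),
            class = "synthetic_vessel_spec")
}

# Dense centreline samples (step 0.25 px) for a spec within an H x W frame.
vessel_curve <- function(spec, h, w, margin = 12) {
  step <- 0.25
  if (spec$shape == "straight") {
    th <- spec$angle_deg * pi / 180
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    half <- min(h, w) / 2 - margin
    u <- seq(-half, half, by = step)
    cbind(row = cy + u * sin(th), col = cx + u * cos(th))
  } else if (spec$shape == "arc") {
    r <- min(h, w)
    cy <- h + r / 2; cx <- (w + 1) / 2
    span <- asin((min(h, w) / 2 - margin) / r)
    th <- seq(-span, span, by = step / r)
    cbind(row = cy - r * cos(th), col = cx + r * sin(th))
  } else {
    xs <- seq(margin, w - margin, by = step)
    amp <- h / 8
    cbind(row = (h + 1) / 2 + amp * sin(2 * pi * (xs - margin) / (w - 2 * margin)),
          col = xs)
  }
}

#' Generate a ground-truthed synthetic vessel video
#'
#' Renders the clip described by a [synthetic_vessel_spec()]: a bright
#' background (mean intensity 0.8, optionally carrying static scleral
#' texture); a dark tube of Gaussian cross-section whose full width at
#' half maximum equals the true diameter; a quasi-regular aperiodic train
#' of dark blobs spaced about `cell_spacing_um` advected along the
#' centreline at the true velocity (periodic along the curve, so
#' statistics are stationary over the clip); per-frame rigid jitter;
#' additive Gaussian noise. The truth record stores
#' the generating parameters and the analytic cross-sectional velocity,
#' volume flow and wall shear rate derived from them with the package's own
#' conversion formulas.
#'
#' @param spec A [synthetic_vessel_spec()].
#' @param calibration A [calibration_profile()].
#' @param n_frames Number of frames (default 300, i.e. 5 s at 60 fps).
#' @param size Frame size `c(H, W)` in pixels.
#' @return List with `stack` (a [frame_stack()]) and `truth` (one-row
#'   tibble).
#' @export
generate_vessel_video <- function(spec, calibration, n_frames = 300,
                                  size = c(128, 128)) {
  stopifnot(inherits(spec, "synthetic_vessel_spec"),
            inherits(calibration, "calibration_profile"), n_frames >= 2)
  h <- size[1]; w <- size[2]
  scale <- calibration$pixel_scale_um
  fps <- calibration$frame_rate_fps
  fwhm_px <- spec$diameter_um / scale
  sigma_v <- fwhm_px / (2 * sqrt(2 * log(2)))
  curve <- vessel_curve(spec, h, w)
  if (any(curve[, 1] < 1 | curve[, 1] > h | curve[, 2] < 1 | curve[, 2] > w)) {
    stop("geometry error: vessel centreline leaves the frame")
  }
  steps <- sqrt(diff(curve[, 1])^2 + diff(curve[, 2])^2)
  arc <- c(0, cumsum(steps))
  L <- arc[length(arc)]

  # per-pixel distance to the curve and arc-length of the nearest point
  py <- matrix(seq_len(h), h, w)
  px <- matrix(seq_len(w), h, w, byrow = TRUE)
  dmin <- matrix(Inf, h, w)
  smin <- matrix(0, h, w)
  idx <- seq_len(nrow(curve))
  for (block in split(idx, ceiling(idx / 200))) {
    for (k in block) {
      d2 <- (py - curve[k, 1])^2 + (px - curve[k, 2])^2
      upd <- d2 < dmin
      dmin[upd] <- d2[upd]
      smin[upd] <- arc[k]
    }
  }
  dmin <- sqrt(dmin)
  support <- which(dmin <= 4 * sigma_v)
  profile <- exp(-dmin[support]^2 / (2 * sigma_v^2))
  s_sup <- smin[support]

  cell_px <- spec$cell_spacing_um / scale
  v_px <- spec$va_mm_s * 1000 / scale / fps
  out <- with_seed(spec$seed, {
    # quasi-regular cell train: erythrocyte columns are roughly evenly
    # spaced (near-uniform time-averaged coverage along the vessel) but
    # with enough spacing, amplitude and width dispersion that the train
    # is aperiodic — a strictly periodic train would alias the streak
    # slope at integer harmonics
    n_blobs <- max(2L, round(L / cell_px))
    blob_pos <- (seq(0, L, length.out = n_blobs + 1)[-1] +
                   stats::runif(n_blobs, -0.35, 0.35) * cell_px) %% L
    blob_amp <- stats::runif(n_blobs, 0.4, 1.6)
    blob_sd <- stats::runif(n_blobs, 0.15, 0.35) * cell_px
    jit <- cbind(stats::rnorm(n_frames, 0, spec$jitter_sigma_px),
                 stats::rnorm(n_frames, 0, spec$jitter_sigma_px))
    if (spec$jitter_sigma_px == 0) jit[] <- 0
    bg_field <- matrix(0.8, h, w)
    if (spec$background_texture > 0) {
      tex <- gaussian_smooth(matrix(stats::rnorm(h * w), h, w), 5)
      bg_field <- bg_field + spec$background_texture * tex / stats::sd(tex)
    }
    arr <- array(0.8, dim = c(h, w, n_frames))
    for (t in seq_len(n_frames)) {
      s_t <- (s_sup - v_px * (t - 1)) %% L
      mod <- numeric(length(s_t))
      for (b in seq_len(n_blobs)) {
        ds <- abs(s_t - blob_pos[b])
        ds <- pmin(ds, L - ds)
        mod <- mod + blob_amp[b] * exp(-ds^2 / (2 * blob_sd[b]^2))
      }
      mod <- pmin(mod, 1)
      fr <- bg_field
      fr[support] <- bg_field[support] -
        spec$contrast * profile * (0.55 + 0.45 * mod)
      if (any(jit[t, ] != 0)) {
        fr <- warp_rigid(fr, jit[t, 1], jit[t, 2], 0)
        attr(fr, "valid") <- NULL
      }
      if (spec$noise_sigma > 0) {
        fr <- fr + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
      }
      arr[, , t] <- pmin(pmax(fr, 0), 1)
    }
    arr
  })
  vs <- cross_sectional_velocity(spec$va_mm_s, spec$diameter_um)
  truth <- tibble::tibble(
    diameter_um = spec$diameter_um, va_mm_s = spec$va_mm_s,
    vs_mm_s = vs, q_pl_s = volume_flow(vs, spec$diameter_um),
    wsr_per_s = wall_shear_rate(vs, spec$diameter_um),
    slope_px_per_frame = v_px, curve_length_px = L, seed = spec$seed
  )
  list(stack = frame_stack(out, calibration,
                           source_id = sprintf("synthetic_%d", spec$seed)),
       truth = truth)
}

#' Generate a ground-truthed synthetic STI
#'
#' A streak pattern (sinusoid plus seeded Gaussian blobs) advected at a
#' known slope with periodic wraparound along the spatial axis, plus
#' optional Gaussian noise; rows are temporally detrended as [build_sti()]
#' would. The truth is the slope itself.
#'
#' @param slope True streak slope in centreline samples per frame
#'   (positive: motion toward increasing `x`).
#' @param shape `c(X, T)`: samples along the vessel and frame count.
#' @param pattern_wavelength Sinusoid wavelength in samples.
#' @param noise_sigma Additive Gaussian noise level.
#' @param dx_um Micrometres per centreline sample.
#' @param dt_s Seconds per frame.
#' @param seed Integer seed.
#' @return List with `sti` (class `sti`) and `truth` (one-row tibble with
#'   `slope`, `va_mm_s`, `signal_sd`).
#' @export
generate_sti <- function(slope, shape = c(100, 120), pattern_wavelength = 20,
                         noise_sigma = 0, dx_um = 1.5, dt_s = 1 / 60,
                         seed = 1) {
  X <- shape[1]; T <- shape[2]
  stopifnot(X >= 2, T >= 2)
  out <- with_seed(seed, {
    n_blobs <- max(2L, round(X / pattern_wavelength))
    pos <- stats::runif(n_blobs, 0, X)
    amp <- stats::runif(n_blobs, 0.5, 1.5)
    pattern <- function(s) {
      s <- s %% X
      p <- 0.4 * sin(2 * pi * s / pattern_wavelength)
      for (b in seq_len(n_blobs)) {
        ds <- abs(s - pos[b])
        ds <- pmin(ds, X - ds)
        p <- p + amp[b] * exp(-ds^2 / (2 * (pattern_wavelength / 5)^2))
      }
      p
    }
    xs <- seq_len(X) - 1
    M <- vapply(seq_len(T), function(t) pattern(xs - slope * (t - 1)),
                numeric(X))
    sig_sd <- stats::sd(as.vector(M))
    if (noise_sigma > 0) {
      M <- M + matrix(stats::rnorm(X * T, 0, noise_sigma), X, T)
    }
    list(M = M, sig_sd = sig_sd)
  })
  M <- sweep(out$M, 1, rowMeans(out$M))
  sti <- structure(
    list(intensity = M, dx_um = dx_um, dt_s = dt_s,
         segment_id = sprintf("synthetic_sti_%d", seed),
         masked_fraction = 0, flagged = FALSE),
    class = "sti"
  )
  va <- abs(slope) * dx_um / 1000 / dt_s
  list(sti = sti,
       truth = tibble::tibble(slope = slope, va_mm_s = va,
                              signal_sd = out$sig_sd, seed = seed))
}

#' Specification of a synthetic two-arm cohort
#'
#' Defaults mirror the structure of a control-versus-myocardial-infarction
#' study: 56 control and 59 MI subjects, about 34 vessel segments each
#' (spread over four views), arm-specific normal distributions for diameter
#' (control 21.43 +/- 7.57 um, MI 22.32 +/- 7.66 um) and axial velocity
#' (control 0.53 +/- 0.15 mm/s, MI 0.49 +/- 0.17 mm/s), truncated at
#' physical bounds (diameter 4-45 um, velocity at least 0.05 mm/s).
#'
#' @param n_control,n_mi Subjects per arm.
#' @param segments_per_subject Mean segment count per subject (Poisson).
#' @param effect Named list with elements `control` and `mi`, each holding
#'   `d_mean`, `d_sd`, `va_mean`, `va_sd`.
#' @param seed Integer seed.
#' @return Object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(
    n_control = 56, n_mi = 59, segments_per_subject = 34,
    effect = list(
      control = list(d_mean = 21.43, d_sd = 7.57, va_mean = 0.53, va_sd = 0.15),
      mi = list(d_mean = 22.32, d_sd = 7.66, va_mean = 0.49, va_sd = 0.17)
    ),
    seed = 1) {
  stopifnot(n_control >= 0, n_mi >= 0, segments_per_subject > 0)
  stopifnot(all(c("control", "mi") %in% names(effect)))
  structure(list(n_control = n_control, n_mi = n_mi,
                 segments_per_subject = segments_per_subject,
                 effect = effect, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Generate a synthetic cohort table
#'
#' Samples per-subject segment records from the arm distributions of a
#' [synthetic_cohort_spec()], derives cross-sectional velocity, volume flow,
#' wall shear rate and diameter group with the package's conversion
#' formulas, and joins with a subjects table.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return A [cohort_table()] (empty tibble when both arms have 0 subjects).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (spec$n_control + spec$n_mi == 0) {
    rec <- tibble::tibble(subject_id = character(), view_id = character(),
                          segment_id = character(), diameter_um = numeric(),
                          va_mm_s = numeric(), vs_mm_s = numeric(),
                          q_pl_s = numeric(), wsr_per_s = numeric(),
                          group = integer(), quality = numeric(),
                          cohort = character())
    class(rec) <- c("cohort_table", class(rec))
    return(rec)
  }
  with_seed(spec$seed, {
    arms <- list(control = spec$n_control, mi = spec$n_mi)
    prefix <- c(control = "C", mi = "M")
    rec_list <- list()
    subj_list <- list()
    for (arm in names(arms)) {
      eff <- spec$effect[[arm]]
      for (i in seq_len(arms[[arm]])) {
        sid <- sprintf("%s%03d", prefix[[arm]], i)
        nseg <- max(1L, stats::rpois(1, spec$segments_per_subject))
        d <- rnorm_trunc(nseg, eff$d_mean, eff$d_sd, 4, 45)
        va <- rnorm_trunc(nseg, eff$va_mean, eff$va_sd, 0.05, Inf)
        rec_list[[length(rec_list) + 1]] <- tibble::tibble(
          subject_id = sid,
          view_id = sprintf("v%d", sample.int(4, nseg, replace = TRUE)),
          segment_id = sprintf("%s_seg%03d", sid, seq_len(nseg)),
          diameter_um = d, va_mm_s = va
        )
        subj_list[[length(subj_list) + 1]] <- tibble::tibble(
          subject_id = sid, cohort = arm)
      }
    }
    records <- dplyr::bind_rows(rec_list)
    records <- dplyr::mutate(
      records,
      vs_mm_s = cross_sectional_velocity(.data$va_mm_s, .data$diameter_um),
      q_pl_s = volume_flow(.data$vs_mm_s, .data$diameter_um),
      wsr_per_s = wall_shear_rate(.data$vs_mm_s, .data$diameter_um),
      group = assign_group(.data$diameter_um),
      quality = 1
    )
    cohort_table(records, dplyr::bind_rows(subj_list))
  })
}
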