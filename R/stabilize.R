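#' Frame sharpness score
#'
#' Variance of the Laplacian-filtered frame, the classical focus measure: a
#' sharp frame has strong second derivatives everywhere detail exists, and
#' any Gaussian blurring strictly reduces them. A constant frame scores 0.
#'
#' @param frame Numeric matrix of intensities.
#' @return Non-negative scalar.
#' @export
sharpness_score <- function(frame) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  h <- nrow(frame); w <- ncol(frame)
  if (h < 3 || w < 3) return(0)
  i <- 2:(h - 1); j <- 2:(w - 1)
  lap <- frame[i - 1, j] + frame[i + 1, j] + frame[i, j - 1] + frame[i, j + 1] -
    4 * frame[i, j]
  v <- stats::var(as.vector(lap))
  if (!is.finite(v)) 0 else v
}

#' Select the sharpest frame of a stack
#'
#' The sharpest frame serves as the registration reference. Ties are broken
#' toward the lowest index.
#'
#' @param stack A [frame_stack()].
#' @return 1-based frame index.
#' @export
select_reference <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  scores <- vapply(seq_len(n_frames(stack)),
                   function(t) sharpness_score(stack$frames[, , t]), numeric(1))
  which.max(scores)
}

# Sub-pixel translation of `frame` by phase correlation against `ref`.
# Returns c(dy, dx): the shift that maps `frame` onto `ref`. The peak
# search is restricted to |shift| <= max_shift: eye motion between frames
# is bounded, and an unbounded search can lock onto moving intravascular
# texture instead of the static scene.
phase_correlate <- function(ref, frame, max_shift = Inf, eps = 1e-12) {
  Fr <- stats::fft(ref)
  Ff <- stats::fft(frame)
  R <- Fr * Conj(Ff)
  R <- R / (Mod(R) + eps)
  corr <- Re(stats::fft(R, inverse = TRUE))
  h <- nrow(corr); w <- ncol(corr)
  search <- corr
  if (is.finite(max_shift)) {
    ky <- pmin(0:(h - 1), h - 0:(h - 1))
    kx <- pmin(0:(w - 1), w - 0:(w - 1))
    search[ky > max_shift, ] <- -Inf
    search[, kx > max_shift] <- -Inf
  }
  k <- which.max(search)
  py <- (k - 1) %% h + 1
  px <- (k - 1) %/% h + 1
  # 3-point parabolic refinement on the wrapped correlation surface
  wrap <- function(i, n) ((i - 1) %% n) + 1
  sub_fit <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (abs(den) < eps) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  fy <- sub_fit(corr[wrap(py - 1, h), px], corr[py, px], corr[wrap(py + 1, h), px])
  fx <- sub_fit(corr[py, wrap(px - 1, w)], corr[py, px], corr[py, wrap(px + 1, w)])
  dy <- (py - 1) + fy; dx <- (px - 1) + fx
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(dy = dy, dx = dx)
}

# Rigid warp with bilinear interpolation. (dy, dx) in pixels, theta in
# degrees, rotation about the frame centre; the transform maps the input
# onto the reference grid. Out-of-bounds samples are filled by edge
# replication; `attr(,"valid")` marks in-bounds pixels.
warp_rigid <- function(frame, dy, dx, theta_deg = 0) {
  h <- nrow(frame); w <- ncol(frame)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- theta_deg * pi / 180
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  # inverse map: output (y,x) -> source coords
  y0 <- yy - dy - cy; x0 <- xx - dx - cx
  sy <- cos(th) * y0 - sin(th) * x0 + cy
  sx <- sin(th) * y0 + cos(th) * x0 + cx
  valid <- sy >= 1 & sy <= h & sx >= 1 & sx <= w
  sy <- pmin(pmax(sy, 1), h)
  sx <- pmin(pmax(sx, 1), w)
  iy <- pmin(floor(sy), h - 1); ix <- pmin(floor(sx), w - 1)
  fy <- sy - iy; fx <- sx - ix
  idx <- function(a, b) frame[cbind(as.vector(a), as.vector(b))]
  out <- (1 - fy) * (1 - fx) * idx(iy, ix) +
    (1 - fy) * fx * idx(iy, ix + 1) +
    fy * (1 - fx) * idx(iy + 1, ix) +
    fy * fx * idx(iy + 1, ix + 1)
  out <- matrix(out, h, w)
  attr(out, "valid") <- valid
  out
}

register_frame <- function(ref, frame, max_rotation_deg, rotation_step_deg,
                           max_shift = Inf) {
  angles <- 0
  if (max_rotation_deg > 0) {
    angles <- unique(c(0, seq(-max_rotation_deg, max_rotation_deg,
                              by = rotation_step_deg)))
  }
  best <- NULL
  for (th in angles) {
    fr <- if (th == 0) frame else {
      w <- warp_rigid(frame, 0, 0, th)
      attr(w, "valid") <- NULL
      w
    }
    sh <- phase_correlate(ref, fr, max_shift = max_shift)
    warped <- warp_rigid(frame, sh["dy"], sh["dx"], th)
    mse <- mean((warped - ref)^2)
    if (is.null(best) || mse < best$mse) {
      best <- list(dy = unname(sh["dy"]), dx = unname(sh["dx"]), theta = th,
                   mse = mse, frame = warped)
    }
  }
  best
}

#' Register a frame stack to a reference frame
#'
#' Rigid (translation + rotation) intensity-based registration of every frame
#' to the chosen reference: translation by sub-pixel phase correlation,
#' rotation by grid search over a small angular range, the candidate with the
#' lowest mean-squared intensity error winning. The reference frame passes
#' through bit-exact with an identity transform. A frame whose registered
#' residual exceeds its unregistered residual is flagged and passed through
#' untransformed rather than silently degraded.
#'
#' Out-of-bounds pixels created by warping are filled by edge replication;
#' the returned `valid_mask` marks pixels in-bounds in at least 90% of
#' frames so that downstream spatio-temporal sampling can avoid
#' persistently replicated borders without one badly-registered frame
#' poisoning the mask.
#'
#' @param stack A [frame_stack()].
#' @param reference Reference frame index; default [select_reference()].
#' @param max_rotation_deg Half-width of the rotation search (degrees);
#'   0 disables rotation.
#' @param rotation_step_deg Grid step of the rotation search.
#' @param max_shift_px Largest translation searched, in pixels; defaults to
#'   a quarter of the smaller frame dimension. Bounding the search keeps
#'   the correlation peak from locking onto moving intravascular texture.
#' @return A list with `stack` (the stabilized [frame_stack()]) and
#'   `registration`, a list of class `registration_result` holding
#'   `reference_index`, a tibble `transforms`
#'   (`frame`, `dy_px`, `dx_px`, `theta_deg`, `residual`, `flagged`) and
#'   `valid_mask`.
#' @export
register_stack <- function(stack, reference = NULL,
                           max_rotation_deg = 2, rotation_step_deg = 0.5,
                           max_shift_px = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  T <- n_frames(stack)
  if (is.null(reference)) reference <- select_reference(stack)
  stopifnot(reference >= 1, reference <= T)
  ref <- stack$frames[, , reference]
  if (is.null(max_shift_px)) max_shift_px <- min(dim(ref)) / 4
  out <- stack$frames
  invalid_count <- matrix(0L, nrow(ref), ncol(ref))
  rows <- vector("list", T)
  for (t in seq_len(T)) {
    if (t == reference) {
      rows[[t]] <- list(frame = t, dy_px = 0, dx_px = 0, theta_deg = 0,
                        residual = 0, flagged = FALSE)
      next
    }
    fr <- stack$frames[, , t]
    pre_mse <- mean((fr - ref)^2)
    reg <- register_frame(ref, fr, max_rotation_deg, rotation_step_deg,
                          max_shift = max_shift_px)
    if (reg$mse <= pre_mse * 1.05) {
      out[, , t] <- reg$frame
      invalid_count <- invalid_count + !attr(reg$frame, "valid")
      rows[[t]] <- list(frame = t, dy_px = reg$dy, dx_px = reg$dx,
                        theta_deg = reg$theta, residual = reg$mse,
                        flagged = FALSE)
    } else {
      rows[[t]] <- list(frame = t, dy_px = 0, dx_px = 0, theta_deg = 0,
                        residual = pre_mse, flagged = TRUE)
    }
  }
  transforms <- dplyr::bind_rows(rows)
  n_flag <- sum(transforms$flagged)
  if (n_flag > 0) {
    message(n_flag, " frame(s) failed to improve under registration; passed through unchanged")
  }
  # a pixel stays usable if it was in-bounds in at least 90% of frames;
  # one badly-estimated frame must not poison the whole mask
  reg_res <- structure(
    list(reference_index = reference, transforms = transforms,
         valid_mask = invalid_count <= ceiling(0.1 * T)),
    class = "registration_result"
  )
  list(stack = frame_stack(out, stack$calibration, stack$source_id),
       registration = reg_res)
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> reference frame %d, %d transforms, %d flagged\n",
              x$reference_index, nrow(x$transforms), sum(x$transforms$flagged)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.registration_result <- function(x, ...) x$transforms
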