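# Shared fixtures: all synthetic, built in code at test time.

cal_2um <- function() calibration_profile(2.0, 60)
cal_1um <- function() calibration_profile(1.0, 60)

# Hard-edged dark band of width w at angle theta through the frame centre.
band_frame <- function(n, w, theta_deg, lo = 0.3, hi = 0.8) {
  th <- theta_deg * pi / 180
  cy <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  d <- abs(-sin(th) * (xx - cy) + cos(th) * (yy - cy))
  m <- matrix(hi, n, n)
  m[d <= w / 2] <- lo
  m
}

# Ground-truth band membership mask for band_frame geometry.
band_truth_mask <- function(n, w, theta_deg) {
  band_frame(n, w, theta_deg, lo = 1, hi = 0) > 0
}

# Textured frame with reproducible detail for sharpness/registration tests.
texture_frame <- function(n, seed = 1) {
  set.seed(seed)
  f <- matrix(runif(n * n), n, n)
  as.matrix(EBImage::gblur(f, sigma = 1)) * 0.8 + 0.1
}

# A vector of paired differences rescaled to an exact sample SD and mean.
diffs_with_sd <- function(n, target_sd, target_mean = 0, seed = 1) {
  set.seed(seed)
  d <- rnorm(n)
  (d - mean(d)) / sd(d) * target_sd + target_mean
}
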