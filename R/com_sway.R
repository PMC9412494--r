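#' Center-of-mass proxy trajectory (hip midpoint)
#'
#' The body's center of mass is approximated by the midpoint of the left
#' and right hip joints (`COM_HIP`), computed pointwise over the window.
#'
#' @param win A `gait_window` (or any sequence carrying both hips).
#' @return List with `t` and `xyz` (`n x 3`, mm) of the midpoint.
#' @export
com_trajectory <- function(win) {
  l <- win$xyz[, , "HIP_L"]
  r <- win$xyz[, , "HIP_R"]
  list(t = win$t, xyz = (l + r) / 2)
}

#' Mediolateral and vertical sway of the center of mass
#'
#' Sway is the maximum absolute oscillation away from straight walking
#' toward the sensor. The straight reference is a per-trial line of the
#' lateral (`x`) or vertical (`y`) coordinate against the forward coordinate
#' (`z`); `ML_SWAY` and `V_SWAY` are the maximum absolute deviations from
#' those lines, in mm. Fitting against `z` (not time) makes the reference
#' the actual walking line, so walking at a constant angle to the camera
#' axis does not inflate the lateral sway.
#'
#' The reference line is estimated jointly with a first-harmonic term at the
#' dominant oscillation frequency (chosen by a coarse-to-fine least-squares
#' scan over 0.3-3 Hz, the stride-to-step band of adult gait) under a robust
#' bisquare loss.
#' The harmonic term keeps the periodic gait oscillation from tilting the
#' line on the short analysis window, and the robust loss keeps one-sided
#' excursions from dragging it; both are then measured in full, because the
#' sway is the deviation from the *line component only*. An ordinary
#' least-squares line over the 2 m corridor (one to three oscillation
#' periods) would over-read a pure sinusoidal sway by 8-16%.
#'
#' @param com Trajectory from [com_trajectory()] (needs >= 10 samples and a
#'   forward progression of at least 0.2 m).
#' @return List of class `com_sway_params`: `ML_SWAY`, `V_SWAY` (mm) and the
#'   input trajectory (for plotting/QA).
#' @export
sway_params <- function(com) {
  n <- nrow(com$xyz)
  if (is.null(n) || n < 10)
    kg_stop("need at least 10 samples for sway estimation",
            "kinegait_insufficient_data")
  z <- com$xyz[, "z"]
  if (diff(range(z)) < 200)
    kg_stop("forward progression under 0.2 m; cannot fit reference line",
            "kinegait_insufficient_progress")
  structure(list(ML_SWAY = max_line_deviation(com$t, z, com$xyz[, "x"]),
                 V_SWAY = max_line_deviation(com$t, z, com$xyz[, "y"]),
                 trajectory = com),
            class = "com_sway_params")
}

# Maximum absolute deviation of v from its straight reference line in z.
# The line is fit robustly together with a first-harmonic regressor so that
# neither the periodic sway nor an isolated excursion tilts it.
max_line_deviation <- function(t, z, v) {
  ls <- stats::lm.fit(cbind(1, z), v)
  if (max(abs(ls$residuals)) < 1e-9) return(max(abs(ls$residuals)))
  # coarse-to-fine scan for the dominant oscillation frequency (0.3-3 Hz
  # covers stride and step rates of adult gait), scored by least squares
  rss_at <- function(f)
    sum(stats::lm.fit(cbind(1, z, sin(2 * pi * f * t),
                            cos(2 * pi * f * t)), v)$residuals^2)
  coarse <- seq(0.3, 3, by = 0.05)
  f1 <- coarse[which.min(vapply(coarse, rss_at, numeric(1)))]
  fine <- seq(max(0.3, f1 - 0.05), f1 + 0.05, by = 0.005)
  f_star <- fine[which.min(vapply(fine, rss_at, numeric(1)))]
  X <- cbind(1, z, sin(2 * pi * f_star * t), cos(2 * pi * f_star * t))
  fit <- tryCatch(
    suppressWarnings(MASS::rlm(X, v, psi = MASS::psi.bisquare, maxit = 60)),
    error = function(e) NULL)
  best <- if (is.null(fit)) ls$coefficients else fit$coefficients
  max(abs(v - best[1] - best[2] * z))
}
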