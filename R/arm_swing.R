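#' Wrist displacement relative to the pelvis
#'
#' Decomposes the wrist trajectory into body-referenced components, in mm:
#' * `AP` (anteroposterior): `pelvis_z - wrist_z`, positive when the wrist
#'   is anterior (closer to the camera than the pelvis);
#' * `ML` (mediolateral): `wrist_x - pelvis_x`;
#' * `UD` (up-down): `wrist_y - pelvis_y`.
#'
#' @param win A `gait_window`.
#' @param side `"L"` or `"R"`.
#' @return `n x 3` matrix with columns `AP`, `ML`, `UD` (mm).
#' @export
wrist_relative_series <- function(win, side) {
  side <- match.arg(side, c("L", "R"))
  w <- win$xyz[, , paste0("WRIST_", side)]
  p <- win$xyz[, , "PELVIS"]
  cbind(AP = p[, "z"] - w[, "z"],
        ML = w[, "x"] - p[, "x"],
        UD = w[, "y"] - p[, "y"])
}

#' Linear arm-swing metrics from a relative wrist series
#'
#' Per direction `d` in AP/ML/UD: `SWAY_ANT_d` is the maximum of the
#' component (peak anterior/leftward/upward excursion), `SWAY_POS_d` the
#' minimum, and `SWAY_RANGE_d = SWAY_ANT_d - SWAY_POS_d` the peak-to-peak
#' swing amplitude. `PATH_TOT` is the total 3D distance travelled by the
#' wrist (relative to the pelvis) inside the window; `SWAY_AREA` the area of
#' the 2D convex hull of the (AP, ML) points; `SPEED_AP` the maximum
#' absolute central-difference velocity of the AP component.
#'
#' @param rel Matrix from [wrist_relative_series()] (>= 10 samples).
#' @param dt Sample spacing in seconds (default 0.02, the 50 Hz grid).
#' @return Named numeric vector (mm, mm^2, mm/s).
#' @export
linear_metrics <- function(rel, dt = 0.02) {
  if (nrow(rel) < 10)
    kg_stop("need at least 10 samples", "kinegait_insufficient_data")
  out <- c()
  for (d in c("AP", "ML", "UD")) {
    v <- rel[, d]
    out[paste0("SWAY_ANT_", d)] <- max(v)
    out[paste0("SWAY_POS_", d)] <- min(v)
    out[paste0("SWAY_RANGE_", d)] <- max(v) - min(v)
  }
  out["PATH_TOT"] <- sum(sqrt(rowSums(diff(rel)^2)))
  out["SWAY_AREA"] <- hull_area(rel[, "AP"], rel[, "ML"])
  ap <- rel[, "AP"]
  n <- length(ap)
  vel <- (ap[3:n] - ap[1:(n - 2)]) / (2 * dt)
  out["SPEED_AP"] <- max(abs(vel))
  out
}

# Convex hull area by the shoelace formula; degenerate point sets get 0.
hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) {
    kg_warn("fewer than 3 distinct points; SWAY_AREA set to 0",
            "kinegait_degenerate_hull")
    return(0)
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) {
    kg_warn("collinear points; SWAY_AREA set to 0",
            "kinegait_degenerate_hull")
    return(0)
  }
  hx <- pts[h, 1]; hy <- pts[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Angular arm-swing metrics (sagittal shoulder-arm angle)
#'
#' The arm vector (wrist minus shoulder) and the same-side trunk vector (hip
#' minus shoulder) are projected onto the sagittal plane (AP-UD, i.e. z-y);
#' the signed planar angle between the projections is positive when the arm
#' is anterior of the trunk line. `ANGLE_ANT` is the maximum (peak forward
#' swing), `ANGLE_POS` the minimum (peak backward swing), and
#' `ANGLE_RANGE = ANGLE_ANT - ANGLE_POS`, all in degrees. Samples where
#' either projected vector is shorter than 10 mm are excluded (a warning is
#' raised if more than 5% are).
#'
#' @param win A `gait_window`.
#' @param side `"L"` or `"R"`.
#' @return Named numeric vector `ANGLE_ANT`, `ANGLE_POS`, `ANGLE_RANGE`
#'   (degrees).
#' @export
angular_metrics <- function(win, side) {
  side <- match.arg(side, c("L", "R"))
  sh <- win$xyz[, , paste0("SHOULDER_", side)]
  wr <- win$xyz[, , paste0("WRIST_", side)]
  hp <- win$xyz[, , paste0("HIP_", side)]
  # sagittal projections: (z, y) components
  az <- wr[, "z"] - sh[, "z"]; ay <- wr[, "y"] - sh[, "y"]
  tz <- hp[, "z"] - sh[, "z"]; ty <- hp[, "y"] - sh[, "y"]
  na <- sqrt(az^2 + ay^2)
  nt <- sqrt(tz^2 + ty^2)
  ok <- na >= 10 & nt >= 10
  if (!any(ok))
    kg_stop("projected arm/trunk vectors degenerate throughout window",
            "kinegait_insufficient_data")
  if (mean(!ok) > 0.05)
    kg_warn(sprintf("%.0f%% of samples excluded for near-zero projections",
                    100 * mean(!ok)),
            "kinegait_degenerate_samples")
  # signed angle, positive when the arm points anterior (-z) of the trunk
  ang <- atan2(ty[ok] * az[ok] - tz[ok] * ay[ok],
               tz[ok] * az[ok] + ty[ok] * ay[ok]) * 180 / pi
  c(ANGLE_ANT = max(ang), ANGLE_POS = min(ang),
    ANGLE_RANGE = max(ang) - min(ang))
}

#' All arm-swing metrics for one side
#'
#' Convenience wrapper combining [linear_metrics()] and [angular_metrics()].
#'
#' @param win A `gait_window`.
#' @param side `"L"` or `"R"`.
#' @return Named numeric vector of the full per-arm parameter set.
#' @export
arm_swing_params <- function(win, side) {
  rel <- wrist_relative_series(win, side)
  c(linear_metrics(rel, dt = 1 / win$rate), angular_metrics(win, side))
}

#' Absolute symmetry angle (ASA)
#'
#' Quantifies left/right asymmetry of a positive gait parameter:
#' \deqn{ASA = |(45° − \arctan(P_{MORE}/P_{LESS})) / 90°| \times 100\%}
#' where \eqn{P_{MORE}} and \eqn{P_{LESS}} are the larger and smaller of the
#' two sides' values. ASA is 0% for perfect symmetry and approaches the
#' supremum 50% as one side vanishes (`p_less = 0` returns exactly 50). It
#' is symmetric in its arguments and scale-invariant:
#' `asa(k*x, k*y) == asa(x, y)` for any `k > 0`.
#'
#' @param p_left,p_right Non-negative parameter values for the two sides
#'   (not both zero). Vectorized.
#' @return ASA in percent, in `[0, 50]`.
#' @export
#' @examples
#' asa(40.34, 18.06)  # ~23.2%
#' asa(3, 3)          # 0: perfect symmetry
asa <- function(p_left, p_right) {
  if (any(p_left < 0) || any(p_right < 0))
    kg_stop("ASA inputs must be non-negative", "kinegait_domain_error")
  if (any(p_left == 0 & p_right == 0))
    kg_stop("ASA undefined when both sides are zero",
            "kinegait_undefined_asymmetry")
  p_more <- pmax(p_left, p_right)
  p_less <- pmin(p_left, p_right)
  abs((45 - atan2(p_more, p_less) * 180 / pi) / 90) * 100
}

#' Arm-swing asymmetry indices for a trial
#'
#' Applies [asa()] to the three representative per-arm amplitude parameters:
#' * `ASA_ANGLE` over the two sides' `ANGLE_RANGE`,
#' * `ASA_PATH` over `PATH_TOT`,
#' * `ASA_AP_RANGE` over `SWAY_RANGE_AP`.
#'
#' @param left,right Per-arm parameter vectors from [arm_swing_params()].
#' @return Named numeric vector of the three indices, in percent.
#' @export
asymmetry_indices <- function(left, right) {
  c(ASA_ANGLE = asa(left[["ANGLE_RANGE"]], right[["ANGLE_RANGE"]]),
    ASA_PATH = asa(left[["PATH_TOT"]], right[["PATH_TOT"]]),
    ASA_AP_RANGE = asa(left[["SWAY_RANGE_AP"]], right[["SWAY_RANGE_AP"]]))
}

#' Limb synchrony indices
#'
#' Pearson correlations between anteroposterior limb signals inside the
#' window:
#' * `SI_ARMS`: between the left and right wrist-relative-pelvis AP series.
#'   Arms swing in opposition during healthy gait, so values near -1
#'   indicate strong arm-arm synchrony.
#' * `SI_ARM_LEG_L` / `SI_ARM_LEG_R`: between the z-component of one side's
#'   arm segment (`wrist_z - shoulder_z`) and the z-component of the
#'   opposite leg segment (`ankle_z - hip_z`). The opposite arm and leg move
#'   forward together, so healthy gait yields positive values;
#'   `SI_ARM_LEG` is their mean.
#'
#' @param win A `gait_window` with >= 25 samples.
#' @return Named numeric vector `SI_ARMS`, `SI_ARM_LEG_L`, `SI_ARM_LEG_R`,
#'   `SI_ARM_LEG`, each in `[-1, 1]`.
#' @export
synchrony_indices <- function(win) {
  if (length(win$t) < 25)
    kg_stop("need at least 25 samples for synchrony indices",
            "kinegait_insufficient_data")
  ap_l <- wrist_relative_series(win, "L")[, "AP"]
  ap_r <- wrist_relative_series(win, "R")[, "AP"]
  seg <- function(joint_a, joint_b)
    jcoord(win, joint_a, "z") - jcoord(win, joint_b, "z")
  arm <- list(L = seg("WRIST_L", "SHOULDER_L"), R = seg("WRIST_R", "SHOULDER_R"))
  leg <- list(L = seg("ANKLE_L", "HIP_L"), R = seg("ANKLE_R", "HIP_R"))
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      kg_stop("zero-variance series; correlation undefined",
              "kinegait_undefined_correlation")
    stats::cor(a, b)
  }
  si_al <- c(L = safe_cor(arm$L, leg$R), R = safe_cor(arm$R, leg$L))
  c(SI_ARMS = safe_cor(ap_l, ap_r),
    SI_ARM_LEG_L = si_al[["L"]], SI_ARM_LEG_R = si_al[["R"]],
    SI_ARM_LEG = mean(si_al))
}
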