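#' Configuration for the synthetic walking simulator
#'
#' Defines one simulated walking trial toward the camera along a walkway,
#' with closed-form ground truth for every parameter the pipeline estimates.
#' Defaults approximate a healthy adult walking at a comfortable pace in
#' front of a ~30 fps depth sensor.
#'
#' @param step_length_m Step length (m, default 0.60).
#' @param step_time_s Step duration (s, default 0.55); the stride period is
#'   twice this and the walking speed is `step_length_m / step_time_s`.
#' @param stance_fraction Fraction of the gait cycle spent in stance per
#'   foot (default 0.62).
#' @param start_z_m,end_z_m Pelvis distance from the camera at the start and
#'   end of the trial (m; defaults 5.5 and 1.0).
#' @param walkway_length_m Physical walkway length (m, default 10); purely
#'   descriptive metadata.
#' @param arm_amp_deg Length-2 vector `c(L, R)` of sagittal arm-swing
#'   angular amplitudes in degrees (default `c(25, 25)`); the angular range
#'   of each arm is twice its amplitude.
#' @param arm_anterior_split Fraction of each arm's angular range that lies
#'   anterior of the trunk line (default 0.5, symmetric swing).
#' @param arm_length_mm Shoulder-to-wrist distance (mm, default 550).
#' @param com_ml_amp_mm,com_v_amp_mm Lateral and vertical center-of-mass
#'   oscillation amplitudes (mm; defaults 55 and 40). Lateral sway runs at
#'   the stride frequency, vertical at the step frequency.
#' @param fps_mean Mean camera frame rate (fps, default 30).
#' @param jitter_sd_s Standard deviation of the frame-interval jitter
#'   (s, default 0.003).
#' @param noise_sd_mm Isotropic Gaussian positional noise added to every
#'   joint coordinate (mm, default 2).
#' @param seed Integer random seed; fixes the full trial output.
#' @param subject_id,group Metadata carried into the trial.
#' @return A `synth_config` list.
#' @export
synth_config <- function(step_length_m = 0.60, step_time_s = 0.55,
                         stance_fraction = 0.62,
                         start_z_m = 5.5, end_z_m = 1.0,
                         walkway_length_m = 10,
                         arm_amp_deg = c(L = 25, R = 25),
                         arm_anterior_split = 0.5,
                         arm_length_mm = 550,
                         com_ml_amp_mm = 55, com_v_amp_mm = 40,
                         fps_mean = 30, jitter_sd_s = 0.003,
                         noise_sd_mm = 2, seed = 1L,
                         subject_id = "synthetic", group = "") {
  if (length(arm_amp_deg) == 1) arm_amp_deg <- c(L = arm_amp_deg, R = arm_amp_deg)
  names(arm_amp_deg) <- c("L", "R")
  cfg <- list(step_length_m = step_length_m, step_time_s = step_time_s,
              stance_fraction = stance_fraction,
              start_z_m = start_z_m, end_z_m = end_z_m,
              walkway_length_m = walkway_length_m,
              arm_amp_deg = arm_amp_deg,
              arm_anterior_split = arm_anterior_split,
              arm_length_mm = arm_length_mm,
              com_ml_amp_mm = com_ml_amp_mm, com_v_amp_mm = com_v_amp_mm,
              fps_mean = fps_mean, jitter_sd_s = jitter_sd_s,
              noise_sd_mm = noise_sd_mm, seed = as.integer(seed),
              subject_id = subject_id, group = group)
  if (any(c(arm_amp_deg, com_ml_amp_mm, com_v_amp_mm, noise_sd_mm) < 0))
    kg_stop("amplitudes and noise must be non-negative",
            "kinegait_config_error")
  if (stance_fraction <= 0 || stance_fraction >= 1)
    kg_stop("stance_fraction must lie in (0, 1)", "kinegait_config_error")
  if (start_z_m <= end_z_m)
    kg_stop("start_z_m must exceed end_z_m", "kinegait_config_error")
  v <- step_length_m / step_time_s
  if ((start_z_m - end_z_m) / v < 2 * step_time_s)
    kg_stop("configuration implies less than one full stride",
            "kinegait_config_error")
  structure(cfg, class = "synth_config")
}

# Fixed body geometry (mm offsets from the pelvis).
BODY <- list(hip_halfwidth = 70, shoulder_halfwidth = 180,
             shoulder_height = 450, pelvis_height = 900, ankle_height = 80)

# Swing-phase ankle transport profile on tau in [0,1]: a blend of linear
# and cosine-ramp motion. The linear share keeps the foot's landing/lift-off
# velocity above the pelvis velocity, so the extrema of the pelvis-relative
# ankle position coincide with the true foot-contact times (a pure cosine
# ramp, with zero endpoint velocity, would drift those extrema into swing
# and bias stance-duration estimates).
swing_ramp <- function(tau, alpha = 0.6) {
  alpha * tau + (1 - alpha) * (1 - cos(pi * tau)) / 2
}

#' Generate a synthetic walking trial with ground truth
#'
#' Simulates a subject walking toward the camera: the pelvis advances at
#' constant speed with sinusoidal lateral (stride-frequency) and vertical
#' (step-frequency) center-of-mass motion; the ankles alternate stance
#' (anteroposterior position frozen) and swing (smooth forward transport)
#' phases with the configured stance fraction; the wrists swing as sagittal
#' pendulums of the configured per-side amplitude, anti-phase between arms
#' and in phase with the contralateral leg; the remaining joints ride
#' rigidly on the pelvis or their parent segment. Frame timestamps are drawn
#' at the jittered frame rate and isotropic Gaussian positional noise is
#' added last, so the ground truth stays closed-form. The caller's RNG state
#' is left untouched; `cfg$seed` fully determines the output.
#'
#' @param cfg A [synth_config()].
#' @return List with `seq` (a [skeleton_sequence()]) and `truth`, the exact
#'   parameter values implied by the configuration (step length/time,
#'   cadence, gait velocity, stance/double-support, per-side angular ranges
#'   and AP sway ranges, ASA indices, COM sway amplitudes, and per-side
#'   heel-strike/toe-off times).
#' @export
generate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  L <- cfg$step_length_m * 1000
  T_step <- cfg$step_time_s
  S <- 2 * T_step
  sf <- cfg$stance_fraction
  v <- L / T_step                       # mm/s
  start_z <- cfg$start_z_m * 1000
  D <- (cfg$start_z_m - cfg$end_z_m) * 1000 / v
  with_preserved_seed(cfg$seed, {
    # jittered timestamps
    dts <- c()
    while (sum(dts) < D) {
      dts <- c(dts, pmax(0.005,
                         stats::rnorm(64, 1 / cfg$fps_mean, cfg$jitter_sd_s)))
    }
    t <- cumsum(c(0, dts))
    t <- t[t <= D]
    n <- length(t)

    pelvis_z <- start_z - v * t
    pelvis_x <- cfg$com_ml_amp_mm * sin(2 * pi * t / S)
    pelvis_y <- BODY$pelvis_height + cfg$com_v_amp_mm * sin(4 * pi * t / S)

    # heel-strike schedule: right foot strikes at h_R0 + k*S, left offset by T
    h_R0 <- 0.3 * S
    hs_times <- function(h0) {
      k <- seq(floor((-2 * S - h0) / S), ceiling((D + 2 * S - h0) / S))
      h0 + k * S
    }
    hs <- list(L = hs_times(h_R0 + T_step), R = hs_times(h_R0))

    ankle_z_series <- function(h) {
      # stance position after strike at h_k: lead of L/2 ahead of the pelvis
      zk <- (start_z - v * h) - L / 2
      vapply(t, function(ti) {
        k <- max(which(h <= ti))
        t_off <- h[k] + sf * S
        if (ti < t_off) zk[k]
        else {
          tau <- (ti - t_off) / ((1 - sf) * S)
          zk[k] - 2 * L * swing_ramp(tau)
        }
      }, numeric(1))
    }
    ankle_z <- list(L = ankle_z_series(hs$L), R = ankle_z_series(hs$R))

    # sagittal arm pendulum, anterior max of the left arm at right heel strikes
    A <- cfg$arm_amp_deg * pi / 180
    off <- (2 * cfg$arm_anterior_split - 1) * A
    phase <- 2 * pi * (t - h_R0) / S
    theta <- list(L = off[["L"]] + A[["L"]] * cos(phase),
                  R = off[["R"]] - A[["R"]] * cos(phase))

    joints <- kinect_joints()
    xyz <- array(0, dim = c(n, 3, 32),
                 dimnames = list(NULL, c("x", "y", "z"), joints))
    set_j <- function(name, x, y, z) {
      xyz[, "x", name] <<- x; xyz[, "y", name] <<- y; xyz[, "z", name] <<- z
    }
    set_j("PELVIS", pelvis_x, pelvis_y, pelvis_z)
    set_j("SPINE_NAVEL", pelvis_x, pelvis_y + 150, pelvis_z)
    set_j("SPINE_CHEST", pelvis_x, pelvis_y + 300, pelvis_z)
    set_j("NECK", pelvis_x, pelvis_y + 550, pelvis_z)
    set_j("HEAD", pelvis_x, pelvis_y + 700, pelvis_z)
    set_j("NOSE", pelvis_x, pelvis_y + 720, pelvis_z - 100)
    for (s in c("L", "R")) {
      sgn <- if (s == "L") 1 else -1
      hip_x <- pelvis_x + sgn * BODY$hip_halfwidth
      set_j(paste0("HIP_", s), hip_x, pelvis_y, pelvis_z)
      sh_x <- pelvis_x + sgn * BODY$shoulder_halfwidth
      sh_y <- pelvis_y + BODY$shoulder_height
      set_j(paste0("SHOULDER_", s), sh_x, sh_y, pelvis_z)
      set_j(paste0("CLAVICLE_", s), pelvis_x + sgn * 90, pelvis_y + 520,
            pelvis_z)
      wr_y <- sh_y - cfg$arm_length_mm * cos(theta[[s]])
      wr_z <- pelvis_z - cfg$arm_length_mm * sin(theta[[s]])
      set_j(paste0("WRIST_", s), sh_x, wr_y, wr_z)
      set_j(paste0("ELBOW_", s), sh_x, (sh_y + wr_y) / 2, (pelvis_z + wr_z) / 2)
      dir_y <- (wr_y - sh_y) / cfg$arm_length_mm
      dir_z <- (wr_z - pelvis_z) / cfg$arm_length_mm
      set_j(paste0("HAND_", s), sh_x, wr_y + 80 * dir_y, wr_z + 80 * dir_z)
      set_j(paste0("HANDTIP_", s), sh_x, wr_y + 160 * dir_y, wr_z + 160 * dir_z)
      set_j(paste0("THUMB_", s), sh_x + sgn * 30, wr_y + 40 * dir_y,
            wr_z + 40 * dir_z)
      set_j(paste0("EYE_", s), pelvis_x + sgn * 30, pelvis_y + 710,
            pelvis_z - 80)
      set_j(paste0("EAR_", s), pelvis_x + sgn * 70, pelvis_y + 700, pelvis_z)
      az <- ankle_z[[s]]
      set_j(paste0("ANKLE_", s), hip_x, BODY$ankle_height, az)
      set_j(paste0("KNEE_", s), hip_x,
            (pelvis_y + BODY$ankle_height) / 2, (pelvis_z + az) / 2)
      set_j(paste0("FOOT_", s), hip_x, BODY$ankle_height - 40, az - 120)
    }
    if (cfg$noise_sd_mm > 0)
      xyz <- xyz + array(stats::rnorm(length(xyz), 0, cfg$noise_sd_mm),
                         dim = dim(xyz))
    conf <- matrix(1, n, 32, dimnames = list(NULL, joints))
    seq <- skeleton_sequence(t, xyz, conf = conf,
                             subject_id = cfg$subject_id,
                             trial_id = cfg$seed, group = cfg$group)
    truth <- synth_truth(cfg, hs, D)
    list(seq = seq, truth = truth)
  })
}

# Closed-form parameter values implied by a configuration.
synth_truth <- function(cfg, hs, D) {
  T_step <- cfg$step_time_s
  S <- 2 * T_step
  sf <- cfg$stance_fraction
  A <- cfg$arm_amp_deg
  off <- (2 * cfg$arm_anterior_split - 1) * A
  ang_ant <- off + A
  ang_pos <- off - A
  deg2 <- function(d) d * pi / 180
  ap_ant <- cfg$arm_length_mm * sin(deg2(ang_ant))
  ap_pos <- cfg$arm_length_mm * sin(deg2(ang_pos))
  ap_range <- ap_ant - ap_pos
  in_trial <- function(x) x[x >= 0 & x <= D]
  list(step_length_m = cfg$step_length_m,
       step_time_s = T_step,
       stride_length_m = 2 * cfg$step_length_m,
       gait_vel_ms = cfg$step_length_m / T_step,
       cadence_steps_min = 60 / T_step,
       stance_pct = 100 * sf,
       double_support_s = T_step * (2 * sf - 1),
       step_width_m = 2 * BODY$hip_halfwidth / 1000,
       angle_range_deg = 2 * A,
       angle_ant_deg = ang_ant,
       angle_pos_deg = ang_pos,
       sway_range_ap_mm = ap_range,
       asa_angle = asa(2 * A[["L"]], 2 * A[["R"]]),
       asa_ap_range = asa(ap_range[["L"]], ap_range[["R"]]),
       ml_sway_mm = cfg$com_ml_amp_mm,
       v_sway_mm = cfg$com_v_amp_mm,
       heel_strikes = lapply(hs, in_trial),
       toe_offs = lapply(hs, function(h) in_trial(h + sf * S)),
       duration_s = D)
}

#' Generate a cohort of synthetic trials on disk
#'
#' Writes `n_trials` trial JSON files per configuration (seeds derived
#' deterministically from each config's seed) plus a `manifest.csv` of
#' per-trial ground-truth values.
#'
#' @param configs Non-empty list of [synth_config()] objects.
#' @param n_trials Trials per configuration (default 2).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame (one row per written trial,
#'   with a `file` column).
#' @export
synth_cohort <- function(configs, n_trials = 2, dir) {
  if (!length(configs))
    kg_stop("empty configuration list", "kinegait_config_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (r in seq_len(n_trials)) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + 7919L * (r - 1L)
      tr <- generate_trial(cfg_r)
      fn <- file.path(dir, sprintf("%s_trial%d.json", cfg$subject_id, r))
      write_trial(tr$seq, fn)
      th <- tr$truth
      rows[[length(rows) + 1]] <- data.frame(
        file = basename(fn), subject_id = cfg$subject_id, trial = r,
        group = cfg$group, seed = cfg_r$seed,
        step_length_m = th$step_length_m, step_time_s = th$step_time_s,
        gait_vel_ms = th$gait_vel_ms, stance_pct = th$stance_pct,
        angle_range_L = th$angle_range_deg[["L"]],
        angle_range_R = th$angle_range_deg[["R"]],
        sway_range_ap_L = th$sway_range_ap_mm[["L"]],
        sway_range_ap_R = th$sway_range_ap_mm[["R"]],
        asa_angle = th$asa_angle, asa_ap_range = th$asa_ap_range,
        ml_sway_mm = th$ml_sway_mm, v_sway_mm = th$v_sway_mm)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
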