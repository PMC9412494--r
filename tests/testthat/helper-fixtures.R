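# Shared fixtures, built in code.

# Minimal hand-built skeleton sequence: all joints ride rigidly on a moving
# pelvis unless overridden.
make_sequence <- function(t, pelvis_xyz, overrides = list(), conf = NULL,
                          ...) {
  n <- length(t)
  joints <- kinect_joints()
  xyz <- array(0, dim = c(n, 3, 32),
               dimnames = list(NULL, c("x", "y", "z"), joints))
  for (j in joints) xyz[, , j] <- pelvis_xyz
  for (j in names(overrides)) xyz[, , j] <- overrides[[j]]
  skeleton_sequence(t, xyz, conf = conf, ...)
}

# Straight constant-speed walk toward the camera (z in mm).
straight_pelvis <- function(t, start_z_mm = 5500, v_mm_s = 1000,
                            x_mm = 0, y_mm = 900) {
  cbind(rep(x_mm, length(t)), rep(y_mm, length(t)), start_z_mm - v_mm_s * t)
}

# A default simulated trial + its analysis row, computed once per test run.
default_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- generate_trial(synth_config(seed = 42))
      row <- suppressWarnings(analyze_trial(tr$seq))
      cache <<- list(trial = tr, row = row)
    }
    cache
  }
})

# Preprocess a sequence up to the gait window with defaults.
to_window <- function(seq, gap_near = 1.5, gap_far = 3.5) {
  extract_gap(lowpass_8hz(resample_50hz(seq)), gap_near, gap_far)
}

# Mirror a trial: x -> -x and swap side-labelled joints.
mirror_sequence <- function(seq) {
  xyz <- seq$xyz
  xyz[, "x", ] <- -xyz[, "x", ]
  jn <- dimnames(xyz)[[3]]
  swapped <- jn
  swapped[grepl("_L$", jn)] <- sub("_L$", "_R", jn[grepl("_L$", jn)])
  swapped[grepl("_R$", jn)] <- sub("_R$", "_L", jn[grepl("_R$", jn)])
  xyz2 <- xyz
  xyz2[, , swapped] <- xyz[, , jn]
  skeleton_sequence(seq$t, xyz2, conf = seq$conf,
                    subject_id = seq$meta$subject_id,
                    trial_id = seq$meta$trial_id, group = seq$meta$group)
}
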