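test_that("wrist-relative components follow the stated sign conventions", {
  t <- seq(0, 3.3, by = 0.02)
  pel <- straight_pelvis(t, start_z_mm = 4500)
  # wrist 100 mm nearer the camera than the pelvis: AP = +100
  wl <- pel + cbind(rep(0, length(t)), 0, rep(-100, length(t)))
  seq <- make_sequence(t, pel, overrides = list(WRIST_L = wl))
  win <- extract_gap(lowpass_8hz(resample_50hz(seq)), 1.5, 3.5)
  rel <- wrist_relative_series(win, "L")
  expect_equal(unname(rel[, "AP"]), rep(100, nrow(rel)), tolerance = 1e-6)
  # wrist coincident with pelvis: all components zero
  rel0 <- wrist_relative_series(
    extract_gap(lowpass_8hz(resample_50hz(make_sequence(t, pel))), 1.5, 3.5),
    "R")
  expect_equal(max(abs(rel0)), 0, tolerance = 1e-9)
})

test_that("linear metrics match analytic values for a sinusoidal AP swing", {
  t <- seq(0, 4, length.out = 201)          # dt = 0.02
  rel <- cbind(AP = 100 * sin(2 * pi * t), ML = rep(0, 201), UD = rep(0, 201))
  m <- suppressWarnings(linear_metrics(rel, dt = 0.02))
  expect_equal(m[["SWAY_ANT_AP"]], 100, tolerance = 0.01)
  expect_equal(m[["SWAY_POS_AP"]], -100, tolerance = 0.01)
  expect_equal(m[["SWAY_RANGE_AP"]], 200, tolerance = 0.02)
  expect_equal(m[["SWAY_AREA"]], 0)
  # max |d/dt 100 sin(2 pi t)| = 200 pi; central differences on the 50 Hz grid
  expect_equal(m[["SPEED_AP"]], 200 * pi, tolerance = 0.02 * 200 * pi)
  # PATH_TOT cannot be smaller than the AP range
  expect_gte(m[["PATH_TOT"]], m[["SWAY_RANGE_AP"]])
})

test_that("convex hull area of a sampled circle approaches pi r^2", {
  th <- seq(0, 2 * pi, length.out = 400)
  r <- 120
  rel <- cbind(AP = r * cos(th), ML = r * sin(th), UD = rep(0, 400))
  m <- linear_metrics(rel, dt = 0.02)
  expect_equal(m[["SWAY_AREA"]], pi * r^2, tolerance = 0.02 * pi * r^2)
})

test_that("angular metrics reproduce constructed sagittal geometry", {
  t <- seq(0, 3.3, by = 0.02)
  n <- length(t)
  pel <- straight_pelvis(t, start_z_mm = 4500)
  sh <- pel + cbind(rep(180, n), rep(450, n), rep(0, n))
  hip <- pel + cbind(rep(70, n), rep(0, n), rep(0, n))
  arm_at <- function(theta_deg) {
    th <- theta_deg * pi / 180
    sh + cbind(rep(0, n), -550 * cos(th), -550 * sin(th))
  }
  mkwin <- function(wrist)
    extract_gap(lowpass_8hz(resample_50hz(
      make_sequence(t, pel, overrides = list(SHOULDER_L = sh, HIP_L = hip,
                                             WRIST_L = wrist)))), 1.5, 3.5)
  # arm hanging along the trunk line: angle 0 throughout
  am0 <- angular_metrics(mkwin(arm_at(rep(0, n))), "L")
  expect_equal(am0[["ANGLE_ANT"]], 0, tolerance = 1e-6)
  expect_equal(am0[["ANGLE_RANGE"]], 0, tolerance = 1e-6)
  # fixed 30 degrees anterior
  am30 <- angular_metrics(mkwin(arm_at(rep(30, n))), "L")
  expect_equal(am30[["ANGLE_ANT"]], 30, tolerance = 1e-6)
  # symmetric +/-25 degree swing: range 50
  amswing <- angular_metrics(mkwin(arm_at(25 * sin(2 * pi * t / 1.1))), "L")
  expect_equal(amswing[["ANGLE_RANGE"]], 50, tolerance = 0.5)
  expect_equal(amswing[["ANGLE_ANT"]], 25, tolerance = 0.3)
  expect_equal(amswing[["ANGLE_POS"]], -25, tolerance = 0.3)
})

test_that("asa satisfies its limit cases and algebraic properties", {
  expect_equal(asa(7.3, 7.3), 0)
  expect_equal(asa(1, 0), 50)
  expect_equal(asa(0, 1), 50)
  # symmetry and scale invariance over a generated grid
  set.seed(5)
  for (i in 1:25) {
    x <- runif(1, 0.01, 500); y <- runif(1, 0.01, 500)
    k <- runif(1, 0.1, 40)
    expect_equal(asa(x, y), asa(y, x), tolerance = 1e-12)
    expect_equal(asa(k * x, k * y), asa(x, y), tolerance = 1e-9)
    expect_gte(asa(x, y), 0)
    expect_lte(asa(x, y), 50)
  }
  # strictly increasing in the more/less ratio
  ratios <- c(1, 1.2, 1.8, 3, 8, 50)
  vals <- vapply(ratios, function(r) asa(r, 1), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(asa(-1, 2), class = "kinegait_domain_error")
  expect_error(asa(0, 0), class = "kinegait_undefined_asymmetry")
})

test_that("asymmetry indices use the range, path and AP-range parameters", {
  left <- c(ANGLE_RANGE = 40, PATH_TOT = 2000, SWAY_RANGE_AP = 300)
  right <- c(ANGLE_RANGE = 40, PATH_TOT = 2000, SWAY_RANGE_AP = 300)
  expect_equal(unname(asymmetry_indices(left, right)), c(0, 0, 0))
  right2 <- c(ANGLE_RANGE = 20, PATH_TOT = 1000, SWAY_RANGE_AP = 150)
  ai <- asymmetry_indices(left, right2)
  expect_equal(unname(ai["ASA_ANGLE"]), asa(40, 20))
  expect_equal(unname(ai["ASA_PATH"]), asa(2000, 1000))
  expect_equal(unname(ai["ASA_AP_RANGE"]), asa(300, 150))
})

test_that("synchrony indices hit the exact-copy and anti-phase limits", {
  tr <- generate_trial(synth_config(seed = 83, noise_sd_mm = 0))
  win <- to_window(tr$seq)
  # identical arms: copy the left wrist onto the right
  win_same <- win
  win_same$xyz[, , "WRIST_R"] <- win$xyz[, , "WRIST_L"]
  win_same$xyz[, "x", "WRIST_R"] <- -win$xyz[, "x", "WRIST_L"]
  si_same <- synchrony_indices(win_same)
  expect_equal(si_same[["SI_ARMS"]], 1, tolerance = 1e-9)
  # anti-phase simulator arms
  si <- synchrony_indices(win)
  expect_lt(si[["SI_ARMS"]], -0.99)
  expect_gt(si[["SI_ARM_LEG_L"]], 0.7)
  expect_gt(si[["SI_ARM_LEG_R"]], 0.7)
  expect_true(all(abs(c(si)) <= 1))
})

test_that("noisy anti-phase arms match the attenuation a Monte-Carlo oracle predicts", {
  # sinusoid amplitude A with iid noise sd s on each series:
  # E[r] ~ -(A^2/2) / (A^2/2 + s^2)
  A <- 230; s <- 40
  t <- seq(0, 1.8, by = 0.02)
  n <- length(t)
  oracle <- local({
    set.seed(999)
    mean(replicate(300, {
      a <- A * sin(2 * pi * t / 1.1) + rnorm(n, 0, s)
      b <- -A * sin(2 * pi * t / 1.1) + rnorm(n, 0, s)
      cor(a, b)
    }))
  })
  set.seed(1234)
  measured <- mean(replicate(100, {
    a <- A * sin(2 * pi * t / 1.1) + rnorm(n, 0, s)
    b <- -A * sin(2 * pi * t / 1.1) + rnorm(n, 0, s)
    cor(a, b)
  }))
  expect_equal(measured, oracle, tolerance = 0.05)
  expect_equal(oracle, -(A^2 / 2) / (A^2 / 2 + s^2), tolerance = 0.05)
})

test_that("structural identities hold on every analyzed trial", {
  rows <- rbind(default_trial()$row,
                suppressWarnings(analyze_trial(generate_trial(
                  synth_config(seed = 91, arm_amp_deg = c(L = 30, R = 14),
                               arm_anterior_split = 0.6))$seq)))
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    for (s in c("L", "R")) {
      for (d in c("AP", "ML", "UD"))
        expect_equal(row[[paste0("SWAY_RANGE_", d, "_", s)]],
                     row[[paste0("SWAY_ANT_", d, "_", s)]] -
                       row[[paste0("SWAY_POS_", d, "_", s)]])
      expect_equal(row[[paste0("ANGLE_RANGE_", s)]],
                   row[[paste0("ANGLE_ANT_", s)]] -
                     row[[paste0("ANGLE_POS_", s)]])
      expect_gte(row[[paste0("PATH_TOT_", s)]],
                 row[[paste0("SWAY_RANGE_AP_", s)]])
    }
    for (p in c("ASA_ANGLE", "ASA_PATH", "ASA_AP_RANGE")) {
      expect_gte(row[[p]], 0)
      expect_lte(row[[p]], 50)
    }
    for (p in c("SI_ARMS", "SI_ARM_LEG_L", "SI_ARM_LEG_R"))
      expect_lte(abs(row[[p]]), 1)
  }
})

test_that("mirroring leaves ASA and |SI| invariant", {
  tr <- generate_trial(synth_config(seed = 97, arm_amp_deg = c(L = 27, R = 17)))
  row <- suppressWarnings(analyze_trial(tr$seq))
  row_m <- suppressWarnings(analyze_trial(mirror_sequence(tr$seq)))
  for (p in c("ASA_ANGLE", "ASA_PATH", "ASA_AP_RANGE"))
    expect_equal(row_m[[p]], row[[p]], tolerance = 1e-9)
  expect_equal(row_m$SI_ARMS, row$SI_ARMS, tolerance = 1e-9)
  expect_equal(abs(row_m$SI_ARM_LEG_L), abs(row$SI_ARM_LEG_R),
               tolerance = 1e-9)
})
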