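#' Run the full pipeline on one trial
#'
#' Reads (or takes) a skeletal trial, resamples to 50 Hz, low-pass filters,
#' restricts to the GAP, detects gait events, and computes the complete
#' parameter record: spatiotemporal parameters per side, COM sway, linear
#' and angular arm-swing metrics per arm, ASA asymmetry indices and
#' synchrony indices. Any stage failure is re-raised with the stage name and
#' trial id attached.
#'
#' @param trial Path to a trial JSON file, or a [skeleton_sequence()].
#' @param gap_near,gap_far GAP bounds in metres (see [extract_gap()]).
#' @param cutoff_hz,filter_order Low-pass settings (see [lowpass_8hz()]).
#' @return One-row data frame: ids, provenance (GAP and filter settings),
#'   then per-side columns suffixed `_L`/`_R` plus the overall parameters.
#' @export
analyze_trial <- function(trial, gap_near = 1.5, gap_far = 3.5,
                          cutoff_hz = 8, filter_order = 4) {
  seq <- if (is.character(trial)) read_trial(trial) else trial
  id <- paste0(seq$meta$subject_id, "/", seq$meta$trial_id)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      kg_stop(sprintf("stage '%s' failed for trial %s: %s",
                      name, id, conditionMessage(e)),
              c(paste0("kinegait_stage_", name), class(e)[1]))
    })
  }
  rs <- stage("resample", resample_50hz(seq))
  fl <- stage("filter", lowpass_8hz(rs, cutoff_hz, filter_order))
  win <- stage("gap", extract_gap(fl, gap_near, gap_far))
  ev <- stage("events", detect_events(win))
  st <- stage("spatiotemporal", spatiotemporal(win, ev))
  sway <- stage("com_sway", sway_params(com_trajectory(win)))
  arm <- list(L = stage("arm_swing", arm_swing_params(win, "L")),
              R = stage("arm_swing", arm_swing_params(win, "R")))
  asym <- stage("asymmetry", asymmetry_indices(arm$L, arm$R))
  sync <- stage("synchrony", synchrony_indices(win))
  row <- data.frame(subject_id = seq$meta$subject_id,
                    trial_id = seq$meta$trial_id,
                    group = seq$meta$group,
                    gap_near_m = gap_near, gap_far_m = gap_far,
                    cutoff_hz = cutoff_hz, filter_order = filter_order,
                    stringsAsFactors = FALSE)
  for (s in c("L", "R")) {
    side_par <- c(st[[s]], arm[[s]])
    names(side_par) <- paste0(names(side_par), "_", s)
    row <- cbind(row, as.data.frame(as.list(side_par)))
  }
  overall <- c(GAIT_VEL = st$GAIT_VEL, CADENCE = st$CADENCE,
               STEP_NUM = st$STEP_NUM, STRIDE_NUM = st$STRIDE_NUM,
               ML_SWAY = sway$ML_SWAY, V_SWAY = sway$V_SWAY,
               asym, sync)
  cbind(row, as.data.frame(as.list(overall)))
}

#' Analyze every trial in a directory
#'
#' @param dir Directory of trial JSON files.
#' @param pattern File pattern (default `"\\.json$"`).
#' @param ... Passed to [analyze_trial()].
#' @return Data frame with one row per trial.
#' @export
analyze_dir <- function(dir, pattern = "\\.json$", ...) {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(files))
    kg_stop(paste0("no trial files in ", dir), "kinegait_io_error")
  do.call(rbind, lapply(files, analyze_trial, ...))
}

# Parameter-name bookkeeping used by the reporting layer.
sided_base_names <- function(df) {
  nm <- names(df)
  ls <- sub("_L$", "", nm[grepl("_L$", nm)])
  rs <- sub("_R$", "", nm[grepl("_R$", nm)])
  setdiff(intersect(ls, rs), c("SI_ARM_LEG"))
}

ARM_SWING_PARAMS <- c("SWAY_ANT_AP", "SWAY_ANT_ML", "SWAY_ANT_UD",
                      "SWAY_POS_AP", "SWAY_POS_ML", "SWAY_POS_UD",
                      "SWAY_RANGE_AP", "SWAY_RANGE_ML", "SWAY_RANGE_UD",
                      "PATH_TOT", "SWAY_AREA", "SPEED_AP",
                      "ANGLE_ANT", "ANGLE_POS", "ANGLE_RANGE",
                      "ASA_ANGLE", "ASA_PATH", "ASA_AP_RANGE",
                      "SI_ARMS", "SI_ARM_LEG")
GAIT_PARAMS <- c("STEP_LEN", "STEP_WIDTH", "STEP_VEL", "STEP_TIME",
                 "STRIDE_LEN", "DOUBLE_SUPP", "STANCE_DUR",
                 "GAIT_VEL", "CADENCE", "STEP_NUM", "STRIDE_NUM",
                 "ML_SWAY", "V_SWAY")

# Observations for one base parameter: per-side columns pooled as two
# observations per trial (as in side-wise group testing), per-trial columns
# as one.
param_observations <- function(df, param) {
  if (param %in% names(df)) return(df[[param]])
  cols <- intersect(paste0(param, c("_L", "_R")), names(df))
  if (!length(cols)) return(NULL)
  unlist(df[cols], use.names = FALSE)
}

signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Two-group statistical comparison of gait parameters
#'
#' For each parameter: group medians with first/third quartiles, the
#' Mann-Whitney test (reported as the rank sum of group A,
#' `W = U + n_a (n_a + 1) / 2`, with exact p-values for small untied
#' samples and the tie-corrected normal approximation otherwise), Student's
#' t-test as a parametric companion, Shapiro-Wilk normality p per group,
#' and significance stars (`*` p<0.05, `**` p<0.01, `***` p<0.001).
#' Per-side parameters contribute two observations per trial (left and right
#' pooled); per-trial parameters one. Parameters whose pooled observations
#' are all identical are skipped with a note.
#'
#' @param rows_a,rows_b Data frames of analyzed trials (from
#'   [analyze_trial()]/[analyze_dir()]), one group each.
#' @param params Base parameter names to compare; defaults to every gait,
#'   COM and arm-swing parameter present.
#' @return Data frame of class `group_comparison`, one row per parameter.
#' @export
compare_groups <- function(rows_a, rows_b, params = NULL) {
  if (is.null(params)) {
    cand <- c(ARM_SWING_PARAMS, GAIT_PARAMS)
    params <- cand[vapply(cand, function(p)
      !is.null(param_observations(rows_a, p)) &&
        !is.null(param_observations(rows_b, p)), logical(1))]
  }
  out <- lapply(params, function(p) {
    a <- param_observations(rows_a, p)
    b <- param_observations(rows_b, p)
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 3 || length(b) < 3)
      kg_stop(paste0("need >= 3 observations per group for ", p),
              "kinegait_insufficient_data")
    qa <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
    qb <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
    if (length(unique(c(a, b))) == 1) {
      return(data.frame(parameter = p, n_a = length(a), n_b = length(b),
                        median_a = qa[2], q1_a = qa[1], q3_a = qa[3],
                        median_b = qb[2], q1_b = qb[1], q3_b = qb[3],
                        rank_sum = NA_real_, p_mw = NA_real_,
                        t_stat = NA_real_, p_t = NA_real_,
                        shapiro_a = NA_real_, shapiro_b = NA_real_,
                        stars = "", note = "all observations identical"))
    }
    mw <- suppressWarnings(stats::wilcox.test(a, b))
    rank_sum <- unname(mw$statistic) + length(a) * (length(a) + 1) / 2
    tt <- tryCatch(stats::t.test(a, b),
                   error = function(e)
                     list(statistic = NA_real_, p.value = NA_real_))
    sh <- function(x) if (length(unique(x)) > 2 && length(x) >= 3 &&
                          length(x) <= 5000)
      stats::shapiro.test(x)$p.value else NA_real_
    data.frame(parameter = p, n_a = length(a), n_b = length(b),
               median_a = qa[2], q1_a = qa[1], q3_a = qa[3],
               median_b = qb[2], q1_b = qb[1], q3_b = qb[3],
               rank_sum = rank_sum, p_mw = mw$p.value,
               t_stat = unname(tt$statistic), p_t = tt$p.value,
               shapiro_a = sh(a), shapiro_b = sh(b),
               stars = signif_stars(mw$p.value), note = "")
  })
  res <- do.call(rbind, out)
  class(res) <- c("group_comparison", class(res))
  res
}

#' Format a group comparison as a printable table
#'
#' Renders each row as `median (Q1, Q3) | statistic | p | stars`, the layout
#' used in clinical gait-comparison tables.
#'
#' @param x A `group_comparison`.
#' @param digits Significant digits for medians/quartiles (default 2).
#' @return Character data frame with one formatted row per parameter.
#' @export
format_comparison <- function(x, digits = 2) {
  fmt <- function(m, q1, q3)
    sprintf("%.*f (%.*f, %.*f)", digits, m, digits, q1, digits, q3)
  data.frame(parameter = x$parameter,
             group_a = fmt(x$median_a, x$q1_a, x$q3_a),
             group_b = fmt(x$median_b, x$q1_b, x$q3_b),
             statistic = ifelse(is.na(x$rank_sum), "",
                                sprintf("%.0f", x$rank_sum)),
             p = ifelse(is.na(x$p_mw), "",
                        ifelse(x$p_mw < 0.001, "<0.001",
                               sprintf("%.3f", x$p_mw))),
             stars = x$stars,
             stringsAsFactors = FALSE)
}

#' Correlation matrix between arm-swing and gait/COM parameters
#'
#' Spearman's rank correlation (primary, nonparametric) and Pearson's
#' correlation (parametric companion) of every arm-swing parameter against
#' every spatiotemporal and COM parameter, with per-cell significance tiers
#' at 0.05 / 0.01 / 0.001. Per-side parameters are pooled left+right.
#' Constant columns yield `NA` cells marked `"undefined"`.
#'
#' @param rows Data frame of analyzed trials (>= 5 rows).
#' @param row_params,col_params Parameter sets; default arm-swing versus
#'   spatiotemporal + COM.
#' @return Long-format data frame: `arm_param`, `gait_param`, `rho`,
#'   `p_rho`, `r`, `p_r`, `tier`.
#' @export
correlation_matrix <- function(rows, row_params = NULL, col_params = NULL) {
  if (nrow(rows) < 5)
    kg_stop("need at least 5 trials for correlation analysis",
            "kinegait_insufficient_data")
  pick <- function(cand) cand[vapply(cand, function(p)
    !is.null(param_observations(rows, p)), logical(1))]
  if (is.null(row_params)) row_params <- pick(ARM_SWING_PARAMS)
  if (is.null(col_params)) col_params <- pick(GAIT_PARAMS)
  # pooled observation vectors must align: duplicate per-trial columns when
  # pairing against per-side (pooled, 2n) columns
  obs <- function(p, n2) {
    v <- param_observations(rows, p)
    if (length(v) == nrow(rows) && n2) rep(v, 2) else v
  }
  cells <- list()
  for (rp in row_params) {
    for (cp in col_params) {
      vr0 <- param_observations(rows, rp)
      vc0 <- param_observations(rows, cp)
      two <- length(vr0) > nrow(rows) || length(vc0) > nrow(rows)
      vr <- obs(rp, two); vc <- obs(cp, two)
      ok <- is.finite(vr) & is.finite(vc)
      vr <- vr[ok]; vc <- vc[ok]
      if (length(vr) < 5 || stats::sd(vr) == 0 || stats::sd(vc) == 0) {
        cells[[length(cells) + 1]] <- data.frame(
          arm_param = rp, gait_param = cp, rho = NA_real_, p_rho = NA_real_,
          r = NA_real_, p_r = NA_real_, tier = "undefined")
        next
      }
      spearman <- suppressWarnings(
        stats::cor.test(vr, vc, method = "spearman"))
      pearson <- stats::cor.test(vr, vc, method = "pearson")
      p <- spearman$p.value
      tier <- if (p < 0.001) "p<0.001" else if (p < 0.01) "p<0.01" else
        if (p < 0.05) "p<0.05" else "ns"
      cells[[length(cells) + 1]] <- data.frame(
        arm_param = rp, gait_param = cp,
        rho = unname(spearman$estimate), p_rho = p,
        r = unname(pearson$estimate), p_r = pearson$p.value, tier = tier)
    }
  }
  do.call(rbind, cells)
}
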