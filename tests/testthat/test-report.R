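# Small simulated two-group table reused across reporting tests.
report_rows <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mk <- function(i, amp_l, amp_r, sl, grp)
        suppressWarnings(analyze_trial(generate_trial(synth_config(
          seed = 800 + i, arm_amp_deg = c(L = amp_l, R = amp_r),
          step_length_m = sl, subject_id = sprintf("%s%02d", grp, i),
          group = grp))$seq))
      a <- do.call(rbind, lapply(1:4, function(i)
        mk(i, 26 + i, 24 + i, 0.64, "HC")))
      b <- do.call(rbind, lapply(5:8, function(i)
        mk(i, 14 + i, 8 + i, 0.56, "PD")))
      cache <<- list(a = a, b = b)
    }
    cache
  }
})

test_that("analyze_trial yields a complete deterministic parameter row", {
  tr <- default_trial()$trial
  row <- default_trial()$row
  expect_equal(nrow(row), 1)
  metric_cols <- setdiff(names(row),
                         c("subject_id", "trial_id", "group"))
  expect_true(all(vapply(row[metric_cols], is.numeric, logical(1))))
  expect_false(anyNA(row[metric_cols]))
  row2 <- suppressWarnings(analyze_trial(tr$seq))
  expect_identical(row2, row)
})

test_that("a standing-still trial surfaces a stage-tagged event error", {
  t <- seq(0, 4, by = 1 / 30)
  still <- make_sequence(t, straight_pelvis(t, start_z_mm = 2500,
                                            v_mm_s = 60))
  expect_error(suppressWarnings(analyze_trial(still)),
               "stage", class = "kinegait_error")
})

test_that("Mann-Whitney agrees with exhaustive rank enumeration for n <= 8", {
  brute_mw <- function(x, y) {
    # exact rank-sum null distribution by enumerating all assignments
    pooled <- c(x, y)
    n1 <- length(x)
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(n1)])
    combos <- combn(length(pooled), n1)
    w_all <- apply(combos, 2, function(idx) sum(r[idx]))
    mean_w <- mean(w_all)
    p <- mean(abs(w_all - mean_w) >= abs(w_obs - mean_w) - 1e-9)
    list(W = w_obs - n1 * (n1 + 1) / 2, p = p)
  }
  set.seed(55)
  for (rep in 1:5) {
    x <- runif(6, 0, 10)
    y <- runif(7, 0, 10)
    ours <- suppressWarnings(stats::wilcox.test(x, y))
    oracle <- brute_mw(x, y)
    expect_equal(unname(ours$statistic), oracle$W)
    expect_equal(ours$p.value, oracle$p, tolerance = 1e-9)
  }
})

test_that("identical groups are not flagged as different", {
  rows <- report_rows()$a
  cmp <- compare_groups(rows, rows,
                        params = c("STEP_LEN", "ANGLE_RANGE", "GAIT_VEL"))
  expect_true(all(cmp$p_mw > 0.9))
  expect_true(all(cmp$stars == ""))
  expect_equal(cmp$median_a, cmp$median_b)
})

test_that("group comparison reports rank sums, quartiles, both tests and stars", {
  rr <- report_rows()
  cmp <- compare_groups(rr$a, rr$b)
  expect_s3_class(cmp, "group_comparison")
  expect_true(all(c("rank_sum", "p_mw", "t_stat", "p_t", "shapiro_a",
                    "stars") %in% names(cmp)))
  expect_true(all(cmp$q1_a <= cmp$median_a & cmp$median_a <= cmp$q3_a))
  expect_true(all(cmp$p_mw >= 0 & cmp$p_mw <= 1, na.rm = TRUE))
  # per-side parameters pool two observations per trial
  expect_equal(cmp$n_a[cmp$parameter == "STEP_LEN"], 2 * nrow(rr$a))
  expect_equal(cmp$n_a[cmp$parameter == "GAIT_VEL"], nrow(rr$a))
  # the injected group separation in step length is detected
  expect_lt(cmp$p_mw[cmp$parameter == "STEP_LEN"], 0.01)
  # formatted rendering: median (Q1, Q3) | statistic | p | stars
  fmt <- format_comparison(cmp)
  expect_match(fmt$group_a[1], "^-?[0-9.]+ \\(-?[0-9.]+, -?[0-9.]+\\)$")
  expect_true(all(fmt$stars %in% c("", "*", "**", "***")))
})

test_that("two cohorts with distinct arm-swing amplitude separate at p < 0.001 reliably", {
  # Monte-Carlo power oracle on the group-comparison layer: ANGLE_RANGE-like
  # observations, means 38 vs 27 deg, sd 5, n = 26 vs 32 (per-side pooling
  # doubles the per-trial counts used here)
  set.seed(321)
  hits <- mean(replicate(200, {
    a <- rnorm(26, 38, 5)
    b <- rnorm(32, 27, 5)
    suppressWarnings(stats::wilcox.test(a, b))$p.value < 0.001
  }))
  expect_gte(hits, 0.95)
})

test_that("correlation matrix pairs arm-swing with gait parameters", {
  rr <- report_rows()
  rows <- rbind(rr$a, rr$b)
  cm <- correlation_matrix(rows)
  expect_true(all(c("arm_param", "gait_param", "rho", "p_rho", "r", "p_r",
                    "tier") %in% names(cm)))
  expect_true(all(abs(cm$rho) <= 1, na.rm = TRUE))
  # a parameter against itself gives rho 1
  cm_self <- correlation_matrix(rows, row_params = "ANGLE_RANGE",
                                col_params = "ANGLE_RANGE")
  expect_equal(cm_self$rho, 1)
  # arm amplitude co-varies with the injected step-length difference
  cell <- cm[cm$arm_param == "ANGLE_RANGE" & cm$gait_param == "STEP_LEN", ]
  expect_gt(cell$rho, 0.5)
})

test_that("Spearman beats Pearson on a monotone nonlinear relation", {
  set.seed(77)
  x <- runif(30, -2, 2)
  y <- x^3 + rnorm(30, 0, 0.002)
  rows <- data.frame(ANGLE_RANGE = x, GAIT_VEL = y)
  # five rows minimum satisfied; build via the public interface
  cm <- correlation_matrix(rows, row_params = "ANGLE_RANGE",
                           col_params = "GAIT_VEL")
  expect_gt(cm$rho, 0.99)
  expect_lt(cm$r, cm$rho)
})

test_that("independent columns reach nominal type-I error", {
  set.seed(131)
  hits <- mean(replicate(1000, {
    x <- rnorm(30); y <- rnorm(30)
    suppressWarnings(cor.test(x, y, method = "spearman"))$p.value < 0.05
  }))
  expect_lt(abs(hits - 0.05), 0.025)
})

test_that("constant columns are marked undefined", {
  rows <- data.frame(ANGLE_RANGE = rep(3, 8), GAIT_VEL = rnorm(8))
  cm <- correlation_matrix(rows, row_params = "ANGLE_RANGE",
                           col_params = "GAIT_VEL")
  expect_true(is.na(cm$rho))
  expect_equal(cm$tier, "undefined")
})
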