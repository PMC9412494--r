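# Peak detection with topographic prominence. Event detection is the one
# signal-processing primitive the pipeline's temporal estimates hinge on,
# so it is implemented (and oracle-tested) here rather than borrowed.

# Strict local maxima with plateau handling (plateau -> its centre index).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  dx <- diff(x)
  s <- sign(dx)
  # carry the previous non-zero sign across plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) < 0) + 1L
  idx[idx > 1 & idx < n]
}

peak_prominence <- function(x, i) {
  h <- x[i]
  # walk left/right to the nearest strictly higher ground (or the edge);
  # prominence is height above the higher of the two intervening minima
  left <- x[seq_len(i - 1)]
  higher_l <- which(left > h)
  min_l <- if (length(higher_l)) min(x[(max(higher_l) + 1):i]) else min(x[1:i])
  right <- x[(i + 1):length(x)]
  higher_r <- which(right > h)
  min_r <- if (length(higher_r)) min(x[i:(i + min(higher_r))]) else
    min(x[i:length(x)])
  h - max(min_l, min_r)
}

#' Find prominent peaks in a uniformly sampled signal
#'
#' Local maxima are accepted if their topographic prominence reaches
#' `min_prominence` and they are at least `min_distance` samples apart
#' (higher peaks win ties in the distance pruning).
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence, in the units of `x`.
#' @param min_distance Minimum separation in samples.
#' @return Integer vector of peak indices, increasing.
#' @export
find_peaks <- function(x, min_prominence = 0, min_distance = 1) {
  cand <- local_maxima(x)
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  keep <- logical(length(x))
  for (i in cand[order(x[cand], decreasing = TRUE)]) {
    window <- max(1, i - min_distance + 1):min(length(x), i + min_distance - 1)
    if (!any(keep[window])) keep[i] <- TRUE
  }
  which(keep)
}

#' Detect heel-strike and toe-off events from ankle trajectories
#'
#' Works exclusively on the anteroposterior (`z`) component of the ankle
#' joints, expressed relative to the pelvis to remove forward drift:
#' `f(t) = pelvis_z(t) - ankle_z(t)` is the ankle's forward position relative
#' to the body. Its local maxima mark heel strikes (foot maximally ahead)
#' and its local minima mark toe-offs (foot maximally behind). Peaks must
#' have prominence >= `min_prominence_mm` and be >= `min_separation_s` apart.
#'
#' @param win A `gait_window`.
#' @param min_prominence_mm Peak prominence threshold in mm (default 10).
#' @param min_separation_s Minimum separation between same-type events of
#'   one side, in seconds (default 0.3).
#' @return A `gait_events` list: `heel_strike` and `toe_off`, each with `L`
#'   and `R` numeric vectors of event times in seconds (increasing).
#'   Emits a `kinegait_alternation_warning` if left/right heel strikes do
#'   not alternate.
#' @export
detect_events <- function(win, min_prominence_mm = 10,
                          min_separation_s = 0.3) {
  pz <- jcoord(win, "PELVIS", "z")
  dist <- max(1L, round(min_separation_s * win$rate))
  ev <- list(heel_strike = list(), toe_off = list())
  for (side in c("L", "R")) {
    f <- pz - jcoord(win, paste0("ANKLE_", side), "z")
    hs <- find_peaks(f, min_prominence_mm, dist)
    to <- find_peaks(-f, min_prominence_mm, dist)
    ev$heel_strike[[side]] <- win$t[hs]
    ev$toe_off[[side]] <- win$t[to]
  }
  if (!length(ev$heel_strike$L) && !length(ev$heel_strike$R))
    kg_stop("no qualifying gait events in window", "kinegait_no_events")
  merged <- rbind(
    data.frame(t = ev$heel_strike$L,
               side = rep("L", length(ev$heel_strike$L))),
    data.frame(t = ev$heel_strike$R,
               side = rep("R", length(ev$heel_strike$R))))
  merged <- merged[order(merged$t), ]
  if (nrow(merged) >= 2 && any(merged$side[-1] == merged$side[-nrow(merged)])) {
    bad <- merged$t[which(merged$side[-1] == merged$side[-nrow(merged)]) + 1]
    kg_warn(paste0("heel strikes do not alternate near t = ",
                   paste(sprintf("%.2f", bad), collapse = ", ")),
            "kinegait_alternation_warning")
  }
  structure(ev, class = "gait_events")
}

other_side <- function(side) if (side == "L") "R" else "L"

#' Spatiotemporal gait parameters from a window and its events
#'
#' Per-side parameters are averaged over the steps (or strides) of that side
#' detected inside the GAP; overall parameters use the GAP geometry.
#' Definitions (side `s`, contralateral `o`, all positions in the filtered
#' window):
#' * `STEP_LEN` (m): mean `|ankle_s_z - ankle_o_z|` at the heel strikes of `s`.
#' * `STEP_WIDTH` (m): mean `|ankle_L_x - ankle_R_x|` at the heel strikes of `s`.
#' * `STEP_TIME` (s): mean interval from a heel strike of `o` to the next
#'   heel strike of `s`.
#' * `STEP_VEL` (m/s): per-event `step length / step time`, averaged.
#' * `STRIDE_LEN` (m): mean `|diff(ankle_s_z)|` between consecutive heel
#'   strikes of `s`.
#' * `DOUBLE_SUPP` (s): mean `toe_off_o - heel_strike_s` over valid pairs.
#' * `STANCE_DUR` (% of gait cycle): mean `(toe_off_s - heel_strike_s)` over
#'   the stride time, x100.
#' * `GAIT_VEL` (m/s): GAP length over traversal time (`t_exit - t_entry`).
#' * `CADENCE` (steps/min): `60 * STEP_NUM / (t_exit - t_entry)`.
#' * `STEP_NUM`, `STRIDE_NUM`: counts inside the window, summed over sides.
#'
#' Sides with fewer than 2 heel strikes get `NA` stride metrics and a
#' `kinegait_sparse_side_warning`.
#'
#' @param win A `gait_window`.
#' @param ev A `gait_events` object from [detect_events()].
#' @return A list of class `spatiotemporal_params`: per-side named vectors
#'   (`L`, `R`) and overall scalars.
#' @export
spatiotemporal <- function(win, ev) {
  if (length(ev$heel_strike$L) + length(ev$heel_strike$R) < 2)
    kg_stop("need at least 2 heel strikes", "kinegait_insufficient_data")
  az <- list(L = jcoord(win, "ANKLE_L", "z"), R = jcoord(win, "ANKLE_R", "z"))
  ax <- list(L = jcoord(win, "ANKLE_L", "x"), R = jcoord(win, "ANKLE_R", "x"))
  at_time <- function(v, tt) approx(win$t, v, xout = tt, rule = 2)$y
  per_side <- list()
  for (s in c("L", "R")) {
    o <- other_side(s)
    hs <- ev$heel_strike[[s]]
    hso <- ev$heel_strike[[o]]
    tos <- ev$toe_off[[s]]
    too <- ev$toe_off[[o]]
    step_len <- if (length(hs))
      mean(abs(at_time(az[[s]], hs) - at_time(az[[o]], hs))) / 1000 else NA_real_
    step_width <- if (length(hs))
      mean(abs(at_time(ax$L, hs) - at_time(ax$R, hs))) / 1000 else NA_real_
    # step time / velocity: contralateral HS -> this side's HS
    st <- c(); sv <- c()
    for (h in hs) {
      prev <- hso[hso < h]
      if (length(prev)) {
        dt <- h - max(prev)
        st <- c(st, dt)
        sl <- abs(at_time(az[[s]], h) - at_time(az[[o]], h)) / 1000
        sv <- c(sv, sl / dt)
      }
    }
    step_time <- if (length(st)) mean(st) else NA_real_
    step_vel <- if (length(sv)) mean(sv) else NA_real_
    if (length(hs) >= 2) {
      stride_len <- mean(abs(diff(at_time(az[[s]], hs)))) / 1000
      stride_times <- diff(hs)
    } else {
      if (length(hs) < 2)
        kg_warn(paste0("side ", s, " has < 2 heel strikes; stride metrics NA"),
                "kinegait_sparse_side_warning")
      stride_len <- NA_real_
      stride_times <- numeric(0)
    }
    # double support: toe-off of the other side ends the support that began
    # at this side's heel strike
    ds <- c()
    ref_stride <- if (length(stride_times)) median(stride_times) else
      if (!is.na(step_time)) 2 * step_time else NA_real_
    for (h in hs) {
      nxt <- too[too > h]
      if (length(nxt)) {
        d <- min(nxt) - h
        if (is.na(ref_stride) || d < ref_stride) ds <- c(ds, d)
      }
    }
    double_supp <- if (length(ds)) mean(ds) else NA_real_
    # stance: heel strike to own toe-off, normalized by own stride time
    stance <- c()
    if (length(hs) >= 2) {
      for (k in seq_len(length(hs) - 1)) {
        t_on <- hs[k]
        t_next <- hs[k + 1]
        off <- tos[tos > t_on & tos < t_next]
        if (length(off))
          stance <- c(stance, (min(off) - t_on) / (t_next - t_on) * 100)
      }
    }
    stance_dur <- if (length(stance)) mean(stance) else NA_real_
    per_side[[s]] <- c(STEP_LEN = step_len, STEP_WIDTH = step_width,
                       STEP_VEL = step_vel, STEP_TIME = step_time,
                       STRIDE_LEN = stride_len, DOUBLE_SUPP = double_supp,
                       STANCE_DUR = stance_dur)
  }
  traversal <- win$gap$t_exit - win$gap$t_entry
  # complete steps: heel strikes with a preceding contralateral heel strike
  all_hs <- sort(c(ev$heel_strike$L, ev$heel_strike$R))
  step_num <- 0L
  for (s in c("L", "R")) {
    o <- other_side(s)
    for (h in ev$heel_strike[[s]])
      if (any(ev$heel_strike[[o]] < h)) step_num <- step_num + 1L
  }
  stride_num <- sum(vapply(c("L", "R"), function(s)
    max(0L, length(ev$heel_strike[[s]]) - 1L), integer(1)))
  structure(list(
    L = per_side$L, R = per_side$R,
    GAIT_VEL = win$gap$length / traversal,
    CADENCE = 60 * step_num / traversal,
    STEP_NUM = step_num, STRIDE_NUM = stride_num,
    traversal_s = traversal),
    class = "spatiotemporal_params")
}
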