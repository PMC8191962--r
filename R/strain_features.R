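## The 158-feature extraction scheme.
##
## Every trace is first upsampled to a uniform 500 Hz grid (linear
## interpolation) to reduce discretization error of peak timings and
## integrals. Strain values inside the +/-5 % dead zone are ignored by all
## contraction calculations: only samples with strain < -5 % contribute to
## the integrals, and a segment whose excursion never passes -5 % has no
## defined peak time.

DEAD_ZONE <- 5        # percent; |strain| <= 5 carries no contraction signal
RESAMPLE_HZ <- 500    # Hz; analysis grid for all features

#' Resample a strain trace onto a uniform grid
#'
#' Linear interpolation onto a uniform grid from 0 to the last original
#' sample. The original endpoints are preserved (the last original time is
#' appended when it does not fall on the grid).
#'
#' @param trace A [strain_trace()] with at least two samples.
#' @param rate Target rate in Hz (default 500).
#' @return A resampled [strain_trace()].
#' @export
resample_trace <- function(trace, rate = RESAMPLE_HZ) {
  if (length(trace$time) < 2L)
    stop("trace '", trace$segment_id, "': need at least 2 samples to resample")
  t_end <- trace$time[length(trace$time)]
  grid <- seq(0, t_end, by = 1 / rate)
  if (grid[length(grid)] < t_end - 1e-12) grid <- c(grid, t_end)
  s <- stats::approx(trace$time, trace$strain, xout = grid, rule = 2)$y
  strain_trace(trace$segment_id, grid, s)
}

#' Dead-zone mask of a trace
#'
#' @param trace A [strain_trace()].
#' @return Logical vector, `TRUE` exactly where strain < -5 % — the only
#'   samples that contribute to contraction integrals. Samples inside
#'   \[-5, 5\] and positive (stretch) samples are excluded.
#' @export
dead_zone_mask <- function(trace) {
  trace$strain < -DEAD_ZONE
}

#' Peak contraction magnitude and its timing
#'
#' The peak value is the maximum percentage of contraction,
#' `P = max(-strain)`, clipped below at 0 for traces that never shorten.
#' Its timing is the time of the first global strain minimum; when the
#' excursion never passes the -5 % dead zone the timing is undefined (`NA`),
#' since no qualifying contraction event exists to date.
#'
#' @param trace A resampled [strain_trace()].
#' @return List with `P` (percent, >= 0) and `T_peak` (seconds or `NA`).
#' @export
peak_features <- function(trace) {
  P <- max(-trace$strain)
  if (P <= 0) return(list(P = 0, T_peak = NA_real_))
  T_peak <- if (P > DEAD_ZONE) trace$time[which.min(trace$strain)] else NA_real_
  list(P = P, T_peak = T_peak)
}

#' Dead-zone-masked strain integral
#'
#' Integral of `|strain|` over the region where strain < -5 %, restricted
#' to \[0, `t_end`\]. The trace is treated as piecewise linear between its
#' samples: fully qualifying panels contribute their trapezoid, and panels
#' that cross the -5 % boundary are split at the crossing point (located by
#' linear interpolation), so the masked integral of the interpolant is
#' computed exactly — the integrand jumps from 0 to 5 at a crossing, and a
#' plain per-sample mask would bias each crossing by O(grid step). When
#' `t_end` falls between grid samples the trace is interpolated there so
#' the integration window is exact. The result is in percent-seconds,
#' non-negative, and non-decreasing in `t_end`.
#'
#' @param trace A resampled [strain_trace()].
#' @param t_end Upper integration bound in seconds, within the trace span.
#' @return Integral in %·s.
#' @export
strain_integral <- function(trace, t_end) {
  tmax <- trace$time[length(trace$time)]
  if (!is.finite(t_end) || t_end <= 0 || t_end > tmax + 1e-9)
    stop("t_end (", t_end, ") outside trace span (0, ", tmax, "]")
  keep <- trace$time <= t_end + 1e-12
  t <- trace$time[keep]
  s <- trace$strain[keep]
  if (t[length(t)] < t_end - 1e-12) {
    t <- c(t, t_end)
    s <- c(s, stats::approx(trace$time, trace$strain, xout = t_end)$y)
  }
  n <- length(t)
  if (n < 2L) return(0)
  t1 <- t[-n]; t2 <- t[-1]
  s1 <- s[-n]; s2 <- s[-1]
  in1 <- s1 < -DEAD_ZONE
  in2 <- s2 < -DEAD_ZONE
  # crossing time of the -5 % boundary within a panel (linear trace)
  tc <- t1 + (-DEAD_ZONE - s1) * (t2 - t1) / (s2 - s1)
  area <- numeric(n - 1L)
  both <- in1 & in2
  area[both] <- (t2[both] - t1[both]) * (-s1[both] - s2[both]) / 2
  enter <- !in1 & in2                       # crosses into the masked region
  area[enter] <- (t2[enter] - tc[enter]) * (DEAD_ZONE - s2[enter]) / 2
  leave <- in1 & !in2                       # crosses out of it
  area[leave] <- (tc[leave] - t1[leave]) * (-s1[leave] + DEAD_ZONE) / 2
  sum(area)
}

#' Per-segment integral features
#'
#' Computes the three strain-integral features of one segment:
#' `I_avc`, the cumulative contraction from QRS onset to aortic valve
#' closure (the strain that ejects blood); `I_peak`, the cumulative
#' contraction up to the segment's own strain peak (total strain deployed);
#' and the mechanical-efficiency marker `E = I_peak - I_avc`. `E` is
#' positive exactly when the peak falls after AVC with qualifying strain in
#' between — cumulative strain wasted after the valve has closed. A segment
#' with undefined peak timing gets `I_peak = 0` and hence `E = -I_avc`.
#'
#' @param trace A resampled [strain_trace()].
#' @param t_avc AVC time in seconds from QRS onset.
#' @return List `P`, `T_peak`, `I_avc`, `I_peak`, `E`.
#' @export
segment_features <- function(trace, t_avc) {
  pk <- peak_features(trace)
  I_avc <- strain_integral(trace, t_avc)
  I_peak <- if (is.na(pk$T_peak) || pk$T_peak <= 0) 0
            else strain_integral(trace, pk$T_peak)
  list(P = pk$P, T_peak = pk$T_peak,
       I_avc = I_avc, I_peak = I_peak, E = I_peak - I_avc)
}

#' Per-view feature block
#'
#' Extracts the 52 features of one apical view: the AVC time; per-segment
#' peak magnitudes with their view mean/std and max-min spread (contraction
#' heterogeneity); per-segment peak timings with mean/std and spread
#' (dyssynchrony); and for each of the three integral families the six
#' segment values, view mean/std, the two side (wall) sums and the side
#' difference. Segments with undefined peak timing are excluded from the
#' timing statistics (their count is reported in attribute
#' `"n_undefined_tpeak"`); when all six are undefined the view is flagged
#' low quality via attribute `"low_quality"` and a warning.
#'
#' @param rec A validated [view_recording()].
#' @param rate Analysis rate in Hz.
#' @return Named numeric vector of the view's features (names per
#'   [feature_names()] grammar), with attributes as described.
#' @export
view_features <- function(rec, rate = RESAMPLE_HZ) {
  rec <- validate_view_recording(rec)
  v <- rec$view
  segs <- view_segments(v)
  sf <- lapply(rec$traces[segs], function(tr)
    segment_features(resample_trace(tr, rate), rec$t_avc))
  P <- vapply(sf, `[[`, numeric(1), "P")
  Tp <- vapply(sf, `[[`, numeric(1), "T_peak")
  Iavc <- vapply(sf, `[[`, numeric(1), "I_avc")
  Ipeak <- vapply(sf, `[[`, numeric(1), "I_peak")
  E <- vapply(sf, `[[`, numeric(1), "E")

  n_undef <- sum(is.na(Tp))
  low_quality <- n_undef == length(segs)
  if (low_quality)
    warning("view ", v, ": no segment has a defined peak time; ",
            "flagged low-quality")
  Tp_def <- Tp[!is.na(Tp)]
  t_stats <- function(x) {
    if (length(x) == 0L) c(mean = NA_real_, std = NA_real_, delta = NA_real_)
    else c(mean = mean(x), std = stats::sd(x), delta = max(x) - min(x))
  }
  ts <- t_stats(Tp_def)

  sides <- view_sides(v)
  sd1 <- names(sides)[1]; sd2 <- names(sides)[2]
  fam_block <- function(x) {
    s1 <- sum(x[sides[[sd1]]]); s2 <- sum(x[sides[[sd2]]])
    c(x, mean = mean(x), std = stats::sd(x),
      stats::setNames(c(s1, s2, s1 - s2),
                      c(sd1, sd2, paste0(sd1, "m", sd2))))
  }

  out <- c(
    stats::setNames(rec$t_avc, paste0("Tavc_", v)),
    stats::setNames(c(P, mean(P), stats::sd(P)),
                    paste0("P_", v, "_", c(segs, "mean", "std"))),
    stats::setNames(c(Tp, ts[["mean"]], ts[["std"]]),
                    paste0("Tpeak_", v, "_", c(segs, "mean", "std"))),
    stats::setNames(max(P) - min(P), paste0("dP_", v)),
    stats::setNames(ts[["delta"]], paste0("dTpeak_", v)),
    stats::setNames(fam_block(Iavc), paste0("Iavc_", v, "_", .integral_qualifiers(v))),
    stats::setNames(fam_block(Ipeak), paste0("Ipeak_", v, "_", .integral_qualifiers(v))),
    stats::setNames(fam_block(E), paste0("E_", v, "_", .integral_qualifiers(v))))
  attr(out, "n_undefined_tpeak") <- n_undef
  attr(out, "low_quality") <- low_quality
  out
}

#' Extract the full 158-feature vector of one patient
#'
#' Concatenates the three per-view blocks (4ch, 3ch, 2ch — 52 features each)
#' and the two clinician-supplied scalars, QRS duration (ms) and LVEF (%),
#' in canonical [feature_names()] order.
#'
#' @param p A validated [patient_record()].
#' @param rate Analysis rate in Hz.
#' @return Named numeric vector of length 158.
#' @export
extract_patient_features <- function(p, rate = RESAMPLE_HZ) {
  p <- validate_patient_record(p)
  blocks <- lapply(strain_views(), function(v) {
    if (is.null(p$views[[v]]))
      stop("patient ", p$patient_id, ": missing view ", v)
    view_features(p$views[[v]], rate)
  })
  out <- c(unlist(blocks), QRS = p$qrs_duration, LVEF = p$lvef)
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Extract the feature table of a whole cohort
#'
#' @param cohort List of [patient_record()]s.
#' @param rate Analysis rate in Hz.
#' @return Data frame: `patient_id`, `response`, then the 158 feature
#'   columns in canonical order, one row per patient.
#' @export
extract_cohort_features <- function(cohort, rate = RESAMPLE_HZ) {
  rows <- lapply(cohort, extract_patient_features, rate = rate)
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(patient_id = vapply(cohort, `[[`, character(1), "patient_id"),
             response = vapply(cohort, `[[`, character(1), "response"),
             tab, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Classify CRT response from end-systolic volumes
#'
#' A patient is a responder when the LV end-systolic volume decreased by
#' strictly more than 15 % between baseline and the 6-month follow-up.
#'
#' @param esv_baseline,esv_followup End-systolic volumes in mL (> 0).
#' @return `"responder"` or `"non-responder"` (vectorized).
#' @export
classify_response <- function(esv_baseline, esv_followup) {
  if (any(!is.finite(esv_baseline)) || any(!is.finite(esv_followup)) ||
      any(esv_baseline <= 0) || any(esv_followup <= 0))
    stop("end-systolic volumes must be positive")
  ifelse((esv_baseline - esv_followup) / esv_baseline > 0.15,
         "responder", "non-responder")
}
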