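## Synthetic LBBB-like strain cohorts.
##
## Each segment curve is a sum of raised-cosine lobes: one negative
## (systolic shortening) lobe of chosen depth, width and peak time, plus an
## optional positive rebound lobe directly after it (the paradoxical
## stretch typical of septal segments under left bundle branch block).
## Raised cosines keep extrema and integrals in closed form, so every
## downstream feature has an analytic oracle.

#' Segment curve parameters
#'
#' @param amplitude Peak shortening magnitude in percent (> 0).
#' @param t_peak Time of the shortening peak in seconds (> 0).
#' @param width Full width of the raised-cosine lobe in seconds (> 0). The
#'   lobe spans `[t_peak - width/2, t_peak + width/2]` and must fit inside
#'   `[0, cycle_length]`.
#' @param rebound_fraction In `[0, 1)`: relative amplitude of a positive
#'   rebound lobe (same width) centred at `t_peak + width`; 0 disables it.
#' @param noise_sd Additive Gaussian noise standard deviation in percent.
#' @return An object of class `segment_params`.
#' @export
segment_params <- function(amplitude, t_peak, width,
                           rebound_fraction = 0, noise_sd = 0) {
  stopifnot(amplitude > 0, t_peak > 0, width > 0,
            rebound_fraction >= 0, rebound_fraction < 1, noise_sd >= 0)
  structure(list(amplitude = amplitude, t_peak = t_peak, width = width,
                 rebound_fraction = rebound_fraction, noise_sd = noise_sd),
            class = "segment_params")
}

.raised_cosine <- function(t, center, width, depth) {
  x <- (t - center) / width
  ifelse(abs(x) <= 0.5, depth * 0.5 * (1 + cos(2 * pi * x)), 0)
}

#' Simulate one segment's strain curve
#'
#' The noiseless curve is a negative raised-cosine lobe (depth
#' `amplitude`, centred at `t_peak`) plus, when `rebound_fraction > 0`, a
#' positive raised-cosine lobe of relative amplitude `rebound_fraction`
#' centred at `t_peak + width` (truncated at the cycle end); strain is 0 at
#' t = 0. Noise is drawn from the current RNG state, so results are
#' reproducible under `set.seed()`.
#'
#' @param p A [segment_params()] object.
#' @param cycle_length Cardiac cycle length in seconds.
#' @param rate Sampling rate in Hz (default 100, a typical clinical strain
#'   export rate above the 60 frames/s acquisition floor).
#' @param segment_id Segment label for the returned trace.
#' @return A [strain_trace()] spanning `[0, cycle_length]`.
#' @export
make_segment_curve <- function(p, cycle_length, rate = 100, segment_id = "BS") {
  stopifnot(inherits(p, "segment_params"), cycle_length > 0, rate > 0)
  if (p$t_peak + p$width / 2 > cycle_length)
    stop("segment curve does not fit the cycle: t_peak + width/2 = ",
         p$t_peak + p$width / 2, " > ", cycle_length)
  if (p$t_peak - p$width / 2 < -1e-12)
    stop("segment curve starts before t = 0: t_peak - width/2 = ",
         p$t_peak - p$width / 2)
  t <- seq(0, cycle_length, by = 1 / rate)
  s <- .raised_cosine(t, p$t_peak, p$width, -p$amplitude)
  if (p$rebound_fraction > 0)
    s <- s + .raised_cosine(t, p$t_peak + p$width, p$width,
                            p$rebound_fraction * p$amplitude)
  if (p$noise_sd > 0)
    s <- s + stats::rnorm(length(t), 0, p$noise_sd)
  strain_trace(segment_id, t, s)
}

#' Cohort generator configuration
#'
#' Defines the study conditions the generator emulates: cohort size and
#' responder fraction, cycle timing, and the responder effect structure.
#' Responders differ from non-responders by three offsets: the septal
#' shortening peak is displaced beyond aortic valve closure (post-systolic
#' septal shortening, producing positive septal efficiency values, i.e.
#' wasted septal work), and the lateral wall contracts more and later
#' (larger, AVC-crossing lateral cumulative strain). Setting all offsets to
#' zero yields a null cohort with no group structure.
#'
#' @param n_patients Number of patients.
#' @param responder_fraction Fraction labelled responder; the responder
#'   count is `round(responder_fraction * n_patients)` exactly.
#' @param cycle_length_s Cardiac cycle length (s).
#' @param t_avc_s Named numeric vector of per-view AVC times (s).
#' @param effects Named list of responder offsets: `septal_t_peak` (s,
#'   added to the septal/anteroseptal peak time), `lateral_amplitude`
#'   (percentage points added to lateral peak shortening), `lateral_t_peak`
#'   (s added to the lateral peak time).
#' @param noise_sd Per-sample additive noise (percent strain).
#' @param rate_hz Export sampling rate (Hz).
#' @param seed Integer seed governing all randomness.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 130,
                          responder_fraction = 0.64,
                          cycle_length_s = 0.8,
                          t_avc_s = c("4ch" = 0.38, "3ch" = 0.37, "2ch" = 0.36),
                          effects = list(septal_t_peak = 0.12,
                                         lateral_amplitude = 4,
                                         lateral_t_peak = 0.08),
                          noise_sd = 1,
                          rate_hz = 100,
                          seed = 1L) {
  stopifnot(n_patients >= 0,
            responder_fraction >= 0, responder_fraction <= 1,
            all(strain_views() %in% names(t_avc_s)),
            all(t_avc_s < cycle_length_s), all(t_avc_s > 0),
            noise_sd >= 0, rate_hz > 0)
  for (k in c("septal_t_peak", "lateral_amplitude", "lateral_t_peak"))
    if (is.null(effects[[k]])) effects[[k]] <- 0
  structure(list(n_patients = as.integer(n_patients),
                 responder_fraction = responder_fraction,
                 cycle_length_s = cycle_length_s,
                 t_avc_s = t_avc_s[strain_views()],
                 effects = effects,
                 noise_sd = noise_sd,
                 rate_hz = rate_hz,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## population-level curve parameters (percent, seconds); chosen for
## physiological plausibility: peak strain 5-25 %, shortening peak shortly
## before AVC, septal rebound stretch present in all LBBB patients
.POP <- list(
  amp_mean = 16, amp_sd = 2.5, amp_min = 5, amp_max = 25,
  t_peak_mean = 0.32, t_peak_sd = 0.02,       # generic wall
  septal_t_peak_mean = 0.30,                  # early septal shortening
  lateral_t_peak_mean = 0.33,                 # lateral wall peaks last
  width_mean = 0.55, width_sd = 0.03,
  septal_width_mean = 0.45,                   # narrower early septal lobe
  septal_rebound = 0.25,                      # post-peak rebound stretch
  esv_mean = 180, esv_sd = 35, esv_min = 100, esv_max = 300,
  qrs_mean = 167, qrs_sd = 20, lvef_mean = 29, lvef_sd = 7
)

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## walls receiving the responder offsets: the septal and lateral walls as
## seen in the 4ch view (the view in which the septal/lateral opposition
## is imaged); the other views keep group-independent mechanics
.SEPTAL_SEGS <- c(BS = "4ch", MS = "4ch", AS = "4ch")
.LATERAL_SEGS <- c(BL = "4ch", ML = "4ch", AL = "4ch")

#' Names of the features the generator's responder effects act on
#'
#' The septal peak-time offset drives the 4ch septal efficiency features
#' (wasted septal work); the lateral amplitude and delay offsets drive the
#' lateral cumulative-strain-to-peak features.
#'
#' @return Character vector of five feature names.
#' @export
planted_features <- function() {
  c("E_4ch_BS", "E_4ch_MS", "E_4ch_AS", "E_4ch_S", "Ipeak_4ch_L")
}

.draw_patient <- function(cfg, pid, label) {
  eff <- if (label == "responder") cfg$effects
         else list(septal_t_peak = 0, lateral_amplitude = 0, lateral_t_peak = 0)
  views <- list()
  for (v in strain_views()) {
    segs <- view_segments(v)
    traces <- lapply(segs, function(sg) {
      septal <- !is.na(.SEPTAL_SEGS[sg]) && .SEPTAL_SEGS[sg] == v
      lateral <- !is.na(.LATERAL_SEGS[sg]) && .LATERAL_SEGS[sg] == v
      tp_mean <- if (septal) .POP$septal_t_peak_mean
                 else if (lateral) .POP$lateral_t_peak_mean
                 else .POP$t_peak_mean
      wd_mean <- if (septal) .POP$septal_width_mean else .POP$width_mean
      amp <- .clip(stats::rnorm(1, .POP$amp_mean, .POP$amp_sd),
                   .POP$amp_min, .POP$amp_max)
      tp <- stats::rnorm(1, tp_mean, .POP$t_peak_sd)
      wd <- stats::rnorm(1, wd_mean, .POP$width_sd)
      reb <- 0
      if (septal) {
        tp <- tp + eff$septal_t_peak
        reb <- .POP$septal_rebound
      }
      if (lateral) {
        amp <- .clip(amp + eff$lateral_amplitude, .POP$amp_min, .POP$amp_max + 10)
        tp <- tp + eff$lateral_t_peak
      }
      ## keep the lobe inside [0, cycle]
      wd <- .clip(wd, 0.2, min(2 * tp, 2 * (cfg$cycle_length_s - tp)))
      p <- segment_params(amp, tp, wd, rebound_fraction = reb,
                          noise_sd = cfg$noise_sd)
      make_segment_curve(p, cfg$cycle_length_s, cfg$rate_hz, segment_id = sg)
    })
    views[[v]] <- view_recording(v, traces, cfg$t_avc_s[[v]])
  }
  esv0 <- .clip(stats::rnorm(1, .POP$esv_mean, .POP$esv_sd),
                .POP$esv_min, .POP$esv_max)
  drop <- if (label == "responder") stats::runif(1, 0.20, 0.45)
          else stats::runif(1, -0.08, 0.12)
  esv1 <- esv0 * (1 - drop)
  qrs <- .clip(stats::rnorm(1, .POP$qrs_mean, .POP$qrs_sd), 120, 220)
  lvef <- .clip(stats::rnorm(1, .POP$lvef_mean, .POP$lvef_sd), 10, 45)
  patient_record(pid, views, qrs, lvef, esv0, esv1)
}

#' Generate a synthetic cohort
#'
#' Labels are assigned first (exact responder count after rounding), then
#' each patient's curve parameters are drawn conditioned on the label.
#' Responder/non-responder ESV pairs are drawn so that the stored response
#' label always agrees with [classify_response()]. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @return List with `cohort` (list of [patient_record()]) and `labels`
#'   (character vector).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1")
  set.seed(cfg$seed)
  n_resp <- round(cfg$responder_fraction * cfg$n_patients)
  labels <- sample(c(rep("responder", n_resp),
                     rep("non-responder", cfg$n_patients - n_resp)))
  ids <- sprintf("SYN%03d", seq_len(cfg$n_patients))
  cohort <- mapply(function(pid, lab) .draw_patient(cfg, pid, lab),
                   ids, labels, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  list(cohort = cohort, labels = labels)
}

#' Write a synthetic cohort to disk as view files plus a manifest
#'
#' Emits one waveform file per view per patient and a cohort manifest, so
#' the whole pipeline can be exercised end-to-end from files.
#'
#' @param cohort List of [patient_record()]s.
#' @param dir Output directory (created if needed).
#' @param header Optional named character vector of `# key: value` comment
#'   lines prepended to the manifest.
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(p) {
    files <- stats::setNames(
      sprintf("%s_%s.csv", p$patient_id, strain_views()), strain_views())
    for (v in strain_views())
      write_view_file(p$views[[v]], file.path(dir, files[[v]]))
    data.frame(patient_id = p$patient_id,
               file_4ch = files[["4ch"]], file_3ch = files[["3ch"]],
               file_2ch = files[["2ch"]],
               qrs_ms = p$qrs_duration, lvef_pct = p$lvef,
               esv_baseline_ml = p$esv_baseline,
               esv_followup_ml = p$esv_followup,
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  con <- file(manifest, "w", encoding = "UTF-8")
  if (!is.null(header))
    writeLines(paste0("# ", names(header), ": ", header), con)
  utils::write.csv(do.call(rbind, rows), con, row.names = FALSE)
  close(con)
  invisible(manifest)
}
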