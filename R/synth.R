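#' Built-in measurement-status descriptions
#'
#' Six statuses emulating everyday physiological conditions: resting,
#' listening to calm or excited music, watching relaxed or scared videos,
#' and immediately after exercise. Each carries the mean percent change of
#' heart rate relative to resting (0 for resting, about 5-6% for calm
#' music / scared video, 7-8% for excited music / relaxed video, 48% for
#' exercising), a per-beat heart-rate spread, and additive-noise levels
#' (baseline wander, 60 Hz mains, broadband).
#'
#' @return Named list of `status_spec` lists with fields `status_name`,
#'   `hr_change_pct`, `hr_sd` (bpm) and `noise` (list with `baseline_amp`
#'   mV, `baseline_hz`, `mains_amp` mV, `white_sd` mV).
#' @export
status_specs <- function() {
  mk <- function(name, pct, sd, base_amp = 0.05, base_hz = 0.3,
                 mains_amp = 0.02, white_sd = 0.01) {
    structure(list(status_name = name, hr_change_pct = pct, hr_sd = sd,
                   noise = list(baseline_amp = base_amp, baseline_hz = base_hz,
                                mains_amp = mains_amp, white_sd = white_sd)),
              class = "status_spec")
  }
  list(
    resting       = mk("resting",       0,  2.5),
    calm_music    = mk("calm_music",    5.5, 3),
    excited_music = mk("excited_music", 7.5, 3),
    relaxed_video = mk("relaxed_video", 7.5, 3),
    scared_video  = mk("scared_video",  5.5, 3),
    exercising    = mk("exercising",   48,  6, base_amp = 0.10,
                       base_hz = 0.35, white_sd = 0.02))
}

# Reference heart rate (bpm) at which base section durations are defined.
.REF_HR <- 70

#' Generate a population of synthetic ECG subject profiles
#'
#' Each subject gets an individual beat morphology (amplitudes and widths of
#' the P, Q, R, S and T waves, built as smooth compact-support bumps), base
#' durations for the four beat sections (PR interval, QRS complex, ST
#' interval, TP segment) constrained to sum to one beat period at the 70 bpm
#' reference heart rate, and heart-rate slopes for the PR and ST sections.
#' The QRS duration does not vary with heart rate, and the TP segment
#' absorbs the remainder of the RR interval (60000/HR ms), so it shrinks the
#' most as heart rate rises - the ordering the regression stage is expected
#' to recover.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; the population is fully reproducible.
#' @return List of `subject_profile` objects. Fields per profile:
#'   `subject_id`, `rest_hr` (bpm), `wave_params` (5 x (amp mV, width_frac)),
#'   `base_durations` (named ms at 70 bpm), `duration_slopes` (named ms/bpm;
#'   the TP entry is the implied local slope of the remainder law at 70 bpm,
#'   recorded for reference and not used in generation), `rng_seed`.
#' @examples
#' pop <- make_population(3, seed = 1)
#' pop[[1]]$base_durations
#' @export
make_population <- function(n_subjects, seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    stop("`n_subjects` must be a positive count", call. = FALSE)
  n_subjects <- as.integer(n_subjects)
  set.seed(as.integer(seed))
  rng_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  pop <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    wp <- rbind(
      P = c(amp = stats::runif(1, 0.10, 0.22), width_frac = stats::runif(1, 0.55, 0.70)),
      Q = c(amp = -stats::runif(1, 0.06, 0.15), width_frac = stats::runif(1, 0.15, 0.20)),
      R = c(amp = stats::runif(1, 0.90, 1.70), width_frac = stats::runif(1, 0.44, 0.52)),
      S = c(amp = -stats::runif(1, 0.12, 0.30), width_frac = stats::runif(1, 0.15, 0.20)),
      T = c(amp = stats::runif(1, 0.25, 0.50), width_frac = stats::runif(1, 0.60, 0.75)))
    base <- c(pr = stats::runif(1, 130, 175), qrs = stats::runif(1, 85, 110),
              st = stats::runif(1, 280, 330))
    base <- c(base, tp = 60000 / .REF_HR - sum(base))
    slopes <- c(pr = -0.8 * stats::runif(1, 0.75, 1.25), qrs = 0,
                st = -2.5 * stats::runif(1, 0.75, 1.25))
    slopes <- c(slopes,
                tp = -60000 / .REF_HR^2 - slopes[["pr"]] - slopes[["st"]])
    pop[[i]] <- structure(
      list(subject_id = sprintf("S%02d", i),
           rest_hr = stats::runif(1, 62, 78),
           wave_params = wp,
           base_durations = base,
           duration_slopes = slopes,
           rng_seed = rng_seeds[i]),
      class = "subject_profile")
  }
  sig <- vapply(pop, function(p) paste(signif(p$wave_params, 10), collapse = ","), "")
  if (anyDuplicated(sig)) stop("degenerate population: duplicate morphologies")
  pop
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s  rest HR %.1f bpm\n", x$subject_id, x$rest_hr))
  cat("  base durations (ms at 70 bpm): ",
      paste(sprintf("%s=%.1f", names(x$base_durations), x$base_durations),
            collapse = " "), "\n")
  invisible(x)
}

# Section durations (ms) for one beat at heart rate `hr`.
# PR and ST follow the linear law base + slope*(hr - 70); QRS is flat; TP is
# the remainder of the RR interval so that the beat period is exactly
# 60000/hr ms. `jitter` is additive on PR/ST (TP re-absorbs it).
section_law <- function(profile, hr, jitter = c(0, 0)) {
  b <- profile$base_durations; s <- profile$duration_slopes
  rr <- 60000 / hr
  pr <- b[["pr"]] + s[["pr"]] * (hr - .REF_HR) + jitter[1]
  qrs <- b[["qrs"]]
  st <- b[["st"]] + s[["st"]] * (hr - .REF_HR) + jitter[2]
  tp <- rr - pr - qrs - st
  c(pr = pr, qrs = qrs, st = st, tp = tp)
}

# Render one Hann (raised-cosine) bump into `sig` (modified in place by
# returning the updated vector). Support is [centre - halfw, centre + halfw].
add_bump <- function(sig, centre, halfw, amp) {
  if (halfw < 1) return(sig)
  idx <- max(1L, centre - halfw):min(length(sig), centre + halfw)
  sig[idx] <- sig[idx] + amp * 0.5 * (1 + cos(pi * (idx - centre) / halfw))
  sig
}

#' Synthesize one ECG record with ground-truth fiducials
#'
#' Renders a single-lead record beat by beat. Per-beat heart rate is drawn
#' from a truncated normal around the status target (the subject's resting
#' heart rate scaled by the status' percent change), each beat's four
#' sections follow the subject's heart-rate law (see [make_population()]),
#' and the waveform is a sum of smooth compact-support bumps, so every wave
#' onset/offset and peak has an exact ground-truth sample index. Baseline
#' wander, 60 Hz mains interference and white noise are added per the
#' status' noise spec.
#'
#' @param profile a `subject_profile` from [make_population()].
#' @param status a `status_spec` or the name of one of [status_specs()].
#' @param duration_s record length in seconds (> 0).
#' @param fs sampling rate in Hz (>= 100, default 500).
#' @param seed integer seed; fixed (profile, status, seed) reproduces the
#'   record exactly.
#' @param noise_scale multiplier on all three noise amplitudes (0 = clean).
#' @param hr_fixed if non-NULL, every beat uses exactly this heart rate
#'   (bpm) and section jitter is disabled.
#' @param hr_clip admissible instantaneous heart-rate range (bpm).
#' @param amp_hr_coef named numeric, fractional amplitude change per bpm
#'   above 70 for each wave. The default gives the R wave a mild increase
#'   and the T wave a decrease with rising heart rate - the
#'   amplitude-vs-heart-rate effect reported for exercise ECG, which time
#'   normalization deliberately does not correct. Set all zero for
#'   amplitude-stationary beats.
#' @param section_jitter_sd per-beat biological scatter (ms, standard
#'   deviation, truncated at 2.5 sd) added to the PR and ST durations and
#'   absorbed by TP. The defaults give section-vs-heart-rate regressions
#'   the graded determination typical of real recordings (TP tightest,
#'   then ST, then PR, QRS flat) instead of implausibly exact lines.
#'   Disabled when `hr_fixed` is set.
#' @return A list of class `ecg_synthesis`: `record` (an [ecg_record()]),
#'   `truth` (data.frame of 0-based landmark sample indices per complete
#'   beat: Pon, Ppeak, QRSon, Qpeak, Rpeak, Speak, QRSoff, Tpeak, Toff,
#'   Pon_next), `hr` (per-beat scheduled bpm), `sections_ms` (per-beat
#'   realized section durations, ms), `clean` (noise-free samples).
#' @export
synthesize_record <- function(profile, status, duration_s = 20, fs = 500,
                              seed = 1L, noise_scale = 1, hr_fixed = NULL,
                              hr_clip = c(40, 180),
                              amp_hr_coef = c(P = 0, Q = 0, R = 0.002,
                                              S = 0, T = -0.003),
                              section_jitter_sd = c(pr = 12, st = 22)) {
  stopifnot(inherits(profile, "subject_profile"))
  if (is.character(status)) status <- status_specs()[[match.arg(status, names(status_specs()))]]
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be positive", call. = FALSE)
  if (!is.numeric(fs) || fs < 100)
    stop("`fs` below 100 Hz cannot resolve the QRS complex", call. = FALSE)
  set.seed(as.integer(seed))
  n <- as.integer(round(duration_s * fs))
  target_hr <- profile$rest_hr * (1 + status$hr_change_pct / 100)

  pon <- 0L  # 0-based sample index of the current beat's P onset
  rows <- list(); hrs <- numeric(0); secs <- list()
  sig <- numeric(n + as.integer(2 * fs))  # head-room for the final partial beat
  wp <- profile$wave_params
  while (pon < n) {
    hr <- if (!is.null(hr_fixed)) hr_fixed else
      min(max(stats::rnorm(1, target_hr, status$hr_sd), hr_clip[1]), hr_clip[2])
    jit <- if (is.null(hr_fixed)) {
      raw <- stats::rnorm(2, 0, section_jitter_sd)
      pmin(pmax(raw, -2.5 * section_jitter_sd), 2.5 * section_jitter_sd)
    } else c(0, 0)
    d <- section_law(profile, hr, jit)
    if (any(d < 25)) d <- section_law(profile, hr, jit / 2)
    if (any(d < 25)) d <- section_law(profile, hr, c(0, 0))
    if (any(d < 20))
      stop(sprintf("degenerate section durations at %.0f bpm for %s",
                   hr, profile$subject_id), call. = FALSE)
    ns <- round(d * fs / 1000)
    rr_n <- round(60000 / hr * fs / 1000)
    ns[["tp"]] <- rr_n - sum(ns[c("pr", "qrs", "st")])
    qon <- pon + ns[["pr"]]; qoff <- qon + ns[["qrs"]]
    toff <- qoff + ns[["st"]]; pon_next <- toff + ns[["tp"]]

    h_p <- floor(wp["P", "width_frac"] * ns[["pr"]] / 2)
    h_q <- max(2, floor(wp["Q", "width_frac"] * ns[["qrs"]]))
    h_r <- max(3, floor(wp["R", "width_frac"] * ns[["qrs"]] / 2))
    h_s <- max(2, floor(wp["S", "width_frac"] * ns[["qrs"]]))
    h_t <- floor(wp["T", "width_frac"] * ns[["st"]] / 2)
    cp <- pon + h_p
    cq <- qon + h_q
    cr <- qon + round(ns[["qrs"]] / 2)
    cs <- qoff - h_s
    ct <- toff - h_t
    # amplitude modulation with heart rate (floor keeps polarity intact)
    gain <- pmax(1 + amp_hr_coef[c("P", "Q", "R", "S", "T")] * (hr - .REF_HR),
                 0.2)
    # +1: R vectors are 1-based, landmarks are 0-based
    sig <- add_bump(sig, cp + 1L, h_p, wp["P", "amp"] * gain[["P"]])
    sig <- add_bump(sig, cq + 1L, h_q, wp["Q", "amp"] * gain[["Q"]])
    sig <- add_bump(sig, cr + 1L, h_r, wp["R", "amp"] * gain[["R"]])
    sig <- add_bump(sig, cs + 1L, h_s, wp["S", "amp"] * gain[["S"]])
    sig <- add_bump(sig, ct + 1L, h_t, wp["T", "amp"] * gain[["T"]])
    rows[[length(rows) + 1L]] <-
      data.frame(Pon = pon, Ppeak = cp, QRSon = qon, Qpeak = cq, Rpeak = cr,
                 Speak = cs, QRSoff = qoff, Tpeak = ct, Toff = toff,
                 Pon_next = pon_next)
    hrs <- c(hrs, hr)
    secs[[length(secs) + 1L]] <- ns / fs * 1000
    pon <- as.integer(pon_next)
  }
  truth <- do.call(rbind, rows)
  complete <- truth$Pon_next <= n
  clean <- sig[seq_len(n)]

  noisy <- clean
  nz <- status$noise
  if (noise_scale > 0) {
    t <- (seq_len(n) - 1) / fs
    noisy <- noisy +
      noise_scale * nz$baseline_amp *
        sin(2 * pi * nz$baseline_hz * t + stats::runif(1, 0, 2 * pi)) +
      noise_scale * nz$mains_amp *
        sin(2 * pi * 60 * t + stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(n, 0, noise_scale * nz$white_sd)
  }
  rec <- ecg_record(noisy, fs = fs, subject_id = profile$subject_id,
                    status = status$status_name,
                    record_id = sprintf("%s_%s_seed%d", profile$subject_id,
                                        status$status_name, as.integer(seed)))
  sections_ms <- do.call(rbind, secs)
  structure(list(record = rec, truth = truth[complete, , drop = FALSE],
                 hr = hrs[complete],
                 sections_ms = as.data.frame(sections_ms)[complete, , drop = FALSE],
                 clean = clean),
            class = "ecg_synthesis")
}

#' @export
print.ecg_synthesis <- function(x, ...) {
  cat(sprintf("<ecg_synthesis> %s: %d complete beats, mean HR %.1f bpm\n",
              x$record$record_id, nrow(x$truth), mean(x$hr)))
  invisible(x)
}

#' Synthesize a multi-subject, multi-status cohort
#'
#' Convenience wrapper producing one or more records per subject and status.
#'
#' @param population list from [make_population()].
#' @param statuses character vector of status names (see [status_specs()]).
#' @param records_per_status records per subject and status.
#' @param duration_s,fs,noise_scale passed to [synthesize_record()].
#' @param seed integer master seed; record seeds are derived from it.
#' @return List of `ecg_synthesis` objects.
#' @export
synthesize_cohort <- function(population, statuses = "resting",
                              records_per_status = 1, duration_s = 20,
                              fs = 500, noise_scale = 1, seed = 1L) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L,
                      length(population) * length(statuses) * records_per_status)
  out <- list(); k <- 0L
  for (p in population) for (st in statuses) for (r in seq_len(records_per_status)) {
    k <- k + 1L
    syn <- synthesize_record(p, st, duration_s = duration_s, fs = fs,
                             seed = seeds[k], noise_scale = noise_scale)
    syn$record$record_id <- sprintf("%s_%s_r%d", p$subject_id, st, r)
    out[[k]] <- syn
  }
  out
}
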