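#' Z-score a sample vector
#'
#' Centres to mean 0 and scales to unit standard deviation (unbiased, n-1
#' denominator).
#'
#' @param x numeric vector with positive spread.
#' @return The standardized vector.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop("constant input cannot be z-scored", call. = FALSE)
  (x - mean(x)) / s
}

# cubic-spline resampling of one half-open section [0, n_in) to n_out
# samples; identity when n_in == n_out.
resample_section <- function(y, n_out) {
  n_in <- length(y)
  if (n_in < 2 || n_out < 2)
    stop("degenerate section (fewer than 2 samples)", call. = FALSE)
  if (n_in == n_out) return(y)
  xout <- (seq_len(n_out) - 1) * (n_in / n_out)
  stats::spline(x = seq_len(n_in) - 1, y = y, xout = xout, method = "fmm")$y
}

new_normalized_beat <- function(samples, fiducials, method, beat) {
  structure(
    list(samples = samples, fiducials = fiducials, method = method,
         hr = beat$hr, fs = beat$fs, record_id = beat$record_id,
         subject_id = beat$subject_id, status = beat$status),
    class = "normalized_beat")
}

#' @export
print.normalized_beat <- function(x, ...) {
  cat(sprintf("<normalized_beat> %s [%s]: %d samples, source HR %.1f bpm\n",
              x$record_id, x$method, length(x$samples), x$hr))
  invisible(x)
}

#' Non-linear (per-section) beat normalization
#'
#' The proposed normalization: each of the four half-open beat sections
#' (PR, QRS, ST, TP) is independently resampled by cubic-spline
#' interpolation to its reference duration at the reference heart rate
#' (the durations a fitted section model predicts at 70 bpm), the sections
#' are concatenated in order, and the whole beat is amplitude z-scored.
#' Every beat so normalized has the same length,
#' `sum(round(refs * fs / 1000))` samples, regardless of its heart rate.
#'
#' @param beat an `ecg_beat` from [segment_beats()].
#' @param refs named numeric of reference durations (ms) for pr, qrs, st,
#'   tp, from [reference_durations()].
#' @return A `normalized_beat` (method `"proposed"`) with fiducials mapped
#'   onto the normalized grid.
#' @export
normalize_beat_proposed <- function(beat, refs) {
  stopifnot(inherits(beat, "ecg_beat"))
  f <- beat$fiducials
  fs <- beat$fs
  bounds <- c(0, f[["QRSon"]], f[["QRSoff"]], f[["Toff"]], f[["Pon_next"]])
  if (any(diff(bounds) < 2))
    stop("degenerate section in beat", call. = FALSE)
  n_ref <- unname(round(refs[c("pr", "qrs", "st", "tp")] * fs / 1000))
  pieces <- vector("list", 4)
  for (s in 1:4)
    pieces[[s]] <- resample_section(
      beat$samples[(bounds[s] + 1):bounds[s + 1]], n_ref[s])
  samples <- zscore(unlist(pieces, use.names = FALSE))
  new_bounds <- c(0, cumsum(n_ref))
  map <- function(idx) {
    s <- findInterval(idx, bounds[-5], rightmost.closed = FALSE)
    s <- pmin(pmax(s, 1), 4)
    new_bounds[s] + round((idx - bounds[s]) *
                            (n_ref[s] / (bounds[s + 1] - bounds[s])))
  }
  fid <- c(Pon = 0, Ppeak = map(f[["Ppeak"]]), QRSon = new_bounds[2],
           Qpeak = map(f[["Qpeak"]]), Rpeak = map(f[["Rpeak"]]),
           Speak = map(f[["Speak"]]), QRSoff = new_bounds[3],
           Tpeak = map(f[["Tpeak"]]), Toff = new_bounds[4],
           Pon_next = new_bounds[5])
  new_normalized_beat(samples, fid, "proposed", beat)
}

#' Linear whole-beat normalization (comparator)
#'
#' The conventional RR-based method: the entire beat is uniformly resampled
#' to the reference RR interval and z-scored. One global time-scale factor;
#' section proportions are preserved, not corrected.
#'
#' @param beat an `ecg_beat`.
#' @param ref_rr reference beat duration in ms (default one beat at
#'   70 bpm, 60000/70 ms).
#' @return A `normalized_beat` (method `"linear"`).
#' @export
normalize_beat_linear <- function(beat, ref_rr = 60000 / 70) {
  stopifnot(inherits(beat, "ecg_beat"))
  n_in <- length(beat$samples)
  if (n_in < 2) stop("empty beat", call. = FALSE)
  n_out <- round(ref_rr * beat$fs / 1000)
  samples <- zscore(resample_section(beat$samples, n_out))
  scale <- n_out / n_in
  fid <- round(beat$fiducials * scale)
  fid[["Pon_next"]] <- n_out
  new_normalized_beat(samples, fid, "linear", beat)
}

#' Fixed-duration T-wave normalization (comparator)
#'
#' Resamples only the T wave to a fixed 120 ms duration (the approximate
#' resting T duration), leaving the rest of the beat untouched, then
#' z-scores. The delineator does not emit a T onset, so the T section is
#' taken as [Tpeak - (Toff - Tpeak), Toff), a symmetric proxy around the
#' peak; this approximation applies to this comparator only.
#'
#' @param beat an `ecg_beat`.
#' @param t_ms target T-wave duration in ms (default 120).
#' @return A `normalized_beat` (method `"twave120"`).
#' @export
normalize_beat_twave <- function(beat, t_ms = 120) {
  stopifnot(inherits(beat, "ecg_beat"))
  f <- beat$fiducials
  if (anyNA(f[c("Tpeak", "Toff")])) stop("missing T wave", call. = FALSE)
  fs <- beat$fs
  t_on <- max(f[["QRSoff"]], f[["Tpeak"]] - (f[["Toff"]] - f[["Tpeak"]]))
  n_t <- f[["Toff"]] - t_on
  if (n_t < 2) stop("degenerate T section", call. = FALSE)
  n_out <- round(t_ms * fs / 1000)
  t_new <- resample_section(beat$samples[(t_on + 1):f[["Toff"]]], n_out)
  samples <- zscore(c(beat$samples[seq_len(t_on)], t_new,
                      beat$samples[(f[["Toff"]] + 1):length(beat$samples)]))
  shift <- n_out - n_t
  fid <- f
  fid[["Tpeak"]] <- t_on + round((f[["Tpeak"]] - t_on) * n_out / n_t)
  for (k in c("Toff", "Pon_next")) fid[[k]] <- f[[k]] + shift
  new_normalized_beat(samples, fid, "twave120", beat)
}

#' Length-matched raw beats (no time normalization)
#'
#' Baseline for comparisons: the beat is truncated (or padded with its last
#' sample) to a common length and z-scored, with no time-axis correction.
#'
#' @param beat an `ecg_beat`.
#' @param length_out common length in samples.
#' @return A `normalized_beat` (method `"raw"`).
#' @export
normalize_beat_raw <- function(beat, length_out) {
  stopifnot(inherits(beat, "ecg_beat"))
  n <- length(beat$samples)
  samples <- if (n >= length_out) beat$samples[seq_len(length_out)]
             else c(beat$samples, rep(beat$samples[n], length_out - n))
  fid <- pmin(beat$fiducials, length_out)
  new_normalized_beat(zscore(samples), fid, "raw", beat)
}

#' Normalize a list of beats by any method
#'
#' Applies the chosen normalization to every beat, dropping (and counting)
#' beats that fail, e.g. because a section is degenerate.
#'
#' @param beats list of `ecg_beat` objects.
#' @param method one of "proposed", "linear", "twave120", "raw".
#' @param refs reference durations, required for `"proposed"`.
#' @param ref_rr reference RR (ms) for `"linear"`.
#' @param t_ms T target (ms) for `"twave120"`.
#' @param raw_length common length for `"raw"`; default the maximum beat
#'   length in `beats` (shorter beats are padded with their last sample,
#'   preserving the section misalignment raw beats actually suffer).
#' @return List of `normalized_beat`s with attribute `n_skipped`.
#' @export
normalize_beats <- function(beats, method = c("proposed", "linear",
                                              "twave120", "raw"),
                            refs = NULL, ref_rr = 60000 / 70, t_ms = 120,
                            raw_length = NULL) {
  method <- match.arg(method)
  if (method == "proposed" && is.null(refs))
    stop("`refs` required for the proposed method", call. = FALSE)
  if (method == "raw" && is.null(raw_length))
    raw_length <- max(vapply(beats, function(b) length(b$samples), 1L))
  out <- list(); skipped <- 0L
  for (b in beats) {
    nb <- tryCatch(switch(method,
                          proposed = normalize_beat_proposed(b, refs),
                          linear = normalize_beat_linear(b, ref_rr),
                          twave120 = normalize_beat_twave(b, t_ms),
                          raw = normalize_beat_raw(b, raw_length)),
                   error = function(e) NULL)
    if (is.null(nb)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- nb
  }
  attr(out, "n_skipped") <- skipped
  out
}
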