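#' Align equal-length beats at the median R position
#'
#' Circularly shifts each beat so its R peak lands on the median R index of
#' the group, the overlap used when averaging beats into a template. With
#' `at_r = FALSE` the beats are stacked as cut (aligned at their Pon start)
#' with no shift - the appropriate treatment for raw, un-normalized beats,
#' for which R alignment would itself be a fiducial-based time correction.
#'
#' @param beats list of equal-length `normalized_beat`s.
#' @param at_r align at the median R peak (default) or not at all.
#' @return List with `mat` (one aligned beat per row) and `r_index` (the
#'   common 0-based R position).
#' @export
align_beats <- function(beats, at_r = TRUE) {
  lens <- vapply(beats, function(b) length(b$samples), 1L)
  if (length(unique(lens)) != 1) stop("beats must share one length", call. = FALSE)
  r <- vapply(beats, function(b) as.integer(b$fiducials[["Rpeak"]]), 1L)
  r_med <- as.integer(round(stats::median(r)))
  n <- lens[1]
  mat <- t(vapply(seq_along(beats), function(i) {
    shift <- if (at_r) (r[i] - r_med) %% n else 0L
    x <- beats[[i]]$samples
    if (shift == 0) x else c(x[(shift + 1):n], x[seq_len(shift)])
  }, numeric(n)))
  list(mat = mat, r_index = r_med)
}

#' Per-subject template similarity for a cohort, by method
#'
#' The full similarity protocol of the template stage: per subject,
#' normalize all beats by `method`, build the representative beat from the
#' subject's resting beats (aligned at the median R except for raw beats,
#' with outlier rejection), then score every beat against that template
#' with lag-tolerant Pearson correlation.
#'
#' @param beats list of `ecg_beat`s for the whole cohort.
#' @param method normalization method tag.
#' @param refs reference durations for the proposed method.
#' @param raw_length common raw length (default cohort maximum).
#' @param max_lag_ms lag window for [similarity()].
#' @return data.frame: subject_id, status, mean similarity, n beats,
#'   outlier percent (from the resting template pool).
#' @export
cohort_similarity <- function(beats, method, refs = NULL, raw_length = NULL,
                              max_lag_ms = 25) {
  subs <- vapply(beats, `[[`, "", "subject_id")
  if (is.null(raw_length))
    raw_length <- max(vapply(beats, function(b) length(b$samples), 1L))
  rows <- list()
  for (s in unique(subs)) {
    nb <- normalize_beats(beats[subs == s], method, refs = refs,
                          raw_length = raw_length)
    if (length(nb) < 5) next
    stt <- vapply(nb, `[[`, "", "status")
    fs <- nb[[1]]$fs
    mat <- align_beats(nb, at_r = method != "raw")$mat
    restm <- mat[stt == "resting", , drop = FALSE]
    if (nrow(restm) < 3) next
    os <- detect_outliers(restm)
    tpl <- representative_beat(restm, os)
    sims <- vapply(seq_len(nrow(mat)), function(i)
      similarity(tpl$samples, mat[i, ], max_lag_ms = max_lag_ms, fs = fs), 0)
    for (st in unique(stt))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, status = st, method = method,
        similarity = mean(sims[stt == st]), n_beats = sum(stt == st),
        outlier_pct = 100 * sum(os$outlier_mask) / length(os$rho))
  }
  do.call(rbind, rows)
}

#' Detect outlier beats against the temporary mean beat
#'
#' The temporary beat is the elementwise mean of all aligned candidate
#' beats; each beat's Pearson correlation rho with it is computed, and a
#' beat is an outlier when rho falls below mean(rho) - 0.5 * sd(rho).
#'
#' @param beats list of >= 3 equal-length `normalized_beat`s, or a numeric
#'   matrix of already-aligned beats (one per row).
#' @return Object of class `template_stats`: `rho`, `mu_rho`, `sigma_rho`,
#'   `threshold`, logical `outlier_mask`.
#' @export
detect_outliers <- function(beats) {
  mat <- if (is.matrix(beats)) beats else align_beats(beats)$mat
  if (nrow(mat) < 3) stop("need at least 3 beats", call. = FALSE)
  tmp <- colMeans(mat)
  rho <- as.numeric(apply(mat, 1, stats::cor, y = tmp))
  outlier_stats(rho)
}

#' Outlier statistics from a vector of correlation coefficients
#'
#' The decision rule itself: given each beat's correlation rho with the
#' temporary mean beat, a beat is an outlier when
#' rho < mean(rho) - 0.5 * sd(rho) (unbiased standard deviation).
#'
#' @param rho numeric vector of correlation coefficients.
#' @return A `template_stats` object (see [detect_outliers()]).
#' @export
outlier_stats <- function(rho) {
  mu <- mean(rho)
  sigma <- stats::sd(rho)
  thr <- mu - 0.5 * sigma
  structure(list(rho = rho, mu_rho = mu, sigma_rho = sigma,
                 threshold = thr, outlier_mask = rho < thr),
            class = "template_stats")
}

#' @export
print.template_stats <- function(x, ...) {
  cat(sprintf("<template_stats> n = %d, mu_rho = %.4f, sigma_rho = %.4f, threshold = %.4f, outliers = %d\n",
              length(x$rho), x$mu_rho, x$sigma_rho, x$threshold,
              sum(x$outlier_mask)))
  invisible(x)
}

#' Build the representative beat from inlier beats
#'
#' Elementwise mean over the beats that survived outlier rejection.
#'
#' @param beats list of equal-length `normalized_beat`s or an aligned
#'   matrix (as passed to [detect_outliers()]).
#' @param stats a `template_stats` from [detect_outliers()]; computed
#'   afresh when omitted.
#' @return Object of class `representative_beat`: `samples`, `r_index`,
#'   `n_inliers`, `subject_id`.
#' @export
representative_beat <- function(beats, stats = NULL) {
  if (is.matrix(beats)) {
    mat <- beats; r_index <- NA_integer_; subject <- ""
  } else {
    al <- align_beats(beats)
    mat <- al$mat; r_index <- al$r_index
    subject <- unique(vapply(beats, `[[`, "", "subject_id"))[1]
  }
  if (is.null(stats)) stats <- detect_outliers(mat)
  inl <- !stats$outlier_mask
  if (sum(inl) < 2) stop("fewer than 2 inlier beats", call. = FALSE)
  structure(list(samples = colMeans(mat[inl, , drop = FALSE]),
                 r_index = r_index, n_inliers = sum(inl),
                 subject_id = subject),
            class = "representative_beat")
}

#' @export
print.representative_beat <- function(x, ...) {
  cat(sprintf("<representative_beat> %s: %d samples from %d inliers\n",
              x$subject_id, length(x$samples), x$n_inliers))
  invisible(x)
}

#' Similarity of a beat to a representative beat
#'
#' Maximum Pearson correlation over integer lags within +/- `max_lag_ms`,
#' computed on the overlapping part only (no zero padding).
#'
#' @param template a `representative_beat` or numeric vector.
#' @param beat a `normalized_beat` or numeric vector of the same length.
#' @param max_lag_ms lag window in ms (default 25).
#' @param fs sampling rate (Hz) used to convert the lag window.
#' @return Correlation in [-1, 1].
#' @export
similarity <- function(template, beat, max_lag_ms = 25, fs = 500) {
  tv <- if (is.numeric(template)) template else template$samples
  bv <- if (is.numeric(beat)) beat else beat$samples
  if (length(tv) != length(bv)) stop("length mismatch", call. = FALSE)
  n <- length(tv)
  max_lag <- as.integer(round(max_lag_ms * fs / 1000))
  best <- -1
  for (lag in -max_lag:max_lag) {
    if (lag >= 0) { a <- tv[(1 + lag):n]; b <- bv[1:(n - lag)] }
    else { a <- tv[1:(n + lag)]; b <- bv[(1 - lag):n] }
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    if (r > best) best <- r
  }
  best
}

#' Percent of beats flagged as outliers
#'
#' @param beats list of equal-length normalized beats for one subject and
#'   method (>= 3).
#' @return Percent of beats below the outlier threshold.
#' @export
outlier_ratio <- function(beats) {
  st <- detect_outliers(beats)
  100 * sum(st$outlier_mask) / length(st$rho)
}
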