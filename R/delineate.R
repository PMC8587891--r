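# Dyadic (undecimated) wavelet delineation of ECG fiducial points, in the
# Mallat/Zhong quadratic-spline family: the transform at scale 2^j is
# proportional to the derivative of the signal smoothed at that scale, so
# wave peaks appear as zero-crossings between opposite-sign modulus maxima
# and wave boundaries as the decay of the modulus.

# causal convolution, same length as x, front-padded with x[1]
causal_conv <- function(x, f) {
  n <- length(x); p <- length(f)
  xx <- c(rep(x[1], p), x, rep(x[n], p))
  y <- stats::filter(xx, f, method = "convolution", sides = 1)
  as.numeric(y[(p + 1):(p + n)])
}

shift_left <- function(v, d) {
  n <- length(v)
  if (d <= 0) return(v)
  c(v[(d + 1):n], rep(v[n], d))
}

#' Dyadic quadratic-spline wavelet transform
#'
#' Undecimated (a-trous) transform at scales 2^1..2^`scales` with the
#' quadratic-spline derivative wavelet; each output column is time-aligned
#' with the input and has the same length.
#'
#' @param rec an [ecg_record()] or numeric vector.
#' @param scales number of dyadic scales (default 5).
#' @param fs sampling rate, only used when `rec` is a bare vector.
#' @return Numeric matrix, one column per scale.
#' @export
dyadic_wavelet <- function(rec, scales = 5, fs = NULL) {
  x <- if (inherits(rec, "ecg_record")) rec$samples else as.numeric(rec)
  n <- length(x)
  if (n < 3 * 2^(scales - 1) + 1)
    stop("record shorter than the largest analysis filter", call. = FALSE)
  W <- matrix(0, n, scales)
  a <- x
  delay_a <- 0
  for (j in seq_len(scales)) {
    u <- 2^(j - 1)
    g <- numeric(u + 1); g[1] <- 2; g[u + 1] <- -2
    h <- numeric(3 * u + 1); h[c(1, u + 1, 2 * u + 1, 3 * u + 1)] <- c(1, 3, 3, 1) / 8
    wj <- causal_conv(a, g)
    W[, j] <- shift_left(wj, as.integer(round(delay_a + u / 2)))
    a <- causal_conv(a, h)
    delay_a <- delay_a + 1.5 * u
  }
  W
}

# local extrema indices of v (strict on one side to survive plateaus)
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  d1 <- diff(v)
  which(d1[-(n - 1)] * d1[-1] < 0 | (d1[-(n - 1)] != 0 & d1[-1] == 0)) + 1L
}

# per-sample detection threshold: k * RMS of v over `win`-sample blocks
block_threshold <- function(v, win, k) {
  n <- length(v)
  nb <- max(1L, ceiling(n / win))
  thr <- numeric(n)
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * win + 1):min(b * win, n)
    thr[idx] <- k * sqrt(mean(v[idx]^2))
  }
  thr
}

# boundary search: walk from modulus-maximum `mm` in direction `dir`
# (-1 onset, +1 offset) until |w| drops below frac*|w[mm]|; limited to
# `max_step` samples.
mm_boundary <- function(w, mm, dir, frac, max_step) {
  lim <- abs(w[mm]) * frac
  i <- mm
  steps <- 0
  n <- length(w)
  while (steps < max_step) {
    j <- i + dir
    if (j < 1 || j > n) break
    if (abs(w[j]) < lim) return(j)
    i <- j; steps <- steps + 1
  }
  i
}

#' Detect ECG fiducial points
#'
#' R peaks are found as zero-crossings between opposite-sign modulus-maxima
#' pairs of the scale-2^2 transform exceeding a scale-adaptive threshold
#' (3x the RMS over sliding 2 s blocks), confirmed at scale 2^3, with a
#' 200 ms refractory period. QRS onset/offset come from the decay of the
#' scale-2^2 modulus around the flanking maxima; P and T peaks from
#' zero-crossings of the scale-2^4 transform inside search windows before /
#' after the QRS (the T window shrinks with heart rate, as the TP segment
#' does); P onset and T offset from boundary criteria at scale 2^3. Beats
#' whose landmarks are not in physiological order, or that lack a P or T
#' wave, are dropped.
#'
#' @param rec a pre-processed [ecg_record()].
#' @param cfg a [run_config()].
#' @return data.frame, one row per detected beat, columns Pon, Ppeak,
#'   QRSon, Qpeak, Rpeak, Speak, QRSoff, Tpeak, Toff (0-based sample
#'   indices, strictly increasing within each row).
#' @export
detect_fiducials <- function(rec, cfg = run_config()) {
  validate_record(rec)
  x <- rec$samples
  fs <- rec$fs
  n <- length(x)
  ms <- function(m) as.integer(round(m * fs / 1000))
  W <- dyadic_wavelet(rec, scales = 5)
  w2 <- W[, 2]; w3 <- W[, 3]; w4 <- W[, 4]

  ## ---- R peaks: modulus-maxima pairs at scale 2^2 ----
  thr2 <- block_threshold(w2, win = 2 * fs, k = 3)
  thr3 <- block_threshold(w3, win = 2 * fs, k = 3)
  ext <- local_extrema(w2)
  ext <- ext[abs(w2[ext]) > thr2[ext]]
  if (!length(ext)) stop("no R peaks found (flat or too-noisy record)", call. = FALSE)
  cand <- list()
  for (i in seq_len(length(ext) - 1)) {
    e1 <- ext[i]; e2 <- ext[i + 1]
    if (w2[e1] > 0 && w2[e2] < 0 && (e2 - e1) <= ms(120)) {
      seg <- w2[e1:e2]
      zc_rel <- which(seg[-length(seg)] > 0 & seg[-1] <= 0)
      if (!length(zc_rel)) next
      zc <- e1 + zc_rel[1] - 1L
      # confirm at scale 2^3
      lo <- max(1L, zc - ms(40)); hi <- min(n, zc + ms(40))
      if (max(abs(w3[lo:hi])) < 0.5 * thr3[zc]) next
      cand[[length(cand) + 1L]] <- c(zc = zc, strength = min(abs(w2[c(e1, e2)])),
                                     e1 = e1, e2 = e2)
    }
  }
  if (!length(cand)) stop("no R peaks found (flat or too-noisy record)", call. = FALSE)
  cand <- do.call(rbind, cand)
  # refractory: greedy keep-strongest within 200 ms
  ord <- order(-cand[, "strength"])
  keep <- logical(nrow(cand))
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i, "zc"] - cand[taken, "zc"]) > ms(200))) {
      keep[i] <- TRUE; taken <- c(taken, i)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand[, "zc"]), , drop = FALSE]

  # refine R to the signal extremum near the zero-crossing
  rpeaks <- apply(cand, 1, function(r) {
    lo <- max(1L, as.integer(r["zc"]) - ms(20)); hi <- min(n, as.integer(r["zc"]) + ms(20))
    lo + which.max(abs(x[lo:hi])) - 1L
  })
  if (length(rpeaks) < 2) stop("fewer than 2 complete beats detected", call. = FALSE)
  med_rr <- stats::median(diff(rpeaks))
  hr_est <- 60 * fs / med_rr

  ## ---- per-beat QRS boundaries, P and T waves ----
  out <- vector("list", length(rpeaks))
  for (b in seq_along(rpeaks)) {
    r <- rpeaks[b]
    e1 <- as.integer(cand[b, "e1"]); e2 <- as.integer(cand[b, "e2"])
    qwin_lo <- max(1L, r - ms(70)); qwin_hi <- min(n, r + ms(70))
    qrs_max2 <- max(abs(w2[qwin_lo:qwin_hi]))
    # earliest / latest significant scale-2 extremum of the complex; a
    # second, lower threshold catches shallow Q/S flank waves immediately
    # adjacent to the main pair
    ext_all <- local_extrema(w2)
    ext_all <- ext_all[ext_all >= qwin_lo & ext_all <= qwin_hi]
    ext_q <- ext_all[abs(w2[ext_all]) >= 0.06 * qrs_max2]
    if (!length(ext_q)) next
    mm_first <- min(ext_q); mm_last <- max(ext_q)
    pre <- ext_all[ext_all < mm_first & ext_all >= mm_first - ms(30) &
                     abs(w2[ext_all]) >= 0.03 * qrs_max2]
    if (length(pre)) mm_first <- min(pre)
    post <- ext_all[ext_all > mm_last & ext_all <= mm_last + ms(30) &
                      abs(w2[ext_all]) >= 0.03 * qrs_max2]
    if (length(post)) mm_last <- max(post)
    qrs_on <- mm_boundary(w2, mm_first, -1L, 0.05, ms(60))
    qrs_off <- mm_boundary(w2, mm_last, +1L, 0.05, ms(60))

    # P wave: zero-crossing of largest +/- pair at scale 2^4
    p_lo <- max(1L, qrs_on - ms(250))
    p_hi <- qrs_on - ms(40 * min(70 / hr_est, 1))
    p_res <- find_wave(x, w4, w3, p_lo, p_hi, qrs_max_ref = max(abs(w4[qwin_lo:qwin_hi])),
                       min_rel = 0.05, fs = fs)
    # T wave: HR-adaptive window after the QRS
    t_lo <- qrs_off + ms(60 * min(70 / hr_est, 1))
    t_hi <- min(n, qrs_off + ms(450 * min(70 / hr_est, 2)))
    t_res <- find_wave(x, w4, w3, t_lo, t_hi, qrs_max_ref = max(abs(w4[qwin_lo:qwin_hi])),
                       min_rel = 0.05, fs = fs)
    if (is.null(p_res) || is.null(t_res)) next

    # Q and S peaks: extrema adjacent to R inside the QRS
    qpk <- if (qrs_on < r) qrs_on + which.min(x[qrs_on:r]) - 1L else qrs_on
    spk <- if (r < qrs_off) r + which.min(x[r:qrs_off]) - 1L else qrs_off
    # monophasic fallback: pin just inside the boundary, preserving the
    # strict landmark ordering
    if (x[qpk] >= x[qrs_on] || qpk <= qrs_on) qpk <- qrs_on + 1L
    if (x[spk] >= x[qrs_off] || spk >= qrs_off) spk <- qrs_off - 1L
    row <- c(Pon = p_res$on, Ppeak = p_res$peak, QRSon = qrs_on, Qpeak = qpk,
             Rpeak = r, Speak = spk, QRSoff = qrs_off, Tpeak = t_res$peak,
             Toff = t_res$off)
    if (any(diff(row) <= 0)) next                # physiological order only
    out[[b]] <- row
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) < 2)
    stop("fewer than 2 complete beats delineated", call. = FALSE)
  res <- as.data.frame(out) - 1L  # 0-based indices
  # all R detections, including beats later rejected for missing P/T waves
  attr(res, "rpeaks") <- as.integer(rpeaks) - 1L
  attr(res, "n_rejected") <- length(rpeaks) - nrow(res)
  res
}

# Locate one mono-phasic wave (P or T) inside [lo, hi]: the zero-crossing
# between the largest opposite-sign modulus-maxima pair at scale 2^4 gives
# the peak; boundary decay at scale 2^3 gives onset/offset. Returns NULL
# when no significant wave is present.
find_wave <- function(x, w4, w3, lo, hi, qrs_max_ref, min_rel, fs) {
  n <- length(x)
  ms <- function(m) as.integer(round(m * fs / 1000))
  lo <- max(1L, lo); hi <- min(n, hi)
  if (hi - lo < ms(40)) return(NULL)
  seg <- lo:hi
  ext <- local_extrema(w4[seg])
  if (length(ext) < 2) return(NULL)
  ext <- seg[1] + ext - 1L
  sig <- max(abs(w4[ext]))
  if (sig < min_rel * qrs_max_ref) return(NULL)
  # largest positive extremum followed by largest negative one (upright wave)
  pos <- ext[w4[ext] > 0]; neg <- ext[w4[ext] < 0]
  best <- NULL; best_str <- 0
  for (p in pos) {
    after <- neg[neg > p & neg - p <= ms(300)]
    if (!length(after)) next
    q <- after[which.max(abs(w4[after]))]
    str <- min(w4[p], -w4[q])
    if (str > best_str) { best_str <- str; best <- c(p, q) }
  }
  if (is.null(best)) return(NULL)
  segpq <- w4[best[1]:best[2]]
  zc_rel <- which(segpq[-length(segpq)] > 0 & segpq[-1] <= 0)
  if (!length(zc_rel)) return(NULL)
  zc <- best[1] + zc_rel[1] - 1L
  plo <- max(1L, zc - ms(16)); phi <- min(n, zc + ms(16))
  peak <- plo + which.max(x[plo:phi]) - 1L
  # boundaries at the finer scale: strongest scale-3 extrema near the
  # wave's own scale-4 flank maxima (not the neighbouring waves')
  lwin <- max(1L, best[1] - ms(40)):peak
  rwin <- peak:min(n, best[2] + ms(40))
  mmL <- lwin[which.max(abs(w3[lwin]))]
  mmR <- rwin[which.max(abs(w3[rwin]))]
  on <- mm_boundary(w3, mmL, -1L, 0.05, ms(160))
  off <- mm_boundary(w3, mmR, +1L, 0.05, ms(160))
  list(on = on, peak = peak, off = off)
}

#' Segment a record into Pon-to-Pon beats
#'
#' Beat i spans the half-open interval [Pon_i, Pon_(i+1)); the final
#' incomplete beat is dropped. Instantaneous heart rate is 60/RR of the
#' beat (RR from consecutive R peaks); beats outside the configured clip
#' range are excluded and counted in the `n_excluded` attribute.
#'
#' @param rec an [ecg_record()].
#' @param fids data.frame from [detect_fiducials()] (or the generator's
#'   ground truth).
#' @param cfg a [run_config()].
#' @return List of `ecg_beat` objects (fields `samples`, `fiducials`
#'   re-indexed to beat start, `hr`, `record_id`, `subject_id`, `status`),
#'   with attribute `n_excluded`.
#' @export
segment_beats <- function(rec, fids, cfg = run_config()) {
  stopifnot(inherits(rec, "ecg_record"))
  need <- c("Pon", "Ppeak", "QRSon", "Qpeak", "Rpeak", "Speak", "QRSoff",
            "Tpeak", "Toff")
  if (!all(need %in% names(fids))) stop("missing landmark columns", call. = FALSE)
  fids <- fids[need]
  if (nrow(fids) < 2) stop("need at least 2 fiducial sets", call. = FALSE)
  if (any(apply(fids, 1, function(r) any(diff(r) <= 0))) ||
      any(diff(fids$Pon) <= 0))
    stop("fiducials out of physiological order", call. = FALSE)
  beats <- list(); excluded <- 0L
  for (i in seq_len(nrow(fids) - 1)) {
    p0 <- fids$Pon[i]; p1 <- fids$Pon[i + 1]
    rr <- (fids$Rpeak[i + 1] - fids$Rpeak[i]) / rec$fs
    hr <- 60 / rr
    if (hr < cfg$hr_clip[1] || hr > cfg$hr_clip[2]) { excluded <- excluded + 1L; next }
    if (fids$Toff[i] >= p1) { excluded <- excluded + 1L; next }  # T spills into next beat
    f <- as.numeric(fids[i, ]) - p0
    names(f) <- need
    f <- c(f, Pon_next = p1 - p0)
    beats[[length(beats) + 1L]] <- structure(
      list(samples = rec$samples[(p0 + 1):p1],   # 0-based half-open [p0, p1)
           fiducials = f, hr = hr, fs = rec$fs,
           record_id = rec$record_id, subject_id = rec$subject_id,
           status = rec$status),
      class = "ecg_beat")
  }
  attr(beats, "n_excluded") <- excluded
  beats
}

#' @export
print.ecg_beat <- function(x, ...) {
  cat(sprintf("<ecg_beat> %s: %d samples @ %g Hz, HR %.1f bpm\n",
              x$record_id, length(x$samples), x$fs, x$hr))
  invisible(x)
}
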