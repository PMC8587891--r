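#' Per-beat section durations
#'
#' Splits a Pon-to-Pon beat into its four contiguous sections and returns
#' their durations in milliseconds: PR interval (Pon-QRSon), QRS complex
#' (QRSon-QRSoff), ST interval (QRSoff-Toff) and TP segment (Toff-next
#' Pon). Sections are half-open, so the four durations sum exactly to the
#' beat duration.
#'
#' @param beat an `ecg_beat` from [segment_beats()].
#' @return data.frame with one row: pr, qrs, st, tp (ms) and hr (bpm).
#' @export
section_durations <- function(beat) {
  stopifnot(inherits(beat, "ecg_beat"))
  f <- beat$fiducials
  need <- c("Pon", "QRSon", "QRSoff", "Toff", "Pon_next")
  if (anyNA(f[need])) stop("missing landmark", call. = FALSE)
  k <- 1000 / beat$fs
  out <- data.frame(pr = (f[["QRSon"]] - f[["Pon"]]) * k,
                    qrs = (f[["QRSoff"]] - f[["QRSon"]]) * k,
                    st = (f[["Toff"]] - f[["QRSoff"]]) * k,
                    tp = (f[["Pon_next"]] - f[["Toff"]]) * k,
                    hr = beat$hr)
  if (any(out[1, 1:4] <= 0)) stop("zero-length section", call. = FALSE)
  out
}

#' Durations table for a list of beats
#'
#' @param beats list of `ecg_beat` objects.
#' @return data.frame with columns pr, qrs, st, tp (ms), hr (bpm),
#'   subject_id, status.
#' @export
section_table <- function(beats) {
  do.call(rbind, lapply(beats, function(b) {
    d <- section_durations(b)
    d$subject_id <- b$subject_id
    d$status <- b$status
    d
  }))
}

#' Fit a (piecewise-)linear duration-vs-heart-rate model for one section
#'
#' Least-squares fit of section duration (ms) against heart rate (bpm),
#' optionally as a continuous piecewise-linear function with 1, 2 or 3
#' segments. Breakpoints are chosen by grid search over interior heart-rate
#' deciles, minimizing the residual sum of squares; continuity is enforced
#' by fitting hinge bases. Because the models are nested, RMSE can only
#' decrease (to numerical precision) as segments are added.
#'
#' @param data data.frame from [section_table()] (needs the section column
#'   and `hr`).
#' @param section one of "pr", "qrs", "st", "tp".
#' @param n_pieces number of linear segments: 1, 2 or 3.
#' @param min_points minimum observations required per requested segment.
#' @return Object of class `section_model`: coefficients per piece
#'   (intercept ms, slope ms/bpm), breakpoints (bpm), `r2`, `rmse_ms`,
#'   `rmse_s`, and the heart-rate range of the data.
#' @examples
#' d <- data.frame(hr = seq(50, 130, 2))
#' d$tp <- 900 - 6 * d$hr
#' fit <- fit_section_model(d, "tp")
#' coef(fit)          # intercept 900, slope -6
#' predict(fit, newdata = 70)
#' @export
fit_section_model <- function(data, section = c("pr", "qrs", "st", "tp"),
                              n_pieces = 1, min_points = 10) {
  section <- match.arg(section)
  stopifnot(n_pieces %in% 1:3)
  y <- data[[section]]
  x <- data$hr
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < min_points * n_pieces)
    stop("insufficient data for the requested number of segments", call. = FALSE)
  if (diff(range(x)) < 20)
    stop("heart-rate spread below 20 bpm; fit would be ill-conditioned",
         call. = FALSE)

  hinge <- function(x, b) pmax(x - b, 0)
  fit_with <- function(bps) {
    X <- cbind(1, x)
    for (b in bps) X <- cbind(X, hinge(x, b))
    f <- stats::lm.fit(X, y)
    list(sse = sum(f$residuals^2), coef = f$coefficients, bps = bps)
  }

  grid <- unique(stats::quantile(x, probs = seq(0.1, 0.9, 0.1), names = FALSE))
  best <- NULL
  if (n_pieces == 1) {
    best <- fit_with(numeric(0))
  } else if (n_pieces == 2) {
    for (b in grid) {
      f <- fit_with(b)
      if (is.null(best) || f$sse < best$sse) best <- f
    }
  } else {
    for (i in seq_along(grid)) for (j in seq_along(grid)) {
      if (j <= i) next
      f <- fit_with(grid[c(i, j)])
      if (is.null(best) || f$sse < best$sse) best <- f
    }
  }

  n <- length(y)
  sst <- sum((y - mean(y))^2)
  beta <- best$coef
  bps <- best$bps
  # per-piece (intercept, slope) on the pieces' own scale
  pieces <- matrix(NA_real_, n_pieces, 2,
                   dimnames = list(NULL, c("intercept", "slope")))
  a <- beta[1]; b <- beta[2]
  pieces[1, ] <- c(a, b)
  if (n_pieces > 1) for (k in seq_along(bps)) {
    b <- b + beta[2 + k]
    a <- a - beta[2 + k] * bps[k]
    pieces[k + 1, ] <- c(a, b)
  }
  structure(
    list(section = section, n_pieces = n_pieces, breakpoints = bps,
         pieces = pieces, coef_basis = beta,
         r2 = if (sst > 0) 1 - best$sse / sst else 1,
         rmse_ms = sqrt(best$sse / n), rmse_s = sqrt(best$sse / n) / 1000,
         hr_range = range(x), n = n),
    class = "section_model")
}

#' @export
print.section_model <- function(x, ...) {
  cat(sprintf("<section_model> %s: %d piece(s), r2 = %.3f, RMSE = %.2f ms (%.4f s)\n",
              toupper(x$section), x$n_pieces, x$r2, x$rmse_ms, x$rmse_s))
  if (length(x$breakpoints))
    cat("  breakpoints (bpm):", paste(round(x$breakpoints, 1), collapse = ", "), "\n")
  for (k in seq_len(nrow(x$pieces)))
    cat(sprintf("  piece %d: %.2f %+.3f * HR  [ms]\n", k,
                x$pieces[k, 1], x$pieces[k, 2]))
  invisible(x)
}

#' @export
coef.section_model <- function(object, ...) object$pieces

#' @export
predict.section_model <- function(object, newdata, ...) {
  hr <- if (is.data.frame(newdata)) newdata$hr else as.numeric(newdata)
  beta <- object$coef_basis
  y <- beta[1] + beta[2] * hr
  for (k in seq_along(object$breakpoints))
    y <- y + beta[2 + k] * pmax(hr - object$breakpoints[k], 0)
  unname(y)
}

#' @export
plot.section_model <- function(x, data = NULL, ...) {
  hr <- seq(x$hr_range[1], x$hr_range[2], length.out = 200)
  if (!is.null(data))
    graphics::plot(data$hr, data[[x$section]], pch = 16, cex = 0.4,
                   col = "grey50", xlab = "heart rate [bpm]",
                   ylab = paste(toupper(x$section), "duration [ms]"), ...)
  else
    graphics::plot(hr, predict(x, hr), type = "n",
                   xlab = "heart rate [bpm]",
                   ylab = paste(toupper(x$section), "duration [ms]"), ...)
  graphics::lines(hr, predict(x, hr), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Fit all four section models
#'
#' @param data data.frame from [section_table()].
#' @param n_pieces segments per section (recycled to length 4).
#' @return Named list of `section_model`s (pr, qrs, st, tp).
#' @export
fit_all_sections <- function(data, n_pieces = 1) {
  n_pieces <- rep(n_pieces, length.out = 4)
  stats::setNames(
    lapply(seq_along(c("pr", "qrs", "st", "tp")), function(i)
      fit_section_model(data, c("pr", "qrs", "st", "tp")[i], n_pieces[i])),
    c("pr", "qrs", "st", "tp"))
}

#' Reference section durations at the normalization heart rate
#'
#' Evaluates each fitted section model at the reference heart rate
#' (70 bpm by default), giving the target durations the normalizer
#' resamples every beat to.
#'
#' @param models named list from [fit_all_sections()].
#' @param ref_hr reference heart rate (bpm).
#' @param hr_clip admissible heart-rate range; `ref_hr` outside it is an
#'   error.
#' @return Named numeric: pr, qrs, st, tp reference durations (ms).
#' @export
reference_durations <- function(models, ref_hr = 70, hr_clip = c(40, 180)) {
  if (ref_hr < hr_clip[1] || ref_hr > hr_clip[2])
    stop("`ref_hr` outside the admissible heart-rate range", call. = FALSE)
  out <- vapply(models, function(m) predict(m, ref_hr), 0)
  if (any(out <= 0)) stop("non-positive reference duration", call. = FALSE)
  out
}

#' Percent heart-rate change per status relative to resting
#'
#' @param hr_by_status data.frame with columns `status` and `hr` (one row
#'   per beat or record), or a named list of heart-rate vectors.
#' @param resting name of the baseline status.
#' @return Named numeric vector of percent changes
#'   (100 * (mean HR_status - mean HR_rest) / mean HR_rest).
#' @export
percent_hr_change <- function(hr_by_status, resting = "resting") {
  if (is.data.frame(hr_by_status))
    hr_by_status <- split(hr_by_status$hr, hr_by_status$status)
  if (!resting %in% names(hr_by_status))
    stop("resting baseline missing", call. = FALSE)
  base <- mean(hr_by_status[[resting]])
  if (!is.finite(base) || base <= 0)
    stop("invalid resting baseline", call. = FALSE)
  vapply(hr_by_status, function(h) 100 * (mean(h) - base) / base, 0)
}
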