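# The frozen 29-feature inventory computed from the five peak landmarks
# (P, Q, R, S, T) of a normalized beat, using coordinates (t in ms, a in
# z-units): 9 signed amplitude differences, 9 time differences, 5 slopes,
# 5 Euclidean distances in the (t, a) plane, and 1 area.
.AMP_PAIRS <- list(c("P", "R"), c("P", "S"), c("P", "T"), c("Q", "R"),
                   c("Q", "S"), c("Q", "T"), c("R", "S"), c("R", "T"),
                   c("S", "T"))
.SLOPE_PAIRS <- list(c("P", "Q"), c("Q", "R"), c("R", "S"), c("S", "T"),
                     c("P", "T"))

#' Names of the 29 fiducial features, in their frozen order
#'
#' @return Character vector of length 29.
#' @export
feature_names <- function() {
  pn <- function(p) paste0(p[1], p[2])
  c(paste0("amp_", vapply(.AMP_PAIRS, pn, "")),
    paste0("dur_", vapply(.AMP_PAIRS, pn, "")),
    paste0("slope_", vapply(.SLOPE_PAIRS, pn, "")),
    paste0("dist_", vapply(.SLOPE_PAIRS, pn, "")),
    "area_QRS")
}

#' Extract the 29 fiducial features from a normalized beat
#'
#' Peak coordinates are read off the normalized grid: time in ms, amplitude
#' in z-units. Features 1-9 are signed amplitude differences between peak
#' pairs, 10-18 the corresponding time differences, 19-23 slopes and 24-28
#' Euclidean distances in the (time, amplitude) plane for five adjacent
#' pairs, and 29 the trapezoidal area of the absolute amplitude over the
#' QRS complex. Amplitude features are scale-free (the beat is z-scored)
#' and all features are invariant to a rigid time shift of the beat.
#'
#' @param beat a `normalized_beat` with all nine landmarks.
#' @return Named numeric vector of length 29.
#' @export
extract_features <- function(beat) {
  stopifnot(inherits(beat, "normalized_beat"))
  f <- beat$fiducials
  need <- c("Ppeak", "Qpeak", "Rpeak", "Speak", "Tpeak", "QRSon", "QRSoff")
  if (anyNA(f[need])) stop("missing landmark", call. = FALSE)
  k <- 1000 / beat$fs
  idx <- f[c(P = "Ppeak", Q = "Qpeak", R = "Rpeak", S = "Speak", T = "Tpeak")]
  t <- as.numeric(idx) * k
  a <- beat$samples[as.integer(idx) + 1L]
  names(t) <- names(a) <- c("P", "Q", "R", "S", "T")
  amp <- vapply(.AMP_PAIRS, function(p) a[p[2]] - a[p[1]], 0)
  dur <- vapply(.AMP_PAIRS, function(p) t[p[2]] - t[p[1]], 0)
  slope <- vapply(.SLOPE_PAIRS, function(p)
    (a[p[2]] - a[p[1]]) / (t[p[2]] - t[p[1]]), 0)
  dist <- vapply(.SLOPE_PAIRS, function(p)
    sqrt((t[p[2]] - t[p[1]])^2 + (a[p[2]] - a[p[1]])^2), 0)
  qrs <- (f[["QRSon"]]:(f[["QRSoff"]] - 1L)) + 1L
  y <- abs(beat$samples[qrs])
  area <- sum((y[-1] + y[-length(y)]) / 2) * k
  out <- c(amp, dur, slope, dist, area)
  names(out) <- feature_names()
  if (any(!is.finite(out))) stop("non-finite feature", call. = FALSE)
  out
}

#' Feature matrix for a list of normalized beats
#'
#' @param beats list of `normalized_beat`s.
#' @return data.frame: 29 feature columns plus `subject_id` and `status`;
#'   beats with missing landmarks are dropped (attribute `n_skipped`).
#' @export
features_table <- function(beats) {
  rows <- list(); skipped <- 0L
  for (b in beats) {
    v <- tryCatch(extract_features(b), error = function(e) NULL)
    if (is.null(v)) { skipped <- skipped + 1L; next }
    d <- as.data.frame(as.list(v))
    d$subject_id <- b$subject_id
    d$status <- b$status
    rows[[length(rows) + 1L]] <- d
  }
  out <- do.call(rbind, rows)
  attr(out, "n_skipped") <- skipped
  out
}

#' Relief-F feature weights for a two-class problem
#'
#' Standard Relief-F: for every instance, the k nearest same-class
#' neighbours ("hits") and k nearest other-class neighbours ("misses") are
#' found under Manhattan distance on z-scored features; each feature's
#' weight accumulates the mean per-feature difference to misses minus the
#' mean difference to hits, normalized by the feature's range and the
#' number of instances.
#'
#' @param x numeric matrix or data.frame of features (rows = instances).
#' @param y class labels (exactly two classes).
#' @param k number of neighbours (default 10, capped at class size - 1).
#' @return Object of class `feature_weights`: named `weights`, `k`.
#' @export
relieff_weights <- function(x, y, k = 10) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2)
    stop("exactly two classes required", call. = FALSE)
  y <- droplevels(y)
  n <- nrow(x); p <- ncol(x)
  xz <- scale(x)
  xz[, attr(xz, "scaled:scale") == 0] <- 0
  rng <- apply(xz, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  k <- min(k, min(table(y)) - 1L)
  if (k < 1) stop("need at least k+1 instances per class", call. = FALSE)
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- rowSums(abs(sweep(xz, 2, xz[i, ])))
    d[i] <- Inf
    same <- y == y[i]
    hits <- order(ifelse(same, d, Inf))[seq_len(k)]
    miss <- order(ifelse(same, Inf, d))[seq_len(k)]
    dh <- colMeans(abs(sweep(xz[hits, , drop = FALSE], 2, xz[i, ])))
    dm <- colMeans(abs(sweep(xz[miss, , drop = FALSE], 2, xz[i, ])))
    w <- w + (dm - dh) / rng
  }
  structure(list(weights = stats::setNames(w / n, colnames(x)), k = k),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("<feature_weights> k = %d\n", x$k))
  print(round(sort(x$weights, decreasing = TRUE), 4))
  invisible(x)
}

#' Summed Relief-F weights across subjects (rest vs exercise)
#'
#' For each subject, the resting-state beats are randomly subsampled
#' (without replacement) to the exercising-state count so the two classes
#' are balanced, Relief-F is run on that subject's z-scored features, and
#' the per-subject weights are summed across subjects.
#'
#' @param feat data.frame from [features_table()] containing both statuses.
#' @param rest,exercise status labels of the two classes.
#' @param k neighbours per class.
#' @param seed integer seed for the balancing subsample.
#' @return A `feature_weights` object with the summed weights.
#' @export
relieff_by_subject <- function(feat, rest = "resting", exercise = "exercising",
                               k = 10, seed = 1L) {
  set.seed(as.integer(seed))
  fcols <- feature_names()
  total <- numeric(length(fcols))
  subjects <- unique(feat$subject_id)
  for (s in subjects) {
    fr <- feat[feat$subject_id == s & feat$status == rest, fcols, drop = FALSE]
    fe <- feat[feat$subject_id == s & feat$status == exercise, fcols, drop = FALSE]
    if (!nrow(fr) || !nrow(fe)) next
    if (nrow(fr) > nrow(fe))
      fr <- fr[sample.int(nrow(fr), nrow(fe)), , drop = FALSE]
    x <- rbind(fr, fe)
    y <- rep(c(rest, exercise), c(nrow(fr), nrow(fe)))
    total <- total + relieff_weights(x, y, k)$weights
  }
  structure(list(weights = stats::setNames(total, fcols), k = k),
            class = "feature_weights")
}
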