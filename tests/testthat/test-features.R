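# build a normalized_beat with landmarks at chosen (t ms, amplitude) points
beat_with_landmarks <- function(t_ms, amps, fs = 500, qrs_on_ms = 140,
                                qrs_off_ms = 200) {
  idx <- round(t_ms * fs / 1000)
  n <- max(idx) + 50
  x <- numeric(n)
  x[idx + 1] <- amps
  f <- c(Pon = 0, Ppeak = idx[["P"]], QRSon = round(qrs_on_ms * fs / 1000),
         Qpeak = idx[["Q"]], Rpeak = idx[["R"]], Speak = idx[["S"]],
         QRSoff = round(qrs_off_ms * fs / 1000), Tpeak = idx[["T"]],
         Toff = max(idx) + 10, Pon_next = n)
  structure(list(samples = x, fiducials = f, method = "proposed", hr = 70,
                 fs = fs, record_id = "fx", subject_id = "S1",
                 status = "resting"),
            class = "normalized_beat")
}

test_that("the 29 features follow their closed-form definitions", {
  t <- c(P = 40, Q = 150, R = 170, S = 190, T = 320)
  a <- c(P = 0.2, Q = -0.3, R = 2.0, S = -0.5, T = 0.6)
  fv <- extract_features(beat_with_landmarks(t, a))
  expect_length(fv, 29)
  expect_identical(names(fv), feature_names())
  # category sizes 9 / 9 / 5 + 5 / 1
  expect_identical(sum(startsWith(names(fv), "amp_")), 9L)
  expect_identical(sum(startsWith(names(fv), "dur_")), 9L)
  expect_identical(sum(startsWith(names(fv), "slope_")) +
                     sum(startsWith(names(fv), "dist_")), 10L)
  expect_identical(sum(startsWith(names(fv), "area_")), 1L)
  # worked values for the Q-R pair
  expect_equal(unname(fv[["amp_QR"]]), 2.3)
  expect_equal(unname(fv[["dur_QR"]]), 20)
  expect_equal(unname(fv[["slope_QR"]]), 0.115)
  expect_equal(unname(fv[["dist_QR"]]), sqrt(20^2 + 2.3^2))
  expect_equal(unname(fv[["amp_PT"]]), 0.4)
  expect_equal(unname(fv[["dur_PT"]]), 280)
})

test_that("features are invariant to amplitude scale and time shifts", {
  t <- c(P = 40, Q = 150, R = 170, S = 190, T = 320)
  a <- c(P = 0.2, Q = -0.3, R = 2.0, S = -0.5, T = 0.6)
  b <- beat_with_landmarks(t, a)
  b$samples <- zscore(b$samples)
  scaled <- b
  scaled$samples <- zscore(b$samples * 2)   # z-score removes the gain
  expect_equal(extract_features(scaled), extract_features(b))
  shifted <- beat_with_landmarks(t + 40, a)  # all landmarks +20 samples
  fv1 <- extract_features(beat_with_landmarks(t, a))
  fv2 <- extract_features(shifted)
  expect_equal(fv2[1:28], fv1[1:28])
  bad <- b
  bad$fiducials[["Tpeak"]] <- NA
  expect_error(extract_features(bad), "missing landmark")
})

test_that("cohort extraction yields finite, constant-length vectors", {
  feat <- fixture_features()
  fc <- feat[, feature_names()]
  expect_identical(ncol(fc), 29L)
  expect_true(all(is.finite(as.matrix(fc))))
})

test_that("Relief-F rewards separating features and ignores noise", {
  set.seed(20)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  x[, 3] <- y                       # perfect separator
  w <- relieff_weights(x, y, k = 10)$weights
  expect_identical(names(which.max(w)), "f3")
  expect_gt(w[["f3"]], 5 * max(abs(w[setdiff(names(w), "f3")])))
  # duplicated columns earn identical weights
  x2 <- cbind(x, f3b = x[, 3])
  w2 <- relieff_weights(x2, y, k = 10)$weights
  expect_lt(abs(w2[["f3"]] - w2[["f3b"]]), 1e-9)
  # a pure-noise feature's weight vanishes
  set.seed(21)
  xn <- matrix(rnorm(500 * 3), 500, 3,
               dimnames = list(NULL, paste0("g", 1:3)))
  yn <- rep(c(0, 1), each = 250)
  xn[, 1] <- yn + rnorm(500, 0, 0.1)
  wn <- relieff_weights(xn, yn, k = 10)$weights
  expect_lt(abs(wn[["g2"]]), 0.05)
  expect_lt(abs(wn[["g3"]]), 0.05)
  expect_error(relieff_weights(x, rep(1, n)), "two classes")
})

test_that("amplitude features dominate the rest-vs-exercise contrast", {
  feat <- fixture_features()
  w <- relieff_by_subject(feat, k = 10, seed = 42)
  ord <- names(sort(w$weights, decreasing = TRUE))
  amp_rank <- mean(match(grep("^amp_", names(w$weights), value = TRUE), ord))
  dur_rank <- mean(match(grep("^dur_", names(w$weights), value = TRUE), ord))
  expect_lt(amp_rank, dur_rank)
  # a majority of the top 8 are amplitude features
  expect_gte(sum(startsWith(head(ord, 8), "amp_")), 5)
})
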