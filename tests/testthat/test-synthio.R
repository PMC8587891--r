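test_that("population generation is deterministic and well-constrained", {
  p1 <- make_population(15, seed = 1)
  p2 <- make_population(15, seed = 1)
  expect_identical(p1, p2)
  expect_length(p1, 15)
  # subjects mutually distinct
  sigs <- vapply(p1, function(p) paste(p$wave_params, collapse = ","), "")
  expect_false(anyDuplicated(sigs) > 0)
  # base durations sum to one beat period at the 70 bpm reference
  one <- make_population(1, seed = 7)[[1]]
  expect_lt(abs(sum(one$base_durations) - 60000 / 70), 1)
  # slope ordering invariant: beta_TP < beta_ST < beta_PR <= 0, beta_QRS = 0
  for (p in p1) {
    s <- p$duration_slopes
    expect_true(s[["tp"]] < s[["st"]])
    expect_true(s[["st"]] < s[["pr"]])
    expect_lte(s[["pr"]], 0)
    expect_identical(s[["qrs"]], 0)
  }
  expect_error(make_population(0, seed = 1), "positive count")
})

test_that("synthesized records are reproducible with beat counts set by HR", {
  pop <- make_population(2, seed = 3)
  a <- synthesize_record(pop[[1]], "resting", 20, 500, seed = 5)
  b <- synthesize_record(pop[[1]], "resting", 20, 500, seed = 5)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth, b$truth)
  # ~20 * HR / 60 beats; R count within 1 of HR/3
  for (hr in c(60, 90, 120)) {
    syn <- synthesize_record(pop[[2]], "resting", 20, 500, seed = 8,
                             noise_scale = 0, hr_fixed = hr)
    expect_lte(abs(nrow(syn$truth) - hr / 3), 1.5)
  }
  expect_error(synthesize_record(pop[[1]], "resting", -1), "positive")
  expect_error(synthesize_record(pop[[1]], "resting", 20, fs = 80), "100 Hz")
})

test_that("section durations follow the generator's heart-rate law", {
  pop <- make_population(1, seed = 11)
  p <- pop[[1]]
  s70 <- synthesize_record(p, "resting", 20, 500, seed = 2, noise_scale = 0,
                           hr_fixed = 70)
  s120 <- synthesize_record(p, "resting", 20, 500, seed = 2, noise_scale = 0,
                            hr_fixed = 120)
  m70 <- colMeans(s70$sections_ms)
  m120 <- colMeans(s120$sections_ms)
  sl <- p$duration_slopes
  # PR and ST shrink linearly; QRS is flat
  expect_lt(abs((m120[["pr"]] - m70[["pr"]]) - sl[["pr"]] * 50), 3)
  expect_lt(abs((m120[["st"]] - m70[["st"]]) - sl[["st"]] * 50), 3)
  expect_lt(abs(m120[["qrs"]] - m70[["qrs"]]), 3)
  # TP absorbs the RR remainder: TP(120) - TP(70) =
  #   (60000/120 - 60000/70) - (beta_pr + beta_st) * 50
  expected_tp <- (60000 / 120 - 60000 / 70) - (sl[["pr"]] + sl[["st"]]) * 50
  expect_lt(abs((m120[["tp"]] - m70[["tp"]]) - expected_tp), 4)
  # sections always sum to the RR interval
  expect_equal(unname(rowSums(s120$sections_ms)),
               rep(60000 / 120, nrow(s120$sections_ms)), tolerance = 0.005)
})

test_that("status heart-rate targets are met (48% exercise change)", {
  pop <- make_population(1, seed = 4)
  pop[[1]]$rest_hr <- 70
  # >= 100 beats: three 40 s records
  hrs <- unlist(lapply(1:3, function(i)
    synthesize_record(pop[[1]], "exercising", 40, 500, seed = i)$hr))
  expect_gte(length(hrs), 100)
  expect_lt(abs(mean(hrs) - 70 * 1.48) / (70 * 1.48), 0.02)
  rest <- synthesize_record(pop[[1]], "resting", 40, 500, seed = 9)
  expect_lt(abs(mean(rest$hr) - 70) / 70, 0.02)
})

test_that("noise-free records place ground-truth peaks on waveform extrema", {
  syn <- fixture_clean_syn()
  x <- syn$clean
  for (i in seq_len(nrow(syn$truth))) {
    tr <- syn$truth[i, ]
    r <- tr$Rpeak + 1
    expect_equal(x[r], max(x[(tr$QRSon + 1):(tr$QRSoff + 1)]))
    p <- tr$Ppeak + 1
    expect_equal(x[p], max(x[(tr$Pon + 1):(tr$QRSon + 1)]))
    t <- tr$Tpeak + 1
    expect_equal(x[t], max(x[(tr$QRSoff + 1):(tr$Toff + 1)]))
  }
  # signal is exactly flat in the TP segments (compact-support waves)
  tr1 <- syn$truth[1, ]
  tp_seg <- x[(tr1$Toff + 5):(tr1$Pon_next - 3)]
  expect_true(all(abs(tp_seg) < 1e-12))
})

test_that("heart-rate-dependent amplitude modulation scales R and T waves", {
  pop <- make_population(1, seed = 21)
  p <- pop[[1]]
  s70 <- synthesize_record(p, "resting", 10, 500, seed = 2, noise_scale = 0,
                           hr_fixed = 70)
  s120 <- synthesize_record(p, "resting", 10, 500, seed = 2, noise_scale = 0,
                            hr_fixed = 120)
  r70 <- s70$clean[s70$truth$Rpeak[2] + 1]
  r120 <- s120$clean[s120$truth$Rpeak[2] + 1]
  expect_equal(r120 / r70, 1 + 0.002 * 50, tolerance = 0.02)
  t70 <- s70$clean[s70$truth$Tpeak[2] + 1]
  t120 <- s120$clean[s120$truth$Tpeak[2] + 1]
  expect_equal(t120 / t70, 1 - 0.003 * 50, tolerance = 0.02)
  # and can be switched off
  z <- synthesize_record(p, "resting", 10, 500, seed = 2, noise_scale = 0,
                         hr_fixed = 120, amp_hr_coef = c(P = 0, Q = 0, R = 0,
                                                         S = 0, T = 0))
  expect_equal(z$clean[z$truth$Rpeak[2] + 1], r70, tolerance = 1e-6)
})
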