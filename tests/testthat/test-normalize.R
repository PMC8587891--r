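test_that("z-scoring matches its definition and rejects constants", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  z <- zscore(rnorm(100, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(zscore(rep(5, 3)), "constant")
})

test_that("per-section normalization is the identity at the reference", {
  beat <- make_ref_beat(pr_n = 75, qrs_n = 50, st_n = 150, tp_n = 154)
  refs <- c(pr = 150, qrs = 100, st = 300, tp = 308)  # == sections at 500 Hz
  nb <- normalize_beat_proposed(beat, refs)
  expect_equal(nb$samples, zscore(beat$samples), tolerance = 1e-9)
  expect_identical(nb$method, "proposed")
  # fiducials land on the section boundaries
  expect_identical(unname(nb$fiducials[["QRSon"]]), 75)
  expect_identical(unname(nb$fiducials[["QRSoff"]]), 125)
  expect_identical(unname(nb$fiducials[["Toff"]]), 275)
  expect_identical(unname(nb$fiducials[["Pon_next"]]), 429)
})

test_that("normalized beats share one exact length and reference sections", {
  beats <- fixture_cohort_beats()[seq(1, 900, by = 60)]
  refs <- fixture_refs()
  n_ref <- sum(round(refs * 500 / 1000))
  for (b in beats) {
    nb <- normalize_beat_proposed(b, refs)
    expect_identical(length(nb$samples), as.integer(n_ref))
    # each section's normalized duration equals its reference sample count
    f <- nb$fiducials
    expect_identical(unname(f[["QRSon"]]), unname(round(refs[["pr"]] * 0.5)))
    expect_identical(unname(f[["QRSoff"]] - f[["QRSon"]]),
                     unname(round(refs[["qrs"]] * 0.5)))
    expect_identical(unname(f[["Toff"]] - f[["QRSoff"]]),
                     unname(round(refs[["st"]] * 0.5)))
    # amplitude is z-scored
    expect_lt(abs(mean(nb$samples)), 1e-6)
    expect_lt(abs(sd(nb$samples) - 1), 1e-6)
  }
})

test_that("normalization is idempotent once a beat sits at the reference", {
  beat <- make_ref_beat()
  refs <- c(pr = 150, qrs = 100, st = 300, tp = 308)
  once <- normalize_beat_proposed(beat, refs)
  again_beat <- structure(
    list(samples = once$samples, fiducials = once$fiducials, hr = 70,
         fs = 500, record_id = "x", subject_id = "s", status = "resting"),
    class = "ecg_beat")
  twice <- normalize_beat_proposed(again_beat, refs)
  expect_lt(max(abs(twice$samples - once$samples)), 1e-9)
})

test_that("linear comparator resamples whole beats to the reference RR", {
  b <- make_ref_beat(pr_n = 70, qrs_n = 50, st_n = 140, tp_n = 140)  # 400 smp
  nb <- normalize_beat_linear(b, ref_rr = 857.14)
  expect_identical(length(nb$samples), 429L)  # round(857.14 * 0.5)
  # identity (up to z-score) when the beat is already at the reference RR
  b2 <- make_ref_beat(pr_n = 75, qrs_n = 50, st_n = 150, tp_n = 154)  # 429
  nb2 <- normalize_beat_linear(b2, ref_rr = 858)
  expect_equal(nb2$samples, zscore(b2$samples), tolerance = 1e-9)
  empty <- b
  empty$samples <- numeric(1)
  expect_error(normalize_beat_linear(empty), "empty|degenerate")
})

test_that("T-wave comparator fixes the T section at 120 ms", {
  b <- make_ref_beat()
  f <- b$fiducials
  t_on <- max(f[["QRSoff"]], f[["Tpeak"]] - (f[["Toff"]] - f[["Tpeak"]]))
  n_t <- f[["Toff"]] - t_on
  nb <- normalize_beat_twave(b)
  expect_identical(length(nb$samples),
                   as.integer(length(b$samples) - n_t + 60))
  expect_identical(unname(nb$fiducials[["Toff"]] - t_on), 60)
  # identity when the measured T duration already equals the target
  nb2 <- normalize_beat_twave(b, t_ms = n_t * 2)  # n_t samples = n_t*2 ms
  expect_equal(nb2$samples, zscore(b$samples), tolerance = 1e-9)
  bad <- b
  bad$fiducials[["Tpeak"]] <- NA
  expect_error(normalize_beat_twave(bad), "missing T")
})

test_that("normalization aligns beats across heart rates within a subject", {
  pop <- fixture_population()
  p <- pop[[6]]
  cfg <- run_config()
  syn60 <- synthesize_record(p, "resting", 12, 500, seed = 81,
                             noise_scale = 0, hr_fixed = 60)
  syn120 <- synthesize_record(p, "resting", 12, 500, seed = 82,
                              noise_scale = 0, hr_fixed = 120)
  b60 <- segment_beats(syn60$record, syn60$truth, cfg)[[2]]
  b120 <- segment_beats(syn120$record, syn120$truth, cfg)[[2]]
  refs <- fixture_refs()
  n60 <- normalize_beat_proposed(b60, refs)
  n120 <- normalize_beat_proposed(b120, refs)
  cor_prop <- cor(n60$samples, n120$samples)
  # against length-matched raw beats
  len <- max(length(b60$samples), length(b120$samples))
  r60 <- normalize_beat_raw(b60, len)
  r120 <- normalize_beat_raw(b120, len)
  cor_raw <- cor(r60$samples, r120$samples)
  expect_gt(cor_prop, cor_raw)
  expect_gt(cor_prop, 0.98)
  # normalized TP section matches the reference duration within 1 sample
  tp_n <- length(n120$samples) - n120$fiducials[["Toff"]]
  expect_lte(abs(tp_n - round(refs[["tp"]] * 0.5)), 1)
})

test_that("batch normalization skips degenerate beats but keeps the rest", {
  beats <- fixture_cohort_beats()[1:20]
  broken <- beats[[3]]
  broken$fiducials[["QRSoff"]] <- broken$fiducials[["QRSon"]] + 1
  beats[[3]] <- broken
  nb <- normalize_beats(beats, "proposed", refs = fixture_refs())
  expect_identical(attr(nb, "n_skipped"), 1L)
  expect_identical(length(nb), 19L)
})
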