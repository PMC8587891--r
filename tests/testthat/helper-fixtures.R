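# Shared fixtures, built once per test run and memoized. The cohort is the
# package's reference study condition: 10 subjects, resting + exercising,
# 3 twenty-second records per subject and status at 500 Hz, default noise.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fixture_population <- function() memo("population", function() {
  make_population(10, seed = 42)
})

# processed beats for the full cohort (preprocess -> delineate -> segment)
fixture_cohort_beats <- function() memo("cohort_beats", function() {
  cfg <- run_config(seed = 42)
  cohort <- synthesize_cohort(fixture_population(),
                              c("resting", "exercising"),
                              records_per_status = 3, duration_s = 20,
                              seed = 42)
  beats <- list()
  for (syn in cohort) {
    pp <- preprocess_record(syn$record, cfg)
    fid <- tryCatch(detect_fiducials(pp$record, cfg), error = function(e) NULL)
    if (is.null(fid)) next
    beats <- c(beats, segment_beats(pp$record, fid, cfg))
  }
  beats
})

fixture_refs <- function() memo("refs", function() {
  reference_durations(fit_all_sections(section_table(fixture_cohort_beats())))
})

fixture_features <- function() memo("features", function() {
  nb <- normalize_beats(fixture_cohort_beats(), "proposed",
                        refs = fixture_refs())
  features_table(nb)
})

# one clean single-subject record with ground truth, for landmark tests
fixture_clean_syn <- function() memo("clean_syn", function() {
  synthesize_record(fixture_population()[[1]], "resting", duration_s = 20,
                    fs = 500, seed = 7, noise_scale = 0)
})

# a synthetic ecg_beat with exactly known section lengths (in samples) and
# a smooth waveform; used by normalization tests
make_ref_beat <- function(pr_n = 75, qrs_n = 50, st_n = 150, tp_n = 154,
                          fs = 500, hr = 70) {
  n <- pr_n + qrs_n + st_n + tp_n
  t <- seq_len(n)
  x <- sin(2 * pi * t / n) + 0.5 * sin(2 * pi * 3 * t / n)
  x[pr_n + (1:qrs_n)] <- x[pr_n + (1:qrs_n)] + 1.5 * sin(pi * (1:qrs_n) / qrs_n)
  f <- c(Pon = 0, Ppeak = round(pr_n / 2), QRSon = pr_n,
         Qpeak = pr_n + round(0.2 * qrs_n), Rpeak = pr_n + round(qrs_n / 2),
         Speak = pr_n + round(0.8 * qrs_n), QRSoff = pr_n + qrs_n,
         Tpeak = pr_n + qrs_n + round(st_n * 0.7),
         Toff = pr_n + qrs_n + st_n, Pon_next = n)
  structure(list(samples = x, fiducials = f, hr = hr, fs = fs,
                 record_id = "synthetic_ref", subject_id = "SX",
                 status = "resting"),
            class = "ecg_beat")
}
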