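test_that("the outlier rule matches its closed form on a worked example", {
  st <- outlier_stats(c(0.99, 0.98, 0.97, 0.50))
  expect_equal(st$mu_rho, 0.86)
  expect_equal(st$sigma_rho, sd(c(0.99, 0.98, 0.97, 0.50)))
  expect_equal(st$sigma_rho, 0.2401, tolerance = 1e-3)
  expect_equal(st$threshold, st$mu_rho - 0.5 * st$sigma_rho)
  expect_identical(st$outlier_mask, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("outlier masks equal a brute-force recomputation for random rho", {
  set.seed(10)
  for (i in 1:50) {
    rho <- runif(sample(3:40, 1), -1, 1)
    st <- outlier_stats(rho)
    mu <- sum(rho) / length(rho)
    sg <- sqrt(sum((rho - mu)^2) / (length(rho) - 1))
    expect_identical(st$outlier_mask, rho < mu - 0.5 * sg)
  }
})

test_that("identical beats produce no outliers; tiny groups are rejected", {
  m <- matrix(rep(sin(1:100 / 5), 5), nrow = 5, byrow = TRUE)
  st <- detect_outliers(m)
  expect_equal(st$rho, rep(1, 5), tolerance = 1e-12)
  expect_lt(st$sigma_rho, 1e-12)
  expect_false(any(st$outlier_mask))
  expect_error(detect_outliers(m[1:2, ]), "at least 3")
})

test_that("a corrupted beat is excluded and the template stays faithful", {
  set.seed(3)
  truth <- sin(seq(0, 2 * pi, length.out = 200)) +
    2 * exp(-((1:200) - 60)^2 / 20)
  mat <- t(replicate(10, truth + rnorm(200, 0, 0.05)))
  mat <- rbind(mat, -truth)           # inverted-polarity corrupt beat
  st <- detect_outliers(mat)
  expect_true(st$outlier_mask[11])
  expect_false(any(st$outlier_mask[1:10]))
  tpl <- representative_beat(mat, st)
  expect_identical(tpl$n_inliers, 10L)
  expect_gt(cor(tpl$samples, truth), 0.99)
  # elementwise mean over inliers only
  expect_equal(tpl$samples, colMeans(mat[1:10, ]))
  all_out <- st
  all_out$outlier_mask <- rep(TRUE, 11)
  expect_error(representative_beat(mat, all_out), "inlier")
})

test_that("similarity is a lag-tolerant, scale-invariant correlation", {
  set.seed(4)
  x <- sin(seq(0, 6 * pi, length.out = 500)) + rnorm(500, 0, 0.02)
  expect_equal(similarity(x, x), 1)
  shifted <- c(x[6:500], x[1:5])       # 10 ms at 500 Hz
  expect_gte(similarity(x, shifted), 0.999)
  noise <- rnorm(500)
  expect_lt(abs(similarity(x, noise, max_lag_ms = 0)), 0.3)
  # affine amplitude invariance and symmetry at zero lag
  expect_equal(similarity(x, 3 * x + 2, max_lag_ms = 0), 1)
  expect_equal(similarity(x, shifted, max_lag_ms = 0),
               similarity(shifted, x, max_lag_ms = 0))
  expect_error(similarity(x, x[1:100]), "mismatch")
})

test_that("outlier ratio is a simple percentage", {
  rho <- c(rep(0.99, 17), 0.2, 0.1, 0.15)
  st <- outlier_stats(rho)
  expect_identical(100 * sum(st$outlier_mask) / 20, 15)
  m <- matrix(rep(sin(1:80 / 3), 6), nrow = 6, byrow = TRUE)
  expect_identical(outlier_ratio(m), 0)
})

test_that("templates are stable in the number of generating beats", {
  # 5 vs 20 generating beats changes mean similarity by < 0.02
  beats <- fixture_cohort_beats()
  subs <- vapply(beats, `[[`, "", "subject_id")
  stt <- vapply(beats, `[[`, "", "status")
  refs <- fixture_refs()
  diffs <- numeric(0)
  for (s in unique(subs)[1:5]) {
    nb <- normalize_beats(beats[subs == s & stt == "resting"], "proposed",
                          refs = refs)
    mat <- align_beats(nb)$mat
    eval_rows <- 21:min(40, nrow(mat))
    t5 <- representative_beat(mat[1:5, ], detect_outliers(mat[1:5, ]))
    t20 <- representative_beat(mat[1:20, ], detect_outliers(mat[1:20, ]))
    s5 <- mean(vapply(eval_rows, function(i) similarity(t5$samples, mat[i, ]), 0))
    s20 <- mean(vapply(eval_rows, function(i) similarity(t20$samples, mat[i, ]), 0))
    diffs <- c(diffs, abs(s5 - s20))
  }
  expect_lt(mean(diffs), 0.02)
})

test_that("the proposed method leaves fewer outliers than the linear one", {
  beats <- fixture_cohort_beats()
  sim_p <- cohort_similarity(beats, "proposed", refs = fixture_refs())
  sim_l <- cohort_similarity(beats, "linear")
  expect_lte(mean(unique(sim_p[, c("subject_id", "outlier_pct")])$outlier_pct),
             mean(unique(sim_l[, c("subject_id", "outlier_pct")])$outlier_pct))
})
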