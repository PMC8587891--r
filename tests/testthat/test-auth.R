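# small separable two-subject feature set built directly in feature space
separable_features <- function(n_per = 40, gap = 6, sd = 0.3, seed = 1) {
  set.seed(seed)
  fcols <- feature_names()
  mk <- function(center, id) {
    m <- matrix(rnorm(n_per * 29, center, sd), n_per, 29,
                dimnames = list(NULL, fcols))
    d <- as.data.frame(m)
    d$subject_id <- id
    d$status <- "resting"
    d
  }
  rbind(mk(0, "A"), mk(gap, "B"))
}

test_that("the 80:20 split is stratified, seeded, and guarded", {
  feat <- separable_features(50)
  sp <- split_experiment1(feat, seed = 5)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$test), 20L)
  expect_identical(as.integer(table(sp$train$subject_id)), c(40L, 40L))
  sp2 <- split_experiment1(feat, seed = 5)
  expect_identical(sp$train, sp2$train)
  expect_error(split_experiment1(separable_features(5)), "fewer than")
})

test_that("cross-status test sets pair genuine beats with equal impostors", {
  feat <- fixture_features()
  ex <- feat[feat$status == "exercising", ]
  sp <- split_experiment2(ex, seed = 9)
  for (s in names(sp$exercising)) {
    g <- sp$exercising[[s]]$genuine
    i <- sp$exercising[[s]]$impostor
    expect_identical(nrow(i), nrow(g))
    expect_true(all(i$subject_id != s))
  }
  sp2 <- split_experiment2(ex, seed = 9)
  expect_identical(sp$exercising[[1]]$impostor, sp2$exercising[[1]]$impostor)
  expect_error(split_experiment2(ex[ex$subject_id == "S01", ]), "2 subjects")
})

test_that("well-separated subjects are verified perfectly; shuffles are not", {
  feat <- separable_features(40)
  models <- train_auth_models(feat, "svm_gaussian", seed = 3)
  expect_length(models, 2)
  expect_true(all(vapply(models, `[[`, 0, "cv_accuracy") == 1))
  rep <- evaluate_models(models, feat)
  expect_equal(rep$acc, 100)
  # label shuffling drives cross-validated accuracy to chance
  shuf <- feat
  set.seed(11)
  shuf$subject_id <- sample(shuf$subject_id)
  m2 <- train_auth_models(shuf, "svm_gaussian", seed = 3)
  cv <- vapply(m2, `[[`, 0, "cv_accuracy")
  expect_true(all(cv > 0.4 & cv < 0.6))
  expect_error(train_auth_models(feat[feat$subject_id == "A", ],
                                 "svm_gaussian"), "2 subjects")
})

test_that("all four classifier kinds train and score sensibly", {
  feat <- separable_features(30)
  for (kind in c("svm_quadratic", "knn1", "dtree")) {
    models <- train_auth_models(feat, kind, seed = 4)
    rep <- evaluate_models(models, feat)
    expect_gte(rep$acc, 95)
  }
})

test_that("FAR/FRR/ACC arithmetic matches hand counts", {
  # a 1-NN model with known geometry: genuine prototype at 0, impostor at 10
  fcols <- feature_names()
  proto <- rbind(matrix(0, 5, 29), matrix(10, 5, 29))
  colnames(proto) <- fcols
  train <- as.data.frame(proto)
  train$subject_id <- rep(c("G", "X"), each = 5)
  models <- train_auth_models(train, "knn1", seed = 1)
  # 50 genuine probes, 2 placed at the impostor prototype; 50 impostors,
  # 1 placed at the genuine prototype
  probe <- function(center, n) matrix(rnorm(n * 29, center, 0.1), n, 29,
                                      dimnames = list(NULL, fcols))
  gen <- rbind(probe(0, 48), probe(10, 2))
  imp <- rbind(probe(10, 49), probe(0, 1))
  test <- list(G = list(genuine = as.data.frame(gen),
                        impostor = as.data.frame(imp)))
  rep <- evaluate_models(models[ "G"], test)
  expect_equal(rep$frr, 4)    # 2 of 50 genuine rejected
  expect_equal(rep$far, 2)    # 1 of 50 impostors accepted
  expect_equal(rep$acc, 97)
})

test_that("EER matches the analytic value for two Gaussian score clouds", {
  set.seed(6)
  g <- rnorm(1e5, 1, 1)
  i <- rnorm(1e5, -1, 1)
  res <- eer_from_scores(g, i)
  expect_lt(abs(res$eer - 100 * pnorm(-1)), 0.4)
  # EER is invariant under strictly monotone score transforms
  res2 <- eer_from_scores(exp(g / 2), exp(i / 2))
  expect_equal(res2$eer, res$eer, tolerance = 1e-9)
  # FAR falls and FRR rises with the threshold
  roc <- res$roc
  expect_true(all(diff(roc$far) <= 0))
  expect_true(all(diff(roc$frr) >= 0))
  # degenerate ROC convention
  expect_equal(eer_from_scores(rep(1, 10), rep(1, 10))$eer, 50)
})
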