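#' Stratified 80:20 split of resting features (model-selection experiment)
#'
#' Splits each subject's beats independently at the given ratio, so train
#' and test keep the subject proportions.
#'
#' @param feat data.frame from [features_table()] (resting state).
#' @param ratio train fraction (default 0.8).
#' @param seed integer seed.
#' @param min_beats minimum beats per subject.
#' @return List with `train` and `test` data.frames.
#' @export
split_experiment1 <- function(feat, ratio = 0.8, seed = 1L, min_beats = 10) {
  set.seed(as.integer(seed))
  counts <- table(feat$subject_id)
  if (any(counts < min_beats))
    stop("fewer than ", min_beats, " beats for subject(s): ",
         paste(names(counts)[counts < min_beats], collapse = ", "),
         call. = FALSE)
  tr_idx <- unlist(lapply(split(seq_len(nrow(feat)), feat$subject_id),
                          function(ix) sample(ix, round(ratio * length(ix)))))
  list(train = feat[sort(tr_idx), , drop = FALSE],
       test = feat[-sort(tr_idx), , drop = FALSE])
}

#' Per-status genuine/impostor test sets (cross-status experiment)
#'
#' For every subject and status, the genuine set is the subject's own beats
#' in that status and the impostor set is an equal-count seeded sample
#' (without replacement) from the other subjects' beats in the same status.
#'
#' @param feat data.frame of test features across statuses.
#' @param seed integer seed controlling the impostor sampling.
#' @return Nested list `[[status]][[subject]]` with `genuine` and
#'   `impostor` data.frames.
#' @export
split_experiment2 <- function(feat, seed = 1L) {
  set.seed(as.integer(seed))
  subjects <- unique(feat$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  out <- list()
  for (st in unique(feat$status)) {
    fs <- feat[feat$status == st, , drop = FALSE]
    out[[st]] <- list()
    for (s in subjects) {
      gen <- fs[fs$subject_id == s, , drop = FALSE]
      pool <- fs[fs$subject_id != s, , drop = FALSE]
      if (!nrow(gen)) next
      if (nrow(pool) < nrow(gen))
        stop("impostor pool smaller than genuine count for ", s, " / ", st,
             call. = FALSE)
      imp <- pool[sample.int(nrow(pool), nrow(gen)), , drop = FALSE]
      out[[st]][[s]] <- list(genuine = gen, impostor = imp)
    }
  }
  out
}

# stratified fold assignment; retries (new seed) if any fold loses a class
make_folds <- function(y, k, seed) {
  for (attempt in 1:3) {
    set.seed(seed + attempt - 1L)
    folds <- integer(length(y))
    for (cl in levels(y)) {
      ix <- which(y == cl)
      folds[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
    ok <- all(vapply(seq_len(k), function(f)
      nlevels(droplevels(y[folds != f])) == nlevels(y), TRUE))
    if (ok) return(folds)
  }
  stop("could not build folds with both classes present", call. = FALSE)
}

fit_one <- function(x, y, kind, gamma = NULL) {
  switch(kind,
    svm_gaussian = e1071::svm(x, y, kernel = "radial", gamma = gamma,
                              cost = 1, scale = FALSE),
    svm_quadratic = e1071::svm(x, y, kernel = "polynomial", degree = 2,
                               gamma = gamma, coef0 = 1, cost = 1,
                               scale = FALSE),
    knn1 = list(x = x, y = y),       # memorize; scored at prediction time
    dtree = rpart::rpart(y ~ ., data = data.frame(x, y = y),
                         method = "class",
                         control = rpart::rpart.control(minbucket = 3,
                                                        minsplit = 10,
                                                        cp = 0)))
}

# continuous genuine-likeness score (decision threshold is 0 for all kinds)
score_one <- function(fit, kind, x) {
  if (kind %in% c("svm_gaussian", "svm_quadratic")) {
    pr <- stats::predict(fit, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1]
    if (!grepl("^genuine", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
    unname(dv)
  } else if (kind == "knn1") {
    gx <- fit$x[fit$y == "genuine", , drop = FALSE]
    ix <- fit$x[fit$y == "other", , drop = FALSE]
    dg <- apply(x, 1, function(r) min(sqrt(colSums((t(gx) - r)^2))))
    di <- apply(x, 1, function(r) min(sqrt(colSums((t(ix) - r)^2))))
    unname(di - dg)                # positive iff the 1-NN is genuine
  } else {
    p <- stats::predict(fit, data.frame(x), type = "prob")[, "genuine"]
    unname(p - 0.5)
  }
}

#' Train one-vs-rest verification models
#'
#' One binary model per subject: that subject's training beats are the
#' genuine class, everyone else's the impostor class. Feature z-scaling is
#' fitted on the training set only. For the SVM kernels, the kernel width
#' gamma is tuned per subject by stratified 10-fold cross-validation over a
#' 10-point logarithmic grid spanning 1/n_features x [1e-2, 1e2]; the cost
#' parameter is fixed at 1. kNN uses k = 1; the decision tree uses minimum
#' leaf size 3 and minimum split size 10.
#'
#' @param train data.frame from [features_table()] (feature columns plus
#'   `subject_id`).
#' @param kind one of "svm_gaussian", "svm_quadratic", "knn1", "dtree".
#' @param cv_folds folds for the gamma search (default 10).
#' @param seed integer seed (folds).
#' @return List of `auth_model`s (class `auth_model_set`), one per subject.
#' @export
train_auth_models <- function(train, kind = c("svm_gaussian", "svm_quadratic",
                                              "knn1", "dtree"),
                              cv_folds = 10, seed = 1L) {
  kind <- match.arg(kind)
  fcols <- feature_names()
  subjects <- unique(train$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  x_all <- as.matrix(train[, fcols])
  models <- list()
  for (s in subjects) {
    y <- factor(ifelse(train$subject_id == s, "genuine", "other"),
                levels = c("genuine", "other"))
    ctr <- colMeans(x_all)
    scl <- apply(x_all, 2, stats::sd)
    scl[scl == 0] <- 1
    xz <- sweep(sweep(x_all, 2, ctr), 2, scl, "/")
    gamma <- NULL; cv_acc <- NA_real_
    if (kind %in% c("svm_gaussian", "svm_quadratic")) {
      grid <- (1 / length(fcols)) * 10^seq(-2, 2, length.out = 10)
      folds <- make_folds(y, cv_folds, as.integer(seed))
      best <- -Inf
      for (g in grid) {
        correct <- 0L
        for (f in seq_len(cv_folds)) {
          tr <- folds != f
          m <- fit_one(xz[tr, , drop = FALSE], y[tr], kind, g)
          pred <- score_one(m, kind, xz[!tr, , drop = FALSE]) > 0
          correct <- correct + sum(pred == (y[!tr] == "genuine"))
        }
        acc <- correct / length(y)
        if (acc > best) { best <- acc; gamma <- g }
      }
      cv_acc <- best
    }
    fit <- fit_one(xz, y, kind, gamma)
    models[[s]] <- structure(
      list(subject_id = s, kind = kind, fit = fit, center = ctr, scale = scl,
           gamma = gamma, cv_accuracy = cv_acc),
      class = "auth_model")
  }
  structure(models, class = "auth_model_set")
}

#' @export
print.auth_model <- function(x, ...) {
  cat(sprintf("<auth_model> %s [%s]%s%s\n", x$subject_id, x$kind,
              if (!is.null(x$gamma)) sprintf(", gamma = %.4g", x$gamma) else "",
              if (!is.na(x$cv_accuracy)) sprintf(", CV acc = %.3f", x$cv_accuracy) else ""))
  invisible(x)
}

#' @export
print.auth_model_set <- function(x, ...) {
  cat(sprintf("<auth_model_set> %d subjects [%s]\n", length(x), x[[1]]$kind))
  invisible(x)
}

#' Decision scores of an authentication model
#'
#' @param object an `auth_model`.
#' @param newdata data.frame or matrix with the 29 feature columns.
#' @param ... unused.
#' @return Numeric scores; positive means "accept as this subject" at the
#'   default threshold.
#' @export
predict.auth_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, feature_names(), drop = FALSE])
  xz <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  score_one(object$fit, object$kind, xz)
}

#' Equal error rate from genuine and impostor scores
#'
#' Sweeps the acceptance threshold over the score range; FAR falls and FRR
#' rises monotonically, and the EER is the common value at their
#' linearly-interpolated crossing. If every score is identical the ROC is
#' degenerate and 50 is returned.
#'
#' @param genuine,impostor numeric score vectors.
#' @return List: `eer` (percent) and `roc` (data.frame threshold/far/frr).
#' @export
eer_from_scores <- function(genuine, impostor) {
  thr <- sort(unique(c(genuine, impostor)))
  if (length(thr) < 2)
    return(list(eer = 50,
                roc = data.frame(threshold = thr, far = 50, frr = 50)))
  thr <- c(thr[1] - 1e-9, thr)  # include an accept-everything point
  gs <- sort(genuine); is <- sort(impostor)
  # findInterval(t, sorted, left.open = TRUE) counts elements < t
  far <- 100 * (length(is) - findInterval(thr, is, left.open = TRUE)) /
    length(is)
  frr <- 100 * findInterval(thr, gs, left.open = TRUE) / length(gs)
  d <- far - frr
  i <- which(d[-length(d)] >= 0 & d[-1] <= 0)
  if (!length(i)) {
    eer <- (far[which.min(abs(d))] + frr[which.min(abs(d))]) / 2
  } else {
    i <- i[1]
    if (d[i] == d[i + 1]) eer <- (far[i] + frr[i]) / 2
    else {
      w <- d[i] / (d[i] - d[i + 1])
      eer <- far[i] + w * (far[i + 1] - far[i])
    }
  }
  list(eer = eer, roc = data.frame(threshold = thr, far = far, frr = frr))
}

#' Evaluate verification models on genuine/impostor test sets
#'
#' Decisions at the models' native zero-score threshold give ACC, FAR and
#' FRR; the full threshold sweep gives each subject's EER. Metrics are
#' macro-averaged over subjects.
#'
#' @param models an `auth_model_set`.
#' @param test either a data.frame (each model's genuine set is the rows
#'   with its `subject_id`, impostors are all other rows) or a per-subject
#'   list with `genuine` and `impostor` data.frames (one status entry of
#'   [split_experiment2()]).
#' @return Object of class `eval_report`: per-subject data.frame and
#'   macro-averaged `acc`, `far`, `frr`, `eer` (percent).
#' @export
evaluate_models <- function(models, test) {
  per <- list()
  for (m in models) {
    if (is.data.frame(test)) {
      gen <- test[test$subject_id == m$subject_id, , drop = FALSE]
      imp <- test[test$subject_id != m$subject_id, , drop = FALSE]
    } else {
      if (is.null(test[[m$subject_id]])) next
      gen <- test[[m$subject_id]]$genuine
      imp <- test[[m$subject_id]]$impostor
    }
    if (!nrow(gen) || !nrow(imp))
      stop("empty genuine or impostor set for ", m$subject_id, call. = FALSE)
    sg <- predict(m, gen)
    si <- predict(m, imp)
    fa <- sum(si > 0); fr <- sum(sg <= 0)
    n <- length(sg) + length(si)
    per[[m$subject_id]] <- data.frame(
      subject_id = m$subject_id,
      n_genuine = length(sg), n_impostor = length(si),
      acc = 100 * (n - fa - fr) / n,
      far = 100 * fa / length(si),
      frr = 100 * fr / length(sg),
      eer = eer_from_scores(sg, si)$eer)
  }
  per <- do.call(rbind, per)
  structure(list(per_subject = per,
                 acc = mean(per$acc), far = mean(per$far),
                 frr = mean(per$frr), eer = mean(per$eer)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d subjects: ACC %.2f%%  FAR %.2f%%  FRR %.2f%%  EER %.2f%%\n",
              nrow(x$per_subject), x$acc, x$far, x$frr, x$eer))
  invisible(x)
}
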