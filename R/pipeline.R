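#' Run the end-to-end pipeline on a synthetic cohort
#'
#' Orchestrates the stages in their fixed order - synth, preprocess,
#' delineate, analyze-hr, normalize, enroll, evaluate - reading and
#' writing plain-text artifacts under `out_dir` and recording a JSON run
#' manifest. Any subset of consecutive stages can be run; each stage
#' checks that its upstream artifacts exist and names the missing stage
#' otherwise. All randomness derives from the config seed, so a rerun
#' with the same configuration reproduces the artifacts.
#'
#' Per-beat rejection counters (delineation failures, normalization skips,
#' outlier beats) are accumulated in the manifest: these quality-control
#' drops are scientifically meaningful, not noise.
#'
#' @param out_dir artifact directory (created if needed).
#' @param config a [run_config()].
#' @param stages character vector of stages to run, in order.
#' @param n_subjects cohort size for the synth stage.
#' @param statuses statuses to synthesize.
#' @param records_per_status records per subject and status.
#' @param method normalization method for the normalize stage.
#' @param model_kind classifier for the evaluate stage.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(out_dir, config = run_config(),
                         stages = c("synth", "preprocess", "delineate",
                                    "analyze-hr", "normalize", "enroll",
                                    "evaluate"),
                         n_subjects = 5,
                         statuses = c("resting", "exercising"),
                         records_per_status = 2,
                         method = "proposed",
                         model_kind = "svm_gaussian") {
  all_stages <- c("synth", "preprocess", "delineate", "analyze-hr",
                  "normalize", "enroll", "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else
    list(config = unclass(config), stages_done = character(0),
         counters = list())
  need <- function(stage, what) {
    if (!stage %in% manifest$stages_done)
      stop(sprintf("missing %s: run the '%s' stage first", what, stage),
           call. = FALSE)
  }
  rec_dir <- file.path(out_dir, "records")
  pp_dir <- file.path(out_dir, "preprocessed")
  fid_dir <- file.path(out_dir, "fiducials")

  for (stage in all_stages[all_stages %in% stages]) {
    if (stage == "synth") {
      dir.create(rec_dir, showWarnings = FALSE)
      pop <- make_population(n_subjects, seed = config$seed)
      cohort <- synthesize_cohort(pop, statuses, records_per_status,
                                  fs = config$fs_expected, seed = config$seed)
      for (syn in cohort) {
        base <- file.path(rec_dir, syn$record$record_id)
        write_record(syn$record, paste0(base, ".csv"))
        write_fiducials(syn$truth, paste0(base, "_truth.csv"))
      }
      manifest$counters$n_records <- length(cohort)
    } else if (stage == "preprocess") {
      need("synth", "raw records")
      dir.create(pp_dir, showWarnings = FALSE)
      for (f in list.files(rec_dir, pattern = "\\.csv$", full.names = TRUE)) {
        if (grepl("_truth\\.csv$", f)) next
        rec <- read_record(f)
        pp <- preprocess_record(rec, config)
        write_record(pp$record, file.path(pp_dir, basename(f)))
      }
    } else if (stage == "delineate") {
      need("preprocess", "pre-processed records")
      dir.create(fid_dir, showWarnings = FALSE)
      n_fail <- 0L
      for (f in list.files(pp_dir, pattern = "\\.csv$", full.names = TRUE)) {
        rec <- read_record(f)
        fid <- tryCatch(detect_fiducials(rec, config), error = function(e) NULL)
        if (is.null(fid)) { n_fail <- n_fail + 1L; next }
        write_fiducials(fid, file.path(
          fid_dir, sub("\\.csv$", "_fid.csv", basename(f))))
      }
      manifest$counters$delineation_failures <- n_fail
    } else if (stage == "analyze-hr") {
      need("delineate", "fiducial tables")
      beats <- collect_beats(pp_dir, fid_dir, config)
      tab <- section_table(beats)
      models <- fit_all_sections(tab)
      refs <- reference_durations(models, config$ref_hr, config$hr_clip)
      jsonlite::write_json(
        list(refs = as.list(refs),
             models = lapply(models, function(m)
               list(section = m$section, r2 = m$r2, rmse_ms = m$rmse_ms,
                    breakpoints = m$breakpoints,
                    pieces = as.data.frame(m$pieces)))),
        file.path(out_dir, "section_models.json"), auto_unbox = TRUE,
        digits = NA)
    } else if (stage == "normalize") {
      need("analyze-hr", "section models")
      refs <- unlist(jsonlite::read_json(
        file.path(out_dir, "section_models.json"), simplifyVector = TRUE)$refs)
      beats <- collect_beats(pp_dir, fid_dir, config)
      nb <- normalize_beats(beats, method, refs = refs)
      manifest$counters$normalization_skips <- attr(nb, "n_skipped")
      by_subj <- split(nb, vapply(nb, `[[`, "", "subject_id"))
      dir.create(file.path(out_dir, "normalized"), showWarnings = FALSE)
      for (s in names(by_subj))
        write_beats(by_subj[[s]],
                    file.path(out_dir, "normalized", paste0(s, ".csv")),
                    meta = list(subject_id = s, method = method))
      write_beats_meta(nb, file.path(out_dir, "normalized", "beats_meta.csv"))
    } else if (stage == "enroll") {
      need("normalize", "normalized beats")
      nb <- load_normalized(out_dir)
      rest <- nb[vapply(nb, `[[`, "", "status") == "resting"]
      by_subj <- split(rest, vapply(rest, `[[`, "", "subject_id"))
      n_out <- 0L
      dir.create(file.path(out_dir, "templates"), showWarnings = FALSE)
      for (s in names(by_subj)) {
        st <- detect_outliers(by_subj[[s]])
        n_out <- n_out + sum(st$outlier_mask)
        tpl <- representative_beat(by_subj[[s]], st)
        write_beats(matrix(tpl$samples, 1),
                    file.path(out_dir, "templates", paste0(s, ".csv")),
                    meta = list(subject_id = s, n_inliers = tpl$n_inliers,
                                mu_rho = st$mu_rho, sigma_rho = st$sigma_rho,
                                threshold = st$threshold))
      }
      manifest$counters$outlier_beats <- n_out
    } else if (stage == "evaluate") {
      need("normalize", "normalized beats")
      nb <- load_normalized(out_dir)
      feat <- features_table(nb)
      rest <- feat[feat$status == "resting", , drop = FALSE]
      sp <- split_experiment1(rest, seed = config$seed)
      models <- train_auth_models(sp$train, model_kind, seed = config$seed)
      rep <- evaluate_models(models, sp$test)
      jsonlite::write_json(
        list(model_kind = model_kind, acc = rep$acc, far = rep$far,
             frr = rep$frr, eer = rep$eer, per_subject = rep$per_subject),
        file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
      flat <- cbind(rep$per_subject, status = "resting", method = method,
                    model = model_kind)
      utils::write.csv(flat, file.path(out_dir, "evaluation_per_subject.csv"),
                       row.names = FALSE)
    }
    manifest$stages_done <- union(manifest$stages_done, stage)
  }
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# rebuild ecg_beat lists from on-disk preprocessed records + fiducials
collect_beats <- function(pp_dir, fid_dir, config) {
  beats <- list()
  for (f in list.files(fid_dir, pattern = "_fid\\.csv$", full.names = TRUE)) {
    rec <- read_record(file.path(pp_dir, sub("_fid\\.csv$", ".csv", basename(f))))
    fid <- read_fiducials(f)
    beats <- c(beats, segment_beats(rec, fid, config))
  }
  beats
}

# sidecar with per-beat metadata so normalized beats can be reloaded
write_beats_meta <- function(nb, path) {
  meta <- data.frame(
    subject_id = vapply(nb, `[[`, "", "subject_id"),
    status = vapply(nb, `[[`, "", "status"),
    record_id = vapply(nb, `[[`, "", "record_id"),
    hr = vapply(nb, `[[`, 0, "hr"),
    fs = vapply(nb, `[[`, 0, "fs"),
    method = vapply(nb, `[[`, "", "method"))
  fid <- do.call(rbind, lapply(nb, function(b) as.data.frame(as.list(b$fiducials))))
  utils::write.csv(cbind(meta, fid), path, row.names = FALSE)
}

load_normalized <- function(out_dir) {
  meta <- utils::read.csv(file.path(out_dir, "normalized", "beats_meta.csv"))
  out <- list(); k <- 0L
  for (s in unique(meta$subject_id)) {
    m <- read_beats(file.path(out_dir, "normalized", paste0(s, ".csv")))
    rows <- which(meta$subject_id == s)
    for (j in seq_along(rows)) {
      r <- meta[rows[j], ]
      fid <- as.numeric(r[!(names(r) %in% c("subject_id", "status", "record_id",
                                            "hr", "fs", "method"))])
      names(fid) <- setdiff(names(r), c("subject_id", "status", "record_id",
                                        "hr", "fs", "method"))
      k <- k + 1L
      out[[k]] <- structure(
        list(samples = m[j, ], fiducials = fid, method = r$method, hr = r$hr,
             fs = r$fs, record_id = r$record_id, subject_id = r$subject_id,
             status = r$status),
        class = "normalized_beat")
    }
  }
  out
}
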