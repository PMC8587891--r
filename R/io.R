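#' Read an ECG record from disk
#'
#' Two layouts are supported. `format = "csv"` expects a two-column file
#' `time_s,amplitude_mV` with a side-car JSON metadata file (same path with
#' extension `.json`) holding at least `fs`; `subject_id`, `status` and
#' `record_id` are picked up when present. `format = "wfdb"` expects a
#' waveform-database-style pair: a plain-text header `<name>.hea`
#' (`record n_sig fs n_samp` then one signal line `file format gain units`)
#' and a 16-bit little-endian signal file `<name>.dat`.
#'
#' No resampling is performed; amplitudes are returned in mV.
#'
#' @param path path to the CSV file or to the `.hea` header.
#' @param format `"csv"` or `"wfdb"`.
#' @param fs sampling rate override when the metadata side-car is absent.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    dat <- utils::read.csv(path)
    if (ncol(dat) < 2) stop("CSV must have columns time_s,amplitude_mV", call. = FALSE)
    meta_path <- paste0(sub("\\.[^.]*$", "", path), ".json")
    meta <- list()
    if (file.exists(meta_path)) meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(meta$fs)) meta$fs <- fs
    if (is.null(meta$fs)) {
      dt <- diff(dat[[1]])
      if (length(dt) && sd(dt) < 1e-9 * mean(dt)) meta$fs <- 1 / mean(dt)
    }
    if (is.null(meta$fs) || !is.finite(meta$fs) || meta$fs <= 0)
      stop("sampling rate missing or invalid (no side-car metadata, no `fs`)",
           call. = FALSE)
    if (anyNA(dat[[2]])) stop("NaN/NA amplitudes in ", path, call. = FALSE)
    rec <- ecg_record(dat[[2]], fs = meta$fs,
                      subject_id = meta$subject_id %||% "",
                      status = meta$status %||% "",
                      record_id = meta$record_id %||% basename(path),
                      t0 = if (nrow(dat)) dat[[1]][1] else 0)
  } else {
    hdr <- readLines(path, warn = FALSE)
    top <- strsplit(trimws(hdr[1]), "\\s+")[[1]]
    if (length(top) < 4) stop("malformed header: ", path, call. = FALSE)
    fs_h <- as.numeric(top[3]); n_samp <- as.numeric(top[4])
    if (!is.finite(fs_h) || fs_h <= 0)
      stop("header declares invalid sampling rate: ", top[3], call. = FALSE)
    sig <- strsplit(trimws(hdr[2]), "\\s+")[[1]]
    dat_file <- file.path(dirname(path), sig[1])
    gain <- as.numeric(sig[3])
    raw <- readBin(dat_file, "integer", n = n_samp, size = 2, endian = "little")
    meta <- list()
    for (ln in hdr[startsWith(hdr, "#")]) {
      kv <- strsplit(sub("^#\\s*", "", ln), ":", fixed = TRUE)[[1]]
      if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
    }
    rec <- ecg_record(raw / gain, fs = fs_h,
                      subject_id = meta$subject_id %||% "",
                      status = meta$status %||% "",
                      record_id = sub("\\.hea$", "", basename(path)))
  }
  validate_record(rec)
}

#' Write an ECG record to disk
#'
#' Inverse of [read_record()]; see there for the layouts. The CSV round-trip
#' is exact to the printed precision (15 significant digits); the
#' wfdb-style layout quantizes to 16-bit integers at `gain` units per mV.
#'
#' @param rec an [ecg_record()].
#' @param path output path (CSV file or `.hea` header path).
#' @param format `"csv"` or `"wfdb"`.
#' @param gain integer quantization gain for the wfdb-style layout (per mV).
#' @return `path`, invisibly.
#' @export
write_record <- function(rec, path, format = c("csv", "wfdb"), gain = 2000) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "ecg_record"))
  if (format == "csv") {
    t <- rec$t0 + (seq_along(rec$samples) - 1) / rec$fs
    df <- data.frame(time_s = sprintf("%.15g", t),
                     amplitude_mV = sprintf("%.15g", rec$samples))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    meta_path <- paste0(sub("\\.[^.]*$", "", path), ".json")
    jsonlite::write_json(
      list(fs = rec$fs, subject_id = rec$subject_id, status = rec$status,
           record_id = rec$record_id),
      meta_path, auto_unbox = TRUE, digits = NA)
  } else {
    base <- sub("\\.hea$", "", path)
    name <- basename(base)
    q <- as.integer(round(pmax(pmin(rec$samples * gain, 32767), -32768)))
    writeBin(q, paste0(base, ".dat"), size = 2, endian = "little")
    hdr <- c(sprintf("%s 1 %.10g %d", name, rec$fs, length(rec$samples)),
             sprintf("%s.dat 16 %d mV", name, as.integer(gain)),
             paste0("# subject_id: ", rec$subject_id),
             paste0("# status: ", rec$status))
    writeLines(hdr, paste0(base, ".hea"))
  }
  invisible(path)
}

#' Write / read a matrix of equal-length normalized beats
#'
#' Beats are stored as a CSV matrix (one row per beat) with a side-car JSON
#' metadata file; the round trip is lossless to better than 1e-9 relative.
#'
#' @param beats a list of `normalized_beat` objects or a numeric matrix.
#' @param path output CSV path.
#' @param meta optional named list merged into the side-car metadata.
#' @return `path` (`write_beats`) or a numeric matrix with attribute
#'   `"meta"` (`read_beats`).
#' @export
write_beats <- function(beats, path, meta = list()) {
  if (is.list(beats) && !is.matrix(beats)) {
    lens <- vapply(beats, function(b) length(beat_samples(b)), 1L)
    if (length(unique(lens)) > 1)
      stop("ragged beat lengths: ", paste(unique(lens), collapse = ","),
           call. = FALSE)
    method <- unique(vapply(beats, function(b)
      if (inherits(b, "normalized_beat")) b$method else "raw", ""))
    if (length(method) == 1 && is.null(meta$method)) meta$method <- method
    m <- if (length(beats)) do.call(rbind, lapply(beats, beat_samples))
         else matrix(numeric(0), 0, 0)
  } else m <- as.matrix(beats)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(sprintf("s%d", seq_len(max(ncol(m), 0))), collapse = ","), con)
  if (nrow(m))
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                       con, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  meta$n_beats <- nrow(m); meta$length <- ncol(m)
  jsonlite::write_json(meta, paste0(sub("\\.[^.]*$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_beats
#' @export
read_beats <- function(path) {
  dat <- utils::read.csv(path)
  m <- as.matrix(dat)
  dimnames(m) <- NULL
  meta_path <- paste0(sub("\\.[^.]*$", "", path), ".json")
  if (file.exists(meta_path))
    attr(m, "meta") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  m
}

# samples of either a raw Beat or a normalized_beat
beat_samples <- function(b) {
  if (is.numeric(b)) b else b$samples
}

#' Write / read per-beat fiducial landmark tables
#'
#' One row per beat, columns = the nine landmark sample indices (0-based),
#' the same layout the synthetic generator uses for its ground truth, so
#' detected and true landmarks can be diffed directly.
#'
#' @param fids data.frame with columns Pon, Ppeak, QRSon, Qpeak, Rpeak,
#'   Speak, QRSoff, Tpeak, Toff.
#' @param path CSV path.
#' @export
write_fiducials <- function(fids, path) {
  utils::write.csv(fids, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiducials
#' @export
read_fiducials <- function(path) utils::read.csv(path)

`%||%` <- function(a, b) if (is.null(a)) b else a
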