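#' Construct a single-lead ECG record
#'
#' The basic container passed between all pipeline stages: a vector of
#' amplitude samples in millivolts plus sampling-rate and identity metadata.
#'
#' @param samples numeric vector of amplitudes (mV).
#' @param fs sampling rate in Hz; must be positive.
#' @param subject_id,status,record_id character metadata.
#' @param t0 time offset of the first sample, in seconds.
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1.2 * seq(0, 4, by = 1 / 500)), fs = 500)
#' rec
#' @export
ecg_record <- function(samples, fs, subject_id = "", status = "",
                       record_id = "", t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  fs <- as.numeric(fs)
  if (anyNA(samples) || !all(is.finite(samples)))
    stop("`samples` must be finite and free of NA", call. = FALSE)
  structure(
    list(samples = samples, fs = fs,
         subject_id = as.character(subject_id),
         status = as.character(status),
         record_id = as.character(record_id),
         t0 = as.numeric(t0)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s  subject=%s status=%s\n",
              x$record_id, x$subject_id, x$status))
  cat(sprintf("  %d samples @ %g Hz (%.2f s), range [%.3f, %.3f] mV\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

# Minimum record length demanded by every downstream stage (seconds).
.MIN_RECORD_S <- 2

validate_record <- function(rec, min_s = .MIN_RECORD_S) {
  if (!inherits(rec, "ecg_record")) stop("not an `ecg_record`", call. = FALSE)
  if (length(rec$samples) < min_s * rec$fs)
    stop(sprintf("record too short: %.3f s < required %g s",
                 length(rec$samples) / rec$fs, min_s), call. = FALSE)
  invisible(rec)
}

#' Pipeline run configuration
#'
#' Collects every tunable shared across stages. Defaults follow the method's
#' reference operating point: 500 Hz sampling, 60 Hz mains, 0.5 Hz 3rd-order
#' high-pass for baseline wander, Daubechies-6 wavelet denoising at level 4,
#' a 70 bpm reference heart rate for normalization, and a 40-180 bpm
#' plausibility clip on per-beat heart rates.
#'
#' @param fs_expected expected sampling rate (Hz).
#' @param mains_hz power-line frequency to notch (Hz).
#' @param hpf_cutoff,hpf_order Butterworth high-pass cutoff (Hz) and order.
#' @param wavelet wavelet identifier for denoising (only "db6" is built in).
#' @param wavelet_level decomposition depth for denoising.
#' @param ref_hr reference heart rate (bpm) that normalization maps beats to.
#' @param hr_clip length-2 numeric, admissible instantaneous heart-rate
#'   range (bpm); beats outside are discarded.
#' @param seed integer seed from which all stage randomness derives.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fs_expected = 500, mains_hz = 60, hpf_cutoff = 0.5,
                       hpf_order = 3, wavelet = "db6", wavelet_level = 4,
                       ref_hr = 70, hr_clip = c(40, 180), seed = 1L) {
  stopifnot(fs_expected > 0, mains_hz > 0, hpf_cutoff > 0, hpf_order >= 1,
            wavelet_level >= 1, ref_hr > 0, length(hr_clip) == 2,
            hr_clip[1] < hr_clip[2])
  structure(list(fs_expected = fs_expected, mains_hz = mains_hz,
                 hpf_cutoff = hpf_cutoff, hpf_order = as.integer(hpf_order),
                 wavelet = wavelet, wavelet_level = as.integer(wavelet_level),
                 ref_hr = ref_hr, hr_clip = as.numeric(hr_clip),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %-13s %s\n", k, paste(x[[k]], collapse = ",")))
  invisible(x)
}

#' Write / read a run configuration as flat key-value text
#'
#' @param cfg a [run_config()] object.
#' @param path file path.
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- vapply(names(cfg), function(k)
    paste0(k, " = ", paste(cfg[[k]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  defaults <- run_config()
  out <- unclass(defaults)
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(out)) stop("unknown config key: ", k, call. = FALSE)
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    out[[k]] <- if (k == "wavelet") v else as.numeric(v)
  }
  do.call(run_config, out)
}
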