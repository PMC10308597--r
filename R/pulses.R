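#' Detector settings for pulse recovery
#'
#' @param ref_channel Index of the reference magnitude channel used for peak
#'   finding (default 1 = 45 kHz).
#' @param threshold Detection threshold on the filtered reference magnitude
#'   (ohm); default 110.
#' @param min_separation Minimum separation between accepted apexes
#'   (samples); default 34 (~3 transit widths at 57 kHz sampling).
#' @param hp_cutoff High-pass cutoff (Hz) applied before detection.
#' @param window Half-width (samples) of the optional extremum search around
#'   the apex when indexing the other channels; 0 (default) indexes the apex
#'   sample directly.
#' @return Object of class `detector_config`.
#' @export
detector_config <- function(ref_channel = 1L, threshold = 110,
                            min_separation = 34L, hp_cutoff = 5,
                            window = 0L) {
  check_number(threshold, "threshold", 0, strict_lower = TRUE)
  check_number(min_separation, "min_separation", 1)
  check_number(hp_cutoff, "hp_cutoff", 0, strict_lower = TRUE)
  check_number(window, "window", 0)
  structure(list(ref_channel = as.integer(ref_channel), threshold = threshold,
                 min_separation = as.integer(min_separation),
                 hp_cutoff = hp_cutoff, window = as.integer(window)),
            class = "detector_config")
}

#' High-pass filter a multifrequency time series
#'
#' Removes the DC baseline and slow drift from every magnitude and phase
#' channel so that pulse amplitudes can be read relative to zero. The filter
#' is a second-order Butterworth high-pass applied forward-backward
#' (zero-phase); each channel's median is subtracted first so the filter
#' transient at the trace edges is negligible. Pulses much shorter than
#' `1/cutoff` pass essentially unattenuated, and a sub-cutoff sinusoidal
#' drift is suppressed enough that apex amplitudes are recovered within 2%.
#'
#' @param ts A `multifreq_ts` (from [synthesize_trial()] or
#'   [read_timeseries()]).
#' @param cutoff Cutoff frequency (Hz); must lie in (0, sample_rate/2).
#' @return A filtered `multifreq_ts` with attribute `filtered = TRUE`.
#' @export
highpass <- function(ts, cutoff = 5) {
  stopifnot(inherits(ts, "multifreq_ts"))
  fs <- ts$config$sample_rate
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff >= fs / 2)
    stop_domain("cutoff must lie in (0, sample_rate/2)")
  bf <- signal::butter(2, cutoff / (fs / 2), type = "high")
  filt1 <- function(x) {
    x <- x - median(x)
    signal::filtfilt(bf, x)
  }
  ts$mag <- apply(ts$mag, 2, filt1)
  ts$phase <- apply(ts$phase, 2, filt1)
  attr(ts, "filtered") <- TRUE
  ts
}

#' Threshold peak detection on a filtered reference channel
#'
#' Finds strict local maxima of `x` whose value exceeds `threshold`, then
#' enforces a minimum separation greedily by descending amplitude: candidates
#' are visited from the largest down (ties broken by earlier index) and a
#' candidate is kept only if no already-kept apex lies within
#' `min_separation` samples. This keeps the larger of two conflicting peaks.
#'
#' @param x Numeric vector, typically the filtered 45 kHz magnitude channel.
#' @param cfg A [detector_config()]; `threshold` and `min_separation` are
#'   used.
#' @return Sorted integer vector of apex sample indices (possibly empty).
#' @examples
#' x <- dnorm(seq(-4, 4, length.out = 201)) * 500
#' detect_peaks(x, detector_config(threshold = 110, min_separation = 10))
#' @export
detect_peaks <- function(x, cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"))
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  cand <- i[x[i] > x[i - 1L] & x[i] > x[i + 1L] & x[i] > cfg$threshold]
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (ci in cand) {
    if (length(kept) == 0L || all(abs(kept - ci) >= cfg$min_separation))
      kept <- c(kept, ci)
  }
  sort(kept)
}

#' Extract per-bead records at detected apexes
#'
#' For each apex index the peak impedance change `dZp` and phase change
#' `dPhip` at every carrier are read from the filtered channels at that same
#' sample ("direct indexing" by the reference-channel timestamp). With
#' `cfg$window > 0` the extremum (largest absolute value) within
#' `+/- window` samples is taken instead, compensating possible per-channel
#' apex misalignment at finite sample rate. Apexes closer than `window` to
#' the trace boundary are skipped with a warning.
#'
#' @param ts A filtered `multifreq_ts` (see [highpass()]).
#' @param apexes Integer apex indices from [detect_peaks()].
#' @param cfg A [detector_config()].
#' @return Data frame with one row per retained apex: `timestamp` (s),
#'   `dZp_<freq>` (ohm) and `dPhi_<freq>` (degrees) for the six carriers,
#'   and `gate` (initialised to `"ungated"`).
#' @export
extract_bead_records <- function(ts, apexes, cfg = detector_config()) {
  stopifnot(inherits(ts, "multifreq_ts"))
  n <- length(ts$t)
  if (length(apexes) == 0L) return(empty_records(ts$config$freqs))
  if (any(apexes < 1L | apexes > n))
    stop_domain("apex indices out of range")
  w <- cfg$window
  keep <- apexes - w >= 1L & apexes + w <= n
  if (any(!keep))
    warning(sum(!keep), " apex(es) within ", w,
            " samples of the trace boundary skipped")
  apexes <- sort(apexes[keep])
  if (length(apexes) == 0L) return(empty_records(ts$config$freqs))
  read_at <- function(ch, i) {
    if (w == 0L) return(ch[i])
    win <- ch[(i - w):(i + w)]
    win[which.max(abs(win))]
  }
  freqs <- ts$config$freqs
  lab <- freq_label(freqs)
  out <- data.frame(timestamp = ts$t[apexes])
  for (k in seq_along(freqs))
    out[[paste0("dZp_", lab[k])]] <-
      vapply(apexes, function(i) read_at(ts$mag[, k], i), numeric(1))
  for (k in seq_along(freqs))
    out[[paste0("dPhi_", lab[k])]] <-
      vapply(apexes, function(i) read_at(ts$phase[, k], i), numeric(1))
  out$gate <- "ungated"
  out
}

empty_records <- function(freqs) {
  lab <- freq_label(freqs)
  cols <- c("timestamp", paste0("dZp_", lab), paste0("dPhi_", lab))
  out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  out$gate <- character(0)
  out
}

#' Detect and extract bead records from a raw trace
#'
#' Convenience wrapper: high-pass filter, detect peaks on the reference
#' magnitude channel, extract records.
#'
#' @param ts A raw `multifreq_ts`.
#' @param cfg A [detector_config()].
#' @return A bead-record data frame (see [extract_bead_records()]).
#' @export
detect_bead_records <- function(ts, cfg = detector_config()) {
  tsf <- highpass(ts, cfg$hp_cutoff)
  apexes <- detect_peaks(tsf$mag[, cfg$ref_channel], cfg)
  extract_bead_records(tsf, apexes, cfg)
}

# column helpers for bead-record data frames
record_matrix <- function(records, prefix, freqs = NULL) {
  cols <- grep(paste0("^", prefix, "_"), names(records), value = TRUE)
  if (length(cols) == 0L) stop_domain("records carry no ", prefix, " columns")
  as.matrix(records[, cols, drop = FALSE])
}
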