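#' Gating rules for metallization subpopulations
#'
#' @param neg_freq_idx Indices (into the 6 carriers) checked for negative
#'   `dZp`; default `c(2, 3, 4)` = 150 kHz, 380 kHz, 2 MHz. Negative pulses
#'   at these mid frequencies are never produced by nonmetallized beads.
#' @param drop_threshold Minimum decrease `dZp(45 kHz) - dZp(150 kHz)` (ohm)
#'   qualifying as the "sharp drop" of the densest-metallization subset. The
#'   default is half the Coulter amplitude of the 8.2 um working bead
#'   (~169 ohm).
#' @return Object of class `gate_config`.
#' @export
gate_config <- function(neg_freq_idx = c(2L, 3L, 4L),
                        drop_threshold = coulter_delta_r(8.2e-6,
                                                         aperture_model()) / 2) {
  if (!all(neg_freq_idx %in% 1:6))
    stop_domain("neg_freq_idx must be indices into the 6 carriers")
  check_number(drop_threshold, "drop_threshold", 0, strict_lower = TRUE)
  structure(list(neg_freq_idx = as.integer(neg_freq_idx),
                 drop_threshold = drop_threshold),
            class = "gate_config")
}

#' Assign metallization subpopulation gates
#'
#' Partitions bead records into three rule-based subpopulations:
#' * `M_hi` - negative `dZp` at one of the mid frequencies AND a large drop
#'   from 45 kHz to 150 kHz (`>= drop_threshold`): the densest
#'   metallization, whose shell both shunts the displaced fluid and flips
#'   the pulse sign sharply;
#' * `M_med` - the negativity condition only;
#' * `M_lo` - everything else; these spectra match nonmetallized beads.
#'
#' Every record receives exactly one label.
#'
#' @param records Bead-record data frame carrying all six `dZp` columns.
#' @param cfg A [gate_config()].
#' @return `records` with the `gate` column filled.
#' @export
gate_beads <- function(records, cfg = gate_config()) {
  dZ <- record_matrix(records, "dZp")
  if (ncol(dZ) < max(cfg$neg_freq_idx))
    stop_domain("records carry fewer dZp channels than neg_freq_idx expects")
  neg <- apply(dZ[, cfg$neg_freq_idx, drop = FALSE] < 0, 1, any)
  drop <- (dZ[, 1] - dZ[, 2]) >= cfg$drop_threshold
  records$gate <- ifelse(neg & drop, "M_hi", ifelse(neg, "M_med", "M_lo"))
  records
}

#' Mean pulse spectrum of a set of bead records
#'
#' @param records Bead-record data frame with at least one row.
#' @return List with `dZp` and `dPhip` (per-frequency arithmetic means) and
#'   `n` (number of records).
#' @export
mean_spectrum <- function(records) {
  if (nrow(records) < 1L) stop_domain("mean_spectrum needs at least one record")
  list(dZp = colMeans(record_matrix(records, "dZp")),
       dPhip = colMeans(record_matrix(records, "dPhi")),
       n = nrow(records))
}
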