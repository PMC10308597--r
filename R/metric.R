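# The metallization metric: z-scored 11 MHz magnitude/phase features,
# two-class Fisher discriminant, per-bead projection, trial mean.

#' Extract the metric features from bead records
#'
#' Returns the two features used by the metallization metric: the peak
#' impedance change and peak phase change at the feature frequency
#' (default 11 MHz), where high- and low-metal beads contrast most starkly.
#'
#' @param records Bead-record data frame.
#' @param feature_freq Carrier frequency (Hz) whose channels are used.
#' @return Numeric matrix with columns `dZp` and `dPhip`.
#' @export
metric_features <- function(records, feature_freq = 11e6) {
  lab <- freq_label(feature_freq)
  zc <- paste0("dZp_", lab)
  pc <- paste0("dPhi_", lab)
  if (!all(c(zc, pc) %in% names(records)))
    stop_domain("records carry no ", lab, " feature columns")
  cbind(dZp = records[[zc]], dPhip = records[[pc]])
}

#' Fit the per-feature z-score scaler
#'
#' Pooled (all training beads, both classes) per-feature mean and standard
#' deviation; the transform is `x -> (x - mean) / sd`.
#'
#' @param x Numeric feature matrix (rows = beads).
#' @return List with `mean` and `sd` vectors, class `feature_scaler`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_domain("need at least 2 rows to fit a scaler")
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  if (any(s <= 0 | !is.finite(s)))
    stop_domain("zero-variance feature: cannot z-score")
  structure(list(mean = mu, sd = s), class = "feature_scaler")
}

apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Fit the two-class Fisher linear discriminant metric
#'
#' Computes the Fisher direction `w` proportional to
#' `S_w^{-1} (mu_high - mu_low)` on z-scored features, where `S_w` is the
#' within-class scatter matrix, normalizes `w` to unit length, and fixes the
#' orientation so that high-metal beads project higher. The decision
#' threshold is the midpoint of the projected class means. (The per-bead
#' projection is the 1-D "principal component" of the discriminant.)
#'
#' @param x Feature matrix (rows = beads), unscaled; the scaler is fitted on
#'   the pooled rows unless supplied.
#' @param labels Character/factor vector with levels `"high"` and `"low"`.
#' @param scaler Optional pre-fitted [fit_scaler()] result.
#' @param feature_freq Frequency (Hz) the features came from (stored for
#'   bookkeeping).
#' @return Object of class `metric_model` with fields `feature_freq`,
#'   `feature_means`, `feature_sds`, `w` (unit norm), `sign`,
#'   `class_means_projected` (oriented, named `low`/`high`) and
#'   `decision_threshold`.
#' @export
fit_lda <- function(x, labels, scaler = NULL, feature_freq = 11e6) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (!setequal(unique(labels), c("high", "low")))
    stop_domain("labels must contain both 'high' and 'low'")
  if (is.null(scaler)) scaler <- fit_scaler(x)
  z <- apply_scaler(scaler, x)
  zh <- z[labels == "high", , drop = FALSE]
  zl <- z[labels == "low", , drop = FALSE]
  if (nrow(zh) < 2L || nrow(zl) < 2L)
    stop_domain("need at least 2 beads per class")
  mu_h <- colMeans(zh)
  mu_l <- colMeans(zl)
  Sw <- crossprod(sweep(zh, 2, mu_h)) + crossprod(sweep(zl, 2, mu_l))
  w <- tryCatch(solve(Sw, mu_h - mu_l), error = function(e)
    stop_domain("within-class scatter is singular; regularize by adding ",
                "eps*I with eps = 1e-6 * trace to Sw"))
  w <- w / sqrt(sum(w^2))
  sgn <- if (sum(w * (mu_h - mu_l)) >= 0) 1 else -1
  ph <- sgn * sum(w * mu_h)
  pl <- sgn * sum(w * mu_l)
  structure(list(feature_freq = feature_freq,
                 feature_means = scaler$mean,
                 feature_sds = scaler$sd,
                 w = as.numeric(w), sign = sgn,
                 class_means_projected = c(low = pl, high = ph),
                 decision_threshold = (ph + pl) / 2),
            class = "metric_model")
}

#' Train the metallization metric from high/low-metal bead records
#'
#' Convenience wrapper combining [metric_features()], [fit_scaler()] and
#' [fit_lda()] on two training record sets.
#'
#' @param records_high,records_low Bead-record data frames of the high-metal
#'   and low-metal training beads.
#' @param feature_freq Feature carrier (Hz), default 11 MHz.
#' @return A `metric_model`.
#' @export
fit_metric <- function(records_high, records_low, feature_freq = 11e6) {
  x <- rbind(metric_features(records_high, feature_freq),
             metric_features(records_low, feature_freq))
  labels <- c(rep("high", nrow(records_high)), rep("low", nrow(records_low)))
  fit_lda(x, labels, feature_freq = feature_freq)
}

#' @export
print.metric_model <- function(x, ...) {
  cat("<metric_model>\n")
  cat(sprintf("  features at %s Hz; w = (%.4f, %.4f), sign = %+d\n",
              format(x$feature_freq), x$w[1], x$w[2], x$sign))
  cat(sprintf("  projected class means: low %.3f, high %.3f; threshold %.3f\n",
              x$class_means_projected["low"], x$class_means_projected["high"],
              x$decision_threshold))
  invisible(x)
}

#' Per-bead metallization scores
#'
#' Projects each bead's z-scored features on the oriented discriminant
#' direction: `score = sign * (z(x) . w)`. Higher scores mean more
#' metallization.
#'
#' @param records Bead-record data frame carrying the feature channels.
#' @param model A `metric_model` from [fit_lda()] or [fit_metric()].
#' @return Numeric vector of scores, one per record.
#' @export
score_beads <- function(records, model) {
  stopifnot(inherits(model, "metric_model"))
  x <- metric_features(records, model$feature_freq)
  scaler <- structure(list(mean = model$feature_means, sd = model$feature_sds),
                      class = "feature_scaler")
  as.numeric(model$sign * (apply_scaler(scaler, x) %*% model$w))
}

#' Trial-level metallization metric
#'
#' The arithmetic mean of the per-bead scores represents the trial and serves
#' as its degree-of-metallization measure.
#'
#' @param scores Numeric vector of per-bead scores (length >= 1).
#' @return Single numeric value.
#' @export
trial_metric <- function(scores) {
  if (length(scores) < 1L || any(is.na(scores)))
    stop_domain("trial_metric needs at least one non-missing score")
  mean(scores)
}

#' Serialize / restore a metric model as JSON
#'
#' @param model A `metric_model`.
#' @param path File path.
#' @return `read_metric_model` returns the restored `metric_model`;
#'   `write_metric_model` returns `path` invisibly.
#' @export
write_metric_model <- function(model, path) {
  stopifnot(inherits(model, "metric_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metric_model
#' @export
read_metric_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$class_means_projected <- unlist(m$class_means_projected)
  structure(m, class = "metric_model")
}
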