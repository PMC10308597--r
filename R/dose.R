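# Dose-response: 4PL fitting, limit of detection, trial classification.

fourpl <- function(x, a, b, c, d) d + (a - d) / (1 + (x / c)^b)

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{y = d + \frac{a - d}{1 + (x/c)^b}}
#' where `a` is the response at zero concentration (floor for an increasing
#' assay), `d` the response at saturation, `c` the inflection concentration
#' and `b` the Hill slope. Zero concentrations are valid as-is for `b > 0`
#' (the curve evaluates to `a`), so fitting is done on the linear
#' concentration axis. Initialisation: `a` = mean response at the lowest
#' concentration, `d` = mean response at the highest, `c` = concentration
#' whose mean response is nearest the mid-response, `b = 1`. Fitting uses
#' Levenberg-Marquardt least squares with `c` bounded positive.
#' Non-convergence or degenerate data never error silently: the returned fit
#' carries `converged = FALSE` and a diagnostic message.
#'
#' @param conc Concentrations (nM), non-negative, at least 4 distinct values.
#' @param y Responses (trial metrics), same length.
#' @return Object of class `dose_fit` with fields `a`, `b`, `c`, `d`,
#'   `residual_sd`, `converged`, `message`, and the data.
#' @examples
#' x <- c(0, 2, 6, 20, 60, 200)
#' y <- 5 + (0 - 5) / (1 + (x / 20)^1.5)
#' fit <- fit_4pl(x, y)
#' unlist(fit[c("a", "b", "c", "d")])
#' @export
fit_4pl <- function(conc, y) {
  if (any(conc < 0)) stop_domain("concentrations must be non-negative")
  if (length(conc) != length(y)) stop_domain("conc and y lengths differ")
  if (length(unique(conc)) < 4L)
    stop_domain("need at least 4 distinct concentrations")
  dat <- data.frame(x = conc, y = y)
  bad <- function(msg) structure(
    list(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
         residual_sd = NA_real_, converged = FALSE, message = msg,
         conc = conc, y = y, fit = NULL),
    class = "dose_fit")
  if (sd(y) == 0) return(bad("constant response: 4PL is degenerate"))
  means <- tapply(dat$y, dat$x, mean)
  xs <- as.numeric(names(means))
  a0 <- means[[which.min(xs)]]
  d0 <- means[[which.max(xs)]]
  mid <- (a0 + d0) / 2
  cpos <- xs[xs > 0]
  c0 <- cpos[which.min(abs(means[match(cpos, xs)] - mid))]
  if (length(c0) == 0L || !is.finite(c0)) c0 <- median(cpos)
  # Levenberg-Marquardt on the residual function with a numeric Jacobian
  # (a symbolic gradient of (x/c)^b is undefined at x = 0)
  resid_fn <- function(p) dat$y - fourpl(dat$x, p[1], p[2], p[3], p[4])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(a = a0, b = 1, c = c0, d = d0), fn = resid_fn,
                       lower = c(-Inf, -Inf, 1e-12, -Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) return(bad(conditionMessage(fit)))
  p <- fit$par
  if (any(!is.finite(p))) return(bad("non-finite parameters"))
  if (!fit$info %in% 1:4) return(bad(fit$message))
  structure(list(a = p[["a"]], b = p[["b"]], c = p[["c"]], d = p[["d"]],
                 residual_sd = sqrt(fit$deviance / max(1, length(y) - 4)),
                 converged = TRUE, message = "converged",
                 conc = conc, y = y, fit = fit),
            class = "dose_fit")
}

#' @export
print.dose_fit <- function(x, ...) {
  cat("<dose_fit 4PL>", if (x$converged) "converged" else
    paste("NOT converged:", x$message), "\n")
  if (x$converged)
    cat(sprintf("  a = %.4g, b = %.4g, c = %.4g nM, d = %.4g (residual sd %.3g)\n",
                x$a, x$b, x$c, x$d, x$residual_sd))
  invisible(x)
}

#' @export
predict.dose_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$conc else
    if (is.data.frame(newdata)) newdata$x else newdata
  fourpl(x, object$a, object$b, object$c, object$d)
}

#' Invert a 4PL curve
#'
#' Closed-form inverse `x = c * ((a - d)/(y - d) - 1)^(1/b)`, defined for
#' responses strictly between the floor and ceiling.
#'
#' @param fit A converged `dose_fit` (or list with `a`, `b`, `c`, `d`).
#' @param y Response value(s) in the open interval between `a` and `d`.
#' @return Concentration(s) (nM); `NA` where `y` is outside the open range.
#' @export
inverse_4pl <- function(fit, y) {
  lo <- min(fit$a, fit$d)
  hi <- max(fit$a, fit$d)
  ratio <- (fit$a - fit$d) / (y - fit$d) - 1
  out <- fit$c * ratio^(1 / fit$b)
  out[y <= lo | y >= hi] <- NA_real_
  out
}

#' Limit of detection from a 4PL fit and blank replicates
#'
#' The LOD is the smallest concentration at which the fitted curve exceeds
#' `mean(blank) + 3 * sd(blank)`, obtained in closed form from
#' [inverse_4pl()]. If the cutoff lies beyond the fitted ceiling the LOD is
#' undefined and flagged (`beyond_range = TRUE`).
#'
#' @param fit A converged `dose_fit`.
#' @param blank_scores Two or more replicate blank trial metrics, or `NULL`
#'   if `blank_mean`/`blank_sd` are given directly.
#' @param blank_mean,blank_sd Optional direct blank statistics.
#' @return List with `lod` (nM, `NA` if undefined), `cutoff`,
#'   `beyond_range` and `message`.
#' @export
estimate_lod <- function(fit, blank_scores = NULL,
                         blank_mean = NULL, blank_sd = NULL) {
  if (!isTRUE(fit$converged)) stop_domain("LOD requires a converged 4PL fit")
  if (!is.null(blank_scores)) {
    if (length(blank_scores) < 2L && is.null(blank_sd))
      stop_domain("need >= 2 blank replicates or a blank sd")
    blank_mean <- mean(blank_scores)
    if (is.null(blank_sd)) blank_sd <- sd(blank_scores)
  }
  if (is.null(blank_mean) || is.null(blank_sd))
    stop_domain("supply blank_scores or blank_mean and blank_sd")
  if (blank_sd < 0) stop_domain("blank sd must be non-negative")
  cutoff <- blank_mean + 3 * blank_sd
  ceiling_ <- max(fit$a, fit$d)
  floor_ <- min(fit$a, fit$d)
  if (cutoff >= ceiling_)
    return(list(lod = NA_real_, cutoff = cutoff, beyond_range = TRUE,
                message = "cutoff exceeds the fitted ceiling: LOD beyond tested range"))
  if (cutoff <= floor_)
    return(list(lod = 0, cutoff = cutoff, beyond_range = FALSE,
                message = "cutoff at or below the fitted floor"))
  list(lod = as.numeric(inverse_4pl(fit, cutoff)), cutoff = cutoff,
       beyond_range = FALSE, message = "ok")
}

#' Classify a trial against the trained metric threshold
#'
#' A trial is called positive when its metallization metric exceeds the
#' midpoint between the projected high- and low-metal training means.
#'
#' @param metric Trial-level metallization metric ([trial_metric()]).
#' @param model A trained `metric_model`.
#' @return `"positive"` or `"negative"` (vectorised over `metric`).
#' @export
classify_trial <- function(metric, model) {
  stopifnot(inherits(model, "metric_model"))
  ifelse(metric > model$decision_threshold, "positive", "negative")
}
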