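# Independent oracles and fixture builders used across the suite.

DEFAULT_FREQS <- c(45e3, 150e3, 380e3, 2e6, 11e6, 35e6)
FREQ_LABS <- c("45k", "150k", "380k", "2M", "11M", "35M")

# Brute-force peak enumeration: naive scan for strict local maxima above the
# threshold, then greedy pruning by descending amplitude (ties: earlier
# index) with an explicit pairwise distance check. Deliberately loop-based
# and separate from the package implementation.
brute_peaks <- function(x, threshold, min_sep) {
  n <- length(x)
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    if (x[i] > x[i - 1L] && x[i] > x[i + 1L] && x[i] > threshold)
      cand <- c(cand, i)
  }
  if (length(cand) == 0L) return(integer(0))
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (ci in ord) {
    ok <- TRUE
    for (kj in kept) if (abs(kj - ci) < min_sep) ok <- FALSE
    if (ok) kept <- c(kept, ci)
  }
  sort(kept)
}

# Numerical slab-resistance integral for a sphere of diameter d centred in a
# cylindrical aperture of diameter D: independent check of the d^3 scaling
# of the resistive-pulse amplitude.
slab_delta_r <- function(d, D, rho, n = 20001) {
  z <- seq(-d / 2, d / 2, length.out = n)
  A <- pi * D^2 / 4
  a <- pi * (d^2 / 4 - z^2)
  dz <- z[2] - z[1]
  sum(rho * (1 / (A - a) - 1 / A)) * dz
}

# random trace generator for detector property tests: baseline noise plus a
# random number of Gaussian bumps of random height/width/location
rand_trace <- function(seed, n = 600) {
  set.seed(seed)
  x <- rnorm(n, 0, 30)
  k <- sample(0:6, 1)
  for (j in seq_len(k)) {
    pos <- sample(10:(n - 10), 1)
    amp <- runif(1, 40, 400)
    wid <- runif(1, 2, 12)
    i <- pmax(1, pmin(n, (pos - 40):(pos + 40)))
    x[i] <- x[i] + amp * exp(-((i - pos)^2) / (2 * wid^2))
  }
  x
}

# build a bead-record data frame from per-bead dZp (and optionally dPhip)
# matrices with columns in carrier order
make_records <- function(dZp, dPhip = NULL) {
  dZp <- matrix(dZp, ncol = 6)
  dPhip <- if (is.null(dPhip)) matrix(0, nrow(dZp), 6)
           else matrix(dPhip, ncol = 6)
  out <- data.frame(timestamp = seq_len(nrow(dZp)))
  for (k in 1:6) out[[paste0("dZp_", FREQ_LABS[k])]] <- dZp[, k]
  for (k in 1:6) out[[paste0("dPhi_", FREQ_LABS[k])]] <- dPhip[, k]
  out$gate <- rep("ungated", nrow(dZp))
  out
}

# reference four-parameter logistic used to generate dose-response fixtures
gen_4pl <- function(x, a, b, c, d) d + (a - d) / (1 + (x / c)^b)

# score a raw feature matrix with a fitted metric model
score_beads_matrix <- function(model, x) {
  sc <- structure(list(mean = model$feature_means, sd = model$feature_sds),
                  class = "feature_scaler")
  as.numeric(model$sign * (beadpulse:::apply_scaler(sc, x) %*% model$w))
}

# trial specs emulating the direct-conjugation training bead sets:
# high-metal (dense silver film) and low-metal (background metallization)
high_metal_spec <- function(seed, n_beads = 60) {
  trial_spec(n_beads = n_beads, probe_concentration = 0,
             binding_params = list(floor = 0.85, ceiling = 0.85,
                                   c50 = 30, hill = 1.2),
             seed = seed)
}
low_metal_spec <- function(seed, n_beads = 60) {
  trial_spec(n_beads = n_beads, probe_concentration = 0,
             binding_params = list(floor = 0.02, ceiling = 0.02,
                                   c50 = 30, hill = 1.2),
             seed = seed)
}
# strictly nonmetallized beads (no background metallization)
nonmetallized_spec <- function(seed, n_beads = 60, ...) {
  trial_spec(n_beads = n_beads, probe_concentration = 0,
             binding_params = list(floor = 0, ceiling = 0.85,
                                   c50 = 30, hill = 1.2),
             seed = seed, ...)
}

# acquisition with all noise and drift switched off
quiet_acq <- function(duration = 0.2, seed = 1L, ...) {
  acquisition_config(duration = duration, noise_sd_mag = 0,
                     noise_sd_phase = 0, drift_amp = 0, seed = seed, ...)
}
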