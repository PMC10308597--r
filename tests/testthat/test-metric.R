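test_that("z-score scaler normalizes and is affine-invariant", {
  set.seed(1)
  x <- cbind(rnorm(100, 50, 9), rnorm(100, -2, 0.4))
  sc <- fit_scaler(x)
  z <- beadpulse:::apply_scaler(sc, x)
  expect_equal(colMeans(z), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(1, 1), tolerance = 1e-12)
  # affine pre-transform leaves the z-scored features unchanged
  x2 <- sweep(x * 3.7, 2, c(10, -5), "+")
  z2 <- beadpulse:::apply_scaler(fit_scaler(x2), x2)
  expect_equal(z2, z, tolerance = 1e-10)
  expect_error(fit_scaler(cbind(rep(1, 10), rnorm(10))), "variance")
})

test_that("Fisher discriminant matches closed form and reference LDA", {
  set.seed(7)
  n <- 200
  xh <- matrix(rnorm(2 * n), n) + matrix(c(3, 3), n, 2, byrow = TRUE)
  xl <- matrix(rnorm(2 * n), n) + matrix(c(-3, -3), n, 2, byrow = TRUE)
  x <- rbind(xh, xl)
  labels <- rep(c("high", "low"), each = n)
  model <- fit_lda(x, labels)
  expect_equal(sqrt(sum(model$w^2)), 1, tolerance = 1e-12)

  # closed-form Fisher direction computed independently from scratch
  sc <- fit_scaler(x)
  z <- beadpulse:::apply_scaler(sc, x)
  zh <- z[1:n, ]; zl <- z[-(1:n), ]
  Sw <- (n - 1) * (cov(zh) + cov(zl))
  w_ref <- solve(Sw) %*% (colMeans(zh) - colMeans(zl))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  cosang <- abs(sum(model$w * w_ref))
  expect_equal(cosang, 1, tolerance = 1e-8)

  # reference implementation agrees on the direction
  ld <- MASS::lda(z, grouping = labels)
  w_mass <- ld$scaling[, 1] / sqrt(sum(ld$scaling[, 1]^2))
  expect_equal(abs(sum(model$w * w_mass)), 1, tolerance = 1e-8)

  # perfectly separable clouds: thresholded projection is 100% correct
  scores <- score_beads_matrix(model, x)
  expect_true(all(scores[1:n] > model$decision_threshold))
  expect_true(all(scores[-(1:n)] < model$decision_threshold))

  # a flipped discriminant direction is absorbed by the orientation sign
  flipped <- model
  flipped$w <- -model$w
  flipped$sign <- -model$sign
  expect_equal(score_beads_matrix(flipped, x), scores, tolerance = 1e-12)
  # row order is irrelevant to the fitted model
  perm <- sample(2 * n)
  model3 <- fit_lda(x[perm, ], labels[perm])
  expect_equal(model3$w, model$w, tolerance = 1e-10)
  expect_equal(model3$decision_threshold, model$decision_threshold,
               tolerance = 1e-10)
})

test_that("isotropic within-class covariance aligns w with the mean difference", {
  set.seed(11)
  n <- 4000
  x <- rbind(matrix(rnorm(2 * n), n) + matrix(c(2, 1), n, 2, byrow = TRUE),
             matrix(rnorm(2 * n), n) + matrix(c(-2, -1), n, 2, byrow = TRUE))
  # identity scaler so the feature space itself is isotropic within class
  unit <- structure(list(mean = c(0, 0), sd = c(1, 1)),
                    class = "feature_scaler")
  model <- fit_lda(x, rep(c("high", "low"), each = n), scaler = unit)
  mu_diff <- colMeans(x[1:n, ]) - colMeans(x[-(1:n), ])
  mu_diff <- mu_diff / sqrt(sum(mu_diff^2))
  expect_equal(abs(sum(model$w * mu_diff)), 1, tolerance = 0.01)
})

test_that("class centroids project onto the stored class means", {
  set.seed(3)
  x <- rbind(matrix(rnorm(200, 2), 100), matrix(rnorm(200, -2), 100))
  labels <- rep(c("high", "low"), each = 100)
  model <- fit_lda(x, labels)
  sc <- structure(list(mean = model$feature_means, sd = model$feature_sds),
                  class = "feature_scaler")
  zc_h <- colMeans(beadpulse:::apply_scaler(sc, x[1:100, ]))
  proj_h <- model$sign * sum(zc_h * model$w)
  expect_equal(proj_h, unname(model$class_means_projected["high"]),
               tolerance = 1e-10)
  expect_gt(model$class_means_projected["high"],
            model$class_means_projected["low"])
  expect_equal(model$decision_threshold,
               mean(model$class_means_projected), tolerance = 1e-12)
})

test_that("trial metric is the permutation-invariant mean of scores", {
  expect_equal(trial_metric(0.7), 0.7)
  s <- rnorm(60)
  expect_equal(trial_metric(s), trial_metric(sample(s)))
  expect_error(trial_metric(numeric(0)), "one")
})

test_that("metric separates high- and low-metal bead sets", {
  acq <- acquisition_config(duration = 0.8, seed = 1)
  train_hi <- simulate_bead_records(high_metal_spec(101), config = acq)
  train_lo <- simulate_bead_records(low_metal_spec(102), config = acq)
  model <- fit_metric(train_hi$records, train_lo$records)

  # held-out full-pipeline trials
  ap <- aperture_model()
  sh <- synthesize_trial(high_metal_spec(201),
                         ap, acquisition_config(duration = 0.8, seed = 201))
  sl <- synthesize_trial(low_metal_spec(202),
                         ap, acquisition_config(duration = 0.8, seed = 202))
  rh <- detect_bead_records(sh$ts)
  rl <- detect_bead_records(sl$ts)
  scores <- c(score_beads(rh, model), score_beads(rl, model))
  y <- c(rep(1, nrow(rh)), rep(0, nrow(rl)))
  auc <- suppressMessages(as.numeric(pROC::auc(y, scores)))
  expect_gte(auc, 0.95)
  expect_gt(trial_metric(score_beads(rh, model)),
            trial_metric(score_beads(rl, model)))
})

test_that("trial metric increases with dose", {
  doses <- c(0.5, 2, 5, 15, 30, 60, 120, 200)
  acq <- acquisition_config(seed = 5)
  model <- fit_metric(
    simulate_bead_records(high_metal_spec(301), config = acq)$records,
    simulate_bead_records(low_metal_spec(302), config = acq)$records)
  pts <- do.call(rbind, lapply(1:10, function(s) {
    data.frame(dose = doses, metric = sapply(doses, function(conc) {
      r <- simulate_bead_records(trial_spec(n_beads = 60,
                                            probe_concentration = conc,
                                            seed = s), config = acq)
      trial_metric(score_beads(r$records, model))
    }))
  }))
  expect_gte(cor(pts$dose, pts$metric, method = "spearman"), 0.9)
})

test_that("training is reproducible and survives JSON round-trip", {
  acq <- acquisition_config(seed = 2)
  hi <- simulate_bead_records(high_metal_spec(55), config = acq)$records
  lo <- simulate_bead_records(low_metal_spec(56), config = acq)$records
  m1 <- fit_metric(hi, lo)
  m2 <- fit_metric(hi, lo)
  expect_identical(m1, m2)
  path <- tempfile(fileext = ".json")
  write_metric_model(m1, path)
  m3 <- read_metric_model(path)
  expect_equal(m3$w, m1$w, tolerance = 1e-12)
  expect_equal(m3$decision_threshold, m1$decision_threshold, tolerance = 1e-12)
  expect_equal(score_beads(hi, m3), score_beads(hi, m1), tolerance = 1e-10)
})
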