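test_that("sim_config validates its invariants", {
  expect_error(sim_config(3), "at least 4")
  expect_error(sim_config(10, sigma0 = -0.1), "non-negative")
  expect_error(sim_config(10, sigma0 = 0.1, sigma1 = -0.5), "non-negative")
  expect_error(sim_config(10, kappa0 = 10, kappa1 = 20), "concentration")
  bad_fc <- matrix(0.99, 4, 4); diag(bad_fc) <- 1; bad_fc[1, 2] <- -0.99
  bad_fc[2, 1] <- -0.99
  expect_error(sim_config(10, n_rois = 4, template_fc = bad_fc),
               "positive definite")
  # null mode forces the effective slopes to zero
  cfg <- sim_config(10, mode = "null", sigma1 = 0.5, kappa1 = 30)
  expect_equal(cfg$sigma1, 0)
  expect_equal(cfg$kappa1, 0)
})

test_that("simulate_subject_fc is exact at zero noise and always a valid correlation matrix", {
  tz <- atanh(matrix(0.4, 5, 5) - diag(0.4, 5))
  out <- simulate_subject_fc(tz, 0.5, 0, 0)
  expect_equal(out, tanh(tz) + diag(1 - tanh(diag(tz))), tolerance = 1e-15)
  set.seed(21)
  for (i in 1:20) {
    C <- simulate_subject_fc(tz, runif(1), 0.2, 0.4)
    expect_true(isSymmetric(C))
    expect_equal(unname(diag(C)), rep(1, 5))
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
    expect_true(all(abs(C) <= 1 + 1e-12))
  }
  expect_error(simulate_subject_fc(matrix(1:25, 5), 0.5, 0.1, 0.1), "symmetric")
  expect_error(simulate_subject_fc(tz, 1, 0.1, -0.3), "non-negative")
  set.seed(99); a <- simulate_subject_fc(tz, 0.3, 0.1, 0.2)
  set.seed(99); b <- simulate_subject_fc(tz, 0.3, 0.1, 0.2)
  expect_identical(a, b)
})

test_that("trait-independent noise yields equal FC spread across trait levels, trait-scaled noise does not", {
  tz <- atanh(matrix(0.4, 6, 6) - diag(0.4, 6))
  pair_dist <- function(sigma1, tn, n = 200) {
    replicate(n, {
      v1 <- vectorize_upper(simulate_subject_fc(tz, tn, 0.1, sigma1))
      v2 <- vectorize_upper(simulate_subject_fc(tz, tn, 0.1, sigma1))
      fc_profile_dissim(v1, v2)
    })
  }
  set.seed(22)
  d_lo <- pair_dist(0, 0.1); d_hi <- pair_dist(0, 0.9)
  expect_gt(t.test(d_lo, d_hi)$p.value, 0.01)   # null: equal means
  d_lo2 <- pair_dist(0.4, 0.1); d_hi2 <- pair_dist(0.4, 0.9)
  expect_gt(mean(d_hi2), mean(d_lo2))           # AnnaK ordering
  expect_lt(t.test(d_lo2, d_hi2)$p.value, 1e-6)
})

test_that("simulate_timeseries reproduces the requested correlation", {
  set.seed(23)
  X <- simulate_timeseries(diag(3), 1e4)
  expect_true(all(abs(cor(X)[upper.tri(diag(3))]) < 0.05))
  corr <- matrix(c(1, 0.9, 0.9, 1), 2)
  Y <- simulate_timeseries(corr, 1e4)
  expect_equal(cor(Y)[1, 2], 0.9, tolerance = 0.02)
  set.seed(42); A <- simulate_timeseries(corr, 50)
  set.seed(42); B <- simulate_timeseries(corr, 50)
  expect_identical(A, B)
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_timeseries(bad, 10), "positive definite")
})

test_that("simulate_gaze returns the canonical path at zero dispersion", {
  gz <- utils::modifyList(
    sim_config(4)$gaze,
    list(n_frames = 300, blink_rate = 0, offscreen_rate = 0, dropout_rate = 0))
  canon <- canonical_gaze(gz)
  tr <- simulate_gaze(canon, 0.7, 0, 0, gz)
  expect_equal(tr$x, unname(canon[, 1]))
  expect_equal(tr$y, unname(canon[, 2]))
  # two zero-sigma subjects are identical, so gaze dissimilarity is 0
  tr2 <- simulate_gaze(canon, 0.2, 0, 0, gz)
  expect_equal(gaze_dissim(preprocess_gaze(tr), preprocess_gaze(tr2)), 0)
})

test_that("gaze dissimilarity grows with dyad trait when the deviation is trait-scaled", {
  gz <- utils::modifyList(
    sim_config(4)$gaze,
    list(n_frames = 300, blink_rate = 0, offscreen_rate = 0, dropout_rate = 0))
  canon <- canonical_gaze(gz)
  set.seed(24)
  mean_d <- vapply(c(0.1, 0.9), function(tn) {
    mean(replicate(40, {
      a <- simulate_gaze(canon, tn, 5, 60, gz)
      b <- simulate_gaze(canon, tn, 5, 60, gz)
      gaze_dissim(a, b)
    }))
  }, numeric(1))
  expect_gt(mean_d[2], mean_d[1])
})

test_that("simulate_embedding stays unit-norm and disperses with trait", {
  set.seed(25)
  mu <- rnorm(32); mu <- mu / sqrt(sum(mu^2))
  expect_identical(simulate_embedding(mu, 0.5, Inf, 0), mu)
  for (i in 1:10) {
    expect_equal(sum(simulate_embedding(mu, runif(1), 20, 10)^2), 1,
                 tolerance = 1e-12)
  }
  expect_error(simulate_embedding(mu, 1, 5, 10), "negative")
  expect_error(simulate_embedding(2 * mu, 0.5, 10, 0), "unit-norm")
  mean_cos_d <- vapply(c(0.1, 0.9), function(tn) {
    mean(replicate(150, semantic_dissim(simulate_embedding(mu, tn, 40, 35),
                                        simulate_embedding(mu, tn, 40, 35))))
  }, numeric(1))
  expect_gt(mean_cos_d[2], mean_cos_d[1])
})

test_that("simulate_cohort delivers the configured shapes, reproducibly", {
  cfg <- quick_sim(8, seed = 77)
  coh <- simulate_cohort(cfg)
  expect_length(coh$subject_ids, 8)
  expect_true(all(vapply(coh$timeseries$movie,
                         function(ts) all(dim(ts$values) == c(151, 6)), TRUE)))
  expect_true(all(vapply(coh$timeseries$rest,
                         function(ts) nrow(ts$values) == 180, TRUE)))
  expect_true(all(coh$trait >= 10 & coh$trait <= 28))
  expect_length(coh$embedding[[1]], 48)
  coh2 <- simulate_cohort(quick_sim(8, seed = 77))
  expect_identical(coh$trait, coh2$trait)
  expect_identical(coh$timeseries$movie$S001$values,
                   coh2$timeseries$movie$S001$values)
  expect_identical(coh$gaze$S005$x, coh2$gaze$S005$x)
})

test_that("enlarging the cohort leaves the first subjects unchanged", {
  small <- simulate_cohort(quick_sim(6, seed = 31))
  large <- simulate_cohort(quick_sim(10, seed = 31))
  expect_identical(small$trait, large$trait[1:6])
  expect_identical(small$timeseries$movie$S003$values,
                   large$timeseries$movie$S003$values)
  expect_identical(small$embedding$S006, large$embedding$S006)
})

test_that("covariates track their target trait correlations", {
  cfg <- sim_config(400, covariate_spec = c(fantasy = 0.6, noise = 0),
                    gaze = list(n_frames = 60), embed_dim = 8,
                    n_timepoints = 10, rest_timepoints = 10, seed = 5)
  coh <- simulate_cohort(cfg)
  expect_gt(cor(coh$covariates$fantasy, coh$trait), 0.4)
  expect_lt(abs(cor(coh$covariates$noise, coh$trait)), 0.15)
})

test_that("cohorts survive a disk round trip", {
  coh <- simulate_cohort(quick_sim(5, seed = 9))
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(back$subject_ids, coh$subject_ids)
  expect_equal(unname(back$trait), unname(coh$trait))
  expect_equal(back$timeseries$movie$S002$values,
               coh$timeseries$movie$S002$values, tolerance = 1e-12)
  expect_equal(back$gaze$S001$x, coh$gaze$S001$x, tolerance = 1e-12)
  expect_equal(back$embedding$S004, coh$embedding$S004, tolerance = 1e-12)
  expect_equal(back$covariates$fantasy, coh$covariates$fantasy,
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
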