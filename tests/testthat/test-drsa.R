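# dRSA core: exclusion window, PCR estimator and its oracles, dRSA matrices,
# lag profiles, and the subsampling loop.

test_that("autocorrelation exclusion window: white series and boxcar oracle", {
  set.seed(21)
  # 15 stimuli -> 105 pairs, so chance-level r^2 between slices (~1/104)
  # sits far below the 10% threshold
  white <- center_columns(as_rdm_series(matrix(runif(105 * 80, 0, 2), 105, 80),
                                        15, 50, "m", "w"))
  expect_equal(autocorr_exclusion_window(white, 0.10), 1L)

  smoothed <- smooth_rdm_series(white, kernel_ms = 100)  # 5-sample boxcar
  got <- autocorr_exclusion_window(smoothed, 0.10)
  # independent brute-force lag scan
  v <- smoothed$values
  oracle <- NA
  for (delta in 1:79) {
    r2 <- mean(vapply(1:(80 - delta), function(t)
      stats::cor(v[, t], v[, t + delta])^2, numeric(1)))
    if (r2 < 0.10) { oracle <- delta; break }
  }
  expect_equal(got, oracle)

  # never dropping below threshold -> window = length, with warning
  const_drift <- as_rdm_series(outer(rnorm(10), seq(0, 1, length.out = 30)),
                               5, 50, "m", "d")
  expect_warning(w <- autocorr_exclusion_window(const_drift, 0.10), "never")
  expect_equal(w, 30L)
})

test_that("PCR: self-regression gives beta 1; no-drop equals OLS", {
  cfg <- drsa_config(var_threshold = 0, max_components = 75, seed = 1)
  set.seed(2)
  x <- rnorm(20); x <- x - mean(x)
  expect_equal(pcr_similarity(x, x, list(), cfg), 1)

  # back-projected PCR with nothing dropped == multiple regression
  n <- 30
  block <- matrix(rnorm(n * 9), n, 9)
  block <- sweep(block, 2, colMeans(block))
  test <- rnorm(n); test <- test - mean(test)
  y <- rnorm(n); y <- y - mean(y)
  b_pcr <- pcr_similarity(y, test, list(block), cfg)
  b_ols <- unname(stats::coef(stats::lm(y ~ block + test))["test"])
  expect_equal(b_pcr, b_ols, tolerance = 1e-8)

  # zero-variance test slice -> NaN
  expect_true(is.nan(pcr_similarity(y, rep(0, n), list(block), cfg)))
})

test_that("PCR suppresses a test predictor when nuisance spans the response", {
  set.seed(3)
  n <- 91
  y <- rnorm(n); y <- y - mean(y)
  z <- rnorm(n); z <- z - mean(z)
  x <- 0.6 * y / stats::sd(y) + 0.8 * z / stats::sd(z)
  x <- x - mean(x)
  B <- cbind(y, matrix(rnorm(n * 60), n, 60))
  B <- sweep(B, 2, colMeans(B))
  cfg <- drsa_config(seed = 1)
  beta_with <- pcr_similarity(y, x, list(B), cfg)
  beta_without <- pcr_similarity(y, x, list(), cfg)
  expect_lt(abs(beta_with), 0.05 * abs(beta_without))
})

test_that("estimator sanity: PCR tracks correlation on random instances", {
  set.seed(8)
  cfg <- drsa_config(seed = 1)
  n <- 91
  betas <- cors <- numeric(300)
  for (i in 1:300) {
    x <- rnorm(n); x <- x - mean(x)
    y <- stats::runif(1, -1, 1) * x + rnorm(n, sd = 0.8)
    y <- y - mean(y)
    betas[i] <- pcr_similarity(y, x, list(), cfg)
    cors[i] <- stats::cor(x, y)
  }
  expect_gt(stats::cor(betas, cors, method = "spearman"), 0.99)
})

test_that("correlation estimator: diagonal identity, Pearson oracle, lag band", {
  w <- micro_world()
  r <- w$rdms$posture_vd
  cfg <- drsa_config(lag_range_s = 0.5, segment_s = 2, seed = 1)
  m <- drsa_matrix(r, r, cfg = cfg, estimator = "correlation")
  n_time <- ncol(r$values)
  expect_equal(diag(m$betas), rep(1, n_time))
  # direct two-line Pearson oracle at random in-band cells
  set.seed(5)
  L <- round(0.5 * w$fs)
  for (k in 1:100) {
    tx <- sample(n_time, 1)
    ty <- sample(max(1, tx - L):min(n_time, tx + L), 1)
    expect_equal(m$betas[tx, ty], stats::cor(r$values[, tx], r$values[, ty]),
                 tolerance = 1e-12)
  }
  # cells outside the lag band are not computed
  expect_true(is.na(m$betas[1, 1 + L + 1]))
  expect_true(all(!is.na(m$betas[abs(row(m$betas) - col(m$betas)) <= L])))
})

test_that("drsa_matrix pcr equals per-cell pcr_similarity", {
  w <- micro_world()
  cfg <- drsa_config(lag_range_s = 0.4, segment_s = 2, seed = 1)
  neural <- w$rdms$posture_vd
  test <- w$rdms$motion_vd
  nuis <- list(w$rdms$posture_vd)
  m <- drsa_matrix(neural, test, nuis, cfg, estimator = "pcr")
  excl <- autocorr_exclusion_window(test, cfg$autocorr_r2_threshold)
  n_time <- ncol(test$values)
  set.seed(6)
  for (k in 1:8) {
    tx <- sample(n_time, 1)
    ty <- sample(max(1, tx - 16):min(n_time, tx + 16), 1)
    own <- test$values[, abs(seq_len(n_time) - tx) >= excl, drop = FALSE]
    expect_equal(m$betas[tx, ty],
                 pcr_similarity(neural$values[, ty], test$values[, tx],
                                list(nuis[[1]]$values, own), cfg),
                 tolerance = 1e-10)
  }
})

test_that("drsa_matrix validates its inputs", {
  w <- micro_world()
  r <- w$rdms$posture_vd
  cfg <- drsa_config(lag_range_s = 0.4, segment_s = 2, seed = 1)
  r_short <- r; r_short$values <- r$values[, 1:10]
  expect_error(drsa_matrix(r, r_short, cfg = cfg), "time points")
  r_fs <- r; r_fs$fs <- 100
  expect_error(drsa_matrix(r, r_fs, cfg = cfg), "sampling rate")
  r_raw <- r; r_raw$values <- r$values + 1  # not centered
  expect_error(drsa_matrix(r_raw, r_raw, cfg = cfg), "centered")
})

test_that("lag profile: constants, superdiagonal oracle, grid arithmetic", {
  n_time <- 60
  mk <- function(betas, fs, lag_range_s)
    structure(list(betas = betas, fs = fs, estimator = "correlation",
                   test_model = "x", lag_range_s = lag_range_s,
                   exclusion_window = NA), class = "drsa_matrix")
  const <- mk(matrix(0.7, n_time, n_time), 20, 1)
  p <- lag_profile(const)
  expect_equal(p$values, rep(0.7, 41))
  expect_true(all(p$n_averaged > 0))
  expect_equal(p$lags_s, (-20:20) / 20)

  # nonzero only on the k-th superdiagonal -> peak exactly at k / fs
  k <- 5
  b <- matrix(0, n_time, n_time)
  b[cbind(1:(n_time - k), (1 + k):n_time)] <- 2
  p2 <- lag_profile(mk(b, 20, 1))
  expect_equal(peak_lag(p2)$lag_s, k / 20)
  # equals a brute-force diagonal mean at every lag
  for (l in -20:20) {
    tx <- seq_len(n_time); ty <- tx + l
    ok <- ty >= 1 & ty <= n_time
    expect_equal(p2$values[l + 21], mean(b[cbind(tx[ok], ty[ok])]))
  }

  # 100 Hz, +/- 1 s -> 201 lag samples
  p3 <- lag_profile(mk(matrix(0, 250, 250), 100, 1))
  expect_length(p3$lags_s, 201)
})

test_that("peak_lag breaks ties to the earliest lag", {
  p <- list(lags_s = c(-0.1, 0, 0.1), values = c(1, 2, 2))
  expect_equal(peak_lag(p)$lag_s, 0)
})

test_that("subsampling degenerates to single-pass dRSA at full duration", {
  w <- micro_world()
  cfg <- drsa_config(lag_range_s = 0.5, segment_s = 2, n_iterations = 5,
                     seed = 3)
  expect_message(
    sub <- drsa_subsample(w$models, w$models$posture_vd, cfg,
                          estimator = "correlation",
                          test_models = "motion_vd"),
    "single-pass")
  neural <- prepare_rdm_series(compute_rdm_series(w$models$posture_vd), 30)
  direct <- lag_profile(drsa_matrix(neural, w$rdms$motion_vd,
                                    cfg = cfg, estimator = "correlation"))
  expect_equal(sub$motion_vd$values, direct$values, tolerance = 1e-12)
  expect_equal(sub$motion_vd$n_iterations, 1L)
})

test_that("subsampling is seed-deterministic and averaging shrinks variance", {
  w <- micro_world()
  mk_cfg <- function(n_iter, seed)
    drsa_config(lag_range_s = 0.5, segment_s = 1.5, n_iterations = n_iter,
                seed = seed)
  spec <- implant_spec(list(implant("posture_vd", 1, 0)), noise_weight = 0.5,
                       seed = 17)
  a <- drsa_subsample(w$models, spec, mk_cfg(4, 5), estimator = "correlation",
                      test_models = "posture_vd")
  b <- drsa_subsample(w$models, spec, mk_cfg(4, 5), estimator = "correlation",
                      test_models = "posture_vd")
  expect_identical(a$posture_vd$values, b$posture_vd$values)

  # empirical variance scaling of the iteration mean: var at 40 iterations
  # is far below var at 4 (approximately 1/10)
  peak_at <- function(n_iter, seed)
    drsa_subsample(w$models, spec, mk_cfg(n_iter, seed),
                   estimator = "correlation",
                   test_models = "posture_vd")$posture_vd$values[21]
  seeds <- 101:106
  v4 <- stats::var(vapply(seeds, peak_at, numeric(1), n_iter = 4))
  v40 <- stats::var(vapply(seeds, peak_at, numeric(1), n_iter = 40))
  expect_lt(v40, 0.5 * v4)
})

test_that("time-reversing neural and model series mirrors the lag profile", {
  w <- micro_world()
  cfg <- drsa_config(lag_range_s = 0.4, segment_s = 2, seed = 1)
  rev_series <- function(r) {
    r$values <- r$values[, rev(seq_len(ncol(r$values)))]
    r
  }
  for (est in c("correlation", "pcr")) {
    p_fwd <- lag_profile(drsa_matrix(w$rdms$posture_vd, w$rdms$motion_vd,
                                     list(w$rdms$posture_vd), cfg, est))
    p_rev <- lag_profile(drsa_matrix(rev_series(w$rdms$posture_vd),
                                     rev_series(w$rdms$motion_vd),
                                     list(rev_series(w$rdms$posture_vd)),
                                     cfg, est))
    expect_equal(p_rev$values, rev(p_fwd$values), tolerance = 1e-8)
  }
})
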