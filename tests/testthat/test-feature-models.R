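# Stimulus-feature models: smoothing kernel, optical flow, posture, the
# vertical-axis Procrustes alignment, derivatives, and the gaze model.

test_that("gaussian blur: constant invariance and analytic impulse response", {
  img <- matrix(0.37, 20, 20)
  expect_equal(gaussian_blur(img, 3), img)
  # impulse response equals the truncated, normalized sampled Gaussian
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  out <- gaussian_blur(imp, 2)
  r <- ceiling(4 * 2)
  k1 <- exp(-(-r:r)^2 / (2 * 4)); k1 <- k1 / sum(k1)
  analytic <- matrix(0, 41, 41)
  analytic[21 + (-r:r), 21 + (-r:r)] <- outer(k1, k1)
  expect_lt(max(abs(out - analytic)) / max(analytic), 1e-6)
})

test_that("pixelwise model vectorizes smoothed frames", {
  w <- acceptance_world()
  m <- pixelwise_model(w$frames, sigma = 2)
  expect_equal(dim(m$features), c(5, 24 * 22, 150))
  expect_equal(m$metric, "one_minus_pearson")
  # spatially constant frame is unchanged by smoothing
  fr <- w$frames; fr$frames[1, , , 1] <- 0.5
  m2 <- pixelwise_model(fr, sigma = 2)
  expect_equal(m2$features[1, , 1], rep(0.5, 24 * 22))
})

test_that("optical flow: static movie, known translation, feature counts", {
  # static movie -> zero magnitude everywhere
  fr <- structure(list(frames = array(0.3, c(3, 12, 12, 4)), fs = 10),
                  class = "frame_stack")
  fl <- optical_flow_model(fr, sigma = 2)
  expect_true(all(fl$magnitude$features == 0))
  expect_equal(dim(fl$magnitude$features), c(3, 144, 4))
  expect_equal(dim(fl$direction$features), c(3, 2 * 144, 4))

  # smooth blob translating exactly 1 px/frame rightward: average estimated
  # flow over the blob support within 20% of (1, 0)
  H <- 40; W <- 40
  blob <- function(cx, cy) outer(seq_len(H), seq_len(W), function(y, x)
    exp(-((x - cx)^2 + (y - cy)^2) / (2 * 9)))
  f1 <- blob(18, 20); f2 <- blob(19, 20)
  est <- dynrsa:::lk_flow(f1, f2, window_sigma = 3)
  support <- (f1 + f2) / 2 > 0.05
  expect_lt(abs(mean(est$u[support]) - 1), 0.2)
  expect_lt(abs(mean(est$v[support]) - 0), 0.2)
})

test_that("posture model: 39 features, zero self-dissimilarity, direct formula", {
  kin <- generate_kinematics(4, 13, 1, 50, cutoff_hz = 5, seed = 5)
  m <- posture_view_dependent(kin)
  expect_equal(dim(m$features)[2], 39)

  # identical trajectories -> dissimilarity 0 at every time point
  kin2 <- kin
  kin2$positions[2, , , ] <- kin2$positions[1, , , ]
  r <- compute_rdm_series(posture_view_dependent(kin2))
  expect_equal(r$values[1, ], rep(0, 50))  # pair (1,2) is row 1

  # 1 - Pearson from a hand-rolled covariance formula at one (i, j, t)
  x <- m$features[1, , 7]; y <- m$features[3, , 7]
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
  r_hand <- cov_xy / (sqrt(sum((x - mean(x))^2) / (length(x) - 1)) *
                        sqrt(sum((y - mean(y))^2) / (length(x) - 1)))
  rs <- compute_rdm_series(m)
  expect_equal(rs$values[2, 7], 1 - r_hand, tolerance = 1e-12)  # pair (1,3)
})

test_that("vertical-axis Procrustes alignment removes rigid transforms", {
  set.seed(4)
  A <- matrix(rnorm(30), 10, 3)
  th <- 1.1
  R <- diag(3)
  R[1, 1] <- cos(th); R[1, 2] <- -sin(th)
  R[2, 1] <- sin(th); R[2, 2] <- cos(th)  # rotation about axis 3
  B <- A %*% t(R) + matrix(rep(c(3, -2, 5), each = 10), 10, 3)
  expect_lt(view_invariant_posture_dissim(A, B), 1e-10)
  # symmetric by construction
  C <- A + matrix(rnorm(30, sd = 0.5), 10, 3)
  expect_identical(view_invariant_posture_dissim(A, C),
                   view_invariant_posture_dissim(C, A))
  # view-dependent dissimilarity of the rigid pair stays > 0
  vd <- 1 - stats::cor(as.vector(t(A)), as.vector(t(B)))
  expect_gt(vd, 0.05)
  expect_error(view_invariant_posture_dissim(A[1, , drop = FALSE],
                                             B[1, , drop = FALSE]),
               "2 markers")
})

test_that("optimal rotation angle matches a brute-force grid search", {
  set.seed(9)
  A <- matrix(rnorm(24), 8, 3)
  B <- A
  th <- 0.8
  B[, 1:2] <- B[, 1:2] %*% t(matrix(c(cos(th), sin(th), -sin(th), cos(th)),
                                    2, 2))
  B <- B + matrix(rnorm(24, sd = 0.3), 8, 3)
  al <- dynrsa:::align_vertical(A, B, vertical_axis = 3)
  grid <- seq(-pi, pi, by = 0.01 * pi / 180)
  a0 <- sweep(A, 2, colMeans(A)); b0 <- sweep(B, 2, colMeans(B))
  ssq <- vapply(grid, function(t2) {
    Rr <- matrix(c(cos(t2), sin(t2), -sin(t2), cos(t2)), 2, 2)
    br <- b0; br[, 1:2] <- br[, 1:2] %*% t(Rr)
    sum((a0 - br)^2)
  }, numeric(1))
  expect_lt(abs(al$theta - grid[which.min(ssq)]) * 180 / pi, 0.02)
})

test_that("temporal derivative: constant, linear, quadratic oracles", {
  f <- array(0, c(3, 2, 10))
  tt <- 1:10
  f[1, 1, ] <- 5                 # constant -> zero motion
  f[2, 1, ] <- 3 * tt            # linear slope 3 -> constant motion 3
  f[3, 1, ] <- tt^2              # quadratic -> constant acceleration 2
  f[, 2, ] <- 1                  # second feature constant
  m <- new_mts <- dynrsa:::new_model_timeseries("x", f, 10, "one_minus_pearson")
  d1 <- motion_from_features(m)
  expect_equal(d1$features[1, 1, ], rep(0, 10))
  expect_equal(d1$features[2, 1, ], rep(3, 10))
  d2 <- motion_from_features(d1)
  # interior samples carry the analytic second difference
  expect_equal(d2$features[3, 1, 3:8], rep(2, 6))
  expect_error(motion_from_features(
    dynrsa:::new_model_timeseries("y", f[, , 1, drop = FALSE], 10, "e")),
    "2 time points")
})

test_that("motion of a time-reversed trajectory is the negated reversal", {
  w <- micro_world()
  m <- w$models$posture_vd
  rev_m <- m
  rev_m$features <- m$features[, , rev(seq_len(dim(m$features)[3]))]
  d_fwd <- motion_from_features(m)$features
  d_rev <- motion_from_features(rev_m)$features
  # interior of the grid (the half-sample edge convention differs at ends)
  Tn <- dim(d_fwd)[3]
  expect_equal(d_rev[, , 2:(Tn - 1)], -d_fwd[, , rev(2:(Tn - 1))],
               tolerance = 1e-12)
})

test_that("gaze model uses Euclidean distance on the four channels", {
  gz <- generate_gaze(3, 1, 50, seed = 2, cutoff_hz = 5)
  gz$gaze[2, , ] <- gz$gaze[1, , ]             # identical pair
  gz$gaze[3, , 1] <- gz$gaze[1, , 1] + c(3, 4, 0, 0)  # 3-4-5 triangle
  m <- gaze_model(gz)
  expect_equal(m$metric, "euclidean")
  r <- compute_rdm_series(m)
  expect_equal(r$values[1, ], rep(0, 50))      # pair (1,2)
  expect_equal(r$values[2, 1], 5)              # pair (1,3) at t = 1
  # random pair against an explicit sqrt-of-sum-of-squares
  expect_equal(r$values[3, 10],
               sqrt(sum((gz$gaze[2, , 10] - gz$gaze[3, , 10])^2)))
})

test_that("view-invariant motion model is zero for rigidly transformed twins", {
  kin <- generate_kinematics(3, 6, 1, 40, cutoff_hz = 5, seed = 6)
  th <- 0.7
  R2 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  for (t in seq_len(dim(kin$positions)[4])) {
    P <- kin$positions[1, , , t]
    P[, 1:2] <- P[, 1:2] %*% t(R2)
    kin$positions[2, , , t] <- P + rep(c(1, -2, 0.5), each = 6)
  }
  mi <- motion_view_invariant(kin)
  r <- compute_rdm_series(mi)
  expect_lt(max(abs(r$values[1, ])), 1e-8)   # pair (1,2)
  expect_gt(mean(abs(r$values[2, ])), 1e-4)  # pair (1,3) genuinely differs
})
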