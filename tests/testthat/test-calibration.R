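test_that("concentration levels are equally spaced and validated", {
  expect_equal(make_levels(2, 0, 1), c(0, 1))
  l30 <- make_levels(30, 0, 1)
  expect_length(l30, 30)
  expect_equal(unique(round(diff(l30), 12)), round(1 / 29, 12))
  expect_equal(make_levels(5, 0, 2), c(0, 0.5, 1, 1.5, 2))
  expect_error(make_levels(1), ">= 2")
})

test_that("pigment colors follow the forward model and are monotone", {
  expect_equal(pigment_color(0, c(1, 1, 1), c(0, 0, 0)), rep(1, 3),
               ignore_attr = TRUE)
  expect_equal(pigment_color(1, c(log(10), 0, 0), c(0, 0, 0)), c(0.1, 1, 1),
               ignore_attr = TRUE)
  cs <- seq(0, 2, by = 0.25)
  cols <- pigment_color(cs, c(0.4, 0.7, 1.1), c(0.03, 0.05, 0.06))
  expect_true(all(diff(cols[, 1]) <= 0 & diff(cols[, 2]) <= 0 &
                    diff(cols[, 3]) <= 0))
})

test_that("naive under-color removal matches its closed form", {
  expect_equal(rgb_to_cmyk(c(1, 1, 1)), c(0, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(rgb_to_cmyk(c(0, 0, 0)), c(0, 0, 0, 1), ignore_attr = TRUE)
  expect_equal(rgb_to_cmyk(c(1, 0, 0)), c(0, 1, 1, 0), ignore_attr = TRUE)
  expect_error(rgb_to_cmyk(c(1.5, 0, 0)), "\\[0, 1\\]")
})

test_that("the patch grid is a complete unique cross product", {
  ps <- build_patch_set(30, 30, default_basis())
  expect_equal(nrow(ps$patches), 900)
  keys <- paste(ps$patches$mel_level, ps$patches$hem_level)
  expect_equal(length(unique(keys)), 900)
  expect_equal(sort(unique(ps$patches$mel_level)), 0:29)

  one <- build_patch_set(2, 2, default_basis())
  expect_equal(nrow(one$patches), 4)
})

test_that("LUT returns exact hits and matches an exhaustive scan", {
  ps <- build_patch_set(10, 10, default_basis())
  lut <- fit_lut(ps)
  F <- as.matrix(ps$patches[, c("mel_R", "mel_G", "mel_B",
                                "hem_R", "hem_G", "hem_B")])
  Tg <- as.matrix(ps$patches[, c("mel_C", "mel_M", "mel_Y", "mel_K",
                                 "hem_C", "hem_M", "hem_Y", "hem_K")])
  # exact hit: stored CMYK, zero error
  hit <- predict(lut, F[37, , drop = FALSE])
  expect_equal(as.vector(hit), as.vector(Tg[37, ]))

  # random off-grid queries against a brute-force scan
  set.seed(5)
  Q <- matrix(runif(50 * 6, 0.02, 1), 50, 6)
  pred <- predict(lut, Q)
  for (i in 1:50) {
    d2 <- rowSums(sweep(F, 2, Q[i, ])^2)
    expect_equal(as.vector(pred[i, ]), as.vector(Tg[which.min(d2), ]))
  }
})

test_that("LUT ties break to the lowest patch index", {
  rgb <- matrix(rep(c(0.5, 0.5, 0.5), 3), 3, byrow = TRUE)
  mel_cmyk <- rbind(c(0.1, 0.2, 0.3, 0.4), c(0.9, 0.8, 0.7, 0.6),
                    c(0.5, 0.5, 0.5, 0.5))
  ps <- manual_patch_set(rgb, rgb, mel_cmyk, mel_cmyk)
  lut <- fit_lut(ps)
  pred <- predict(lut, matrix(0.5, 1, 6))
  expect_equal(as.vector(pred)[1:4], mel_cmyk[1, ])
})

test_that("regression recovers planted coefficients on full-rank features", {
  set.seed(8)
  n <- 200
  # range chosen so planted targets stay inside [0, 1] (predictions clamp)
  mel_rgb <- matrix(runif(n * 3, 0.2, 1), n, 3)
  hem_rgb <- matrix(runif(n * 3, 0.2, 1), n, 3)
  coefs <- test_linear_coefs()
  mk_targets <- function(rgb) cbind(log(rgb), 1) %*% t(coefs)
  ps <- manual_patch_set(mel_rgb, hem_rgb, mk_targets(mel_rgb), mk_targets(hem_rgb))
  fit <- fit_regression(ps)
  for (layer in c("mel", "hem")) {
    expect_equal(unname(fit$coefficients[layer, , ]), unname(coefs),
                 tolerance = 1e-8)
  }
  pred <- predict(fit, cbind(mel_rgb, hem_rgb))
  truth <- cbind(mk_targets(mel_rgb), mk_targets(hem_rgb))
  expect_lt(sqrt(mean((pred - truth)^2)), 1e-8)
})

test_that("regression handles constant targets and target noise", {
  set.seed(9)
  n <- 900
  mel_rgb <- matrix(runif(n * 3, 0.2, 1), n, 3)
  hem_rgb <- matrix(runif(n * 3, 0.2, 1), n, 3)
  const <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), each = n), n, 4)
  ps <- manual_patch_set(mel_rgb, hem_rgb, const, const)
  fit <- fit_regression(ps)
  expect_equal(unname(fit$coefficients["mel", , 1:3]), matrix(0, 4, 3),
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["mel", , 4]), c(0.2, 0.4, 0.6, 0.8),
               tolerance = 1e-10)

  sigma <- 0.02
  coefs <- test_linear_coefs()
  noisy <- function(rgb) cbind(log(rgb), 1) %*% t(coefs) +
    matrix(rnorm(n * 4, sd = sigma), n, 4)
  ps2 <- manual_patch_set(mel_rgb, hem_rgb, noisy(mel_rgb), noisy(hem_rgb))
  fit2 <- fit_regression(ps2)
  pred <- predict(fit2, cbind(mel_rgb, hem_rgb))
  targ <- as.matrix(ps2$patches[, c("mel_C", "mel_M", "mel_Y", "mel_K",
                                    "hem_C", "hem_M", "hem_Y", "hem_K")])
  rmse <- sqrt(mean((pred - targ)^2))
  expect_lt(abs(rmse - sigma) / sigma, 0.2)
})

test_that("regression fits synthetic single-pigment patch sets exactly", {
  # single-pigment log-RGB features are collinear by construction; aliased
  # coefficients are dropped but fitted values must still be exact for
  # targets in the model class
  ps <- build_patch_set(12, 12, default_basis(),
                        transform = test_linear_transform())
  fit <- fit_regression(ps)
  expect_true(all(fit$rank >= 2))
  pred <- predict(fit, as.matrix(ps$patches[, c("mel_R", "mel_G", "mel_B",
                                                "hem_R", "hem_G", "hem_B")]))
  targ <- as.matrix(ps$patches[, c("mel_C", "mel_M", "mel_Y", "mel_K",
                                   "hem_C", "hem_M", "hem_Y", "hem_K")])
  expect_lt(sqrt(mean((pred - targ)^2)), 1e-10)
})

test_that("the neural estimator has the stated size and trains deterministically", {
  ps <- build_patch_set(6, 6, default_basis(),
                        transform = test_linear_transform())
  m1 <- fit_mlp(ps, epochs = 3, seed = 4)
  expect_equal(m1$n_params, 1414)
  m2 <- fit_mlp(ps, epochs = 3, seed = 4)
  q <- as.matrix(ps$patches[, c("mel_R", "mel_G", "mel_B",
                                "hem_R", "hem_G", "hem_B")])
  expect_identical(predict(m1, q), predict(m2, q))
  expect_length(m1$mel$loss_history, 3)
  expect_true(all(is.finite(m1$mel$loss_history)))
  expect_true(all(predict(m1, q) >= 0 & predict(m1, q) <= 1))
})

test_that("leave-one-out cross-validation honours each estimator's contract", {
  # regression on targets from its own model class: exact
  ps <- build_patch_set(10, 10, default_basis(),
                        transform = test_linear_transform())
  cv <- loocv(ps, "regression")
  expect_lt(cv$rmse, 1e-6)
  expect_length(cv$per_patch_errors, 100)

  # lut with two patches: each fold is forced onto the other patch
  rgb <- rbind(c(0.2, 0.3, 0.4), c(0.8, 0.7, 0.6))
  cmyk <- rbind(c(0.1, 0.1, 0.1, 0.1), c(0.6, 0.6, 0.6, 0.6))
  ps2 <- manual_patch_set(rgb, rgb, cmyk, cmyk)
  cv2 <- loocv(ps2, "lut")
  expected <- sqrt(mean((cmyk[1, ] - cmyk[2, ])^2))
  expect_equal(cv2$per_patch_errors, rep(expected, 2), tolerance = 1e-12)

  # mlp smoke at a reduced grid: completes with finite error
  ps3 <- build_patch_set(5, 5, default_basis(),
                         transform = test_linear_transform())
  cv3 <- loocv(ps3, "mlp", seed = 1, epochs = 5)
  expect_true(is.finite(cv3$rmse))
  expect_length(cv3$per_patch_errors, 25)

  expect_error(loocv(manual_patch_set(rgb[1, , drop = FALSE],
                                      rgb[1, , drop = FALSE],
                                      cmyk[1, , drop = FALSE],
                                      cmyk[1, , drop = FALSE]), "lut"),
               ">= 2")
})

test_that("method comparison is a two-sided paired t-test with guards", {
  set.seed(3)
  a <- runif(100, 0.02, 0.05)

  same <- compare_methods(a, a)
  expect_true(same$degenerate)
  expect_false(same$significant)
  expect_equal(same$p_value, 1)

  shifted <- compare_methods(a, a + 0.02)
  expect_true(shifted$significant)
  expect_lt(shifted$p_value, 1e-10)

  # hand-computable 5-element oracle
  x <- c(0.031, 0.035, 0.029, 0.040, 0.033)
  y <- c(0.034, 0.036, 0.031, 0.038, 0.036)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  p_manual <- 2 * pt(-abs(t_manual), df = 4)
  res <- compare_methods(x, y)
  expect_equal(res$p_value, p_manual, tolerance = 1e-12)
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)

  # symmetry
  expect_equal(compare_methods(x, y)$p_value, compare_methods(y, x)$p_value)

  expect_error(compare_methods(a, a[1:50]), "lengths")
})
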