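test_that("render_skin implements the log-linear forward model", {
  z <- matrix(0, 4, 4)
  zero_basis <- pigment_basis(c(1, 1, 1), c(0, 1, 0), bias = c(0, 0, 0))
  img <- render_skin(concentration_map(z, z), zero_basis)
  expect_equal(as.vector(img$rgb), rep(1, 48))

  half <- pigment_basis(rep(log(2), 3), c(0, 1, 0), bias = c(0, 0, 0))
  img2 <- render_skin(concentration_map(matrix(1, 4, 4), z), half)
  expect_equal(as.vector(img2$rgb), rep(0.5, 48))
  expect_identical(img2$provenance, "rendered")

  expect_error(concentration_map(matrix(0, 4, 4), matrix(0, 4, 5)),
               "dimensions differ")
})

test_that("rendered maps invert analytically through projection", {
  b <- default_basis()
  for (seed in 1:3) {
    cm <- with_seed_test(seed, concentration_map(
      matrix(runif(256, 0, 0.8), 16), matrix(runif(256, 0, 0.6), 16),
      matrix(runif(256, -0.2, 0), 16)))
    img <- render_skin(cm, b)
    expect_false(any(img$clamped))
    res <- separate(img, basis = b)
    expect_lt(max(abs(res$map$melanin - cm$melanin)), 1e-9)
    expect_lt(max(abs(res$map$hemoglobin - cm$hemoglobin)), 1e-9)
    expect_lt(max(abs(res$map$shading - cm$shading)), 1e-9)
  }
})

test_that("render_skin is monotone in melanin", {
  b <- default_basis()
  base <- concentration_map(matrix(0.3, 8, 8), matrix(0.2, 8, 8))
  up <- concentration_map(matrix(0.5, 8, 8), matrix(0.2, 8, 8))
  expect_true(all(render_skin(up, b)$rgb <= render_skin(base, b)$rgb))
})

test_that("sensor noise respects sigma, seed and the zero case", {
  img <- skin_image(array(0.5, c(64, 64, 3)))
  expect_identical(add_sensor_noise(img, 0), img)
  n1 <- add_sensor_noise(img, 0.01, seed = 7)
  n2 <- add_sensor_noise(img, 0.01, seed = 7)
  expect_identical(n1$rgb, n2$rgb)
  expect_false(identical(n1$rgb, add_sensor_noise(img, 0.01, seed = 8)$rgb))
  s <- stats::sd(n1$rgb - img$rgb)
  expect_lt(abs(s - 0.01) / 0.01, 0.15)
  expect_error(add_sensor_noise(img, -1), "nonnegative")
})

test_that("virtual press is white at zero ink, monotone and injective", {
  expect_equal(virtual_print_capture(rep(0, 4), rep(0, 4)), rep(1, 3),
               ignore_attr = TRUE)

  # increasing any single ink never increases any RGB channel
  grid <- seq(0, 1, length.out = 5)
  base <- c(0.2, 0.3, 0.1, 0.05)
  for (ink in 1:4) {
    prev <- NULL
    for (g in grid) {
      v <- base; v[ink] <- g
      rgb <- virtual_print_capture(v, base)
      if (!is.null(prev)) expect_true(all(rgb <= prev + 1e-12))
      prev <- rgb
    }
  }

  # all 900 patch CMYK pairs from a 30x30 grid map to distinct RGB
  ps <- build_patch_set(30, 30, default_basis())
  rgbs <- t(mapply(function(i) {
    virtual_print_capture(as.numeric(ps$patches[i, c("mel_C", "mel_M", "mel_Y", "mel_K")]),
                          as.numeric(ps$patches[i, c("hem_C", "hem_M", "hem_Y", "hem_K")]))
  }, seq_len(nrow(ps$patches))))
  expect_equal(nrow(unique(round(rgbs, 12))), 900)

  expect_error(virtual_print_capture(c(2, 0, 0, 0), rep(0, 4)), "\\[0, 1\\]")
})

test_that("phantoms are reproducible and structured as documented", {
  g <- make_phantom("gradient", 8, 8, seed = 1)
  # melanin varies only with column, hemoglobin only with row
  expect_true(all(apply(g$melanin, 2, function(col) diff(range(col)) == 0)))
  expect_true(all(apply(g$hemoglobin, 1, function(row) diff(range(row)) == 0)))

  p1 <- make_phantom("palm_like", 32, 32, seed = 5)
  p2 <- make_phantom("palm_like", 32, 32, seed = 5)
  expect_identical(p1$melanin, p2$melanin)
  expect_identical(p1$hemoglobin, p2$hemoglobin)

  bl <- make_phantom("blobs", 64, 64, seed = 3)
  centers <- attr(bl, "centers")
  peak <- which(bl$hemoglobin == max(bl$hemoglobin), arr.ind = TRUE)
  d <- sqrt((centers[, "row"] - peak[1, 1])^2 + (centers[, "col"] - peak[1, 2])^2)
  expect_lt(min(d), 1.5)

  expect_error(make_phantom("swirl", 8, 8), "valid kinds")
})

test_that("palm phantom shading is flat where the color-plane roi sits", {
  p <- make_phantom("palm_like", 64, 64, seed = 2)
  central <- p$shading[25:40, 25:40]
  expect_equal(diff(range(central)), 0)
  expect_lt(min(p$shading), 0)  # corners darkened
})
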