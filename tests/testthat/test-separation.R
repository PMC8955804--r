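test_that("PCA recovers a known color distribution plane", {
  set.seed(1)
  u <- c(0.2, 0.9, 0.4); u <- u / sqrt(sum(u^2))
  v0 <- c(0.8, 0.1, 0.6); v0 <- v0 - sum(v0 * u) * u; v0 <- v0 / sqrt(sum(v0^2))
  origin <- c(0.4, 0.5, 0.6)
  a <- runif(400, -0.2, 0.2); b <- runif(400, -0.1, 0.1)
  dens <- t(origin + outer(u, a) + outer(v0, b))
  rgb <- array(exp(-dens), c(20, 20, 3))
  img <- skin_image(rgb)
  plane <- estimate_color_plane(img, roi = c(0, 0, 20, 20))
  true_normal <- c(u[2] * v0[3] - u[3] * v0[2],
                   u[3] * v0[1] - u[1] * v0[3],
                   u[1] * v0[2] - u[2] * v0[1])
  expect_lt(dir_angle_deg(plane$normal, true_normal) * pi / 180, 1e-6)
  expect_gt(plane$explained_variance[1], plane$explained_variance[2])
})

test_that("a constant-color region is rejected as rank-deficient", {
  img <- skin_image(array(0.5, c(16, 16, 3)))
  expect_error(estimate_color_plane(img), "rank-deficient")
})

test_that("the plane of a zero-shading render contains both pigment vectors", {
  b <- default_basis()
  cm <- with_seed_test(4, concentration_map(
    matrix(runif(1024, 0, 0.8), 32), matrix(runif(1024, 0, 0.6), 32)))
  img <- render_skin(cm, b)
  plane <- estimate_color_plane(img, roi = c(0, 0, 32, 32))
  for (vec in list(b$melanin_vector, b$hemoglobin_vector)) {
    proj <- sum(vec * plane$basis_u) * plane$basis_u +
      sum(vec * plane$basis_v) * plane$basis_v
    expect_lt(sqrt(sum((vec - proj)^2)) / sqrt(sum(vec^2)), 1e-6)
  }
})

test_that("shading removal is an exact oblique decomposition", {
  u <- c(1, 0, 0); v <- c(0, 1, 0)
  plane <- color_plane(u, v, origin = c(0.2, 0.3, 0.4))
  illum <- c(1, 1, 1) / sqrt(3)

  # pure-shading pixel: density = origin + 0.3 * illum
  d <- plane$origin + 0.3 * illum
  img <- skin_image(array(exp(-d), c(1, 1, 3)))
  res <- remove_shading(img, plane, illum)
  expect_equal(as.vector(res$coords[1, 1, ]), c(0, 0), tolerance = 1e-12)
  expect_equal(res$shading[1, 1], 0.3, tolerance = 1e-12)

  # adding any multiple of illum changes only the shading coordinate
  set.seed(2)
  dens <- matrix(runif(30, 0.1, 1), 10, 3)
  mk <- function(D) skin_image(array(exp(-D), c(nrow(D), 1, 3)))
  r0 <- remove_shading(mk(dens), plane, illum)
  r1 <- remove_shading(mk(dens + outer(runif(10, -0.1, 0.3), illum)), plane, illum)
  expect_equal(r0$coords, r1$coords, tolerance = 1e-10)

  # reconstruction is exact to machine precision
  M <- cbind(u, v, illum)
  uvs <- cbind(as.vector(r0$coords[, , 1]), as.vector(r0$coords[, , 2]),
               as.vector(r0$shading))
  recon <- sweep(uvs %*% t(M), 2, plane$origin, `+`)
  expect_lt(max(abs(recon - dens)), 1e-12)

  # illumination in the plane is ill-posed
  expect_error(remove_shading(mk(dens), plane, c(1, 1, 0)), "ill-posed")
})

test_that("2-D ICA recovers planted mixing directions within 2 degrees", {
  plane <- color_plane(c(1, 0, 0), c(0, 1, 0), origin = c(0.3, 0.3, 0.3))
  w_m <- c(0.9, 0.3); w_h <- c(0.25, 0.95)
  for (seed in 1:3) {
    set.seed(seed)
    c_m <- runif(5000, 0, 1); c_h <- runif(5000, 0, 1)
    coords <- array(NA_real_, c(50, 100, 2))
    coords[, , 1] <- 0.1 + c_m * w_m[1] + c_h * w_h[1]
    coords[, , 2] <- 0.1 + c_m * w_m[2] + c_h * w_h[2]
    basis <- estimate_pigment_vectors(coords, plane, seed = seed)
    to2 <- function(v) c(sum(v * plane$basis_u), sum(v * plane$basis_v))
    # labeling rule: w_h has the larger G/R ratio once lifted
    expect_lt(dir_angle_deg(to2(basis$hemoglobin_vector), w_h), 2)
    expect_lt(dir_angle_deg(to2(basis$melanin_vector), w_m), 2)
  }
})

test_that("ICA is equivariant under invertible linear maps of the data", {
  plane <- color_plane(c(1, 0, 0), c(0, 1, 0), origin = c(0.3, 0.3, 0.3))
  set.seed(9)
  S <- cbind(runif(6000), runif(6000)^2)
  A_true <- cbind(c(0.9, 0.35), c(0.2, 1.0))
  X <- S %*% t(A_true)
  M <- cbind(c(0.7, -0.3), c(0.4, 1.1))
  as_coords <- function(X) array(c(X[, 1], X[, 2]), c(60, 100, 2))
  b1 <- estimate_pigment_vectors(as_coords(X), plane)
  b2 <- estimate_pigment_vectors(as_coords(X %*% t(M)), plane)
  to2 <- function(v) c(sum(v * plane$basis_u), sum(v * plane$basis_v))
  d1 <- list(to2(b1$melanin_vector), to2(b1$hemoglobin_vector))
  d2 <- list(to2(b2$melanin_vector), to2(b2$hemoglobin_vector))
  # directions recovered from the mapped data must be the mapped directions
  # (up to order and sign)
  for (d in lapply(d1, function(v) M %*% v)) {
    best <- min(vapply(d2, function(e) dir_angle_deg(d, e), 0))
    expect_lt(best, 2)
  }
})

test_that("pigment vector estimation is deterministic and validates input", {
  plane <- color_plane(c(1, 0, 0), c(0, 1, 0), origin = c(0, 0, 0))
  set.seed(11)
  coords <- array(runif(2 * 400), c(20, 20, 2))
  # near-isotropic data: estimated axes may acquire negative components,
  # which the basis constructor flags
  b1 <- suppressWarnings(estimate_pigment_vectors(coords, plane, seed = 1))
  b2 <- suppressWarnings(estimate_pigment_vectors(coords, plane, seed = 1))
  expect_identical(b1$melanin_vector, b2$melanin_vector)
  expect_identical(b1$bias, b2$bias)
  expect_error(estimate_pigment_vectors(coords[1:4, 1:4, , drop = FALSE], plane),
               ">= 100 samples")
})

test_that("projection maps bias to zero and pigment axes to unit loads", {
  b <- default_basis()
  plane <- plane_from_basis(b)
  to_coords <- function(d) {
    rel <- d - plane$origin
    c(sum(rel * plane$basis_u), sum(rel * plane$basis_v))
  }
  mk <- function(p) array(p, c(1, 1, 2))
  at_bias <- to_coords(b$bias)
  m0 <- project_concentrations(mk(at_bias), matrix(0, 1, 1), b, plane)
  expect_equal(m0$melanin[1, 1], 0, tolerance = 1e-12)
  expect_equal(m0$hemoglobin[1, 1], 0, tolerance = 1e-12)

  pure <- to_coords(b$bias + 2 * b$melanin_vector)
  m2 <- project_concentrations(mk(pure), matrix(0, 1, 1), b, plane)
  expect_equal(m2$melanin[1, 1], 2, tolerance = 1e-10)
  expect_equal(m2$hemoglobin[1, 1], 0, tolerance = 1e-10)
})

test_that("separate recovers palm-like phantoms with and without noise", {
  b <- default_basis()
  cm <- make_phantom("palm_like", 96, 96, seed = 21)
  img <- render_skin(cm, b)
  res <- separate(img, seed = 21)
  expect_gt(abs_cor(res$map$melanin, cm$melanin), 0.99)
  expect_gt(abs_cor(res$map$hemoglobin, cm$hemoglobin), 0.99)

  noisy <- add_sensor_noise(img, 0.005, seed = 22)
  resn <- separate(noisy, seed = 22)
  expect_gt(abs_cor(resn$map$melanin, cm$melanin), 0.95)
  expect_gt(abs_cor(resn$map$hemoglobin, cm$hemoglobin), 0.95)
})

test_that("shading along the illumination direction never leaks into pigments", {
  b <- default_basis()
  cm <- make_phantom("palm_like", 48, 48, seed = 31)
  extra <- -outer(seq(0, 0.25, length.out = 48), seq(0, 0.15, length.out = 48), `+`)
  cm2 <- concentration_map(cm$melanin, cm$hemoglobin, cm$shading + extra)
  r1 <- separate(render_skin(cm, b), basis = b)
  r2 <- separate(render_skin(cm2, b), basis = b)
  expect_lt(max(abs(r1$map$melanin - r2$map$melanin)), 1e-6)
  expect_lt(max(abs(r1$map$hemoglobin - r2$map$hemoglobin)), 1e-6)
  expect_lt(max(abs((r2$map$shading - r1$map$shading) - extra)), 1e-6)
})
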