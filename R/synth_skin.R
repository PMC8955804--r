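# Forward optical model and fixture generation: renders RGB skin from known
# concentration maps under the modified Lambert-Beer law, and simulates the
# print-and-capture loop for calibration patches.

#' Construct a pigment basis
#'
#' Holds the geometry of pigment component separation: optical-density
#' direction vectors for melanin and hemoglobin (density per unit
#' concentration, per R/G/B channel), the illumination direction along which
#' shading acts, and a bias point (the stationary baseline density of skin).
#'
#' @param melanin_vector,hemoglobin_vector numeric length-3, nonnegative
#'   optical density per unit concentration for each channel. Must be
#'   linearly independent.
#' @param illumination_direction numeric length-3; normalized to unit norm.
#' @param bias numeric length-3 baseline optical density.
#' @param plane optional [color_plane] the vectors were estimated in
#'   (attached by [estimate_pigment_vectors()]).
#' @param check_absorbers if `TRUE` (default), negative vector components
#'   are an error; estimation routines relax this to a warning because
#'   finite-sample ICA can leave tiny negative components.
#' @return object of class `pigment_basis`.
#' @export
#' @examples
#' b <- pigment_basis(c(0.74, 0.90, 1.10), c(0.40, 1.10, 0.75))
#' b$illumination_direction
pigment_basis <- function(melanin_vector, hemoglobin_vector,
                          illumination_direction = c(1, 1, 1) / sqrt(3),
                          bias = c(0, 0, 0),
                          plane = NULL,
                          check_absorbers = TRUE) {
  melanin_vector <- as.numeric(melanin_vector)
  hemoglobin_vector <- as.numeric(hemoglobin_vector)
  illumination_direction <- as.numeric(illumination_direction)
  bias <- as.numeric(bias)
  stopifnot(length(melanin_vector) == 3, length(hemoglobin_vector) == 3,
            length(illumination_direction) == 3, length(bias) == 3)
  if (!all(is.finite(c(melanin_vector, hemoglobin_vector,
                       illumination_direction, bias)))) {
    stop("pigment_basis: all components must be finite")
  }
  neg <- c(melanin_vector, hemoglobin_vector) < 0
  if (any(neg)) {
    msg <- "pigment vectors have negative components (pigments are absorbers)"
    if (check_absorbers) stop("pigment_basis: ", msg) else warning(msg)
  }
  nrm <- sqrt(sum(illumination_direction^2))
  if (nrm < 1e-12) stop("pigment_basis: illumination_direction has zero norm")
  illumination_direction <- illumination_direction / nrm
  ang <- vector_angle(melanin_vector, hemoglobin_vector)
  if (!is.finite(ang) || ang <= 1e-6) {
    stop("pigment_basis: melanin_vector and hemoglobin_vector are not ",
         "linearly independent (angle ", format(ang), " rad)")
  }
  structure(
    list(melanin_vector = melanin_vector,
         hemoglobin_vector = hemoglobin_vector,
         illumination_direction = illumination_direction,
         bias = bias,
         plane = plane),
    class = "pigment_basis")
}

#' Default pigment basis used for synthetic fixtures
#'
#' Plausible density shapes only (hemoglobin absorbs green most strongly;
#' melanin density rises monotonically toward blue), chosen chromatic
#' enough that neither pigment axis sits close to the gray illumination
#' direction - that keeps the 3-way unmixing (melanin, hemoglobin,
#' shading) well conditioned. Nothing downstream depends on these exact
#' numbers, only on recovery of whatever basis was actually used.
#'
#' @param bias numeric length-3 baseline density.
#' @return a [pigment_basis].
#' @export
default_basis <- function(bias = c(0.03, 0.05, 0.06)) {
  pigment_basis(melanin_vector = c(0.40, 0.70, 1.10),
                hemoglobin_vector = c(0.25, 1.15, 0.55),
                bias = bias)
}

vector_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-300 || nb < 1e-300) return(NA_real_)
  acos(min(1, max(-1, sum(a * b) / (na * nb))))
}

#' Construct a concentration map
#'
#' Per-pixel scalar fields of relative melanin and hemoglobin concentration
#' (unitless) and a signed log-intensity shading offset along the
#' illumination direction.
#'
#' @param melanin,hemoglobin,shading numeric matrices of identical
#'   dimensions (rows x cols, origin top-left). `shading` defaults to zero.
#' @return object of class `concentration_map` with fields `melanin`,
#'   `hemoglobin`, `shading`, `width`, `height`.
#' @export
concentration_map <- function(melanin, hemoglobin,
                              shading = matrix(0, nrow(melanin), ncol(melanin))) {
  melanin <- as.matrix(melanin)
  hemoglobin <- as.matrix(hemoglobin)
  shading <- as.matrix(shading)
  dims <- list(melanin = dim(melanin), hemoglobin = dim(hemoglobin),
               shading = dim(shading))
  if (!identical(dims$melanin, dims$hemoglobin) ||
      !identical(dims$melanin, dims$shading)) {
    stop("concentration_map: field dimensions differ: melanin ",
         paste(dims$melanin, collapse = "x"), ", hemoglobin ",
         paste(dims$hemoglobin, collapse = "x"), ", shading ",
         paste(dims$shading, collapse = "x"))
  }
  if (!all(is.finite(melanin)) || !all(is.finite(hemoglobin)) ||
      !all(is.finite(shading))) {
    stop("concentration_map: fields must be finite (no NaN/Inf)")
  }
  structure(
    list(melanin = melanin, hemoglobin = hemoglobin, shading = shading,
         width = ncol(melanin), height = nrow(melanin)),
    class = "concentration_map")
}

#' Construct a skin image
#'
#' @param rgb numeric array `height x width x 3` of linear reflectance
#'   values; clamped into `[2^-16, 1]`.
#' @param provenance one of `"captured"`, `"rendered"`, `"flat-fielded"`.
#' @param clamped optional logical matrix flagging pixels that were clamped
#'   during rendering (excluded from round-trip checks).
#' @return object of class `skin_image`.
#' @export
skin_image <- function(rgb, provenance = c("captured", "rendered", "flat-fielded"),
                       clamped = NULL) {
  provenance <- match.arg(provenance)
  rgb <- as_rgb_array(rgb)
  structure(list(rgb = clamp_reflectance(rgb), provenance = provenance,
                 clamped = clamped),
            class = "skin_image")
}

as_rgb_array <- function(rgb) {
  if (is.matrix(rgb)) stop("skin_image: rgb must be a height x width x 3 array")
  rgb <- unclass(rgb)
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("skin_image: rgb must be a height x width x 3 array")
  }
  storage.mode(rgb) <- "double"
  rgb
}

#' @export
print.skin_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<skin_image %dx%d, %s, range [%.4g, %.4g]>\n",
              d[1], d[2], x$provenance, min(x$rgb), max(x$rgb)))
  invisible(x)
}

#' @export
print.concentration_map <- function(x, ...) {
  cat(sprintf("<concentration_map %dx%d: melanin [%.3g, %.3g], hemoglobin [%.3g, %.3g], shading [%.3g, %.3g]>\n",
              x$height, x$width, min(x$melanin), max(x$melanin),
              min(x$hemoglobin), max(x$hemoglobin),
              min(x$shading), max(x$shading)))
  invisible(x)
}

#' Render an RGB skin image from a concentration map
#'
#' Forward model (modified Lambert-Beer law): per pixel and channel `c`,
#' `rgb_c = exp(-(melanin * mel_vec_c + hemoglobin * hem_vec_c + bias_c)
#' + shading * illum_c)` and clamped to the representable range. Shading enters
#' additively in log space along the illumination direction, i.e. it scales
#' intensity multiplicatively in the same way on all channels. Pixels whose
#' value was clamped are flagged so exact round-trip checks can skip them.
#'
#' @param conc a [concentration_map].
#' @param basis a [pigment_basis].
#' @return a [skin_image] with `provenance = "rendered"`.
#' @export
#' @examples
#' cm <- make_phantom("gradient", 16, 16, seed = 1)
#' img <- render_skin(cm, default_basis())
render_skin <- function(conc, basis) {
  stopifnot(inherits(conc, "concentration_map"), inherits(basis, "pigment_basis"))
  h <- conc$height; w <- conc$width
  rgb <- array(0, dim = c(h, w, 3))
  raw <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    density <- conc$melanin * basis$melanin_vector[ch] +
      conc$hemoglobin * basis$hemoglobin_vector[ch] + basis$bias[ch]
    raw[, , ch] <- exp(-density + conc$shading * basis$illumination_direction[ch])
  }
  rgb <- clamp_reflectance(raw)
  clamped <- (raw[, , 1] < SKINFAB_EPS | raw[, , 1] > 1 |
                raw[, , 2] < SKINFAB_EPS | raw[, , 2] > 1 |
                raw[, , 3] < SKINFAB_EPS | raw[, , 3] > 1)
  skin_image(rgb, provenance = "rendered", clamped = clamped)
}

#' Add sensor noise to a skin image
#'
#' i.i.d. Gaussian noise in reflectance units, then re-clamped into
#' `[2^-16, 1]`. Identical seeds give identical output.
#'
#' @param img a [skin_image].
#' @param sigma noise standard deviation in reflectance units (>= 0).
#' @param seed integer RNG seed.
#' @return a [skin_image] of the same provenance.
#' @export
add_sensor_noise <- function(img, sigma, seed = 1L) {
  stopifnot(inherits(img, "skin_image"))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    stop("add_sensor_noise: sigma must be a single nonnegative number")
  }
  if (sigma == 0) return(img)
  noisy <- with_seed(seed, img$rgb + rnorm(length(img$rgb), sd = sigma))
  skin_image(clamp_reflectance(array(noisy, dim = dim(img$rgb))),
             provenance = img$provenance, clamped = img$clamped)
}

# Evaluate expr with a temporary RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Virtual press model
#'
#' Deterministic smooth stand-in for physically printing a two-layer patch
#' and photographing it: light passes through the melanin layer, then the
#' hemoglobin layer, reflects off an opaque white layer, and passes back up.
#' Each layer's transmittance is `exp(-sum_i D_i * ink_density[i, ])` over
#' inks i in {C, M, Y, K}, so the observed reflectance is
#' `(T_mel * T_hem)^2 * white_reflectance`.
#'
#' @param ink_density 4 x 3 matrix of per-ink optical density vectors
#'   (rows C, M, Y, K; columns R, G, B).
#' @param white_reflectance reflectance of the bottom white layer.
#' @return object of class `virtual_press`.
#' @export
virtual_press <- function(ink_density = default_ink_density(),
                          white_reflectance = 1) {
  ink_density <- as.matrix(ink_density)
  stopifnot(identical(dim(ink_density), c(4L, 3L)), all(ink_density >= 0),
            white_reflectance > 0, white_reflectance <= 1)
  rownames(ink_density) <- c("C", "M", "Y", "K")
  colnames(ink_density) <- c("R", "G", "B")
  structure(list(ink_density = ink_density,
                 white_reflectance = white_reflectance),
            class = "virtual_press")
}

#' @rdname virtual_press
#' @export
default_ink_density <- function() {
  # C absorbs red, M green, Y blue, K all; unequal magnitudes keep the
  # patch-grid map injective
  rbind(C = c(1.50, 0.30, 0.10),
        M = c(0.20, 1.40, 0.30),
        Y = c(0.05, 0.20, 1.20),
        K = c(1.80, 1.70, 1.60))
}

#' Simulate printing and capturing a two-layer patch
#'
#' @param mel_cmyk,hem_cmyk numeric length-4 CMYK ink amounts in `[0, 1]`
#'   for the melanin and hemoglobin layers.
#' @param press a [virtual_press].
#' @return length-3 RGB reflectance vector in `(0, 1]`.
#' @export
#' @examples
#' virtual_print_capture(c(0, 0, 0, 0), c(0, 0, 0, 0))  # white
virtual_print_capture <- function(mel_cmyk, hem_cmyk, press = virtual_press()) {
  stopifnot(inherits(press, "virtual_press"))
  mel_cmyk <- as.numeric(mel_cmyk); hem_cmyk <- as.numeric(hem_cmyk)
  if (length(mel_cmyk) != 4 || length(hem_cmyk) != 4 ||
      any(mel_cmyk < 0 | mel_cmyk > 1) || any(hem_cmyk < 0 | hem_cmyk > 1)) {
    stop("virtual_print_capture: CMYK components must be length 4 in [0, 1]")
  }
  d <- drop((mel_cmyk + hem_cmyk) %*% press$ink_density)  # one-way density
  clamp_reflectance(exp(-2 * d) * press$white_reflectance)
}

#' Generate synthetic concentration phantoms
#'
#' Reproducible fixtures emulating the spatial structure of skin pigment
#' fields:
#' * `"gradient"`: melanin ramps left-to-right with column index,
#'   hemoglobin top-to-bottom with row index; no shading.
#' * `"blobs"`: Gaussian hemoglobin spots on a constant melanin background;
#'   spot centers are recorded in `attr(, "centers")`.
#' * `"palm_like"`: melanin as a low-frequency field plus skewed
#'   fine-grain mottle, hemoglobin as vessel-like ridges plus fine-grain
#'   perfusion texture (the two fields are decorrelated, matching the
#'   separation model's independence assumption), and smooth shading that
#'   is flat in the central region (where the color-plane roi sits) and
#'   falls off toward the edges.
#'
#' @param kind one of `"gradient"`, `"blobs"`, `"palm_like"`.
#' @param width,height positive pixel dimensions.
#' @param seed integer RNG seed; identical seeds give identical maps.
#' @return a [concentration_map].
#' @export
make_phantom <- function(kind, width, height, seed = 1L) {
  kinds <- c("gradient", "blobs", "palm_like")
  if (!is.character(kind) || length(kind) != 1 || !(kind %in% kinds)) {
    stop("make_phantom: unknown kind ", deparse(kind),
         "; valid kinds: ", paste(kinds, collapse = ", "))
  }
  stopifnot(width >= 1, height >= 1)
  with_seed(seed, switch(
    kind,
    gradient = phantom_gradient(width, height),
    blobs = phantom_blobs(width, height),
    palm_like = phantom_palm(width, height)))
}

phantom_gradient <- function(w, h) {
  col_ramp <- if (w > 1) (seq_len(w) - 1) / (w - 1) else 0
  row_ramp <- if (h > 1) (seq_len(h) - 1) / (h - 1) else 0
  mel <- matrix(rep(0.8 * col_ramp, each = h), nrow = h)
  hem <- matrix(rep(0.6 * row_ramp, times = w), nrow = h)
  concentration_map(mel, hem)
}

phantom_blobs <- function(w, h) {
  mel <- matrix(0.35, h, w)
  hem <- matrix(0.02, h, w)
  # jittered 2x2 grid keeps centers well separated so each is a local max
  base <- expand.grid(fx = c(0.3, 0.7), fy = c(0.3, 0.7))
  n_blobs <- nrow(base)
  cx <- base$fx * w + runif(n_blobs, -0.04, 0.04) * w
  cy <- base$fy * h + runif(n_blobs, -0.04, 0.04) * h
  amp <- runif(n_blobs, 0.4, 0.7)
  sig <- pmax(1.5, min(w, h) / 16)
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  for (k in seq_len(n_blobs)) {
    hem <- hem + amp[k] * exp(-((xs - cx[k])^2 + (ys - cy[k])^2) / (2 * sig^2))
  }
  cm <- concentration_map(mel, hem)
  attr(cm, "centers") <- cbind(row = cy, col = cx)
  cm
}

# coarse random grid bilinearly upsampled -> smooth low-frequency field
smooth_field <- function(w, h, grid = 6) {
  g <- matrix(runif(grid * grid), grid, grid)
  gx <- seq(0, 1, length.out = grid)
  fx <- if (w > 1) (seq_len(w) - 1) / (w - 1) else 0
  fy <- if (h > 1) (seq_len(h) - 1) / (h - 1) else 0
  interp1 <- function(v, x) {
    i <- pmin(findInterval(x, gx), grid - 1)
    t <- (x - gx[i]) / (gx[i + 1] - gx[i])
    v[i] * (1 - t) + v[i + 1] * t
  }
  # interpolate rows then columns
  rows <- vapply(seq_len(grid), function(j) interp1(g[, j], fy),
                 numeric(length(fy)))
  t(vapply(seq_len(h), function(r) interp1(rows[r, ], fx), numeric(length(fx))))
}

phantom_palm <- function(w, h, n_vessels = 8) {
  # melanin: low-frequency field plus skewed fine-grain mottle
  mel <- 0.10 + 0.30 * smooth_field(w, h, grid = 6) +
    0.60 * matrix(runif(w * h)^2, h, w)
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  # hemoglobin: fine-grain perfusion texture plus vessel-like ridges
  hem <- 0.03 + 0.55 * matrix(runif(w * h)^2, h, w)
  sig <- pmax(1.5, min(w, h) / 64)
  for (k in seq_len(n_vessels)) {
    theta <- runif(1, 0, pi)
    # line through a random point, direction theta
    px <- runif(1, 0, w); py <- runif(1, 0, h)
    d <- (xs - px) * sin(theta) - (ys - py) * cos(theta)
    hem <- hem + runif(1, 0.3, 0.5) * exp(-d^2 / (2 * sig^2))
  }
  # the separation model assumes independent pigment fields; remove the
  # residual sample correlation the finite field sizes leave behind
  beta <- stats::cov(as.vector(mel), as.vector(hem)) /
    stats::var(as.vector(hem))
  mel <- mel - beta * (hem - mean(hem))
  # shading: flat inside the central half, quadratic falloff to the corners
  rx <- (xs - (w + 1) / 2) / (w / 2)
  ry <- (ys - (h + 1) / 2) / (h / 2)
  r <- sqrt(rx^2 + ry^2)
  shading <- -0.35 * pmax(r - 0.5, 0)^2
  concentration_map(mel, hem, shading)
}
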