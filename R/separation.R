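# Pigment component separation: color-plane PCA in optical-density space,
# oblique shading removal along the illumination direction, 2-D fixed-point
# ICA for the pigment axes, and projection onto them.

#' Construct a color plane
#'
#' The 2-D plane in optical-density space on which shading-free skin colors
#' lie, spanned by orthonormal vectors `basis_u`, `basis_v` through `origin`.
#'
#' @param basis_u,basis_v orthonormal length-3 vectors spanning the plane.
#' @param origin length-3 mean density of the training region.
#' @param explained_variance optional length-3 PCA variance fractions.
#' @return object of class `color_plane` (fields above plus unit `normal`).
#' @export
color_plane <- function(basis_u, basis_v, origin, explained_variance = NULL) {
  basis_u <- as.numeric(basis_u); basis_v <- as.numeric(basis_v)
  origin <- as.numeric(origin)
  stopifnot(length(basis_u) == 3, length(basis_v) == 3, length(origin) == 3)
  if (abs(sum(basis_u^2) - 1) > 1e-8 || abs(sum(basis_v^2) - 1) > 1e-8 ||
      abs(sum(basis_u * basis_v)) > 1e-8) {
    stop("color_plane: basis_u and basis_v must be orthonormal")
  }
  normal <- cross3(basis_u, basis_v)
  normal <- normal / sqrt(sum(normal^2))
  structure(list(basis_u = basis_u, basis_v = basis_v, origin = origin,
                 normal = normal, explained_variance = explained_variance),
            class = "color_plane")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Optical density of a skin image
#'
#' @param img a [skin_image].
#' @return `height x width x 3` array of densities `-log(rgb)`.
#' @export
optical_density <- function(img) {
  stopifnot(inherits(img, "skin_image"))
  -log(clamp_reflectance(img$rgb))
}

# roi -> logical mask (h x w). roi may be NULL (central window covering 25%
# of the image area), c(x, y, w, h) in 0-based pixel coords, or a mask.
roi_mask <- function(img, roi = NULL) {
  d <- dim(img$rgb); h <- d[1]; w <- d[2]
  if (is.null(roi)) {
    rw <- max(4L, round(w / 2)); rh <- max(4L, round(h / 2))
    x0 <- floor((w - rw) / 2); y0 <- floor((h - rh) / 2)
    roi <- c(x0, y0, rw, rh)
  }
  if (is.logical(roi)) {
    stopifnot(identical(dim(roi), c(h, w)))
    return(roi)
  }
  stopifnot(is.numeric(roi), length(roi) == 4)
  x0 <- roi[1]; y0 <- roi[2]; rw <- roi[3]; rh <- roi[4]
  if (x0 < 0 || y0 < 0 || x0 + rw > w || y0 + rh > h || rw < 1 || rh < 1) {
    stop("roi_mask: roi (x=", x0, ", y=", y0, ", w=", rw, ", h=", rh,
         ") outside image ", w, "x", h)
  }
  m <- matrix(FALSE, h, w)
  m[(y0 + 1):(y0 + rh), (x0 + 1):(x0 + rw)] <- TRUE
  m
}

#' Estimate the skin color distribution plane
#'
#' PCA of the optical densities of roi pixels; the plane is spanned by the
#' first two principal directions. The roi should be a small region little
#' affected by changes in illumination intensity, so that its colors lie on
#' the pigment plane.
#'
#' @param img a [skin_image].
#' @param roi `NULL` (central window covering a quarter of the image area),
#'   a length-4 vector `c(x, y, w, h)` in 0-based pixel coordinates, or a
#'   logical mask of image size.
#' @return a [color_plane] with explained-variance fractions.
#' @export
estimate_color_plane <- function(img, roi = NULL) {
  mask <- roi_mask(img, roi)
  if (sum(mask) < 16) stop("estimate_color_plane: roi must contain >= 16 pixels")
  dens <- optical_density(img)
  X <- cbind(dens[, , 1][mask], dens[, , 2][mask], dens[, , 3][mask])
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  if (p$sdev[2]^2 < 1e-12) {
    stop("estimate_color_plane: roi color variation is rank-deficient ",
         "(2nd principal variance ", format(p$sdev[2]^2),
         "); use a larger or more varied roi")
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  color_plane(basis_u = p$rotation[, 1], basis_v = p$rotation[, 2],
              origin = p$center, explained_variance = ev)
}

#' Remove shading by oblique projection onto the color plane
#'
#' Each pixel's density `d` is decomposed exactly as
#' `d = origin + u * basis_u + v * basis_v + s * illum` (a 3x3 linear
#' solve). This is an oblique projection along the illumination direction
#' onto the plane - not an orthogonal one unless `illum` is parallel to the
#' plane normal - so illumination-intensity variation lands entirely in the
#' shading field `s`.
#'
#' @param img a [skin_image].
#' @param plane a [color_plane].
#' @param illum length-3 illumination direction (defaults to
#'   `(1,1,1)/sqrt(3)`); must not lie in the plane.
#' @return list with `coords` (`h x w x 2` array of in-plane coordinates
#'   `(u, v)`) and `shading` (`h x w` matrix).
#' @export
remove_shading <- function(img, plane, illum = c(1, 1, 1) / sqrt(3)) {
  stopifnot(inherits(img, "skin_image"), inherits(plane, "color_plane"))
  illum <- as.numeric(illum)
  illum <- illum / sqrt(sum(illum^2))
  if (abs(sum(plane$normal * illum)) <= 1e-6) {
    stop("remove_shading: illumination direction lies in the color plane; ",
         "shading removal is ill-posed")
  }
  dens <- optical_density(img)
  d <- dim(dens); h <- d[1]; w <- d[2]
  M <- cbind(plane$basis_u, plane$basis_v, illum)
  D <- cbind(as.vector(dens[, , 1]) - plane$origin[1],
             as.vector(dens[, , 2]) - plane$origin[2],
             as.vector(dens[, , 3]) - plane$origin[3])
  uvs <- D %*% t(solve(M))
  coords <- array(uvs[, 1:2], dim = c(h, w, 2))
  list(coords = coords, shading = matrix(uvs[, 3], h, w))
}

#' Estimate pigment vectors by 2-D independent component analysis
#'
#' Within the color plane there are exactly two sources (melanin and
#' hemoglobin), so ICA runs in the 2-D plane coordinates: center, whiten,
#' then fixed-point iteration with a tanh contrast, initialized at the
#' rotation angle of maximal contrast (deflation; in 2-D the second
#' whitened direction is the orthogonal complement of the first).
#' The two mixing directions are lifted back to 3-D density space and
#' disambiguated deterministically:
#' * sign: flipped so that at least half the pixels get nonnegative
#'   concentration on each axis;
#' * label: the lifted vector with the larger green-to-red density ratio is
#'   hemoglobin (hemoglobin absorbs green strongly), the other melanin;
#' * scale: lifted vectors are normalized to unit norm, so concentrations
#'   are relative (recovery is assessed after affine alignment).
#'
#' The bias point is set from the per-axis minimum concentration over the
#' data (configurable percentile), so each pigment's concentration floor
#' touches zero.
#'
#' @param coords `h x w x 2` array (or n x 2 matrix) of plane coordinates
#'   from [remove_shading()].
#' @param plane the [color_plane] the coordinates live in.
#' @param seed integer seed, kept for interface stability; the angle-scan
#'   initialization makes the estimator fully deterministic, so the seed
#'   does not influence the result.
#' @param max_iter,tol fixed-point iteration controls.
#' @param bias_percentile percentile (in \[0, 100\]) of the per-axis
#'   concentration distribution used as the zero floor; default 0 (minimum).
#' @return a [pigment_basis] with the plane attached; attribute
#'   `"ica_iterations"` records the iteration count.
#' @export
estimate_pigment_vectors <- function(coords, plane, seed = 1L,
                                     max_iter = 500L, tol = 1e-8,
                                     bias_percentile = 0) {
  stopifnot(inherits(plane, "color_plane"))
  X <- if (is.array(coords) && length(dim(coords)) == 3) {
    cbind(as.vector(coords[, , 1]), as.vector(coords[, , 2]))
  } else as.matrix(coords)
  stopifnot(ncol(X) == 2)
  if (nrow(X) < 100) {
    stop("estimate_pigment_vectors: need >= 100 samples, got ", nrow(X))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(Xc)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[2] < 1e-14 * max(e$values[1], 1)) {
    stop("estimate_pigment_vectors: degenerate 2-D distribution ",
         "(second eigenvalue ", format(e$values[2]), ")")
  }
  K <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)  # ZCA whitening
  Z <- Xc %*% K
  # initialization: scan the rotation angle for the direction of maximal
  # tanh contrast (deviation of E log cosh from its Gaussian value), then
  # refine by fixed-point iteration; deterministic, immune to bad random
  # starts near the contrast saddle
  EG_GAUSS <- 0.3745672  # E[log cosh(u)], u ~ N(0,1)
  angles <- seq(0, pi, length.out = 181)[1:180]
  J <- vapply(angles, function(t) {
    (mean(log(cosh(Z %*% c(cos(t), sin(t))))) - EG_GAUSS)^2
  }, 0)
  if (max(J) < 1e-6) {
    warning("estimate_pigment_vectors: data look near-Gaussian; ",
            "ICA directions may be unstable")
  }
  t0 <- angles[which.max(J)]
  w <- c(cos(t0), sin(t0))
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    wz <- Z %*% w
    g <- tanh(wz)
    w_new <- colMeans(Z * as.vector(g)) - mean(1 - g^2) * w
    w_new <- w_new / sqrt(sum(w_new^2))
    if (abs(abs(sum(w_new * w)) - 1) < tol) {
      w <- w_new; converged <- TRUE; break
    }
    w <- w_new
  }
  if (!converged) {
    stop("estimate_pigment_vectors: fixed-point ICA did not converge in ",
         max_iter, " iterations (last direction change ",
         format(abs(abs(sum(w_new * w)) - 1)), ")")
  }
  W <- rbind(w, c(-w[2], w[1]))          # unmixing rows in whitened space
  A <- solve(K) %*% t(W)                 # mixing columns in plane coords
  # concentrations under each candidate axis: solve coords = A %*% conc
  conc <- t(solve(A, t(Xc)))
  lift <- function(a) a[1] * plane$basis_u + a[2] * plane$basis_v
  # sign rule: orient each axis so its lifted density vector points toward
  # absorption (positive component sum); with the minimum-based bias floor
  # this leaves every pixel's concentration nonnegative at the floor
  for (j in 1:2) {
    if (sum(lift(A[, j])) < 0) {
      A[, j] <- -A[, j]; conc[, j] <- -conc[, j]
    }
  }
  v1 <- lift(A[, 1]); v2 <- lift(A[, 2])
  gr <- function(v) v[2] / max(v[1], 1e-12)
  hem_first <- gr(v1) >= gr(v2)
  hem3 <- if (hem_first) v1 else v2
  mel3 <- if (hem_first) v2 else v1
  mel_conc <- conc[, if (hem_first) 2 else 1]
  hem_conc <- conc[, if (hem_first) 1 else 2]
  # normalize to unit density norm; rescale concentrations to match
  nm <- sqrt(sum(mel3^2)); nh <- sqrt(sum(hem3^2))
  mel3 <- mel3 / nm; hem3 <- hem3 / nh
  mel_conc <- mel_conc * nm; hem_conc <- hem_conc * nh
  q <- bias_percentile / 100
  floor_m <- stats::quantile(mel_conc, q, names = FALSE)
  floor_h <- stats::quantile(hem_conc, q, names = FALSE)
  # bias point in plane coords: mean + floors along each axis
  Ab <- cbind(if (hem_first) c(A[, 2] / nm) else c(A[, 1] / nm),
              if (hem_first) c(A[, 1] / nh) else c(A[, 2] / nh))
  bias2 <- mu + as.vector(Ab %*% c(floor_m, floor_h))
  bias3 <- plane$origin + bias2[1] * plane$basis_u + bias2[2] * plane$basis_v
  basis <- pigment_basis(mel3, hem3, bias = bias3, plane = plane,
                         check_absorbers = FALSE)
  attr(basis, "ica_iterations") <- iters
  basis
}

#' Build the exact color plane implied by a pigment basis
#'
#' Orthonormalizes the two pigment density vectors (Gram-Schmidt) and puts
#' the origin at the basis bias point, so that projection with the true
#' basis needs no PCA step.
#'
#' @param basis a [pigment_basis].
#' @return a [color_plane].
#' @export
plane_from_basis <- function(basis) {
  stopifnot(inherits(basis, "pigment_basis"))
  u <- basis$melanin_vector / sqrt(sum(basis$melanin_vector^2))
  v <- basis$hemoglobin_vector - sum(basis$hemoglobin_vector * u) * u
  v <- v / sqrt(sum(v^2))
  color_plane(u, v, origin = basis$bias)
}

#' Project plane coordinates onto the pigment axes
#'
#' Solves, per pixel, the 2x2 system expressing the bias-subtracted plane
#' coordinate as `melanin * w_m + hemoglobin * w_h`, where `w_m`, `w_h` are
#' the pigment vectors expressed in plane coordinates. The shading field is
#' passed through unchanged. Negative concentrations are kept (diagnostic);
#' clamping to zero happens at the calibration boundary.
#'
#' @param coords `h x w x 2` plane-coordinate array from [remove_shading()].
#' @param shading `h x w` shading matrix from [remove_shading()].
#' @param basis a [pigment_basis].
#' @param plane the [color_plane] the coordinates refer to; defaults to the
#'   plane stored in `basis` by [estimate_pigment_vectors()].
#' @return a [concentration_map].
#' @export
project_concentrations <- function(coords, shading, basis,
                                   plane = basis$plane) {
  stopifnot(inherits(basis, "pigment_basis"))
  if (is.null(plane)) {
    stop("project_concentrations: no color plane supplied and none stored ",
         "in the basis")
  }
  stopifnot(inherits(plane, "color_plane"))
  d <- dim(coords); h <- d[1]; w <- d[2]
  to2 <- function(v) c(sum(v * plane$basis_u), sum(v * plane$basis_v))
  W2 <- cbind(to2(basis$melanin_vector), to2(basis$hemoglobin_vector))
  cn <- kappa(W2, exact = TRUE)
  if (!is.finite(cn) || cn > 1e8) {
    stop("project_concentrations: pigment vectors are near-parallel in the ",
         "plane (condition number ", format(cn), ")")
  }
  bias2 <- to2(basis$bias - plane$origin)
  P <- cbind(as.vector(coords[, , 1]) - bias2[1],
             as.vector(coords[, , 2]) - bias2[2])
  conc <- P %*% t(solve(W2))
  concentration_map(matrix(conc[, 1], h, w), matrix(conc[, 2], h, w),
                    as.matrix(shading))
}

#' Separate a skin image into pigment concentration maps
#'
#' Full pigment component separation: estimate the color plane by PCA over
#' the roi (skipped when a trusted `basis` with an attached plane is
#' supplied), remove shading by oblique projection along the illumination
#' direction, estimate the melanin and hemoglobin axes by 2-D ICA (skipped
#' when `basis` is supplied), and project every pixel onto them.
#'
#' @inheritParams estimate_color_plane
#' @param illum length-3 illumination direction.
#' @param seed integer seed for the ICA initialization.
#' @param basis optional known [pigment_basis]; when given, ICA is skipped
#'   and, if the basis carries no plane, [plane_from_basis()] supplies the
#'   exact one.
#' @param bias_percentile passed to [estimate_pigment_vectors()].
#' @return list with `map` (a [concentration_map]) and `basis` (the
#'   [pigment_basis] used).
#' @export
#' @examples
#' cm <- make_phantom("palm_like", 48, 48, seed = 7)
#' img <- render_skin(cm, default_basis())
#' res <- separate(img, seed = 7)
separate <- function(img, roi = NULL, illum = c(1, 1, 1) / sqrt(3),
                     seed = 1L, basis = NULL, bias_percentile = 0) {
  stopifnot(inherits(img, "skin_image"))
  if (is.null(basis)) {
    plane <- estimate_color_plane(img, roi)
    proj <- remove_shading(img, plane, illum)
    basis <- estimate_pigment_vectors(proj$coords, plane, seed = seed,
                                      bias_percentile = bias_percentile)
  } else {
    stopifnot(inherits(basis, "pigment_basis"))
    plane <- if (is.null(basis$plane)) plane_from_basis(basis) else basis$plane
    basis$plane <- plane
    proj <- remove_shading(img, plane, illum)
  }
  # remove_shading returns the density-space offset s (positive = denser =
  # darker); the concentration map stores the log-intensity offset, so the
  # sign flips and a rendered map round-trips to itself
  map <- project_concentrations(proj$coords, -proj$shading, basis, plane)
  list(map = map, basis = basis)
}
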