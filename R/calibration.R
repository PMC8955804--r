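# Calibration: the patch grid crossing pigment concentrations, RGB
# encodings of concentration, RGB -> CMYK conversion, and the three
# interchangeable concentration -> CMYK estimators (lookup table,
# log-linear regression, small neural network) with leave-one-out
# cross-validation and paired comparison.

#' Equally spaced pigment concentration levels
#'
#' @param n number of levels (>= 2).
#' @param c_min,c_max concentration range endpoints (`c_min < c_max`).
#' @return numeric vector of `n` equally spaced values including both
#'   endpoints.
#' @export
#' @examples
#' make_levels(30, 0, 1)  # the standard 30-level grid, step 1/29
make_levels <- function(n, c_min = 0, c_max = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("make_levels: n must be >= 2")
  }
  stopifnot(c_min < c_max)
  seq(c_min, c_max, length.out = as.integer(n))
}

#' RGB encoding of a pigment concentration
#'
#' The color a single pigment of concentration `c` presents under the
#' forward model: `rgb_ch = exp(-(c * vector_ch + bias_ch))`, clamped into
#' `[2^-16, 1]`.
#'
#' @param c nonnegative concentration (vectorized).
#' @param vector length-3 pigment density vector.
#' @param bias length-3 baseline density.
#' @return matrix with one RGB row per concentration (or a length-3 vector
#'   for scalar input).
#' @export
pigment_color <- function(c, vector, bias = c(0, 0, 0)) {
  stopifnot(all(c >= 0), length(vector) == 3, length(bias) == 3)
  out <- clamp_reflectance(exp(-(outer(c, vector) +
                                   matrix(bias, length(c), 3, byrow = TRUE))))
  colnames(out) <- c("R", "G", "B")
  if (length(c) == 1) drop(out) else out
}

#' Convert RGB to CMYK
#'
#' Default transform is naive under-color removal:
#' `K = 1 - max(R, G, B)`; for `K < 1`, `C = (1 - R - K) / (1 - K)` and
#' analogously for M (green) and Y (blue); a pure black pixel maps to
#' `(0, 0, 0, 1)`. A different color transform (e.g. one derived from a
#' press ICC profile) can be substituted wherever a `transform` argument is
#' accepted.
#'
#' @param rgb length-3 vector or n x 3 matrix with values in `[0, 1]`.
#' @param transform function mapping an n x 3 RGB matrix to an n x 4 CMYK
#'   matrix; defaults to [cmyk_naive()].
#' @return length-4 vector or n x 4 matrix of CMYK values in `[0, 1]`.
#' @export
#' @examples
#' rgb_to_cmyk(c(1, 0, 0))  # pure red -> (0, 1, 1, 0)
rgb_to_cmyk <- function(rgb, transform = cmyk_naive) {
  vec <- is.null(dim(rgb))
  rgb <- if (vec) matrix(rgb, 1, 3) else as.matrix(rgb)
  stopifnot(ncol(rgb) == 3)
  if (any(rgb < 0 | rgb > 1)) {
    stop("rgb_to_cmyk: RGB values must lie in [0, 1]")
  }
  out <- transform(rgb)
  if (!is.matrix(out) || ncol(out) != 4) {
    stop("rgb_to_cmyk: transform must return an n x 4 CMYK matrix")
  }
  colnames(out) <- c("C", "M", "Y", "K")
  if (vec) drop(out) else out
}

#' @rdname rgb_to_cmyk
#' @export
cmyk_naive <- function(rgb) {
  K <- 1 - apply(rgb, 1, max)
  denom <- ifelse(K < 1, 1 - K, 1)
  C <- ifelse(K < 1, (1 - rgb[, 1] - K) / denom, 0)
  M <- ifelse(K < 1, (1 - rgb[, 2] - K) / denom, 0)
  Y <- ifelse(K < 1, (1 - rgb[, 3] - K) / denom, 0)
  cbind(C = pmin(pmax(C, 0), 1), M = pmin(pmax(M, 0), 1),
        Y = pmin(pmax(Y, 0), 1), K = pmin(pmax(K, 0), 1))
}

#' Log-linear color transform
#'
#' Builds a transform of the regression model class: each CMYK channel is
#' an affine function of `(log R, log G, log B)`. Useful both as a
#' pluggable transform and for exact-recovery checks of the regression
#' estimator.
#'
#' @param coefs 4 x 4 matrix; row i holds `(a_R, a_G, a_B, b)` for output
#'   channel i in C, M, Y, K order.
#' @return a transform function suitable for [rgb_to_cmyk()].
#' @export
make_log_linear_transform <- function(coefs) {
  coefs <- as.matrix(coefs)
  stopifnot(identical(dim(coefs), c(4L, 4L)), all(is.finite(coefs)))
  function(rgb) {
    L <- log(pmax(rgb, SKINFAB_EPS))
    out <- cbind(L, 1) %*% t(coefs)
    colnames(out) <- c("C", "M", "Y", "K")
    out
  }
}

#' Build the calibration patch set
#'
#' The full cross-product of melanin and hemoglobin concentration levels.
#' Each patch carries the two per-pigment RGB encodings and the CMYK
#' targets for the two colored layers obtained from `transform`. The
#' standard grid is 30 levels per pigment, i.e. 900 patches.
#'
#' @param n_mel,n_hem level counts per pigment.
#' @param basis a [pigment_basis] defining the pigment colors.
#' @param mel_range,hem_range concentration ranges `c(min, max)`.
#' @param transform RGB -> CMYK transform (see [rgb_to_cmyk()]).
#' @return object of class `patch_set`: a list with `patches` (data frame,
#'   one row per patch with 0-based `mel_level`/`hem_level`, concentrations,
#'   6 RGB and 8 CMYK columns), `n_mel`, `n_hem`, `basis`.
#' @export
#' @examples
#' ps <- build_patch_set(5, 5, default_basis())
#' nrow(ps$patches)
build_patch_set <- function(n_mel = 30, n_hem = 30, basis = default_basis(),
                            mel_range = c(0, 1), hem_range = c(0, 1),
                            transform = cmyk_naive) {
  stopifnot(inherits(basis, "pigment_basis"))
  mel_levels <- make_levels(n_mel, mel_range[1], mel_range[2])
  hem_levels <- make_levels(n_hem, hem_range[1], hem_range[2])
  grid <- expand.grid(hem_level = seq_len(n_hem) - 1L,
                      mel_level = seq_len(n_mel) - 1L)[, 2:1]
  mel_conc <- mel_levels[grid$mel_level + 1L]
  hem_conc <- hem_levels[grid$hem_level + 1L]
  mel_rgb <- pigment_color(mel_conc, basis$melanin_vector, basis$bias)
  hem_rgb <- pigment_color(hem_conc, basis$hemoglobin_vector, basis$bias)
  mel_cmyk <- rgb_to_cmyk(mel_rgb, transform)
  hem_cmyk <- rgb_to_cmyk(hem_rgb, transform)
  if (any(mel_cmyk < 0 | mel_cmyk > 1) || any(hem_cmyk < 0 | hem_cmyk > 1)) {
    stop("build_patch_set: transform produced CMYK outside [0, 1]")
  }
  patches <- data.frame(grid,
                        mel_conc = mel_conc, hem_conc = hem_conc,
                        mel_R = mel_rgb[, 1], mel_G = mel_rgb[, 2],
                        mel_B = mel_rgb[, 3],
                        hem_R = hem_rgb[, 1], hem_G = hem_rgb[, 2],
                        hem_B = hem_rgb[, 3],
                        mel_C = mel_cmyk[, 1], mel_M = mel_cmyk[, 2],
                        mel_Y = mel_cmyk[, 3], mel_K = mel_cmyk[, 4],
                        hem_C = hem_cmyk[, 1], hem_M = hem_cmyk[, 2],
                        hem_Y = hem_cmyk[, 3], hem_K = hem_cmyk[, 4])
  structure(list(patches = patches, n_mel = as.integer(n_mel),
                 n_hem = as.integer(n_hem), basis = basis),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set %d x %d = %d patches>\n",
              x$n_mel, x$n_hem, nrow(x$patches)))
  invisible(x)
}

RGB_COLS <- c("mel_R", "mel_G", "mel_B", "hem_R", "hem_G", "hem_B")
CMYK_COLS <- c("mel_C", "mel_M", "mel_Y", "mel_K",
               "hem_C", "hem_M", "hem_Y", "hem_K")

patch_features <- function(ps) as.matrix(ps$patches[, RGB_COLS])
patch_targets <- function(ps) as.matrix(ps$patches[, CMYK_COLS])

# normalize prediction input to an n x 6 feature matrix
as_feature_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features)) {
    stopifnot(ncol(features$mel_rgb) == 3, ncol(features$hem_rgb) == 3)
    features <- cbind(features$mel_rgb, features$hem_rgb)
  }
  features <- as.matrix(features)
  stopifnot(ncol(features) == 6)
  colnames(features) <- RGB_COLS
  features
}

#' Fit the lookup-table estimator
#'
#' Stores every patch; a query (the 6-vector of the two per-pigment RGB
#' encodings) returns the stored CMYK pair of the patch minimizing
#' root-mean-square feature distance. Ties go to the lowest patch index.
#' An exact feature hit therefore returns that patch's CMYK with zero
#' error.
#'
#' @param ps a [build_patch_set()] result.
#' @return object of class `skinfab_lut` with a [predict][predict.skinfab_lut]
#'   method.
#' @export
fit_lut <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  if (nrow(ps$patches) == 0) stop("fit_lut: empty patch set")
  structure(list(features = patch_features(ps), targets = patch_targets(ps)),
            class = "skinfab_lut")
}

#' Predict CMYK from a fitted LUT
#'
#' @param object a `skinfab_lut`.
#' @param features n x 6 matrix (mel RGB then hem RGB), or a list with
#'   `mel_rgb` and `hem_rgb` n x 3 matrices.
#' @param ... unused.
#' @return n x 8 matrix of CMYK values (melanin layer then hemoglobin
#'   layer).
#' @export
predict.skinfab_lut <- function(object, features, ...) {
  q <- as_feature_matrix(features)
  F <- object$features
  # squared distances via ||q||^2 - 2 q.f + ||f||^2; chunk queries to bound
  # memory on per-pixel use
  f2 <- rowSums(F^2)
  n <- nrow(q)
  idx <- integer(n)
  chunk <- 4096L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    qc <- q[s:e, , drop = FALSE]
    d2 <- outer(rowSums(qc^2), f2, `+`) - 2 * qc %*% t(F)
    idx[s:e] <- max.col(-d2, ties.method = "first")
  }
  out <- object$targets[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the log-linear regression estimator
#'
#' Ordinary least squares per colored layer and per CMYK channel on the
#' features `(log R, log G, log B)` of that layer's pigment color:
#' `D_i = a_R log R + a_G log G + a_B log B + b`. Predictions are clamped
#' into `[0, 1]`.
#'
#' Single-pigment color encodings are exactly collinear in log space (all
#' three log channels are affine in the one concentration), so the design
#' matrix of a synthetic patch set is rank-deficient by construction.
#' Aliased coefficients are therefore dropped (set to zero) via
#' column-pivoted QR, as `lm()` does; fitted values remain unique on the
#' feature subspace the patches span. Only complete degeneracy (rank < 2,
#' i.e. constant features without usable variation) is rejected.
#'
#' @param ps a [build_patch_set()] result with >= 4 patches.
#' @return object of class `skinfab_regression`; `$coefficients` is a
#'   `2 x 4 x 4` array (layer, channel, `(a_R, a_G, a_B, b)`), `$rank` the
#'   per-layer design rank.
#' @export
fit_regression <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  pt <- ps$patches
  if (nrow(pt) < 4) stop("fit_regression: need >= 4 patches")
  coefs <- array(NA_real_, c(2, 4, 4),
                 dimnames = list(c("mel", "hem"), c("C", "M", "Y", "K"),
                                 c("a_R", "a_G", "a_B", "b")))
  rank <- c(mel = 0L, hem = 0L)
  for (layer in c("mel", "hem")) {
    L <- log(pmax(as.matrix(pt[, paste0(layer, c("_R", "_G", "_B"))]),
                  SKINFAB_EPS))
    X <- cbind(L, 1)
    qr_x <- qr(X)
    rank[layer] <- qr_x$rank
    if (qr_x$rank < 2) {
      stop("fit_regression: log-RGB features of the ", layer,
           " layer carry no usable variation (rank ", qr_x$rank,
           " of 4, condition ", format(kappa(X)), ")")
    }
    Y <- as.matrix(pt[, paste0(layer, c("_C", "_M", "_Y", "_K"))])
    B <- qr.coef(qr_x, Y)                 # 4 x 4: rows aR,aG,aB,b
    B[is.na(B)] <- 0                      # aliased columns dropped
    coefs[layer, , ] <- t(B)
  }
  structure(list(coefficients = coefs, rank = rank),
            class = "skinfab_regression")
}

#' Predict CMYK from the regression estimator
#'
#' @param object a `skinfab_regression`.
#' @inheritParams predict.skinfab_lut
#' @return n x 8 CMYK matrix, clamped into `[0, 1]`.
#' @export
predict.skinfab_regression <- function(object, features, ...) {
  q <- as_feature_matrix(features)
  out <- matrix(NA_real_, nrow(q), 8,
                dimnames = list(NULL, CMYK_COLS))
  for (k in 1:2) {
    layer <- c("mel", "hem")[k]
    L <- log(pmax(q[, (3 * k - 2):(3 * k), drop = FALSE], SKINFAB_EPS))
    B <- t(matrix(object$coefficients[layer, , ], 4, 4))  # aR,aG,aB,b x chan
    out[, (4 * k - 3):(4 * k)] <- cbind(L, 1) %*% B
  }
  pmin(pmax(out, 0), 1)
}

#' Fit the neural-network estimator
#'
#' Two networks of identical structure, one per colored layer: 3 inputs
#' (the layer's RGB encoding) -> fully connected hidden layers of 20, 30
#' and 20 ReLU units -> 4 linear outputs (CMYK). Trained with Adam
#' (step 1e-3, batch 32) on mean-squared error; seed-deterministic; the
#' per-epoch training loss curve is recorded.
#'
#' @param ps a [build_patch_set()] result.
#' @param epochs training epochs (default 30).
#' @param seed integer seed controlling initialization and shuffling.
#' @return object of class `skinfab_mlp` with fields `mel`, `hem` (each a
#'   trained network plus loss history) and `n_params` (1414 per network).
#' @export
fit_mlp <- function(ps, epochs = 30, seed = 1L) {
  stopifnot(inherits(ps, "patch_set"))
  if (nrow(ps$patches) == 0) stop("fit_mlp: empty patch set")
  pt <- ps$patches
  fit_one <- function(layer, s) {
    X <- as.matrix(pt[, paste0(layer, c("_R", "_G", "_B"))])
    Y <- as.matrix(pt[, paste0(layer, c("_C", "_M", "_Y", "_K"))])
    mlp_train(X, Y, hidden = c(20, 30, 20), epochs = epochs, seed = s)
  }
  mel <- fit_one("mel", seed)
  hem <- fit_one("hem", seed + 1000L)
  structure(list(mel = mel, hem = hem, epochs = epochs, seed = seed,
                 n_params = mlp_n_params(mel$net)),
            class = "skinfab_mlp")
}

#' Predict CMYK from the neural-network estimator
#'
#' @param object a `skinfab_mlp`.
#' @inheritParams predict.skinfab_lut
#' @return n x 8 CMYK matrix, clamped into `[0, 1]`.
#' @export
predict.skinfab_mlp <- function(object, features, ...) {
  q <- as_feature_matrix(features)
  out <- cbind(mlp_forward(object$mel$net, q[, 1:3, drop = FALSE]),
               mlp_forward(object$hem$net, q[, 4:6, drop = FALSE]))
  colnames(out) <- CMYK_COLS
  pmin(pmax(out, 0), 1)
}

fit_method <- function(ps, method, seed = 1L, epochs = 30) {
  switch(method,
         lut = fit_lut(ps),
         regression = fit_regression(ps),
         mlp = fit_mlp(ps, epochs = epochs, seed = seed),
         stop("unknown calibration method ", deparse(method),
              "; valid: lut, regression, mlp"))
}

# patch_set with rows idx removed
patch_subset <- function(ps, keep) {
  ps$patches <- ps$patches[keep, , drop = FALSE]
  rownames(ps$patches) <- NULL
  ps
}

#' Leave-one-out cross-validation of a calibration method
#'
#' For each patch, the estimator is trained on all other patches and
#' predicts the held-out patch's 8 CMYK components (both colored layers).
#' The per-patch error is the root-mean-square over those 8 components; the
#' overall RMSE is the root of the mean squared error over all held-out
#' components.
#'
#' @param ps a [build_patch_set()] result with >= 2 patches.
#' @param method `"lut"`, `"regression"` or `"mlp"`.
#' @param seed seed for methods with stochastic training.
#' @param epochs MLP training epochs per fold.
#' @return list with `rmse` (scalar) and `per_patch_errors` (one RMSE per
#'   patch).
#' @export
loocv <- function(ps, method = c("lut", "regression", "mlp"), seed = 1L,
                  epochs = 30) {
  method <- match.arg(method)
  stopifnot(inherits(ps, "patch_set"))
  n <- nrow(ps$patches)
  if (n < 2) stop("loocv: need >= 2 patches")
  feats <- patch_features(ps)
  targs <- patch_targets(ps)
  per_patch <- numeric(n)
  sq_sum <- 0
  for (i in seq_len(n)) {
    model <- fit_method(patch_subset(ps, -i), method, seed = seed,
                        epochs = epochs)
    pred <- predict(model, feats[i, , drop = FALSE])
    sq <- (pred - targs[i, ])^2
    per_patch[i] <- sqrt(mean(sq))
    sq_sum <- sq_sum + sum(sq)
  }
  list(rmse = sqrt(sq_sum / (8 * n)), per_patch_errors = per_patch)
}

#' Compare two methods' per-patch LOOCV errors
#'
#' Two-sided paired t-test on matched per-patch error vectors; the
#' difference is called significant when `p < alpha`. When the paired
#' differences have zero variance the test statistic is degenerate
#' (`degenerate = TRUE`): identical error vectors report `p = 1`, while an
#' exactly constant nonzero shift is the limit of an infinite t statistic
#' and reports `p = 0`.
#'
#' @param errors_a,errors_b equal-length per-patch error vectors from
#'   [loocv()] on the same patch set.
#' @param alpha significance level (default 0.05).
#' @return list with `p_value`, `significant`, `degenerate`, `statistic`,
#'   `df`, `mean_diff`.
#' @export
compare_methods <- function(errors_a, errors_b, alpha = 0.05) {
  errors_a <- as.numeric(errors_a); errors_b <- as.numeric(errors_b)
  if (length(errors_a) != length(errors_b)) {
    stop("compare_methods: error vectors have different lengths (",
         length(errors_a), " vs ", length(errors_b), ")")
  }
  d <- errors_a - errors_b
  if (length(d) < 2 ||
      sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.eps)) {
    # zero-variance differences: the t statistic is undefined for a zero
    # mean (identical errors) and diverges for a constant shift
    shifted <- abs(mean(d)) > 0
    return(list(p_value = if (shifted) 0 else 1,
                significant = shifted,
                degenerate = TRUE,
                statistic = if (shifted) sign(mean(d)) * Inf else NA_real_,
                df = length(d) - 1,
                mean_diff = mean(d)))
  }
  tt <- t.test(errors_a, errors_b, paired = TRUE)
  list(p_value = tt$p.value,
       significant = tt$p.value < alpha,
       degenerate = FALSE,
       statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       mean_diff = mean(d))
}
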