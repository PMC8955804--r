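# Independent oracles and shared fixtures for the test suite.

# Reference Floyd-Steinberg implementation: a straightforward scalar double
# loop, written independently of the package's C++ kernel. Raster scan,
# threshold 0.5 (ties fire a dot), error pushed 7/16 right, 3/16 below-left,
# 5/16 below, 1/16 below-right, out-of-image targets dropped.
fs_reference <- function(x) {
  h <- nrow(x); w <- ncol(x)
  acc <- x
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      v <- acc[r, c]
      bit <- if (v >= 0.5) 1L else 0L
      out[r, c] <- bit
      e <- v - bit
      if (c < w) acc[r, c + 1] <- acc[r, c + 1] + e * 7 / 16
      if (r < h) {
        if (c > 1) acc[r + 1, c - 1] <- acc[r + 1, c - 1] + e * 3 / 16
        acc[r + 1, c] <- acc[r + 1, c] + e * 5 / 16
        if (c < w) acc[r + 1, c + 1] <- acc[r + 1, c + 1] + e * 1 / 16
      }
    }
  }
  out
}

# a log-linear CMYK transform of the regression model class whose outputs
# stay inside [0, 1] over the unit concentration grid
test_linear_coefs <- function() {
  rbind(C = c(-0.20, -0.10, -0.05, 0.10),
        M = c(-0.05, -0.25, -0.10, 0.15),
        Y = c(-0.10, -0.05, -0.30, 0.10),
        K = c(-0.15, -0.15, -0.15, 0.05))
}

test_linear_transform <- function() {
  make_log_linear_transform(test_linear_coefs())
}

# build a patch_set-shaped object with arbitrary feature/target columns,
# bypassing build_patch_set (for full-rank regression fixtures, tie cases)
manual_patch_set <- function(mel_rgb, hem_rgb, mel_cmyk, hem_cmyk,
                             basis = default_basis()) {
  n <- nrow(mel_rgb)
  patches <- data.frame(
    mel_level = seq_len(n) - 1L, hem_level = 0L,
    mel_conc = 0, hem_conc = 0,
    mel_R = mel_rgb[, 1], mel_G = mel_rgb[, 2], mel_B = mel_rgb[, 3],
    hem_R = hem_rgb[, 1], hem_G = hem_rgb[, 2], hem_B = hem_rgb[, 3],
    mel_C = mel_cmyk[, 1], mel_M = mel_cmyk[, 2],
    mel_Y = mel_cmyk[, 3], mel_K = mel_cmyk[, 4],
    hem_C = hem_cmyk[, 1], hem_M = hem_cmyk[, 2],
    hem_Y = hem_cmyk[, 3], hem_K = hem_cmyk[, 4])
  structure(list(patches = patches, n_mel = n, n_hem = 1L, basis = basis),
            class = "patch_set")
}

# angle between two directions, ignoring sign, in degrees
dir_angle_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

abs_cor <- function(a, b) abs(stats::cor(as.vector(a), as.vector(b)))

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}
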