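# End-to-end orchestration: flat-field, separate, calibrate, halftone,
# stack - driven by a validated configuration, fully seed-deterministic.

#' Pipeline configuration
#'
#' Validates and freezes every tunable of [run_pipeline()]. The
#' configuration is serialized into the output manifest so a job is fully
#' described by (config, seed, input image).
#'
#' @param roi PCA region: `NULL` (central window covering a quarter of the
#'   image area) or `c(x, y, w, h)` in 0-based pixel coordinates.
#' @param illum length-3 illumination direction.
#' @param method calibration estimator: `"lut"`, `"regression"` or
#'   `"mlp"`.
#' @param n_mel,n_hem calibration grid level counts (default 30 x 30, i.e.
#'   900 patches).
#' @param mel_range,hem_range concentration ranges of the calibration
#'   grid, or `NULL` to span `[0, max]` of the concentrations recovered
#'   from the image.
#' @param clear1_n,clear2_n,clear3_n clear-layer sublayer counts; the
#'   defaults (1, 2, 4) are the configuration that scored best in
#'   subjective evaluation of the printed samples.
#' @param src_dpi,dst_dpi `(horizontal, vertical)` dpi of the input raster
#'   and of the printer grid (default 720 x 1200).
#' @param seed integer seed used by every stochastic stage.
#' @param epochs MLP training epochs (used when `method = "mlp"`).
#' @param srgb_decode decode file inputs from sRGB to linear reflectance.
#' @param save_intermediates persist concentration maps and basis JSON
#'   next to the job.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(roi = NULL,
                            illum = c(1, 1, 1) / sqrt(3),
                            method = c("regression", "lut", "mlp"),
                            n_mel = 30, n_hem = 30,
                            mel_range = NULL, hem_range = NULL,
                            clear1_n = 1, clear2_n = 2, clear3_n = 4,
                            src_dpi = c(360, 360), dst_dpi = c(720, 1200),
                            seed = 1L, epochs = 30,
                            srgb_decode = TRUE,
                            save_intermediates = FALSE) {
  method <- match.arg(method)
  stopifnot(length(illum) == 3, n_mel >= 2, n_hem >= 2,
            clear1_n >= 1, clear2_n >= 1, clear3_n >= 1,
            all(src_dpi > 0), all(dst_dpi > 0), epochs >= 1)
  if (!is.null(roi)) stopifnot(is.numeric(roi), length(roi) == 4)
  for (rg in list(mel_range, hem_range)) {
    if (!is.null(rg)) stopifnot(length(rg) == 2, rg[1] < rg[2])
  }
  structure(
    list(roi = roi, illum = as.numeric(illum), method = method,
         n_mel = as.integer(n_mel), n_hem = as.integer(n_hem),
         mel_range = mel_range, hem_range = hem_range,
         clear1_n = as.integer(clear1_n), clear2_n = as.integer(clear2_n),
         clear3_n = as.integer(clear3_n),
         src_dpi = rep(as.numeric(src_dpi), length.out = 2),
         dst_dpi = rep(as.numeric(dst_dpi), length.out = 2),
         seed = as.integer(seed), epochs = as.integer(epochs),
         srgb_decode = isTRUE(srgb_decode),
         save_intermediates = isTRUE(save_intermediates)),
    class = "pipeline_config")
}

#' Flat-field a skin image with a diffuse-reflector reference
#'
#' Divides the skin image, pixel by pixel and channel by channel, by a
#' diffuse-reflector image taken with identical geometry, approximately
#' cancelling illumination non-uniformity; the result is clamped into
#' `[2^-16, 1]`.
#'
#' @param img a [skin_image].
#' @param reference a [skin_image] of a diffuse reflector, same
#'   dimensions, all values above the representable floor.
#' @return a [skin_image] with provenance `"flat-fielded"`.
#' @export
flat_field <- function(img, reference) {
  stopifnot(inherits(img, "skin_image"), inherits(reference, "skin_image"))
  if (!identical(dim(img$rgb), dim(reference$rgb))) {
    stop("flat_field: image is ", paste(dim(img$rgb), collapse = "x"),
         " but reference is ", paste(dim(reference$rgb), collapse = "x"))
  }
  bad <- which(reference$rgb <= SKINFAB_EPS, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("flat_field: reference at/below the representable floor at pixel (row ",
         bad[1, 1], ", col ", bad[1, 2], ", channel ", bad[1, 3], ")")
  }
  skin_image(clamp_reflectance(img$rgb / reference$rgb),
             provenance = "flat-fielded")
}

#' Run the full skin-reproduction pipeline
#'
#' Stages, in order: optional flat-fielding against a diffuse-reflector
#' reference; pigment component separation (PCA plane, shading removal,
#' ICA unless a basis is supplied); clamping of negative concentrations;
#' calibration of concentration to per-layer CMYK on a synthetic patch
#' grid with the selected estimator; nearest-neighbour resampling to the
#' printer grid; Floyd-Steinberg halftoning of both colored layers; layer
#' stack assembly; job writing. Deterministic: config + seed + inputs
#' fully determine the bytes on disk.
#'
#' @param cfg a [pipeline_config()].
#' @param image input: a [skin_image] or a PNG/TIFF path.
#' @param out_dir output job directory.
#' @param reference optional diffuse-reflector [skin_image] or path.
#' @param basis optional known [pigment_basis] (skips ICA).
#' @return invisibly, a list with the job `manifest`, the recovered `map`
#'   and `basis`, the fitted `model`, and per-layer ink `coverage`.
#' @export
run_pipeline <- function(cfg, image, out_dir, reference = NULL, basis = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  img <- stage("load", {
    if (is.character(image)) read_skin_image(image, cfg$srgb_decode)
    else { stopifnot(inherits(image, "skin_image")); image }
  })
  if (!is.null(reference)) {
    img <- stage("flat_field", {
      ref <- if (is.character(reference)) {
        read_skin_image(reference, cfg$srgb_decode)
      } else reference
      flat_field(img, ref)
    })
  }
  sep <- stage("separate",
               separate(img, roi = cfg$roi, illum = cfg$illum,
                        seed = cfg$seed, basis = basis))
  map <- sep$map
  mel <- pmax(map$melanin, 0)
  hem <- pmax(map$hemoglobin, 0)
  model_and_ps <- stage("calibrate", {
    mel_range <- cfg$mel_range %||% c(0, max(max(mel), 1e-6))
    hem_range <- cfg$hem_range %||% c(0, max(max(hem), 1e-6))
    ps <- build_patch_set(cfg$n_mel, cfg$n_hem, sep$basis,
                          mel_range = mel_range, hem_range = hem_range)
    list(model = fit_method(ps, cfg$method, seed = cfg$seed,
                            epochs = cfg$epochs),
         ps = ps)
  })
  cmyk <- stage("convert", {
    feats <- list(
      mel_rgb = pigment_color(as.vector(mel), sep$basis$melanin_vector,
                              sep$basis$bias),
      hem_rgb = pigment_color(as.vector(hem), sep$basis$hemoglobin_vector,
                              sep$basis$bias))
    pred <- predict(model_and_ps$model, feats)
    list(mel = array(pred[, 1:4], c(map$height, map$width, 4)),
         hem = array(pred[, 5:8], c(map$height, map$width, 4)))
  })
  bits <- stage("halftone", {
    resample_layer <- function(arr) {
      lapply(1:4, function(i)
        resample_to_printer(arr[, , i], cfg$src_dpi, cfg$dst_dpi))
    }
    list(mel = halftone_cmyk(resample_layer(cmyk$mel)),
         hem = halftone_cmyk(resample_layer(cmyk$hem)))
  })
  stack <- stage("stack",
                 build_stack(bits$mel, bits$hem,
                             clear2_n = cfg$clear2_n, clear3_n = cfg$clear3_n,
                             clear1_n = cfg$clear1_n, dpi = cfg$dst_dpi,
                             seed = cfg$seed))
  manifest <- stage("write", {
    mf <- write_job(stack, out_dir)
    cfg_out <- cfg
    class(cfg_out) <- NULL
    jsonlite::write_json(cfg_out, file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    if (cfg$save_intermediates) {
      write_concentration_map(map, out_dir, prefix = "map")
      write_basis_json(sep$basis, file.path(out_dir, "basis.json"))
    }
    mf
  })
  coverage <- vapply(bits, function(layer) mean(vapply(layer, mean, 0)), 0)
  invisible(list(manifest = manifest, map = map, basis = sep$basis,
                 model = model_and_ps$model, coverage = coverage))
}
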