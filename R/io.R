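# Raster and sidecar I/O: skin images as PNG/TIFF (sRGB-decoded to linear
# reflectance on read by default), concentration maps as a trio of
# single-channel TIFFs with a JSON sidecar naming the channels, and pigment
# bases as JSON.

#' sRGB transfer functions
#'
#' Standard sRGB electro-optical transfer function and its inverse, used to
#' decode 8/16-bit image files to linear reflectance (and back on write).
#'
#' @param x numeric values in `[0, 1]`.
#' @return transformed values in `[0, 1]`.
#' @export
srgb_to_linear <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' @rdname srgb_to_linear
#' @export
linear_to_srgb <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) "png"
  else if (ext %in% c("tif", "tiff")) "tiff"
  else stop("unsupported image format '", ext, "' for ", path,
            " (use png or tiff)")
}

#' Read a skin image from PNG or TIFF
#'
#' 8- or 16-bit files are read, an alpha channel (if any) is dropped, and
#' values are decoded from sRGB to linear reflectance unless
#' `srgb_decode = FALSE` (the camera pipeline of a given capture setup may
#' already be linear).
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param srgb_decode decode sRGB to linear reflectance (default `TRUE`).
#' @param provenance provenance tag for the resulting [skin_image].
#' @return a [skin_image].
#' @export
read_skin_image <- function(path, srgb_decode = TRUE, provenance = "captured") {
  fmt <- image_format(path)
  raw <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(raw)) != 3 || dim(raw)[3] < 3) {
    stop("read_skin_image: ", path, " is not an RGB image")
  }
  rgb <- raw[, , 1:3, drop = FALSE]
  if (srgb_decode) rgb <- srgb_to_linear(rgb)
  skin_image(array(rgb, dim = dim(rgb)), provenance = provenance)
}

#' Write a skin image to PNG or TIFF
#'
#' @param img a [skin_image].
#' @param path destination path; format chosen by extension.
#' @param srgb_encode encode linear reflectance to sRGB before quantizing
#'   (default `TRUE`, the inverse of [read_skin_image()]'s default).
#' @param bits bit depth for TIFF output (8 or 16); PNG output is 8-bit.
#' @return `path`, invisibly.
#' @export
write_skin_image <- function(img, path, srgb_encode = TRUE, bits = 16) {
  stopifnot(inherits(img, "skin_image"), bits %in% c(8, 16))
  fmt <- image_format(path)
  rgb <- img$rgb
  if (srgb_encode) rgb <- linear_to_srgb(rgb)
  rgb <- pmin(pmax(rgb, 0), 1)
  if (fmt == "png") {
    png::writePNG(rgb, path)
  } else {
    tiff::writeTIFF(rgb, path, bits.per.sample = as.integer(bits))
  }
  invisible(path)
}

#' Write a concentration map as a TIFF trio with a JSON sidecar
#'
#' Each field (melanin, hemoglobin, shading) is written as a 32-bit float
#' single-channel TIFF, affinely rescaled into `[0, 1]`; the sidecar
#' records the channel names, file names and the `(min, max)` used for
#' each rescaling so [read_concentration_map()] can invert it.
#'
#' @param map a [concentration_map].
#' @param dir destination directory (created if missing).
#' @param prefix file-name prefix (default `"conc"`).
#' @return sidecar path, invisibly.
#' @export
write_concentration_map <- function(map, dir, prefix = "conc") {
  stopifnot(inherits(map, "concentration_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  channels <- list()
  for (ch in c("melanin", "hemoglobin", "shading")) {
    v <- map[[ch]]
    lo <- min(v); hi <- max(v)
    scaled <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
    fn <- sprintf("%s_%s.tiff", prefix, ch)
    tiff::writeTIFF(scaled, file.path(dir, fn), bits.per.sample = 32L)
    channels[[ch]] <- list(file = fn, min = lo, max = hi)
  }
  sidecar <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(
    list(type = "concentration_map", width = map$width, height = map$height,
         channels = channels),
    sidecar, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a concentration map written by [write_concentration_map()]
#'
#' @param sidecar path to the JSON sidecar.
#' @return a [concentration_map].
#' @export
read_concentration_map <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  stopifnot(identical(meta$type, "concentration_map"))
  dir <- dirname(sidecar)
  get <- function(ch) {
    info <- meta$channels[[ch]]
    m <- tiff::readTIFF(file.path(dir, info$file))
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * (info$max - info$min) + info$min
  }
  concentration_map(get("melanin"), get("hemoglobin"), get("shading"))
}

#' Serialize a pigment basis (with its plane) to JSON
#'
#' @param basis a [pigment_basis].
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_basis_json <- function(basis, path) {
  stopifnot(inherits(basis, "pigment_basis"))
  x <- list(melanin_vector = basis$melanin_vector,
            hemoglobin_vector = basis$hemoglobin_vector,
            illumination_direction = basis$illumination_direction,
            bias = basis$bias)
  if (!is.null(basis$plane)) {
    x$plane <- list(basis_u = basis$plane$basis_u,
                    basis_v = basis$plane$basis_v,
                    origin = basis$plane$origin,
                    explained_variance = basis$plane$explained_variance)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a pigment basis written by [write_basis_json()]
#'
#' @param path JSON path.
#' @return a [pigment_basis].
#' @export
read_basis_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  plane <- if (!is.null(x$plane)) {
    color_plane(x$plane$basis_u, x$plane$basis_v, x$plane$origin,
                x$plane$explained_variance)
  }
  pigment_basis(x$melanin_vector, x$hemoglobin_vector,
                x$illumination_direction, x$bias, plane = plane,
                check_absorbers = FALSE)
}

#' Write a patch set to CSV (+ JSON metadata)
#'
#' One row per patch (indices, concentrations, 6 RGB and 8 CMYK columns);
#' the metadata JSON records the grid shape and the basis.
#'
#' @param ps a [build_patch_set()] result.
#' @param csv_path destination CSV path; metadata goes to the same path
#'   with extension `.json`.
#' @return `csv_path`, invisibly.
#' @export
write_patch_set <- function(ps, csv_path) {
  stopifnot(inherits(ps, "patch_set"))
  utils::write.csv(ps$patches, csv_path, row.names = FALSE)
  meta_path <- paste0(tools::file_path_sans_ext(csv_path), ".json")
  jsonlite::write_json(
    list(type = "patch_set", n_mel = ps$n_mel, n_hem = ps$n_hem,
         basis = list(melanin_vector = ps$basis$melanin_vector,
                      hemoglobin_vector = ps$basis$hemoglobin_vector,
                      illumination_direction = ps$basis$illumination_direction,
                      bias = ps$basis$bias)),
    meta_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(csv_path)
}

#' Read a patch set written by [write_patch_set()]
#'
#' @param csv_path CSV path (the `.json` metadata must sit alongside).
#' @return a `patch_set`.
#' @export
read_patch_set <- function(csv_path) {
  patches <- utils::read.csv(csv_path)
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(csv_path), ".json"),
                              simplifyVector = TRUE)
  stopifnot(identical(meta$type, "patch_set"))
  basis <- pigment_basis(meta$basis$melanin_vector,
                         meta$basis$hemoglobin_vector,
                         meta$basis$illumination_direction,
                         meta$basis$bias, check_absorbers = FALSE)
  structure(list(patches = patches, n_mel = as.integer(meta$n_mel),
                 n_hem = as.integer(meta$n_hem), basis = basis),
            class = "patch_set")
}
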