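# Layer stack assembly: the ordered multilayer print job
# clear / melanin / clear / hemoglobin / clear / white, with configurable
# clear-layer thicknesses (sublayer counts), and lossless job I/O.

LAYER_ORDER <- c("clear1", "melanin", "clear2", "hemoglobin", "clear3", "white")

layer_spec <- function(kind, name, sublayer_count, content = NULL) {
  stopifnot(kind %in% c("clear", "color", "white"),
            sublayer_count >= 1)
  if (kind == "color") {
    stopifnot(is.list(content), length(content) == 4)
    dims <- lapply(content, dim)
    if (length(unique(dims)) != 1) {
      stop("layer_spec: the 4 ink channels of ", name,
           " have differing dimensions")
    }
    for (ch in content) {
      if (!all(ch %in% c(0L, 1L))) {
        stop("layer_spec: color layer channels must be strictly binary")
      }
    }
  }
  list(kind = kind, name = name,
       sublayer_count = as.integer(sublayer_count), content = content)
}

#' Assemble the multilayer print job
#'
#' Canonical top-to-bottom order: a protective clear layer, the melanin
#' (epidermis) layer, a clear spacer, the hemoglobin (dermis) layer, a
#' clear spacer, and an opaque white reflective layer playing the role of
#' paper. The two colored layers are always a single sublayer each - their
#' concentration is expressed in area gradation by the halftone, not in
#' thickness - while the clear layers may comprise several sublayers to
#' tune perceived depth.
#'
#' @param mel_bits,hem_bits halftoned colored layers: each a named list of
#'   4 binary matrices as returned by [halftone_cmyk()], sharing
#'   dimensions.
#' @param clear2_n,clear3_n sublayer counts of the spacer clear layers
#'   (>= 1).
#' @param clear1_n sublayer count of the top protective clear layer
#'   (default 1).
#' @param dpi length-2 `(horizontal, vertical)` dpi recorded in the job.
#' @param seed seed recorded for provenance.
#' @return object of class `layer_stack` with fields `layers` (ordered
#'   layer specs), `dims`, `dpi`, `total_layers` (physical sublayer
#'   total) and `provenance`.
#' @export
build_stack <- function(mel_bits, hem_bits, clear2_n, clear3_n, clear1_n = 1,
                        dpi = c(720, 1200), seed = NA_integer_) {
  if (clear1_n < 1 || clear2_n < 1 || clear3_n < 1) {
    stop("build_stack: clear-layer sublayer counts must be >= 1")
  }
  dm <- dim(mel_bits[[1]]); dh <- dim(hem_bits[[1]])
  if (!identical(dm, dh)) {
    stop("build_stack: melanin bitmaps are ", paste(dm, collapse = "x"),
         " but hemoglobin bitmaps are ", paste(dh, collapse = "x"))
  }
  layers <- list(
    layer_spec("clear", "clear1", clear1_n),
    layer_spec("color", "melanin", 1, mel_bits),
    layer_spec("clear", "clear2", clear2_n),
    layer_spec("color", "hemoglobin", 1, hem_bits),
    layer_spec("clear", "clear3", clear3_n),
    layer_spec("white", "white", 1, matrix(1L, dm[1], dm[2])))
  structure(
    list(layers = layers, dims = dm, dpi = rep(dpi, length.out = 2),
         total_layers = as.integer(unname(clear1_n + clear2_n + clear3_n + 3)),
         provenance = list(seed = seed)),
    class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack %dx%d, %d physical layers>\n",
              x$dims[1], x$dims[2], x$total_layers))
  for (l in x$layers) {
    cat(sprintf("  %-10s %-5s x%d\n", l$name, l$kind, l$sublayer_count))
  }
  invisible(x)
}

#' Enumerate the clear-layer thickness samples
#'
#' Cross product of clear2 and clear3 sublayer counts, clear2 varying
#' slowest: with the standard counts `{2, 4, 6}` this yields the nine
#' sample configurations (sample 1 = (2,2), sample 2 = (2,4), ...,
#' sample 9 = (6,6)).
#'
#' @param counts sorted vector of sublayer counts (default `c(2, 4, 6)`).
#' @return data frame with columns `sample`, `clear2_n`, `clear3_n`.
#' @export
enumerate_samples <- function(counts = c(2, 4, 6)) {
  if (length(counts) == 0) stop("enumerate_samples: empty count set")
  counts <- as.integer(counts)
  g <- expand.grid(clear3_n = counts, clear2_n = counts)[, 2:1]
  data.frame(sample = seq_len(nrow(g)), g, row.names = NULL)
}

JOB_SCHEMA_VERSION <- "skinfab-job/1"

#' Write a print job to disk
#'
#' One 1-bit-content PNG per ink channel per color layer (plus the white
#' layer's coverage mask) and a JSON manifest recording schema version,
#' layer order, kinds, sublayer counts, dimensions, dpi, file paths,
#' provenance and a content hash. Round-trips losslessly via [read_job()].
#'
#' @param stack a [build_stack()] result.
#' @param out_dir destination directory (created if missing).
#' @return the manifest, invisibly; written to `out_dir/manifest.json`.
#' @export
write_job <- function(stack, out_dir) {
  stopifnot(inherits(stack, "layer_stack"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("write_job: cannot create ", out_dir)
  layers_meta <- list()
  for (l in stack$layers) {
    files <- character(0)
    if (l$kind == "color") {
      for (ch in names(l$content)) {
        fn <- sprintf("%s_%s.png", l$name, ch)
        png::writePNG(l$content[[ch]] + 0, file.path(out_dir, fn))
        files <- c(files, fn)
      }
    } else if (l$kind == "white") {
      fn <- "white_coverage.png"
      png::writePNG(l$content + 0, file.path(out_dir, fn))
      files <- fn
    }
    layers_meta[[length(layers_meta) + 1]] <-
      list(name = l$name, kind = l$kind, sublayer_count = l$sublayer_count,
           files = as.list(files))
  }
  manifest <- list(schema = JOB_SCHEMA_VERSION,
                   dims = as.integer(stack$dims),
                   dpi = as.numeric(stack$dpi),
                   total_layers = stack$total_layers,
                   provenance = stack$provenance,
                   layers = layers_meta)
  manifest$config_hash <- manifest_hash(manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

manifest_hash <- function(manifest) {
  manifest$config_hash <- NULL
  # canonicalize so a JSON round trip (which may unbox singleton vectors)
  # hashes identically
  manifest$layers <- lapply(manifest$layers, function(l) {
    l$files <- as.list(unlist(l$files))
    l$sublayer_count <- as.integer(l$sublayer_count)
    l
  })
  manifest$dims <- as.integer(manifest$dims)
  manifest$dpi <- as.numeric(manifest$dpi)
  s <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' Read a print job from disk
#'
#' @param job_dir directory containing `manifest.json` and the layer
#'   bitmaps written by [write_job()].
#' @return a `layer_stack` equal (bit-identical channels) to the one
#'   written.
#' @export
read_job <- function(job_dir) {
  mf_path <- file.path(job_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("read_job: no manifest at ", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(mf$schema, JOB_SCHEMA_VERSION)) {
    stop("read_job: unknown schema ", deparse(mf$schema))
  }
  read_bits <- function(fn) {
    m <- png::readPNG(file.path(job_dir, fn))
    if (length(dim(m)) == 3) m <- m[, , 1]
    matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  }
  get_layer <- function(name) Filter(function(l) l$name == name, mf$layers)[[1]]
  load_color <- function(name) {
    l <- get_layer(name)
    bits <- lapply(unlist(l$files), read_bits)
    names(bits) <- sub(sprintf("^%s_([CMYK])\\.png$", name), "\\1",
                       unlist(l$files))
    bits
  }
  counts <- vapply(mf$layers, function(l) l$sublayer_count, 0)
  names(counts) <- vapply(mf$layers, function(l) l$name, "")
  stack <- build_stack(load_color("melanin"), load_color("hemoglobin"),
                       clear2_n = counts["clear2"], clear3_n = counts["clear3"],
                       clear1_n = counts["clear1"], dpi = as.numeric(mf$dpi),
                       seed = mf$provenance$seed %||% NA_integer_)
  stack
}

#' Validate a job manifest against the published schema
#'
#' Structural checks: schema tag, six layers in canonical order, colored
#' layers single-sublayer with four channel files, positive dims/dpi, and
#' a matching content hash.
#'
#' @param manifest a manifest list as returned by [write_job()] or read
#'   from `manifest.json`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_manifest <- function(manifest) {
  if (!identical(manifest$schema, JOB_SCHEMA_VERSION)) {
    stop("manifest: wrong schema tag")
  }
  names_got <- vapply(manifest$layers, function(l) l$name, "")
  if (!identical(names_got, LAYER_ORDER)) {
    stop("manifest: layer order is ", paste(names_got, collapse = ", "),
         "; expected ", paste(LAYER_ORDER, collapse = ", "))
  }
  for (l in manifest$layers) {
    if (l$name %in% c("melanin", "hemoglobin")) {
      if (l$sublayer_count != 1) stop("manifest: colored layers must be single")
      if (length(unlist(l$files)) != 4) stop("manifest: colored layer needs 4 channel files")
    }
  }
  if (length(manifest$dims) != 2 || any(manifest$dims < 1)) stop("manifest: bad dims")
  if (length(manifest$dpi) != 2 || any(manifest$dpi <= 0)) stop("manifest: bad dpi")
  mf2 <- manifest
  if (!identical(manifest_hash(mf2), manifest$config_hash)) {
    stop("manifest: content hash mismatch")
  }
  invisible(TRUE)
}
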