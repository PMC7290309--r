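#' En face angiogram image
#'
#' The common currency of the package: a 2-D 8-bit grayscale raster with a
#' physical scale. Pixels are stored as an integer matrix in `[0, 255]`,
#' row-major with the origin at the top-left; `pixels[r, c]` addresses row
#' `r`, column `c` (1-based in R). The default scale corresponds to a
#' 3 x 3 mm field sampled on a 232 x 232 grid.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @param mm_per_pixel positive physical scale in mm per pixel.
#' @param label image provenance, one of `"original"`, `"averaged"`,
#'   `"denoised"`, `"clean"`.
#' @param seed integer seed used to generate the image, if synthetic.
#' @param provenance free-text provenance string.
#' @return An object of class `enface_image` with fields `pixels`,
#'   `mm_per_pixel`, `label`, `seed`, `provenance`.
#' @export
enface_image <- function(pixels, mm_per_pixel = 3 / 232,
                         label = c("original", "averaged", "denoised", "clean"),
                         seed = NA_integer_, provenance = "") {
  label <- match.arg(label)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stopf("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 32 || ncol(pixels) < 32) {
    stopf("image must be at least 32 x 32 pixels, got %d x %d",
          nrow(pixels), ncol(pixels))
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stopf("intensities must lie in [0, 255] with no missing values")
  }
  if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1 || mm_per_pixel <= 0) {
    stopf("`mm_per_pixel` must be a positive scalar")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, mm_per_pixel = as.numeric(mm_per_pixel),
         label = label, seed = as.integer(seed),
         provenance = as.character(provenance)),
    class = "enface_image"
  )
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d px, %.5f mm/px (%.2f x %.2f mm), label = %s\n",
              nrow(x$pixels), ncol(x$pixels), x$mm_per_pixel,
              nrow(x$pixels) * x$mm_per_pixel, ncol(x$pixels) * x$mm_per_pixel,
              x$label))
  cat(sprintf("  intensity range [%d, %d]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.enface_image <- function(x) dim(x$pixels)

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z]+$", "", path), ".json")

#' Read an en face image from a PNG or TIFF file
#'
#' Accepts single-channel 8-bit or 16-bit rasters; 16-bit input is rescaled
#' so its maximum maps to 255. Multi-channel (color) input is rejected rather
#' than silently converted to luminance. A JSON sidecar with the same stem
#' (as written by [write_enface()]) is merged when present; an explicit
#' `mm_per_pixel` argument overrides the sidecar.
#'
#' @param path file path to a `.png` or `.tif`/`.tiff` raster.
#' @param mm_per_pixel optional physical scale override.
#' @return An [enface_image()].
#' @export
read_enface <- function(path, mm_per_pixel = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stopf("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stopf("unsupported raster format '.%s' (expected PNG or TIFF)", ext)
  )
  if (length(dim(raw)) == 3) {
    if (dim(raw)[3] == 1) {
      raw <- raw[, , 1]
    } else {
      stopf("expected single-channel image, got %d channels", dim(raw)[3])
    }
  }
  # readers return [0,1] floats; recover integer levels. 16-bit input is
  # detected by sub-8-bit quantization and rescaled by its maximum.
  levels255 <- raw * 255
  if (max(abs(levels255 - round(levels255))) > 1e-6) {
    mx <- max(raw)
    raw <- if (mx > 0) raw / mx else raw
    px <- round(raw * 255)
  } else {
    px <- round(levels255)
  }
  meta <- list(mm_per_pixel = 3 / 232, label = "original",
               seed = NA_integer_, provenance = path)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta[names(side)] <- side
  }
  if (!is.null(mm_per_pixel)) meta$mm_per_pixel <- mm_per_pixel
  enface_image(matrix(px, nrow(raw), ncol(raw)),
               mm_per_pixel = meta$mm_per_pixel, label = meta$label,
               seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
               provenance = meta$provenance)
}

#' Write an en face image as lossless 8-bit PNG plus a JSON sidecar
#'
#' The sidecar (same path stem, `.json`) records `mm_per_pixel`, `label`,
#' `seed` and `provenance` so that a read-back round trip preserves both the
#' pixels and the metadata exactly.
#'
#' @param image an [enface_image()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_enface <- function(image, path) {
  stopifnot(inherits(image, "enface_image"))
  if (!dir.exists(dirname(path))) stopf("directory does not exist: %s", dirname(path))
  png::writePNG(image$pixels / 255, path)
  jsonlite::write_json(
    list(mm_per_pixel = image$mm_per_pixel, label = image$label,
         seed = image$seed, provenance = image$provenance),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
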