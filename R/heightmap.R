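#' Construct a height map
#'
#' The AFM data model: a 2D raster of surface heights (nm, substrate = 0) on
#' a uniform square pixel grid. By convention rows run along the image y
#' (axial) direction and columns along x (lateral); straightened fibrils run
#' along y.
#'
#' @param heights numeric matrix of heights in nm (rows = y, cols = x).
#' @param pixel_size_nm pixel edge length in nm (> 0).
#' @param axis_height_nm optional estimated height of the fibril screw axis
#'   above the substrate, nm.
#' @return an object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size_nm, axis_height_nm = NULL) {
  heights <- as.matrix(heights)
  if (!is.numeric(heights) || any(!is.finite(heights)))
    stop("heights must be a finite numeric matrix")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L || pixel_size_nm <= 0)
    stop("pixel_size_nm must be a single positive number")
  structure(list(heights = heights, pixel_size_nm = pixel_size_nm,
                 axis_height_nm = axis_height_nm),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("AFM height map: %d x %d px, %.4g nm/px, height range [%.3g, %.3g] nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size_nm,
              min(x$heights), max(x$heights)))
  if (!is.null(x$axis_height_nm))
    cat(sprintf("  estimated axis height: %.3g nm\n", x$axis_height_nm))
  invisible(x)
}

#' @export
plot.height_map <- function(x, ...) {
  nx <- ncol(x$heights); ny <- nrow(x$heights)
  graphics::image(seq_len(nx) * x$pixel_size_nm, seq_len(ny) * x$pixel_size_nm,
                  t(x$heights), asp = 1, xlab = "x (nm)", ylab = "y (nm)",
                  col = grDevices::hcl.colors(64, "YlOrBr", rev = TRUE), ...)
  invisible(x)
}

#' Write a height map as TSV with a JSON sidecar
#'
#' The grid is written as a plain tab-separated table (full `%.17g` precision,
#' so the round trip through [read_height_tsv()] is bit-exact) and the pixel
#' size and units go to `<path>.json`.
#'
#' @param hm a [height_map()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_height_tsv <- function(hm, path) {
  stopifnot(inherits(hm, "height_map"))
  con <- file(path, "w")
  on.exit(close(con))
  apply(hm$heights, 1L, function(row)
    writeLines(paste(sprintf("%.17g", row), collapse = "\t"), con))
  meta <- list(pixel_size_nm = hm$pixel_size_nm, units = "nm")
  if (!is.null(hm$axis_height_nm)) meta$axis_height_nm <- hm$axis_height_nm
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a height map from TSV (+ JSON sidecar)
#'
#' @param path TSV path written by [write_height_tsv()], or any whitespace-
#'   separated numeric grid. Pixel size is taken from `<path>.json` if present,
#'   else from `pixel_size_nm`.
#' @param pixel_size_nm fallback pixel size, nm.
#' @return a [height_map()].
#' @export
read_height_tsv <- function(path, pixel_size_nm = NULL) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  side <- paste0(path, ".json")
  axis_h <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    pixel_size_nm <- meta$pixel_size_nm
    axis_h <- meta$axis_height_nm
  }
  if (is.null(pixel_size_nm))
    stop("pixel size not found: no JSON sidecar and no pixel_size_nm given")
  height_map(m, pixel_size_nm, axis_h)
}

#' Write a height map as 32-bit TIFF
#'
#' Requires the `tiff` package. Heights are stored normalized to [0, 1];
#' the scale factor and pixel size go to a JSON sidecar as for
#' [write_height_tsv()].
#' @param hm a [height_map()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_height_tiff <- function(hm, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  scale <- max(hm$heights, 1e-12)
  tiff::writeTIFF(hm$heights / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_nm = hm$pixel_size_nm, units = "nm",
                            height_scale_nm = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a height map from 32-bit float TIFF
#' @param path TIFF path; pixel size from `<path>.json` or `pixel_size_nm`.
#' @param pixel_size_nm fallback pixel size, nm.
#' @return a [height_map()].
#' @export
read_height_tiff <- function(path, pixel_size_nm = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  m <- tiff::readTIFF(path, as.is = FALSE)
  side <- paste0(path, ".json")
  scale <- 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    pixel_size_nm <- meta$pixel_size_nm
    if (!is.null(meta$height_scale_nm)) scale <- meta$height_scale_nm
  }
  if (is.null(pixel_size_nm))
    stop("pixel size not found: no JSON sidecar and no pixel_size_nm given")
  height_map(m * scale, pixel_size_nm)
}
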