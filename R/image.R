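#' Grayscale image container
#'
#' An `echo_image` is a plain numeric matrix carrying a declared intensity
#' range. Pixels are stored as floating point; clipping to the declared range
#' happens only on construction and on export, never inside filter sums.
#'
#' @param pixels Numeric matrix of intensities (rows = image height).
#' @param intensity_range Length-2 numeric, the declared `(min, max)` display
#'   range. Defaults to `c(0, 255)` (8-bit convention).
#' @param clip Clip pixels into `intensity_range` on construction? Default
#'   `TRUE`.
#'
#' @return An `echo_image`: a numeric matrix with an `intensity_range`
#'   attribute.
#' @examples
#' img <- echo_image(matrix(runif(64, 0, 255), 8, 8))
#' intensity_range(img)
#' @export
echo_image <- function(pixels, intensity_range = c(0, 255), clip = TRUE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  }
  if (any(!is.finite(pixels))) {
    stop("image intensities must all be finite", call. = FALSE)
  }
  if (length(intensity_range) != 2L || !is.numeric(intensity_range) ||
      intensity_range[2L] <= intensity_range[1L]) {
    stop("`intensity_range` must be an increasing (min, max) pair",
         call. = FALSE)
  }
  pixels <- unclass(pixels)
  if (clip) {
    pixels[] <- pmin(pmax(pixels, intensity_range[1L]), intensity_range[2L])
  }
  structure(pixels,
            intensity_range = as.numeric(intensity_range),
            class = c("echo_image", "matrix", "array"))
}

#' @rdname echo_image
#' @param x An object.
#' @export
is_echo_image <- function(x) inherits(x, "echo_image")

#' @rdname echo_image
#' @export
intensity_range <- function(x) {
  rng <- attr(x, "intensity_range")
  if (is.null(rng)) c(0, 255) else rng
}

# Coerce a matrix-or-image argument, preserving/declaring the range.
as_echo_image <- function(x, intensity_range = NULL, clip = FALSE) {
  if (is_echo_image(x)) {
    if (!is.null(intensity_range)) attr(x, "intensity_range") <- intensity_range
    return(x)
  }
  echo_image(x, intensity_range %||% c(0, 255), clip = clip)
}

#' @export
print.echo_image <- function(x, ...) {
  rng <- intensity_range(x)
  cat(sprintf("<echo_image> %d x %d, intensity range [%g, %g]\n",
              nrow(x), ncol(x), rng[1L], rng[2L]))
  cat(sprintf("  pixel range observed: [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

# ---- padding -----------------------------------------------------------

# Index vector implementing 1-D padding of length n by r on each side.
pad_index <- function(n, r, padding) {
  idx <- seq.int(1L - r, n + r)
  switch(padding,
    reflect = {
      # mirror without repeating the edge pixel: 1 2 3 -> 3 2 |1 2 3| 2 1
      if (n == 1L) rep(1L, length(idx))
      else {
        period <- 2L * (n - 1L)
        j <- (idx - 1L) %% period
        ifelse(j < n, j + 1L, period - j + 1L)
      }
    },
    edge = pmin(pmax(idx, 1L), n),
    zero = ifelse(idx >= 1L & idx <= n, idx, NA_integer_),
    stop(sprintf("unknown padding '%s'", padding), call. = FALSE)
  )
}

#' Pad an image for neighborhood filtering
#'
#' @param image Numeric matrix or `echo_image`.
#' @param radius Nonnegative integer pad width.
#' @param padding One of `"reflect"` (mirror without repeating the edge
#'   pixel), `"edge"` (replicate the edge pixel), `"zero"`.
#' @return Numeric matrix of size `(h + 2r) x (w + 2r)`.
#' @keywords internal
#' @export
pad_image <- function(image, radius, padding = c("reflect", "edge", "zero")) {
  padding <- match.arg(padding)
  m <- unclass(image)
  if (radius == 0L) return(m)
  ri <- pad_index(nrow(m), radius, padding)
  ci <- pad_index(ncol(m), radius, padding)
  if (padding == "zero") {
    out <- matrix(0, length(ri), length(ci))
    ok_r <- !is.na(ri); ok_c <- !is.na(ci)
    out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
    out
  } else {
    m[ri, ci, drop = FALSE]
  }
}

# ---- file I/O ----------------------------------------------------------

#' Read and write grayscale images
#'
#' PNG and TIFF, 8- or 16-bit grayscale. Color inputs are rejected. On read,
#' intensities are rescaled from the file's \[0, 1\] convention to the
#' declared range; on write they are rescaled back and clipped.
#'
#' @param path File path; format inferred from the `.png` / `.tif(f)`
#'   extension.
#' @param intensity_range Declared range for the returned `echo_image`.
#' @return `read_image()` returns an `echo_image`; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path, intensity_range = c(0, 255)) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] > 1L) {
      stop("color images are not supported; provide a single-channel ",
           "grayscale PNG/TIFF", call. = FALSE)
    }
    arr <- arr[, , 1L]
  }
  span <- diff(intensity_range)
  echo_image(arr * span + intensity_range[1L], intensity_range)
}

#' @rdname read_image
#' @param image `echo_image` or numeric matrix.
#' @param bit_depth 8 or 16.
#' @export
write_image <- function(image, path, bit_depth = 8) {
  image <- as_echo_image(image)
  rng <- intensity_range(image)
  scaled <- (unclass(image) - rng[1L]) / diff(rng)
  scaled <- pmin(pmax(scaled, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = bit_depth),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  )
  invisible(path)
}

#' Plot an image as a ggplot raster
#'
#' @param object An `echo_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot echo_image
#' @export
autoplot.echo_image <- function(object, ...) {
  rng <- intensity_range(object)
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    intensity = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = rng) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}
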