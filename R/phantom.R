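#' Shape primitives for synthetic phantoms
#'
#' Building blocks for [phantom_spec()]. Coordinates are in pixel units with
#' `(row, col)` centers; shapes are rasterized in list order, later shapes
#' overwriting earlier ones.
#'
#' @param center Length-2 `(row, col)` center.
#' @param axes Length-2 `(semi_row, semi_col)` semi-axes in pixels.
#' @param intensity Fill intensity.
#' @return A shape description list.
#' @examples
#' shape_ellipse(c(32, 32), c(20, 12), intensity = 200)
#' @export
shape_ellipse <- function(center, axes, intensity) {
  stopifnot(length(center) == 2L, length(axes) == 2L, all(axes > 0))
  list(type = "ellipse", center = as.numeric(center),
       axes = as.numeric(axes), intensity = as.numeric(intensity))
}

#' @rdname shape_ellipse
#' @param radius_outer,radius_inner Outer and inner radii (pixels) of the
#'   ring, `radius_outer > radius_inner >= 0`.
#' @export
shape_annulus <- function(center, radius_outer, radius_inner, intensity) {
  stopifnot(length(center) == 2L, radius_outer > radius_inner,
            radius_inner >= 0)
  list(type = "annulus", center = as.numeric(center),
       radius_outer = as.numeric(radius_outer),
       radius_inner = as.numeric(radius_inner),
       intensity = as.numeric(intensity))
}

#' @rdname shape_ellipse
#' @param size Length-2 `(height, width)` of the rectangle in pixels.
#' @export
shape_rectangle <- function(center, size, intensity) {
  stopifnot(length(center) == 2L, length(size) == 2L, all(size > 0))
  list(type = "rectangle", center = as.numeric(center),
       size = as.numeric(size), intensity = as.numeric(intensity))
}

#' Phantom specification
#'
#' Describes a deterministic piecewise-constant test image: a background
#' intensity plus an ordered list of shape primitives. Used to exercise the
#' denoising filters without clinical images.
#'
#' @param height,width Positive integer canvas size.
#' @param shapes List of shapes from [shape_ellipse()], [shape_annulus()],
#'   [shape_rectangle()].
#' @param background_intensity Background fill.
#' @param intensity_range Declared display range.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(height, width, shapes = list(),
                         background_intensity = 40,
                         intensity_range = c(0, 255)) {
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(height >= 1L, width >= 1L)
  ints <- c(background_intensity,
            vapply(shapes, function(s) s$intensity, numeric(1)))
  if (any(ints < intensity_range[1L] | ints > intensity_range[2L])) {
    stop("all shape and background intensities must lie within ",
         "`intensity_range`", call. = FALSE)
  }
  structure(list(height = height, width = width, shapes = shapes,
                 background_intensity = background_intensity,
                 intensity_range = as.numeric(intensity_range)),
            class = "phantom_spec")
}

#' Built-in phantom presets
#'
#' `"fourchamber"` sketches an apical four-chamber echocardiographic view as
#' a bright myocardial annulus containing four dark elliptical chambers;
#' `"step"` is a two-level vertical step edge (left 50, right 200);
#' `"impulse"` is a single bright center pixel on a dark background.
#'
#' @param preset One of `"fourchamber"`, `"step"`, `"impulse"`.
#' @param height,width Canvas size.
#' @return A `phantom_spec`.
#' @examples
#' img <- make_phantom(phantom_preset("step", 32, 32))
#' @export
phantom_preset <- function(preset = c("fourchamber", "step", "impulse"),
                           height = 128, width = 128) {
  preset <- match.arg(preset)
  h <- height; w <- width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  switch(preset,
    step = {
      k <- floor(w / 2) + 1  # first column of the bright right half
      phantom_spec(h, w,
        shapes = list(shape_rectangle(c(cy, (k + w) / 2), c(h, w - k + 1),
                                      200)),
        background_intensity = 50)
    },
    impulse = phantom_spec(h, w,
      shapes = list(shape_rectangle(c(ceiling(cy), ceiling(cx)), c(1, 1),
                                    255)),
      background_intensity = 0),
    fourchamber = phantom_spec(h, w,
      shapes = list(
        # myocardium: bright ellipse with darker blood-pool chambers
        shape_ellipse(c(cy, cx), c(0.42 * h, 0.38 * w), 190),
        shape_ellipse(c(cy - 0.16 * h, cx - 0.15 * w), c(0.17 * h, 0.13 * w), 70),
        shape_ellipse(c(cy - 0.16 * h, cx + 0.15 * w), c(0.17 * h, 0.13 * w), 70),
        shape_ellipse(c(cy + 0.18 * h, cx - 0.14 * w), c(0.13 * h, 0.11 * w), 70),
        shape_ellipse(c(cy + 0.18 * h, cx + 0.14 * w), c(0.13 * h, 0.11 * w), 70)
      ),
      background_intensity = 25)
  )
}

#' Rasterize a phantom
#'
#' Deterministic: the same spec always yields the same image. A pixel at
#' integer coordinates `(i, j)` belongs to a shape if its center satisfies
#' the shape's inequality (ellipse: normalized squared distance `<= 1`).
#' Shapes whose extent exceeds the canvas are clipped with a warning.
#'
#' @param spec A [phantom_spec()] (or a preset name, passed to
#'   [phantom_preset()]).
#' @return An `echo_image` (the noise-free ground truth).
#' @export
make_phantom <- function(spec) {
  if (is.character(spec)) spec <- phantom_preset(spec)
  stopifnot(inherits(spec, "phantom_spec"))
  img <- matrix(spec$background_intensity, spec$height, spec$width)
  rows <- matrix(seq_len(spec$height), spec$height, spec$width)
  cols <- matrix(rep(seq_len(spec$width), each = spec$height),
                 spec$height, spec$width)
  for (s in spec$shapes) {
    mask <- switch(s$type,
      ellipse = ((rows - s$center[1L]) / s$axes[1L])^2 +
                ((cols - s$center[2L]) / s$axes[2L])^2 <= 1,
      annulus = {
        d2 <- (rows - s$center[1L])^2 + (cols - s$center[2L])^2
        d2 <= s$radius_outer^2 & d2 > s$radius_inner^2
      },
      rectangle = abs(rows - s$center[1L]) <= s$size[1L] / 2 &
                  abs(cols - s$center[2L]) <= s$size[2L] / 2,
      stop(sprintf("unknown shape type '%s'", s$type), call. = FALSE)
    )
    if (shape_exceeds_canvas(s, spec$height, spec$width)) {
      warning(sprintf("%s shape exceeds the %dx%d canvas; clipped",
                      s$type, spec$height, spec$width), call. = FALSE)
    }
    img[mask] <- s$intensity
  }
  echo_image(img, spec$intensity_range)
}

shape_exceeds_canvas <- function(s, h, w) {
  ext <- switch(s$type,
    ellipse = c(s$center - s$axes, s$center + s$axes),
    annulus = c(s$center - s$radius_outer, s$center + s$radius_outer),
    rectangle = c(s$center - s$size / 2, s$center + s$size / 2)
  )
  ext[1L] < 0.5 || ext[2L] < 0.5 || ext[3L] > h + 0.5 || ext[4L] > w + 0.5
}

#' Speckle noise specification
#'
#' `"multiplicative_gamma"` models fully developed speckle: each pixel is
#' multiplied by an i.i.d. Gamma(shape = L, rate = L) field with unit mean
#' and variance 1/L, where L is the number of looks (smaller L = heavier
#' speckle). `"additive_gaussian"` adds zero-mean Gaussian noise of standard
#' deviation `sigma_add`.
#'
#' @param model `"multiplicative_gamma"` or `"additive_gaussian"`.
#' @param looks Positive Gamma shape L (multiplicative model).
#' @param sigma_add Nonnegative SD (additive model).
#' @param seed Integer seed for reproducible noise.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(model = c("multiplicative_gamma", "additive_gaussian"),
                       looks = 4, sigma_add = 10, seed = 1L) {
  model <- match.arg(model)
  if (model == "multiplicative_gamma" && (!is.numeric(looks) || looks <= 0)) {
    stop("`looks` (Gamma shape L) must be > 0", call. = FALSE)
  }
  if (model == "additive_gaussian" && (!is.numeric(sigma_add) || sigma_add < 0)) {
    stop("`sigma_add` must be >= 0", call. = FALSE)
  }
  structure(list(model = model, looks = looks, sigma_add = sigma_add,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Corrupt an image with speckle or additive noise
#'
#' @param image `echo_image` or numeric matrix.
#' @param noise A [noise_spec()].
#' @return Noisy `echo_image`, clipped to the intensity range.
#' @examples
#' clean <- make_phantom(phantom_preset("step", 64, 64))
#' noisy <- add_speckle(clean, noise_spec(looks = 4, seed = 42))
#' @export
add_speckle <- function(image, noise = noise_spec()) {
  stopifnot(inherits(noise, "noise_spec"))
  image <- as_echo_image(image)
  n_px <- length(image)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(noise$seed)
  out <- if (noise$model == "multiplicative_gamma") {
    unclass(image) * matrix(stats::rgamma(n_px, shape = noise$looks,
                                          rate = noise$looks),
                            nrow(image), ncol(image))
  } else {
    unclass(image) + matrix(stats::rnorm(n_px, 0, noise$sigma_add),
                            nrow(image), ncol(image))
  }
  echo_image(out, intensity_range(image), clip = TRUE)
}
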