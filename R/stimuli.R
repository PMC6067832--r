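#' Retina pixel-centre coordinates for a model
#'
#' @param model A [GCALModel-class].
#' @return List with numeric vectors `x` (columns) and `y` (rows), in sheet
#'   coordinates centred on zero.
#' @export
retinaCoords <- function(model) {
  g <- model@geometry
  step <- 2 * g$ret_r / g$n_ret
  ax <- -g$ret_r + (seq_len(g$n_ret) - 0.5) * step
  list(x = ax, y = ax)
}

renderGrid <- function(n, r) {
  step <- 2 * r / n
  -r + (seq_len(n) - 0.5) * step
}

#' Sinusoidal grating stimulus
#'
#' Renders `I(x, y) = 0.5 + (contrast / 2) sin(2 pi f u + phase)` on the
#' retina grid, where `u` is the coordinate perpendicular to the grating
#' orientation and `f` is in cycles per unit sheet length (the V1-visible
#' image width).  Contrast is the fraction of the full luminance range
#' `[0, 1]`, so an 80% grating spans 0.10 to 0.90.
#'
#' @param sf Spatial frequency in cycles per image width (1.5 = low,
#'   6 = medium in the test battery).
#' @param contrast Contrast fraction in `[0, 1]`.
#' @param orientation Bar orientation in radians; `pi/2` is vertical.
#' @param phase Phase in radians.
#' @param model Optional [GCALModel-class]; its retina grid is used.
#' @param n,r Grid size and bounds radius, used when `model` is missing.
#' @return Luminance matrix in `[0, 1]`.
#' @examples
#' img <- gratingStimulus(1.5, 0.8, n = 48, r = 0.5)
#' range(img)
#' @export
gratingStimulus <- function(sf, contrast, orientation = pi / 2, phase = 0,
                            model = NULL, n = NULL, r = NULL) {
  if (contrast < 0 || contrast > 1)
    stop("contrast must lie in [0, 1] (fraction of the input range)",
         call. = FALSE)
  if (!is.null(model)) {
    g <- model@geometry
    n <- g$n_ret; r <- g$ret_r
  }
  ax <- renderGrid(n, r)
  # u: coordinate perpendicular to the bars (for vertical bars, u = x)
  u <- outer(ax, ax, function(y, x) x * sin(orientation) - y * cos(orientation))
  0.5 + (contrast / 2) * sin(2 * pi * sf * u + phase)
}

#' Draw parameters for one training stimulus
#'
#' One training image contains exactly two elongated Gaussian blobs with
#' independent uniform positions over the retina bounds and independent
#' uniform orientations over `[0, pi)`.  Consumes the R RNG.
#'
#' @param model A [GCALModel-class] (for the retina bounds).
#' @return Data frame with one row per blob: `x`, `y`, `orientation`.
#' @export
drawTrainingParams <- function(model) {
  g <- model@geometry
  nb <- model@config$stimuli$training$n_blobs
  data.frame(x = stats::runif(nb, -g$ret_r, g$ret_r),
             y = stats::runif(nb, -g$ret_r, g$ret_r),
             orientation = stats::runif(nb, 0, pi))
}

#' Render a pair of oriented Gaussian blobs
#'
#' The training stimulus family: anisotropic Gaussians (minor-axis width
#' `sigma_minor`, elongated by `aspect_ratio` along the orientation axis)
#' summed and capped at luminance 1.
#'
#' @param params Data frame from [drawTrainingParams()] (columns `x`, `y`,
#'   `orientation`), one row per blob.
#' @param model A [GCALModel-class].
#' @return Luminance matrix in `[0, 1]` with attribute `params`.
#' @export
renderGaussianPair <- function(params, model) {
  g <- model@geometry
  tr <- model@config$stimuli$training
  s_min <- tr$sigma_minor
  s_maj <- tr$sigma_minor * tr$aspect_ratio
  ax <- renderGrid(g$n_ret, g$ret_r)
  xs <- matrix(ax, g$n_ret, g$n_ret, byrow = TRUE)
  ys <- matrix(ax, g$n_ret, g$n_ret)
  img <- matrix(0, g$n_ret, g$n_ret)
  for (i in seq_len(nrow(params))) {
    th <- params$orientation[i]
    dx <- xs - params$x[i]
    dy <- ys - params$y[i]
    u <- dx * cos(th) + dy * sin(th)   # along the major axis
    v <- -dx * sin(th) + dy * cos(th)
    img <- img + tr$peak * exp(-(u^2 / (2 * s_maj^2) + v^2 / (2 * s_min^2)))
  }
  img <- pmin(img, 1)
  attr(img, "params") <- params
  img
}

#' Draw and render one training stimulus
#'
#' @param model A [GCALModel-class].
#' @return Luminance matrix in `[0, 1]` with attribute `params`.
#' @export
trainingStimulus <- function(model) {
  renderGaussianPair(drawTrainingParams(model), model)
}

#' Post-training test battery
#'
#' `type = "cs"` gives the contrast-sensitivity battery: vertical gratings at
#' the low (1.5 cycles/image) and medium (6 cycles/image) spatial frequencies,
#' each at contrasts 5%, 10%, 20%, 40% and 80% (10 stimuli).  `type = "map"`
#' gives the orientation-map battery: `map_orientations` orientations times
#' `map_phases` phases at `map_contrast` and `map_sf`.  `type = "oblique"`
#' adds horizontal and 45-degree versions of the contrast battery (off the
#' default path; responses did not differ for vertical vs oblique testing).
#'
#' @param type One of `"cs"`, `"map"`, `"oblique"`.
#' @param config Configuration list (measurement block is consulted).
#' @return Data frame with columns `sf`, `contrast`, `orientation`, `phase`.
#' @examples
#' nrow(testBattery("cs"))  # 10
#' @export
testBattery <- function(type = c("cs", "map", "oblique"),
                        config = gcalConfig()) {
  type <- match.arg(type)
  ms <- config$stimuli$measurement
  if (type == "cs") {
    expand.grid(sf = c(1.5, 6), contrast = c(0.05, 0.1, 0.2, 0.4, 0.8),
                orientation = pi / 2, phase = 0)
  } else if (type == "oblique") {
    expand.grid(sf = c(1.5, 6), contrast = c(0.05, 0.1, 0.2, 0.4, 0.8),
                orientation = c(0, pi / 4), phase = 0)
  } else {
    expand.grid(sf = ms$map_sf, contrast = ms$map_contrast,
                orientation = seq(0, pi, length.out = ms$map_orientations + 1)[
                  seq_len(ms$map_orientations)],
                phase = seq(0, 2 * pi, length.out = ms$map_phases + 1)[
                  seq_len(ms$map_phases)])
  }
}

#' Export a stimulus as an 8-bit grayscale PNG
#'
#' @param image Luminance matrix in `[0, 1]`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeStimulusPNG <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
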