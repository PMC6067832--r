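#' GCALModel: a built simulator instance
#'
#' Wraps the compiled simulation engine (an external pointer) together with
#' the resolved configuration, sheet geometry, build seed, and a perturbation
#' log.  Create with [buildModel()]; the engine state is reference-semantic,
#' so training and perturbation functions modify the model in place and also
#' return it invisibly.
#'
#' @slot ptr External pointer to the compiled engine state.
#' @slot config Resolved configuration list (see [gcalConfig()]).
#' @slot geometry Sheet geometry (unit counts, bounds radii).
#' @slot seed Integer seed used at build time.
#' @slot log Environment holding the perturbation/event log.
#' @export
setClass("GCALModel",
         representation(ptr = "externalptr", config = "list",
                        geometry = "list", seed = "integer",
                        log = "environment"))

setValidity("GCALModel", function(object) {
  if (identical(object@ptr, methods::new("externalptr")))
    return("engine pointer is NULL; build the model with buildModel()")
  TRUE
})

#' OrientationMap: per-unit orientation preference and selectivity
#'
#' Result of [orientationMap()]: preference angles in `[0, pi)` and
#' vector-sum selectivity in `[0, 1]` for every V1 unit, plus the per-unit
#' responses to each measured orientation (phase-aggregated).
#'
#' @slot preference Matrix of preferred orientations (radians), `NA` where a
#'   unit never responded.
#' @slot selectivity Matrix of selectivity magnitudes in `[0, 1]`.
#' @slot responses Array `n_v1 x n_v1 x n_orientations` of responses.
#' @slot orientations Measured orientations (radians).
#' @export
setClass("OrientationMap",
         representation(preference = "matrix", selectivity = "matrix",
                        responses = "array", orientations = "numeric"))

#' Perturbation: a named parameter change
#'
#' A single scalar change to the resolved configuration, addressed by dotted
#' path, applied multiplicatively (`scale`) or absolutely (`set`).
#'
#' @slot parameter Dotted configuration path, e.g.
#'   `"projections.v1_lateral_inhibitory.strength"`.
#' @slot mode Either `"scale"` or `"set"`.
#' @slot value The scale factor or new value.
#' @export
setClass("Perturbation",
         representation(parameter = "character", mode = "character",
                        value = "numeric"))

setValidity("Perturbation", function(object) {
  if (!object@mode %in% c("scale", "set")) return("mode must be scale or set")
  if (object@mode == "scale" && object@value <= 0)
    return("scale values must be positive")
  TRUE
})

#' Construct a Perturbation
#'
#' @param parameter Dotted configuration path of the scalar to change.
#' @param mode `"scale"` (multiply) or `"set"` (assign).
#' @param value Scale factor or new value.
#' @return A [Perturbation-class] object.
#' @examples
#' perturbation("projections.v1_lateral_inhibitory.strength", "scale", 0.9)
#' @export
perturbation <- function(parameter, mode = c("scale", "set"), value) {
  mode <- match.arg(mode)
  methods::new("Perturbation", parameter = parameter, mode = mode,
               value = as.numeric(value))
}

setMethod("show", "GCALModel", function(object) {
  g <- object@geometry
  cat("GCALModel\n")
  cat(sprintf("  retina %dx%d | LGN On/Off %dx%d | V1 %dx%d\n",
              g$n_ret, g$n_ret, g$n_lgn, g$n_lgn, g$n_v1, g$n_v1))
  cat(sprintf("  iterations trained: %d\n", iterations(object)))
  cat(sprintf("  build seed: %d\n", object@seed))
  n <- nrow(object@log$events)
  if (!is.null(n) && n > 0)
    cat(sprintf("  perturbations applied: %d\n", n))
  invisible(object)
})

setMethod("show", "OrientationMap", function(object) {
  sel <- object@selectivity[is.finite(object@selectivity)]
  cat("OrientationMap\n")
  cat(sprintf("  units: %d x %d, orientations measured: %d\n",
              nrow(object@preference), ncol(object@preference),
              length(object@orientations)))
  cat(sprintf("  median selectivity: %.3f\n", stats::median(sel)))
  invisible(object)
})

setMethod("show", "Perturbation", function(object) {
  op <- if (object@mode == "scale") "x" else ":="
  cat(sprintf("Perturbation: %s %s %g\n", object@parameter, op, object@value))
  invisible(object)
})

#' Number of completed training iterations
#' @param model A [GCALModel-class].
#' @return Integer iteration count.
#' @export
iterations <- function(model) as.integer(net_get_param(model@ptr, "iteration"))

#' Resolved configuration of a model
#' @param model A [GCALModel-class].
#' @return The configuration list the model was built with.
#' @export
modelConfig <- function(model) model@config

#' Read a live engine parameter
#'
#' Returns the current value of a tunable scalar, which may differ from the
#' built configuration after perturbations.
#'
#' @param model A [GCALModel-class].
#' @param parameter Dotted configuration path.
#' @return Numeric scalar.
#' @export
modelParameter <- function(model, parameter) {
  net_get_param(model@ptr, resolveParamPath(parameter))
}
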