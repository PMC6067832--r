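#' Build a simulator instance
#'
#' Assembles the four sheets (retina, LGN On, LGN Off, V1) and their
#' projections: fixed difference-of-Gaussians kernels from retina to LGN,
#' divisive gain-control pooling within each LGN channel, plastic afferent
#' connection fields from both LGN channels onto V1 (random weights under a
#' Gaussian envelope, jointly normalized per V1 unit), and isotropic-Gaussian
#' lateral excitatory/inhibitory fields within V1.  Homeostatic thresholds
#' start at their configured operating point.  Identical `(config, seed)`
#' pairs produce bitwise-identical models.
#'
#' @param config Configuration list from [gcalConfig()] or [loadConfig()].
#' @param seed Integer seed; initializes the R RNG used for the random
#'   afferent weights and, subsequently, the training stimulus stream.
#' @return A [GCALModel-class].
#' @examples
#' m <- buildModel(seed = 1)
#' m
#' @export
buildModel <- function(config = gcalConfig(), seed = 1L) {
  set.seed(as.integer(seed))
  geom <- computeGeometry(config)
  ptr <- net_build(geom, engineScalars(config))
  n <- net_aff_size(ptr)
  net_init_aff(ptr, stats::runif(n),
               config$projections$lgn_to_v1$envelope_sigma)
  log <- new.env(parent = emptyenv())
  log$events <- data.frame(iteration = integer(), parameter = character(),
                           mode = character(), value = numeric(),
                           stringsAsFactors = FALSE)
  methods::new("GCALModel", ptr = ptr, config = config, geometry = geom,
               seed = as.integer(seed), log = log)
}

#' Present a stimulus without learning
#'
#' Runs one full presentation (LGN step, then recurrent V1 settling) with all
#' plasticity and homeostatic adaptation frozen.  The persistent model state
#' is untouched; measurement uses separate activity buffers.
#'
#' @param model A [GCALModel-class].
#' @param image Luminance matrix in `[0, 1]` at retina resolution.
#' @return List with elements `lgn_on`, `lgn_off`, `v1` (activity matrices)
#'   and attribute `last_change` (max per-unit change on the final settle
#'   step).
#' @export
presentStimulus <- function(model, image) {
  stopifnot(all(is.finite(image)), min(image) >= 0, max(image) <= 1)
  ch <- net_present(model@ptr, asEngineImage(image), FALSE)
  out <- net_activities(model@ptr, TRUE)
  attr(out, "last_change") <- ch
  out
}

#' LGN drive for an image (linear DoG stage)
#'
#' The signed center-surround drive before gain control and rectification:
#' positive values drive the On channel, negative values the Off channel.
#'
#' @param model A [GCALModel-class].
#' @param image Luminance matrix at retina resolution.
#' @return Matrix of drive values at LGN resolution.
#' @export
lgnDrive <- function(model, image) {
  net_lgn_drive(model@ptr, asEngineImage(image))
}

# the engine stores sheets row-major; R matrices are column-major, so hand
# images over transposed (and transpose returned maps back)
asEngineImage <- function(image) as.numeric(t(image))

#' Snapshot and restore the full model state
#'
#' `modelSnapshot()` captures everything needed to reproduce the run from
#' this point: configuration, build seed, all weights, thresholds, smoothed
#' activity traces, sheet activities, iteration counter, perturbation log,
#' the live engine parameters (which may have been perturbed), and the R RNG
#' state driving the stimulus stream.  `restoreModel()` rebuilds a model from
#' a snapshot; continuing training from a restored snapshot is bit-identical
#' to an uninterrupted run.
#'
#' @param model A [GCALModel-class].
#' @return For `modelSnapshot`, a plain list of arrays and scalars.
#' @export
modelSnapshot <- function(model) {
  pars <- c("gamma_L", "gamma_S", "gc_k0", "gamma_A", "gamma_E", "gamma_I",
            "alpha_A", "alpha_E", "alpha_I", "lambda", "mu", "beta",
            "settle_steps", "slope", "lgn_scale")
  live <- vapply(pars, function(p) net_get_param(model@ptr, p), numeric(1))
  if (!exists(".Random.seed", envir = globalenv()))
    set.seed(NULL)
  list(config = model@config, seed = model@seed,
       state = net_get_state(model@ptr),
       params = as.list(live),
       events = model@log$events,
       rng_state = get(".Random.seed", envir = globalenv()))
}

#' @rdname modelSnapshot
#' @param snapshot A list produced by `modelSnapshot()`.
#' @return For `restoreModel`, a [GCALModel-class] equivalent to the
#'   snapshotted one (the global RNG is restored as well).
#' @export
restoreModel <- function(snapshot) {
  geom <- computeGeometry(snapshot$config)
  ptr <- net_build(geom, engineScalars(snapshot$config))
  net_set_state(ptr, snapshot$state)
  for (nm in names(snapshot$params))
    net_set_param(ptr, nm, snapshot$params[[nm]])
  log <- new.env(parent = emptyenv())
  log$events <- snapshot$events
  assign(".Random.seed", snapshot$rng_state, envir = globalenv())
  methods::new("GCALModel", ptr = ptr, config = snapshot$config,
               geometry = geom, seed = snapshot$seed, log = log)
}

#' Save / load a model snapshot on disk
#'
#' Snapshots are stored as a plain named list of numeric arrays (RDS); the
#' round trip is bit-exact.
#'
#' @param model A [GCALModel-class].
#' @param path File path.
#' @return `loadModel` returns the restored [GCALModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(modelSnapshot(model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) restoreModel(readRDS(path))

#' Settling convergence diagnostic
#'
#' Presents an image without learning and reports the maximum per-unit V1
#' change on the final settle step.
#'
#' @param model A [GCALModel-class].
#' @param image Luminance matrix at retina resolution.
#' @return Numeric scalar.
#' @export
settleChange <- function(model, image) {
  net_present(model@ptr, asEngineImage(image), FALSE)
}

# stable hash of the persistent engine state (for side-effect tests)
stateHash <- function(model) {
  st <- net_get_state(model@ptr)
  sum(vapply(st, function(x) sum(as.numeric(x) * seq_along(x)), numeric(1)))
}
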