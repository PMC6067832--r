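#' Default model configuration
#'
#' Returns the complete set of tunable scalars for the simulator as a nested
#' named list.  Every perturbation studied by the package is a pure override
#' of one of these values, addressed by its dotted path (for example
#' `projections.v1_lateral_inhibitory.strength`).
#'
#' Sheet densities follow the standard small GCAL configuration: retina and
#' LGN at 24 units per unit sheet length, V1 at 48, so the subcortical sheets
#' carry one quarter of the units per visual area.  Projection radii, kernel
#' widths, strengths and learning rates are the published GCAL operating
#' point; learning rates are density-independent (they are divided by the
#' connection-field size before the per-connection Hebbian increment).
#'
#' @param ... named overrides merged over the defaults, e.g.
#'   `homeostasis = list(adaptation_rate = 0)`.  Unknown names are an error.
#' @return A nested list of configuration values.
#' @examples
#' cfg <- gcalConfig()
#' cfg$projections$lgn_to_v1$learning_rate
#' @export
gcalConfig <- function(...) {
  defaults <- list(
    sheets = list(
      retina_density = 24,
      lgn_density    = 24,
      v1_density     = 48,
      area           = 1.0,
      # NULL = auto-fit so every connection field lies fully inside its
      # source sheet; a numeric value forces the bounds radius.
      lgn_radius     = NULL,
      retina_radius  = NULL
    ),
    projections = list(
      retina_to_lgn = list(
        strength       = 2.33,
        radius         = 0.375,
        sigma_center   = 0.037,
        sigma_surround = 0.148
      ),
      lgn_gain_control = list(
        strength   = 0.6,
        radius     = 0.25,
        sigma      = 0.125,
        saturation = 0.11
      ),
      lgn_to_v1 = list(
        strength       = 1.5,
        radius         = 0.27083,
        learning_rate  = 0.01,
        envelope_sigma = 0.135
      ),
      v1_lateral_excitatory = list(
        strength      = 1.7,
        radius        = 0.104,
        sigma         = 0.05,
        learning_rate = 0.0
      ),
      v1_lateral_inhibitory = list(
        strength      = 1.4,
        radius        = 0.22917,
        sigma         = 0.075,
        learning_rate = 0.03
      )
    ),
    homeostasis = list(
      target_activity = 0.024,
      adaptation_rate = 0.01,
      smoothing       = 0.991,
      threshold_init  = 0.15
    ),
    timecourse = list(
      settle_steps = 17
    ),
    output = list(
      slope = 1.0,
      lgn_scale = 0.5
    ),
    stimuli = list(
      training = list(
        n_blobs      = 2,
        sigma_minor  = 0.088388,
        aspect_ratio = 4.66667,
        peak         = 1.0
      ),
      measurement = list(
        map_sf             = 3.0,
        map_orientations   = 12,
        map_phases         = 8,
        map_contrast       = 0.8,
        histogram_sf       = 6.0,
        histogram_contrast = 0.8,
        n_bins             = 36
      )
    )
  )
  overrides <- list(...)
  if (length(overrides) == 0L) return(defaults)
  mergeConfig(defaults, overrides)
}

# recursive merge that rejects unknown keys (with a nearest-key hint)
mergeConfig <- function(base, overrides, prefix = "") {
  if (is.null(names(overrides)) && length(overrides) > 0L)
    stop("configuration overrides must be named", call. = FALSE)
  for (nm in names(overrides)) {
    path <- paste0(prefix, nm)
    if (!nm %in% names(base)) {
      near <- agrep(nm, names(base), value = TRUE, max.distance = 0.4)
      hint <- if (length(near)) paste0("; nearest valid key: '",
                                       prefix, near[1L], "'") else ""
      stop("unknown configuration key '", path, "'", hint, call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- mergeConfig(base[[nm]], overrides[[nm]],
                                prefix = paste0(path, "."))
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Read a configuration file with optional dotted-path overrides
#'
#' Loads a YAML (or JSON, which YAML subsumes) configuration file, merges it
#' over [gcalConfig()] defaults, then applies command-line style overrides of
#' the form `"projections.v1_lateral_inhibitory.strength=0.9"`.  Unknown keys
#' are rejected with the nearest valid key named.
#'
#' @param path Path to a YAML/JSON file, or `NULL` for pure defaults.
#' @param overrides Character vector of `dotted.path=value` assignments.
#' @return A resolved configuration list.
#' @export
loadConfig <- function(path = NULL, overrides = character()) {
  cfg <- gcalConfig()
  if (!is.null(path)) {
    parsed <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop("cannot parse configuration file '", path, "': ",
           conditionMessage(e), call. = FALSE))
    if (!is.null(parsed)) cfg <- mergeConfig(cfg, parsed)
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop("override must look like dotted.path=value: '", ov, "'",
           call. = FALSE)
    cfg <- setConfigPath(cfg, kv[1L], as.numeric(kv[2L]))
  }
  cfg
}

# set a scalar by dotted path, validating every component
setConfigPath <- function(cfg, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- cfg
  for (i in seq_along(keys)) {
    nm <- keys[i]
    if (!nm %in% names(node)) {
      near <- agrep(nm, names(node), value = TRUE, max.distance = 0.4)
      hint <- if (length(near)) paste0("; nearest valid key: '", near[1L], "'")
              else ""
      stop("unknown configuration key '", path, "' (at '", nm, "')", hint,
           call. = FALSE)
    }
    if (i < length(keys)) node <- node[[nm]]
  }
  expr <- paste0("cfg", paste0("[['", keys, "']]", collapse = ""))
  eval(parse(text = paste0(expr, " <- value")))
  cfg
}

getConfigPath <- function(cfg, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- cfg
  for (nm in keys) {
    if (!nm %in% names(node))
      stop("unknown configuration key '", path, "'", call. = FALSE)
    node <- node[[nm]]
  }
  node
}

# flatten the configuration into the scalar list the engine expects
engineScalars <- function(cfg) {
  p <- cfg$projections
  list(
    gamma_L      = p$retina_to_lgn$strength,
    dog_radius   = p$retina_to_lgn$radius,
    dog_sigma_c  = p$retina_to_lgn$sigma_center,
    dog_sigma_s  = p$retina_to_lgn$sigma_surround,
    gamma_S      = p$lgn_gain_control$strength,
    gc_radius    = p$lgn_gain_control$radius,
    gc_sigma     = p$lgn_gain_control$sigma,
    gc_k0        = p$lgn_gain_control$saturation,
    gamma_A      = p$lgn_to_v1$strength,
    aff_radius   = p$lgn_to_v1$radius,
    alpha_A      = p$lgn_to_v1$learning_rate,
    gamma_E      = p$v1_lateral_excitatory$strength,
    exc_radius   = p$v1_lateral_excitatory$radius,
    exc_sigma    = p$v1_lateral_excitatory$sigma,
    alpha_E      = p$v1_lateral_excitatory$learning_rate,
    gamma_I      = p$v1_lateral_inhibitory$strength,
    inh_radius   = p$v1_lateral_inhibitory$radius,
    inh_sigma    = p$v1_lateral_inhibitory$sigma,
    alpha_I      = p$v1_lateral_inhibitory$learning_rate,
    mu           = cfg$homeostasis$target_activity,
    lambda       = cfg$homeostasis$adaptation_rate,
    beta         = cfg$homeostasis$smoothing,
    theta_init   = cfg$homeostasis$threshold_init,
    settle_steps = cfg$timecourse$settle_steps,
    slope        = cfg$output$slope,
    lgn_scale    = cfg$output$lgn_scale
  )
}

# sheet geometry: V1 spans the unit visual area; LGN and retina bounds are
# enlarged (to a whole number of grid steps) so that no connection field is
# truncated at a sheet edge.
computeGeometry <- function(cfg) {
  s <- cfg$sheets
  v1_r <- s$area / 2
  n_v1 <- round(2 * v1_r * s$v1_density)
  v1_step <- 2 * v1_r / n_v1
  lgn_step <- 1 / s$lgn_density
  if (is.null(s$lgn_radius)) {
    need <- (v1_r - v1_step / 2) + cfg$projections$lgn_to_v1$radius
    half <- ceiling(need / lgn_step + 0.5)
  } else {
    half <- round(s$lgn_radius / lgn_step)
  }
  n_lgn <- 2L * as.integer(half)
  lgn_r <- half * lgn_step
  ret_step <- 1 / s$retina_density
  if (abs(ret_step - lgn_step) > 1e-12)
    stop("retina and LGN densities must match (shared grid for the DoG filter)")
  dog_hw <- floor(cfg$projections$retina_to_lgn$radius / lgn_step + 1e-9)
  if (is.null(s$retina_radius)) {
    half_ret <- half + dog_hw
  } else {
    half_ret <- round(s$retina_radius / ret_step)
  }
  n_ret <- 2L * as.integer(half_ret)
  ret_r <- half_ret * ret_step
  list(n_ret = as.integer(n_ret), n_lgn = as.integer(n_lgn),
       n_v1 = as.integer(n_v1), ret_r = ret_r, lgn_r = lgn_r, v1_r = v1_r,
       ret_lgn_off = as.integer(half_ret - half))
}
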