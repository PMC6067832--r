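# mapping from dotted configuration paths to live engine parameters
paramPathTable <- function() {
  c("projections.retina_to_lgn.strength"            = "gamma_L",
    "projections.lgn_gain_control.strength"         = "gamma_S",
    "projections.lgn_gain_control.saturation"       = "gc_k0",
    "projections.lgn_to_v1.strength"                = "gamma_A",
    "projections.lgn_to_v1.learning_rate"           = "alpha_A",
    "projections.v1_lateral_excitatory.strength"    = "gamma_E",
    "projections.v1_lateral_excitatory.learning_rate" = "alpha_E",
    "projections.v1_lateral_inhibitory.strength"    = "gamma_I",
    "projections.v1_lateral_inhibitory.learning_rate" = "alpha_I",
    "homeostasis.target_activity"                   = "mu",
    "homeostasis.adaptation_rate"                   = "lambda",
    "homeostasis.smoothing"                         = "beta",
    "timecourse.settle_steps"                       = "settle_steps")
}

resolveParamPath <- function(path) {
  tab <- paramPathTable()
  if (!path %in% names(tab))
    stop("unknown parameter path '", path, "'; valid paths:\n  ",
         paste(names(tab), collapse = "\n  "), call. = FALSE)
  unname(tab[path])
}

#' Apply a perturbation to a live model
#'
#' Changes exactly one scalar of the running model (`scale`: multiply;
#' `set`: assign).  Weights, thresholds and activity traces are untouched;
#' the change is stamped into the model's perturbation log with the current
#' iteration.
#'
#' @param model A [GCALModel-class]; modified in place.
#' @param spec A [Perturbation-class] (see [perturbation()]), or a list of
#'   them.
#' @return The model, invisibly.
#' @examples
#' m <- buildModel(seed = 1)
#' applyPerturbation(m,
#'   perturbation("projections.v1_lateral_inhibitory.strength", "scale", 0.9))
#' modelParameter(m, "projections.v1_lateral_inhibitory.strength")
#' @export
applyPerturbation <- function(model, spec) {
  if (is.list(spec)) {
    for (s in spec) applyPerturbation(model, s)
    return(invisible(model))
  }
  stopifnot(methods::is(spec, "Perturbation"))
  nm <- resolveParamPath(spec@parameter)
  old <- net_get_param(model@ptr, nm)
  new <- if (spec@mode == "scale") old * spec@value else spec@value
  net_set_param(model@ptr, nm, new)
  model@log$events <- rbind(model@log$events,
                            data.frame(iteration = iterations(model),
                                       parameter = spec@parameter,
                                       mode = spec@mode, value = spec@value,
                                       stringsAsFactors = FALSE))
  invisible(model)
}

#' Registry of named experiment protocols
#'
#' Each protocol is a pre-training phase followed by a perturbed phase.  The
#' registry covers the unmodified control, the chronic and first-episode
#' (FES) best-fit models, the alternative single- and double-change models
#' B-G, and the parameter sweeps of the broader model classes.
#'
#' * `unmodified` - no perturbation, trained straight through.
#' * `chronic_best` - 10% reduced V1 lateral inhibition plus a tripled
#'   LGN-to-V1 afferent learning rate.
#' * `fes_best` - 15% reduced retina-to-LGN and LGN-to-V1 strengths.
#' * `model_b` - 25% increased V1 lateral excitation.
#' * `model_c` - 25% reduced V1 lateral inhibition.
#' * `model_d` - 20% increased lateral excitation + excitatory learning
#'   rate 0.01.
#' * `model_e` - 10% reduced lateral inhibition + excitatory learning
#'   rate 0.01.
#' * `model_f` - afferent learning rate 0.03 alone.
#' * `model_g` - FES afferent reduction + afferent learning rate 0.03.
#'
#' @return Named list; each element has `label` and `perturbations` (list of
#'   [Perturbation-class]).
#' @export
gcalProtocols <- function() {
  P <- perturbation
  list(
    unmodified = list(label = "unmodified control", perturbations = list()),
    chronic_best = list(
      label = "chronic best fit: 10% reduced V1 lateral inhibition + tripled afferent learning rate",
      perturbations = list(
        P("projections.v1_lateral_inhibitory.strength", "scale", 0.90),
        P("projections.lgn_to_v1.learning_rate", "scale", 3))),
    fes_best = list(
      label = "FES best fit: 15% reduced retinal and LGN efferent strength",
      perturbations = list(
        P("projections.retina_to_lgn.strength", "scale", 0.85),
        P("projections.lgn_to_v1.strength", "scale", 0.85))),
    model_b = list(
      label = "25% increased V1 lateral excitation",
      perturbations = list(
        P("projections.v1_lateral_excitatory.strength", "scale", 1.25))),
    model_c = list(
      label = "25% reduced V1 lateral inhibition",
      perturbations = list(
        P("projections.v1_lateral_inhibitory.strength", "scale", 0.75))),
    model_d = list(
      label = "20% increased excitation + excitatory learning rate 0.01",
      perturbations = list(
        P("projections.v1_lateral_excitatory.strength", "scale", 1.20),
        P("projections.v1_lateral_excitatory.learning_rate", "set", 0.01))),
    model_e = list(
      label = "10% reduced inhibition + excitatory learning rate 0.01",
      perturbations = list(
        P("projections.v1_lateral_inhibitory.strength", "scale", 0.90),
        P("projections.v1_lateral_excitatory.learning_rate", "set", 0.01))),
    model_f = list(
      label = "afferent learning rate 0.03 alone",
      perturbations = list(
        P("projections.lgn_to_v1.learning_rate", "set", 0.03))),
    model_g = list(
      label = "15% reduced afferents + afferent learning rate 0.03",
      perturbations = list(
        P("projections.retina_to_lgn.strength", "scale", 0.85),
        P("projections.lgn_to_v1.strength", "scale", 0.85),
        P("projections.lgn_to_v1.learning_rate", "set", 0.03)))
  )
}

#' Parameter sweeps over the broader model classes
#'
#' Generates the one-parameter sweep protocols: lateral excitation and
#' inhibition changed by 10-50%, homeostatic adaptation rate reduced by up
#' to 90%, excitatory learning rate raised up to 0.2, LGN gain control
#' reduced by 25-75%, and joint retinal/LGN afferent reductions of 10-50%.
#'
#' @return Named list in the same shape as [gcalProtocols()].
#' @export
table2Sweeps <- function() {
  P <- perturbation
  out <- list()
  for (f in c(1.10, 1.20, 1.25, 1.50))
    out[[sprintf("exc_up_%d", round(100 * (f - 1)))]] <- list(
      label = sprintf("%d%% increased V1 lateral excitation", round(100 * (f - 1))),
      perturbations = list(
        P("projections.v1_lateral_excitatory.strength", "scale", f)))
  for (f in c(0.90, 0.80, 0.75, 0.50))
    out[[sprintf("inh_down_%d", round(100 * (1 - f)))]] <- list(
      label = sprintf("%d%% reduced V1 lateral inhibition", round(100 * (1 - f))),
      perturbations = list(
        P("projections.v1_lateral_inhibitory.strength", "scale", f)))
  for (f in c(0.50, 0.25, 0.10))
    out[[sprintf("homeo_down_%d", round(100 * (1 - f)))]] <- list(
      label = sprintf("%d%% reduced homeostatic adaptation rate", round(100 * (1 - f))),
      perturbations = list(
        P("homeostasis.adaptation_rate", "scale", f)))
  for (v in c(0.01, 0.02, 0.1, 0.2))
    out[[sprintf("exc_lr_%g", v)]] <- list(
      label = sprintf("excitatory learning rate %g", v),
      perturbations = list(
        P("projections.v1_lateral_excitatory.learning_rate", "set", v)))
  for (f in c(0.75, 0.50, 0.25))
    out[[sprintf("gc_down_%d", round(100 * (1 - f)))]] <- list(
      label = sprintf("%d%% reduced LGN contrast gain control", round(100 * (1 - f))),
      perturbations = list(
        P("projections.lgn_gain_control.strength", "scale", f)))
  for (f in c(0.90, 0.85, 0.75, 0.50))
    out[[sprintf("aff_down_%d", round(100 * (1 - f)))]] <- list(
      label = sprintf("%d%% reduced retinal and LGN efferent strength", round(100 * (1 - f))),
      perturbations = list(
        P("projections.retina_to_lgn.strength", "scale", f),
        P("projections.lgn_to_v1.strength", "scale", f)))
  out
}

#' Run a named (or fully specified) experiment protocol
#'
#' Pre-trains the default model, applies the protocol's perturbations, trains
#' the perturbed phase, and takes the standard measurements (contrast
#' response battery, orientation map, tuning histogram).  Passing a
#' pre-trained `base` snapshot skips the pre-training phase, so seed-matched
#' protocol pairs can branch from the same developmental history (restoring
#' the snapshot also restores the RNG, so both branches see the identical
#' stimulus stream).
#'
#' @param protocol Protocol name in [gcalProtocols()] / [table2Sweeps()], or
#'   a list with elements `label` and `perturbations`.
#' @param seed Build seed (ignored when `base` is given).
#' @param pretrain Iterations before the perturbation.
#' @param post Iterations after the perturbation.
#' @param base Optional snapshot from [modelSnapshot()] of a pre-trained
#'   unperturbed model.
#' @param measure Take measurements after training (set `FALSE` to get just
#'   the trained model).
#' @param config Configuration for a fresh build.
#' @return List: `protocol`, `label`, `model`, `contrast_response`,
#'   `orientation_map`, `tuning`, `phases`.
#' @export
runProtocol <- function(protocol, seed = 1L, pretrain = 10000, post = 10000,
                        base = NULL, measure = TRUE, config = gcalConfig()) {
  if (is.character(protocol)) {
    reg <- c(gcalProtocols(), table2Sweeps())
    if (!protocol %in% names(reg))
      stop("unknown protocol '", protocol, "'; registered: ",
           paste(names(reg), collapse = ", "), call. = FALSE)
    name <- protocol
    protocol <- reg[[protocol]]
  } else name <- protocol$label
  if (is.null(base)) {
    model <- buildModel(config, seed)
    trainModel(model, pretrain)
  } else {
    model <- restoreModel(base)
  }
  applyPerturbation(model, protocol$perturbations)
  trainModel(model, post)
  out <- list(protocol = name, label = protocol$label, model = model,
              phases = data.frame(
                phase = c("pretrain", "perturbed"),
                iterations = c(iterations(model) - post, post)))
  if (measure) {
    out$contrast_response <- contrastResponse(model)
    diag <- tuningDiagnostics(model)
    out$orientation_map <- diag$map
    out$tuning <- diag
  }
  out
}

#' Sequential first-episode-then-chronic protocol
#'
#' Models the clinical time course in one run: normal development, an acute
#' phase with 15% reduced retinal and LGN efferent strengths, normalization
#' of those strengths (keeping every synaptic weight learned during the
#' acute phase, as treatment normalizes drive but not experience), then the
#' chronic perturbation (10% reduced V1 lateral inhibition plus tripled
#' afferent learning rate) for the remaining iterations.
#'
#' @param seed Build seed (ignored when `base` is given).
#' @param pretrain Iterations of normal development (10,000 or 20,000 in the
#'   full protocol).
#' @param fes_iters Acute-phase iterations (default 1,000).
#' @param chronic_iters Chronic-phase iterations (default 9,000).
#' @param base Optional pre-trained snapshot, as in [runProtocol()].
#' @param config Configuration for a fresh build.
#' @return List: `model`, `fes_checkpoint` (contrast response + tuning after
#'   the acute phase), `final` (same after the chronic phase), and
#'   `restored_strengths` (the two afferent strengths after normalization).
#' @export
sequentialProtocol <- function(seed = 1L, pretrain = 10000, fes_iters = 1000,
                               chronic_iters = 9000, base = NULL,
                               config = gcalConfig()) {
  if (is.null(base)) {
    model <- buildModel(config, seed)
    trainModel(model, pretrain)
  } else {
    model <- restoreModel(base)
    config <- model@config
  }
  base_ret <- config$projections$retina_to_lgn$strength
  base_aff <- config$projections$lgn_to_v1$strength
  applyPerturbation(model, gcalProtocols()$fes_best$perturbations)
  trainModel(model, fes_iters)
  fes_cr <- contrastResponse(model)
  fes_tuning <- tuningDiagnostics(model)
  # normalize afferent strengths to baseline; learned weights untouched
  applyPerturbation(model, list(
    perturbation("projections.retina_to_lgn.strength", "set", base_ret),
    perturbation("projections.lgn_to_v1.strength", "set", base_aff)))
  restored <- c(
    retina_to_lgn = modelParameter(model, "projections.retina_to_lgn.strength"),
    lgn_to_v1 = modelParameter(model, "projections.lgn_to_v1.strength"))
  applyPerturbation(model, gcalProtocols()$chronic_best$perturbations)
  trainModel(model, chronic_iters)
  final_cr <- contrastResponse(model)
  final_tuning <- tuningDiagnostics(model)
  cr40 <- function(cr) cr[cr$contrast == 0.4, ]
  list(model = model,
       fes_checkpoint = list(contrast_response = fes_cr,
                             contrast40 = cr40(fes_cr),
                             tuning = fes_tuning),
       final = list(contrast_response = final_cr,
                    contrast40 = cr40(final_cr),
                    tuning = final_tuning),
       restored_strengths = restored)
}

#' Compare two contrast-response tables
#'
#' @param a,b Data frames from [contrastResponse()] over the same battery.
#' @return Data frame with the per-stimulus difference in mean activation
#'   (`a - b`) and the relative change.
#' @export
compareContrastResponse <- function(a, b) {
  stopifnot(nrow(a) == nrow(b), all(a$sf == b$sf),
            all(a$contrast == b$contrast))
  data.frame(sf = a$sf, contrast = a$contrast,
             mean_a = a$mean_activation, mean_b = b$mean_activation,
             diff = a$mean_activation - b$mean_activation,
             rel = ifelse(b$mean_activation > 0,
                          a$mean_activation / b$mean_activation - 1, NA))
}
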