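test_that("perturbations change exactly the named scalar", {
  m <- smallModel(seed = 1)
  w0 <- gcalsim:::net_get_state(m@ptr)
  g0 <- modelParameter(m, "projections.v1_lateral_inhibitory.strength")
  applyPerturbation(m,
    perturbation("projections.v1_lateral_inhibitory.strength", "scale", 0.9))
  expect_equal(modelParameter(m, "projections.v1_lateral_inhibitory.strength"),
               0.9 * g0)
  # weights, thresholds, traces bitwise unchanged
  expect_identical(gcalsim:::net_get_state(m@ptr), w0)
  # logged with an iteration stamp
  expect_equal(nrow(m@log$events), 1)
  expect_equal(m@log$events$iteration, 0)
})

test_that("scaling the afferent learning rate by 3 gives 0.03", {
  m <- smallModel(seed = 1)
  applyPerturbation(m,
    perturbation("projections.lgn_to_v1.learning_rate", "scale", 3))
  expect_equal(modelParameter(m, "projections.lgn_to_v1.learning_rate"), 0.03)
})

test_that("identity and inverse perturbations restore the exact state", {
  m <- smallModel(seed = 2)
  snap0 <- gcalsim:::net_get_state(m@ptr)
  p <- "projections.retina_to_lgn.strength"
  v0 <- modelParameter(m, p)
  applyPerturbation(m, perturbation(p, "scale", 1.0))
  expect_identical(modelParameter(m, p), v0)
  applyPerturbation(m, perturbation(p, "scale", 0.85))
  applyPerturbation(m, perturbation(p, "set", v0))
  expect_identical(modelParameter(m, p), v0)
  expect_identical(gcalsim:::net_get_state(m@ptr), snap0)
})

test_that("unknown parameter paths fail listing the valid ones", {
  m <- smallModel(seed = 1)
  expect_error(applyPerturbation(m, perturbation("no.such.path", "scale", 2)),
               "valid paths")
  expect_error(perturbation("x", "scale", -1), "positive")
})

test_that("the registry defines the study's named models", {
  reg <- gcalProtocols()
  expect_true(all(c("unmodified", "chronic_best", "fes_best", "model_b",
                    "model_c", "model_d", "model_e", "model_f", "model_g")
                  %in% names(reg)))
  ch <- reg$chronic_best$perturbations
  expect_equal(ch[[1]]@parameter, "projections.v1_lateral_inhibitory.strength")
  expect_equal(ch[[1]]@value, 0.90)
  expect_equal(ch[[2]]@parameter, "projections.lgn_to_v1.learning_rate")
  expect_equal(ch[[2]]@value, 3)
  fe <- reg$fes_best$perturbations
  expect_equal(vapply(fe, function(p) p@value, numeric(1)), c(0.85, 0.85))
  sw <- table2Sweeps()
  # sweep classes: excitation, inhibition, homeostasis, excitatory learning,
  # gain control, afferents
  expect_true(any(grepl("^exc_up", names(sw))))
  expect_true(any(grepl("^inh_down", names(sw))))
  expect_true(any(grepl("^homeo_down", names(sw))))
  expect_true(any(grepl("^exc_lr", names(sw))))
  expect_true(any(grepl("^gc_down", names(sw))))
  expect_true(any(grepl("^aff_down", names(sw))))
  expect_error(runProtocol("no_such_model", pretrain = 0, post = 0),
               "registered")
})

test_that("seed-matched protocol branches replay the same stimulus stream", {
  m <- smallModel(seed = 31)
  trainModel(m, 30)
  snap <- modelSnapshot(m)
  r1 <- runProtocol("unmodified", base = snap, post = 30)
  r2 <- runProtocol("unmodified", base = snap, post = 30)
  expect_identical(r1$contrast_response, r2$contrast_response)
  expect_identical(gcalsim:::net_get_state(r1$model@ptr),
                   gcalsim:::net_get_state(r2$model@ptr))
  # a perturbed branch from the same snapshot sees identical stimuli,
  # so differences are attributable to the perturbation alone
  r3 <- runProtocol("fes_best", base = snap, post = 30)
  expect_equal(modelParameter(r3$model,
                              "projections.retina_to_lgn.strength"),
               0.85 * snap$config$projections$retina_to_lgn$strength)
})

test_that("the sequential protocol restores strengths but not weights", {
  m <- smallModel(seed = 32)
  trainModel(m, 30)
  snap <- modelSnapshot(m)
  res <- sequentialProtocol(base = snap, fes_iters = 20, chronic_iters = 20)
  cfg <- snap$config
  expect_equal(unname(res$restored_strengths["retina_to_lgn"]),
               cfg$projections$retina_to_lgn$strength)
  expect_equal(unname(res$restored_strengths["lgn_to_v1"]),
               cfg$projections$lgn_to_v1$strength)
  # chronic perturbation active at the end
  expect_equal(modelParameter(res$model,
                              "projections.lgn_to_v1.learning_rate"), 0.03)
  expect_equal(nrow(res$final$contrast40), 2)  # both SFs at 40% contrast
  expect_named(res$fes_checkpoint,
               c("contrast_response", "contrast40", "tuning"))
})

test_that("strength normalization alone does not touch learned weights", {
  m <- smallModel(seed = 33)
  trainModel(m, 20)
  applyPerturbation(m, gcalProtocols()$fes_best$perturbations)
  trainModel(m, 20)
  w_before <- gcalsim:::net_get_state(m@ptr)
  cfg <- modelConfig(m)
  applyPerturbation(m, list(
    perturbation("projections.retina_to_lgn.strength", "set",
                 cfg$projections$retina_to_lgn$strength),
    perturbation("projections.lgn_to_v1.strength", "set",
                 cfg$projections$lgn_to_v1$strength)))
  expect_identical(gcalsim:::net_get_state(m@ptr), w_before)
})
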