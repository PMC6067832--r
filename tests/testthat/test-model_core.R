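test_that("identical (config, seed) pairs build bitwise-identical models", {
  m1 <- smallModel(seed = 42)
  m2 <- smallModel(seed = 42)
  expect_identical(gcalsim:::net_get_state(m1@ptr),
                   gcalsim:::net_get_state(m2@ptr))
  m3 <- smallModel(seed = 43)
  expect_false(identical(gcalsim:::net_get_state(m1@ptr)$aff_w,
                         gcalsim:::net_get_state(m3@ptr)$aff_w))
})

test_that("default geometry has a 48x48 V1 over 24-density subcortex", {
  m <- fixture("default_untrained", buildModel(seed = 1))
  g <- m@geometry
  expect_equal(g$n_v1, 48)
  # 24 units per unit sheet length; the central unit area holds 24x24
  expect_equal(g$n_lgn / (2 * g$lgn_r), 24)
})

test_that("plastic projections are normalized to unit weight sums at build", {
  m <- fixture("default_untrained", buildModel(seed = 1))
  st <- gcalsim:::net_struct(m@ptr)
  for (p in list(st$aff, st$exc, st$inh)) {
    sums <- vapply(seq_len(length(p$off) - 1), function(i) {
      if (p$off[i + 1] > p$off[i]) sum(p$w[(p$off[i] + 1):p$off[i + 1]])
      else 1
    }, numeric(1))
    expect_lt(max(abs(sums - 1)), 1e-9)
  }
})

test_that("a connection field larger than its source sheet is rejected", {
  cfg <- smallConfig()
  cfg$sheets$lgn_radius <- 0.5   # too tight for the afferent radius
  expect_error(buildModel(cfg, seed = 1), "lgn_to_v1")
})

test_that("the DoG stage is balanced and has center-surround structure", {
  m <- fixture("small1", smallModel(seed = 1))
  n <- m@geometry$n_ret
  # uniform image: zero drive
  expect_lt(max(abs(lgnDrive(m, matrix(0.5, n, n)))), 1e-12)
  # single bright pixel: positive at the center, negative annulus
  img <- matrix(0, n, n)
  cr <- ceiling(n / 2)
  img[cr, cr] <- 1
  d <- lgnDrive(m, img)
  pk <- which(d == max(d), arr.ind = TRUE)[1, ]
  expect_gt(max(d), 0)
  ring <- d[pk[1] + (-2:2), pk[2] + (-2:2)]
  expect_lt(min(ring), 0)
  # On drive for I equals Off drive (negated) for 1 - I
  set.seed(3)
  img2 <- matrix(runif(n * n), n, n)
  d1 <- lgnDrive(m, img2)
  d2 <- lgnDrive(m, 1 - img2)
  expect_equal(d1, -d2, tolerance = 1e-12)
})

test_that("gain control compresses contrast and is monotone in its strength", {
  m <- smallModel(seed = 2)
  resp <- function(contrast) {
    a <- presentStimulus(m, gratingStimulus(3, contrast, model = m))
    mean(a$lgn_on)
  }
  r80 <- resp(0.8); r20 <- resp(0.2)
  expect_lt(r80 / r20, 4)            # compressive with gain control on
  # halving gain-control strength cannot decrease the response
  gcalsim:::net_set_param(m@ptr, "gamma_S",
                          0.5 * gcalsim:::net_get_param(m@ptr, "gamma_S"))
  expect_gte(resp(0.8), r80)
  # with gain control off, response is linear in contrast (below ceiling)
  gcalsim:::net_set_param(m@ptr, "gamma_S", 0)
  lo <- resp(0.005); hi <- resp(0.02)
  expect_equal(hi / lo, 4, tolerance = 1e-6)
  # zero-contrast grating: silent LGN
  a0 <- presentStimulus(m, gratingStimulus(3, 0, model = m))
  expect_equal(max(a0$lgn_on), 0)
  expect_equal(max(a0$lgn_off), 0)
})

test_that("V1 settling is silent without input and matches the closed form", {
  m <- smallModel(seed = 1)
  n <- m@geometry$n_ret
  a <- presentStimulus(m, matrix(0.5, n, n))
  expect_equal(max(a$v1), 0)
  # single V1 unit, no lateral connections: f(gamma_A x - theta)
  cfg <- tinyConfig()
  cfg$sheets$v1_density <- 1
  cfg$projections$v1_lateral_excitatory$strength <- 0
  cfg$projections$v1_lateral_inhibitory$strength <- 0
  m1 <- buildModel(cfg, seed = 4)
  img <- gratingStimulus(3, 0.8, model = m1)
  out <- presentStimulus(m1, img)
  ref <- referencePresent(m1, img)
  gamma_A <- gcalsim:::net_get_param(m1@ptr, "gamma_A")
  theta <- gcalsim:::net_get_state(m1@ptr)$theta
  closed <- min(max(gamma_A * ref$affdrive - theta, 0), 1)
  expect_equal(as.numeric(out$v1), closed, tolerance = 1e-12)
})

test_that("a full presentation matches a naive double-loop reference", {
  for (seed in c(1, 2)) {
    m <- buildModel(tinyConfig(), seed = seed)
    set.seed(seed + 100)
    img <- trainingStimulus(m)
    got <- presentStimulus(m, img)
    ref <- referencePresent(m, img)
    expect_equal(as.numeric(t(got$lgn_on)), ref$lgn_on, tolerance = 1e-9)
    expect_equal(as.numeric(t(got$lgn_off)), ref$lgn_off, tolerance = 1e-9)
    expect_equal(as.numeric(t(got$v1)), ref$v1, tolerance = 1e-9)
  }
})

test_that("all activities stay inside [0, 1] for arbitrary valid images", {
  m <- fixture("small1", smallModel(seed = 1))
  n <- m@geometry$n_ret
  set.seed(9)
  for (i in 1:5) {
    img <- matrix(runif(n * n), n, n)
    a <- presentStimulus(m, img)
    for (x in a) {
      expect_gte(min(x), 0)
      expect_lte(max(x), 1)
    }
  }
})

test_that("the untrained model responds equally to orthogonal gratings", {
  m <- fixture("default_untrained", buildModel(seed = 1))
  r1 <- mean(presentStimulus(m, gratingStimulus(3, 0.8, pi / 2,
                                                model = m))$v1)
  r2 <- mean(presentStimulus(m, gratingStimulus(3, 0.8, 0, model = m))$v1)
  expect_lt(abs(r1 - r2) / max(r1, r2), 0.05)
})

test_that("the settling diagnostic reports a finite final-step change", {
  m <- fixture("small1", smallModel(seed = 1))
  ch <- settleChange(m, gratingStimulus(3, 0.8, model = m))
  expect_true(is.finite(ch))
  expect_gte(ch, 0)
})
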