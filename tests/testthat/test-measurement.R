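test_that("vector summation recovers hand-built tuning exactly", {
  oris <- seq(0, pi, length.out = 9)[1:8]
  # every unit responds only at pi/2: preference pi/2, selectivity 1
  resp <- array(0, dim = c(3, 3, 8))
  resp[, , which.min(abs(oris - pi / 2))] <- 0.7
  vs <- orientationVectorSum(resp, oris)
  expect_equal(as.numeric(vs$preference), rep(pi / 2, 9), tolerance = 1e-6)
  expect_equal(as.numeric(vs$selectivity), rep(1, 9), tolerance = 1e-12)
  # equal response at all orientations: selectivity 0
  resp[] <- 0.3
  vs <- orientationVectorSum(resp, oris)
  expect_lt(max(vs$selectivity), 1e-12)
  # silent unit: preference undefined
  resp[] <- 0; resp[1, 1, 2] <- 1
  vs <- orientationVectorSum(resp, oris)
  expect_true(is.na(vs$preference[2, 2]))
  expect_equal(vs$preference[1, 1], oris[2])
})

test_that("excess kurtosis matches analytic references", {
  # uniform distribution on [0, pi): excess kurtosis -1.2
  x <- seq(0, pi, length.out = 20001)[-20001]
  expect_equal(weightedExcessKurtosis(x), -1.2, tolerance = 1e-3)
  # narrow normal sample: approximately 0
  set.seed(2)
  g <- rnorm(200000, pi / 2, 0.1)
  expect_equal(weightedExcessKurtosis(g), 0, tolerance = 0.05)
  # weights replicate observations
  x2 <- c(1, 2, 2, 2, 5)
  expect_equal(weightedExcessKurtosis(c(1, 2, 5), c(1, 3, 1)),
               weightedExcessKurtosis(x2))
})

test_that("tuning histograms locate the peak and diagnose bimodality", {
  oris <- seq(0, pi, length.out = 13)[1:12]
  map <- methods::new("OrientationMap",
                      preference = matrix(NA_real_, 1, 1),
                      selectivity = matrix(0, 1, 1),
                      responses = array(0, c(1, 1, 12)),
                      orientations = oris)
  # narrow concentration near pi/2
  set.seed(4)
  ang <- matrix(rnorm(400, pi / 2, 0.07) %% pi, 20, 20)
  map@preference <- ang
  w <- matrix(1, 20, 20)
  h <- tuningHistogram(map, activity = w, n_bins = 36)
  expect_lt(abs(h$peak_orientation - pi / 2), pi / 36 + 1e-9)
  expect_false(h$bimodal)
  # two equal narrow modes flanking pi/2 -> bimodal
  ang2 <- matrix(c(rnorm(200, pi / 2 - 0.5, 0.05),
                   rnorm(200, pi / 2 + 0.5, 0.05)) %% pi, 20, 20)
  map@preference <- ang2
  h2 <- tuningHistogram(map, activity = w, n_bins = 36)
  expect_true(h2$bimodal)
  expect_gt(h2$excess_kurtosis, h$excess_kurtosis - 5)  # both defined
  # all-zero weights are an error, not a silent zero histogram
  expect_error(tuningHistogram(map, activity = 0 * w), "zero")
})

test_that("histogram mass equals the summed activation weights", {
  oris <- seq(0, pi, length.out = 9)[1:8]
  map <- methods::new("OrientationMap",
                      preference = matrix(runif(64, 0, pi - 1e-6), 8, 8),
                      selectivity = matrix(0.5, 8, 8),
                      responses = array(0.1, c(8, 8, 8)),
                      orientations = oris)
  act <- matrix(runif(64), 8, 8)
  h <- tuningHistogram(map, activity = act, n_bins = 18)
  expect_equal(sum(h$counts), sum(act), tolerance = 1e-12)
  expect_equal(h$total_weight, sum(act))
})

test_that("zero-contrast stimuli produce zero mean activation", {
  m <- fixture("small_trained_400", {
    mm <- smallModel(seed = 8)
    trainModel(mm, 400)
    mm
  })
  bat <- testBattery("cs")
  bat$contrast <- 0
  cr <- contrastResponse(m, bat[1:2, ])
  expect_equal(cr$mean_activation, c(0, 0))
  expect_equal(cr$max_activation, c(0, 0))
})

test_that("contrast-response tables satisfy mean <= max >= 0", {
  m <- fixture("small_trained_400", {
    mm <- smallModel(seed = 8)
    trainModel(mm, 400)
    mm
  })
  cr <- fixture("small_cr", contrastResponse(m))
  expect_true(all(cr$mean_activation >= 0))
  expect_true(all(cr$max_activation >= cr$mean_activation))
})

test_that("measurement leaves the model state untouched", {
  m <- fixture("small_trained_400", {
    mm <- smallModel(seed = 8)
    trainModel(mm, 400)
    mm
  })
  before <- gcalsim:::net_get_state(m@ptr)
  rng_before <- .Random.seed
  invisible(contrastResponse(m))
  invisible(orientationMap(m))
  expect_identical(gcalsim:::net_get_state(m@ptr), before)
  expect_identical(.Random.seed, rng_before)
})

test_that("an untrained isotropic model has near-zero median selectivity", {
  m <- smallModel(seed = 21)
  map <- orientationMap(m)
  expect_lt(median(map@selectivity), 0.1)
})

test_that("map smoothness is zero for a constant map and large for noise", {
  mk <- function(p) methods::new("OrientationMap", preference = p,
                                 selectivity = 0 * p + 1,
                                 responses = array(1, c(nrow(p), ncol(p), 1)),
                                 orientations = pi / 2)
  expect_equal(mapSmoothness(mk(matrix(1, 10, 10))), 0)
  set.seed(6)
  noisy <- mapSmoothness(mk(matrix(runif(400, 0, pi), 20, 20)))
  expect_gt(noisy, pi / 6)   # random maps are far from smooth
})
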