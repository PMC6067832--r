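#' Contrast-response measurement
#'
#' Presents each grating in a battery with plasticity and homeostatic
#' adaptation frozen and records the mean and max activation over all V1
#' units.  The model state is unchanged afterwards.
#'
#' @param model A trained [GCALModel-class].
#' @param battery Data frame from [testBattery()] (columns `sf`, `contrast`,
#'   `orientation`, `phase`).
#' @return Data frame: `sf`, `contrast`, `orientation`, `phase`,
#'   `mean_activation`, `max_activation`, `sd_activation`.
#' @export
contrastResponse <- function(model, battery = testBattery("cs")) {
  res <- battery
  res$mean_activation <- NA_real_
  res$max_activation <- NA_real_
  res$sd_activation <- NA_real_
  for (i in seq_len(nrow(battery))) {
    img <- gratingStimulus(battery$sf[i], battery$contrast[i],
                           battery$orientation[i], battery$phase[i],
                           model = model)
    act <- presentStimulus(model, img)$v1
    res$mean_activation[i] <- mean(act)
    res$max_activation[i] <- max(act)
    res$sd_activation[i] <- stats::sd(act)
  }
  res
}

#' Orientation preference and selectivity map
#'
#' Presents the orientation-map battery (full-contrast gratings over a set of
#' orientations and phases), aggregates each unit's response over phases by
#' the maximum, and computes per-unit preference and selectivity by vector
#' summation on the doubled-angle circle:
#' `z = sum_o R_o exp(2 i theta_o)`, preference `Arg(z) / 2` (mod pi),
#' selectivity `|z| / sum_o R_o`.  Units with no response to any orientation
#' get `NA` preference and are excluded from downstream histograms.
#'
#' @param model A trained [GCALModel-class].
#' @return An [OrientationMap-class].
#' @export
orientationMap <- function(model) {
  ms <- model@config$stimuli$measurement
  bat <- testBattery("map", model@config)
  oris <- sort(unique(bat$orientation))
  nv <- model@geometry$n_v1
  resp <- array(0, dim = c(nv, nv, length(oris)))
  for (k in seq_along(oris)) {
    sub <- bat[bat$orientation == oris[k], ]
    acc <- matrix(0, nv, nv)
    for (i in seq_len(nrow(sub))) {
      img <- gratingStimulus(sub$sf[i], sub$contrast[i], sub$orientation[i],
                             sub$phase[i], model = model)
      acc <- pmax(acc, presentStimulus(model, img)$v1)
    }
    resp[, , k] <- acc
  }
  vs <- orientationVectorSum(resp, oris)
  methods::new("OrientationMap", preference = vs$preference,
               selectivity = vs$selectivity,
               responses = resp, orientations = oris)
}

#' Preference and selectivity by vector summation over orientation
#'
#' Doubles each orientation angle (orientation is a circular variable with
#' period pi), sums the per-orientation responses as unit vectors scaled by
#' response, and halves the resultant angle.  Selectivity is the resultant
#' length divided by the summed response, so a unit responding to exactly one
#' orientation has selectivity 1 and an untuned unit has selectivity 0.
#'
#' @param responses Array `n x m x k` (or matrix `units x k`) of nonnegative
#'   responses to `k` orientations.
#' @param orientations Numeric vector of the `k` orientations (radians).
#' @return List with `preference` (radians in `[0, pi)`, `NA` where a unit
#'   never responded) and `selectivity` (in `[0, 1]`), shaped like the first
#'   two dimensions of `responses`.
#' @export
orientationVectorSum <- function(responses, orientations) {
  if (length(dim(responses)) == 2)
    responses <- array(responses, dim = c(dim(responses)[1], 1,
                                          dim(responses)[2]))
  stopifnot(dim(responses)[3] == length(orientations))
  d <- dim(responses)[1:2]
  tot <- apply(responses, c(1, 2), sum)
  zr <- matrix(0, d[1], d[2]); zi <- matrix(0, d[1], d[2])
  for (k in seq_along(orientations)) {
    zr <- zr + responses[, , k] * cos(2 * orientations[k])
    zi <- zi + responses[, , k] * sin(2 * orientations[k])
  }
  pref <- (atan2(zi, zr) / 2) %% pi
  sel <- matrix(0, d[1], d[2])
  ok <- tot > 0
  sel[ok] <- sqrt(zr[ok]^2 + zi[ok]^2) / tot[ok]
  pref[!ok] <- NA_real_
  list(preference = pref, selectivity = sel)
}

#' Map smoothness: mean absolute circular difference between 4-neighbours
#'
#' @param map An [OrientationMap-class].
#' @return Mean absolute orientation difference (radians) over all
#'   horizontally and vertically adjacent unit pairs with defined preference.
#' @export
mapSmoothness <- function(map) {
  p <- map@preference
  circdiff <- function(a, b) {
    d <- abs(a - b) %% pi
    pmin(d, pi - d)
  }
  dh <- circdiff(p[, -1], p[, -ncol(p)])
  dv <- circdiff(p[-1, ], p[-nrow(p), ])
  mean(c(dh, dv), na.rm = TRUE)
}

#' Activation-weighted orientation tuning histogram
#'
#' Builds the orientation tuning histogram of the sheet: every V1 unit
#' contributes its activation (by default, the response to the medium-SF
#' vertical grating at 80% contrast) at its preferred orientation.  Also
#' computes the excess kurtosis (Fisher convention, normal = 0) of the
#' activation-weighted sample of preference angles treated as linear values
#' in `[0, pi)`, the histogram peak, and a bimodality diagnostic: after
#' 3-bin smoothing, two local maxima whose separating trough falls below 80%
#' of the lower peak.
#'
#' @param map An [OrientationMap-class].
#' @param activity V1 activation matrix used as weights.  If `model` is
#'   given and `activity` is `NULL`, the default grating response is used.
#' @param model Optional [GCALModel-class] used to compute the default
#'   weighting activity.
#' @param n_bins Number of histogram bins over `[0, pi)` (default 36).
#' @return List: `breaks`, `mids`, `counts` (weighted), `peak_orientation`,
#'   `excess_kurtosis`, `bimodal`, `n_peaks`, `total_weight`.
#' @export
tuningHistogram <- function(map, activity = NULL, model = NULL,
                            n_bins = NULL) {
  if (is.null(activity)) {
    if (is.null(model))
      stop("supply either an activity matrix or a model", call. = FALSE)
    ms <- model@config$stimuli$measurement
    img <- gratingStimulus(ms$histogram_sf, ms$histogram_contrast,
                           model = model)
    activity <- presentStimulus(model, img)$v1
  }
  if (is.null(n_bins)) {
    n_bins <- if (!is.null(model))
      model@config$stimuli$measurement$n_bins else 36L
  }
  ang <- as.numeric(map@preference)
  w <- as.numeric(activity)
  keep <- is.finite(ang) & w > 0
  ang <- ang[keep]; w <- w[keep]
  if (length(w) == 0 || sum(w) <= 0)
    stop("undefined histogram: total activation weight is zero",
         call. = FALSE)
  breaks <- seq(0, pi, length.out = n_bins + 1)
  bin <- pmin(findInterval(ang, breaks, rightmost.closed = TRUE), n_bins)
  counts <- vapply(seq_len(n_bins),
                   function(b) sum(w[bin == b]), numeric(1))
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  list(breaks = breaks, mids = mids, counts = counts,
       peak_orientation = mids[which.max(counts)],
       excess_kurtosis = weightedExcessKurtosis(ang, w),
       bimodal = histogramBimodal(counts)$bimodal,
       n_peaks = histogramBimodal(counts)$n_peaks,
       total_weight = sum(w))
}

#' Weighted excess kurtosis (Fisher convention)
#'
#' Fourth standardized central moment minus 3 of a weighted sample; a normal
#' sample gives approximately 0, a uniform distribution gives -1.2.
#'
#' @param x Numeric sample.
#' @param w Nonnegative weights.
#' @return Excess kurtosis.
#' @export
weightedExcessKurtosis <- function(x, w = rep(1, length(x))) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  m2 <- sum(w * (x - m)^2) / sw
  m4 <- sum(w * (x - m)^4) / sw
  m4 / m2^2 - 3
}

# peak structure of a (possibly noisy) histogram: smooth with a 3-bin
# running mean, find strict local maxima at least 10% of the global max,
# and call the profile bimodal when the trough between the two largest
# maxima drops below 80% of the lower of the two.
histogramBimodal <- function(counts, trough_frac = 0.8) {
  n <- length(counts)
  sm <- counts
  if (n >= 3)
    sm <- c(counts[1],
            (counts[-c(1, 2)] + counts[-c(1, n)] + counts[-c(n - 1, n)]) / 3,
            counts[n])
  peaks <- integer(0)
  for (i in seq_len(n)) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < n) sm[i + 1] else -Inf
    if (sm[i] > left && sm[i] >= right && sm[i] >= 0.1 * max(sm))
      peaks <- c(peaks, i)
  }
  if (length(peaks) < 2)
    return(list(bimodal = FALSE, n_peaks = length(peaks)))
  ord <- peaks[order(sm[peaks], decreasing = TRUE)][1:2]
  lo <- min(ord); hi <- max(ord)
  trough <- min(sm[lo:hi])
  lower_peak <- min(sm[lo], sm[hi])
  list(bimodal = trough < trough_frac * lower_peak, n_peaks = length(peaks))
}

#' Summary orientation-tuning diagnostics for a model
#'
#' Convenience wrapper: orientation map, tuning histogram, peak shift and
#' bimodality flags in one call.
#'
#' @param model A trained [GCALModel-class].
#' @param map Optionally a precomputed [OrientationMap-class].
#' @return List: `map`, `histogram`, `peak_shift` (radians from pi/2),
#'   `peak_shifted` (more than one bin), `broadened` (bimodal or shifted).
#' @export
tuningDiagnostics <- function(model, map = NULL) {
  if (is.null(map)) map <- orientationMap(model)
  h <- tuningHistogram(map, model = model)
  bin_w <- pi / length(h$counts)
  shift <- abs(h$peak_orientation - pi / 2)
  list(map = map, histogram = h, peak_shift = shift,
       peak_shifted = shift > bin_w,
       broadened = isTRUE(h$bimodal) || shift > bin_w)
}
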