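#' Hebbian update with divisive normalization (reference primitive)
#'
#' The learning rule applied to every plastic connection field: each weight
#' grows by `alpha * pre * post`, then the unit's whole weight vector is
#' divided by its sum, so per-unit weight sums stay at 1.  `alpha` here is
#' the raw per-connection rate; projections in the simulator divide their
#' configured density-independent rate by the connection-field size before
#' applying it.
#'
#' @param weights Numeric weight vector of one target unit (sum 1).
#' @param pre Presynaptic activity vector, same length.
#' @param post Postsynaptic activity scalar.
#' @param alpha Per-connection learning rate, `>= 0`.
#' @return Updated, renormalized weight vector.
#' @examples
#' hebbianUpdate(c(0.5, 0.5), c(1, 0), 1, 0.1)  # (0.6, 0.5)/1.1
#' @export
hebbianUpdate <- function(weights, pre, post, alpha) {
  stopifnot(alpha >= 0, length(pre) == length(weights), post >= 0)
  if (alpha == 0 || post == 0) return(weights)
  w <- weights + alpha * pre * post
  s <- sum(w)
  if (s <= 0)
    stop("degenerate unit: weight sum is zero at normalization",
         call. = FALSE)
  w / s
}

#' Homeostatic threshold update (reference primitive)
#'
#' Each V1 unit keeps an exponentially smoothed activity trace
#' `ybar <- (1 - beta) * y + beta * ybar` and moves its threshold toward the
#' point where the trace equals the target rate:
#' `theta <- theta + lambda * (ybar - mu)`.
#'
#' @param theta Threshold vector.
#' @param trace Smoothed activity trace vector.
#' @param activity Current settled activity vector.
#' @param mu Target mean activity.
#' @param lambda Adaptation rate (0 freezes thresholds).
#' @param beta Smoothing factor in `[0, 1)`.
#' @return List with updated `theta` and `trace`.
#' @export
homeostaticUpdate <- function(theta, trace, activity, mu, lambda, beta) {
  trace <- (1 - beta) * activity + beta * trace
  theta <- theta + lambda * (trace - mu)
  list(theta = theta, trace = trace)
}

#' Train a model
#'
#' Runs `n` iterations of the developmental loop: draw a training stimulus
#' (pair of oriented Gaussians), compute the LGN response with gain control,
#' settle V1 through its lateral connections, apply the Hebbian update to
#' every plastic projection (using the final settled activity), and update
#' the homeostatic thresholds.  Fully reproducible given the model and the
#' R RNG state.
#'
#' @param model A [GCALModel-class]; modified in place.
#' @param n Number of iterations (`>= 0`).
#' @param log_every If positive, record mean V1 activity and mean threshold
#'   every `log_every` iterations.
#' @return Invisibly, the model.  When `log_every > 0` the training log is
#'   attached as attribute `"log"` (a data frame).
#' @export
trainModel <- function(model, n, log_every = 0) {
  stopifnot(n >= 0)
  logs <- if (log_every > 0) vector("list", ceiling(n / log_every)) else NULL
  li <- 0L
  for (i in seq_len(n)) {
    img <- trainingStimulus(model)
    net_present(model@ptr, asEngineImage(img), TRUE)
    if (log_every > 0 && i %% log_every == 0) {
      st <- net_get_state(model@ptr)
      li <- li + 1L
      logs[[li]] <- data.frame(iteration = iterations(model),
                               mean_v1 = mean(st$v1),
                               mean_theta = mean(st$theta),
                               mean_trace = mean(st$trace))
    }
  }
  if (log_every > 0)
    attr(model, "log") <- do.call(rbind, logs[seq_len(li)])
  invisible(model)
}

#' Write a training log to CSV
#'
#' @param model A model returned by [trainModel()] with `log_every > 0`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeTrainingLog <- function(model, path) {
  log <- attr(model, "log")
  if (is.null(log)) stop("model carries no training log; rerun trainModel() ",
                         "with log_every > 0", call. = FALSE)
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
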