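#' Rating scale: shared step calibrations
#'
#' Constructs the shared category structure of a rating-scale Rasch model:
#' `M` ordered step calibrations (thresholds) \eqn{\tau_1, \dots, \tau_M} in
#' logits, defining `M + 1` response categories coded `0..M`. All items in a
#' bank share one rating scale; this is what distinguishes the rating-scale
#' model from the partial-credit model, where every item carries its own
#' thresholds.
#'
#' A threshold \eqn{\tau_j} is the point on the latent scale (relative to the
#' item difficulty) at which categories `j - 1` and `j` are equally probable.
#' Thresholds need not be ordered for the model to be well defined; ordering
#' is a category-quality question handled by [category_diagnostics()].
#'
#' @param thresholds numeric vector of M finite step calibrations, in logits.
#' @return An object of class `rating_scale`.
#' @examples
#' rating_scale(c(-4.16, -1.50, 2.66))
#' @export
rating_scale <- function(thresholds) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || !all(is.finite(thresholds)))
    stop("thresholds must be a non-empty vector of finite logits", call. = FALSE)
  structure(list(thresholds = thresholds, n_categories = length(thresholds) + 1L),
            class = "rating_scale")
}

#' @export
print.rating_scale <- function(x, ...) {
  cat("Rating scale: ", x$n_categories, " categories (0..",
      x$n_categories - 1L, "), step calibrations [logits]:\n", sep = "")
  cat(" ", paste(format(x$thresholds, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

as_rating_scale <- function(scale) {
  if (inherits(scale, "rating_scale")) return(scale)
  rating_scale(scale)
}

# Cumulative exponent ladder of the rating-scale model, stabilised by
# subtracting the row maximum before exponentiation. theta - delta may be a
# vector; returns a matrix [length(x), M + 1] of unnormalised log-weights.
rsm_exponents <- function(theta_minus_delta, thresholds) {
  k <- seq_along(thresholds)
  # exponent_k = k * (theta - delta) - cumsum(tau)_k, exponent_0 = 0
  outer(theta_minus_delta, c(0, k)) -
    rep(c(0, cumsum(thresholds)), each = length(theta_minus_delta))
}

#' Rating-scale model category probabilities
#'
#' Closed-form category probabilities of the rating-scale Rasch model,
#' \deqn{P(X = k) \propto \exp\!\Big(\sum_{j=1}^{k} (\theta - \delta - \tau_j)\Big),}
#' with the empty sum for `k = 0` equal to zero. Exponents are centred on
#' their maximum before exponentiation so extreme logits do not overflow.
#'
#' @param theta person measure, logits; `theta` and `difficulty` may be
#'   vectors (recycled against each other).
#' @param difficulty item difficulty \eqn{\delta}, logits.
#' @param scale a [rating_scale()] (or bare threshold vector).
#' @return If `theta - difficulty` is scalar, a probability vector over
#'   categories `0..M`; otherwise a matrix with one row per element.
#' @examples
#' category_probabilities(0, 0, rating_scale(c(-4.16, -1.50, 2.66)))
#' @export
category_probabilities <- function(theta, difficulty, scale) {
  scale <- as_rating_scale(scale)
  if (!all(is.finite(theta)) || !all(is.finite(difficulty)))
    stop("theta and difficulty must be finite", call. = FALSE)
  ex <- rsm_exponents(theta - difficulty, scale$thresholds)
  w <- exp(ex - apply(ex, 1L, max))
  p <- w / rowSums(w)
  colnames(p) <- as.character(0:(scale$n_categories - 1L))
  if (nrow(p) == 1L) p[1L, ] else p
}

#' Adjacent-category logistic probability
#'
#' The conditional probability of scoring `j` rather than `j - 1`,
#' \eqn{P_j / (P_j + P_{j-1}) = \mathrm{logistic}(\theta - \delta - \tau_j)}.
#' This is the adjacent-logit form that defines the step calibration: the
#' value is exactly 0.5 when \eqn{\theta - \delta = \tau_j}.
#'
#' @param theta person measure, logits.
#' @param difficulty item difficulty, logits.
#' @param tau_j the step calibration for the step `j-1 -> j`, logits.
#' @return probability in (0, 1), strictly increasing in `theta`.
#' @export
adjacent_logit_probability <- function(theta, difficulty, tau_j) {
  if (!all(is.finite(c(theta, difficulty, tau_j))))
    stop("theta, difficulty and tau_j must be finite", call. = FALSE)
  stats::plogis(theta - difficulty - tau_j)
}

#' Model-expected item score
#'
#' The expectation \eqn{E = \sum_k k\,P(X = k)} of the category distribution:
#' the score a person at `theta` is expected to give the item. Strictly
#' increasing in `theta`, with range (0, M).
#'
#' @inheritParams category_probabilities
#' @return expected score in score units (vector if `theta` is a vector).
#' @export
expected_score <- function(theta, difficulty, scale) {
  scale <- as_rating_scale(scale)
  p <- category_probabilities(theta, difficulty, scale)
  k <- 0:(scale$n_categories - 1L)
  if (is.matrix(p)) drop(p %*% k) else sum(k * p)
}

#' Item information under the rating-scale model
#'
#' Fisher information of one item about the person measure. For the
#' rating-scale model this equals the variance of the category score,
#' \eqn{W = \sum_k k^2 P_k - (\sum_k k P_k)^2}. Information is the currency
#' of adaptive item selection ([select_next_item()]) and the inverse of the
#' squared standard error of measurement.
#'
#' @inheritParams category_probabilities
#' @return information in logit^-2 (vector if `theta` is a vector).
#' @export
item_information <- function(theta, difficulty, scale) {
  scale <- as_rating_scale(scale)
  p <- category_probabilities(theta, difficulty, scale)
  k <- 0:(scale$n_categories - 1L)
  if (is.matrix(p)) {
    drop(p %*% (k^2)) - drop(p %*% k)^2
  } else {
    sum(k^2 * p) - sum(k * p)^2
  }
}

# Vectorised model moments for a whole person x item grid: category
# probabilities (list over k), expected score E, score variance W and fourth
# central moment C as n x i matrices. Workhorse for JMLE and fit statistics.
rsm_moments <- function(theta, delta, thresholds, fourth = FALSE, third = FALSE) {
  M <- length(thresholds)
  cumtau <- c(0, cumsum(thresholds))
  D <- outer(theta, delta, "-")
  A <- lapply(0:M, function(k) k * D - cumtau[k + 1L])
  mx <- Reduce(pmax, A)
  Wk <- lapply(A, function(a) exp(a - mx))
  Z <- Reduce(`+`, Wk)
  P <- lapply(Wk, function(w) w / Z)
  E <- Reduce(`+`, Map(function(k, p) k * p, 0:M, P))
  E2 <- Reduce(`+`, Map(function(k, p) k^2 * p, 0:M, P))
  W <- pmax(E2 - E^2, .Machine$double.eps)
  out <- list(P = P, E = E, W = W)
  if (third)
    out$mu3 <- Reduce(`+`, Map(function(k, p) (k - E)^3 * p, 0:M, P))
  if (fourth)
    out$C <- Reduce(`+`, Map(function(k, p) (k - E)^4 * p, 0:M, P))
  out
}

#' Log-likelihood of a response pattern
#'
#' \eqn{\ell(\theta) = \sum_i \log P(x_i \mid \theta)} over the administered
#' items. Used by the Newton-Raphson estimator and by brute-force likelihood
#' checks.
#'
#' @param responses a data.frame (or list) with numeric `difficulty` and
#'   integer `category` entries, one per administered item.
#' @param theta person measure, logits.
#' @param scale a [rating_scale()].
#' @return log-probability (finite for finite theta).
#' @export
log_likelihood <- function(responses, theta, scale) {
  scale <- as_rating_scale(scale)
  difficulty <- responses$difficulty
  x <- responses$category
  if (length(x) == 0L) stop("empty response set", call. = FALSE)
  if (any(x < 0L | x > scale$n_categories - 1L))
    stop("category out of range 0..M", call. = FALSE)
  ll <- 0
  for (i in seq_along(x)) {
    p <- category_probabilities(theta, difficulty[i], scale)
    ll <- ll + log(p[[x[i] + 1L]])
  }
  ll
}

#' Ability estimate
#'
#' Container for a person measure: `theta` (logits), its standard error
#' `se = 1 / sqrt(total information)`, the number of responses used, a
#' convergence flag, and an `extreme` flag marking all-minimum/all-maximum
#' raw scores (which have no finite maximum-likelihood estimate and are
#' interiorised by 0.25 score units before estimation).
#'
#' @param theta,se,n_items,converged,extreme fields; see Description.
#' @return object of class `ability_estimate`.
#' @export
ability_estimate <- function(theta, se, n_items, converged = TRUE, extreme = FALSE) {
  structure(list(theta = theta, se = se, n_items = as.integer(n_items),
                 converged = isTRUE(converged), extreme = isTRUE(extreme)),
            class = "ability_estimate")
}

#' @export
print.ability_estimate <- function(x, ...) {
  cat(sprintf("theta = %.3f logits (SE %.3f) from %d item%s%s%s\n",
              x$theta, x$se, x$n_items, if (x$n_items == 1L) "" else "s",
              if (x$extreme) ", extreme score" else "",
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Newton-Raphson person-measure estimation
#'
#' Maximum-likelihood estimate of the person measure from a set of scored
#' items under the rating-scale model. Iterates
#' \deqn{\theta \leftarrow \theta + \frac{\sum_i x_i - \sum_i E_i(\theta)}
#'       {\sum_i W_i(\theta)}}
#' where \eqn{E_i} is [expected_score()] and \eqn{W_i} is
#' [item_information()], until the update falls below `tol` or `max_iter` is
#' reached. Safeguards: each step is capped at 1 logit and theta is clamped
#' to \eqn{[-10, 10]}.
#'
#' Extreme raw scores (all items at the minimum or maximum category) have no
#' finite MLE; the raw score is moved 0.25 score units toward the interior
#' and the estimate flagged `extreme = TRUE`.
#'
#' @param responses data.frame with columns `difficulty` (logits) and
#'   `category` (integer 0..M), one row per administered item.
#' @param scale a [rating_scale()].
#' @param init starting value, logits.
#' @param tol convergence tolerance on the theta update, logits.
#' @param max_iter iteration cap.
#' @return an [ability_estimate()].
#' @examples
#' sc <- rating_scale(c(-4.16, -1.50, 2.66))
#' estimate_theta(data.frame(difficulty = c(0, 1, -1), category = c(2, 1, 2)), sc)
#' @export
estimate_theta <- function(responses, scale, init = 0, tol = 0.001, max_iter = 50L) {
  scale <- as_rating_scale(scale)
  difficulty <- responses$difficulty
  x <- as.integer(responses$category)
  M <- scale$n_categories - 1L
  if (length(x) == 0L) stop("empty response set", call. = FALSE)
  if (any(!is.finite(difficulty))) stop("all items must be calibrated", call. = FALSE)
  if (any(x < 0L | x > M)) stop("category out of range 0..M", call. = FALSE)

  raw <- sum(x)
  extreme <- raw == 0L || raw == M * length(x)
  target <- raw
  if (extreme) target <- if (raw == 0L) 0.25 else raw - 0.25

  theta <- min(max(init, -10), 10)
  converged <- FALSE
  info <- NA_real_
  for (it in seq_len(max_iter)) {
    E <- sum(expected_score(theta, difficulty, scale))
    info <- sum(item_information(theta, difficulty, scale))
    step <- (target - E) / info
    step <- sign(step) * min(abs(step), 1)
    theta <- min(max(theta + step, -10), 10)
    if (abs(step) < tol) { converged <- TRUE; break }
  }
  info <- sum(item_information(theta, difficulty, scale))
  ability_estimate(theta = theta, se = 1 / sqrt(info), n_items = length(x),
                   converged = converged, extreme = extreme)
}
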