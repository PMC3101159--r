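#' Cohort specification for response simulation
#'
#' Describes a simulated respondent population: `n_persons` draws from a
#' normal latent distribution with the given mean and standard deviation
#' (logits). The defaults reproduce the reference survey population
#' (mean 2.30, SD 1.99 logits, 300 respondents). An arbitrary quantile
#' function may replace the normal law.
#'
#' @param n_persons cohort size.
#' @param mean,sd latent distribution parameters, logits (`sd > 0`).
#' @param seed integer seed making the cohort reproducible; `NULL` uses the
#'   current RNG state.
#' @param quantile_fun optional quantile function `q(p)` for the latent
#'   distribution (overrides `mean`/`sd`).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_persons = 300L, mean = 2.30, sd = 1.99,
                        seed = NULL, quantile_fun = NULL) {
  if (n_persons < 1L) stop("n_persons must be >= 1", call. = FALSE)
  if (is.null(quantile_fun) && (!is.finite(sd) || sd <= 0))
    stop("sd must be > 0", call. = FALSE)
  structure(list(n_persons = as.integer(n_persons), mean = mean, sd = sd,
                 seed = seed, quantile_fun = quantile_fun),
            class = "cohort_spec")
}

#' Draw one item response from the model
#'
#' Inverse-CDF draw over [category_probabilities()]: a uniform variate is
#' placed against the cumulative category distribution at (`theta`,
#' `difficulty`). Deterministic given the RNG state.
#'
#' @param theta person measure, logits.
#' @param difficulty item difficulty, logits.
#' @param scale a [rating_scale()].
#' @param u optional uniform variate(s) in (0, 1); defaults to `runif`.
#' @return integer category `0..M` (vectorised over `u`).
#' @export
simulate_response <- function(theta, difficulty, scale, u = NULL) {
  scale <- as_rating_scale(scale)
  p <- category_probabilities(theta, difficulty, scale)
  if (is.matrix(p)) stop("simulate_response takes scalar theta/difficulty", call. = FALSE)
  if (is.null(u)) u <- stats::runif(1L)
  cum <- cumsum(p)
  vapply(u, function(ui) sum(ui > cum), 0L)
}

#' Simulate a full cohort against a calibrated bank
#'
#' Draws person measures from the cohort's latent law and a complete
#' persons-by-items response matrix by inverse-CDF sampling under the
#' rating-scale model. Fully reproducible from `(spec, bank, seed)`.
#'
#' `item_shift` perturbs item difficulties at generation time (a positive
#' shift makes endorsement rarer), emulating e.g. a follow-up year in which
#' perceptions of some item group deteriorated; the bank itself is not
#' modified.
#'
#' @param spec a [cohort_spec()].
#' @param bank calibrated [item_bank()].
#' @param item_shift numeric scalar or vector (one per calibrated item) of
#'   difficulty shifts in logits, default 0.
#' @return list with `theta` (true person measures) and `responses`
#'   (integer matrix, persons x calibrated items, colnames = item ids).
#' @examples
#' sim <- simulate_cohort(cohort_spec(50, seed = 1), jcq37_bank())
#' dim(sim$responses)
#' @export
simulate_cohort <- function(spec, bank, item_shift = 0) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(bank, "item_bank"))
  cal <- calibrated_items(bank)
  J <- nrow(cal)
  delta <- cal$difficulty + rep_len(item_shift, J)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_persons
  if (is.null(spec$quantile_fun)) {
    theta <- stats::rnorm(n, spec$mean, spec$sd)
  } else {
    theta <- spec$quantile_fun(stats::runif(n))
  }
  mo <- rsm_moments(theta, delta, bank$scale$thresholds)
  M <- bank$scale$n_categories - 1L
  U <- matrix(stats::runif(n * J), n, J)
  X <- matrix(0L, n, J)
  cum <- mo$P[[1L]]
  for (k in seq_len(M)) {          # X = number of cumulative probs below U
    X <- X + (U > cum)
    if (k < M) cum <- cum + mo$P[[k + 1L]]
  }
  dimnames(X) <- list(paste0("P", seq_len(n)), cal$item_id)
  list(theta = theta, responses = X)
}

#' Model-consistent responder for simulated CAT sessions
#'
#' Wraps a fixed true measure into the responder callback expected by
#' [run_cat()]: each administered item is answered by [simulate_response()]
#' at that measure.
#'
#' @param theta true person measure, logits.
#' @param scale the bank's [rating_scale()].
#' @return function of a one-row item data.frame returning a category.
#' @export
simulated_responder <- function(theta, scale) {
  scale <- as_rating_scale(scale)
  function(item) simulate_response(theta, item$difficulty, scale)
}
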