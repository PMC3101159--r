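#' Joint maximum likelihood calibration of a response matrix
#'
#' Estimates item difficulties, the shared step calibrations and person
#' measures from a persons-by-items matrix of integer categories (`0..M`,
#' `NA` = not administered) under the rating-scale Rasch model, by
#' alternating damped Newton-Raphson updates of the three parameter blocks
#' until the largest parameter change falls below `config$tol`.
#'
#' Identification: unanchored runs constrain the mean item difficulty to 0
#' and the step calibrations to sum to 0 (the model is invariant to a joint
#' location shift between difficulties and thresholds, and between persons
#' and items). When `anchors` is supplied, the anchored item difficulties
#' are held fixed at their given values and no centering is applied, so
#' estimated thresholds land on the anchor bank's scale.
#'
#' Person updates use Warm's weighted-likelihood score (the raw-score
#' residual plus \eqn{\sum \mu_3 / (2 \sum W)}), which removes the
#' first-order outward bias of the plain maximum-likelihood measure and is
#' finite at extreme raw scores, so every respondent informs the threshold
#' estimates. Reported person measures are re-estimated afterwards by
#' [estimate_persons()] under the package's extreme-score convention.
#' Items whose observed responses have no variance (all responses in one
#' category) carry no information about their own difficulty and are
#' dropped from calibration with a warning.
#'
#' @param responses integer matrix, persons as rows (rownames = person ids),
#'   items as columns (colnames = item ids), entries in `0..M` or `NA`.
#' @param anchors optional [item_bank()] whose difficulties are held fixed.
#' @param config list; recognised entries `tol` (default 1e-4 logits),
#'   `max_iter` (default 200), `n_categories` (default: max observed + 1).
#' @return object of class `calibration_result` with elements `bank`
#'   (estimated [item_bank()]), `person_measures` (list of
#'   [ability_estimate()]), `fit` (per-item and per-person statistics),
#'   `reliability`, `misfit_item_ids`, `dimensionality`
#'   ([residual_pca()] output), `category_report`
#'   ([category_diagnostics()] output), `converged`, `n_iter`.
#' @export
jmle_calibrate <- function(responses, anchors = NULL, config = list()) {
  tol <- config$tol %||% 1e-4
  max_iter <- config$max_iter %||% 200L
  X <- validate_response_matrix(responses)

  if (!is.null(anchors)) {
    stopifnot(inherits(anchors, "item_bank"))
    M <- anchors$scale$n_categories - 1L
  } else {
    M <- config$n_categories %||% (max(X, na.rm = TRUE) + 1L)
    M <- as.integer(M) - 1L
  }
  if (any(X > M, na.rm = TRUE))
    stop("observed category exceeds M = ", M, call. = FALSE)

  item_ids <- colnames(X)
  # items with no variance are inestimable
  item_var <- apply(X, 2L, function(v) stats::var(v[!is.na(v)]))
  dead_items <- which(!is.na(item_var) & item_var == 0)
  if (length(dead_items)) {
    warning("dropping ", length(dead_items),
            " item(s) with no response variance: ",
            paste(item_ids[dead_items], collapse = ", "), call. = FALSE)
    X <- X[, -dead_items, drop = FALSE]
    item_ids <- colnames(X)
  }
  if (ncol(X) < 2L) stop("need at least 2 items with variance", call. = FALSE)

  n <- nrow(X); J <- ncol(X)
  obs <- !is.na(X)
  Xz <- X; Xz[!obs] <- 0L

  raw <- rowSums(Xz * obs)
  maxraw <- M * rowSums(obs)
  # during calibration, persons carry Warm weighted-likelihood measures:
  # finite at extreme raw scores, so every respondent informs the thresholds
  est_person <- rowSums(obs) >= 1L

  anchored <- !is.null(anchors)
  if (anchored) {
    ai <- match(as.integer(item_ids), anchors$items$item_id)
    if (anyNA(ai))
      stop("anchor bank lacks items: ",
           paste(item_ids[is.na(ai)], collapse = ", "), call. = FALSE)
    delta <- anchors$items$difficulty[ai]
    if (anyNA(delta)) stop("anchored items must be calibrated", call. = FALSE)
    tau <- anchors$scale$thresholds
  } else {
    # logit-of-proportion starting values
    pbar <- colSums(Xz) / (M * colSums(obs))
    delta <- stats::qlogis(pmin(pmax(pbar, 0.02), 0.98)) * -1
    delta <- delta - mean(delta)
    tau <- rep(0, M)
  }
  theta <- rep(0, n)
  prop <- (raw + 0.5) / (maxraw + 1)
  theta <- stats::qlogis(prop)

  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    mo <- rsm_moments(theta, delta, tau, third = TRUE)
    # persons: Warm's weighted-likelihood score, r - sum(E) + sum(mu3)/(2 sum(W)),
    # which removes the first-order outward bias of the raw MLE
    h_p <- rowSums(mo$W * obs)
    g_p <- rowSums((Xz - mo$E) * obs) + rowSums(mo$mu3 * obs) / (2 * h_p)
    step_p <- ifelse(est_person, g_p / h_p, 0)
    step_p <- pmin(pmax(step_p, -1), 1)
    theta <- pmin(pmax(theta + step_p, -10), 10)

    mo <- rsm_moments(theta, delta, tau)
    # items (skip when anchored); the step is projected onto mean-zero so the
    # mean-difficulty-0 identification holds throughout
    if (!anchored) {
      g_i <- colSums((mo$E - Xz) * obs * est_person)
      h_i <- colSums(mo$W * obs * est_person)
      step_i <- pmin(pmax(g_i / h_i, -1), 1)
      step_i <- step_i - mean(step_i)
      delta <- delta + step_i
    } else step_i <- 0

    # shared thresholds: full Newton on the cumulative-category score
    mo <- rsm_moments(theta, delta, tau)
    Pge <- vector("list", M)              # P(X >= j), j = 1..M
    acc <- 0
    for (j in M:1) { acc <- acc + mo$P[[j + 1L]]; Pge[[j]] <- acc }
    use <- obs * est_person
    g_t <- vapply(1:M, function(j) sum((Pge[[j]] - (Xz >= j)) * use), 0)
    H <- matrix(0, M, M)
    for (j in 1:M) for (l in j:M) {
      H[j, l] <- H[l, j] <- sum((Pge[[max(j, l)]] - Pge[[j]] * Pge[[l]]) * use)
    }
    step_t <- tryCatch(solve(H, g_t), error = function(e) g_t / diag(H))
    step_t <- pmin(pmax(step_t, -0.5), 0.5)
    # the threshold location is never identified by the data: unanchored runs
    # pin sum(tau) = 0; anchored runs inherit the anchor scale's location
    # (with delta fixed, a joint shift of persons and thresholds is
    # likelihood-invariant, so only the spacing is estimable). Projecting the
    # step keeps the constraint exact throughout.
    step_t <- step_t - mean(step_t)
    tau <- tau + step_t

    if (max(abs(step_p), abs(step_i), abs(step_t)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("JMLE did not converge in ", max_iter,
            " iterations; returning partial estimates", call. = FALSE)

  scale <- rating_scale(tau)
  # item standard errors from the information accumulated over persons
  mo <- rsm_moments(theta, delta, tau)
  se_i <- 1 / sqrt(colSums(mo$W * obs * est_person))

  bank <- item_bank(data.frame(
    item_id = as.integer(item_ids), label = paste("item", item_ids),
    difficulty = delta, se = se_i, infit = NA_real_, outfit = NA_real_,
    status = "calibrated", stringsAsFactors = FALSE), scale)

  # final person measures: fully converged NR per person, extremes interiorised
  person_measures <- estimate_persons(X, bank)
  names(person_measures) <- rownames(X)

  fit <- fit_statistics(X, bank, person_measures)
  bank$items$infit <- fit$item$infit
  bank$items$outfit <- fit$item$outfit

  rel <- separation_reliability(person_measures)
  misfit_ids <- fit$item$item_id[fit$item$infit < 0.5 | fit$item$infit > 1.5]
  dim_sum <- residual_pca(X, bank, person_measures)
  cat_rep <- category_diagnostics(X, bank, person_measures)

  structure(list(bank = bank, person_measures = person_measures, fit = fit,
                 reliability = rel, misfit_item_ids = misfit_ids,
                 dimensionality = dim_sum, category_report = cat_rep,
                 converged = converged, n_iter = it),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Rating-scale calibration: %d items, %d persons%s (%d iterations)\n",
              nrow(x$bank$items), length(x$person_measures),
              if (x$converged) "" else " [NOT converged]", x$n_iter))
  cat(sprintf("Person-separation reliability: %.3f\n", x$reliability))
  cat(sprintf("Misfit items (infit outside 0.5-1.5): %s\n",
              if (length(x$misfit_item_ids))
                paste(x$misfit_item_ids, collapse = ", ") else "none"))
  cat(sprintf("Variance explained by measures: %.1f%%; first contrast eigenvalue %.2f (%.1f%%)\n",
              x$dimensionality$variance_explained_by_measures,
              x$dimensionality$first_contrast_eigenvalue,
              x$dimensionality$first_contrast_variance))
  invisible(x)
}

#' Person measures for a response matrix against a fixed bank
#'
#' Vectorised Newton-Raphson maximum-likelihood measures for every row of a
#' response matrix, holding the bank's difficulties and thresholds fixed
#' (the scoring step of an already-calibrated instrument). Extreme raw
#' scores are interiorised by 0.25 score units and flagged.
#'
#' @param X integer response matrix (persons x items, `0..M`, `NA` allowed),
#'   colnames = item ids present in the bank.
#' @param bank calibrated [item_bank()].
#' @param tol,max_iter Newton-Raphson controls.
#' @return list of [ability_estimate()], one per row.
#' @export
estimate_persons <- function(X, bank, tol = 1e-4, max_iter = 100L) {
  X <- validate_response_matrix(X)
  cal <- calibrated_items(bank)
  idx <- match(as.integer(colnames(X)), cal$item_id)
  if (anyNA(idx)) stop("response matrix contains uncalibrated items", call. = FALSE)
  delta <- cal$difficulty[idx]
  tau <- bank$scale$thresholds
  M <- length(tau)
  obs <- !is.na(X)
  Xz <- X; Xz[!obs] <- 0L
  raw <- rowSums(Xz * obs)
  maxraw <- M * rowSums(obs)
  extreme <- raw == 0 | raw == maxraw
  target <- raw
  target[raw == 0] <- 0.25
  target[raw == maxraw] <- maxraw[raw == maxraw] - 0.25
  theta <- stats::qlogis((raw + 0.5) / (maxraw + 1))
  conv <- rep(FALSE, nrow(X))
  for (i in seq_len(max_iter)) {
    mo <- rsm_moments(theta, delta, tau)
    g <- target - rowSums(mo$E * obs)
    h <- rowSums(mo$W * obs)
    step <- pmin(pmax(g / h, -1), 1)
    theta <- pmin(pmax(theta + step, -10), 10)
    conv <- conv | abs(step) < tol
    if (all(abs(step) < tol)) break
  }
  mo <- rsm_moments(theta, delta, tau)
  se <- 1 / sqrt(rowSums(mo$W * obs))
  lapply(seq_len(nrow(X)), function(p)
    ability_estimate(theta[p], se[p], sum(obs[p, ]), conv[p], extreme[p]))
}

#' Infit and outfit mean-square fit statistics
#'
#' Standardized residuals \eqn{z_{ni} = (x_{ni} - E_{ni}) / \sqrt{W_{ni}}}
#' are formed for every scored cell at the person's measure and the item's
#' difficulty. Outfit is the plain mean of \eqn{z^2} over the margin
#' (outlier-sensitive); infit is the information-weighted version
#' \eqn{\sum (x - E)^2 / \sum W}. Both have expectation 1 under the model.
#' The standardized Z is the Wilson-Hilferty cube-root transform of the
#' mean-square using its model variance, giving an approximate standard
#' normal deviate.
#'
#' Persons with extreme raw scores are excluded: their interiorised measures
#' would contribute structurally biased residuals.
#'
#' @param responses response matrix (persons x items, `0..M`, `NA` allowed).
#' @param bank calibrated [item_bank()] covering the matrix columns.
#' @param person_measures list of [ability_estimate()] aligned with rows.
#' @return list with data.frames `item` (`item_id`, `infit`, `outfit`,
#'   `infit_z`, `outfit_z`) and `person` (same per person).
#' @export
fit_statistics <- function(responses, bank, person_measures) {
  X <- validate_response_matrix(responses)
  cal <- calibrated_items(bank)
  idx <- match(as.integer(colnames(X)), cal$item_id)
  if (anyNA(idx)) stop("fit_statistics: uncalibrated items in matrix", call. = FALSE)
  delta <- cal$difficulty[idx]
  tau <- bank$scale$thresholds
  theta <- vapply(person_measures, function(a) a$theta, 0)
  extreme <- vapply(person_measures, function(a) a$extreme, TRUE)

  keep <- !extreme
  Xk <- X[keep, , drop = FALSE]
  mo <- rsm_moments(theta[keep], delta, tau, fourth = TRUE)
  obs <- !is.na(Xk)
  Xz <- Xk; Xz[!obs] <- 0L
  R2 <- (Xz - mo$E)^2 * obs          # squared raw residuals
  Z2 <- R2 / mo$W                    # squared standardized residuals

  msq <- function(margin) {
    if (margin == "item") {
      N <- colSums(obs)
      outfit <- colSums(Z2) / N
      infit <- colSums(R2) / colSums(mo$W * obs)
      q2_out <- colSums((mo$C / mo$W^2) * obs) / N^2 - 1 / N
      q2_in <- colSums((mo$C - mo$W^2) * obs) / colSums(mo$W * obs)^2
    } else {
      N <- rowSums(obs)
      outfit <- rowSums(Z2) / N
      infit <- rowSums(R2) / rowSums(mo$W * obs)
      q2_out <- rowSums((mo$C / mo$W^2) * obs) / N^2 - 1 / N
      q2_in <- rowSums((mo$C - mo$W^2) * obs) / rowSums(mo$W * obs)^2
    }
    q_out <- sqrt(pmax(q2_out, 1e-12))
    q_in <- sqrt(pmax(q2_in, 1e-12))
    list(infit = infit, outfit = outfit,
         infit_z = (infit^(1 / 3) - 1) * (3 / q_in) + q_in / 3,
         outfit_z = (outfit^(1 / 3) - 1) * (3 / q_out) + q_out / 3)
  }

  im <- msq("item")
  pm <- msq("person")
  person_tab <- data.frame(person = rownames(X)[keep],
                           infit = pm$infit, outfit = pm$outfit,
                           infit_z = pm$infit_z, outfit_z = pm$outfit_z,
                           stringsAsFactors = FALSE, row.names = NULL)
  list(item = data.frame(item_id = cal$item_id[idx], infit = im$infit,
                         outfit = im$outfit, infit_z = im$infit_z,
                         outfit_z = im$outfit_z, row.names = NULL),
       person = person_tab)
}

#' Screen a calibrated bank for misfitting items
#'
#' Items whose infit mean-square lies inside the closed interval
#' `[lower, upper]` are retained; the rest are flagged `misfit`. The screen
#' is single-pass: the retained bank is not recalibrated.
#'
#' @param bank an [item_bank()] whose items carry infit values (or a
#'   `calibration_result`, whose bank is used).
#' @param lower,upper infit mean-square acceptance bounds (defaults 0.5, 1.5).
#' @return list with `bank` (retained items, status unchanged) and
#'   `misfit_item_ids`.
#' @export
misfit_filter <- function(bank, lower = 0.5, upper = 1.5) {
  if (inherits(bank, "calibration_result")) bank <- bank$bank
  stopifnot(inherits(bank, "item_bank"))
  it <- bank$items
  ok <- it$status == "calibrated" & !is.na(it$infit) &
    it$infit >= lower & it$infit <= upper
  if (!any(ok)) stop("all items misfit the screen", call. = FALSE)
  list(bank = item_bank(it[ok, , drop = FALSE], bank$scale),
       misfit_item_ids = it$item_id[!ok])
}

#' Person-separation reliability
#'
#' The proportion of observed person-measure variance not attributable to
#' measurement error:
#' \deqn{R = \frac{\mathrm{Var}(\hat\theta) - \overline{SE^2}}
#'       {\mathrm{Var}(\hat\theta)},}
#' floored at 0. Analogous to Cronbach's alpha on the logit scale. Extreme
#' persons are excluded (their SEs reflect the interiorisation convention,
#' not the instrument).
#'
#' @param person_measures list of [ability_estimate()].
#' @return reliability in `[0, 1]`.
#' @export
separation_reliability <- function(person_measures) {
  keep <- !vapply(person_measures, function(a) a$extreme, TRUE)
  if (sum(keep) < 2L) stop("need >= 2 non-extreme person measures", call. = FALSE)
  theta <- vapply(person_measures[keep], function(a) a$theta, 0)
  se2 <- vapply(person_measures[keep], function(a) a$se^2, 0)
  v <- stats::var(theta)
  if (v == 0) {
    warning("zero observed variance of person measures", call. = FALSE)
    return(0)
  }
  max(0, (v - mean(se2)) / v)
}

#' SEM-based CAT stop value
#'
#' The standard error of measurement implied by a reference calibration:
#' \eqn{SEM = SD_x \sqrt{1 - R}}, where \eqn{SD_x} is the standard deviation
#' of the reference person measures and \eqn{R} their separation
#' reliability. Used as the `se_target` of a [cat_config()]: adaptive
#' testing stops once the provisional measure is at least as precise as the
#' full-length reference instrument.
#'
#' @param sd_person standard deviation of reference person measures, logits.
#' @param reliability separation reliability in `[0, 1]`.
#' @return SEM in logits.
#' @examples
#' sem_stop_value(1.99, 0.88)  # 0.6894; the conventional rule truncates to 0.68
#' @export
sem_stop_value <- function(sd_person, reliability) {
  if (!is.finite(sd_person) || sd_person <= 0)
    stop("sd_person must be positive", call. = FALSE)
  if (!is.finite(reliability) || reliability < 0 || reliability > 1)
    stop("reliability must lie in [0, 1]", call. = FALSE)
  sd_person * sqrt(1 - reliability)
}

#' Principal-component diagnostics of standardized residuals
#'
#' Assesses unidimensionality after the Rasch dimension is removed. The
#' standardized residuals \eqn{z_{ni}} are correlated item-by-item and the
#' correlation matrix eigen-decomposed. Under a single latent dimension the
#' residuals are near-independent noise and all eigenvalues sit near 1; a
#' secondary dimension concentrates variance in the first contrast.
#'
#' Conventional criteria: variance explained by the measures of at least
#' 60%, first contrast eigenvalue below 3, first-contrast variance below 5%
#' of the total. All three numbers are reported; policy is the caller's.
#' Variance explained by measures is computed as
#' `100 * Var(E) / (Var(E) + mean(W))` over scored cells — the
#' model-expected score variance against the total of model and residual
#' variance. The first-contrast variance is the eigenvalue as a share of
#' that same total (measure plus residual) variance, the convention under
#' which an eigenvalue of 1.8 on 24 items corresponds to roughly 4%, not
#' 7.5%.
#'
#' @inheritParams fit_statistics
#' @return list with `variance_explained_by_measures` (percent),
#'   `first_contrast_eigenvalue`, `first_contrast_variance` (percent), and
#'   `eigenvalues` (all item-residual eigenvalues).
#' @export
residual_pca <- function(responses, bank, person_measures) {
  X <- validate_response_matrix(responses)
  cal <- calibrated_items(bank)
  idx <- match(as.integer(colnames(X)), cal$item_id)
  if (anyNA(idx)) stop("residual_pca: uncalibrated items in matrix", call. = FALSE)
  keep <- !vapply(person_measures, function(a) a$extreme, TRUE)
  Xk <- X[keep, , drop = FALSE]
  if (ncol(Xk) > nrow(Xk))
    warning("more items than persons: eigenstructure unstable", call. = FALSE)
  theta <- vapply(person_measures[keep], function(a) a$theta, 0)
  mo <- rsm_moments(theta, cal$difficulty[idx], bank$scale$thresholds)
  z <- (Xk - mo$E) / sqrt(mo$W)
  cmat <- stats::cor(z, use = "pairwise.complete.obs")
  cmat[is.na(cmat)] <- 0; diag(cmat) <- 1
  ev <- eigen(cmat, symmetric = TRUE, only.values = TRUE)$values
  obs <- !is.na(Xk)
  varE <- stats::var(mo$E[obs])
  meanW <- mean(mo$W[obs])
  vem <- 100 * varE / (varE + meanW)
  # the residual correlation carries ncol units of variance; the measures add
  # ncol * vem / (100 - vem) more, so the first contrast is reported as a
  # share of the total (measure + residual) raw variance
  total_units <- ncol(Xk) / (1 - vem / 100)
  list(variance_explained_by_measures = vem,
       first_contrast_eigenvalue = ev[1L],
       first_contrast_variance = 100 * ev[1L] / total_units,
       eigenvalues = ev)
}

#' Rating-category quality diagnostics
#'
#' Checks the four conventional guidelines for a functioning rating scale:
#' (1) the average measure of respondents using each category advances
#' monotonically with the category, (2) step calibrations advance,
#' (3) adjacent steps advance by at least 1.4 logits, and (4) by less than
#' 5.0 logits. Categories with no observations leave guideline (1)
#' undetermined (`NA`) with a warning.
#'
#' @inheritParams fit_statistics
#' @return list with `average_measures_per_category` (logits, length M + 1),
#'   `threshold_advances` (length M - 1), and `guideline_flags` (logical,
#'   named `monotone_average_measures`, `steps_advance`,
#'   `advance_at_least_1.4`, `advance_less_than_5`).
#' @export
category_diagnostics <- function(responses, bank, person_measures) {
  X <- validate_response_matrix(responses)
  tau <- bank$scale$thresholds
  M <- length(tau)
  keep <- !vapply(person_measures, function(a) a$extreme, TRUE)
  theta <- vapply(person_measures[keep], function(a) a$theta, 0)
  Xk <- X[keep, , drop = FALSE]
  avg <- vapply(0:M, function(k) {
    hit <- Xk == k
    n_k <- rowSums(hit, na.rm = TRUE)
    if (sum(n_k) == 0) NA_real_ else sum(theta * n_k) / sum(n_k)
  }, 0)
  if (anyNA(avg))
    warning("empty rating category: average-measure guideline undetermined",
            call. = FALSE)
  adv <- diff(tau)
  flags <- c(
    monotone_average_measures = if (anyNA(avg)) NA else all(diff(avg) > 0),
    steps_advance = all(adv > 0),
    advance_at_least_1.4 = all(adv >= 1.4),
    advance_less_than_5 = all(adv < 5.0)
  )
  list(average_measures_per_category = avg, threshold_advances = adv,
       guideline_flags = flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared validation: integer person x item matrix with ids in dimnames.
validate_response_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) stop("responses must be a matrix", call. = FALSE)
  storage.mode(X) <- "integer"
  if (is.null(colnames(X))) stop("response matrix needs item-id colnames", call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- paste0("P", seq_len(nrow(X)))
  if (any(X < 0L, na.rm = TRUE)) stop("negative category in response matrix", call. = FALSE)
  if (nrow(X) < 1L || ncol(X) < 1L) stop("empty response matrix", call. = FALSE)
  X
}
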