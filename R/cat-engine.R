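#' Configuration of an adaptive testing session
#'
#' @param se_target stop when the measure's standard error falls to or below
#'   this value (logits); typically the [sem_stop_value()] of a reference
#'   calibration. `0` makes the criterion unattainable so sessions run to
#'   `max_items`.
#' @param min_items minimum session length before the SE criterion may stop
#'   the test (default 10).
#' @param max_items hard cap on session length; `NULL` means the full bank.
#' @param burn_in number of items answered before estimation starts
#'   (default 3); during burn-in the provisional measure is the initial
#'   mapped value.
#' @param initial_rating_map starting measures (logits) indexed by the
#'   examinee's global self-rating `1..length(map)`; must be monotone
#'   non-decreasing.
#' @param aberrance_mnsq session outfit above this flags the record aberrant
#'   (default 2.0).
#' @param z_flag per-response standardized residuals beyond this are marked
#'   unexpected (default 1.96).
#' @param abort_on_aberrance if `TRUE`, terminate the session early once the
#'   running outfit exceeds `abort_mnsq` (default off).
#' @param abort_mnsq running-outfit threshold for the early abort (default 10).
#' @return object of class `cat_config`.
#' @export
cat_config <- function(se_target, min_items = 10L, max_items = NULL,
                       burn_in = 3L,
                       initial_rating_map = c(-2.0, -0.5, 0.5, 2.0),
                       aberrance_mnsq = 2.0, z_flag = 1.96,
                       abort_on_aberrance = FALSE, abort_mnsq = 10) {
  if (!is.finite(se_target) || se_target < 0)
    stop("se_target must be >= 0", call. = FALSE)
  if (is.unsorted(initial_rating_map))
    stop("initial_rating_map must be monotone in the rating", call. = FALSE)
  cfg <- structure(list(se_target = se_target, min_items = as.integer(min_items),
                        max_items = if (is.null(max_items)) NULL else as.integer(max_items),
                        burn_in = as.integer(burn_in),
                        initial_rating_map = initial_rating_map,
                        aberrance_mnsq = aberrance_mnsq, z_flag = z_flag,
                        abort_on_aberrance = isTRUE(abort_on_aberrance),
                        abort_mnsq = abort_mnsq),
                   class = "cat_config")
  if (cfg$burn_in < 1L || cfg$burn_in >= cfg$min_items)
    stop("need 1 <= burn_in < min_items", call. = FALSE)
  if (!is.null(cfg$max_items) && cfg$min_items > cfg$max_items)
    stop("min_items must not exceed max_items", call. = FALSE)
  cfg
}

# Resolve a config against a concrete bank (fills max_items, checks bounds).
resolve_config <- function(config, bank) {
  n_bank <- nrow(calibrated_items(bank))
  if (is.null(config$max_items)) config$max_items <- n_bank
  if (config$max_items > n_bank)
    stop("max_items exceeds bank size", call. = FALSE)
  if (config$min_items > config$max_items)
    stop("min_items must not exceed max_items", call. = FALSE)
  config
}

#' Starting measure from a global self-rating
#'
#' Maps the examinee's overall self-rating (e.g. overall job satisfaction,
#' `1..4`) to a provisional starting measure via the config's
#' `initial_rating_map`.
#'
#' @param global_rating integer rating `1..length(map)`.
#' @param config a [cat_config()].
#' @return starting measure in logits.
#' @export
initial_theta <- function(global_rating, config) {
  map <- config$initial_rating_map
  if (!is.numeric(global_rating) || length(global_rating) != 1L ||
      is.na(global_rating) || global_rating < 1 || global_rating > length(map) ||
      global_rating != round(global_rating))
    stop("global_rating must be an integer in 1..", length(map), call. = FALSE)
  map[[global_rating]]
}

#' Maximum-information item selection
#'
#' Returns the unadministered calibrated item with the largest
#' [item_information()] at the provisional measure; ties broken by lowest
#' item id.
#'
#' @param theta provisional person measure, logits.
#' @param bank an [item_bank()].
#' @param administered integer vector of already-used item ids.
#' @return one-row data.frame (the selected item).
#' @export
select_next_item <- function(theta, bank, administered = integer()) {
  cal <- calibrated_items(bank)
  cand <- cal[!cal$item_id %in% administered, , drop = FALSE]
  if (nrow(cand) == 0L) stop("item bank exhausted", call. = FALSE)
  info <- item_information(theta, cand$difficulty, bank$scale)
  best <- which(info == max(info))
  pick <- best[which.min(cand$item_id[best])]
  cand[pick, , drop = FALSE]
}

#' CAT stop decision
#'
#' Stop once (a) at least `min_items` have been administered and the current
#' SE is at or below `se_target`, or (b) `max_items` is reached, or (c) the
#' optional aberrance abort fires (running outfit above `abort_mnsq`).
#'
#' @param state list with `n_administered`, `se` (NA during burn-in) and
#'   `running_outfit` (NA during burn-in).
#' @param config a [cat_config()] with `max_items` resolved.
#' @return list `(stop, reason)`; `reason` one of `"se_met"`, `"max_items"`,
#'   `"aberrant"` or `NA` when continuing.
#' @export
should_stop <- function(state, config) {
  n <- state$n_administered
  if (config$abort_on_aberrance && is.finite(state$running_outfit %||% NA_real_) &&
      state$running_outfit > config$abort_mnsq)
    return(list(stop = TRUE, reason = "aberrant"))
  if (!is.null(config$max_items) && n >= config$max_items)
    return(list(stop = TRUE, reason = "max_items"))
  if (n >= config$min_items && is.finite(state$se %||% NA_real_) &&
      state$se <= config$se_target)
    return(list(stop = TRUE, reason = "se_met"))
  list(stop = FALSE, reason = NA_character_)
}

#' Run an adaptive testing session
#'
#' Drives a full CAT: the starting measure comes from the examinee's global
#' self-rating; items are administered one at a time by maximum information
#' at the provisional measure; after `burn_in` responses the measure is
#' re-estimated by Newton-Raphson after every answer; the session stops per
#' [should_stop()]. Every step is logged with the model probability of the
#' observed response, the expected score at the pre-response measure, the
#' post-response measure and SE, the running outfit, and an unexpected-
#' response flag (|z| beyond `z_flag` at the step's post-response measure).
#'
#' @param responder function taking a one-row item data.frame and returning
#'   the observed category (integer `0..M`). See [simulated_responder()].
#' @param bank calibrated [item_bank()].
#' @param config a [cat_config()].
#' @param global_rating the examinee's overall self-rating `1..4`.
#' @return object of class `cat_session`: `steps` (data.frame, one row per
#'   administered item), `final` ([ability_estimate()]), `stop_reason`,
#'   `aberrant`, `outfit`, plus the `config` and scale used.
#' @export
run_cat <- function(responder, bank, config, global_rating) {
  stopifnot(inherits(bank, "item_bank"))
  config <- resolve_config(config, bank)
  scale <- bank$scale
  M <- scale$n_categories - 1L
  theta0 <- initial_theta(global_rating, config)

  theta <- theta0
  administered <- integer()
  resp <- data.frame(item_id = integer(), difficulty = numeric(),
                     category = integer())
  steps <- vector("list", config$max_items)
  n <- 0L
  stop_reason <- NA_character_
  repeat {
    item <- select_next_item(theta, bank, administered)
    x <- responder(item)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
        x < 0 || x > M)
      stop("responder returned an out-of-range category for item ",
           item$item_id, call. = FALSE)
    x <- as.integer(x)
    n <- n + 1L
    administered <- c(administered, item$item_id)
    p_pre <- category_probabilities(theta, item$difficulty, scale)
    e_pre <- expected_score(theta, item$difficulty, scale)
    resp <- rbind(resp, data.frame(item_id = item$item_id,
                                   difficulty = item$difficulty,
                                   category = x))
    estimating <- n > config$burn_in
    if (estimating) {
      est <- estimate_theta(resp, scale, init = theta)
      theta <- est$theta
      se <- est$se
    } else se <- NA_real_
    # running person fit at the current provisional measure
    if (estimating) {
      ez <- expected_score(theta, resp$difficulty, scale)
      wz <- item_information(theta, resp$difficulty, scale)
      z <- (resp$category - ez) / sqrt(wz)
      running_outfit <- mean(z^2)
      z_this <- z[n]
    } else {
      running_outfit <- NA_real_
      z_this <- NA_real_
    }
    steps[[n]] <- data.frame(
      step = n, item_id = item$item_id, difficulty = item$difficulty,
      prob_observed = unname(p_pre[x + 1L]), response = x,
      expected_score = e_pre, theta = theta, se = se,
      outfit = running_outfit,
      unexpected = is.finite(z_this) && abs(z_this) > config$z_flag)
    dec <- should_stop(list(n_administered = n, se = se,
                            running_outfit = running_outfit), config)
    if (dec$stop) { stop_reason <- dec$reason; break }
  }
  final <- estimate_theta(resp, scale, init = theta)
  session <- structure(list(steps = do.call(rbind, steps[seq_len(n)]),
                            responses = resp, final = final,
                            stop_reason = stop_reason, config = config,
                            scale = scale),
                       class = "cat_session")
  pf <- person_fit(session)
  session$outfit <- pf$outfit
  session$aberrant <- pf$aberrant
  session$steps$unexpected <- pf$unexpected
  session
}

#' @export
print.cat_session <- function(x, ...) {
  cat(sprintf("CAT session: %d items, stop = %s%s\n", nrow(x$steps),
              x$stop_reason, if (x$aberrant) " [ABERRANT]" else ""))
  cat(sprintf("Final measure %.2f logits (SE %.2f), outfit MNSQ %.2f\n",
              x$final$theta, x$final$se, x$outfit))
  tab <- x$steps
  tab$response <- paste0(tab$response, ifelse(tab$unexpected, "*", ""))
  tab$theta <- ifelse(tab$step <= x$config$burn_in, NA, tab$theta)
  print(tab[c("step", "difficulty", "prob_observed", "response",
              "expected_score", "theta", "se", "outfit")],
        digits = 3, row.names = FALSE, na.print = "-")
  invisible(x)
}

#' Person fit of a completed session
#'
#' Standardized residuals of every administered response, evaluated at the
#' final measure. The session outfit is the mean squared standardized
#' residual across the administered items; values above the configured
#' threshold (default 2.0) flag the record aberrant (possible carelessness,
#' misunderstanding or response sets). Individual responses with |z| beyond
#' `z_flag` (default 1.96) are marked unexpected.
#'
#' @param session a [run_cat()] result.
#' @return list with `outfit`, `z` (per step), `unexpected` (logical per
#'   step), `aberrant`.
#' @export
person_fit <- function(session) {
  stopifnot(inherits(session, "cat_session"))
  resp <- session$responses
  if (nrow(resp) == 0L) stop("session has no responses", call. = FALSE)
  theta <- session$final$theta
  e <- expected_score(theta, resp$difficulty, session$scale)
  w <- item_information(theta, resp$difficulty, session$scale)
  z <- (resp$category - e) / sqrt(w)
  outfit <- mean(z^2)
  list(outfit = outfit, z = z,
       unexpected = abs(z) > session$config$z_flag,
       aberrant = outfit > session$config$aberrance_mnsq)
}
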