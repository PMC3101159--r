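# Independent brute-force oracles: plain-R evaluations of the rating-scale
# model used to cross-check the package's closed-form and Newton-Raphson
# paths. Deliberately written from the category-exponent definition, not by
# calling package internals.

oracle_probs <- function(theta, delta, tau) {
  ex <- c(0, cumsum(theta - delta - tau))
  w <- exp(ex - max(ex))
  w / sum(w)
}

oracle_ll_grid <- function(difficulty, category, tau,
                           lo = -10, hi = 10, step = 0.001) {
  grid <- seq(lo, hi, by = step)
  ll <- numeric(length(grid))
  for (i in seq_along(difficulty)) {
    ex <- outer(grid - difficulty[i], seq_along(tau), function(t, j) t) # t per step
    ex <- sweep(ex, 2L, tau) # theta - delta - tau_j per step
    ex <- cbind(0, t(apply(ex, 1L, cumsum)))
    mx <- apply(ex, 1L, max)
    p <- exp(ex[cbind(seq_along(grid), category[i] + 1L)] - mx) /
      rowSums(exp(ex - mx))
    ll <- ll + log(p)
  }
  list(grid = grid, ll = ll, argmax = grid[which.max(ll)])
}

# default study scale and bank used across tests
study_scale <- function() rating_scale(c(-4.16, -1.50, 2.66))

study_bank <- function() jcq37_bank()

# small synthetic bank for fast structural tests
toy_bank <- function(difficulties = c(-1, -0.3, 0.2, 0.8, 1.5),
                     tau = c(-1.2, 0, 1.2)) {
  n <- length(difficulties)
  item_bank(data.frame(item_id = seq_len(n), label = paste("toy", seq_len(n)),
                       difficulty = difficulties, se = NA_real_,
                       infit = 1, outfit = 1, status = "calibrated"),
            rating_scale(tau))
}
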