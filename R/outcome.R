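#' Softplus inverse link
#'
#' `log(exp(eta) + 1)`, mapping the linear predictor to a strictly positive
#' mean. For `eta > 1` the function is close to the identity, so regression
#' coefficients can be read on the cards scale. Computed overflow-safely:
#' for large `eta` the value is `eta + log1p(exp(-eta))`.
#'
#' @param eta linear predictor (any real, vectorised).
#' @return Positive means.
#' @examples
#' softplus(0)   # log(2)
#' softplus(10)  # ~10.0000454
#' @export
softplus <- function(eta) {
  out <- ifelse(eta > 0, eta + log1p(exp(-abs(eta))), log1p(exp(eta)))
  pmax(out, .Machine$double.xmin)
}

#' Multiple-inflation specification
#'
#' Extra probability mass is placed on attractive outcomes of the card task:
#' 0 (not playing), the set `A` of geometric-pattern counts (multiples of four
#' plus ten by default), and `cap - 1` (turning over all but the last card).
#' Weight `phi[4]` scales the smooth base distribution; `phi[1:3]` are the
#' inflation masses, with `phi[2]` spread uniformly over `A`.
#'
#' @param set_a integer outcomes sharing the `phi[2]` mass.
#' @param cap support cap (deck size; the folded support is `0:cap`).
#' @return An object of class `"inflation_spec"`.
#' @export
inflation_spec <- function(set_a = c(4L, 8L, 10L, 12L, 16L, 20L, 24L),
                           cap = 32L) {
  cap <- as.integer(cap)
  set_a <- sort(unique(as.integer(set_a)))
  if (cap < 2L) stop("'cap' must be at least 2")
  if (any(set_a < 0L) || any(set_a > cap - 1L))
    stop("'set_a' must lie within 0..(cap - 1)")
  if (any(set_a %in% c(0L, cap - 1L)))
    stop("'set_a' must not overlap the singleton inflation points")
  structure(list(set_a = set_a, cap = cap, zero = 0L, top = cap - 1L),
            class = "inflation_spec")
}

check_phi <- function(phi) {
  if (length(phi) != 4L || any(phi < 0) || abs(sum(phi) - 1) > 1e-8)
    stop("'phi' must be 4 non-negative weights summing to 1")
  invisible(phi)
}

#' Negative binomial probability mass function
#'
#' The gamma-mixture parameterisation with mean `mu` and dispersion `delta`
#' (variance `mu + mu^2/delta`); a thin wrapper around [stats::dnbinom()]
#' with `size = delta`.
#'
#' @param z counts (vectorised).
#' @param mu mean, positive.
#' @param delta dispersion, positive (`delta = 1/kappa`).
#' @param log return log probabilities.
#' @return Probabilities.
#' @export
nb_pmf <- function(z, mu, delta, log = FALSE) {
  if (any(mu <= 0) || any(delta <= 0)) stop("'mu' and 'delta' must be positive")
  stats::dnbinom(z, size = delta, mu = mu, log = log)
}

#' Multiple-inflated, tail-folded outcome distribution
#'
#' The distribution of the latent intention Z on `0:cap`:
#' \itemize{
#'   \item `l = 0`: `phi4 f(0) + phi1`
#'   \item `l` in `A`: `phi4 f(l) + phi2 / |A|`
#'   \item `l = cap - 1`: `phi4 f(cap - 1) + phi3`
#'   \item `l = cap`: `phi4 (1 - F(cap - 1))` (all base mass beyond the deck
#'     is folded onto the cap)
#'   \item otherwise: `phi4 f(l)`
#' }
#' with `f`, `F` the negative binomial pmf and cdf. Sums to 1 exactly.
#'
#' @param l outcomes in `0:cap` (vectorised).
#' @param mu,delta negative binomial mean and dispersion.
#' @param phi inflation weights (length 4, simplex).
#' @param spec an [inflation_spec()].
#' @return Probabilities.
#' @export
inflated_pmf <- function(l, mu, delta, phi, spec = inflation_spec()) {
  check_phi(phi)
  l <- as.integer(l)
  if (any(is.na(l)) || any(l < 0L) || any(l > spec$cap))
    stop("'l' must lie in 0..cap")
  n <- max(length(l), length(mu))
  l <- rep_len(l, n); mu <- rep_len(mu, n)
  p <- phi[4] * nb_pmf(pmin(l, spec$cap - 1L), mu, delta)
  at_cap <- l == spec$cap
  if (any(at_cap))
    p[at_cap] <- phi[4] *
      stats::pnbinom(spec$cap - 1L, size = delta, mu = mu[at_cap],
                     lower.tail = FALSE)
  p[l == spec$zero] <- p[l == spec$zero] + phi[1]
  p[l %in% spec$set_a] <- p[l %in% spec$set_a] + phi[2] / length(spec$set_a)
  p[l == spec$top] <- p[l == spec$top] + phi[3]
  p
}

#' Survival function of the inflated outcome distribution
#'
#' `P(Z >= k)`. Uses the closed form
#' `1 - phi4 F(k - 1) - (inflation mass below k)`, so no cumulative sums over
#' the support are needed; floored at 0.
#'
#' @param k thresholds in `0:(cap + 1)` (vectorised).
#' @inheritParams inflated_pmf
#' @return Probabilities `P(Z >= k)`.
#' @export
inflated_survival <- function(k, mu, delta, phi, spec = inflation_spec()) {
  check_phi(phi)
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 0L) || any(k > spec$cap + 1L))
    stop("'k' must lie in 0..cap+1")
  n <- max(length(k), length(mu))
  k <- rep_len(k, n); mu <- rep_len(mu, n)
  base_cdf <- stats::pnbinom(pmin(k, spec$cap) - 1L, size = delta, mu = mu)
  base_cdf[k == 0L] <- 0
  # base mass folded at the cap is only "below k" once k exceeds the cap
  base_cdf[k > spec$cap] <- 1
  n_a_below <- findInterval(k - 0.5, spec$set_a)
  infl <- phi[1] * (k > spec$zero) + phi[2] * n_a_below / length(spec$set_a) +
    phi[3] * (k > spec$top)
  pmax(0, pmin(1, 1 - phi[4] * base_cdf - infl))
}

#' Likelihood contribution of one observation
#'
#' The parameter-dependent factor of the observation likelihood: for an
#' uncensored trial the pmf of the intention at the observed count, for a
#' censored trial the survival probability `P(Z >= y)` (the intention is only
#' known to be at least the card on which the loss occurred).
#'
#' @param y observed number of cards (for censored trials, the index of the
#'   loss card), vectorised.
#' @param c censor flag, 0 or 1.
#' @inheritParams inflated_pmf
#' @return Probabilities.
#' @export
theta <- function(y, c, mu, delta, phi, spec = inflation_spec()) {
  n <- max(length(y), length(c), length(mu))
  y <- rep_len(as.integer(y), n)
  c <- rep_len(as.integer(c), n)
  mu <- rep_len(mu, n)
  if (any(!c %in% c(0L, 1L))) stop("censor flag 'c' must be 0 or 1")
  if (any(c == 1L & y == 0L))
    stop("a censored trial requires y >= 1 (a card must have been turned)")
  out <- numeric(n)
  if (any(c == 0L))
    out[c == 0L] <- inflated_pmf(y[c == 0L], mu[c == 0L], delta, phi, spec)
  if (any(c == 1L))
    out[c == 1L] <- inflated_survival(y[c == 1L], mu[c == 1L], delta, phi,
                                      spec)
  out
}
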