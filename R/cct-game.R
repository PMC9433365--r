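#' Columbia Card Task game configuration
#'
#' A game round of the Columbia Card Task (CCT) presents `n_cards` face-down
#' cards of which `n_loss` are loss cards, placed uniformly at random. Turning
#' a win card earns `gain` points; turning a loss card subtracts `loss` points
#' and ends the round. The configuration fully determines the censoring
#' mechanism (which cards end the round) and therefore the parameter-free
#' outcome kernel [omega()].
#'
#' Card positions are indexed 1-based (the k-th card turned); intentions and
#' observed outcomes are 0-based counts in `0:n_cards`.
#'
#' @param gain points earned per win card (non-negative).
#' @param loss points subtracted when a loss card is hit (non-negative).
#' @param n_loss number of loss cards in the deck.
#' @param n_cards deck size (32 for the CCT).
#' @return An object of class `"cct_config"`.
#' @examples
#' cfg <- cct_config(gain = 30, loss = 750, n_loss = 1)
#' censor_hazard(1, cfg)
#' @export
cct_config <- function(gain = 30, loss = 250, n_loss = 1, n_cards = 32) {
  stopifnot(length(gain) == 1, length(loss) == 1, length(n_loss) == 1,
            length(n_cards) == 1)
  n_cards <- as.integer(n_cards)
  n_loss <- as.integer(n_loss)
  if (is.na(n_cards) || n_cards < 1L)
    stop("'n_cards' must be a positive integer")
  if (is.na(n_loss) || n_loss < 0L || n_loss > n_cards)
    stop("'n_loss' must be an integer in 0..n_cards")
  if (gain < 0 || loss < 0) stop("'gain' and 'loss' must be non-negative")
  structure(list(gain = as.numeric(gain), loss = as.numeric(loss),
                 n_loss = n_loss, n_cards = n_cards),
            class = "cct_config")
}

#' @export
print.cct_config <- function(x, ...) {
  cat(sprintf("CCT game: %d cards (%d loss), gain %g, loss %g\n",
              x$n_cards, x$n_loss, x$gain, x$loss))
  invisible(x)
}

#' The eight canonical CCT game settings
#'
#' The CCT crosses gain amount (10, 30), loss amount (250, 750) and number of
#' loss cards (1, 3); trials are administered in blocks containing each setting
#' once.
#'
#' @return A data frame with columns `gain`, `loss`, `n_loss` (8 rows).
#' @export
cct_settings <- function() {
  expand.grid(gain = c(10, 30), loss = c(250, 750), n_loss = c(1L, 3L),
              KEEP.OUT.ATTRS = FALSE)
}

#' Per-card censoring hazard
#'
#' Probability that the k-th card turned is a loss card, given the first
#' k - 1 cards were win cards. With `n_loss` loss cards placed uniformly in
#' the deck this is the hypergeometric first-loss hazard
#' `n_loss / (n_cards - k + 1)`.
#'
#' @param k card index (1-based), vectorised.
#' @param config a [cct_config()].
#' @return Hazard probabilities in `[0, 1]`.
#' @export
censor_hazard <- function(k, config) {
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 1L) || any(k > config$n_cards))
    stop("card index 'k' out of range 1..n_cards")
  pmin(1, pmax(0, config$n_loss / (config$n_cards - k + 1)))
}

#' Survival probability of the first k cards
#'
#' Probability that none of the first `k` cards turned is a loss card,
#' `prod_{i=1..k} (1 - p_i)`; an empty product for `k = 0`.
#'
#' @param k number of cards (0-based count), vectorised.
#' @inheritParams censor_hazard
#' @return Probabilities in `[0, 1]`.
#' @export
survival_prob <- function(k, config) {
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 0L) || any(k > config$n_cards))
    stop("'k' out of range 0..n_cards")
  if (config$n_loss == 0L) return(rep(1, length(k)))
  surv <- cumprod(1 - censor_hazard(seq_len(config$n_cards), config))
  c(1, surv)[k + 1L]
}

#' Outcome-probability kernel of the game mechanics
#'
#' Probability of observing `k` cards with censor flag `c` given the latent
#' intention `l`: for uncensored trials (`c = 0`) the player reached their
#' intention, so the probability is `survival_prob(k)` when `l == k` and 0
#' otherwise; for censored trials (`c = 1`) the k-th card was the loss card,
#' with probability `survival_prob(k - 1) * censor_hazard(k)` whenever
#' `l >= k >= 1`. These probabilities depend only on the game settings, never
#' on model parameters (exogenous censoring).
#'
#' @param k observed number of cards, in `0:n_cards` (vectorised).
#' @param c censor flag, 0 or 1 (vectorised).
#' @param l latent intention, in `0:n_cards` (vectorised).
#' @inheritParams censor_hazard
#' @return Probabilities.
#' @export
omega <- function(k, c, l, config) {
  n <- max(length(k), length(c), length(l))
  k <- rep_len(as.integer(k), n)
  c <- rep_len(as.integer(c), n)
  l <- rep_len(as.integer(l), n)
  if (any(!c %in% c(0L, 1L))) stop("censor flag 'c' must be 0 or 1")
  if (any(k < 0L | k > config$n_cards | l < 0L | l > config$n_cards))
    stop("'k' and 'l' must lie in 0..n_cards")
  out <- numeric(n)
  unc <- c == 0L & l == k
  out[unc] <- survival_prob(k[unc], config)
  cen <- c == 1L & k >= 1L & l >= k
  if (any(cen))
    out[cen] <- survival_prob(k[cen] - 1L, config) *
      censor_hazard(k[cen], config)
  out
}

#' Score of a completed CCT round
#'
#' `n_wins * gain - loss * hit_loss`: all win cards turned before the round
#' ended are kept; the loss amount is subtracted once if the round ended on a
#' loss card.
#'
#' @param n_wins number of win cards turned (vectorised).
#' @param hit_loss logical (or 0/1), whether the round ended on a loss card.
#' @inheritParams censor_hazard
#' @return Points.
#' @examples
#' trial_score(10, TRUE, cct_config(gain = 30, loss = 750)) # -450
#' @export
trial_score <- function(n_wins, hit_loss, config) {
  if (any(n_wins < 0)) stop("'n_wins' must be non-negative")
  n_wins * config$gain - config$loss * as.numeric(hit_loss)
}

#' Expected value of an intention
#'
#' Expected points of the strategy "turn over cards until `l` are turned or a
#' loss card appears". Wins turned before a loss are kept; hitting a loss at
#' position j yields `(j - 1) * gain - loss`.
#'
#' @param l intended number of cards, in `0:n_cards` (vectorised).
#' @inheritParams censor_hazard
#' @return Expected points.
#' @export
ev_of_intention <- function(l, config) {
  l <- as.integer(l)
  if (any(l < 0L | l > config$n_cards)) stop("'l' out of range 0..n_cards")
  vapply(l, function(li) {
    if (li == 0L) return(0)
    j <- seq_len(li)
    hit <- survival_prob(j - 1L, config) * censor_hazard(j, config)
    sum(hit * ((j - 1) * config$gain - config$loss)) +
      survival_prob(li, config) * li * config$gain
  }, numeric(1))
}

#' Expected-value-optimal intentions
#'
#' The set of intentions maximising [ev_of_intention()] over `0:n_cards`.
#' Exact ties occur for some game settings; the full argmax set is returned
#' with the smallest maximiser as the convenience scalar.
#'
#' @inheritParams censor_hazard
#' @return A list with `optimal` (smallest maximiser), `argmax` (all
#'   maximisers) and `ev` (the maximum expected value).
#' @export
ev_optimal <- function(config) {
  l <- 0:config$n_cards
  ev <- ev_of_intention(l, config)
  mx <- max(ev)
  arg <- l[abs(ev - mx) < 1e-9]
  list(optimal = arg[1L], argmax = arg, ev = mx)
}

#' Expected-value strategy table for the canonical CCT settings
#'
#' @param n_cards deck size.
#' @return A data frame with one row per game setting and columns `gain`,
#'   `loss`, `n_loss`, `optimal`, `ev`, `ties` (comma-separated argmax set).
#' @export
ev_table <- function(n_cards = 32) {
  st <- cct_settings()
  res <- lapply(seq_len(nrow(st)), function(i) {
    opt <- ev_optimal(cct_config(st$gain[i], st$loss[i], st$n_loss[i], n_cards))
    data.frame(gain = st$gain[i], loss = st$loss[i], n_loss = st$n_loss[i],
               optimal = opt$optimal, ev = opt$ev,
               ties = paste(opt$argmax, collapse = ","))
  })
  do.call(rbind, res)
}
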