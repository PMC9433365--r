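# Enumeration oracles used across tests: play the card game exhaustively over
# all uniform placements of the loss cards, independent of the package's
# closed-form hazard/survival arithmetic.

# all possible first-loss positions and their probabilities, by enumerating
# every placement of n_loss loss cards among n_cards positions
enumerate_first_loss <- function(n_loss, n_cards) {
  if (n_loss == 0) return(data.frame(j = Inf, prob = 1))
  placements <- utils::combn(n_cards, n_loss)
  j <- apply(placements, 2, min)
  tab <- table(j)
  data.frame(j = as.integer(names(tab)),
             prob = as.vector(tab) / ncol(placements))
}

# P(Y = k, C = c | intention l) by playing out each placement
enumerate_outcome_given_intention <- function(l, n_loss, n_cards) {
  fl <- enumerate_first_loss(n_loss, n_cards)
  out <- matrix(0, n_cards + 1, 2, dimnames = list(0:n_cards, c("c0", "c1")))
  for (r in seq_len(nrow(fl))) {
    if (fl$j[r] <= l) out[fl$j[r] + 1, "c1"] <- out[fl$j[r] + 1, "c1"] + fl$prob[r]
    else out[l + 1, "c0"] <- out[l + 1, "c0"] + fl$prob[r]
  }
  out
}

# expected score of intention l by exhaustive play-out
enumerate_ev <- function(l, config) {
  fl <- enumerate_first_loss(config$n_loss, config$n_cards)
  ev <- 0
  for (r in seq_len(nrow(fl))) {
    if (fl$j[r] <= l)
      ev <- ev + fl$prob[r] * ((fl$j[r] - 1) * config$gain - config$loss)
    else
      ev <- ev + fl$prob[r] * l * config$gain
  }
  ev
}

# random simplex weights bounded away from the boundary
random_phi <- function() {
  x <- stats::rgamma(4, 1) + 0.05
  x / sum(x)
}

# small two-segment trial table for fitting tests
tiny_sim <- function(n_persons = 120, n_trials = 8, seed = 11,
                     params = recovery_params(1)) {
  simulate_cct(params, n_persons, n_trials, seed = seed)
}
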