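#' Expected number of cards for one linear-predictor set
#'
#' `sum_l l * sum_s w_s Pr(Z = l | mu_s)` with segment weights `w` (prior
#' `pi` or a posterior row). Lies in `[0, cap]` because the support is folded
#' at the deck size. See [predict.cmm()] for the per-trial version on a
#' fitted model.
#'
#' @param params parameter list (see [cmm_transform()]).
#' @param eta_s numeric vector: the linear predictor per segment for this
#'   trial.
#' @param weights segment weights (defaults to `params$pi`).
#' @param spec an [inflation_spec()].
#' @return Scalar expectation.
#' @export
expected_cards <- function(params, eta_s, weights = params$pi,
                           spec = inflation_spec()) {
  S <- length(params$alpha)
  stopifnot(length(eta_s) == S, length(weights) == S)
  weights <- weights / sum(weights)
  ell <- 0:spec$cap
  out <- 0
  for (s in seq_len(S)) {
    pm <- inflated_pmf(ell, softplus(eta_s[s]), params$delta, params$phi,
                       spec)
    out <- out + weights[s] * sum(ell * pm)
  }
  out
}

#' RMSE and MAD of uncensored predictions
#'
#' Root mean square error and mean absolute deviation of observed minus
#' expected cards, over uncensored trials only (censored trials do not
#' observe the full intention).
#'
#' @param observed observed counts.
#' @param expected expected counts.
#' @param censored optional 0/1 flags; censored rows are dropped.
#' @return A list with `rmse` and `mad`.
#' @export
fit_metrics <- function(observed, expected, censored = NULL) {
  if (!is.null(censored)) {
    keep <- censored == 0
    observed <- observed[keep]; expected <- expected[keep]
  }
  if (!length(observed)) stop("no uncensored observations")
  r <- observed - expected
  list(rmse = sqrt(mean(r^2)), mad = mean(abs(r)))
}

#' Censoring-corrected predicted outcome distribution
#'
#' The joint distribution of the observable pair (cards, censor flag) under
#' one game setting: `P(Y = k, C = c) = sum_l Omega_{kl,c} Pr(Z = l)`, i.e.
#' `survival_prob(k) * Pr(Z = k)` for uncensored outcomes and
#' `survival_prob(k - 1) * hazard(k) * P(Z >= k)` for censored ones. Sums to
#' 1 over all `(k, c)`.
#'
#' @param pmf probability vector of the intention over `0:cap` (e.g. from
#'   [inflated_pmf()], possibly mixture-averaged).
#' @param config a [cct_config()] with `n_cards == length(pmf) - 1`.
#' @return A `(cap + 1) x 2` matrix with columns `uncensored`, `censored`
#'   and outcomes `0:cap` as rows.
#' @export
predicted_joint_distribution <- function(pmf, config) {
  cap <- config$n_cards
  if (length(pmf) != cap + 1L) stop("'pmf' must have length n_cards + 1")
  if (abs(sum(pmf) - 1) > 1e-6) stop("'pmf' must sum to 1")
  k <- 0:cap
  unc <- survival_prob(k, config) * pmf
  surv_up <- rev(cumsum(rev(pmf)))  # P(Z >= k)
  cen <- c(0, survival_prob(0:(cap - 1L), config) *
             censor_hazard(1:cap, config) * surv_up[-1])
  out <- cbind(uncensored = unc, censored = cen)
  rownames(out) <- k
  out
}

# mixture- and posterior-averaged joint distribution over the trials of a fit
# that used a given game-setting subset (all rows by default)
average_joint_distribution <- function(fit, data, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(data))
  cap <- fit$spec$cap
  ell <- 0:cap
  frame <- fit$frame
  W <- fit$posterior[frame$person, , drop = FALSE]
  eta_all <- vapply(seq_len(fit$S), function(s)
    linear_predictor(fit$params$alpha[s], fit$params$gamma,
                     fit$params$gamma_s[s, ], frame$design),
    numeric(frame$design$n))
  acc <- matrix(0, cap + 1L, 2)
  for (i in rows) {
    pm <- numeric(cap + 1L)
    for (s in seq_len(fit$S)) {
      pm <- pm + W[i, s] *
        inflated_pmf(ell, softplus(eta_all[i, s]), fit$params$delta,
                     fit$params$phi, fit$spec)
    }
    cfg <- cct_config(data$gain[i], data$loss[i], data$n_loss[i], cap)
    acc <- acc + predicted_joint_distribution(pm, cfg)
  }
  acc / length(rows)
}

#' Goodness of fit between observed and predicted outcome distributions
#'
#' Chi-square statistic `n * sum (obs - pred)^2 / pred` over the uncensored
#' support, the Pearson correlation of the probability vectors over
#' `0:(cap-1)` (outcome `cap` is unreachable uncensored under full hazard
#' support and is excluded by default), and the Hellinger distance
#' `sqrt(sum (sqrt(obs) - sqrt(pred))^2) / sqrt(2)`. Predicted categories
#' with expected count below `pool_below` are pooled with their left
#' neighbour before the chi-square.
#'
#' @param observed observed probability vector over `0:cap`.
#' @param predicted predicted probability vector over the same support.
#' @param n number of observations behind `observed`.
#' @param include_cap include the folded outcome `cap` in the correlation.
#' @param pool_below minimum expected count per chi-square category.
#' @return A list with `chisq`, `df`, `p_value`, `correlation`, `hellinger`.
#' @export
gof <- function(observed, predicted, n, include_cap = FALSE,
                pool_below = 5) {
  if (length(observed) != length(predicted))
    stop("distributions must share a support")
  observed <- observed / sum(observed)
  predicted <- predicted / sum(predicted)
  K <- length(observed)
  # pool sparse predicted categories leftwards
  grp <- integer(K); g <- 1L; acc <- 0
  for (j in seq_len(K)) {
    grp[j] <- g
    acc <- acc + predicted[j] * n
    if (acc >= pool_below && j < K) { g <- g + 1L; acc <- 0 }
  }
  if (acc < pool_below && g > 1L) grp[grp == g] <- g - 1L
  op <- tapply(observed, grp, sum)
  pp <- tapply(predicted, grp, sum)
  chisq <- n * sum((op - pp)^2 / pp)
  df <- length(op) - 1L
  idx <- if (include_cap) seq_len(K) else seq_len(K - 1L)
  corr <- if (length(idx) > 1 && stats::sd(observed[idx]) > 0 &&
              stats::sd(predicted[idx]) > 0)
    stats::cor(observed[idx], predicted[idx]) else NA_real_
  hell <- sqrt(sum((sqrt(observed) - sqrt(predicted))^2)) / sqrt(2)
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       correlation = corr, hellinger = hell)
}

#' Outcome category profile of a person
#'
#' Proportions over the four outcome categories used to display attraction
#' to special outcomes: (1) zero cards, (2) the geometric-pattern set `A`,
#' (3) `cap - 1` cards, (4) all outcomes. An outcome falling in categories
#' 1-3 contributes weight 1/2 to its special category and 1/2 to category 4;
#' all other outcomes contribute fully to category 4. Proportions are
#' normalised to sum to 1.
#'
#' @param outcomes the person's uncensored outcomes.
#' @param spec an [inflation_spec()].
#' @return Numeric vector of 4 proportions.
#' @export
category_profile <- function(outcomes, spec = inflation_spec()) {
  if (!length(outcomes)) stop("'outcomes' must be nonempty")
  w <- matrix(0, length(outcomes), 4)
  special <- cbind(outcomes == spec$zero, outcomes %in% spec$set_a,
                   outcomes == spec$top)
  any_special <- rowSums(special) > 0
  w[, 1:3] <- special * 0.5
  w[, 4] <- ifelse(any_special, 0.5, 1)
  tot <- colSums(w)
  tot / sum(tot)
}

#' Posterior-weighted segment profiles of external scores
#'
#' For each segment s and each (z-scored) external variable, the
#' posterior-weighted mean `m_s = sum_i w_is z_i / sum_i w_is`, with a Wald
#' chi-square test (df = S - 1) of equality of the segment means. The
#' variance of each weighted mean uses the weighted within-segment variance
#' over the effective sample size `(sum w)^2 / sum w^2`; the test statistic
#' is the inverse-variance-weighted heterogeneity statistic.
#'
#' @param posterior `N x S` posterior membership matrix (rows sum to 1).
#' @param scores data frame or matrix of external variables (one row per
#'   person, aligned with `posterior`); z-scored internally.
#' @return A list with `means` (variables x segments), `wald` (statistic,
#'   df, p-value per variable) and `effective_n` per segment.
#' @export
segment_profile <- function(posterior, scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(posterior))
    stop("'scores' and 'posterior' must have the same number of rows")
  if (any(abs(rowSums(posterior) - 1) > 1e-6))
    stop("posterior rows must sum to 1")
  S <- ncol(posterior)
  z <- scale(scores)
  n_eff <- colSums(posterior)^2 / colSums(posterior^2)
  small <- n_eff < 2
  if (any(small)) {
    warning("segment(s) with effective size < 2 excluded from the Wald test: ",
            paste(which(small), collapse = ", "))
  }
  means <- matrix(NA_real_, ncol(z), S,
                  dimnames = list(colnames(scores),
                                  paste0("segment", seq_len(S))))
  wald <- data.frame(statistic = numeric(ncol(z)), df = integer(ncol(z)),
                     p_value = numeric(ncol(z)),
                     row.names = colnames(scores))
  for (v in seq_len(ncol(z))) {
    m <- colSums(posterior * z[, v]) / colSums(posterior)
    means[v, ] <- m
    vv <- vapply(seq_len(S), function(s) {
      wv <- sum(posterior[, s] * (z[, v] - m[s])^2) / sum(posterior[, s])
      wv / n_eff[s]
    }, numeric(1))
    use <- !small & vv > 0
    if (sum(use) > 1) {
      mw <- sum(m[use] / vv[use]) / sum(1 / vv[use])
      W <- sum((m[use] - mw)^2 / vv[use])
      df <- sum(use) - 1L
      wald[v, ] <- c(W, df, stats::pchisq(W, df, lower.tail = FALSE))
    } else wald[v, ] <- c(NA, NA, NA)
  }
  list(means = means, wald = wald, effective_n = n_eff)
}
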