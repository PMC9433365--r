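# draw latent intentions Z from the inflated outcome distribution, one per mu
draw_intentions <- function(mu, delta, phi, spec) {
  ell <- 0:spec$cap
  P <- vapply(ell, function(l) inflated_pmf(l, mu, delta, phi, spec),
              numeric(length(mu)))
  cp <- P %*% upper.tri(diag(length(ell)), diag = TRUE)
  u <- stats::runif(length(mu))
  as.integer(rowSums(u > cp))
}

# draw the position of the first loss card for each trial (uniform placement
# of n_loss loss cards); distribution P(J = j) = S(j-1) p_j
draw_first_loss <- function(n_loss, n_cards) {
  ids <- unique(n_loss)
  J <- integer(length(n_loss))
  for (nl in ids) {
    sel <- n_loss == nl
    if (nl == 0L) { J[sel] <- n_cards + 1L; next }
    cfg <- cct_config(n_loss = nl, n_cards = n_cards)
    j <- seq_len(n_cards)
    pj <- survival_prob(j - 1L, cfg) * censor_hazard(j, cfg)
    J[sel] <- sample.int(n_cards, sum(sel), replace = TRUE, prob = pj)
  }
  J
}

# simulate y/censored for covariate rows at given parameters (segments drawn
# per person from pi); rows must carry person, trial, gain, loss, n_loss and
# the schema covariates
simulate_from_params <- function(params, rows, schema, spec, scalers = NULL) {
  req <- c("person", "trial", "gain", "loss", "n_loss")
  if (!all(req %in% names(rows)))
    stop("rows must contain columns ", paste(req, collapse = ", "))
  design <- encode_design(schema, rows, scalers = scalers)
  S <- length(params$alpha)
  if (is.null(params$gamma_s)) params$gamma_s <- matrix(0, S, 0)
  pid <- factor(rows$person, levels = unique(rows$person))
  seg_per_person <- sample.int(S, nlevels(pid), replace = TRUE,
                               prob = rep_len(params$pi, S))
  seg <- seg_per_person[as.integer(pid)]
  eta <- numeric(nrow(rows))
  for (s in seq_len(S)) {
    sel <- seg == s
    if (!any(sel)) next
    eta[sel] <- linear_predictor(params$alpha[s], params$gamma,
                                 params$gamma_s[s, ], design)[sel]
  }
  mu <- softplus(eta)
  Z <- draw_intentions(mu, params$delta, params$phi, spec)
  J <- draw_first_loss(as.integer(rows$n_loss), spec$cap)
  censored <- as.integer(J <= Z)
  rows$y <- ifelse(censored == 1L, J, Z)
  rows$censored <- censored
  attr(rows, "latent") <- data.frame(segment = seg, intention = Z,
                                     first_loss = J)
  rows
}

#' Covariate schema of the parameter-recovery design
#'
#' The recovery study models only the three game-setting effects, entered as
#' 0/1 indicators of the riskier setting level: `x_gain` (1 for gain 30),
#' `x_loss` (1 for loss 750) and `x_cards` (1 for three loss cards), so each
#' `beta` is the full effect of switching that setting. The codes are left
#' unscaled so the simulator and the fitter share the same coefficient
#' scale.
#'
#' @return A [cmm_schema()].
#' @export
recovery_schema <- function() {
  cmm_schema(numeric = c("x_gain", "x_loss", "x_cards"),
             unscaled = c("x_gain", "x_loss", "x_cards"))
}

#' Reference true-parameter sets of the recovery study design
#'
#' Two-segment generating parameters used to exercise parameter recovery:
#' game-setting effects `beta` (on the 0/1 codes of [recovery_schema()]),
#' intercepts through their square-root increments `atilde`
#' (`alpha = cumsum(atilde^2)`), dispersion `delta`, inflation logits `tau`
#' and segment logit `sigma`. Set 1 has `beta = (2, -3, -6)`,
#' `atilde = (3.39, 2.92)`; set 2 has `beta = (6, -4, -7.5)`,
#' `atilde = (3.87, 2.83)`; both share `delta = 3`,
#' `tau = (-3.5, -1.9, -2.1)` and `sigma = -0.4`, giving inflation weights
#' close to those seen in card-task data.
#'
#' @param set 1 or 2.
#' @return A parameter list as used by [cmm_transform()], with the
#'   transformed true values in attribute `"transformed"`.
#' @export
recovery_params <- function(set = 1) {
  atilde <- if (set == 1) c(3.39, 2.92) else c(3.87, 2.83)
  beta <- if (set == 1) c(2, -3, -6) else c(6, -4, -7.5)
  tau <- c(-3.5, -1.9, -2.1)
  sigma <- -0.4
  params <- list(alpha = cumsum(atilde^2), gamma = beta,
                 gamma_s = matrix(0, 2, 0), delta = 3,
                 phi = softmax_last(tau), pi = softmax_last(sigma))
  attr(params, "transformed") <- c(atilde1 = atilde[1], atilde2 = atilde[2],
                                   beta1 = beta[1], beta2 = beta[2],
                                   beta3 = beta[3], delta = 3,
                                   tau1 = tau[1], tau2 = tau[2],
                                   tau3 = tau[3], sigma = sigma)
  params
}

#' Simulate Columbia Card Task data from known parameters
#'
#' Generates a long trial table under the model's own data-generating
#' process: each person is assigned a latent segment from `pi`; each block of
#' 8 trials contains the canonical 2x2x2 game settings once, in a freshly
#' randomised order; the latent intention Z is drawn from the inflated
#' outcome distribution at `mu = softplus(eta_its)`; loss cards are placed
#' uniformly, and the trial is censored (`y` = index of the loss card) when
#' the first loss card precedes the intention.
#'
#' @param params generating parameter list (see [cmm_transform()] /
#'   [recovery_params()]).
#' @param n_persons number of persons.
#' @param n_trials trials per person; must be a multiple of 8 (the block
#'   size).
#' @param schema covariate schema used to build `eta`; defaults to
#'   [recovery_schema()].
#' @param spec an [inflation_spec()].
#' @param seed optional seed.
#' @return A trial table with columns `person`, `trial`, `gain`, `loss`,
#'   `n_loss`, the 0/1 codes `x_gain`, `x_loss`, `x_cards`, `y`, `censored`,
#'   and the latent draws in attribute `"latent"`.
#' @export
simulate_cct <- function(params, n_persons = 500, n_trials = 8,
                         schema = recovery_schema(), spec = inflation_spec(),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_persons < 1) stop("'n_persons' must be >= 1")
  st <- cct_settings()
  B <- nrow(st)
  if (n_trials %% B != 0)
    stop("'n_trials' must be a multiple of the block size (", B, ")")
  blocks <- n_trials %/% B
  ord <- unlist(lapply(seq_len(n_persons * blocks),
                       function(i) sample.int(B)))
  rows <- st[ord, , drop = FALSE]
  rows$person <- rep(seq_len(n_persons), each = n_trials)
  rows$trial <- rep(seq_len(n_trials), n_persons)
  rownames(rows) <- NULL
  rows$x_gain <- as.numeric(rows$gain == 30)
  rows$x_loss <- as.numeric(rows$loss == 750)
  rows$x_cards <- as.numeric(rows$n_loss == 3L)
  rows <- rows[, c("person", "trial", "gain", "loss", "n_loss",
                   "x_gain", "x_loss", "x_cards")]
  simulate_from_params(params, rows, schema, spec)
}

#' Parameter-recovery study
#'
#' Repeatedly simulates card-task data at known two-segment parameters and
#' refits the model (with the true values as start values, for speed),
#' summarising the sampling distribution of the ten unique parameters
#' (`beta1..3`, `atilde1..2`, `delta`, `tau1..3`, `sigma`) by mean, median,
#' SD, average estimated SE, RMSE, MAD and 95% CI coverage. Coverage uses
#' `estimate +/- 1.96 SE` on the unconstrained scale for all parameters
#' except `delta`, whose SE is mapped to the natural scale.
#'
#' @param params true generating parameters (e.g. [recovery_params()]).
#' @param n_reps number of replications (>= 2).
#' @param n_persons,n_trials design size per replication.
#' @param seed seed for the whole study (one RNG stream).
#' @param compare_bic_reps also fit a one-segment model on this many of the
#'   replications and tally how often the two-segment BIC is lower.
#' @param schema,spec as in [simulate_cct()].
#' @return An object of class `"cmm_recovery"`: a per-parameter summary table
#'   plus `n_reps`, `n_excluded` (non-convergent replications) and, when
#'   requested, `bic_preference` (fraction of replications preferring two
#'   segments).
#' @export
recovery_study <- function(params, n_reps = 100, n_persons = 500,
                           n_trials = 8, seed = 1, compare_bic_reps = 0,
                           schema = recovery_schema(),
                           spec = inflation_spec()) {
  if (n_reps < 2) stop("'n_reps' must be >= 2")
  set.seed(seed)
  truth <- attr(params, "transformed")
  if (is.null(truth)) {
    v <- cmm_transform(params)
    truth <- c(atilde1 = v[[1]], atilde2 = v[[2]], beta1 = v[[3]],
               beta2 = v[[4]], beta3 = v[[5]], delta = params$delta,
               tau1 = v[[7]], tau2 = v[[8]], tau3 = v[[9]], sigma = v[[10]])
  }
  nm <- c("beta1", "beta2", "beta3", "atilde1", "atilde2", "delta",
          "tau1", "tau2", "tau3", "sigma")
  est <- se <- matrix(NA_real_, n_reps, length(nm),
                      dimnames = list(NULL, nm))
  bic_pref <- rep(NA, n_reps)
  excluded <- 0L
  for (r in seq_len(n_reps)) {
    dat <- simulate_cct(params, n_persons, n_trials, schema, spec)
    fit <- tryCatch(
      cmm(dat, segments = 2, schema = schema, spec = spec, start = params,
          control = cmm_control()),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$convergence$converged &&
      !anyNA(fit$se_transformed)
    if (!ok) { excluded <- excluded + 1L } else {
      v <- fit$par; s <- fit$se_transformed
      # layout: atilde (2), gamma (3), log_delta, tau (3), sigma
      est[r, ] <- c(v[3:5], abs(v[1:2]), exp(v[6]), v[7:9], v[10])
      se[r, ] <- c(s[3:5], s[1:2], exp(v[6]) * s[6], s[7:9], s[10])
      if (r <= compare_bic_reps) {
        fit1 <- cmm(dat, segments = 1, schema = schema, spec = spec,
                    control = cmm_control())
        bic_pref[r] <- cmm_bic(fit) < cmm_bic(fit1)
      }
    }
  }
  keep <- !is.na(est[, 1])
  est <- est[keep, , drop = FALSE]; se <- se[keep, , drop = FALSE]
  tv <- truth[nm]
  cover <- colMeans(abs(sweep(est, 2, tv)) <= 1.96 * se)
  tab <- data.frame(
    parameter = nm, true = unname(tv),
    mean = colMeans(est), median = apply(est, 2, stats::median),
    sd = apply(est, 2, stats::sd), mean_se = colMeans(se),
    rmse = sqrt(colMeans(sweep(est, 2, tv)^2)),
    mad = colMeans(abs(sweep(est, 2, tv))),
    coverage = unname(cover))
  rownames(tab) <- nm
  structure(list(table = tab, n_reps = sum(keep), n_excluded = excluded,
                 bic_preference = if (compare_bic_reps > 0)
                   mean(bic_pref[seq_len(compare_bic_reps)], na.rm = TRUE)
                 else NA_real_,
                 estimates = est, ses = se),
            class = "cmm_recovery")
}

#' @export
print.cmm_recovery <- function(x, digits = 3, ...) {
  cat("Parameter recovery over", x$n_reps, "replications",
      if (x$n_excluded) paste0("(", x$n_excluded, " excluded)"), "\n")
  print(round(x$table[, -1], digits))
  if (!is.na(x$bic_preference))
    cat(sprintf("two-segment BIC preferred in %.0f%% of compared replications\n",
                100 * x$bic_preference))
  invisible(x)
}

#' Fraction of replications in which BIC detects two segments
#'
#' Simulates from two-segment truth and compares the BIC of one- and
#' two-segment fits per replication.
#'
#' @inheritParams recovery_study
#' @return Fraction in `[0, 1]`.
#' @export
bic_preference <- function(params, n_reps = 50, n_persons = 500,
                           n_trials = 8, seed = 1,
                           schema = recovery_schema(),
                           spec = inflation_spec()) {
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  rs <- recovery_study(params, n_reps = max(n_reps, 2),
                       n_persons = n_persons, n_trials = n_trials,
                       seed = seed, compare_bic_reps = n_reps,
                       schema = schema, spec = spec)
  rs$bic_preference
}
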