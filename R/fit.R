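# ---- parameter transforms -------------------------------------------------

par_layout <- function(S, p, q) {
  n <- 0L
  idx <- function(k) { out <- n + seq_len(k); n <<- n + k; out }
  list(atilde = idx(S), gamma = idx(p), gamma_s = idx(S * q),
       log_delta = idx(1L), tau = idx(3L), sigma = idx(S - 1L), n = n + 0L)
}

softmax_last <- function(logits) {
  # softmax over c(logits, 0); the last category is the reference
  z <- c(logits, 0)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Map model parameters to the unconstrained optimisation space
#'
#' Segment intercepts are reparameterised through cumulative squares
#' (`alpha_s = sum_{r<=s} atilde_r^2`, enforcing a non-decreasing, non-negative
#' intercept sequence), the dispersion through its log, and the inflation and
#' segment probabilities through multinomial logits with the last category as
#' reference (`tau`, `sigma`). Coefficients already live on an unconstrained
#' sum-to-zero basis. The map is a bijection on the interior; see
#' [cmm_untransform()] for the inverse.
#'
#' @param params list with elements `alpha` (length S, non-decreasing,
#'   `alpha[1] >= 0`), `gamma` (common free-basis coefficients), `gamma_s`
#'   (S x q matrix, may have 0 columns), `delta` (> 0), `phi` (simplex of 4),
#'   `pi` (simplex of S).
#' @return Named numeric vector of unconstrained parameters.
#' @export
cmm_transform <- function(params) {
  alpha <- params$alpha
  S <- length(alpha)
  if (is.unsorted(alpha) || alpha[1] < 0)
    stop("'alpha' must be non-negative and non-decreasing")
  check_phi(params$phi)
  if (length(params$pi) != S || any(params$pi < 0) ||
      abs(sum(params$pi) - 1) > 1e-8)
    stop("'pi' must be a length-S simplex")
  if (params$delta <= 0) stop("'delta' must be positive")
  if (any(params$phi == 0) || (S > 1 && any(params$pi == 0)))
    stop("boundary 'phi' or 'pi' (exact zeros) cannot be transformed")
  gs <- params$gamma_s
  if (is.null(gs)) gs <- matrix(0, S, 0)
  c(atilde = sqrt(diff(c(0, alpha))),
    gamma = params$gamma,
    gamma_s = as.vector(t(gs)),
    log_delta = log(params$delta),
    tau = log(params$phi[1:3] / params$phi[4]),
    sigma = if (S > 1) log(params$pi[-S] / params$pi[S]) else numeric(0))
}

#' Map unconstrained parameters back to the model scale
#'
#' Inverse of [cmm_transform()].
#'
#' @param vec unconstrained parameter vector.
#' @param S number of segments.
#' @param p number of free common coefficients.
#' @param q number of free segment-specific coefficients (per segment).
#' @return A parameter list (see [cmm_transform()]).
#' @export
cmm_untransform <- function(vec, S, p = 0L, q = 0L) {
  lay <- par_layout(S, p, q)
  if (length(vec) != lay$n) stop("parameter vector has wrong length")
  vec <- unname(vec)
  list(alpha = cumsum(vec[lay$atilde]^2),
       gamma = vec[lay$gamma],
       gamma_s = matrix(vec[lay$gamma_s], nrow = S, byrow = TRUE),
       delta = exp(vec[lay$log_delta]),
       phi = softmax_last(vec[lay$tau]),
       pi = if (S > 1) softmax_last(vec[lay$sigma]) else 1)
}

# ---- internal fit frame ---------------------------------------------------

validate_trials <- function(data, cap) {
  req <- c("person", "trial", "y", "censored")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stop("trial table is empty")
  bad <- which(!data$censored %in% c(0, 1))
  if (length(bad))
    stop("'censored' must be 0/1; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(data$y < 0 | data$y > cap | data$y != floor(data$y))
  if (length(bad))
    stop("'y' must be an integer in 0..", cap, "; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(data$censored == 1 & data$y == 0)
  if (length(bad))
    stop("censored trials require y >= 1; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(data$person, data$trial)
  if (anyDuplicated(key))
    stop("duplicated (person, trial) pairs in trial table")
  invisible(data)
}

make_frame <- function(data, schema, spec, scalers = NULL) {
  validate_trials(data, spec$cap)
  design <- encode_design(schema, data, scalers = scalers)
  pid <- factor(data$person, levels = unique(data$person))
  list(y = as.integer(data$y), cflag = as.integer(data$censored),
       person = as.integer(pid), person_ids = levels(pid),
       N = nlevels(pid), design = design, spec = spec)
}

# N x S matrix of per-person, per-segment log likelihood contributions
person_seg_loglik <- function(params, frame) {
  S <- length(params$alpha)
  out <- matrix(0, frame$N, S)
  for (s in seq_len(S)) {
    eta <- linear_predictor(params$alpha[s], params$gamma,
                            params$gamma_s[s, ], frame$design)
    th <- theta(frame$y, frame$cflag, softplus(eta), params$delta,
                params$phi, frame$spec)
    out[, s] <- rowsum(log(pmax(th, 1e-300)), frame$person)
  }
  out
}

#' Log likelihood of one person's trials under one segment
#'
#' Sum over the person's trials of the log likelihood contribution: the log
#' of the inflated pmf at the observed count for uncensored trials, the log
#' survival `P(Z >= y)` for censored trials, with
#' `mu = softplus(alpha_s + x' beta)`.
#'
#' @param params parameter list (see [cmm_transform()]).
#' @param trials trial table for a single person.
#' @param s segment index.
#' @param schema a [cmm_schema()].
#' @param spec an [inflation_spec()].
#' @param scalers stored z-score scalers (see [encode_design()]).
#' @return Scalar log likelihood (`-Inf` when an observation has zero
#'   probability).
#' @export
person_loglik <- function(params, trials, s = 1L, schema = cmm_schema(),
                          spec = inflation_spec(), scalers = NULL) {
  frame <- make_frame(trials, schema, spec, scalers)
  if (frame$N != 1L) stop("'trials' must belong to a single person")
  if (is.null(params$gamma_s)) params$gamma_s <- matrix(0, length(params$alpha), 0)
  eta <- linear_predictor(params$alpha[s], params$gamma, params$gamma_s[s, ],
                          frame$design)
  th <- theta(frame$y, frame$cflag, softplus(eta), params$delta, params$phi,
              frame$spec)
  if (any(th <= 0)) return(-Inf)
  sum(log(th))
}

#' Mixture log likelihood of a trial table
#'
#' `sum_i log sum_s pi_s exp(l_is)` with `l_is` the person-by-segment log
#' likelihoods, evaluated through log-sum-exp. The parameter-free censoring
#' factor (the game-mechanics kernel) is a constant and is excluded;
#' censoring is exogenous.
#'
#' @inheritParams person_loglik
#' @param data full trial table (columns `person`, `trial`, `y`, `censored`
#'   plus schema covariates).
#' @return Scalar log likelihood.
#' @export
total_loglik <- function(params, data, schema = cmm_schema(),
                         spec = inflation_spec(), scalers = NULL) {
  frame <- make_frame(data, schema, spec, scalers)
  if (is.null(params$gamma_s)) params$gamma_s <- matrix(0, length(params$alpha), 0)
  mixture_loglik(person_seg_loglik(params, frame), params$pi)
}

mixture_loglik <- function(pl, pi) {
  lp <- sweep(pl, 2, log(pi), "+")
  m <- do.call(pmax, as.data.frame(lp))
  sum(m + log(rowSums(exp(lp - m))))
}

# ---- numerical derivatives ------------------------------------------------

num_grad <- function(f, x, step = 1e-4 * (1 + abs(x))) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- step[i]
    g[i] <- (f(x + e) - f(x - e)) / (2 * step[i])
  }
  g
}

num_hessian <- function(f, x, step = 1e-4 * (1 + abs(x))) {
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- step[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / step[i]^2
    if (i < n) for (j in seq((i + 1), n)) {
      ej <- numeric(n); ej[j] <- step[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * step[i] * step[j])
    }
  }
  H
}

# ---- start values ---------------------------------------------------------

#' Start values for the CMM optimiser
#'
#' Intercept starts are spread evenly over the interior of the outcome range
#' (`s * cap / (S + 1)`); inflation-weight starts come from the observed
#' excess mass at each inflated outcome among uncensored trials (observed
#' proportion minus the linear interpolation of the flanking non-inflated
#' outcomes, floored at 1e-3); coefficients start at 0, the dispersion at 2
#' and the segment logits at 0 (equal shares).
#'
#' @inheritParams total_loglik
#' @param S number of segments.
#' @return An unconstrained start vector (see [cmm_transform()]).
#' @export
start_values <- function(data, S, schema = cmm_schema(),
                         spec = inflation_spec()) {
  frame <- make_frame(data, schema, spec)
  cap <- spec$cap
  alpha <- seq_len(S) * cap / (S + 1)
  yu <- frame$y[frame$cflag == 0L]
  prop <- tabulate(yu + 1L, nbins = cap + 1L) / max(1L, length(yu))
  special <- c(spec$zero, spec$set_a, spec$top)
  plain <- setdiff(0:cap, c(special, cap))
  excess <- function(j) {
    lo <- plain[plain < j]; hi <- plain[plain > j]
    interp <- if (!length(lo)) prop[hi[1] + 1L]
    else if (!length(hi)) prop[lo[length(lo)] + 1L]
    else {
      a <- lo[length(lo)]; b <- hi[1]
      prop[a + 1L] + (prop[b + 1L] - prop[a + 1L]) * (j - a) / (b - a)
    }
    max(prop[j + 1L] - interp, 1e-3)
  }
  phi123 <- c(excess(spec$zero),
              sum(vapply(spec$set_a, excess, numeric(1))),
              excess(spec$top))
  phi123 <- pmin(phi123, 0.3)  # keep the base weight dominant at the start
  phi <- c(phi123, 1 - sum(phi123))
  params <- list(alpha = alpha,
                 gamma = numeric(ncol(frame$design$X)),
                 gamma_s = matrix(0, S, ncol(frame$design$Xs)),
                 delta = 2, phi = phi, pi = rep(1 / S, S))
  cmm_transform(params)
}

# ---- the fitting function -------------------------------------------------

#' Fitter control options
#'
#' @param reltol relative convergence tolerance of the quasi-Newton
#'   optimiser: converged once `logL(t) - logL(t-1) <
#'   reltol * (|logL(t)| + reltol)`.
#' @param maxit iteration cap.
#' @param newton perform one guarded Newton-Raphson polish step on a
#'   central-difference Hessian after convergence.
#' @param warm_start_n if positive, first fit on a random subsample of this
#'   many persons and use the result as start values.
#' @param include_omega add the parameter-free log censoring constant to the
#'   reported log likelihood (does not affect the estimates; censoring is
#'   exogenous). Requires game-setting columns `gain`, `loss`, `n_loss`.
#' @param seed seed for the warm-start subsample.
#' @return A list of control settings.
#' @export
cmm_control <- function(reltol = 1e-10, maxit = 2000L, newton = TRUE,
                        warm_start_n = 0L, include_omega = FALSE,
                        seed = NULL) {
  list(reltol = reltol, maxit = as.integer(maxit), newton = isTRUE(newton),
       warm_start_n = as.integer(warm_start_n),
       include_omega = isTRUE(include_omega), seed = seed)
}

omega_constant <- function(data, cap) {
  req <- c("gain", "loss", "n_loss")
  if (!all(req %in% names(data)))
    stop("include_omega requires game-setting columns gain, loss, n_loss")
  sum(log(vapply(seq_len(nrow(data)), function(i) {
    cfg <- cct_config(data$gain[i], data$loss[i], data$n_loss[i], cap)
    omega(data$y[i], data$censored[i], data$y[i], cfg)
  }, numeric(1))))
}

#' Fit a censored mixture model
#'
#' Maximum likelihood estimation of the censored mixture model for
#' sequential risk task data: the latent intention follows a
#' multiple-inflated, tail-folded negative binomial distribution whose mean
#' is `softplus(eta_its)`, with `eta_its = alpha_s + x~' beta~_s + x*' beta*`;
#' censored trials contribute the survival probability `P(Z >= y)`. Person
#' heterogeneity is captured by `S` latent segments with probabilities `pi`.
#' Optimisation runs unconstrained on the transformed scale
#' (see [cmm_transform()]) via BFGS with a strict relative-tolerance stopping
#' rule, followed by one guarded Newton-Raphson step.
#'
#' @param data trial table: columns `person`, `trial`, `y` (observed cards;
#'   for censored trials the index of the loss card), `censored` (0/1), plus
#'   all covariates declared in `schema`.
#' @param segments number of latent segments S.
#' @param schema a [cmm_schema()] declaring the covariates (may be empty).
#' @param spec an [inflation_spec()]; its `cap` must equal the deck size.
#' @param start optional start values: an unconstrained vector or a parameter
#'   list (see [cmm_transform()]). Defaults to [start_values()].
#' @param control a [cmm_control()] list.
#' @return An object of class `"cmm"` with components `params` (estimates on
#'   the model scale), `coefficients` (per-level sum-to-zero coefficients),
#'   `se` (delta-method standard errors on the reported scale), `se_transformed`,
#'   `vcov_transformed`, `loglik`, `bic`, `npar`, `N`, `n_trials`, `posterior`,
#'   `convergence`, `schema`, `spec`, `scalers` and the internal `frame`.
#' @seealso [summary.cmm()], [posterior_probs()], [select_segments()],
#'   [simulate_cct()]
#' @export
cmm <- function(data, segments = 1L, schema = cmm_schema(),
                spec = inflation_spec(), start = NULL,
                control = cmm_control()) {
  cl <- match.call()
  S <- as.integer(segments)
  if (S < 1L) stop("'segments' must be >= 1")
  frame <- make_frame(data, schema, spec)
  p <- ncol(frame$design$X); q <- ncol(frame$design$Xs)
  lay <- par_layout(S, p, q)

  negll <- function(vec) {
    # wild line-search steps can underflow delta or overflow exp(); treat
    # such points as very unlikely rather than erroring out of the optimiser
    val <- tryCatch({
      params <- cmm_untransform(vec, S, p, q)
      -mixture_loglik(person_seg_loglik(params, frame), params$pi)
    }, error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }

  if (is.null(start)) {
    start_vec <- start_values(data, S, schema, spec)
    if (control$warm_start_n > 0L && control$warm_start_n < frame$N) {
      if (!is.null(control$seed)) set.seed(control$seed)
      keep <- sample(frame$person_ids, control$warm_start_n)
      sub <- data[data$person %in% keep, , drop = FALSE]
      warm <- cmm(sub, segments = S, schema = schema, spec = spec,
                  start = start_vec,
                  control = cmm_control(reltol = 1e-6, newton = FALSE))
      start_vec <- warm$par
    }
  } else if (is.list(start)) {
    if (is.null(start$gamma_s)) start$gamma_s <- matrix(0, S, q)
    start_vec <- cmm_transform(start)
  } else start_vec <- start
  if (length(start_vec) != lay$n)
    stop("start vector length ", length(start_vec), ", expected ", lay$n)

  if (control$maxit <= 0L) {
    # evaluation at fixed parameters (e.g. diagnostics on stored estimates)
    opt <- list(par = start_vec, value = negll(start_vec), convergence = 0L,
                counts = c(`function` = 1L, gradient = 0L))
  } else {
    opt <- stats::optim(start_vec, negll, method = "BFGS",
                        control = list(reltol = control$reltol,
                                       maxit = control$maxit))
  }
  converged <- opt$convergence == 0L
  if (!converged)
    warning("optimiser did not converge within ", control$maxit,
            " iterations (code ", opt$convergence, ")")
  par <- opt$par
  ll <- -opt$value

  # Hessian of the negative log likelihood: used both for the Newton polish
  # and for the observed-information standard errors
  newton_step <- FALSE
  g <- num_grad(negll, par)
  H <- num_hessian(negll, par)
  if (control$newton) {
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (!is.null(step) && all(is.finite(step))) {
      cand <- par - step
      llc <- tryCatch(-negll(cand), error = function(e) -Inf)
      # guarded: accept only if the log likelihood does not decrease
      if (is.finite(llc) && llc > ll) {
        par <- cand; ll <- llc; newton_step <- TRUE
        g <- num_grad(negll, par)
        H <- num_hessian(negll, par)
      }
    }
  }
  grad_norm <- sqrt(sum(g^2))

  params <- cmm_untransform(par, S, p, q)
  if (S > 1 && any(params$pi < 1e-4))
    warning("segment probability near the boundary (pi < 1e-4); ",
            "the solution may be degenerate")

  pl <- person_seg_loglik(params, frame)
  lp <- sweep(pl, 2, log(params$pi), "+")
  m <- apply(lp, 1, max)
  post <- exp(lp - m) / rowSums(exp(lp - m))
  rownames(post) <- frame$person_ids

  npar <- lay$n
  bic <- -2 * ll + npar * log(frame$N)

  # delta-method standard errors on the reported scale
  vcov_t <- tryCatch(solve(H), error = function(e) NULL)
  se_t <- if (!is.null(vcov_t) && all(diag(vcov_t) > 0))
    sqrt(diag(vcov_t)) else rep(NA_real_, npar)
  if (anyNA(se_t))
    warning("observed information is singular or not positive definite; ",
            "standard errors reported as missing")
  report <- function(vec) {
    pp <- cmm_untransform(vec, S, p, q)
    out <- c(stats::setNames(pp$alpha, paste0("alpha", seq_len(S))))
    if (p) out <- c(out, levels_from_free(frame$design, "common", pp$gamma))
    if (q) for (s in seq_len(S))
      out <- c(out, stats::setNames(
        levels_from_free(frame$design, "segment", pp$gamma_s[s, ]),
        paste0("seg", s, ".",
               names(levels_from_free(frame$design, "segment",
                                      pp$gamma_s[s, ])))))
    c(out, delta = pp$delta,
      stats::setNames(pp$phi, paste0("phi", 1:4)),
      stats::setNames(pp$pi, paste0("pi", seq_len(S))))
  }
  rep_est <- report(par)
  se_rep <- rep(NA_real_, length(rep_est))
  if (!anyNA(se_t)) {
    J <- matrix(0, length(rep_est), npar)
    h <- 1e-5 * (1 + abs(par))
    for (i in seq_len(npar)) {
      e <- numeric(npar); e[i] <- h[i]
      J[, i] <- (report(par + e) - report(par - e)) / (2 * h[i])
    }
    vr <- J %*% vcov_t %*% t(J)
    se_rep <- sqrt(pmax(diag(vr), 0))
  }
  names(se_rep) <- names(rep_est)

  structure(list(
    params = params, par = par, coefficients = rep_est, se = se_rep,
    se_transformed = stats::setNames(se_t, names(start_vec)[seq_len(npar)]),
    vcov_transformed = vcov_t,
    loglik = ll + if (control$include_omega)
      omega_constant(data, spec$cap) else 0,
    loglik_kernel = ll,
    bic = bic, npar = npar, N = frame$N, n_trials = length(frame$y),
    S = S, posterior = post,
    convergence = list(converged = converged, iterations = opt$counts[["function"]],
                       code = opt$convergence, grad_norm = grad_norm,
                       newton_step = newton_step),
    schema = schema, spec = spec, scalers = frame$design$scalers,
    frame = frame, call = cl), class = "cmm")
}

#' Posterior segment membership probabilities
#'
#' Bayes' rule over segments: row i, column s is
#' `pi_s exp(l_is) / sum_r pi_r exp(l_ir)`.
#'
#' @param fit a fitted [cmm()] model.
#' @return An `N x S` matrix whose rows sum to 1, with person ids as row
#'   names.
#' @export
posterior_probs <- function(fit) {
  stopifnot(inherits(fit, "cmm"))
  fit$posterior
}
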