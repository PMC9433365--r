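test_that("parameter transforms are a bijection with known values", {
  expect_equal(cmmrisk:::softmax_last(c(-3.5, -1.9, -2.1)),
               c(0.02319, 0.11486, 0.09404, 0.76792), tolerance = 1e-4)
  expect_equal(cmmrisk:::softmax_last(-0.4)[1], stats::plogis(-0.4))
  p <- cmm_untransform(c(3.39, 2.92, 1, log(3), -3.5, -1.9, -2.1, -0.4),
                       S = 2, p = 1, q = 0)
  expect_equal(p$alpha, c(3.39^2, 3.39^2 + 2.92^2))
  expect_equal(p$delta, 3)
  set.seed(21)
  for (i in 1:20) {
    S <- sample(1:4, 1)
    pr <- list(alpha = cumsum(stats::runif(S, 0.5, 9)),
               gamma = stats::rnorm(3),
               gamma_s = matrix(stats::rnorm(2 * S), S, 2),
               delta = stats::runif(1, 0.3, 6), phi = random_phi(),
               pi = {x <- stats::rgamma(S, 2) + 0.05; x / sum(x)})
    v <- cmm_transform(pr)
    back <- cmm_untransform(v, S, 3, 2)
    expect_equal(back$alpha, pr$alpha, tolerance = 1e-10)
    expect_equal(back$gamma, pr$gamma, tolerance = 1e-10)
    expect_equal(back$gamma_s, pr$gamma_s, tolerance = 1e-10)
    expect_equal(back$delta, pr$delta, tolerance = 1e-10)
    expect_equal(back$phi, pr$phi, tolerance = 1e-10)
    expect_equal(as.numeric(back$pi), as.numeric(pr$pi), tolerance = 1e-10)
  }
  expect_error(cmm_transform(list(alpha = c(2, 1), gamma = numeric(0),
                                  delta = 1, phi = rep(0.25, 4),
                                  pi = c(0.5, 0.5))), "non-decreasing")
  expect_error(cmm_transform(list(alpha = 1, gamma = numeric(0), delta = 1,
                                  phi = c(1, 0, 0, 0), pi = 1)), "boundary")
})

test_that("person and total log likelihood compose per the mixture formula", {
  params <- list(alpha = c(5, 12), gamma = numeric(0),
                 gamma_s = matrix(0, 2, 0), delta = 2,
                 phi = c(0.1, 0.15, 0.05, 0.7), pi = c(0.4, 0.6))
  trials <- data.frame(person = 1, trial = 1:2, y = c(3, 7),
                       censored = c(0, 1))
  phi <- params$phi
  mu <- softplus(5)
  expect_equal(person_loglik(params, trials[1, ], s = 1),
               log(inflated_pmf(3, mu, 2, phi)))
  expect_equal(person_loglik(params, trials, s = 1),
               log(inflated_pmf(3, mu, 2, phi)) +
                 log(inflated_survival(7, mu, 2, phi)))
  dat2 <- rbind(trials, transform(trials, person = 2))
  l1 <- person_loglik(params, trials, s = 1)
  l2 <- person_loglik(params, trials, s = 2)
  expect_equal(total_loglik(params, dat2),
               2 * log(0.4 * exp(l1) + 0.6 * exp(l2)))
  # S = 1 and degenerate mixtures
  p1 <- list(alpha = 5, gamma = numeric(0), gamma_s = matrix(0, 1, 0),
             delta = 2, phi = phi, pi = 1)
  expect_equal(total_loglik(p1, dat2), 2 * l1)
  pdeg <- params; pdeg$pi <- c(1 - 1e-12, 1e-12)
  expect_equal(total_loglik(pdeg, dat2), 2 * l1, tolerance = 1e-9)
})

test_that("model joint outcome probabilities match exhaustive enumeration", {
  # P(Y=k, C=c) = sum_l Omega_{kl,c} Pr(Z=l) vs enumeration over
  # (intention, loss placements) on a one-person, one-trial model
  phi <- c(0.15, 0.2, 0.05, 0.6)
  mu <- softplus(6); de <- 2
  cfg <- cct_config(n_loss = 3)
  pz <- inflated_pmf(0:32, mu, de, phi)
  model_joint <- function(k, c) {
    if (c == 0) omega(k, 0, k, cfg) * theta(k, 0, mu, de, phi)
    else omega(k, 1, k, cfg) * theta(k, 1, mu, de, phi)
  }
  oracle <- matrix(0, 33, 2)
  for (l in 0:32) {
    oracle <- oracle + pz[l + 1] *
      enumerate_outcome_given_intention(l, 3, 32)
  }
  for (k in c(0, 1, 4, 13, 31, 32)) {
    expect_equal(model_joint(k, 0), oracle[k + 1, 1], tolerance = 1e-12)
    if (k >= 1)
      expect_equal(model_joint(k, 1), oracle[k + 1, 2], tolerance = 1e-12)
  }
  expect_equal(sum(vapply(0:32, model_joint, numeric(1), c = 0)) +
                 sum(vapply(1:32, model_joint, numeric(1), c = 1)), 1,
               tolerance = 1e-12)
})

test_that("start values spread intercepts and read inflation from the data", {
  dat <- tiny_sim(80)
  v4 <- start_values(dat, 4, recovery_schema())
  a <- unname(cumsum(v4[1:4]^2))
  expect_equal(a, c(6.4, 12.8, 19.2, 25.6))
  # a spike at zero raises the zero-inflation start above the top one
  spike <- data.frame(person = 1:60, trial = 1,
                      y = c(rep(0, 35), stats::rpois(25, 10)), censored = 0)
  v <- start_values(spike, 1)
  phi <- cmmrisk:::softmax_last(v[c("tau1", "tau2", "tau3")])
  expect_gt(phi[1], phi[3])
})

test_that("fitting recovers one-segment truth and refit is a fixed point", {
  set.seed(77)
  truth <- list(alpha = 9, gamma = c(1.5, -2, -4), gamma_s = matrix(0, 1, 0),
                delta = 3, phi = cmmrisk:::softmax_last(c(-3.5, -1.9, -2.1)),
                pi = 1)
  dat <- simulate_cct(truth, 400, 8, seed = 78)
  fit <- cmm(dat, 1, recovery_schema())
  est <- fit$params
  se <- fit$se_transformed  # layout: atilde, gamma1..3, log_delta, tau1..3
  expect_true(fit$convergence$converged)
  expect_lt(abs(est$alpha - 9), 3 * (2 * sqrt(9)) * se[1])
  expect_lt(abs(est$gamma[1] - 1.5), 3 * se[2])
  expect_lt(abs(est$gamma[3] - (-4)), 3 * se[4])
  expect_lt(fit$convergence$grad_norm, 1e-3)
  refit <- cmm(dat, 1, recovery_schema(), start = fit$par)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("estimates are unchanged by the exogenous censoring constant", {
  dat <- tiny_sim(60, seed = 13)
  fit_a <- cmm(dat, 1, recovery_schema(),
               control = cmm_control(include_omega = FALSE))
  fit_b <- cmm(dat, 1, recovery_schema(),
               control = cmm_control(include_omega = TRUE))
  expect_equal(fit_a$par, fit_b$par, tolerance = 1e-6)
  # the reported likelihood shifts by the constant, the kernel part agrees
  expect_equal(fit_a$loglik_kernel, fit_b$loglik_kernel, tolerance = 1e-6)
  expect_lt(fit_b$loglik, fit_a$loglik)
})

test_that("segment label order is canonical and posteriors are proper", {
  dat <- tiny_sim(150, seed = 19)
  fit <- cmm(dat, 2, recovery_schema(), start = recovery_params(1))
  expect_true(all(diff(fit$params$alpha) > 0))
  post <- posterior_probs(fit)
  expect_equal(dim(post), c(150, 2))
  expect_equal(unname(rowSums(post)), rep(1, 150), tolerance = 1e-10)
  # permuted start values reach the same maximum
  pstart <- recovery_params(1)
  swap <- list(alpha = pstart$alpha, gamma = pstart$gamma,
               gamma_s = pstart$gamma_s, delta = pstart$delta,
               phi = pstart$phi, pi = rev(pstart$pi))
  fit2 <- cmm(dat, 2, recovery_schema(), start = swap)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
  # equal intercepts make every posterior row equal to pi
  peq <- list(alpha = c(8, 8), gamma = c(1, -1, -2),
              gamma_s = matrix(0, 2, 0), delta = 2,
              phi = c(0.1, 0.2, 0.1, 0.6), pi = c(0.3, 0.7))
  # information at a fixed non-optimum need not be positive definite
  fiteq <- suppressWarnings(
    cmm(dat, 2, recovery_schema(), start = peq,
        control = cmm_control(maxit = 0, newton = FALSE)))
  expect_equal(unname(fiteq$posterior[3, ]), c(0.3, 0.7), tolerance = 1e-10)
})

test_that("posterior assignment separates well-separated segments", {
  wide <- recovery_params(1)
  wide$alpha <- c(4, 26)  # far apart on the cards scale
  attr(wide, "transformed") <- NULL
  dat <- tiny_sim(200, seed = 23, params = wide)
  fit <- cmm(dat, 2, recovery_schema(), start = wide)
  lat <- attr(dat, "latent")
  true_seg <- lat$segment[!duplicated(dat$person)]
  hard <- max.col(fit$posterior)
  agree <- max(mean(hard == true_seg), mean(hard == 3 - true_seg))
  expect_gt(agree, 0.9)
})

test_that("BIC counts free parameters and penalises redundant segments", {
  dat <- tiny_sim(100, seed = 29)
  f1 <- cmm(dat, 1, recovery_schema(), control = cmm_control(newton = FALSE))
  expect_equal(f1$npar, 1 + 3 + 1 + 3)
  f2 <- cmm(dat, 2, recovery_schema(), start = recovery_params(1),
            control = cmm_control(newton = FALSE))
  expect_equal(f2$npar, f1$npar + 2)  # one intercept + one mixture logit
  expect_equal(f2$bic, -2 * f2$loglik + f2$npar * log(f2$N))
  expect_equal(unclass(stats::BIC(f2)), f2$bic, tolerance = 1e-12)
  # equal log likelihood implies larger BIC for larger S
  expect_gt(-2 * f1$loglik + (f1$npar + 2) * log(f1$N), f1$bic)
})

test_that("segment selection applies share, gap and BIC rules", {
  mk <- function(S, bic, pi, alpha) {
    structure(list(S = S, bic = bic,
                   params = list(pi = pi, alpha = alpha)), class = "cmm")
  }
  fits <- list(mk(3, 1000, c(0.2, 0.4, 0.4), c(5, 11, 20)),
               mk(4, 990, c(0.1, 0.3, 0.3, 0.3), c(5, 11, 18, 30)),
               mk(5, 985, c(0.023, 0.1, 0.3, 0.3, 0.277),
                  c(3, 6, 11, 18, 30)))
  sel <- select_segments(fits)
  expect_equal(sel$S, 4)
  expect_match(sel$report$violation[3], "segment share")
  expect_equal(select_segments(fits[1])$S, 3)
  # a BIC increase stops the walk
  fits2 <- list(mk(2, 1000, c(0.5, 0.5), c(5, 15)),
                mk(3, 1010, c(0.3, 0.3, 0.4), c(5, 11, 20)))
  expect_equal(select_segments(fits2)$S, 2)
  expect_error(select_segments(list()), "at least one")
})
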