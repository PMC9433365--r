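test_that("expected cards equals the direct 33-term sum and stays in range", {
  # all mass at zero / at the top outcome
  pz <- list(alpha = 5, gamma = numeric(0), gamma_s = matrix(0, 1, 0),
             delta = 2, phi = c(1, 0, 0, 0), pi = 1)
  expect_equal(expected_cards(pz, eta_s = 5), 0)
  pt <- pz; pt$phi <- c(0, 0, 1, 0)
  expect_equal(expected_cards(pt, eta_s = 5), 31)
  pg <- pz; pg$phi <- c(0.1, 0.25, 0.05, 0.6)
  direct <- sum((0:32) * inflated_pmf(0:32, softplus(7), 2, pg$phi))
  expect_equal(expected_cards(pg, eta_s = 7), direct)
  # mixture weighting
  pm <- list(alpha = c(2, 9), gamma = numeric(0), gamma_s = matrix(0, 2, 0),
             delta = 2, phi = pg$phi, pi = c(0.3, 0.7))
  e1 <- expected_cards(list(alpha = 2, delta = 2, phi = pg$phi, pi = 1),
                       eta_s = 2)
  e2 <- expected_cards(list(alpha = 9, delta = 2, phi = pg$phi, pi = 1),
                       eta_s = 9)
  expect_equal(expected_cards(pm, eta_s = c(2, 9)), 0.3 * e1 + 0.7 * e2)
  set.seed(3)
  for (i in 1:10) {
    e <- expected_cards(pg, eta_s = stats::rnorm(1, 5, 10))
    expect_gte(e, 0); expect_lte(e, 32)
  }
})

test_that("fit metrics compute RMSE and MAD over uncensored trials", {
  expect_equal(fit_metrics(c(1, 2), c(1, 2)), list(rmse = 0, mad = 0))
  m <- fit_metrics(c(3, -4), c(0, 0))
  expect_equal(m$rmse, sqrt(12.5))
  expect_equal(m$mad, 3.5)
  m2 <- fit_metrics(c(3, -4, 99), c(0, 0, 0), censored = c(0, 0, 1))
  expect_equal(m2, m)
  expect_error(fit_metrics(numeric(0), numeric(0)), "no uncensored")
  expect_error(fit_metrics(1, 2, censored = 1), "no uncensored")
})

test_that("predicted joint distribution folds censoring correctly", {
  cfg <- cct_config(n_loss = 1)
  # degenerate intention at 0: never censored
  pmf0 <- c(1, rep(0, 32))
  pj <- predicted_joint_distribution(pmf0, cfg)
  expect_equal(pj["0", "uncensored"], 1)
  expect_equal(sum(pj), 1)
  # degenerate intention at 2
  pmf2 <- c(0, 0, 1, rep(0, 30))
  pj2 <- predicted_joint_distribution(pmf2, cfg)
  expect_equal(pj2["1", "censored"], 1 / 32)
  expect_equal(pj2["2", "censored"], (31 / 32) * (1 / 31))
  expect_equal(pj2["2", "uncensored"], 30 / 32)
  expect_equal(sum(pj2), 1)
  # random inflated pmfs normalise through the kernel
  set.seed(17)
  for (i in 1:20) {
    pz <- inflated_pmf(0:32, stats::runif(1, 0.5, 30),
                       stats::runif(1, 0.3, 6), random_phi())
    cfgi <- cct_config(n_loss = sample(c(1, 3), 1))
    expect_equal(sum(predicted_joint_distribution(pz, cfgi)), 1,
                 tolerance = 1e-10)
  }
})

test_that("predicted joint distribution matches simulated frequencies", {
  truth <- list(alpha = 10, gamma = c(0, 0, 0), gamma_s = matrix(0, 1, 0),
                delta = 3, phi = cmmrisk:::softmax_last(c(-3.5, -1.9, -2.1)),
                pi = 1)
  set.seed(71)
  st <- data.frame(gain = 30, loss = 250, n_loss = 1)
  rows <- data.frame(person = 1:30000, trial = 1, gain = 30, loss = 250,
                     n_loss = 1, x_gain = 1, x_loss = 0, x_cards = 0)
  d <- cmmrisk:::simulate_from_params(truth, rows, recovery_schema(),
                                      inflation_spec())
  mu <- softplus(10 + truth$gamma[1])
  pz <- inflated_pmf(0:32, mu, 3, truth$phi)
  pj <- predicted_joint_distribution(pz, cct_config(30, 250, 1))
  emp_unc <- tabulate(d$y[d$censored == 0] + 1L, 33) / nrow(d)
  emp_cen <- tabulate(d$y[d$censored == 1] + 1L, 33) / nrow(d)
  expect_lt(max(abs(emp_unc - pj[, "uncensored"])), 0.01)
  expect_lt(max(abs(emp_cen - pj[, "censored"])), 0.01)
  g <- gof(emp_unc / sum(emp_unc),
           pj[, "uncensored"] / sum(pj[, "uncensored"]),
           sum(d$censored == 0))
  expect_gt(g$correlation, 0.99)
})

test_that("goodness-of-fit identities hold", {
  p <- inflated_pmf(0:32, 8, 2, c(0.1, 0.2, 0.05, 0.65))
  g <- gof(p, p, 1000)
  expect_equal(g$chisq, 0)
  expect_equal(g$correlation, 1)
  expect_equal(g$hellinger, 0)
  # disjoint point masses: maximal Hellinger distance
  a <- c(1, 0); b <- c(0, 1)
  expect_equal(gof(a, b, 10, pool_below = 0)$hellinger, 1)
  # closed-form two-point case
  g2 <- gof(c(0.5, 0.5), c(0.8, 0.2), 100, pool_below = 0)
  expect_equal(g2$hellinger,
               sqrt((sqrt(0.5) - sqrt(0.8))^2 + (sqrt(0.5) - sqrt(0.2))^2) /
                 sqrt(2), tolerance = 1e-12)
  expect_error(gof(c(0.5, 0.5), c(1, 0, 0), 10), "support")
  # Hellinger symmetry
  set.seed(8)
  x <- random_phi(); y <- random_phi()
  expect_equal(gof(x, y, 10, pool_below = 0)$hellinger,
               gof(y, x, 10, pool_below = 0)$hellinger)
})

test_that("category profiles split special outcomes evenly", {
  expect_equal(category_profile(c(0, 0)), c(0.5, 0, 0, 0.5))
  expect_equal(category_profile(15), c(0, 0, 0, 1))
  expect_equal(category_profile(c(0, 4, 15)), c(1 / 6, 1 / 6, 0, 4 / 6))
  expect_equal(category_profile(31), c(0, 0, 0.5, 0.5))
  expect_equal(sum(category_profile(c(0, 4, 8, 31, 3, 17))), 1)
  expect_error(category_profile(numeric(0)), "nonempty")
})

test_that("segment profiles weight external scores by posteriors", {
  set.seed(41)
  N <- 300
  post <- cbind(stats::runif(N, 0.2, 0.8))
  post <- cbind(post, 1 - post)
  z <- stats::rnorm(N)
  sp <- segment_profile(post, data.frame(score = z))
  # identical posterior rows give equal means and a null Wald statistic
  flat <- matrix(0.5, N, 2)
  sp_flat <- segment_profile(flat, data.frame(score = z))
  expect_equal(sp_flat$means[1, 1], sp_flat$means[1, 2])
  expect_equal(sp_flat$wald$statistic, 0, tolerance = 1e-12)
  # hard assignment reduces to group means
  hard <- cbind(rep(c(1, 0), each = N / 2), rep(c(0, 1), each = N / 2))
  sp_hard <- segment_profile(hard, data.frame(score = z))
  zs <- scale(z)
  expect_equal(unname(sp_hard$means[1, ]),
               c(mean(zs[1:(N / 2)]), mean(zs[(N / 2 + 1):N])),
               tolerance = 1e-10)
  expect_equal(unname(sp_hard$effective_n), c(N / 2, N / 2))
})

test_that("the segment-difference Wald test is calibrated and powerful", {
  set.seed(43)
  N <- 400
  seg <- rep(1:2, each = N / 2)
  post <- cbind(seg == 1, seg == 2) * 0.9 + 0.05
  reject_null <- reject_alt <- 0
  nrep <- 60
  for (i in seq_len(nrep)) {
    z0 <- stats::rnorm(N)                  # unrelated to segments
    z1 <- stats::rnorm(N, mean = (seg - 1.5))  # strongly related
    p0 <- segment_profile(post, data.frame(s = z0))$wald$p_value
    p1 <- segment_profile(post, data.frame(s = z1))$wald$p_value
    reject_null <- reject_null + (p0 < 0.05)
    reject_alt <- reject_alt + (p1 < 0.05)
  }
  expect_gt(reject_alt / nrep, 0.9)
  expect_lt(reject_null / nrep, 0.15)
})
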