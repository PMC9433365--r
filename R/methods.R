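#' @export
print.cmm <- function(x, digits = 3, ...) {
  cat("Censored mixture model (", x$S, " segment",
      if (x$S > 1) "s", ")\n", sep = "")
  cat(sprintf("  %d persons, %d trials; logLik %.2f, BIC %.1f (%d parameters)\n",
              x$N, x$n_trials, x$loglik, x$bic, x$npar))
  tab <- rbind(pi = x$params$pi, alpha = x$params$alpha)
  colnames(tab) <- paste0("segment", seq_len(x$S))
  print(round(tab, digits))
  cat("dispersion delta:", round(x$params$delta, digits),
      "  inflation phi:", paste(round(x$params$phi, digits), collapse = " "),
      "\n")
  if (!x$convergence$converged) cat("WARNING: optimiser did not converge\n")
  invisible(x)
}

#' @export
summary.cmm <- function(object, ...) {
  est <- object$coefficients
  out <- data.frame(estimate = est, se = object$se[names(est)])
  structure(list(table = out, fit = object), class = "summary.cmm")
}

#' @export
print.summary.cmm <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficients (per-level, sum-to-zero within each family):\n")
  print(round(x$table, digits))
  invisible(x)
}

#' Extract CMM coefficients
#'
#' @param object a fitted [cmm()] model.
#' @param as_coefs return a [cmm_coefs()] object (per-family structure,
#'   usable by [effect_span()]) instead of the flat named vector.
#' @param ... unused.
#' @export
coef.cmm <- function(object, as_coefs = FALSE, ...) {
  if (!as_coefs) return(object$coefficients)
  fams <- object$frame$design$families
  est <- object$coefficients
  out <- list()
  for (nm in c(object$frame$design$common,
               object$frame$design$segment_specific)) {
    fm <- fams[[nm]]
    if (fm$kind == "numeric") {
      out[[nm]] <- est[[nm]]
    } else if (fm$kind == "categorical") {
      out[[nm]] <- stats::setNames(est[paste(nm, fm$levels, sep = ".")],
                                   fm$levels)
    } else {
      l1 <- fm$level_grid[[1]]; l2 <- fm$level_grid[[2]]
      m <- matrix(est[paste(nm, fm$levels, sep = ".")],
                  nrow = length(l1), dimnames = list(l1, l2))
      out[[nm]] <- m
    }
  }
  do.call(cmm_coefs, out)
}

#' @export
logLik.cmm <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$N,
            class = "logLik")
}

#' Bayesian information criterion of a CMM fit
#'
#' `-2 logL + npar * log(N persons)`: the persons are the independent
#' likelihood units, so N is the number of persons, not trials.
#'
#' @param fit a fitted [cmm()] model.
#' @return Scalar BIC.
#' @export
cmm_bic <- function(fit) {
  stopifnot(inherits(fit, "cmm"))
  fit$bic
}

#' Predict expected number of cards
#'
#' The mixture expectation of the latent intention,
#' `sum_l l * sum_s w_s Pr(Z = l | eta_its)`, always inside `[0, cap]`
#' because the support is folded at the deck size. Segment weights are the
#' prior probabilities `pi` for unseen persons and the posterior membership
#' row for persons in the estimation sample.
#'
#' @param object a fitted [cmm()] model.
#' @param newdata trial table; defaults to the estimation data.
#' @param weights `"posterior"` (in-sample persons) or `"prior"`.
#' @param ... unused.
#' @return Vector of expected cards per trial row.
#' @export
predict.cmm <- function(object, newdata = NULL,
                        weights = c("posterior", "prior"), ...) {
  weights <- match.arg(weights)
  if (is.null(newdata)) {
    frame <- object$frame
    pid <- frame$person_ids[frame$person]
  } else {
    frame <- make_frame(newdata, object$schema, object$spec,
                        scalers = object$scalers)
    pid <- frame$person_ids[frame$person]
  }
  W <- matrix(object$params$pi, frame$design$n, object$S, byrow = TRUE)
  if (weights == "posterior") {
    hit <- match(pid, rownames(object$posterior))
    known <- !is.na(hit)
    W[known, ] <- object$posterior[hit[known], , drop = FALSE]
  }
  ell <- 0:object$spec$cap
  out <- numeric(frame$design$n)
  for (s in seq_len(object$S)) {
    eta <- linear_predictor(object$params$alpha[s], object$params$gamma,
                            object$params$gamma_s[s, ], frame$design)
    mu <- softplus(eta)
    pm <- vapply(ell, function(l)
      inflated_pmf(l, mu, object$params$delta, object$params$phi,
                   object$spec), numeric(frame$design$n))
    out <- out + W[, s] * drop(pm %*% ell)
  }
  out
}

#' Residuals of a CMM fit
#'
#' Observed minus expected cards; only uncensored trials have a fully
#' observed outcome, so censored trials get `NA`.
#'
#' @param object a fitted [cmm()] model.
#' @param ... passed to [predict.cmm()].
#' @export
residuals.cmm <- function(object, ...) {
  r <- object$frame$y - predict(object, ...)
  r[object$frame$cflag == 1L] <- NA_real_
  r
}

#' Simulate trial tables from a fitted model
#'
#' Draws new data at the fitted parameters under the same covariate rows as
#' the estimation sample (segment membership redrawn from `pi`).
#'
#' @param object a fitted [cmm()] model; requires game-setting columns
#'   `gain`, `loss`, `n_loss` in the stored data to simulate censoring.
#' @param nsim number of replicate tables.
#' @param seed optional seed.
#' @param data trial table giving the covariate and game-setting rows;
#'   defaults to the rows used in fitting if they were supplied.
#' @param ... unused.
#' @return A list of `nsim` trial tables (a single table if `nsim = 1`).
#' @export
simulate.cmm <- function(object, nsim = 1, seed = NULL, data = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(data))
    stop("supply 'data' with columns person, trial, gain, loss, n_loss ",
         "and the schema covariates")
  out <- lapply(seq_len(nsim), function(i)
    simulate_from_params(object$params, data, object$schema, object$spec,
                         object$scalers))
  if (nsim == 1) out[[1]] else out
}

#' Plot observed against predicted outcome distributions
#'
#' Bar heights of the observed uncensored outcome proportions with the
#' model-predicted, censoring-corrected probabilities overlaid (the
#' goodness-of-fit comparison on the uncensored support).
#'
#' @param x a fitted [cmm()] model; the stored data must include the
#'   game-setting columns.
#' @param data the trial table used in fitting (with `gain`, `loss`,
#'   `n_loss`).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.cmm <- function(x, data, ...) {
  pj <- average_joint_distribution(x, data)
  obs_unc <- x$frame$y[x$frame$cflag == 0L]
  cap <- x$spec$cap
  obs <- tabulate(obs_unc + 1L, nbins = cap + 1L)
  obs <- obs / sum(obs)
  pred <- pj[, "uncensored"] / sum(pj[, "uncensored"])
  bp <- graphics::barplot(obs, names.arg = 0:cap, col = "grey80",
                          border = NA, ylim = c(0, max(obs, pred) * 1.05),
                          xlab = "cards turned over (uncensored)",
                          ylab = "probability", ...)
  graphics::points(bp, pred, pch = 19, col = "firebrick")
  graphics::legend("topright", legend = c("observed", "predicted"),
                   pch = c(15, 19), col = c("grey80", "firebrick"),
                   bty = "n")
  invisible(x)
}
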