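#' Choose the number of latent segments
#'
#' Three criteria are applied while walking through fits with increasing S:
#' every segment must hold at least `min_share` of the persons, the
#' segment-specific intercepts must stay at least `min_intercept_gap` apart,
#' and the BIC must improve on the previous model. The chosen S is the
#' largest model violating none of the criteria (equivalently, the model just
#' before the first violation).
#'
#' @param fits list of [cmm()] fits with consecutive segment counts.
#' @param min_share minimum admissible segment probability (default 5%).
#' @param min_intercept_gap minimum distance between adjacent intercepts on
#'   the cards scale.
#' @return A list with `S` (chosen count), `fit` (the chosen model) and
#'   `report` (per-model diagnostics: BIC, smallest share, smallest
#'   intercept gap, which criterion failed).
#' @export
select_segments <- function(fits, min_share = 0.05, min_intercept_gap = 1) {
  if (!length(fits)) stop("'fits' must contain at least one model")
  Ss <- vapply(fits, function(f) f$S, numeric(1))
  if (is.unsorted(Ss, strictly = TRUE))
    stop("'fits' must be ordered by increasing segment count")
  report <- data.frame(S = Ss, bic = vapply(fits, cmm_bic, numeric(1)),
                       min_pi = vapply(fits, function(f) min(f$params$pi),
                                       numeric(1)),
                       min_gap = vapply(fits, function(f)
                         if (f$S > 1) min(diff(f$params$alpha)) else Inf,
                         numeric(1)))
  report$violation <- ""
  chosen <- 1L
  for (i in seq_along(fits)) {
    fails <- character(0)
    if (report$min_pi[i] < min_share) fails <- c(fails, "segment share")
    if (report$min_gap[i] < min_intercept_gap)
      fails <- c(fails, "intercept gap")
    if (i > 1 && report$bic[i] >= report$bic[i - 1])
      fails <- c(fails, "BIC")
    report$violation[i] <- paste(fails, collapse = ", ")
    if (length(fails)) break
    chosen <- i
  }
  list(S = fits[[chosen]]$S, fit = fits[[chosen]], report = report)
}
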