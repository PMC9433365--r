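#' Declare the covariate schema of a CMM
#'
#' Covariates are declared explicitly (no formula parsing). Categorical
#' variables are expanded to one dummy column per level with the per-level
#' coefficients constrained to sum to zero within each variable (and within
#' each interaction family), so the intercept is the mean for a "neutral"
#' person. Numeric variables are z-scored over the estimation sample unless
#' listed in `unscaled`. Variables named in `segment_specific` get their own
#' coefficient vector per mixture segment.
#'
#' @param categorical named list; each element is the character vector of
#'   levels of one categorical variable, e.g. `list(sex = c("boy", "girl"))`.
#'   A data value of `NA` encodes the neutral category (all dummies zero),
#'   used e.g. for lag dummies on the first trials.
#' @param numeric character vector of numeric variable names.
#' @param interactions list of length-2 character vectors naming pairs of
#'   categorical variables whose interaction enters the model.
#' @param segment_specific character vector of variable names whose effects
#'   are segment specific (the `x~` block); the rest form the common block.
#' @param unscaled numeric variables to leave on their raw scale (e.g.
#'   sum-to-zero +/-1 codes produced upstream).
#' @return An object of class `"cmm_schema"`.
#' @export
cmm_schema <- function(categorical = list(), numeric = character(),
                       interactions = list(), segment_specific = character(),
                       unscaled = character()) {
  if (length(categorical) && (is.null(names(categorical)) ||
                              any(!nzchar(names(categorical)))))
    stop("'categorical' must be a named list of level vectors")
  for (v in names(categorical)) {
    lv <- categorical[[v]]
    if (length(lv) < 2L || anyDuplicated(lv))
      stop("variable '", v, "' needs >= 2 distinct levels")
    categorical[[v]] <- as.character(lv)
  }
  vars <- c(names(categorical), numeric)
  if (anyDuplicated(vars)) stop("duplicated variable names in schema")
  for (ia in interactions) {
    if (length(ia) != 2L || !all(ia %in% names(categorical)))
      stop("interactions must pair two declared categorical variables")
  }
  unknown <- setdiff(segment_specific, c(vars, vapply(interactions, paste,
                                                      "", collapse = ":")))
  if (length(unknown))
    stop("segment_specific names not in schema: ",
         paste(unknown, collapse = ", "))
  if (length(setdiff(unscaled, numeric)))
    stop("'unscaled' must name declared numeric variables")
  structure(list(categorical = categorical, numeric = numeric,
                 interactions = interactions,
                 segment_specific = segment_specific, unscaled = unscaled),
            class = "cmm_schema")
}

# orthonormal basis of the sum-to-zero subspace for L levels (L x (L-1))
sumzero_basis <- function(L) {
  qr.Q(qr(matrix(1, L, 1)), complete = TRUE)[, -1L, drop = FALSE]
}

#' Encode a covariate table under a schema
#'
#' Builds the design used internally by the optimiser: each categorical family
#' (variable or interaction) is represented on an orthonormal basis of its
#' sum-to-zero subspace, so optimisation is unconstrained while the reported
#' per-level coefficients satisfy the sum-to-zero constraint exactly. Numeric
#' variables are centred and scaled using the sample mean and standard
#' deviation (stored in the result for reuse at predict time).
#'
#' @param schema a [cmm_schema()].
#' @param data data frame holding one row per trial with all schema columns.
#' @param scalers optional named list of `c(mean, sd)` pairs from a previous
#'   encoding (applied instead of re-estimating; used at predict time).
#' @return A list of class `"cmm_design"` with elements `X` (common-block
#'   basis matrix), `Xs` (segment-specific block, possibly 0 columns),
#'   `families` (per-family metadata incl. the level basis), `scalers`,
#'   and `n`.
#' @export
encode_design <- function(schema, data, scalers = NULL) {
  stopifnot(inherits(schema, "cmm_schema"))
  n <- nrow(data)
  fam <- list()
  cols <- list()
  # main categorical families
  for (v in names(schema$categorical)) {
    lv <- schema$categorical[[v]]
    if (!v %in% names(data)) stop("missing column '", v, "'")
    val <- as.character(data[[v]])
    bad <- !is.na(val) & !val %in% lv
    if (any(bad))
      stop("variable '", v, "': unseen level(s) ",
           paste(unique(val[bad]), collapse = ", "))
    D <- matrix(0, n, length(lv), dimnames = list(NULL, lv))
    idx <- match(val, lv)
    ok <- which(!is.na(idx))
    D[cbind(ok, idx[ok])] <- 1
    K <- sumzero_basis(length(lv))
    fam[[v]] <- list(kind = "categorical", levels = lv, basis = K,
                     nfree = ncol(K))
    cols[[v]] <- D %*% K
  }
  # interaction families
  for (ia in schema$interactions) {
    nm <- paste(ia, collapse = ":")
    l1 <- schema$categorical[[ia[1]]]; l2 <- schema$categorical[[ia[2]]]
    v1 <- as.character(data[[ia[1]]]); v2 <- as.character(data[[ia[2]]])
    cells <- as.vector(outer(l1, l2, paste, sep = ":"))
    D <- matrix(0, n, length(cells), dimnames = list(NULL, cells))
    idx <- match(paste(v1, v2, sep = ":"), cells)
    ok <- which(!is.na(idx))
    D[cbind(ok, idx[ok])] <- 1
    # products of the marginal bases: every margin of the per-cell
    # coefficients sums to zero; rows follow outer(l1, l2), l1 fastest
    K <- matrix(0, length(cells), (length(l1) - 1L) * (length(l2) - 1L))
    K1 <- sumzero_basis(length(l1)); K2 <- sumzero_basis(length(l2))
    col <- 0L
    for (j in seq_len(ncol(K2))) for (i in seq_len(ncol(K1))) {
      col <- col + 1L
      K[, col] <- as.vector(outer(K1[, i], K2[, j]))
    }
    fam[[nm]] <- list(kind = "interaction", vars = ia,
                      levels = cells, level_grid = list(l1, l2),
                      basis = K, nfree = ncol(K))
    cols[[nm]] <- D %*% K
  }
  # numeric variables
  sc <- list()
  for (v in schema$numeric) {
    if (!v %in% names(data)) stop("missing column '", v, "'")
    x <- as.numeric(data[[v]])
    if (anyNA(x)) stop("variable '", v, "' contains missing values")
    if (v %in% schema$unscaled) {
      sc[[v]] <- c(mean = 0, sd = 1)
    } else if (!is.null(scalers) && v %in% names(scalers)) {
      sc[[v]] <- scalers[[v]]
    } else {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) stop("variable '", v, "' is constant")
      sc[[v]] <- c(mean = mean(x), sd = s)
    }
    x <- (x - sc[[v]][["mean"]]) / sc[[v]][["sd"]]
    fam[[v]] <- list(kind = "numeric", levels = v,
                     basis = matrix(1, 1, 1), nfree = 1L)
    cols[[v]] <- matrix(x, ncol = 1, dimnames = list(NULL, v))
  }
  ord <- c(names(schema$categorical),
           vapply(schema$interactions, paste, "", collapse = ":"),
           schema$numeric)
  seg <- intersect(ord, schema$segment_specific)
  com <- setdiff(ord, seg)
  bind <- function(nms) {
    if (!length(nms)) return(matrix(0, n, 0))
    do.call(cbind, cols[nms])
  }
  structure(list(X = bind(com), Xs = bind(seg), families = fam,
                 common = com, segment_specific = seg,
                 scalers = sc, n = n),
            class = "cmm_design")
}

# number of free coefficients in a block
n_free <- function(design, block = c("common", "segment")) {
  block <- match.arg(block)
  nms <- if (block == "common") design$common else design$segment_specific
  sum(vapply(nms, function(f) design$families[[f]]$nfree, numeric(1)))
}

# map free basis coefficients of a block to the named per-level scale
levels_from_free <- function(design, block, gamma) {
  nms <- if (block == "common") design$common else design$segment_specific
  out <- numeric(0)
  pos <- 0L
  for (f in nms) {
    fm <- design$families[[f]]
    g <- gamma[pos + seq_len(fm$nfree)]
    pos <- pos + fm$nfree
    b <- drop(fm$basis %*% g)
    names(b) <- if (fm$kind == "numeric") f else paste(f, fm$levels, sep = ".")
    out <- c(out, b)
  }
  out
}

#' Add lagged loss-experience dummies to a trial table
#'
#' For each lag `j = 1..max_lag`, adds a categorical column `loss_lag<j>`
#' equal to `"yes"` if the person's trial `t - j` ended on a loss card,
#' `"no"` if it did not, and `NA` (the neutral category: all dummies zero,
#' i.e. the categorical mean) for trials with `t <= j`.
#'
#' @param data trial table with columns `person`, `trial`, `censored`.
#' @param max_lag number of lags.
#' @return `data` with `max_lag` added columns, plus an attribute
#'   `"lag_schema"` listing the added categorical declarations.
#' @export
build_lag_covariates <- function(data, max_lag = 1L) {
  stopifnot(max_lag >= 1L,
            all(c("person", "trial", "censored") %in% names(data)))
  sp <- split(seq_len(nrow(data)), data$person)
  for (j in seq_len(max_lag)) data[[paste0("loss_lag", j)]] <- NA_character_
  for (idx in sp) {
    tr <- data$trial[idx]
    if (anyDuplicated(tr)) stop("duplicated trial indices within a person")
    o <- idx[order(tr)]
    cns <- data$censored[o]
    for (j in seq_len(max_lag)) {
      if (length(o) > j) {
        lab <- ifelse(cns[seq_len(length(o) - j)] == 1, "yes", "no")
        data[[paste0("loss_lag", j)]][o[-seq_len(j)]] <- lab
      }
    }
  }
  attr(data, "lag_schema") <- stats::setNames(
    rep(list(c("yes", "no")), max_lag), paste0("loss_lag", seq_len(max_lag)))
  data
}

#' Linear predictor of the CMM
#'
#' `eta_its = alpha_s + x~' beta~_s + x*' beta*` for one segment: the segment
#' intercept plus the segment-specific and common covariate contributions.
#'
#' @param alpha_s segment intercept (scalar).
#' @param gamma free-basis coefficients of the common block.
#' @param gamma_s free-basis coefficients of the segment-specific block (may
#'   be length 0).
#' @param design a `"cmm_design"` from [encode_design()].
#' @return Numeric vector of length `design$n`.
#' @export
linear_predictor <- function(alpha_s, gamma, gamma_s, design) {
  if (length(gamma) != ncol(design$X) || length(gamma_s) != ncol(design$Xs))
    stop("coefficient length does not match design blocks")
  eta <- rep(alpha_s, design$n)
  if (length(gamma)) eta <- eta + drop(design$X %*% gamma)
  if (length(gamma_s)) eta <- eta + drop(design$Xs %*% gamma_s)
  eta
}

#' Bundle per-level coefficients for effect arithmetic
#'
#' A light container for sum-to-zero per-level coefficients, as printed in
#' model output: main effects are named vectors over levels, interactions are
#' matrices with the first variable's levels as rows.
#'
#' @param ... named arguments; main effects as named numeric vectors
#'   (`sex = c(boy = -0.286, girl = 0.286)`), interactions as named matrices
#'   under a `"a:b"` name with `dimnames = list(levels_a, levels_b)`.
#' @return An object of class `"cmm_coefs"`.
#' @export
cmm_coefs <- function(...) {
  x <- list(...)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all coefficient families must be named")
  structure(x, class = "cmm_coefs")
}

#' Total effect of switching a two-level factor
#'
#' The difference in the linear predictor between the two levels of a
#' categorical variable, adding any interaction coefficients evaluated at the
#' conditioning levels in `at`. Under sum-to-zero coding with levels
#' `(l1, l2)` this is `(b_l2 - b_l1) + sum over interactions`; for a
#' symmetric pair `(b, -b)` the span is `2|b|`.
#'
#' @param coefs a [cmm_coefs()] object or a fitted `"cmm"` model.
#' @param variable name of a two-level categorical variable.
#' @param at named character vector fixing levels of interacting variables;
#'   interactions whose other variable is not named in `at` are skipped.
#' @return Absolute effect span on the linear-predictor (cards) scale.
#' @examples
#' co <- cmm_coefs(sex = c(boy = -0.286, girl = 0.286))
#' effect_span(co, "sex") # 0.572
#' @export
effect_span <- function(coefs, variable, at = NULL) {
  if (inherits(coefs, "cmm")) coefs <- stats::coef(coefs, as_coefs = TRUE)
  stopifnot(inherits(coefs, "cmm_coefs"))
  if (!variable %in% names(coefs))
    stop("variable '", variable, "' not among the coefficients")
  main <- coefs[[variable]]
  if (length(main) != 2L)
    stop("'", variable, "' is not a two-level variable")
  diffs <- main[2L] - main[1L]
  for (nm in names(coefs)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !variable %in% parts) next
    other <- setdiff(parts, variable)
    if (is.null(at) || !other %in% names(at)) next
    m <- coefs[[nm]]
    if (parts[1] == variable) {
      contrib <- m[names(main)[2L], at[[other]]] - m[names(main)[1L], at[[other]]]
    } else {
      contrib <- m[at[[other]], names(main)[2L]] - m[at[[other]], names(main)[1L]]
    }
    diffs <- diffs + contrib
  }
  unname(abs(diffs))
}
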