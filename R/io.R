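#' Read a long-format trial table
#'
#' CSV or TSV (by extension, or `sep`), one row per person x trial. Required
#' columns: `person`, `trial`, `y`, `censored`; game settings and covariates
#' travel as extra columns. Validation failures name the offending rows.
#'
#' @param path file path.
#' @param cap deck size used for range validation.
#' @param sep field separator; inferred from the extension by default.
#' @return A validated data frame.
#' @export
read_trials <- function(path, cap = 32, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  dat <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  validate_trials(dat, cap)
  dat
}

#' Write a trial table
#'
#' @param data trial table.
#' @param path output path (`.tsv` writes tab-separated, otherwise CSV).
#' @export
write_trials <- function(data, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(data, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write model parameters to JSON
#'
#' Serialises a parameter list (and optionally the stored z-score scalers)
#' losslessly; [read_params()] restores it.
#'
#' @param params parameter list (see [cmm_transform()]).
#' @param path output path.
#' @param scalers optional named list of `c(mean, sd)` scalers.
#' @export
write_params <- function(params, path, scalers = NULL) {
  obj <- list(alpha = params$alpha, gamma = params$gamma,
              gamma_s = if (!is.null(params$gamma_s) &&
                            ncol(params$gamma_s))
                unclass(as.data.frame(t(params$gamma_s))) else NULL,
              delta = params$delta, phi = params$phi, pi = params$pi,
              scalers = if (!is.null(scalers))
                lapply(scalers, as.list) else NULL)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path JSON file written by [write_params()] or by hand.
#' @return A parameter list; scalers, if present, in attribute `"scalers"`.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse ", path, ": ", conditionMessage(e)))
  for (f in c("alpha", "delta", "phi", "pi"))
    if (is.null(obj[[f]])) stop("parameter file ", path, " lacks '", f, "'")
  S <- length(obj$alpha)
  if (abs(sum(obj$phi) - 1) > 1e-8)
    stop("'phi' in ", path, " does not sum to 1")
  if (abs(sum(obj$pi) - 1) > 1e-8)
    stop("'pi' in ", path, " does not sum to 1")
  gs <- if (is.null(obj$gamma_s)) matrix(0, S, 0) else {
    m <- t(as.matrix(as.data.frame(obj$gamma_s)))
    dimnames(m) <- NULL
    m
  }
  params <- list(alpha = as.numeric(obj$alpha),
                 gamma = as.numeric(obj$gamma %||% numeric(0)),
                 gamma_s = gs, delta = as.numeric(obj$delta),
                 phi = as.numeric(obj$phi), pi = as.numeric(obj$pi))
  if (!is.null(obj$scalers))
    attr(params, "scalers") <- lapply(obj$scalers, unlist)
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a
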