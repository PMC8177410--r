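#' Construct a product unit
#'
#' A product unit is a multiplicative basis function
#' \deqn{B(x) = \prod_i x_i^{w_i}}
#' over a (usually small) subset of covariates, with real exponents
#' \eqn{w_i}. With covariates scaled into \[1, 2\] the bases are strictly
#' positive, so non-integer powers are always defined; a product unit
#' expresses high-order interactions between its covariates with a handful
#' of parameters.
#'
#' Exponents are stored sparsely: covariates not named have exponent 0 and
#' do not enter the product. Structural edits (adding or removing one
#' covariate from the support) are therefore O(1).
#'
#' @param exponents named numeric vector; names are covariate tags
#'   (`"x3"`) or integer indices. Zero entries are dropped.
#' @param exponent_bound maximum allowed `|w_i|` (default 10).
#' @return An object of class `product_unit`.
#' @export
product_unit <- function(exponents = numeric(0), exponent_bound = 10) {
  if (length(exponents)) {
    if (is.null(names(exponents)))
      stop("exponents must be named by covariate tag or index")
    nm <- names(exponents)
    nm <- ifelse(grepl("^x", nm), nm, paste0("x", nm))
    idx <- suppressWarnings(as.integer(sub("^x", "", nm)))
    if (anyNA(idx) || any(idx < 1)) stop("invalid covariate tag in exponents")
    if (anyDuplicated(idx)) stop("duplicate covariate in exponent map")
    exponents <- stats::setNames(as.numeric(exponents), paste0("x", idx))
    exponents <- exponents[exponents != 0]
    exponents <- exponents[order(as.integer(sub("^x", "", names(exponents))))]
    if (any(!is.finite(exponents))) stop("exponents must be finite")
    if (any(abs(exponents) > exponent_bound))
      stop("exponent magnitude exceeds the bound (", exponent_bound, ")")
  } else {
    exponents <- stats::setNames(numeric(0), character(0))
  }
  structure(list(exponents = exponents, exponent_bound = exponent_bound),
            class = "product_unit")
}

# Integer covariate indices of a unit's support.
pu_support <- function(unit) as.integer(sub("^x", "", names(unit$exponents)))

#' Evaluate a product unit at one covariate vector
#'
#' Returns \eqn{\prod_i x_i^{w_i}} over the unit's support; the empty
#' product (no exponents) is 1. Bases must be strictly positive wherever a
#' non-integer exponent applies — guaranteed for design matrices scaled into
#' \[1, 2\].
#'
#' @param unit a [product_unit()].
#' @param x numeric covariate vector (positional; index `i` of the support
#'   picks `x[i]`).
#' @return A single number.
#' @export
pu_eval <- function(unit, x) {
  idx <- pu_support(unit)
  if (!length(idx)) return(1)
  if (max(idx) > length(x))
    stop("covariate vector too short for unit support (needs x", max(idx), ")")
  base <- x[idx]
  w <- unname(unit$exponents)
  bad <- base <= 0 & w != round(w)
  if (any(bad))
    stop("non-positive base for covariate x", idx[which(bad)[1]],
         " with non-integer exponent", call. = FALSE)
  prod(base^w)
}

# Row-wise unit evaluation on a matrix, via exp(log-linear form).
# logX is log(X), precomputed by callers in hot loops.
pu_eval_rows <- function(unit, X, logX = NULL) {
  idx <- pu_support(unit)
  if (!length(idx)) return(rep(1, nrow(X)))
  if (is.null(logX)) {
    if (any(X[, idx, drop = FALSE] <= 0))
      stop("non-positive base in design for unit support", call. = FALSE)
    logX <- log(X[, idx, drop = FALSE])
  } else {
    logX <- logX[, idx, drop = FALSE]
  }
  exp(as.vector(logX %*% unname(unit$exponents)))
}

#' Construct a product-unit neural network model
#'
#' A PUNN is a linear combination of product units plus a bias:
#' \deqn{\eta(x) = b + \sum_k c_k \prod_i x_i^{w_{ki}}}
#' The survival probability is `logistic(eta)`. This is the individual the
#' evolutionary algorithm ([evolve()]) searches over.
#'
#' @param bias real bias term.
#' @param coefficients numeric vector of output coefficients, one per unit.
#' @param units list of [product_unit()]s, same length as `coefficients`.
#' @return An object of class `punn_model`.
#' @export
punn_model <- function(bias = 0, coefficients = numeric(0), units = list()) {
  if (length(coefficients) != length(units))
    stop("one coefficient per product unit required")
  stopifnot(is.finite(bias), all(is.finite(coefficients)))
  if (!all(vapply(units, inherits, logical(1), "product_unit")))
    stop("units must be product_unit objects")
  structure(list(bias = as.numeric(bias),
                 coefficients = as.numeric(coefficients),
                 units = units),
            class = "punn_model")
}

#' @export
print.punn_model <- function(x, ...) {
  cat(sprintf("punn_model: %d product unit(s), %d parameters, bias %.4g\n",
              length(x$units), n_params(x), x$bias))
  invisible(x)
}

#' Number of free parameters in a model
#'
#' For a `punn_model`: 1 (bias) + per unit (1 output coefficient + its
#' number of nonzero exponents). For an `lripu_model`: 1 (intercept) + the
#' linear coefficients + the same per-unit count.
#'
#' @param model a `punn_model` or `lripu_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) UseMethod("n_params")

#' @export
n_params.punn_model <- function(model) {
  1L + sum(vapply(model$units, function(u) 1L + length(u$exponents), integer(1)))
}

#' Network input (logit) of a PUNN at one covariate vector
#'
#' @param model a [punn_model()].
#' @param x scaled covariate vector, strictly positive on all unit supports.
#' @return `bias + sum(coefficients * unit evaluations)`.
#' @export
punn_logit <- function(model, x) {
  vals <- vapply(model$units, pu_eval, numeric(1), x = x)
  model$bias + sum(model$coefficients * vals)
}

# Vectorised logit over the rows of a scaled matrix.
punn_logit_rows <- function(model, X, logX = NULL) {
  eta <- rep(model$bias, nrow(X))
  for (k in seq_along(model$units))
    eta <- eta + model$coefficients[k] * pu_eval_rows(model$units[[k]], X, logX)
  eta
}

#' Overflow-safe logistic (inverse logit)
#'
#' Computes `1/(1 + exp(-eta))` without overflow for large `|eta|`; the
#' result is kept strictly inside (0, 1).
#'
#' @param eta numeric vector of log-odds.
#' @return Probabilities in (0, 1).
#' @export
logistic <- function(eta) {
  p <- ifelse(eta >= 0, 1 / (1 + exp(-eta)), exp(eta) / (1 + exp(eta)))
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Serialize a product unit or PUNN model to JSON
#'
#' Round-trip safe: numbers are written at full precision and
#' [pu_from_json()] / [punn_from_json()] reconstruct an identical object.
#'
#' @param x a `product_unit` or `punn_model`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly `path` when writing to file).
#' @name pu_json
NULL

#' @rdname pu_json
#' @export
pu_to_json <- function(x, path = NULL) {
  obj <- list(type = "product_unit",
              exponent_bound = x$exponent_bound,
              tags = names(x$exponents),
              exponents = unname(x$exponents))
  emit_json(obj, path)
}

#' @rdname pu_json
#' @export
pu_from_json <- function(json) {
  obj <- parse_json(json)
  product_unit(stats::setNames(as.numeric(obj$exponents), unlist(obj$tags)),
               exponent_bound = obj$exponent_bound)
}

#' @rdname pu_json
#' @export
punn_to_json <- function(x, path = NULL) {
  obj <- list(type = "punn_model",
              bias = x$bias,
              coefficients = x$coefficients,
              units = lapply(x$units, function(u)
                list(exponent_bound = u$exponent_bound,
                     tags = names(u$exponents),
                     exponents = unname(u$exponents))))
  emit_json(obj, path)
}

#' @rdname pu_json
#' @export
punn_from_json <- function(json) {
  obj <- parse_json(json)
  punn_model(bias = obj$bias,
             coefficients = as.numeric(unlist(obj$coefficients)),
             units = lapply(obj$units, function(u)
               product_unit(stats::setNames(as.numeric(u$exponents),
                                            unlist(u$tags)),
                            exponent_bound = u$exponent_bound)))
}

emit_json <- function(obj, path = NULL) {
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(s))
  writeLines(s, path)
  invisible(path)
}

parse_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) {
    jsonlite::fromJSON(json, simplifyVector = FALSE)
  } else {
    jsonlite::fromJSON(paste(json, collapse = "\n"), simplifyVector = FALSE)
  }
}
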