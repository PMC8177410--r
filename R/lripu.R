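#' Construct a hybrid LRIPU model
#'
#' The LRIPU classifier (logistic regression using initial covariates and
#' product units) models the log-odds of six-month graft survival as
#' \deqn{\mathrm{ln}\frac{p}{1-p} = \beta_0 + \sum_{j=1}^{p}\beta_j x_j +
#'       \sum_k c_k \prod_i x_i^{w_{ki}}}
#' — an ordinary linear part over all scaled covariates plus the
#' product-unit basis functions taken from an evolved network, with their
#' exponents frozen. Usually built by [fit_lripu()] or parsed from a
#' printed expression by [parse_model_expression()].
#'
#' @param intercept real intercept \eqn{\beta_0}.
#' @param beta named numeric vector of linear coefficients (names
#'   `x1`...`xp`).
#' @param pu_terms list of product-unit terms, each a
#'   `list(coefficient =, unit = product_unit(...))`.
#' @param scaling optional training scaling record (see [scale_design()]);
#'   needed to predict from raw records.
#' @return An object of class `lripu_model`.
#' @export
lripu_model <- function(intercept = 0, beta = numeric(0), pu_terms = list(),
                        scaling = NULL) {
  stopifnot(is.finite(intercept), all(is.finite(beta)))
  if (length(beta) && is.null(names(beta)))
    names(beta) <- paste0("x", seq_along(beta))
  for (term in pu_terms) {
    if (!is.list(term) || !inherits(term$unit, "product_unit") ||
        !is.finite(term$coefficient))
      stop("each pu_term must be list(coefficient =, unit = product_unit)")
  }
  structure(list(intercept = as.numeric(intercept),
                 beta = beta, pu_terms = pu_terms, scaling = scaling),
            class = "lripu_model")
}

#' @export
n_params.lripu_model <- function(model) {
  1L + length(model$beta) +
    sum(vapply(model$pu_terms,
               function(t) 1L + length(t$unit$exponents), integer(1)))
}

#' @export
print.lripu_model <- function(x, ...) {
  cat(sprintf("lripu_model: %d covariates + %d product unit(s), %d parameters\n",
              length(x$beta), length(x$pu_terms), n_params(x)))
  cat(strtrim(print_model_expression(x, max_literal_digits = 4), 200), "\n")
  invisible(x)
}

# Logit of an LRIPU model over rows of an already-scaled matrix.
lripu_logit_scaled <- function(model, S) {
  S <- if (is.null(dim(S))) matrix(S, nrow = 1) else as.matrix(S)
  if (ncol(S) != length(model$beta))
    stop("model expects ", length(model$beta), " covariates, got ", ncol(S))
  eta <- rep(model$intercept, nrow(S)) +
    if (length(model$beta)) as.vector(S %*% unname(model$beta)) else 0
  for (term in model$pu_terms)
    eta <- eta + term$coefficient * pu_eval_rows(term$unit, S)
  eta
}

#' Fit the hybrid LRIPU model
#'
#' Penalized maximum-likelihood logistic regression over the scaled
#' covariates plus one derived feature per product-unit basis function
#' (each unit evaluated row-wise, exponents frozen). Fitting uses
#' iteratively reweighted least squares (IRLS) with a small ridge penalty
#' on all non-intercept coefficients; the one-of-k dummy blocks of the
#' covariate schema are exactly collinear, and the ridge keeps the weighted
#' normal equations solvable. On divergence (typically quasi-separation)
#' the ridge is escalated tenfold up to `max_ridge`; if still divergent the
#' fit fails with a diagnostic.
#'
#' With an empty basis this is plain logistic regression on the covariates.
#'
#' @param dm a scaled [design_matrix()] with both outcome classes.
#' @param basis list of [product_unit()]s from the evolved network.
#' @param ridge initial ridge penalty (default 1e-6).
#' @param max_ridge ceiling for ridge escalation (default 1e-2).
#' @param maxit maximum IRLS iterations (default 100).
#' @param tol convergence threshold on the maximum absolute coefficient
#'   change (default 1e-8); a maximum absolute penalized score below 1e-8
#'   also counts as converged (the collinear dummy blocks leave rounding
#'   noise in coefficient updates at the optimum).
#' @return A list with `model` (the [lripu_model()], carrying the training
#'   scaling) and `report` (class `fit_report`: `converged`, `iterations`,
#'   `deviance`, `ridge`, `se` — standard errors from the inverse penalized
#'   Fisher information — and `metrics`, the training [evaluate()] set).
#' @export
fit_lripu <- function(dm, basis = list(), ridge = 1e-6, max_ridge = 1e-2,
                      maxit = 100, tol = 1e-8) {
  stopifnot(inherits(dm, "design_matrix"))
  if (is.null(dm$y) || nrow(dm$X) == 0L)
    stop("fit_lripu needs a nonempty design with outcomes")
  if (length(unique(dm$y)) < 2L)
    stop("fit_lripu needs both outcome classes present")
  X <- dm$X
  y <- dm$y
  B <- if (length(basis)) {
    do.call(cbind, lapply(basis, function(u) pu_eval_rows(u, X)))
  } else {
    matrix(0, nrow(X), 0)
  }
  B <- matrix(B, nrow = nrow(X))
  Z <- cbind(`(Intercept)` = 1, X, B)
  q <- ncol(Z)

  lambda <- ridge
  repeat {
    res <- irls_logistic(Z, y, lambda, maxit, tol)
    if (!res$diverged) break
    lambda <- if (lambda == 0) 1e-6 else lambda * 10
    if (lambda > max_ridge)
      stop("IRLS diverged even at maximum ridge ", max_ridge,
           " (likely complete separation)", call. = FALSE)
  }

  beta <- res$beta
  k <- length(basis)
  pu_terms <- if (k) {
    lapply(seq_len(k), function(j)
      list(coefficient = unname(beta[1 + ncol(X) + j]), unit = basis[[j]]))
  } else {
    list()
  }
  model <- lripu_model(intercept = unname(beta[1]),
                       beta = stats::setNames(beta[1 + seq_len(ncol(X))],
                                              colnames(X)),
                       pu_terms = pu_terms,
                       scaling = dm$scaling)
  p_hat <- logistic(as.vector(Z %*% beta))
  report <- structure(list(converged = res$converged,
                           iterations = res$iterations,
                           deviance = 2 * length(y) * cross_entropy(p_hat, y),
                           ridge = lambda,
                           se = stats::setNames(res$se, colnames(Z)),
                           metrics = evaluate(p_hat, y)),
                      class = "fit_report")
  list(model = model, report = report)
}

# Ridge-penalized IRLS for logistic regression. The penalty applies to all
# non-intercept coefficients. Returns diverged = TRUE on numerical failure
# so the caller can escalate the ridge.
irls_logistic <- function(Z, y, lambda, maxit, tol) {
  q <- ncol(Z)
  penalty <- diag(c(0, rep(lambda, q - 1)), q)
  beta <- numeric(q)
  eta <- rep(0, nrow(Z))
  converged <- FALSE
  diverged <- FALSE
  iter <- 0
  for (iter in seq_len(maxit)) {
    p <- logistic(eta)
    w <- p * (1 - p)
    z <- eta + (y - p) / w
    A <- crossprod(Z, Z * w) + penalty
    b <- crossprod(Z, w * z)
    beta_new <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) {
      diverged <- TRUE
      break
    }
    delta <- max(abs(beta_new - beta))
    beta <- as.vector(beta_new)
    eta <- as.vector(Z %*% beta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
    # The one-of-k dummy blocks make A nearly singular; coefficient updates
    # can wiggle at rounding level along null directions even at the
    # optimum, so also accept a vanishing penalized score — but only with a
    # small step, since under separation the score vanishes while the
    # coefficients still drift outward.
    score <- crossprod(Z, y - logistic(eta)) - penalty %*% beta
    if (max(abs(score)) < 1e-10 && delta < 1e-3) {
      converged <- TRUE
      break
    }
  }
  # running out of iterations without meeting either criterion is treated
  # as divergence so the caller can escalate the ridge
  if (!converged) diverged <- TRUE
  se <- rep(NA_real_, q)
  if (!diverged) {
    p <- logistic(as.vector(Z %*% beta))
    A <- crossprod(Z, Z * (p * (1 - p))) + penalty
    V <- tryCatch(solve(A), error = function(e) NULL)
    if (!is.null(V)) se <- sqrt(pmax(diag(V), 0))
  }
  list(beta = beta, converged = converged, diverged = diverged,
       iterations = iter, se = se)
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report: %s in %d IRLS iterations, deviance %.3f, ridge %g\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$deviance, x$ridge))
  cat(sprintf("  train CCR %.4f  AUC %.4f  cross-entropy %.4f\n",
              x$metrics$ccr, x$metrics$auc, x$metrics$cross_entropy))
  invisible(x)
}

#' Predict six-month graft survival probability
#'
#' Evaluates the LRIPU log-odds and returns `logistic(eta)`. Raw inputs are
#' first mapped into \[1, 2\] with the training scaling stored in the model
#' (values outside the training range are clipped, with a warning, so that
#' product-unit bases stay positive).
#'
#' @param model an [lripu_model()].
#' @param newdata one of: a scaled or raw [design_matrix()]; a numeric
#'   matrix or vector of raw covariate values (columns `x1`...`xp`); a raw
#'   record (named list) or data frame of records, encoded via `schema`.
#' @param schema a `covariate_schema`, used when `newdata` is a record or
#'   data frame of raw records.
#' @param type `"response"` (probability, default) or `"link"` (log-odds).
#' @return Numeric vector of probabilities (or log-odds), strictly inside
#'   (0, 1) for `"response"`.
#' @export
predict_lripu <- function(model, newdata, schema = NULL,
                          type = c("response", "link")) {
  type <- match.arg(type)
  S <- resolve_scaled(model, newdata, schema)
  eta <- lripu_logit_scaled(model, S)
  if (type == "link") eta else logistic(eta)
}

resolve_scaled <- function(model, newdata, schema = NULL) {
  if (inherits(newdata, "design_matrix")) {
    if (newdata$scaled) return(newdata$X)
    if (is.null(model$scaling))
      stop("model has no scaling record; supply a scaled design")
    return(apply_scaling(model$scaling, newdata$X))
  }
  if (is.data.frame(newdata) || (is.list(newdata) && !is.null(names(newdata)))) {
    if (is.null(schema)) schema <- transplant_schema()
    X <- if (is.data.frame(newdata)) encode_records(newdata, schema)$X
         else matrix(encode(newdata, schema), nrow = 1,
                     dimnames = list(NULL, schema$tag))
    if (is.null(model$scaling))
      stop("model has no scaling record; cannot scale raw records")
    return(apply_scaling(model$scaling, X))
  }
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (is.null(model$scaling))
    stop("model has no scaling record; cannot scale raw values")
  apply_scaling(model$scaling, X)
}

#' Rank transplant candidates for a donor
#'
#' Composes the donor's fields with each candidate recipient's fields into
#' full records, predicts each pair's six-month graft survival probability,
#' and ranks candidates by descending probability. Ties keep the original
#' candidate order (stable sort). A pair that does not compose into a
#' complete, encodable record yields a per-candidate error entry; the
#' remaining candidates are still ranked.
#'
#' @param model a fitted [lripu_model()] with a scaling record.
#' @param donor named list of donor-side fields (e.g. `sex_donor`,
#'   `age_donor`, `death_d`, `ti_in_do`, `io2_donor`).
#' @param candidates list of named lists of the remaining fields, one per
#'   candidate recipient (candidate values override donor values on
#'   overlap).
#' @param schema a `covariate_schema`.
#' @return Data frame with columns `candidate`, `probability`, `rank`
#'   (NA for failed pairs) and `error`, ordered by rank.
#' @export
rank_recipients <- function(model, donor, candidates,
                            schema = transplant_schema()) {
  donor <- as.list(donor)
  ids <- if (!is.null(names(candidates)) && all(nzchar(names(candidates))))
    names(candidates) else as.character(seq_along(candidates))
  prob <- rep(NA_real_, length(candidates))
  err <- rep(NA_character_, length(candidates))
  for (i in seq_along(candidates)) {
    rec <- utils::modifyList(donor, as.list(candidates[[i]]))
    prob[i] <- tryCatch(
      predict_lripu(model, rec, schema = schema),
      error = function(e) {
        err[i] <<- conditionMessage(e)
        NA_real_
      })
  }
  ok <- !is.na(prob)
  ord <- c(which(ok)[order(-prob[ok])], which(!ok))
  out <- data.frame(candidate = ids[ord],
                    probability = prob[ord],
                    rank = ifelse(is.na(prob[ord]), NA_integer_,
                                  seq_along(ord)),
                    error = err[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Print an LRIPU model as a log-odds expression
#'
#' Emits the human-readable `ln(p/(1-p)) = ...` string: intercept, one
#' parenthesised product-unit block per term with caret-delimited
#' superscript exponents (`(x_9_)^2.27^`), then the linear coefficients.
#' Models built by [parse_model_expression()] remember the original numeric
#' literals and reproduce them exactly; otherwise numbers are printed at
#' full (17 significant digit) precision so that
#' `parse_model_expression(print_model_expression(m))` reconstructs `m`
#' exactly.
#'
#' @param model an [lripu_model()].
#' @param max_literal_digits optional cap on significant digits (for
#'   display only; breaks the exact round trip).
#' @return A single string.
#' @export
print_model_expression <- function(model, max_literal_digits = NULL) {
  lit <- attr(model, "literals")
  if (is.null(lit)) lit <- list(intercept = NULL, pu = list(), linear = list())
  pu_lit <- function(k) if (k <= length(lit$pu)) lit$pu[[k]] else NULL
  digits <- if (is.null(max_literal_digits)) 17L else max_literal_digits
  fmt <- function(v, literal = NULL) {
    if (!is.null(literal) && length(literal) == 1L && !is.na(literal) &&
        is.null(max_literal_digits)) return(literal)
    format(abs(v), digits = digits, trim = TRUE, scientific = FALSE)
  }
  sgn <- function(v, lead = FALSE) {
    if (v < 0) "-" else if (lead) "" else "+"
  }
  out <- paste0("ln(p/(1-p)) = ",
                sgn(model$intercept, lead = TRUE),
                fmt(model$intercept, lit$intercept))
  for (k in seq_along(model$pu_terms)) {
    term <- model$pu_terms[[k]]
    u <- term$unit
    kl <- pu_lit(k)
    facs <- vapply(seq_along(u$exponents), function(i) {
      tag_i <- sub("^x", "", names(u$exponents)[i])
      w <- u$exponents[i]
      paste0("(x_", tag_i, "_)^", if (w < 0) "-" else "",
             fmt(w, kl$exponents[i]), "^")
    }, character(1))
    out <- paste0(out, sgn(term$coefficient),
                  fmt(term$coefficient, kl$coefficient),
                  "(", paste0(facs, collapse = ""), ")")
  }
  for (j in seq_along(model$beta)) {
    tag <- names(model$beta)[j]
    out <- paste0(out, sgn(model$beta[j]),
                  fmt(model$beta[j], lit$linear[[tag]]),
                  "(x_", sub("^x", "", tag), "_)")
  }
  out
}

#' Serialize an LRIPU model to JSON and back
#'
#' Full-precision, round-trip-safe persistence of the intercept, linear
#' coefficients, product-unit terms and training scaling record.
#'
#' @param model an [lripu_model()].
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @param json JSON string or file path.
#' @return `lripu_to_json`: JSON string (or `path`, invisibly);
#'   `lripu_from_json`: the reconstructed [lripu_model()].
#' @name lripu_json
NULL

#' @rdname lripu_json
#' @export
lripu_to_json <- function(model, path = NULL) {
  obj <- list(
    type = "lripu_model", schema_version = 1L,
    intercept = model$intercept,
    tags = names(model$beta), beta = unname(model$beta),
    pu_terms = lapply(model$pu_terms, function(t)
      list(coefficient = t$coefficient,
           exponent_bound = t$unit$exponent_bound,
           tags = names(t$unit$exponents),
           exponents = unname(t$unit$exponents))),
    scaling = if (is.null(model$scaling)) NULL else
      list(names = names(model$scaling$min),
           min = unname(model$scaling$min),
           max = unname(model$scaling$max)))
  emit_json(obj, path)
}

#' @rdname lripu_json
#' @export
lripu_from_json <- function(json) {
  obj <- parse_json(json)
  scaling <- if (is.null(obj$scaling)) NULL else
    list(min = stats::setNames(as.numeric(obj$scaling$min),
                               unlist(obj$scaling$names)),
         max = stats::setNames(as.numeric(obj$scaling$max),
                               unlist(obj$scaling$names)))
  lripu_model(
    intercept = obj$intercept,
    beta = stats::setNames(as.numeric(unlist(obj$beta)), unlist(obj$tags)),
    pu_terms = lapply(obj$pu_terms, function(t)
      list(coefficient = t$coefficient,
           unit = product_unit(stats::setNames(as.numeric(t$exponents),
                                               unlist(t$tags)),
                               exponent_bound = t$exponent_bound))),
    scaling = scaling)
}
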