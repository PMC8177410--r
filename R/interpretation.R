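#' Parse a printed LRIPU log-odds expression
#'
#' Parses the human-readable `ln(p/(1-p)) = ...` dialect used to publish
#' the model: an intercept, optional product-unit blocks written as a
#' coefficient times a parenthesised run of caret-superscripted factors
#' (`-4.83((x_1_)^1.46^(x_9_)^2.27^...)`), and signed linear terms
#' (`+0.30(x_1_)`). The dialect is tolerant of the quirks of extracted
#' journal text: the Unicode minus `U+2212` and the ASCII hyphen are
#' interchangeable, whitespace and line breaks are ignored, a stray caret
#' may sit inside a factor's parentheses (`(x_11_^)-1.76^`), and the
#' product-unit block may close with redundant parentheses.
#'
#' The original numeric literal strings are remembered (as an attribute),
#' so [print_model_expression()] reproduces them exactly.
#'
#' @param text character vector (lines are concatenated) or the path of a
#'   file containing the expression.
#' @param n_covariates number of linear coefficients in the model; default
#'   is the largest covariate index mentioned in the text. Covariates not
#'   mentioned get coefficient 0.
#' @return An [lripu_model()] with attributes `source` (the original text)
#'   and `literals`.
#' @export
parse_model_expression <- function(text, n_covariates = NULL) {
  if (length(text) == 1L && !grepl("=", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  src <- paste(text, collapse = "\n")
  s <- gsub("−", "-", src)
  s <- gsub("[[:space:]]+", "", s)

  fail <- function(pos, why)
    stop("parse error at character ", pos, ": ", why, call. = FALSE)

  m <- regexpr("^ln\\(p/\\(1-p\\)\\)=", s)
  if (m == -1) fail(1, "expected the expression to start with 'ln(p/(1-p)) ='")
  pos <- attr(m, "match.length") + 1L

  peek <- function(n = 1) substr(s, pos, pos + n - 1L)
  num_re <- "^[+-]?[0-9]+(\\.[0-9]+)?"
  take_number <- function(lead = FALSE) {
    rest <- substr(s, pos, nchar(s))
    m <- regexpr(num_re, rest)
    if (m == -1) fail(pos, "expected a signed number")
    tok <- substr(rest, 1, attr(m, "match.length"))
    pos <<- pos + attr(m, "match.length")
    sign <- if (startsWith(tok, "-")) -1 else 1
    literal <- sub("^[+-]", "", tok)
    list(value = sign * as.numeric(literal), literal = literal)
  }
  take_factor <- function() {
    rest <- substr(s, pos, nchar(s))
    m <- regexec("^\\(x_([0-9]+)_\\^?\\)\\^?(-?[0-9]+(\\.[0-9]+)?)\\^",
                 rest)[[1]]
    if (m[1] == -1) return(NULL)
    g <- regmatches(rest, list(m))[[1]]
    pos <<- pos + attr(m, "match.length")[1]
    exp_lit <- g[3]
    list(index = as.integer(g[2]),
         value = as.numeric(exp_lit),
         literal = sub("^-", "", exp_lit))
  }

  intercept <- NULL
  beta <- numeric(0)
  pu_terms <- list()
  literals <- list(intercept = NULL, pu = list(), linear = list())

  while (pos <= nchar(s)) {
    num <- take_number()
    if (peek(2) == "((") {
      pos <- pos + 1L                       # consume the outer '('
      exps <- numeric(0)
      exp_lits <- character(0)
      repeat {
        f <- take_factor()
        if (is.null(f)) break
        exps[paste0("x", f$index)] <- f$value
        exp_lits <- c(exp_lits, f$literal)
      }
      if (!length(exps)) fail(pos, "product-unit block has no factors")
      if (peek() != ")") fail(pos, "expected ')' closing the product unit")
      while (pos <= nchar(s) && peek() == ")") pos <- pos + 1L
      bound <- max(10, ceiling(max(abs(exps))))
      pu_terms[[length(pu_terms) + 1L]] <-
        list(coefficient = num$value, unit = product_unit(exps, bound))
      literals$pu[[length(pu_terms)]] <-
        list(coefficient = num$literal, exponents = exp_lits)
    } else if (peek(3) == "(x_") {
      rest <- substr(s, pos, nchar(s))
      m <- regexec("^\\(x_([0-9]+)_\\)", rest)[[1]]
      if (m[1] == -1) fail(pos, "malformed covariate reference")
      idx <- as.integer(regmatches(rest, list(m))[[1]][2])
      pos <- pos + attr(m, "match.length")[1]
      tag <- paste0("x", idx)
      beta[tag] <- num$value
      literals$linear[[tag]] <- num$literal
    } else if (is.null(intercept)) {
      intercept <- num$value
      literals$intercept <- num$literal
    } else {
      fail(pos, "unexpected bare number (intercept already read)")
    }
    if (is.null(intercept)) {
      # a leading product-unit or linear term before any bare number
      intercept <- 0
      literals$intercept <- NULL
    }
  }
  if (is.null(intercept)) fail(pos, "empty expression")

  p <- n_covariates
  if (is.null(p)) {
    mentioned <- c(as.integer(sub("^x", "", names(beta))),
                   unlist(lapply(pu_terms, function(t) pu_support(t$unit))))
    p <- if (length(mentioned)) max(mentioned) else 0L
  }
  full <- stats::setNames(numeric(p), if (p) paste0("x", seq_len(p)) else character(0))
  full[names(beta)] <- beta
  model <- lripu_model(intercept = intercept, beta = full,
                       pu_terms = pu_terms)
  attr(model, "source") <- src
  attr(model, "literals") <- literals
  model
}

#' Load the bundled printed-model fixture
#'
#' Returns the published LRIPU log-odds expression shipped with the
#' package (`extdata/table2_model.txt`), parsed into an [lripu_model()]:
#' intercept 2.50, one product unit over 10 covariates with output
#' coefficient -4.83, and 36 linear coefficients — 48 parameters in all.
#'
#' @return An [lripu_model()] (see [parse_model_expression()]).
#' @export
published_model <- function() {
  path <- system.file("extdata", "table2_model.txt", package = "lripu")
  if (!nzchar(path)) stop("bundled model fixture not found")
  parse_model_expression(path)
}

#' Coefficient and exponent report for an LRIPU model
#'
#' Summarises the model the way its published interpretation reads it:
#' every linear coefficient with its sign class (a positive coefficient
#' raises the predicted survival probability as the covariate grows, all
#' else fixed and outside product-unit supports), every product-unit
#' exponent, the extreme coefficients and exponents, and the parameter
#' counts of the linear and nonlinear parts.
#'
#' @param model an [lripu_model()].
#' @param schema optional `covariate_schema` supplying covariate names.
#' @return A `coefficient_report`: list with `linear` (data frame: `tag`,
#'   `name`, `coefficient`, `sign_class`), `pu` (data frame: `unit`, `tag`,
#'   `name`, `exponent`), `extremes` (largest positive / most negative
#'   linear coefficient, largest / most negative exponent, with tags), and
#'   `counts` (`total`, `linear`, `nonlinear`).
#' @export
build_report <- function(model, schema = NULL) {
  tags <- names(model$beta)
  name_of <- function(tg) {
    if (is.null(schema)) return(NA_character_)
    schema$name[match(tg, schema$tag)]
  }
  linear <- data.frame(
    tag = tags,
    name = vapply(tags, name_of, character(1)),
    coefficient = unname(model$beta),
    sign_class = ifelse(model$beta > 0, "positive",
                        ifelse(model$beta < 0, "negative", "zero")),
    stringsAsFactors = FALSE)
  rownames(linear) <- NULL

  pu <- do.call(rbind, lapply(seq_along(model$pu_terms), function(k) {
    u <- model$pu_terms[[k]]$unit
    if (!length(u$exponents)) return(NULL)
    data.frame(unit = k, tag = names(u$exponents),
               name = vapply(names(u$exponents), name_of, character(1)),
               exponent = unname(u$exponents), stringsAsFactors = FALSE)
  }))
  if (is.null(pu))
    pu <- data.frame(unit = integer(0), tag = character(0),
                     name = character(0), exponent = numeric(0))
  rownames(pu) <- NULL

  pick <- function(df, col, which_fn) {
    if (!nrow(df)) return(list(tag = NA_character_, value = NA_real_))
    i <- which_fn(df[[col]])
    list(tag = df$tag[i], value = df[[col]][i])
  }
  pos <- linear[linear$coefficient > 0, , drop = FALSE]
  neg <- linear[linear$coefficient < 0, , drop = FALSE]
  extremes <- list(
    max_positive_coefficient = pick(pos, "coefficient", which.max),
    max_negative_coefficient = pick(neg, "coefficient", which.min),
    max_exponent = pick(pu, "exponent", which.max),
    min_exponent = pick(pu, "exponent", which.min))

  counts <- list(
    total = n_params(model),
    linear = 1L + length(model$beta),
    nonlinear = sum(vapply(model$pu_terms,
                           function(t) 1L + length(t$unit$exponents),
                           integer(1))))
  structure(list(linear = linear, pu = pu, extremes = extremes,
                 counts = counts),
            class = "coefficient_report")
}

#' @export
print.coefficient_report <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}

#' Render a coefficient report as Markdown
#'
#' @param report a `coefficient_report` from [build_report()].
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  ex <- report$extremes
  fmt_ex <- function(e) if (is.na(e$tag)) "none" else
    sprintf("%.4g (%s)", e$value, e$tag)
  lines <- c(
    sprintf("## Model structure: %d parameters (%d linear, %d nonlinear)",
            report$counts$total, report$counts$linear,
            report$counts$nonlinear),
    "",
    sprintf("- largest positive linear coefficient: %s",
            fmt_ex(ex$max_positive_coefficient)),
    sprintf("- largest-magnitude negative linear coefficient: %s",
            fmt_ex(ex$max_negative_coefficient)),
    sprintf("- largest product-unit exponent: %s", fmt_ex(ex$max_exponent)),
    sprintf("- most negative product-unit exponent: %s",
            fmt_ex(ex$min_exponent)),
    "",
    sprintf("- positive-coefficient covariates: %s",
            paste(report$linear$tag[report$linear$sign_class == "positive"],
                  collapse = ", ")),
    sprintf("- negative-coefficient covariates: %s",
            paste(report$linear$tag[report$linear$sign_class == "negative"],
                  collapse = ", ")))
  lines
}

#' Write a coefficient report as CSV
#'
#' Writes the per-covariate linear table and appends the product-unit
#' exponent rows (with `coefficient` column holding the exponent and
#' `sign_class` `"exponent"`).
#'
#' @param report a `coefficient_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
report_csv <- function(report, path) {
  lin <- cbind(part = "linear", report$linear)
  pu <- if (nrow(report$pu)) {
    data.frame(part = "product_unit", tag = report$pu$tag,
               name = report$pu$name, coefficient = report$pu$exponent,
               sign_class = "exponent", stringsAsFactors = FALSE)
  } else NULL
  utils::write.csv(rbind(lin, pu), path, row.names = FALSE)
  invisible(path)
}

#' Predicted-probability curve along one covariate
#'
#' Sweeps a single scaled covariate across its \[1, 2\] range while all
#' other covariates stay fixed at a baseline, and returns the predicted
#' survival probability along the sweep. The default baseline is the
#' all-ones vector — the scaled minimum of every covariate (zero raw values
#' are unattainable after the \[1, 2\] scaling, so the minimum is the
#' natural reference point).
#'
#' @param model an [lripu_model()].
#' @param tag covariate tag (e.g. `"x33"`) or index.
#' @param baseline scaled covariate vector (defaults to all ones).
#' @param n_grid number of grid points (default 101).
#' @return Data frame with columns `value` (scaled covariate) and
#'   `probability`.
#' @export
covariate_effect_curve <- function(model, tag, baseline = NULL,
                                   n_grid = 101) {
  p <- length(model$beta)
  idx <- if (is.numeric(tag)) as.integer(tag)
         else match(tag, names(model$beta))
  if (is.na(idx) || idx < 1 || idx > p)
    stop("covariate '", tag, "' not in the model")
  if (is.null(baseline)) baseline <- rep(1, p)
  stopifnot(length(baseline) == p, all(baseline >= 1), all(baseline <= 2))
  grid <- seq(1, 2, length.out = n_grid)
  S <- matrix(rep(baseline, each = n_grid), nrow = n_grid)
  S[, idx] <- grid
  colnames(S) <- names(model$beta)
  data.frame(value = grid,
             probability = logistic(lripu_logit_scaled(model, S)))
}
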