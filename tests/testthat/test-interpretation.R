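test_that("the bundled printed-model fixture parses to the published structure", {
  m <- published_model()
  expect_s3_class(m, "lripu_model")
  expect_identical(n_params(m), 48L)
  expect_equal(m$intercept, 2.50)
  expect_identical(length(m$beta), 36L)
  expect_identical(length(m$pu_terms), 1L)
  expect_equal(m$pu_terms[[1]]$coefficient, -4.83)
  u <- m$pu_terms[[1]]$unit
  expect_identical(names(u$exponents),
                   paste0("x", c(1, 9, 11, 14, 15, 23, 24, 26, 29, 33)))
  expect_equal(unname(u$exponents),
               c(1.46, 2.27, -1.76, 3.67, 0.37, 6.03, 3.15, 0.06, 3.96, 1.45))
})

test_that("degenerate and malformed expressions are handled", {
  m0 <- parse_model_expression("ln(p/(1-p)) = 0")
  expect_equal(m0$intercept, 0)
  expect_identical(length(m0$beta), 0L)
  expect_identical(length(m0$pu_terms), 0L)
  expect_identical(n_params(m0), 1L)

  expect_error(parse_model_expression("p = 1/2"), "character 1")
  expect_error(parse_model_expression("ln(p/(1-p)) = 1.5 + bogus"),
               "parse error at character")
  expect_error(parse_model_expression("ln(p/(1-p)) = 1.5+2.0((x_1_)1.3)"),
               "parse error")
})

test_that("unicode and ASCII minus parse identically", {
  a <- parse_model_expression("ln(p/(1-p)) = −2.5−1.1(x_2_)")
  b <- parse_model_expression("ln(p/(1-p)) = -2.5-1.1(x_2_)")
  expect_equal(a$intercept, b$intercept)
  expect_equal(a$beta, b$beta)
})

test_that("print and parse round-trip models exactly", {
  # fixture round trip reproduces every numeric literal
  m <- published_model()
  printed <- print_model_expression(m)
  nums <- function(t) sort(as.numeric(
    regmatches(t, gregexpr("[0-9]+\\.[0-9]+", gsub("−", "-", t)))[[1]]))
  orig <- paste(readLines(table2_path()), collapse = "")
  expect_identical(nums(printed), nums(orig))
  m2 <- parse_model_expression(printed)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$beta, m$beta)
  expect_equal(m2$pu_terms[[1]]$unit$exponents,
               m$pu_terms[[1]]$unit$exponents)

  # full-precision round trip for an arbitrary fitted-style model
  set.seed(31)
  mm <- lripu_model(intercept = rnorm(1),
                    beta = setNames(round(rnorm(5), 6), paste0("x", 1:5)),
                    pu_terms = list(list(coefficient = 1 / 3,
                                         unit = product_unit(c(x2 = pi / 2,
                                                               x4 = -0.125)))))
  back <- parse_model_expression(print_model_expression(mm))
  expect_identical(back$intercept, mm$intercept)
  expect_identical(unname(back$beta), unname(mm$beta))
  expect_identical(unname(back$pu_terms[[1]]$unit$exponents),
                   unname(mm$pu_terms[[1]]$unit$exponents))
  expect_identical(back$pu_terms[[1]]$coefficient, mm$pu_terms[[1]]$coefficient)
})

test_that("the coefficient report classifies signs as published", {
  m <- published_model()
  rep <- build_report(m, transplant_schema())

  positive <- rep$linear$tag[rep$linear$sign_class == "positive"]
  expect_identical(positive,
                   paste0("x", c(1, 3, 5, 6, 8, 15, 16, 17, 18, 21, 22, 23,
                                 25, 26, 28, 31, 32, 33, 34)))
  # every other covariate is negative (the fixture has no zero coefficient)
  expect_identical(sum(rep$linear$sign_class == "zero"), 0L)

  ex <- rep$extremes
  expect_equal(ex$max_positive_coefficient$value, 23.50)
  expect_identical(ex$max_positive_coefficient$tag, "x33")
  expect_identical(rep$linear$name[rep$linear$tag == "x33"], "fvc_pre")
  expect_equal(ex$max_negative_coefficient$value, -23.51)
  expect_identical(ex$max_negative_coefficient$tag, "x35")
  expect_equal(ex$max_exponent$value, 6.03)
  expect_identical(ex$max_exponent$tag, "x23")
  expect_equal(ex$min_exponent$value, -1.76)
  expect_identical(ex$min_exponent$tag, "x11")

  expect_identical(rep$counts$total, 48L)
  expect_identical(rep$counts$linear, 37L)
  expect_identical(rep$counts$nonlinear, 11L)
})

test_that("an all-zero model yields empty sign classes", {
  m <- lripu_model(intercept = 0, beta = setNames(numeric(4), paste0("x", 1:4)))
  rep <- build_report(m)
  expect_identical(sum(rep$linear$sign_class != "zero"), 0L)
  expect_true(is.na(rep$extremes$max_positive_coefficient$tag))
  expect_true(is.na(rep$extremes$max_exponent$tag))
  expect_identical(rep$counts$total, 5L)
})

test_that("report counts satisfy the structural identity", {
  set.seed(4)
  for (i in 1:10) {
    p <- sample(3:8, 1)
    k <- sample(0:2, 1)
    pu_terms <- lapply(seq_len(k), function(j) {
      nsup <- sample.int(p, 1)
      list(coefficient = rnorm(1),
           unit = product_unit(setNames(runif(nsup, -2, 2),
                                        paste0("x", sample.int(p, nsup)))))
    })
    m <- lripu_model(intercept = 1, beta = setNames(rnorm(p), paste0("x", 1:p)),
                     pu_terms = pu_terms)
    rep <- build_report(m)
    supports <- sum(vapply(pu_terms, function(t) length(t$unit$exponents),
                           integer(1)))
    expect_identical(rep$counts$total, 1L + p + k + supports)
    expect_identical(rep$counts$total,
                     rep$counts$linear + rep$counts$nonlinear)
  }
})

test_that("effect curves respond to coefficients as expected", {
  # zero coefficient outside all supports: flat curve
  m <- lripu_model(intercept = 0.4,
                   beta = setNames(c(1.2, 0, -0.8), paste0("x", 1:3)),
                   pu_terms = list(list(coefficient = 0.5,
                                        unit = product_unit(c(x3 = 2)))))
  flat <- covariate_effect_curve(m, "x2")
  expect_equal(diff(range(flat$probability)), 0)

  # single positive linear coefficient: strictly increasing
  up <- covariate_effect_curve(m, "x1")
  expect_true(all(diff(up$probability) > 0))

  # published model, sweeping x35 at the all-ones baseline: strictly
  # decreasing (negative coefficient, outside the product-unit support)
  m2 <- published_model()
  down <- covariate_effect_curve(m2, "x35")
  expect_true(all(diff(down$probability) < 0))
})

test_that("reports are written as CSV and Markdown", {
  rep <- build_report(published_model(), transplant_schema())
  path <- withr::local_tempfile(fileext = ".csv")
  report_csv(rep, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), 36L + 10L)
  md <- report_markdown(rep)
  expect_true(any(grepl("48 parameters", md)))
  expect_true(any(grepl("23.5 \\(x33\\)", md)))
})
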