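test_that("with an empty basis the fit matches a reference logistic regression", {
  dm <- make_uniform_design(250, 3, function(X) -1 + 2 * X[, 1] - 1.5 * X[, 3],
                            seed = 21)
  fit <- fit_lripu(dm, basis = list(), ridge = 0)
  ref <- glm.fit(cbind(1, dm$X), dm$y, family = binomial())
  expect_equal(unname(c(fit$model$intercept, fit$model$beta)),
               unname(coef(ref)), tolerance = 1e-6)
  expect_true(fit$report$converged)
  expect_identical(length(fit$model$pu_terms), 0L)
})

test_that("an intercept-only balanced fit gives intercept zero", {
  # constant covariate scales to all-1 and carries no information; with a
  # 50/50 outcome the intercept is the logit of 0.5 = 0
  X <- matrix(5, 40, 1, dimnames = list(NULL, "x1"))
  dm_raw <- design_matrix(X, y = rep(c(0, 1), 20))
  dm <- suppressWarnings(scale_design(dm_raw))
  fit <- fit_lripu(dm, ridge = 0)
  expect_equal(fit$model$intercept, 0, tolerance = 1e-8)
})

test_that("IRLS matches direct penalized likelihood maximization", {
  # small instances: n = 50, 3 covariates, 1 product unit
  unit <- product_unit(c(x1 = 1.5, x3 = -1))
  for (seed in 1:3) {
    dm <- make_uniform_design(50, 3,
                              function(X) 1 + 0.5 * X[, 2] - 1.5 * X[, 1]^1.5 / X[, 3],
                              seed = seed)
    lam <- 1e-6
    fit <- fit_lripu(dm, basis = list(unit), ridge = lam)
    Z <- cbind(1, dm$X, pu = apply(dm$X, 1, function(r) pu_eval(unit, r)))
    negll <- function(b) {
      eta <- as.vector(Z %*% b)
      lse <- ifelse(eta > 30, eta, log1p(exp(eta)))
      -sum(dm$y * eta - lse) + lam / 2 * sum(b[-1]^2)
    }
    grad <- function(b) {
      p <- lripu::logistic(as.vector(Z %*% b))
      -as.vector(crossprod(Z, dm$y - p)) + lam * c(0, b[-1])
    }
    opt <- optim(rep(0, ncol(Z)), negll, grad, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-15))
    # polish to a vanishing gradient so the oracle itself is at 1e-8 scale
    f_both <- function(b) structure(negll(b), gradient = grad(b))
    pol <- nlm(f_both, opt$par, gradtol = 1e-12, steptol = 1e-14,
               iterlim = 500)
    got <- unname(c(fit$model$intercept, fit$model$beta,
                    fit$model$pu_terms[[1]]$coefficient))
    expect_equal(got, unname(pol$estimate), tolerance = 1e-6)
  }
})

test_that("the ridge escalates under separation instead of diverging", {
  # perfectly separated outcome on one covariate: the unpenalized MLE does
  # not exist, so a ridge-0 fit must escalate to a positive ridge
  X <- matrix(c(seq(1, 1.4, length.out = 10), seq(1.6, 2, length.out = 10)),
              ncol = 1, dimnames = list(NULL, "x1"))
  dm <- design_matrix(X, y = rep(c(0, 1), each = 10), scaled = TRUE,
                      scaling = list(min = c(x1 = 1), max = c(x1 = 2)))
  fit <- fit_lripu(dm, ridge = 0)
  expect_true(fit$report$ridge > 0)
  expect_true(all(is.finite(c(fit$model$intercept, fit$model$beta))))
})

test_that("predictions are probabilities, monotone outside product-unit supports", {
  dm <- make_uniform_design(300, 4,
                            function(X) 0.5 - X[, 2] + 2 * X[, 1]^2 / X[, 3],
                            seed = 5)
  fit <- fit_lripu(dm, basis = list(product_unit(c(x1 = 2, x3 = -1))))
  pr <- predict_lripu(fit$model, dm)
  expect_true(all(pr > 0 & pr < 1))

  # logit 0 -> probability 0.5
  m0 <- lripu_model(intercept = 0, beta = setNames(numeric(2), c("x1", "x2")),
                    scaling = list(min = c(x1 = 0, x2 = 0),
                                   max = c(x1 = 1, x2 = 1)))
  expect_equal(unname(predict_lripu(m0, c(0.4, 0.9))), 0.5)

  # x2 is outside the unit's support: predictions move with the sign of
  # its coefficient along an x2 sweep
  sweep_prob <- covariate_effect_curve(fit$model, "x2")$probability
  sgn <- sign(fit$model$beta[["x2"]])
  expect_true(all(sgn * diff(sweep_prob) > 0))
})

test_that("the printed model evaluated at all-ones matches an independent sum", {
  m <- published_model()
  # independent oracle: pull every signed linear coefficient out of the
  # fixture text by regex and sum the literals
  txt <- gsub("−", "-", paste(readLines(table2_path()), collapse = ""))
  lin <- regmatches(txt, gregexpr("[+-][0-9]+\\.[0-9]+\\(x_[0-9]+_\\)", txt))[[1]]
  coefs <- as.numeric(sub("\\(x_[0-9]+_\\)", "", lin))
  expect_identical(length(coefs), 36L)
  expected_logit <- 2.50 - 4.83 + sum(coefs)
  S <- rep(1, 36)
  expect_equal(unname(lripu:::lripu_logit_scaled(m, S)), expected_logit,
               tolerance = 1e-12)
  expect_equal(unname(predict_lripu(m, design_matrix(
    matrix(S, 1, dimnames = list(NULL, paste0("x", 1:36))),
    scaled = TRUE,
    scaling = list(min = rep(1, 36), max = rep(2, 36))))),
    logistic(expected_logit))
})

test_that("increasing x33 raises the published model's survival probability", {
  m <- published_model()
  curve <- covariate_effect_curve(m, "x33")
  expect_true(all(diff(curve$probability) > 0))
})

test_that("rank_recipients orders candidates by predicted survival", {
  dm <- make_uniform_design(200, 36, function(X) 2 * X[, 33] - X[, 35] - 1,
                            seed = 9)
  sch <- transplant_schema()
  # a raw-scale model: refit quickly on encoded synthetic records instead
  co <- simulate_cohort(cohort_spec(n = 300, seed = 14))
  fit <- fit_lripu(co$design,
                   basis = lapply(co$spec$truth$pu_terms, `[[`, "unit"))
  donor <- list(sex_donor = 1, age_donor = 40, death_d = "TBI",
                ti_in_do = 2, io2_donor = 430)
  cand_base <- make_record()
  cand_base$sex_donor <- NULL; cand_base$age_donor <- NULL
  cand_base$death_d <- NULL; cand_base$ti_in_do <- NULL
  cand_base$io2_donor <- NULL

  c1 <- utils::modifyList(cand_base, list(fvc_pre = 80, fev1_pre = 60))
  c2 <- utils::modifyList(cand_base, list(fvc_pre = 30, fev1_pre = 20,
                                          pre_tx = "ICU"))
  c3 <- cand_base

  # single candidate -> rank 1
  r1 <- rank_recipients(fit$model, donor, list(c1), sch)
  expect_identical(r1$rank, 1L)

  # ranking equals a brute-force sort of independently computed probabilities
  rk <- suppressWarnings(rank_recipients(fit$model, donor, list(c1, c2, c3), sch))
  probs <- suppressWarnings(vapply(list(c1, c2, c3), function(cc)
    predict_lripu(fit$model, utils::modifyList(donor, cc), schema = sch),
    numeric(1)))
  expect_equal(rk$probability, sort(probs, decreasing = TRUE))
  expect_identical(rk$candidate[1],
                   as.character(which.max(probs)))

  # two identical candidates keep their input order (stable tie-break)
  rk2 <- rank_recipients(fit$model, donor, list(a = c1, b = c1), sch)
  expect_identical(rk2$candidate, c("a", "b"))
  expect_equal(rk2$probability[1], rk2$probability[2])

  # an incomposable pair gets an error entry; the rest are still ranked
  broken <- utils::modifyList(cand_base, list(desease2 = "unknown-disease"))
  rk3 <- rank_recipients(fit$model, donor, list(c1, broken), sch)
  expect_true(is.na(rk3$probability[rk3$error != "" & !is.na(rk3$error)]))
  expect_identical(sum(!is.na(rk3$rank)), 1L)
})

test_that("LRIPU models round-trip through JSON with scaling", {
  co <- simulate_cohort(cohort_spec(n = 120, seed = 3))
  fit <- fit_lripu(co$design,
                   basis = lapply(co$spec$truth$pu_terms, `[[`, "unit"))
  js <- lripu_to_json(fit$model)
  back <- lripu_from_json(js)
  expect_equal(back$intercept, fit$model$intercept)
  expect_equal(back$beta, fit$model$beta)
  expect_equal(back$scaling$min, fit$model$scaling$min)
  expect_equal(back$pu_terms[[1]]$coefficient,
               fit$model$pu_terms[[1]]$coefficient)
  expect_equal(back$pu_terms[[1]]$unit$exponents,
               fit$model$pu_terms[[1]]$unit$exponents)
})
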