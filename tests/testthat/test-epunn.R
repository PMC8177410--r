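test_that("fitness is the bounded inverse of mean cross-entropy", {
  # constant p = 0.5 on balanced outcomes: CE = ln 2
  dm <- design_matrix(matrix(1.5, 10, 2), y = rep(c(0, 1), 5),
                      scaled = TRUE, scaling = list(min = c(1, 1), max = c(2, 2)))
  m_flat <- punn_model(bias = 0)
  expect_equal(fitness(m_flat, dm), 1 / (1 + log(2)), tolerance = 1e-12)

  # saturated correct predictions: CE -> 0, fitness -> 1
  dm2 <- make_uniform_design(20, 2, seed = 1)
  m_sep <- punn_model(bias = -500, coefficients = 1000,
                      units = list(product_unit(c(x1 = 0.0))))
  # bias +/- 500 depending on outcome via direct eta check instead:
  eta <- ifelse(dm2$y == 1, 50, -50)
  expect_equal(1 / (1 + lripu:::cross_entropy(logistic(eta), dm2$y)), 1,
               tolerance = 1e-9)

  # duplicating every row leaves fitness unchanged
  m <- punn_model(bias = 0.3, coefficients = -1,
                  units = list(product_unit(c(x1 = 1.5))))
  dm_dup <- design_matrix(rbind(dm2$X, dm2$X), y = c(dm2$y, dm2$y),
                          scaled = TRUE, scaling = dm2$scaling)
  expect_equal(fitness(m, dm2), fitness(m, dm_dup))

  # a model evaluating non-finite gets fitness 0, not an error
  m_bad <- punn_model(bias = 0, coefficients = 1e308,
                      units = list(product_unit(c(x1 = 10))))
  dm_big <- design_matrix(matrix(2, 5, 1), y = c(0, 1, 0, 1, 0),
                          scaled = TRUE, scaling = list(min = 1, max = 2))
  expect_equal(fitness(m_bad, dm_big), 0)
})

test_that("parametric mutation preserves structure, honors scale 0, seeds and bounds", {
  cfg <- ea_config(param_scale = 0, seed = 1)
  m <- punn_model(bias = 1, coefficients = c(0.5, -2),
                  units = list(product_unit(c(x1 = 2, x3 = -1)),
                               product_unit(c(x2 = 0.5))))
  expect_equal(parametric_mutation(m, cfg), m)

  cfg2 <- ea_config(param_scale = 0.5)
  set.seed(99); m1 <- parametric_mutation(m, cfg2)
  set.seed(99); m2 <- parametric_mutation(m, cfg2)
  expect_identical(m1, m2)

  # structure unchanged
  expect_identical(lapply(m1$units, function(u) names(u$exponents)),
                   lapply(m$units, function(u) names(u$exponents)))

  # an exponent at the bound never exceeds it
  cfg3 <- ea_config(param_scale = 50, exponent_bound = 10)
  m_edge <- punn_model(bias = 0, coefficients = 1,
                       units = list(product_unit(c(x1 = 10))))
  set.seed(3)
  for (i in 1:50) {
    mm <- parametric_mutation(m_edge, cfg3)
    expect_true(all(abs(mm$units[[1]]$exponents) <= 10))
  }
})

test_that("structural mutation applies exactly one feasible move", {
  cfg <- ea_config(max_units = 2)
  two_units <- punn_model(bias = 0, coefficients = c(1, -1),
                          units = list(product_unit(c(x1 = 1, x2 = 1)),
                                       product_unit(c(x3 = 1))))
  # at max units the add-unit move is infeasible: park all mass there and
  # the remaining probability is renormalised over the other moves
  cfg_add <- ea_config(max_units = 2, p_add_unit = 1, p_del_unit = 0,
                       p_add_conn = 0, p_del_conn = 0)
  set.seed(5)
  mm <- structural_mutation(two_units, cfg_add, p = 4)
  expect_identical(mm, two_units)   # no feasible move carries probability

  # with default probabilities another move is applied instead, and the
  # unit bound is never exceeded
  set.seed(6)
  for (i in 1:30) {
    mm <- structural_mutation(two_units, cfg, p = 4)
    expect_true(length(mm$units) <= cfg$max_units)
  }

  # delete-unit on a one-unit model gives a bias-only model
  one_unit <- punn_model(bias = 0.2, coefficients = 1,
                         units = list(product_unit(c(x1 = 1))))
  cfg_del <- ea_config(p_add_unit = 0, p_del_unit = 1, p_add_conn = 0,
                       p_del_conn = 0)
  set.seed(1)
  mm <- structural_mutation(one_unit, cfg_del, p = 4)
  expect_identical(length(mm$units), 0L)
  expect_identical(n_params(mm), 1L)

  # parameter-count deltas per move type on a two-unit toy model
  set.seed(42)
  base_np <- n_params(two_units)
  for (i in 1:40) {
    cfg1 <- ea_config(max_units = 3, p_add_unit = 1, p_del_unit = 0,
                      p_add_conn = 0, p_del_conn = 0, init_max_conn = 3)
    d_add_unit <- n_params(structural_mutation(two_units, cfg1, p = 5)) - base_np
    expect_true(d_add_unit %in% (1 + 1:3))  # coefficient + 1..3 exponents

    cfg2 <- ea_config(p_add_unit = 0, p_del_unit = 1, p_add_conn = 0,
                      p_del_conn = 0)
    d_del_unit <- n_params(structural_mutation(two_units, cfg2, p = 5)) - base_np
    expect_true(d_del_unit %in% c(-3, -2))  # unit 1 has 2 exps, unit 2 has 1

    cfg3 <- ea_config(p_add_unit = 0, p_del_unit = 0, p_add_conn = 1,
                      p_del_conn = 0)
    d_add_conn <- n_params(structural_mutation(two_units, cfg3, p = 5)) - base_np
    expect_identical(d_add_conn, 1L)

    cfg4 <- ea_config(p_add_unit = 0, p_del_unit = 0, p_add_conn = 0,
                      p_del_conn = 1)
    d_del_conn <- n_params(structural_mutation(two_units, cfg4, p = 5)) - base_np
    # -1 for an ordinary connection; -2 when the last connection of a unit
    # goes (the unit and its coefficient go with it)
    expect_true(d_del_conn %in% c(-1L, -2L))
  }
})

test_that("evolve is reproducible, elitist-monotone and bound-respecting", {
  dm <- make_uniform_design(120, 3, function(X) -2 + 1.5 * X[, 1]^2 / X[, 2],
                            seed = 8)
  cfg <- ea_config(pop_size = 20, generations = 25, seed = 11)
  ev1 <- evolve(dm, cfg)
  ev2 <- evolve(dm, cfg)
  expect_identical(ev1$trace, ev2$trace)
  expect_identical(ev1$best_model, ev2$best_model)

  expect_false(is.unsorted(ev1$trace$best_fitness))
  expect_identical(nrow(ev1$trace), 26L)

  expect_true(length(ev1$best_model$units) <= cfg$max_units)
  for (u in ev1$best_model$units)
    expect_true(all(abs(u$exponents) <= cfg$exponent_bound))

  # generations = 0 returns the best of the random initial population
  ev0 <- evolve(dm, ea_config(pop_size = 15, generations = 0, seed = 2))
  expect_identical(nrow(ev0$trace), 1L)
  expect_true(ev0$best_fitness > 0)
})

test_that("evolve refuses single-class data", {
  dm <- design_matrix(matrix(runif(20, 1, 2), 10, 2), y = rep(1, 10),
                      scaled = TRUE,
                      scaling = list(min = c(1, 1), max = c(2, 2)))
  expect_error(evolve(dm, ea_config(pop_size = 5, generations = 1)),
               "single class")
})

test_that("ea_config validates fields and round-trips through files", {
  expect_error(ea_config(p_add_unit = 1.2), "probabilities")
  expect_error(ea_config(pop_size = 0), "counts")
  expect_error(ea_config(selection_pressure = 3), "selection_pressure")

  cfg <- ea_config(pop_size = 33, generations = 7, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE), path)
  cfg2 <- read_ea_config(path)
  expect_equal(cfg2, cfg)
})

test_that("evolution traces are written as readable CSV", {
  dm <- make_uniform_design(60, 2, function(X) X[, 1] - 1.5, seed = 3)
  ev <- evolve(dm, ea_config(pop_size = 10, generations = 5, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(ev, path)
  back <- utils::read.csv(path)
  expect_equal(back$best_fitness, ev$trace$best_fitness)
})
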