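#' Evolutionary algorithm configuration
#'
#' Hyperparameters for the mutation-only evolutionary programming search
#' over product-unit network architecture and weights. There is no
#' recombination: offspring are produced by structural mutation (which adds
#' or deletes whole units or single exponent connections) and parametric
#' mutation (Gaussian perturbation of all weights), under rank-based
#' selection with elitism.
#'
#' @param pop_size population size (default 100).
#' @param generations number of generations (default 200); 0 returns the
#'   best of the random initial population.
#' @param max_units maximum product units per individual (default 3).
#' @param exponent_bound maximum exponent magnitude (default 10).
#' @param p_add_unit,p_del_unit,p_add_conn,p_del_conn structural move
#'   probabilities (defaults 0.25 each; renormalised over feasible moves).
#' @param p_structural probability that an offspring undergoes a structural
#'   mutation before its parametric mutation (default 0.5).
#' @param param_scale base standard deviation of the Gaussian parametric
#'   mutation (default 0.5), multiplied by an adaptive temperature.
#' @param adapt_rate adaptation rate of the temperature under the
#'   1/5-success rule (default 0.1): if more than 1/5 of parametric-only
#'   offspring beat their parent the temperature grows by this factor,
#'   otherwise it shrinks.
#' @param elitism number of best individuals copied unchanged (default 1).
#' @param selection_pressure linear-ranking selection pressure in \[1, 2\]
#'   (default 1.5); 1 is uniform, 2 the strongest.
#' @param init_max_conn maximum connections per unit at initialisation
#'   (default 3; exponents start uniform in \[-2, 2\]).
#' @param seed integer RNG seed; recorded in all outputs.
#' @return A list of class `ea_config`.
#' @export
ea_config <- function(pop_size = 100, generations = 200, max_units = 3,
                      exponent_bound = 10,
                      p_add_unit = 0.25, p_del_unit = 0.25,
                      p_add_conn = 0.25, p_del_conn = 0.25,
                      p_structural = 0.5,
                      param_scale = 0.5, adapt_rate = 0.1,
                      elitism = 1, selection_pressure = 1.5,
                      init_max_conn = 3, seed = 1) {
  cfg <- list(pop_size = as.integer(pop_size),
              generations = as.integer(generations),
              max_units = as.integer(max_units),
              exponent_bound = exponent_bound,
              p_add_unit = p_add_unit, p_del_unit = p_del_unit,
              p_add_conn = p_add_conn, p_del_conn = p_del_conn,
              p_structural = p_structural,
              param_scale = param_scale, adapt_rate = adapt_rate,
              elitism = as.integer(elitism),
              selection_pressure = selection_pressure,
              init_max_conn = as.integer(init_max_conn),
              seed = as.integer(seed))
  probs <- unlist(cfg[c("p_add_unit", "p_del_unit", "p_add_conn",
                        "p_del_conn", "p_structural")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$pop_size < 1 || cfg$max_units < 1 || cfg$generations < 0)
    stop("counts must be positive (generations may be 0)")
  if (cfg$selection_pressure < 1 || cfg$selection_pressure > 2)
    stop("selection_pressure must lie in [1, 2]")
  if (cfg$param_scale < 0) stop("param_scale must be non-negative")
  structure(cfg, class = "ea_config")
}

#' Read an EA configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` (requires the `yaml` package)
#'   or `.json`.
#' @return An [ea_config()].
#' @export
read_ea_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  do.call(ea_config, vals[names(vals) %in% names(formals(ea_config))])
}

#' Fitness of a PUNN individual
#'
#' The bounded transform `1/(1 + CE)` of the mean cross-entropy CE of
#' `logistic(punn_logit(model, x))` against the binary outcome, so that
#' fitness lies in (0, 1\] and higher is better. An individual producing a
#' non-finite logit anywhere is penalised with fitness 0 rather than
#' aborting the run.
#'
#' @param model a [punn_model()].
#' @param dm a scaled [design_matrix()] with outcomes.
#' @return Fitness in \[0, 1\].
#' @export
fitness <- function(model, dm) {
  stopifnot(inherits(dm, "design_matrix"), !is.null(dm$y))
  eta <- tryCatch(punn_logit_rows(model, dm$X), error = function(e) NA_real_)
  fitness_from_eta(eta, dm$y)
}

fitness_from_eta <- function(eta, y) {
  if (anyNA(eta) || any(!is.finite(eta))) return(0)
  1 / (1 + cross_entropy(logistic(eta), y))
}

cross_entropy <- function(p, y, clip = 1e-12) {
  p <- pmin(pmax(p, clip), 1 - clip)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Parametric mutation of a PUNN
#'
#' Perturbs the exponents, output coefficients and bias with Gaussian
#' noise of base standard deviation `param_scale * temperature`. Each
#' parameter is perturbed independently with probability 1/2, and each
#' offspring draws a severity multiplier (mostly gentle, occasionally a
#' 10-fold kick) so the search can both fine-tune within a basin and jump
#' across exponent sign changes. The structure (unit count and supports)
#' is unchanged; exponents are clipped to the magnitude bound. Uses R's
#' global RNG stream.
#'
#' @param model a [punn_model()].
#' @param config an [ea_config()].
#' @param temperature adaptive scale multiplier (default 1).
#' @return The mutated `punn_model`.
#' @export
parametric_mutation <- function(model, config, temperature = 1) {
  severity <- sample(c(0.01, 0.1, 1, 10), 1, prob = c(0.1, 0.4, 0.4, 0.1))
  sd <- config$param_scale * temperature * severity
  b <- config$exponent_bound
  perturb <- function(v) {
    mask <- stats::runif(length(v)) < 0.5
    v + mask * stats::rnorm(length(v), 0, sd)
  }
  units <- lapply(model$units, function(u) {
    if (length(u$exponents))
      u$exponents <- pmin(pmax(perturb(u$exponents), -b), b)
    u
  })
  punn_model(bias = perturb(model$bias),
             coefficients = perturb(model$coefficients),
             units = units)
}

#' Structural mutation of a PUNN
#'
#' Applies exactly one architecture move chosen by the configured
#' probabilities, renormalised over the feasible moves:
#' \itemize{
#'   \item add unit — a fresh random unit (infeasible at `max_units`);
#'   \item delete unit — remove a random unit;
#'   \item add connection — give a random unit a new nonzero exponent on a
#'     covariate outside its support;
#'   \item delete connection — remove one exponent; a unit losing its last
#'     connection is removed entirely.
#' }
#' If no move is feasible the model is returned unchanged. Uses R's global
#' RNG stream.
#'
#' @param model a [punn_model()].
#' @param config an [ea_config()].
#' @param p number of covariates available (support universe).
#' @return The mutated `punn_model`.
#' @export
structural_mutation <- function(model, config, p) {
  k <- length(model$units)
  feasible <- c(
    add_unit = k < config$max_units,
    del_unit = k >= 1,
    add_conn = k >= 1 && any(vapply(model$units, function(u)
      length(u$exponents) < p, logical(1))),
    del_conn = k >= 1 && any(vapply(model$units, function(u)
      length(u$exponents) >= 1, logical(1)))
  )
  probs <- unlist(config[c("p_add_unit", "p_del_unit", "p_add_conn",
                           "p_del_conn")])
  probs[!feasible] <- 0
  if (sum(probs) == 0) return(model)
  move <- sample(names(feasible), 1, prob = probs)
  switch(move,
    add_unit = {
      model$units <- c(model$units, list(random_unit(p, config)))
      model$coefficients <- c(model$coefficients, stats::rnorm(1))
      model
    },
    del_unit = {
      drop <- sample.int(k, 1)
      model$units <- model$units[-drop]
      model$coefficients <- model$coefficients[-drop]
      model
    },
    add_conn = {
      open <- which(vapply(model$units, function(u)
        length(u$exponents) < p, logical(1)))
      j <- if (length(open) == 1L) open else sample(open, 1)
      u <- model$units[[j]]
      free <- setdiff(seq_len(p), pu_support(u))
      cov <- if (length(free) == 1L) free else sample(free, 1)
      w <- c(u$exponents, stats::setNames(stats::runif(1, -2, 2),
                                          paste0("x", cov)))
      model$units[[j]] <- product_unit(w, config$exponent_bound)
      model
    },
    del_conn = {
      have <- which(vapply(model$units, function(u)
        length(u$exponents) >= 1, logical(1)))
      j <- if (length(have) == 1L) have else sample(have, 1)
      u <- model$units[[j]]
      drop <- sample.int(length(u$exponents), 1)
      w <- u$exponents[-drop]
      if (length(w) == 0L) {
        model$units <- model$units[-j]
        model$coefficients <- model$coefficients[-j]
      } else {
        model$units[[j]] <- product_unit(w, config$exponent_bound)
      }
      model
    })
}

random_unit <- function(p, config) {
  n_conn <- sample.int(min(config$init_max_conn, p), 1)
  cov <- sample.int(p, n_conn)
  product_unit(stats::setNames(stats::runif(n_conn, -2, 2), paste0("x", cov)),
               config$exponent_bound)
}

random_model <- function(p, config) {
  n_units <- sample.int(config$max_units, 1)
  punn_model(bias = stats::rnorm(1),
             coefficients = stats::rnorm(n_units),
             units = replicate(n_units, random_unit(p, config),
                               simplify = FALSE))
}

#' Evolve a product-unit network on a scaled design
#'
#' Runs the mutation-only evolutionary programming loop: a random initial
#' population, linear rank-based parent selection, structural and
#' parametric mutation, and elitism. The parametric mutation scale adapts
#' by the 1/5-success rule. The whole run is reproducible from
#' `config$seed`.
#'
#' @param dm a scaled [design_matrix()] with both outcome classes present.
#' @param config an [ea_config()].
#' @param verbose print a summary line every 25 generations?
#' @return An `evolution_trace`: list with `trace` (data frame of
#'   per-generation best/mean fitness and best parameter count),
#'   `best_model` (best-ever [punn_model()]), `best_fitness`, and `config`.
#' @export
evolve <- function(dm, config = ea_config(), verbose = FALSE) {
  stopifnot(inherits(dm, "design_matrix"))
  if (is.null(dm$y) || nrow(dm$X) == 0L)
    stop("evolve needs a nonempty design with outcomes")
  if (length(unique(dm$y)) < 2L)
    stop("evolve needs both outcome classes present; got a single class")
  if (!dm$scaled && any(dm$X <= 0))
    stop("design must be scaled (strictly positive) for product units")

  set.seed(config$seed)
  X <- dm$X
  logX <- log(X)
  y <- dm$y
  p <- ncol(X)
  N <- config$pop_size

  eval_fit <- function(model)
    fitness_from_eta(tryCatch(punn_logit_rows(model, X, logX),
                              error = function(e) NA_real_), y)

  pop <- replicate(N, random_model(p, config), simplify = FALSE)
  fit <- vapply(pop, eval_fit, numeric(1))

  # linear ranking probabilities, worst rank 1 ... best rank N
  s <- config$selection_pressure
  rank_prob <- ((2 - s) + 2 * (seq_len(N) - 1) * (s - 1) / max(N - 1, 1)) / N

  best_i <- which.max(fit)
  best_model <- pop[[best_i]]
  best_fit <- fit[best_i]
  trace <- data.frame(generation = 0L, best_fitness = best_fit,
                      mean_fitness = mean(fit),
                      best_n_params = n_params(best_model))
  temperature <- 1

  for (gen in seq_len(config$generations)) {
    ord <- order(fit)                       # ascending: rank 1 = worst
    n_off <- N - config$elitism
    parents <- ord[sample.int(N, n_off, replace = TRUE, prob = rank_prob)]
    offspring <- vector("list", n_off)
    structural <- stats::runif(n_off) < config$p_structural
    for (j in seq_len(n_off)) {
      child <- pop[[parents[j]]]
      if (structural[j]) child <- structural_mutation(child, config, p)
      # anneal: fitter parents get gentler parametric perturbations
      anneal <- max(1 - fit[parents[j]], 0.1)
      offspring[[j]] <- parametric_mutation(child, config,
                                            temperature * anneal)
    }
    off_fit <- vapply(offspring, eval_fit, numeric(1))

    # 1/5-success rule on parametric-only offspring
    pure <- !structural
    if (any(pure)) {
      success <- mean(off_fit[pure] > fit[parents[pure]])
      temperature <- if (success > 0.2) temperature * (1 + config$adapt_rate)
                     else temperature / (1 + config$adapt_rate)
      temperature <- min(max(temperature, 1e-3), 1e3)
    }

    elite_idx <- ord[seq(N, by = -1, length.out = config$elitism)]
    pop <- c(pop[elite_idx], offspring)
    fit <- c(fit[elite_idx], off_fit)

    gi <- which.max(fit)
    if (fit[gi] > best_fit) {
      best_fit <- fit[gi]
      best_model <- pop[[gi]]
    }
    trace <- rbind(trace, data.frame(generation = gen,
                                     best_fitness = best_fit,
                                     mean_fitness = mean(fit),
                                     best_n_params = n_params(best_model)))
    if (verbose && gen %% 25 == 0)
      message(sprintf("gen %4d  best %.5f  mean %.5f  params %d  temp %.3g",
                      gen, best_fit, mean(fit), n_params(best_model),
                      temperature))
  }
  structure(list(trace = trace, best_model = best_model,
                 best_fitness = best_fit, config = config),
            class = "evolution_trace")
}

#' @export
print.evolution_trace <- function(x, ...) {
  cat(sprintf(
    "evolution_trace: %d generations, best fitness %.5f, best model %d params (seed %d)\n",
    max(x$trace$generation), x$best_fitness, n_params(x$best_model),
    x$config$seed))
  invisible(x)
}

#' Write a per-generation evolution trace as CSV
#'
#' @param trace an `evolution_trace` from [evolve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace$trace, path, row.names = FALSE)
  invisible(path)
}
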