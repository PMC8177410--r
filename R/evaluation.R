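#' Classification metrics for survival probabilities
#'
#' Computes the correct classification rate (CCR) at the 0.5 threshold,
#' the area under the ROC curve by the rank (Mann-Whitney) statistic with
#' midrank tie handling, the mean cross-entropy (probabilities clipped at
#' 1e-12), and the confusion counts.
#'
#' @param probabilities predicted survival probabilities in \[0, 1\].
#' @param outcomes binary outcomes (0/1), same length.
#' @return A `metric_set`: list with `ccr`, `auc` (NA with a warning when
#'   only one class is present), `cross_entropy`, `confusion` (named
#'   `tn`, `fp`, `fn`, `tp`) and `n`.
#' @export
evaluate <- function(probabilities, outcomes) {
  stopifnot(length(probabilities) == length(outcomes))
  y <- as.numeric(outcomes)
  if (!all(y %in% c(0, 1))) stop("outcomes must be binary 0/1")
  p <- as.numeric(probabilities)
  pred <- as.numeric(p >= 0.5)
  confusion <- c(tn = sum(pred == 0 & y == 0), fp = sum(pred == 1 & y == 0),
                 fn = sum(pred == 0 & y == 1), tp = sum(pred == 1 & y == 1))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  auc <- if (n1 == 0 || n0 == 0) {
    warning("AUC undefined with a single outcome class", call. = FALSE)
    NA_real_
  } else {
    r <- rank(p)                            # midranks for ties
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(ccr = mean(pred == y), auc = auc,
                 cross_entropy = cross_entropy(p, y),
                 confusion = confusion, n = length(y)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("metric_set (n = %d): CCR %.4f, AUC %s, cross-entropy %.4f\n",
              x$n, x$ccr,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc),
              x$cross_entropy))
  invisible(x)
}

#' Stratified train/test split
#'
#' Seeded shuffling within each outcome class, preserving the class ratio
#' to the nearest record.
#'
#' @param y binary outcome vector.
#' @param frac training fraction (default 0.75).
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, frac = 0.75, seed = 1) {
  set.seed(seed)
  train <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    k <- round(length(idx) * frac)
    train <- c(train, sample(idx, k))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

subset_design <- function(dm, idx) {
  design_matrix(dm$X[idx, , drop = FALSE], y = dm$y[idx],
                scaled = dm$scaled, scaling = dm$scaling)
}

#' Train an LRIPU classifier end to end
#'
#' Runs the evolutionary product-unit search on the training design
#' (optionally several independent runs), takes the product units of the
#' best network as frozen basis functions, and fits the hybrid logistic
#' regression. With `n_runs > 1` every run sees the full training data and
#' each run's basis is scored by stratified `cv_folds`-fold
#' cross-validated cross-entropy of the hybrid fit; the best basis is then
#' refit on the full training data. Cross-validation (rather than a single
#' held-back slice) keeps the evolutionary search from being starved of
#' training rows on cohort-sized data. The candidate set always includes
#' the empty basis, so the hybrid backs off to plain logistic regression
#' when no evolved unit earns its keep out of sample.
#'
#' @param dm a scaled [design_matrix()] with outcomes.
#' @param config an [ea_config()]; run `r` uses seed `config$seed + r - 1`.
#' @param n_runs number of independent EA runs (default 5).
#' @param ridge ridge penalty for the logistic fit.
#' @param cv_folds folds for basis selection (default 4).
#' @return List with `model`, `report`, `basis`, and `runs` (per-run
#'   cross-validated cross-entropy when `n_runs > 1`).
#' @export
train_lripu <- function(dm, config = ea_config(), n_runs = 5,
                        ridge = 1e-6, cv_folds = 4) {
  stopifnot(n_runs >= 1)
  if (n_runs == 1) {
    ev <- evolve(dm, config)
    fit <- fit_lripu(dm, basis = ev$best_model$units, ridge = ridge)
    return(list(model = fit$model, report = fit$report,
                basis = ev$best_model$units, runs = NULL))
  }
  # run 0 is the empty basis (plain LR), the back-off candidate
  runs <- data.frame(run = 0:n_runs, seed = NA_integer_, val_ce = NA_real_)
  bases <- c(list(list()), vector("list", n_runs))
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    ev <- evolve(dm, cfg)
    bases[[r + 1L]] <- ev$best_model$units
    runs$seed[r + 1L] <- cfg$seed
  }
  for (i in seq_along(bases))
    runs$val_ce[i] <- cv_cross_entropy(dm, bases[[i]], folds = cv_folds,
                                       ridge = ridge, seed = config$seed)
  best <- which.min(runs$val_ce)
  fit <- fit_lripu(dm, basis = bases[[best]], ridge = ridge)
  list(model = fit$model, report = fit$report, basis = bases[[best]],
       runs = runs)
}

# Stratified k-fold cross-validated cross-entropy of an LRIPU fit with a
# fixed product-unit basis.
cv_cross_entropy <- function(dm, basis, folds = 4, ridge = 1e-6, seed = 1) {
  set.seed(seed)
  n <- nrow(dm$X)
  fold_of <- integer(n)
  for (cls in unique(dm$y)) {
    w <- which(dm$y == cls)
    fold_of[w] <- sample(rep_len(seq_len(folds), length(w)))
  }
  total <- 0
  for (f in seq_len(folds)) {
    tr <- subset_design(dm, which(fold_of != f))
    te <- subset_design(dm, which(fold_of == f))
    fit <- fit_lripu(tr, basis = basis, ridge = ridge)
    p <- predict_lripu(fit$model,
                       design_matrix(te$X, scaled = TRUE,
                                     scaling = te$scaling))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    total <- total + sum(-(te$y * log(p) + (1 - te$y) * log(1 - p)))
  }
  total / n
}

#' Compare plain logistic regression with the hybrid LRIPU model
#'
#' Splits the data into stratified 75/25 train/test parts, fits plain
#' logistic regression (no product units) and the LRIPU pipeline on the
#' same training part, and reports both models' held-out metrics. Fully
#' seeded and reproducible.
#'
#' @param dm a scaled [design_matrix()] with outcomes.
#' @param split_seed seed for the stratified split.
#' @param config an [ea_config()] for the product-unit search.
#' @param n_runs independent EA runs inside [train_lripu()] (default 1).
#' @param ridge ridge penalty for both fits.
#' @return Data frame with one row per model (`LR`, `LRIPU`) and columns
#'   `ccr`, `auc`, `cross_entropy`, `n_test`, `n_params`.
#' @export
compare_models <- function(dm, split_seed = 1, config = ea_config(),
                           n_runs = 1, ridge = 1e-6) {
  split <- stratified_split(dm$y, frac = 0.75, seed = split_seed)
  dm_train <- subset_design(dm, split$train)
  dm_test <- subset_design(dm, split$test)

  lr <- fit_lripu(dm_train, basis = list(), ridge = ridge)
  hy <- train_lripu(dm_train, config = config, n_runs = n_runs,
                    ridge = ridge)

  row_of <- function(name, model) {
    pr <- predict_lripu(model, design_matrix(dm_test$X, scaled = TRUE,
                                             scaling = dm_test$scaling))
    m <- evaluate(pr, dm_test$y)
    data.frame(model = name, ccr = m$ccr, auc = m$auc,
               cross_entropy = m$cross_entropy, n_test = m$n,
               n_params = n_params(model), stringsAsFactors = FALSE)
  }
  out <- rbind(row_of("LR", lr$model), row_of("LRIPU", hy$model))
  attr(out, "split_seed") <- split_seed
  attr(out, "ea_seed") <- config$seed
  out
}

#' Replicated LR-versus-LRIPU comparison on synthetic cohorts
#'
#' For each seed, simulates a cohort from the spec (with that seed),
#' runs [compare_models()] on it (split and EA seeded by the same seed),
#' and collects the held-out metrics — the harness behind the model
#' comparison experiments.
#'
#' @param spec a [cohort_spec()]; its seed field is replaced per replicate.
#' @param seeds integer vector of replicate seeds.
#' @param config an [ea_config()] template (seed replaced per replicate).
#' @param n_runs EA runs per replicate (default 1).
#' @return Data frame with one row per (seed, model).
#' @export
comparison_experiment <- function(spec = cohort_spec(),
                                  seeds = 1:20,
                                  config = ea_config(),
                                  n_runs = 1) {
  out <- list()
  for (s in seeds) {
    spec_s <- spec
    spec_s$seed <- as.integer(s)
    cohort <- simulate_cohort(spec_s)
    cfg <- config
    cfg$seed <- as.integer(s)
    tab <- compare_models(cohort$design, split_seed = s, config = cfg,
                          n_runs = n_runs)
    tab$seed <- s
    out[[length(out) + 1L]] <- tab
  }
  do.call(rbind, out)
}

#' Linear-coefficient recovery from synthetic cohorts
#'
#' Draws replicate cohorts from a known ground-truth LRIPU model, refits
#' the model with the true product-unit basis (exponents frozen), and
#' checks per replicate whether each linear coefficient lands within
#' `se_mult` estimated standard errors of its true value. Standard errors
#' come from the inverse penalized Fisher information, so contrasts made
#' unidentifiable by the one-of-k dummy coding carry appropriately large
#' uncertainty.
#'
#' @param spec a [cohort_spec()] (default: n = 5000 records of the default
#'   generating model).
#' @param replicates number of seeded replicates (default 100).
#' @param base_seed replicate `i` uses seed `base_seed + i - 1`.
#' @param se_mult the coverage multiple (default 3).
#' @return List with `per_coef` (named per-coefficient success rates
#'   across replicates), `min_rate`, `overall_rate`, and `details`
#'   (logical replicate-by-coefficient matrix).
#' @export
recovery_experiment <- function(spec = cohort_spec(n = 5000),
                                replicates = 100, base_seed = 1,
                                se_mult = 3) {
  truth <- spec$truth
  basis <- lapply(truth$pu_terms, `[[`, "unit")
  p <- length(truth$beta)
  hits <- matrix(NA, replicates, p,
                 dimnames = list(NULL, names(truth$beta)))
  for (i in seq_len(replicates)) {
    spec_i <- spec
    spec_i$seed <- as.integer(base_seed + i - 1)
    cohort <- simulate_cohort(spec_i)
    fit <- fit_lripu(cohort$design, basis = basis)
    est <- fit$model$beta
    se <- fit$report$se[names(truth$beta)]
    hits[i, ] <- abs(est - truth$beta) <= se_mult * se
  }
  per_coef <- colMeans(hits)
  list(per_coef = per_coef, min_rate = min(per_coef),
       overall_rate = mean(hits), details = hits)
}

#' Functional recovery of a known product unit by the evolutionary search
#'
#' Generates train/test data whose log-odds come from a single known
#' product unit (`eta = bias + c * x1^2 / x2` by default, covariates
#' uniform on \[1, 2\]), runs the evolutionary search on the training
#' part, and compares the best network's test cross-entropy with the
#' generator's own (Bayes) test cross-entropy.
#'
#' @param seed integer seed for data generation (the EA uses
#'   `config$seed`).
#' @param n_train,n_test sample sizes (defaults 1000 / 5000).
#' @param n_covariates number of covariates, the first two active
#'   (default 4).
#' @param truth generating [punn_model()]; default bias -4, coefficient
#'   2.5 on the unit `x1^2 * x2^-1`.
#' @param config an [ea_config()] (default: population 200, 300
#'   generations).
#' @return List with `model_ce`, `bayes_ce`, `ce_gap`
#'   (`model_ce - bayes_ce`), `trace` (the [evolve()] result) and
#'   `best_model`.
#' @export
ea_recovery_experiment <- function(seed = 1, n_train = 1000, n_test = 5000,
                                   n_covariates = 4,
                                   truth = punn_model(
                                     bias = -4, coefficients = 2.5,
                                     units = list(product_unit(
                                       c(x1 = 2, x2 = -1)))),
                                   config = ea_config(pop_size = 200,
                                                      generations = 300,
                                                      seed = seed)) {
  set.seed(seed)
  p <- n_covariates
  scaling <- list(min = stats::setNames(rep(1, p), paste0("x", 1:p)),
                  max = stats::setNames(rep(2, p), paste0("x", 1:p)))
  draw <- function(n) {
    X <- matrix(stats::runif(n * p, 1, 2), n,
                dimnames = list(NULL, paste0("x", 1:p)))
    prob <- logistic(punn_logit_rows(truth, X))
    design_matrix(X, y = stats::rbinom(n, 1, prob), scaled = TRUE,
                  scaling = scaling)
  }
  dm_train <- draw(n_train)
  dm_test <- draw(n_test)

  ev <- evolve(dm_train, config)
  eta_test <- punn_logit_rows(ev$best_model, dm_test$X)
  model_ce <- cross_entropy(logistic(eta_test), dm_test$y)
  bayes_ce <- cross_entropy(logistic(punn_logit_rows(truth, dm_test$X)),
                            dm_test$y)
  list(model_ce = model_ce, bayes_ce = bayes_ce,
       ce_gap = model_ce - bayes_ce, trace = ev,
       best_model = ev$best_model)
}
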