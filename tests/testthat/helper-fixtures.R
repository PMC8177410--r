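# Shared builders for small in-code fixtures.

# A schema-valid raw record with every mandatory field populated.
make_record <- function(...) {
  rec <- list(
    sex_rec = 1, age_rec = 52, desease2 = "COPD", pre_tx = "ambulatory",
    sex_donor = 0, age_donor = 45, death_d = "TBI", ti_in_do = 3,
    io2_donor = 450, type_tx = "bilateral", cold_isch = "Medium",
    bypass = 0, Tailor = 0, po2_pre = 62, pco2_pre = 44, fvc_pre = 58,
    fvc_prp = 72, fev1_pre = 38, fev1_prp = 66)
  utils::modifyList(rec, list(...))
}

# A scaled design with iid uniform [1, 2] covariates and outcomes drawn
# from a supplied logit function of the covariate matrix.
make_uniform_design <- function(n, p, logit_fn = function(X) rep(0, n),
                                seed = 1) {
  set.seed(seed)
  X <- matrix(stats::runif(n * p, 1, 2), n,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  prob <- lripu::logistic(logit_fn(X))
  design_matrix(X, y = stats::rbinom(n, 1, prob), scaled = TRUE,
                scaling = list(min = stats::setNames(rep(1, p), colnames(X)),
                               max = stats::setNames(rep(2, p), colnames(X))))
}

table2_path <- function() {
  system.file("extdata", "table2_model.txt", package = "lripu")
}
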