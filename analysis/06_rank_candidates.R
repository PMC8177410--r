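#!/usr/bin/env Rscript
# Donor-recipient matching demo: rank a waiting list of candidate
# recipients for one donor by predicted six-month graft survival under
# the fitted hybrid model from step 03.

suppressPackageStartupMessages(library(lripu))
dir.create("results", showWarnings = FALSE)

model <- lripu_from_json("results/lripu_model.json")

donor <- list(sex_donor = 1, age_donor = 38, death_d = "TBI",
              ti_in_do = 2, io2_donor = 460)

base <- list(sex_rec = 1, age_rec = 50, desease2 = "COPD",
             pre_tx = "ambulatory", type_tx = "bilateral",
             cold_isch = "Medium", bypass = 0, Tailor = 0,
             po2_pre = 64, pco2_pre = 45, fvc_pre = 55, fvc_prp = 75,
             fev1_pre = 35, fev1_prp = 70)
candidates <- list(
  young_good_fvc = modifyList(base, list(age_rec = 32, fvc_pre = 85,
                                         fev1_pre = 55)),
  icu_low_fvc    = modifyList(base, list(pre_tx = "ICU", fvc_pre = 28,
                                         fev1_pre = 18)),
  elderly_copd   = modifyList(base, list(age_rec = 66)),
  cf_young       = modifyList(base, list(age_rec = 24, desease2 = "CF",
                                         fvc_pre = 48)),
  baseline       = base)

ranking <- rank_recipients(model, donor, candidates)
print(ranking)
write.csv(ranking, "results/ranking.csv", row.names = FALSE)
message("wrote results/ranking.csv")
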