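#!/usr/bin/env Rscript
# Link the LV1 brainscores to symptoms: simulate the symptom tables from
# the neutral-faces brainscore (planted indirect path), then run the
# brainscore-anhedonia correlation, the covariate-adjusted regression
# (other MASQ scales + early/recent stress), and the sex-stratified
# bootstrap mediation of T-PRS -> brainscore -> anhedonia.

suppressPackageStartupMessages(library(tprspls))

tprs <- utils::read.table("results/scores/tprs.tsv", header = TRUE, sep = "\t")
score <- stats::setNames(tprs$tprs, tprs$subject_id)
bs <- utils::read.table("results/pls/tprs/brainscores.tsv", header = TRUE,
                        sep = "\t", check.names = FALSE)
grp <- utils::read.table("results/data/activations/groups.tsv", header = TRUE,
                         sep = "\t")
sex <- stats::setNames(grp$group, grp$subject_id)[bs$subject_id]
bsc <- stats::setNames(bs$neutral_faces, bs$subject_id)

cfg <- simulation_config(seed = 20260920L)
sym <- simulate_symptoms(bsc, cfg, group = sex)
dir.create("results/symptoms", showWarnings = FALSE, recursive = TRUE)
utils::write.table(sym, "results/data/symptoms.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

fem <- sex == "female"
assoc <- brainscore_symptom_corr(bsc[fem], sym$anhedonia[fem])
cat(sprintf("women, neutral faces: brainscore-anhedonia R^2 = %.3f (r = %.3f, p = %.2g)\n",
            assoc$r_squared, assoc$r, assoc$p))

adj <- adjusted_regression(
  sym$anhedonia[fem], bsc[fem],
  sym[fem, c("anxious_arousal", "general_distress_depression",
             "general_distress_anxiety", "ctq_total", "life_events_total")])
cat(sprintf("adjusted for the other MASQ scales and stress: beta = %.3f (p = %.2g)\n",
            adj$beta, adj$p))

med <- mediate(score, bsc, sym$anhedonia, strata = sex,
               n_boot = 5000L, seed = 77L)
print(med)

rows <- do.call(rbind, lapply(names(med$strata), function(lab) {
  s <- med$strata[[lab]]
  data.frame(stratum = lab, a = s$a, b = s$b, ab = s$ab, se_ab = s$se_ab,
             ci_lower = s$ci_ab[1], ci_upper = s$ci_ab[2], n = s$n)
}))
utils::write.table(rows, "results/symptoms/mediation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(measure = c("r", "r_squared", "p", "adjusted_beta", "adjusted_p"),
             value = c(assoc$r, assoc$r_squared, assoc$p, adj$beta, adj$p)),
  "results/symptoms/association.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("wrote results/symptoms/{mediation,association}.tsv\n")
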