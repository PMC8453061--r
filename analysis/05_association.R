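#!/usr/bin/env Rscript
# Stage 5: survival association suite.
#
# Crude Cox models of 28-day survival on the standardized wb-mtDNA
# estimate in the whole cohort and the ARDS / non-ARDS strata, the
# adjusted-model ladder within ARDS (age, SAPS, APACHE II, organ
# dysfunction flags, lengths of stay, and the multivariate models),
# sensitivity fits with sex, comorbidities and genetic PCs, plus
# Kaplan-Meier / log-rank on the median split and ROC with the DeLong
# comparison of wb-mtDNA against wb-mtDNA + APACHE II.

suppressMessages(library(mitosurv))
inp <- "results/analysis/inputs"
out <- "results/analysis"

est <- read_tsv(file.path(out, "estimates.tsv"))
pheno <- read_tsv(file.path(inp, "phenotypes.tsv"))
pcs <- read_tsv(file.path(out, "pc_scores.tsv"))
pheno <- merge(pheno, pcs, by = "sample_id", all.x = TRUE)

suite <- run_association_suite(est, pheno)
write_tsv(suite, file.path(out, "association.tsv"))
crude <- suite[suite$model == "crude",
               c("model", "stratum", "n", "events", "hr", "lo95", "hi95",
                 "p", "proportionality_held")]
print(crude, row.names = FALSE, digits = 3)

merged <- merge(est, pheno, by = "sample_id")
ards <- merged[merged$ards == 1, ]
km <- km_logrank(ards, median_split(ards$standardized_estimate))
write_tsv(km$curves, file.path(out, "km_curves.tsv"))
cat(sprintf("\nKM median split (ARDS): log-rank chi-square %.2f, p = %.3g\n",
            km$chisq, km$p))

roc_mt <- roc_delong(ards$standardized_estimate, ards$event)
cc <- !is.na(ards$apache2)
lp <- glm(event ~ standardized_estimate + apache2, family = binomial(),
          data = ards[cc, ])
roc_both <- roc_delong(fitted(lp), ards$event[cc])
cmp <- compare_rocs(ards$standardized_estimate[cc], fitted(lp),
                    ards$event[cc])
cat(sprintf("AUC wb-mtDNA %.3f (%.3f-%.3f); + APACHE II %.3f; DeLong p = %.3f\n",
            roc_mt$auc, roc_mt$ci[1], roc_mt$ci[2], roc_both$auc, cmp$p))
write_tsv(data.frame(score = c("wb_mtdna", "wb_mtdna_plus_apache2"),
                     auc = c(roc_mt$auc, roc_both$auc),
                     lo95 = c(roc_mt$ci[1], roc_both$ci[1]),
                     hi95 = c(roc_mt$ci[2], roc_both$ci[2])),
          file.path(out, "roc_summary.tsv"))
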