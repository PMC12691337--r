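#!/usr/bin/env Rscript
# Stage 3: model adequacy and multi-model comparison.
#
# Builds the adequacy report for the grand average curve (AIC, R2 of the
# predicted-on-observed regression, Lin's CCC, MSPE with its bias
# decomposition), selects the lowest-AIC model, and quantifies the margin
# by AIC evidence ratios and pairwise paired-MSPE accuracy tests. Also
# reports the evidence ratios implied by the published AICs of the source
# experiment for context.

suppressPackageStartupMessages(library(rumengas))

raw <- read_gas_table("results/gas_raw.csv")
curves <- blank_correct(raw)
avg <- average_curve(curves, treatment_id = "grand_average")

models <- c("gompertz", "orskov_mcdonald", "brody", "richards", "dual_pool")
fits <- lapply(models, fit_gas_model, curve = avg)
ranking <- rank_models(fits, avg)

write.csv(ranking$report, "results/model_evaluation.csv", row.names = FALSE)
write.csv(ranking$pmspe_pvalues, "results/pmspe_pvalues.csv")

cat("best model by AIC:", ranking$best_model, "\n\n")
print(ranking$report[, c("model_id", "aic", "r2", "ccc", "mspe",
                         "evidence_ratio")], row.names = FALSE, digits = 4)

cat("\npairwise paired-MSPE p-values:\n")
print(apply(ranking$pmspe_pvalues, c(1, 2), format_pvalue), quote = FALSE)

ref <- reference_model_evaluation()
er <- evidence_ratio(ref$aic, min(ref$aic))
cat("\nevidence ratios implied by the published AICs:\n")
print(data.frame(model_id = ref$model_id, published_aic = ref$aic,
                 evidence_ratio = round(er, 1)), row.names = FALSE)
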