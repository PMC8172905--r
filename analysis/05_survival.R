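#!/usr/bin/env Rscript
# Survival stratification by RSI: Kaplan-Meier curves per stratum,
# log-rank test, univariate Cox hazard ratio, and the maximally selected
# survival cutpoint compared with the fixed 0.46 stratification.

suppressPackageStartupMessages(library(radsens))

survival_tab <- utils::read.delim("results/cohort/survival.tsv")
scores <- utils::read.delim("results/rsi_scores.tsv")
sv <- merge(survival_tab, scores, by = "sample_id", sort = FALSE)
sv$group <- sv$category

km <- lapply(split(sv, sv$group), km_fit)
for (g in names(km)) {
  med <- km[[g]]$time[which(km[[g]]$surv <= 0.5)[1]]
  cat(sprintf("%s: n = %d, median survival %.2f\n",
              g, sum(sv$group == g), med))
  utils::write.table(km[[g]], sprintf("results/km_%s.tsv",
                                      gsub("-", "_", tolower(g))),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

lr <- logrank_test(sv)
cat(sprintf("log-rank: chi-square %.2f, p = %.3g\n", lr$chisq, lr$p))

cx <- cox_univariate(sv, as.integer(sv$group == "RSI-High"))
cat(sprintf("Cox HR (RSI-High vs RSI-Low): %.3f (95%% CI %.3f-%.3f, p = %.3g)\n",
            cx$hr, cx$ci[1], cx$ci[2], cx$p))

cut <- surv_cutpoint(sv, sv$rsi)
cat(sprintf("optimal survival cutpoint: %.4f (|log-rank z| = %.2f, %d/%d split)\n",
            cut$value, cut$statistic, cut$n_low, cut$n_high))
cat("note: the cutpoint is selected and tested on the same cohort, so its\n")
cat("p-value is optimistic; validate on an independent replicate.\n")
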